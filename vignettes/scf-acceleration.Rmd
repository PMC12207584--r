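---
title: "Convergence acceleration for multi-species SCF: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Convergence acceleration for multi-species SCF: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scfaccel)
```

## The model and its assumptions

A self-consistent-field problem is specified here by (i) a list of
symmetry blocks, each belonging to a particle type and carrying a
dimension and a maximal per-orbital occupation $f^{\max}$; (ii) the
particle count of each type; and (iii) a Fock evaluator
$(C, f) \mapsto (E, \{F_b\})$ returning the total energy and one
Hermitian Fock matrix per block *in an orthonormal orbital basis*.  The
solver assumes nothing else about the physics: spin-restricted electrons
($f^{\max}=2$), spin-orbitals ($f^{\max}=1$), high-spin quantum protons,
or any mixture thereof are all just blocks.  Working exclusively in the
orthonormal basis is not a restriction — acceleration has to happen there
anyway — and callers with an overlap matrix $S$ reduce
$FC = SCE$ beforehand with one of the orthonormalizers
(`symmetric_x()`, `canonical_x()`, `cholesky_pivot_select()`).

The central assumptions the accelerators rely on:

* the evaluator's $F$ is the exact derivative of $E$ with respect to the
  density $P = C\,\mathrm{diag}(f)\,C^\dagger$ (this is what makes
  $e = [F, P]$ an orbital gradient and the EDIIS model meaningful);
* $E$ is bounded below on the feasible density set;
* the ground state is an **Aufbau state**: occupations fill orbitals in
  increasing energy order up to $f^{\max}$, with a positive gap at the
  Fermi level.  Optimizing fractional occupations at a degenerate Fermi
  level is explicitly out of scope.

## The iteration

Every Fock evaluation produces an *iteration entry* (states, $F$, $P$,
$[F,P]$, $E$) pushed onto a history stack of capacity $N = 10$ whose head
is the lowest-energy entry ever seen — that entry is never evicted, so
the solver cannot converge onto something worse than it has already
visited.  On overflow the oldest non-minimal entry is dropped.  Before
each extrapolation the history is cleaned: entries whose density distance
to the best one, $\|P_i - P_0\|_F$ accumulated over all blocks, exceeds
$\min_j \|P_j - P_0\|_F / \delta^{\mathrm{history}}$ are discarded
($\delta^{\mathrm{history}} = 10^{-4}$).  The reference entry is excluded
from that minimum, since its own distance is zero and would otherwise
force removal of everything else.

The next Fock matrix is $\bar F = \sum_i c_i F_i$ with weights chosen by
regime:

* **DIIS** ($\varepsilon \le \varepsilon_1 = 10^{-4}$): minimize
  $c^T B c$ with $\sum c_i = 1$, $B_{ij} = \mathrm{Re}\sum_b
  \mathrm{Tr}(e_i^\dagger e_j)$.  The bordered system is solved after
  (1) screening out stale entries with
  $\delta^{\mathrm{DIIS}} B_{ii} > \min_j B_{jj}$
  ($\delta^{\mathrm{DIIS}} = 10^{-4}$; the most recent entry is always
  kept — extrapolation must contain the newest Fock matrix to make
  progress), (2) normalizing by the smallest kept diagonal (a
  `"newest"`-diagonal option is available; the choice only affects
  conditioning, not the solution), and (3) damping the diagonal by
  $1 + d$, $d = 0.02$.
* **EDIIS/ADIIS** ($\varepsilon \ge \varepsilon_2 = 10^{-1}$): both proxy
  energies are quadratic forms on the unit simplex; both are minimized
  and the *minimal error sampling* rule picks the candidate whose mixed
  density changes the current density least (ties to ADIIS).
* **Hybrid** (in between): linear blending
  $c = f_{\mathrm{int}} c^{\mathrm{DIIS}} +
  (1-f_{\mathrm{int}}) c^{\mathrm{EDIIS/ADIIS}}$ with
  $f_{\mathrm{int}} = (\varepsilon_2-\varepsilon)/
  (\varepsilon_2-\varepsilon_1)$.  (The typeset middle branch of the
  source formula evaluates to 1 at $\varepsilon_2$ and 0 at
  $\varepsilon_1$, contradicting its own boundary branches; we implement
  the continuous interpolation they imply.)

When the max-norm orbital gradient is huge
($\|e\|_\infty \ge 1$, an intensive criterion) or the accelerated
iterations stagnate ($\lceil N/2 \rceil$ consecutive accelerated
iterations without lowering the best energy), the **optimal damping
algorithm** takes over: mix the best density $P_0$ with the Aufbau
density $P_1$ of the orbitals diagonalizing $F(P_0)$; if the candidate
did not already descend, fit a cubic from $E(0), E'(0), E(1), E'(1)$
(with exact gradients $E'(\lambda)=\mathrm{Tr}\,F(P(\lambda))(P_1-P_0)$),
step to its interior minimum, take natural orbitals of the mixed density,
and evaluate once.  Several particle types get a per-type mixing
direction $s_\sigma = \max(0, -\partial E/\partial\lambda_\sigma)$,
scaled so the largest component steps to the boundary of the unit box.
If the cubic offers no interior minimum the mixing factor is bisected (at
most 5 times), keeping the best point found.  A stagnation burst hands
$\lceil N/2 \rceil$ consecutive *Fock evaluations* (not accepted steps)
to ODA.

Convergence is declared when the configured error norm (rms by default;
max-norm available) of $[F,P]$ falls below $10^{-7}$.  The solver returns
the lowest-energy entry, and the per-iteration trace records energy, both
error norms, the strategy label, the interpolation factor and the weights.

## The simplex minimizer

Both EDIIS and ADIIS reduce to minimizing
$f(x)=\tfrac12 x^TAx + b\cdot x$ on the unit simplex.  The dimension is
at most the history length, so robustness matters far more than speed.
We use exact coordinate-style line searches: toward each vertex
($x \leftarrow (1-\lambda)x + \lambda e_i$, $\lambda \in (0,1]$) and
along each edge-transfer direction $e_i - e_j$ ($\lambda \in (0, x_j]$),
with the closed-form minimizer of the one-dimensional quadratic
restriction, taking the full step whenever the restriction predicts
descent at the boundary ($g + h\lambda_{\max}/2 < 0$) even when the
slope $g$ vanishes — this escapes interior saddle points of indefinite
objectives, which vertex moves alone cannot leave.  The unconstrained
square-ratio parametrization common in production codes is avoided on
purpose: it destroys convexity and is scale-invariant along rays, which
stalls line searches.

Descents run from every start point — vertices, centroid, offset points
$(3, 1, \dots, 1)/(m+2)$, edge midpoints, and (for $m \le 6$) a coarse
step-$1/6$ simplex grid — and the best result is kept.  For convex
objectives any single start suffices; the multi-start matters only for
indefinite quadratic forms, where a dense-grid fuzz (step $1/200$,
criterion 2 of the acceptance suite) found single-start pairwise search
landing in wrong basins.  Tolerance: relative objective change
$< 10^{-12}$ per sweep, at most $10m$ sweeps.

One substantive correction to the source material: for a quadratic
(Hartree–Fock-form) energy, the EDIIS model equals the true energy of the
mixed density only with the coefficient $-\tfrac12\sum_{i<j} c_i c_j
X_{ij}$ (equivalently $-\tfrac14 c^T X c$), with
$X_{ij} = \langle F_i - F_j | P_i - P_j\rangle$ accumulated over particle
types.  The typeset $-\tfrac12 c\cdot X\cdot c$ over all pairs double
counts; the exactness identity (verified to $10^{-9}$ relative in the
acceptance suite) fixes the coefficient unambiguously.  ADIIS uses the
reference entry of the most recent Fock evaluation (configurable to the
best entry); for quadratic energies its objective is an affine transform
of the true energy ($E_n + 2[E - E_n]$), so the two argmins coincide —
that equivalence is an acceptance criterion, not an assumption.

## The synthetic problem generator

`make_quadratic_problem()` and `make_two_species_problem()` build energy
functionals with exactly the mathematical structure the optimizer
assumes, and nothing more:

$$E(P) = \sum_b \mathrm{Tr}(H_b P_b) + \tfrac12\sum_k v_k\,
\mathrm{Tr}(A^{(k)}_i P_i)\,\mathrm{Tr}(A^{(k)}_j P_j),$$

with Hermitian $A_k$ of unit Frobenius norm.  The separable form
guarantees by construction the adjoint symmetry
$\langle A, G_{tu}[B]\rangle = \langle G_{ut}[A], B\rangle$ and, for
$v_k > 0$ within a type, positive semidefiniteness of the two-body
superoperator; the exact-derivative property of the Fock matrices is
checked by central finite differences ($\le 10^{-8}$) in the tests.
Defaults: core spectra are random with level spacings
$\mathcal{U}(0.2, 1)$ and an extra unit gap after the intended
highest-occupied level; interaction weights are
$\texttt{strength}\cdot\mathcal{U}(0.3, 1)$ with
$\texttt{strength} = 1$, i.e. two-body terms comparable to but not
dominating the level structure — the regime of a well-behaved closed-shell
system; type 1 has $f^{\max}=2$ (restricted electrons), type 2
$f^{\max}=1$ (high-spin protons); inter-type couplings are attractive by
default with each weight capped below the smallest intra-type weight so
the coupled functional stays bounded (additionally verified by sampling
200 random feasible densities at construction).

Two realities of this model deserve emphasis.  First, because the
intra-type quadratic form is positive semidefinite, the energy is
*convex* in each density — unlike real Hartree–Fock exchange.  A
sufficiently strong convex interaction can close the Fermi gap, making
the true minimizer fractional in its occupations; Aufbau-based SCF then
oscillates forever, through no fault of the accelerators (this is the
degenerate-Fermi-level regime that is explicitly out of scope).  The
generators therefore enforce well-posedness constructively: after
construction, a projected-gradient descent on the *relaxed* (convex)
feasible set verifies that the relaxed minimizer is reproduced by Aufbau
filling of its own Fock matrix with a Fermi gap $\ge 10^{-2}$; failing
instances are regenerated from a deterministically derived seed.
`ensure_aufbau = FALSE` disables the check, and is used to build the
deliberately pathological hard-start instances (strength 8, core guess)
on which the optimal-damping criterion is exercised.  Second, the model
has no one-particle/two-particle cost asymmetry, no integral screening
noise, and no basis-set linear dependence; a green convergence test
establishes the correctness of the optimization logic, not performance
claims on molecular systems.

`brute_force_reference()` is the independent oracle: for real
single-block dimension-2 problems with one fully occupied orbital the
occupied subspace is a single rotation angle, scanned at $10^{-4}$ rad
and refined; everything else runs multi-start projected-gradient descent
**on the idempotent-density manifold** — the retraction eigendecomposes
the stepped matrix and refills the natural occupations by greedy Aufbau
(the extreme points of the capped trace simplex), which is exactly the
set the Aufbau SCF iterates on.  (Projecting onto the relaxed convex set
instead can dip below the best idempotent density whenever the gap
closes; we observed a $6.6\times10^{-8}$ discrepancy on a dimension-2
fixture before switching.)

## Numerical choices

* Hermiticity/unitarity checks: warn above $10^{-10}$ relative deviation,
  error above $10^{-6}$.
* Aufbau ties: orbital energies degenerate to within $10^{-12}$ are
  ordered by (block index, orbital index) — determinism over physics,
  since degenerate-occupation optimization is out of scope.  A per-block
  `skip_lowest` parameter exists for Dirac-sea-style filling (default 0,
  not exercised).
* Block accumulation: all inner products and Frobenius norms sum squared
  per-block quantities over every block and particle type, making the
  partitioning equivalent to one big block-diagonal matrix; the rms error
  divides by the *total* element count so duplicating a block does not
  change the norm.
* Complex arithmetic: $B_{ij}$, the EDIIS/ADIIS inner products, and the
  mixing gradients take the real part of the trace inner product (the
  imaginary part is antisymmetric and carries no information for the
  symmetric solves).
* Natural-orbital states from mixed densities: occupations clamped to
  $[0, f^{\max}]$ and rescaled to conserve the trace; orbital energies
  are taken as expectation values $c^\dagger F_0 c$ re-sorted ascending,
  keeping downstream Aufbau bookkeeping consistent.
* Degenerate cubic fits fall through to the quadratic/linear stationary
  point, or to bisection when no interior minimum exists.
* Singular DIIS systems (after damping) fall back to weight 1 on the most
  recent entry with a warning.
* History cleanup runs before every extrapolation (the source leaves the
  schedule open; per-iteration cleanup is the safe default and is
  configurable via `cleanup_every`).
* MESA measures density change against the latest iterate (configurable
  to the best entry); ODA's consecutive-evaluation cap per activation is
  50 (the source leaves it uncapped).
* The stepwise driver counts a macroiteration as *effective* when any
  sub-solve needed more than one Fock build; it stops when the
  macro-energy change drops below $10^{-7}$ or a macroiteration was
  entirely ineffective, then finishes with the simultaneous driver.

## Configuration surface

All tunables live in `scf_config()`: history capacity (10; 20 is a common
choice for harder coupled problems and is what the source experiments
used), DIIS damping 0.02, both $\delta$ parameters $10^{-4}$, hybrid
thresholds $\varepsilon_1 = 10^{-4}$ / $\varepsilon_2 = 10^{-1}$, ODA
trigger 1.0, convergence threshold $10^{-7}$ on the rms error, stepwise
macro threshold $10^{-7}$, and the strategy ladder
`roothaan < diis < hybrid < full`.

## Limitations

* No level shifting, no second-order (trust-region/exact-Hessian) orbital
  rotations, no k-point-weighted extrapolation, no fractional-occupation
  optimization at degenerate Fermi levels, no out-of-core histories.
* The brute-force oracle is itself a local-search method with restarts;
  on multi-species problems with strong attractive coupling it certifies
  only the best minimum found by either route.
* The synthetic functionals are quadratic; behavior specific to
  non-quadratic functionals (where EDIIS and ADIIS genuinely differ) is
  represented in the code paths but not distinguished by the oracles.
* History snapshots serialize to JSON rather than HDF5 (no HDF5 R binding
  is assumed); the layout is documented in `R/serialize.R` and
  round-trips at full double precision.
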