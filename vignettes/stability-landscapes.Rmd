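---
title: "Stability landscapes by routing functions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability landscapes by routing functions: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

An ecological model $\dot x = f(x; a)$ with polynomial or rational rates,
state $x \in \mathbb{R}_{\ge 0}^n$ and positive parameters
$a \in \mathbb{R}_{>0}^k$ has, for each $a$, some number of real positive
steady states, of which some are locally asymptotically stable (all
Jacobian eigenvalues in the open left half-plane). The *stability
landscape* is the partition of the positive parameter orthant into
connected regions on which the number and type of stable steady states are
constant. `stabscape` computes this landscape in three stages: boundary
ideals, routing-function connectivity, and per-region classification.

## Stage 1: the total boundary

The counts can change only where one of three degeneracies occurs at a
steady state:

* **singular boundary** — the Jacobian determinant vanishes (the classical
  discriminant locus: real solutions appear or disappear);
* **Routh–Hurwitz boundary** — some Routh polynomial vanishes (an
  eigenvalue's real part crosses zero: a stability verdict flips);
* **coordinate boundary** — a steady-state coordinate vanishes
  (feasibility changes).

Each is the zero set of an elimination ideal: append the degeneracy
polynomial to the equilibrium ideal $\langle f \rangle$ and eliminate the
state variables. Because the equilibrium ideal of a per-capita-structured
ecological model is reducible, the package first decomposes it by
recursive factor splitting run to a fixed point (each generator that
factors modulo the others splits the system into branches; inconsistent
branches are pruned, and a branch whose solution set is contained in
another's is removed). For the shipped models this reproduces the
primary decomposition into equilibrium-type families ($E_0$, $E_x$,
$E_{xy}$, $E_{xz}$, $E_{co}$, …), and the per-component eliminations are
far cheaper than one monolithic computation. Eliminations are processed
one Routh polynomial at a time and unioned.

Routh polynomials are the leading principal minors
$\Delta_1, \dots, \Delta_{n-1}$ of the Hurwitz matrix
$H_{ij} = c_{n-2i+j}$ together with $c_0$ (via
$\Delta_n = c_0\,\Delta_{n-1}$), where $c_i$ are the monic
characteristic-polynomial coefficients. For $n = 2$ this is $(c_1, c_0)$,
for $n = 3$ it is $(c_2,\; c_2 c_1 - c_3 c_0,\; c_0)$; the implementation
covers $n \le 4$. The singular boundary needs no separate elimination
inside `total_boundary()` because $c_0 = (-1)^n \det J$ is itself a Routh
polynomial; `singular_boundary()` remains available on its own.

The union of all irreducible factors over all components and boundary
types, deduplicated up to unit multiples (content-normalized integer
coefficients, positive leading coefficient), plus — in positive-orthant
mode — the parameter coordinate hyperplanes $a_i = 0$, is the total
boundary: a hypersurface arrangement $\mathcal{B} = \bigcup_i \{g_i = 0\}$.

**Elimination strategies.** The canonical path is a block-order (lex)
Gröbner basis with state variables preceding parameters, delegated to the
sympy computer-algebra system through a subprocess. For two-parameter
slice systems whose components triangularize (generators linear in one
variable with a coefficient free of the remaining variables), a much
faster strategy back-substitutes those generators and finishes with a
single univariate resultant. The resultant can pick up extra
leading-coefficient factors; these only subdivide regions further and
never remove a true wall, so slices use the triangular strategy while all
printed-factor identities are computed with Gröbner bases.

## Stage 2: routing functions and connectivity

For the arrangement complement the package builds the routing function

$$ r_c(a) \;=\; \frac{g_1(a)\cdots g_m(a)\,\prod_{i=1}^k a_i}
  {\bigl(1 + \sum_{i=1}^k (a_i - c_i)^2\bigr)^{D}} , $$

with $2D > k + \sum_i \deg g_i$ (the smallest such integer by default), so
that $r_c$ is bounded, vanishes exactly on the arrangement and the
coordinate hyperplanes, and decays at infinity. The coordinate product
confines all gradient flow to the open positive orthant. For a generic
center $c$ the critical points ("routing points") are finite in number and
nondegenerate, every connected region contains at least one, and
gradient flow along unstable directions connects the routing points of a
region: connected components of the resulting *routing graph* are in
bijection with the regions. Membership queries flow an arbitrary off-
boundary point to a routing point of its region.

Defaults and their reasons:

| quantity | default | why |
|---|---|---|
| center $c$ | uniform on $(0.5, 1.5)^k$, rounded to $10^{-4}$ rationals, seeded | generic w.p. 1; rational so the deterministic resultant path is exact |
| exponent $D$ | $\lfloor \deg N / 2\rfloor + 1$ | smallest integer with $2D > \deg N$ |
| genericity value gap | $10^{-6}$ relative | distinct critical values (at most one point per level) |
| Hessian degeneracy | $10^{-7}$ of the spectral radius | nondegeneracy of critical points |
| dedup tolerance | $10^{-8}$ relative | below it, Newton-polished duplicates; above it, distinct points |
| redraw budget | 5 centers | a failing center is redrawn with a logged seed |

**Critical-point solving.** For $k \le 2$ and modest numerator degree the
cleared-denominator gradient system
$(1+\|a-c\|^2)\,\partial_i N - 2 D N (a_i - c_i) = 0$ is solved
deterministically: resultants in both variable orders (sympy), exact real
root isolation of their squarefree parts, then Newton pairing and
polishing in R. Otherwise a seeded multistart Newton search runs batches
of starts (a jittered stratified grid first, then uniform draws) until two
consecutive batches find nothing new. Three filters then apply:

1. *residual*: the cleared system, relative to its own term magnitudes;
2. *criticality of $r$ itself*: $\|\nabla r\|(1+\|a\|)/|r| < 10^{-6}$.
   This is essential: the singular locus of the arrangement (where two
   factors meet, so $N$ and $\nabla N$ vanish together) solves the cleared
   system exactly but consists of positive-dimensional families, not
   critical points;
3. *boundary exclusion*: the first-order relative distance
   $|g_i|/(\|\nabla g_i\|(1+\|a\|))$ to every factor must exceed
   $10^{-9}$. Degree-based normalizations were found to reject genuine
   routing points inside thin regions of high-degree arrangements.

Each numerator factor is rescaled to unit maximum coefficient before
numeric work — a positive constant multiple of $r_c$, which leaves
critical points, Hessian signatures and flows unchanged but keeps
high-degree products (slice boundaries reach degree 20 with enormous
integer coefficients) inside double-precision dynamic range.

**Gradient flow.** Trajectories of
$\dot y = \operatorname{sign}(r_c)\,\nabla r_c$ are integrated as a
monotone adaptive ascent on $|r_c|$: a step is accepted only if both the
endpoint and the midpoint keep the sign of $r_c$ and do not decrease
$|r_c|$, and its length is capped at a fraction of $1 + \|y\|$. Monotone
ascent cannot cross the boundary (where $r_c = 0$), and the midpoint test
prevents a discrete step from hopping over a thin boundary valley into a
same-signed neighbouring region — a failure mode observed with naive
adaptive stepping. Saddle launches offset by $10^{-4}(1+\|a\|)$ along the
unstable eigenvector, halved until $|r_c|$ increases. Landings are matched
to the nearest routing point within $10^{-5}$ (relative), after a Newton
polish if needed; if the polished landing is a valid routing point that
the solver had missed (small Newton basin, or outside the search box),
it is appended to the graph and traced in turn, so the flow itself
completes the vertex set.

For two-parameter slices the vertex set is additionally seeded from the
sign-grid oracle (below): an ascent is started from one interior
representative of every grid region, which reliably captures routing
points of very small regions — the coral slices contain stability
regions a few percent of the frame in size.

## Stage 3: classification

At each region's routing point the steady states are solved (per
component, by triangular back-substitution with univariate root finding
on the component's Gröbner generators), filtered to real nonnegative
points, typed by their zero-coordinate pattern (tolerance $10^{-9}$;
coordinates in $(10^{-9}, 10^{-6})$ flag the region "near boundary"
rather than risking misclassification), and tested for stability by the
Routh polynomials with an eigenvalue cross-check. The set of types with a
stable representative labels the region; an empty set flags possible
limit cycles, for which `detect_limit_cycle_region()` gathers trajectory
evidence (boundedness, non-convergence, recurrence) with `deSolve` —
evidence, not proof.

## Independent oracles

Two component-counting oracles validate the routing graph:

* **grid flood fill** (`grid_components`): cells of a box are joined only
  when axis-adjacent with identical sign vectors over the arrangement;
  counts must be unchanged under one resolution doubling before being
  trusted. Reliable for the planar fixtures.
* **constant-sign roadmap** (`roadmap_components`): random samples are
  joined to nearest neighbours *within their sign class* whenever the
  connecting segment keeps a constant sign vector. When every boundary
  polynomial is homogeneous — as in the competition-colonization model,
  whose positive orthant is a cone — samples are drawn on the unit
  simplex, since positive scaling is a sign-preserving bijection of
  regions. This matters: the cone's chambers become unboundedly thin
  wedges near the origin, and a fixed-resolution grid fragments there at
  any resolution, while the simplex slice is well-conditioned. The
  per-class neighbour search follows thin wedges along their axis; small
  components get a healing pass with a larger neighbourhood.

The random-arrangement generator (`random_arrangement`) draws small
rational lines and axis-aligned ellipses, rejection-sampled to be pairwise
distinct and nonsingular. It emulates the geometry the method must handle
— curved walls, lens-shaped intersections, nested and unbounded regions —
but not high degrees, near-tangencies, or singular arrangements; passing
its property net therefore demonstrates correct connectivity logic, not
robustness to adversarial geometry.

## Problem sizes used by the shipped analyses

The default analyses run at sizes chosen to resolve the shipped models
comfortably: multistart batches of $1200k$ starts (stratified first
batch), grid oracles at 280–400 cells per axis in the plane, the roadmap
at 15000 simplex samples, slice classification at one routing point per
region, and trajectory evidence over a horizon of 800 time units. The
four-parameter competition-colonization landscape (11 hypersurfaces,
numerator degree 14, $D = 8$) resolves its 16 positive-orthant regions in
under a minute; each coral slice (boundaries up to degree 20 after
substitution) takes roughly half a minute.

## Design decisions on open points

* **Hurwitz matrix convention**: $H_{ij} = c_{n-2i+j}$ (1-based,
  out-of-range coefficients zero) with positivity of
  $\Delta_1, \dots, \Delta_{n-1}, c_0$ as the criterion; verified against
  the explicit $n = 2, 3$ lists.
* **Full-space region counts** (all orthants) are available by building
  the routing function without the coordinate product
  (`restrict_positive = FALSE`); the positive-orthant count is the
  supported, tested mode, and the full-space run is long and off by
  default.
* **Stable-set vocabulary** is keyed by the set itself
  (e.g. `"E_x+E_co"`); display names like "Coral only or coexistence" are
  cosmetic lookups.
* **Ties in critical values** (genericity failure) are resolved by
  redrawing the center, never by perturbing computed values.
* **Exact arithmetic range**: rationals are exact while magnitudes stay
  below $2^{52}$; beyond that (reached only by boundary factors with very
  large printed integer coefficients) arithmetic degrades silently to
  double precision and such factors are treated numerically. All
  printed-value identities in the tests live far below this bound.

## Limitations

* Region **adjacency** (which regions share a wall) is out of scope: the
  graph gives membership, not the wall structure.
* Multistart completeness is not certified; it is mitigated by batch
  stabilization, flow-discovered vertices, the grid assist, and the
  independent oracles, and could still in principle miss a region whose
  every basin is smaller than the sampling resolution.
* Limit-cycle evidence is numerical; no existence or uniqueness proof.
* The full coral boundary with all rate parameters free is beyond the
  symbolic backend at interactive scale; analyses fix $d, \gamma_y,
  \gamma_z, \beta_y$ first, as the shipped `coral_fixed` fixture does.
* Routh machinery covers $n \le 4$ state variables.
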