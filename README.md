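# stabscape

Stability landscapes of ecological ODE models via routing functions.

## What problem this solves

Models of the form `dx/dt = f(x; a)` — polynomial or rational rates,
nonnegative states, positive parameters — underlie much of population
ecology, epidemiology and systems biology. For any fixed parameter vector
`a` the model has some set of steady states, of which some are locally
asymptotically stable. Interventions and environmental change move `a`,
and the biology changes qualitatively only when `a` crosses one of three
algebraic boundaries: the **singular boundary** (real steady states appear
or vanish; the discriminant locus), the **Routh–Hurwitz boundary**
(a stability verdict flips), or a **coordinate boundary** (a steady state
stops being feasible). Between those boundaries, the number and type of
stable steady states are constant.

`stabscape` computes this picture for systems of up to four state
variables:

1. **Boundaries.** The equilibrium ideal is decomposed into
   equilibrium-type components (recursive factor splitting); per component,
   the state variables are eliminated from the ideal together with each
   Routh polynomial and each coordinate condition (block-order Gröbner
   bases, or a triangular/resultant shortcut for slices). The union of
   irreducible factors is the total boundary, a hypersurface arrangement
   `B = ∪ {g_i = 0}` in parameter space.

2. **Regions.** Connected components of the complement of `B` in the
   positive orthant are enumerated with a *routing function*

   ```
   r_c(a) = g_1(a) ··· g_m(a) · a_1 ··· a_k / (1 + |a - c|^2)^D ,  2D > deg(numerator)
   ```

   whose critical points catalogue the regions: every region holds at
   least one, index-0 points are the extrema, and gradient flow along the
   unstable directions of higher-index points connects the critical
   points of each region into one component of the *routing graph*
   (a Morse-theoretic bijection with the regions). Membership of any
   parameter point is answered by flowing it to a routing point.

3. **Classification.** At one routing point per region the steady states
   are solved and Routh–Hurwitz-classified, labelling the region with its
   set of stable steady-state types (e.g. `{E_x, E_co}` = "coral only or
   coexistence"); an empty set flags possible limit cycles.

Built-in fixtures: a two-ellipse toy arrangement, a quadratic
discriminant model, a Holling type II predator–prey model with strong
Allee effect, the Levins–Culver competition–colonization model, and a
coral–bacteria symbiosis model (host + mutualistic + parasitic symbionts).

## Worked example

The two-ellipse arrangement — the plane cut by two crossing ellipses —
has six regions in the positive quadrant. The full pipeline:

```r
library(stabscape)

arr <- fixtures("two_ellipses")
rf  <- build_routing_function(arr, center = c(1.2, 0.7))
rf
#> routing function in 2 parameters: 4 numerator factors, numerator degree 6 , denominator exponent D = 4
#>   center c = ( 1.2, 0.7 )

A   <- critical_points(rf)            # deterministic resultant solve
pts <- lapply(seq_len(nrow(A)), function(i) classify(rf, A[i, ]))
table(vapply(pts, `[[`, 0L, "index"))
#> 0 1
#> 7 2

g <- build_routing_graph(rf, pts)
g
#> routing graph: 9 vertices, 4 edges, 6 connected components

locate(rf, g, c(5, 5))                # inside both ellipses
#> [1] 4
#> attr(,"vertex")
#> [1] 4
```

Nine routing points (seven extrema, two saddles) connect into six
components — one per region — and `locate()` reports which region any
parameter point belongs to.

For an actual model, the Levins–Culver competition–colonization system
(species 2 persists by colonizing faster than species 1 displaces it):

```r
lc  <- fixtures("levins_culver")
arr <- total_boundary(lc)             # 7 eliminated factors + 4 coordinate planes
length(arr)
#> [1] 11

rp <- routing_points(arr, seed = 1, method = "multistart", box = 8)
g  <- build_routing_graph(rp$rf, rp$points)
length(connected_components(g))
#> [1] 16

a <- c(beta_y = 1.03941, beta_z = 1.76600, gamma_y = 0.93685, gamma_z = 0.22883)
classify_region(lc, a)$stable_set
#> E_co -- Coexistence
```

Of the 16 positive-orthant regions, exactly 2 carry a stable coexistence
equilibrium — precisely the regions where `beta_y > gamma_y` and
`beta_z > beta_y(beta_y + gamma_z - gamma_y)/gamma_y`.

Two-parameter stability-landscape slices of the coral model
(`landscape_slice()`) reproduce the same workflow per slice and label each
region with its stable-state set; see the vignette for the method's
numerical details and `inst/scripts/stabscape` for a command-line front
end.

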