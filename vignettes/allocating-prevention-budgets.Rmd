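---
title: "Allocating prevention budgets: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allocating prevention budgets: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prevalloc)
```

## The decision problem

Should scarce prevention money go to the general population or to a
diagnosed high-risk group? `prevalloc` frames this as a linear program over
*cells*: one intervention program `j` offered to one age group `a`. Each
cell carries a per-participant QALY gain $q_{ja}$ and a per-participant net
healthcare cost $c_{ja}$, both lifetime net present values versus usual
care. With $p_{ja}$ the (continuous) number of funded participants and $b$
the budget,

$$\max_{p} \; \sum_{j}\sum_{a} p_{ja}\, q_{ja}
\quad \text{s.t.} \quad
\sum_{j}\sum_{a} p_{ja}\, c_{ja} \le b, \qquad
\sum_{a} p_{ja} \le cap_j \;\; \forall j, \qquad
0 \le p_{ja} \le dem_{ja}.$$

Demand limits $dem_{ja}$ are the size of the eligible target group per age;
capacity limits $cap_j$ cap a program's total participants across ages
(professional supply). Participants are continuous because these programs
are supply-driven and scale smoothly with money; an indivisible-program
(integer) variant is deliberately out of scope, as is stochastic
programming over parameter uncertainty.

Two views of the same data drive the analyses:

* the **league table** of average cost-effectiveness ratios $c_{ja}/q_{ja}$
  (euro per QALY, reported rounded to the nearest 100 euro), which ranks
  cells but ignores how many people each can reach; and
* the **efficiency frontier**: the LP's optimal value as a function of $b$.
  By LP duality this value function is concave and piecewise linear; each
  segment's slope is the budget's shadow price (QALYs per marginal euro) and
  its reciprocal is the segment's incremental cost-effectiveness ratio
  (ICER). Corner points are exactly the budgets where the optimal portfolio
  changes, and a cell funded at one budget may be *defunded* at a higher one
  — the frontier tracer represents exits explicitly rather than assuming
  nested portfolios.

The target populations are assumed disjoint: demands for general-population
programs are declared net of diabetes patients (diabetes-specific programs
take priority where eligibility overlaps). `validate_problem()` asserts the
metadata flag encoding this.

## Solving the LP

No linear-programming package is part of this package's dependency stack, so
the solver is a small two-phase bounded-variable primal simplex written for
exactly this structure (a budget row plus one capacity row per program, with
demand boxes). It refactorizes the basis at every iteration, which is slow
in general but irrelevant at 36 variables and ~13 rows, and it is
deterministic: Dantzig pricing with smallest-index tie-breaks, falling back
to Bland's rule after a stall so cycling cannot occur. Rows are scaled by
their largest coefficient; feasibility tolerances are 1e-9 on scaled data.
Duals come from the final basis: the budget dual (QALY/euro), capacity duals
(QALY/person of supply) and demand duals (QALY/extra eligible person, the
reduced costs of cells at their demand bound). Degenerate optima are
reported with a flag rather than resolved, since dual values need not be
unique there.

Three independent routes check the solver rather than trusting it:

* `oracle_solve()` enumerates every basic solution of small instances
  (guarded to 3 programs x 2 ages) and returns the exact optimum;
* `greedy_solve()` implements the provably optimal fill-cheapest-first rule
  for the capacity-free case and must agree to 1e-9;
* the test suite also cross-checks random instances against the simplex
  implementation in the recommended `boot` package.

Ties between equally cost-effective cells are broken lexicographically
(program code, then age), so a binding capacity is filled youngest-first
among identical cells and repeated runs are byte-identical.

`max_health_min_cost()` defines the frontier's right endpoint by a
lexicographic solve: maximize QALYs with the budget removed, then minimize
spend over the QALY-optimal face (imposed as an exact constraint; the
solver's phase-1 tolerance absorbs the roundoff). Dominated cells
($q \le 0$) are kept in problems but can never enter an optimal basis;
cost-saving cells ($c < 0$, $q > 0$) are allowed and effectively enlarge
the budget, which is why a negative budget can still be feasible.

## Tracing the frontier

Breakpoints are found by bisection on the budget dual, which is
non-increasing in $b$ and constant within a segment: if two budgets have
equal duals, concavity guarantees there is no breakpoint between them, so
recursive subdivision with a relative width of 1e-9 of the endpoint budget
finds every corner. A parametric simplex would be faster but harder to
verify; bisection only needs the solver itself. Segment midpoints supply the
funded set (cells with more than 1e-7 participants) for entering/leaving
bookkeeping; a budget exactly at a breakpoint is assigned to the left
segment. Reported budget grids are log-spaced because interesting budgets
span four orders of magnitude.

## The cohort simulator

The package needs per-cell $(q_{ja}, c_{ja})$ inputs. In practice such
numbers come out of large multi-disease microsimulation models that cannot
be redistributed, so `prevalloc` ships a deliberately simplified stand-in:
a three-state (well, chronic, dead) expected-value cohort model with annual
cycles. It is *synthetic*: its parameter values are chosen for realistic
magnitudes, not estimated for any real population, and nothing in the
package's tests should be read as validation against real epidemiology.
What it does reproduce structurally:

* age-increasing (Gompertz-like) mortality and chronic-disease incidence,
  with the diabetes variant carrying higher baseline risk, higher care
  costs and slightly lower utilities;
* quality of life declining with age, so life-years gained late in life
  count for less than one QALY each;
* care costs that continue in life-years gained — net cost $c$ is
  intervention cost *plus* the full downstream effect on healthcare
  spending, not intervention cost alone;
* interventions as hazard multipliers on the well-to-chronic and/or
  well-to-dead transitions for a limited number of years (reversion encodes
  relapse and non-adherence), with front-loaded annual costs.

Cycle convention: half-cycle (trapezoid) correction for QALYs and care
costs by default, intervention costs charged at cycle start. Year-$k$
amounts are discounted by $(1+r)^{-k}$ with year-0 amounts undiscounted.
The lifetime horizon stops when dead-state occupancy reaches $1 - 10^{-9}$
or at age 105. On a two-state constant-survival model both cycle
conventions admit exact geometric closed forms, which the tests reproduce
to 1e-9.

Discounting defaults to health at 1.5% and costs at 4% per year — the Dutch
pharmacoeconomic guideline convention — and both rates, plus the horizon,
are overridable per scenario.

## The problem generator

`generate_problem()` draws a complete 12 x 3 problem, deterministically per
seed. Its defaults are fixed study conditions, not tuning knobs:

* 6 general-population and 6 diabetes programs; age groups 20-44, 45-64,
  65+ with representative entry ages 32, 55, 72 (mid-interval; 72 for the
  open-ended group);
* per-program demand totals of 150,000-600,000 (general) versus
  15,000-60,000 persons (diabetes) split over ages — the diagnosed
  high-risk group is an order of magnitude smaller;
* capacity at 60% of each program's total demand by default, so supply
  limits genuinely bind at full implementation;
* every cell's average CER calibrated into the published league-table range
  of 1,400-59,600 euro per QALY. Calibration works backwards: effects are
  drawn first, the cell's QALY gain and care-cost consequence are simulated,
  and the intervention's annual cost is then set so the ratio lands on a
  log-uniformly drawn target (additivity of the cost stream makes this
  exact).

Two structural constraints mirror the packaged league table rather than
chance: target ratios *rise with age within a program* (in the packaged
table the 65+ cell is always its program's costliest), and each cell's
intervention cost is floored so that its average CER is non-increasing in
the time horizon. The floor is the closed-form condition
$i \ge (q_s c_l - q_l c_s)/(q_l - q_s)$ for horizon pair (long, short);
without it, cells whose ratio sits below the cost-effectiveness of the
late-life tail (care costs in added life-years per QALY gained) would look
*cheaper* under truncation, and the horizon comparison would not show the
pattern the analysis is about — short horizons cutting off effects that
prevention only delivers late. Draws that cannot satisfy the constraints
(e.g. care-cost consequences alone already exceeding the range ceiling) are
redrawn up to a cap, then raise a calibration error.

What the generator does **not** emulate: correlations between programs,
interaction effects of combined interventions (health gains are additive by
assumption), parameter uncertainty, and real epidemiological magnitudes.
Passing tests therefore demonstrate correctness of the optimization and
simulation machinery under realistic structure, not empirical claims about
Dutch prevention.

## Sensitivity machinery

`scenario_frontiers()` compares frontiers across scenarios on one shared
budget grid (union of all breakpoints plus a log grid), so pointwise
orderings are well defined. Capacity scenarios only toggle constraint rows
and run on any problem; discount and horizon scenarios *re-simulate* every
cell from the cohort configuration — a static problem file does not carry
enough information, and the function says so rather than rescaling
outcomes. The shipped presets are the study's sets: with/without
capacities; horizons of 25, 50 years and lifetime; and discount variants
0%/0%, 1.5%/4% (base), 4%/4%, and health 0%/costs 4%.

Expected orderings, all asserted in the tests: removing capacities moves
the frontier weakly outward and strictly extends the endpoint when a
capacity binds there; longer horizons move it weakly outward; discounting
both streams at 0% moves it outward and at 4%/4% inward relative to base.
Raising the cost discount rate alone does *not* have a signed effect on
every cell here, because net cost streams mix early intervention costs,
late care savings and late longevity costs; the monotonicity tests
therefore target the absolute (non-negative) component streams and the
health rate.

## Numerical choices and edge cases

* Feasibility/optimality tolerance 1e-9 on scaled data; participant values
  clipped to $[0, dem]$ after the solve.
* Funded-set membership at 1e-7 persons; binding-constraint detection at
  1e-7 relative.
* Budget-dual comparisons in the tracer at 1e-7 relative (duals span four
  orders of magnitude, so an absolute tolerance would merge real segments).
* Degenerate cell $q = c = 0$ is an error in `average_cer()`; $q \le 0$ is
  "dominated" (excluded from league tables, kept in problems); $c < 0$,
  $q > 0$ is "cost-saving" and sorts ahead of everything.
* Problem sizes in the test suite are kept small (oracle instances of at
  most 6 cells, a few dozen generated 12 x 3 problems) so the whole suite
  reruns quickly; they were chosen as the smallest sizes that exercise
  every code path, and the frontier checks compare against direct solves on
  50-point grids.

## Known limitations

* The league-table fixture carries ratios only; the per-participant QALYs
  and costs behind those ratios are not available separately, so
  `fixture_problem()` fixes documented per-age QALY constants and derives
  costs from the ratios. It is a demonstration object: optimal allocations
  computed from it illustrate the machinery, nothing more.
* The cohort model has one chronic state; comorbidity, disease-specific
  costs and competing chronic diseases are out of scope.
* Duals at degenerate optima are one valid choice among possibly many; the
  degeneracy flag is the only honest answer there.
* Shadow prices are marginal: they price one extra euro, person of
  capacity, or eligible person, and extrapolate only within the current
  frontier segment.
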