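# prevalloc

Priority setting across portfolios of preventive health interventions:
should a health system spend its prevention budget on the general
population, on a diagnosed high-risk group (diabetes patients), or on a
mix — and how does the answer change with the size of the budget?

`prevalloc` answers this with a resource-allocation model rather than a
league table alone. Cost-effectiveness ratios rank interventions but ignore
how many people each can reach; an allocation model adds target-group sizes
(demand), professional supply limits (capacity) and the budget itself.

## The model

Decision cells are intervention program `j` x age group `a`, each with a
per-participant lifetime QALY gain `q_ja` and net healthcare cost `c_ja`
(net present values versus usual care, euro at price level 2007; health
discounted at 1.5%/year, costs at 4%/year by default). With continuous
participant numbers `p_ja` and budget `b`, the allocator solves the linear
program

    max_p  sum_ja p_ja q_ja
    s.t.   sum_ja p_ja c_ja <= b          (budget)
           sum_a  p_ja      <= cap_j      (capacity, per program)
           0 <= p_ja <= dem_ja            (demand, per cell)

The optimal value as a function of `b` is the concave piecewise-linear
**efficiency frontier**; segment slopes are budget shadow prices and their
reciprocals are incremental cost-effectiveness ratios (ICERs). The package
provides:

* **league tables** — average cost-per-QALY ratios, ranking, band counts,
  plus a packaged fixture of 36 published ratios (12 programs x 3 age
  groups: smoking-cessation support, lifestyle programs, statins and
  blood-pressure medication, for the general population and for diabetes
  patients);
* **allocator** — a deterministic exact LP solve (`solve_allocation`) with
  shadow prices of budget, capacity and demand constraints, an
  active-set enumeration oracle for verification (`oracle_solve`), the
  greedy special case (`greedy_solve`) and the full-implementation
  endpoint (`max_health_min_cost`);
* **frontier** — breakpoint tracing by bisection on the budget dual
  (`trace_frontier`), entry/exit of interventions along the budget axis,
  and budget-table summaries (`summarize_allocation`);
* **cohort simulator** — a three-state (well / chronic / dead) annual-cycle
  Markov cohort model producing per-participant discounted QALY and cost
  differences versus usual care (`simulate_cohort`, `evaluate_cell`), and a
  seeded generator of complete, realistically structured allocation
  problems (`generate_problem`);
* **sensitivity** — frontier comparisons with/without capacity limits,
  across time horizons (25y/50y/lifetime) and discount-rate variants
  (`scenario_frontiers`, `scenario_preset`).

## Worked example

```r
library(prevalloc)

# published league-table fixture: ranking and band counts
fx <- cer_fixture()
rank_by_cer(fx)[1, c("short_name", "age_label", "average_cer")]
#>   short_name age_label average_cer
#>   S1         20-44            1400
count_by_cer_band(fx, 0, 10000)               # 17 cells under 10,000 EUR/QALY
count_by_cer_band(fx, 0, 10000, "diabetes")   # 11 of them target diabetes

# a complete synthetic 12 x 3 problem, deterministic in the seed
problem <- generate_problem(seed = 1)
frontier <- trace_frontier(problem)
frontier
#> <frontier> 53 segments, endpoint (11,123,937,147 euro, 574,206.6 QALYs)

summarize_allocation(problem, 5e8, frontier = frontier)[
  , c("spend", "total_qalys", "pct_spend_general", "icer")]
#>   spend total_qalys pct_spend_general     icer
#> 1 5e+08    85189.33           91.0856 8661.164
```

The frontier object says the model can buy at most ~574,000 QALYs at a
maximal useful budget of ~11.1 billion euro on this synthetic instance; the
summary row says that at a 500-million-euro budget about 91% of optimally
allocated money goes to the general population and the marginal QALY there
costs ~8,700 euro. Cell-level allocations, shadow prices and binding
constraints are on the returned objects.

The `analysis/` directory holds the full pipeline as numbered scripts
(league table, problem generation, frontier and budget tables, sensitivity
analyses), each writing its tables under `results/`:

```sh
Rscript analysis/01_league_table.R
Rscript analysis/02_generate_problem.R
Rscript analysis/03_frontier.R
Rscript analysis/04_sensitivity.R
```

## Scope

The package implements the *method* — model, frontier, sensitivity
machinery — together with the packaged league-table facts. Full
optimal-allocation inputs (per-cell QALYs, costs, demands, capacities) are
not redistributable, so the synthetic generator stands in for them with
the same structure (12 x 3 cells, the packaged CER range, small diabetes
target groups, binding capacities), which is exactly what the
property-based tests exercise. See the methods vignette
(`vignettes/allocating-prevention-budgets.Rmd`) for assumptions, numerical
choices and limitations.
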