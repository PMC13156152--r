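---
title: "Planning equitable substance-abuse intervention networks with equiloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning equitable substance-abuse intervention networks with equiloc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The planning problem

`equiloc` sites and sizes capacitated centers for two substance-abuse
intervention types over a municipality network: *prevention* (group
sessions for people at risk of initiating use; `k = 1`) and *mitigation*
(individual treatment of current users; `k = 2`). The tension is between
efficiency — put capacity where composite consumption risk is largest,
usually the dominant city — and equity — guarantee access to poor, rural
municipalities. The package keeps the two goals as separate objectives and
exposes the whole trade-off curve rather than collapsing them into one
score, so a planner can see what each extra unit of equity costs in risk
coverage.

## Composite indices

Three per-municipality shares feed the risk index: the share of estimated
substance consumers (`alpha`), the share of negative sentiment-labelled
social-media posts (`psi`), and the share of crime incidents (`gamma`).
Each is a simple proportion of the network total, so each sums to one. The
prevention-risk index is their unweighted mean,

\[ R^1_i = \tfrac{1}{3}(\alpha_i + \psi_i + \gamma_i), \qquad
   R^2_i = \tfrac{1}{2} R^1_i , \]

the halving encoding the working assumption that for every two individuals
at mitigation risk there is one at prevention risk. An unweighted mean is
the standard neutral choice for composite indices when no component has an
empirical claim to more weight; the sentiment share in particular is a
noisy proxy (see *Limitations*) and deliberately carries only a third of
the index.

The equity index multiplies deprivations instead of averaging them:

\[ \sigma^1_i = RP_i \cdot MPI_i, \qquad \sigma^2_i = \tfrac12 \sigma^1_i , \]

with `RP` the rurality proportion and `MPI` the multidimensional poverty
index, both in \([0,1]\). Multiplication prevents substitution: only
municipalities that are simultaneously poor *and* remote receive a high
equity priority.

Degenerate inputs are conventions, not errors: if a share's network total
is zero (no posts anywhere, say) the whole share vector is zero. A node
without posts gets `psi = 0`, which understates — never overstates — its
risk; its `alpha` and `gamma` components still count.

## The integer program

Decision variables are integer patient flows `Y[i,j,k]`, integer annual
capacity hours `C[j,k]`, and binary openings `X[j]` — for 23 demand nodes,
23 candidate sites, and 2 interventions that is 1127 integer variables of
which 23 are binary. Objective 1 maximises risk-weighted flow minus
normalised travel distance, with weight `delta`; objective 2 does the same
with the equity index and weight `pi`. Both use the same distance
normaliser `D_Max`, the global maximum of the distance matrix. Constraints:
flows respect demand; per-intervention budgets bound paid capacity hours
(`F^k` is the salary-derived hourly cost); an open center must run at least
`R_min` combined hours; service time `L^k` per patient must fit capacity;
a big-M row forces zero flow to closed sites; and every node must receive
at least `phi` patients across interventions — the equity floor that stops
the optimiser from abandoning remote towns entirely.

Two modelling choices deserve a note:

* **Capacity at closed sites.** The minimum-hours constraint only bounds
  *open* sites from below, so nothing in the printed constraint set stops a
  closed site from carrying paid phantom capacity. We add the linking bound
  `C[j,k] <= floor(Budget^k / F^k) * X[j]`, which also tightens the LP
  relaxation. It removes no integer solution in which closed sites are
  genuinely idle.
* **Big-M.** The default is the total network demand — the tightest generic
  constant, since no arc can carry more than everything demanded. It is
  user-overridable.

The exact solves run on HiGHS branch-and-bound through the SciPy
optimisation bindings (the model matrices are built entirely in R and
passed as sparse triplets; one backend launch solves a whole batch of
scalarisations). The default relative optimality gap is `1e-4`. Both
objective values of every returned solution are recomputed in R from the
flows — solver-reported objectives are never trusted — and
`verify_solution()` re-checks every constraint family post hoc.

An independent pure-R oracle, `brute_force_solve()`, certifies the solver:
it enumerates all opening patterns and integer flow assignments (guarded to
at most 3 sites and 12 patients of total demand) and checks
budget/minimum-hours feasibility in closed form. The test suite asserts
exact objective agreement across randomized tiny instances for both
single-objective forms and epsilon-floored solves.

## Frontier and knee

The epsilon-constraint sweep maximises OF1 subject to `OF2 >= eps` over a
linear grid from the OF2 level of the unconstrained OF1 optimum up to the
OF2 optimum — exactly the range over which the trade-off exists. Infeasible
or gap-limited grid points are recorded and skipped; dominated points are
filtered. The ideal point stacks the two independent optima. The knee is
the frontier point with minimal Euclidean distance to the ideal after
z-score standardisation of each objective over the frontier points
(population standard deviation, i.e. divide by *n*; the ideal is
standardised with the same frontier statistics, which keeps the selection
invariant under positive affine rescaling of either objective). A
zero-variance objective contributes nothing to the distance; ties break to
the lowest index; a single-point frontier is its own knee.

## Baseline heuristic

The comparison point mimics siting by population alone: open centers in the
most populated cities (ties to the earlier node id), each absorbing the
maximum budget-fundable capacity for its own demand, while budget hours are
first reserved so every node still receives its `phi` minimum, routed to
the nearest open center. A candidate is opened only while the remaining
budgets can still fund `R_min` hours. Integer round-ups can overshoot a
budget by a few hours, so a reconciliation pass sheds own-demand patients
(or, if a site cannot sustain its minimum hours, closes it) until every
constraint verifies. On dominant-city networks the result is the expected
pathology: one center in the big city, every other municipality pinned at
the policy minimum — efficient-looking, deeply inequitable.

## Reporting

Coverage within a radius (default 40 km, inclusive threshold) divides the
patients served by centers within range by the node's *demand* — unmet
demand lowers coverage. Per-intervention averages are unweighted means over
nodes; the overall figure is the mean of the two averages. The
scenario-projection helper reproduces the back-of-envelope expansion
arithmetic (each additional center replicates the average per-center share;
scaling capacity scales coverage proportionally), rounding the headline to
the nearest integer percent. Sensitivity tools re-solve the model over
`delta`/`pi` grids and report the maximum relative OF1 variation between
consecutive frontier points as a grid-resolution diagnostic.

## The synthetic generator

No real per-municipality inputs ship with the package, so the generator
reproduces the *structure* the analysis assumes:

* one dominant city holding about 60% of the population, and through
  per-capita post rates also the large majority of social-media posts;
* heavy-tailed (log-normal) populations elsewhere;
* poverty and rurality inversely rank-correlated with population, so
  equity indices concentrate in small remote towns;
* mitigation demand proportional to population (consumer rate 8%) with
  prevention demand half of it — the same 2:1 ratio the risk halving
  encodes;
* haversine distances (Earth radius 6371 km) between sampled centroids, a
  stand-in for road-network driving distances, which can be supplied as CSV
  instead;
* scalar defaults from the study conditions: hourly costs 11,250 and
  38,125 (monthly salaries of 1.8m and 6.1m over 160 monthly hours),
  service times 0.05 and 1 h/patient, 2,080 minimum annual hours,
  `delta = pi = 0.7`.

Where the underlying study does not pin a value, the generator fixes one
and documents it here: budgets default to 50% of the cost of serving all
demand, which lands instances in the interesting few-center regime (the
risk optimum opens one or two centers, the equity optimum a few more); the
minimum-service floor `phi` defaults to half the smallest node's total
demand; and the absolute population scale is kept at a few tens of
thousands of inhabitants network-wide so that exact branch-and-bound
closes the `1e-4` gap in seconds per scalarisation and a 20-point frontier
completes in minutes. The structure (shares, ratios, ranks), not the
absolute scale, is what the analysis depends on; tests that pass on these
networks certify the algebra and the algorithmics, **not** the statistical
fidelity of any real department's data.

The named department fixture (`atlantico_fixture()`) carries the published
scalars — budgets of COP 654 million (prevention) and 3 billion
(mitigation), the salary-derived hourly costs, `R_min = 2080` — and the
published per-municipality post counts (rows reported for merged town
groups are split evenly with the remainder to the first-listed town). All
other per-municipality quantities are synthetic stand-ins from a fixed
internal seed and are labelled as such; objective values computed on the
fixture are **not** comparable to any published case-study values.

## Numerical conventions

* Radius thresholds are inclusive (`d <= r`).
* The budget row is passed to the solver in hours
  (`sum C <= floor(Budget/F)`), an integer-equivalent tightening that
  avoids mixing currency-scale and hour-scale coefficients in one matrix.
* Solver ties between equal-objective optima are accepted as returned;
  tests compare objective values only. The enumeration oracle breaks ties
  to the first pattern in its fixed enumeration order.
* All randomness is seed-explicit; the generator refuses to run without a
  seed, and re-running any stage with the same configuration reproduces
  identical artifact bytes.

## Limitations

The sentiment share treats labelled post counts as given — no text
classification is performed — and under-represents municipalities with
little online activity. Haversine distances understate true travel
effort in broken terrain. Demand is deterministic and single-period. The
heuristic's capacity split across interventions follows the per-intervention
budget independently, the one aspect of the baseline the underlying study
leaves unspecified. And the generator's networks, while structurally
faithful, are not calibrated to any real department: conclusions about a
real region require its real profile and distance tables, which the
pipeline accepts as CSV.
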