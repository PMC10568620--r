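# tkievolve

Deterministic modelling of drug-resistance evolution in EGFR-mutant
non-small cell lung cancer under sequential and combination EGFR-TKI
therapy, for researchers comparing treatment schedules *in silico*:
which drug to give first, when to switch, and how the answer depends on
the tumor's initial resistant subclones.

## The model

Four genotypes evolve under a constant drug regimen: Type-W (EGFR
driver mutation only; sensitive to both drug classes), Type-X (T790M;
resists erlotinib/gefitinib, "drug A"), Type-Y (C797S; resists
osimertinib, "drug B") and Type-Z (T790M + C797S; resists both). Each
grows exponentially at a regimen-specific net rate and mutates
irreversibly toward resistance:

```
dw/dt = a w
dx/dt = g w + b x
dy/dt = h w + c y
dz/dt = k w + p x + q y + f z
```

The system is triangular and solves in closed form (a divided-difference
cascade), so simulating 1000 days of therapy is a handful of
exponentials — sweeping hundreds of thousands of scenarios is cheap and
exact. Built-in rates for regimens A, B and the erlotinib + osimertinib
combination ("C") come from published cell-line measurements
(`default_parameter_table()`); an adaptive ODE integrator
(`numeric_reference_state()`) provides an independent cross-check and
handles the rare degenerate rate combinations.

On top of the propagator the package provides piecewise schedule
simulation with recurrence detection, switch-day optimization,
initial-proportion sweeps, a therapy-selection map over initial Type-X/Y
fractions, parameter-sensitivity grids, selection-map area composition,
a seeded scenario generator for property testing, YAML/JSON run
configuration and a one-call pipeline (`run_all()`). Results are tidy
tibbles with `tidy()`/`glance()` methods and `autoplot()` figures.

## Worked example

```r
library(tkievolve)
params <- default_parameter_table()

# Day-1000 tumor burden of the three standard strategies
sapply(c("A-first", "B-first", "C"),
       function(st) final_total(params, strategy_schedule(st)))
#>     A-first     B-first           C
#> "2.118e+12" "1.088e+12" "4.204e+12"
```

Starting from a detectable 1e9-cell tumor (X0 = Y0 = 1e4, Z0 = 10),
osimertinib-first therapy (switch to erlotinib at day 567) ends with
about half the burden of erlotinib-first (switch at day 307), and the
upfront combination — which suppresses everything except the doubly
resistant clone, but each drug only partially — ends highest.

```r
traj <- simulate_schedule(params, strategy_schedule("B-first"))
glance(traj)
#>   horizon final_total recurrence_day final_dominant
#> 1    1000     1.09e12           478. z
autoplot(traj)

glance(sweep_switch_time(params, "B-first"))
#>   strategy best_switch_day min_final
#> 1 B-first              190   1.08e12
```

The B-first tumor shrinks below baseline and regrows to it at day ~478,
by then dominated by the doubly resistant Type-Z; the switch-day sweep
shows a long plateau of near-optimal switching times (~day 150–950), so
the exact switch day is forgiving.

```r
map <- build_selection_map(params, x_props = c(1e-5, 1e-1), y_props = c(1e-5, 1e-1))
as.data.frame(map[c("x_prop", "y_prop", "best")])
#>   x_prop y_prop    best
#> 1  1e-05  1e-05 B-first
#> 2  1e-05  1e-01 A-first
#> 3  1e-01  1e-05 B-first
#> 4  1e-01  1e-01       C
```

The selection map gives the practical rule: osimertinib-first unless
the tumor already carries a large C797S (Type-Y) clone — then
erlotinib-first — and the combination when both resistant clones are
abundant.

See `vignettes/therapy-scheduling.Rmd` for the model derivation,
parameter provenance, grid choices and limitations.

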