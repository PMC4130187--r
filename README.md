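# immunecouple

Simulation of the innate and adaptive immune response to a replicating
bacterial antigen in a 3D piece of tissue, coupled to the nearest lymph
node.

The package is aimed at computational immunologists and systems-biology
modellers who want a small, fully reproducible multiscale testbed: a
**reaction–diffusion PDE model of the tissue** (antigen *A*, resting and
activated macrophages *M<sub>R</sub>*, *M<sub>A</sub>*, antibodies *F*)
coupled through blood- and lymph-vessel indicator fields to a
**well-mixed ODE model of the lymph node** (antigen-presenting
macrophages *M<sub>A</sub><sup>L</sup>*, T and B lymphocytes, plasma
cells *P*, antibodies *F<sup>L</sup>*).

The antigen replicates logistically up to a carrying capacity
*k<sub>A</sub>* and is destroyed by phagocytosis; activated macrophages
migrate through lymph vessels to the node, where they trigger the
adaptive cascade T → B → plasma cells → antibodies; antibodies return
through blood vessels and opsonize the antigen (trilinear *A·F·M* terms),
accelerating clearance:

    ∂A/∂t  = β_A A (1 − A/k_A) − μ_A A − λ_MR M_R A − λ_MA A M_A
             − λ_AF|MR A F M_R − λ_AF|MA A F M_A + D_A ΔA
    dF^L/dt = ρ_F P − α_F (F^L − F^T) V_BV / V_LN          (and so on)

Everything is advanced with explicit Euler (10⁴ steps/day, Δt = 10⁻⁴ d)
on a 10×10×10 voxel grid with zero-flux boundaries; the two compartments
exchange mass through vessel-averaged flux terms that are conservative to
round-off (asserted in the tests).  A one-factor-at-a-time sensitivity
analysis with the normalised squared-deviation statistic

    Max_err = max_k  Σ_i (E_orig(i) − E_k(i))² / Σ_i E_orig(i)²

ranks the model parameters by their influence on the antigen time course.

The numerical core is compiled (Rcpp); a plain-R reference engine and
scalar-loop oracles back every operator in the test suite.  See the
vignette (`vignettes/coupled-immune-model.Rmd`) for the full model, the
unit conventions and the design decisions.

## Worked example

```r
library(immunecouple)

res <- run_simulation(scenario_preset("case3"))   # full coupled model
res
#> <imm_sim> scenario case3: 30 recorded days, stopped on tolerance
#>   antigen eliminated on day 30 (total <= 1e-06)
#>   negative clamps: 0;  wall time: 6.6 s

glance(res)[, c("elimination_day", "peak_antigen_day", "peak_antigen")]
#> # A tibble: 1 × 3
#>   elimination_day peak_antigen_day peak_antigen
#>             <int>            <int>        <dbl>
#> 1              30               11         14.1
```

The average antigen concentration rises to ~14 cells/mm³ around day 11
while the adaptive cascade spools up (T cells peak on day 4, B cells on
day 6, plasma cells on day 5), after which returning antibodies drive the
total antigen below the 10⁻⁶ stopping tolerance on day 30 — elimination,
in contrast to the innate-only scenario (`case2`), which settles into a
chronic infection.  `tidy()` returns the nine recorded time series in
long form, `autoplot()` draws them, `write_timeseries()` /
`write_snapshot()` export CSV and legacy-VTK files, and

```r
oat <- oat_analysis(sensitivity_spec(parameters = c("gamma_MA", "alpha_F")))
tidy(oat)
#> # A tibble: 2 × 4
#>   parameter description                max_err argmax_variation
#>   <chr>     <chr>                        <dbl>            <dbl>
#> 1 gamma_MA  Macrophage activation rate   14.7                -1
#> 2 alpha_F   Antibodies migration rate    10.3                -1
```

scores parameters by how strongly one-at-a-time perturbation distorts
the antigen time course (here: removing macrophage activation, or the
antibody migration route, each derails clearance completely).

Command-line wrappers live in `inst/scripts/`:

```sh
Rscript inst/scripts/simulate.R --scenario case3 --out results/ --snapshot-days 0,10,20
Rscript inst/scripts/sensitivity.R --params all --out table.csv
```

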