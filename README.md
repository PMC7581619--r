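# biogasMPC

Model-based management of biogas production from anaerobic digestion, for
bioprocess engineers who want to *schedule* gas production — e.g. to
balance a fluctuating renewable supply — rather than just monitor it. The
package implements the full loop as a tested R library plus a thin
command-line front end:

1. **Plant model** — a lumped two-state digestion model: logistic bacterial
   growth with Monod–Haldane kinetics, yield-coupled substrate
   decomposition, and biogas generation proportional to active biomass,

   dn/dt = (μ(s) − b) n (1 − n/n_max) + u_n
   ds/dt = −(1/Y) μ(s) n + u_s
   v     = (k_g1 b + k_g2 μ(s)/Y) m n,   μ(s) = μ_max s / (k_s + s + k_i s²)

   with an RK4 simulator, analytic linearization, exact zero-order-hold
   discretization, and conversion to a second-order input–output
   difference equation.
2. **Adaptive identification** — filtered regressors through
   Λ(q) = (q+l)², batch and recursive least squares with a substrate-input
   switch, giving θ = (b1, b3, b2, b4, 2l−a1, l²−a2) directly from hourly
   operating records.
3. **Minimal realization** — impulse responses, block-Hankel assembly,
   SVD factorization (Ho-Kalman) back to a discrete state-space model
   (A, B, C), with singular-value-based order selection.
4. **Feedstock-determination control** — incremental-form model predictive
   control: stacked prediction matrices (Ψ, Υ, T), least-squares solution
   of ΔU* = (TᵀQ̄T + R̄)⁻¹ TᵀQ̄E, a receding-horizon loop with a zero feed
   floor, and greedy integration of the optimal input into sparse
   feasible feeding events under an output-deviation bound.
5. **Metrics & workbench** — goodness-of-fit index
   GFI = 100(1 − ‖y−ŷ‖/‖y−mean y‖), tracking RMSE, and a synthetic
   operation-data generator emulating a two-term (unfed / fed)
   identification campaign on a 0.2 m³-sludge laboratory digester at an
   organic loading rate of 1.5 g-VS/L/day, 1 h sampling.

See `vignettes/biogas-management.Rmd` for the model, assumptions, tuning
parameters and design decisions.

## Worked example

Run the full pipeline on a synthetic operation record (72 h unfed lead-in,
168 h fed at 1.5 g-VS/L/day, 0.2 L/h measurement noise):

```r
library(biogasMPC)

cfg <- experiment_config(noise_sd = 0.2, seed = 42)
res <- run_pipeline(cfg)

res$identification$poly
#> Discrete input-output model (order 2, 2 inputs / 1 output)
#>   denominator: q^2 + (-0.21023) q + (-0.46187)
#>   bacteria channel:  (4.1067) q + (2.4096)
#>   substrate channel: (20.832) q + (12.135)
```

The identified substrate channel says one g/L/h of substrate feeding adds
about 20.8 L/h of gas one hour later; the denominator roots are the two
process poles at 1 h sampling. After realization to state space, free-run
prediction and closed-loop control give

```r
cat(sprintf("prediction GFI: flow %.1f%%, accumulated %.1f%%\n",
            res$prediction$fit$gfi_rate, res$prediction$fit$gfi_cumulative))
#> prediction GFI: flow 96.1%, accumulated 99.5%
cat(sprintf("optimal tracking RMSE:  %.3f L/h\n", res$optimal$rmse))
#> optimal tracking RMSE:  0.068 L/h
cat(sprintf("feasible tracking RMSE: %.3f L/h (%d feeding events)\n",
            res$feasible$rmse, nrow(res$feasible$result$events)))
#> feasible tracking RMSE: 13.101 L/h (48 feeding events)
```

Flow-rate GFI sits below the accumulated-volume GFI because accumulation
averages out the measurement noise; the optimal (continuous-input)
controller tracks the 22 L/h reference almost exactly, and collapsing that
input into discrete feeding events trades tracking error for operability.

The same stages are available as CLI subcommands
(`synth`, `identify`, `realize`, `control`, `evaluate`, `pipeline`):

```sh
Rscript inst/cli/biogasmpc.R synth    --seed 3 --out series.csv
Rscript inst/cli/biogasmpc.R identify --input series.csv --out params.json
Rscript inst/cli/biogasmpc.R realize  --params params.json --order 2 --out ss.json
Rscript inst/cli/biogasmpc.R control  --model ss.json --mode optimal --duration 168 --out run.csv
```

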