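# oscgrain

Data-driven coarse-graining of coupled phase oscillator networks:
discovering coarse variables from phase-density snapshots, learning their
evolution equations from flow data with an integrator-templated neural
network, and finding reduced "effective" parameters for heterogeneous
ensembles.

## The problem

A network of N coupled phase oscillators,

    dθ_i/dt = ω_i + (K_i/N) Σ_j A_ij sin(θ_j − θ_i)  (+ α_i sin θ_i),

is high dimensional, but its collective behavior is often captured by a
single coarse variable — classically the order parameter R e^{iψ} =
(1/N) Σ_j e^{iθ_j}, whose modulus R ∈ [0, 1] measures phase coherence.
Deriving such variables and their closed evolution equations analytically
requires model-specific insight; for the all-to-all Kuramoto model with
Cauchy-distributed frequencies (scale γ) the known answer is the
Ott–Antonsen reduction

    dR/dt = −γ R + (K/2) R (1 − R²),

with stable fixed point R∞ = √(1 − 2γ/K). `oscgrain` implements a
systematic, data-driven alternative and uses the analytic reduction as its
oracle:

1. **Coarse-variable discovery** — snapshots of oscillator phases are
   binned into permutation-invariant phase densities and embedded with
   diffusion maps (Gaussian kernel `exp(−d²/2ε²)`, α = 1 normalization);
   local-linear-regression residuals separate genuinely new eigenfunction
   directions from harmonics. One significant coordinate φ₁ emerges,
   one-to-one with R.
2. **Evolution-law learning** — matched observations (R(t), R(t+Δt)) from
   thousands of short bursts of full microscopic simulation train a
   feedforward network templated on a fixed-step fourth-order Runge–Kutta
   integrator; its shared sub-network converges to the ODE right-hand-side
   itself. A forward-Euler + geometric-harmonics smoother provides the
   finite-difference baseline, and the same machinery learns the dynamics
   of the *discovered* coordinate φ₁.
3. **Effective-parameter discovery** — for heterogeneous variants
   (per-oscillator coupling K_i, excitable "firing" term α_i sin θ_i,
   Chung-Lu random networks), diffusion maps with an *output-only informed*
   kernel on the steady synchronized phases reveal that one eigenfunction —
   one effective parameter combining (ω, K, α, κ) — determines each
   oscillator's steady phase, matching the analytic balance
   sin(θ_∞) = ω/(R K) where one exists.

Intended users: researchers in computational neuroscience and nonlinear
dynamics working with coupled-oscillator models who want equation-free
coarse variables, reduced parameters, and learned coarse ODEs with an
analytically validated reference implementation.

## Worked example

Discover the coarse variable of a (reduced-size) all-to-all ensemble and
compare the learned evolution law with the analytic one:

```r
library(oscgrain)

## 1. the analytic reference
ott_antonsen_fixed_point(k = 2, gamma = 0.5)
#> [1] 0.7071068

## 2. flow pairs from 500 fresh 2000-oscillator ensembles, dt = 0.05
pairs <- generate_flow_pairs(n_pairs = 500, dt = 0.05,
                             n_oscillators = 2000, seed = 7)
pairs
#> <flow_pairs: 500 pairs of R, dt = 0.05>

## 3. train the RK4-templated network (reference settings)
model <- train_rhs_net(pairs, rk4net_config(epochs = 10000, seed = 1))
model
#> <rhs_model for R: layers 1-24-24-24-1, dt = 0.05, final train loss 1.14e-05>

## 4. compare the learned right-hand-side with the Ott-Antonsen law
grid <- seq(0, 1, length.out = 201)
err <- predict(model, grid) - ott_antonsen_rhs(grid, 2, 0.5)
sqrt(mean(err^2))
#> [1] 0.00790848
max(abs(err))
#> [1] 0.03495374

## 5. learned rollouts converge to the analytic steady state
roll <- integrate_learned(model, y0 = 0.1, times = seq(0, 30, 5))
round(roll, 4)
#> [1] 0.1000 0.6057 0.7044 0.7051 0.7051 0.7051 0.7051
```

The numbers mean: the analytic fixed point is √0.5 ≈ 0.7071; a network
trained only on 0.05-time-unit flow observations of this small ensemble
recovers the right-hand-side to ~8×10⁻³ RMS (the max error, 0.035, sits
at the sparse domain boundary — at the full size, 8,000 oscillators and
2,000 pairs, the acceptance run below brings the maximum under 0.01), and
integrating the learned law from incoherence (R = 0.1) relaxes to 0.7051 —
within the finite-size tolerance of the true steady state.

Coarse-variable discovery runs the same way from simulated trajectories:

```r
cfg <- experiment_config(preset = "ref_coarse_id", scale = "test", seed = 1)
summary <- run_experiment(cfg)
summary$significant_count
#> [1] 1        — a single significant eigenfunction
summary$spearman
#> [1] 0.9987064 — phi_1 is one-to-one with R
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/emergent.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/emergent.R", package = "oscgrain"))')" \
    coarse-id --seed 1 --out run1 --scale test
```

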