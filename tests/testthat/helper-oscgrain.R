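# shared fixture builders (all generated in code, deterministic seeds)

# small all-to-all ensemble with symmetric tail-capped Cauchy frequencies
tiny_ensemble <- function(n = 50, k = 2, gamma = 0.5, eps = 0.01) {
  oscillator_ensemble(sample_cauchy_frequencies(n, gamma, eps), k = k)
}

# equally spaced phases over (0, 2*pi]: coherence cancels to ~machine zero
spaced_phases <- function(n) seq(0, 2 * pi, length.out = n + 1)[-1]

# points sampled on a 1-D arc embedded in the plane (intrinsic dim 1)
arc_points <- function(n = 300, span = 1) {
  s <- seq(0, span, length.out = n)
  cbind(cos(s), sin(s))
}

# noiseless flow pairs from a known scalar ODE via the exact RK4 map
synthetic_pairs <- function(f, y0, dt) {
  flow_pairs(y0, rk4_step(f, y0, dt), dt)
}
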