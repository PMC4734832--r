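# shared fixtures: small, fast synthetic signals built in code

coupled_trace <- function(seed, duration = 60, fs = 1000, c = 0.8,
                          f_theta = 8, f_gamma = 60, ...) {
  spec <- coupling_spec(f_theta = f_theta, f_gamma = f_gamma,
                        coupling_strength = c, ...)
  channel_signal(generate_coupled_signal(spec, duration, fs, seed = seed), 1)
}

# single-cell grid centred on the generative frequencies; wide amplitude
# band so both modulation sidebands are captured
true_cell_grid <- function(f_theta = 8, f_gamma = 60) {
  band_grid(phase_freqs = f_theta, amp_freqs = f_gamma, amp_bw = 20)
}

random_simplex <- function(n) {
  w <- stats::rexp(n)
  w / sum(w)
}

# brute-force entropy oracle, deliberately written without reusing
# package internals
mi_oracle <- function(p) {
  h <- 0
  for (v in p) if (v > 0) h <- h - v * log(v)
  (log(length(p)) - h) / log(length(p))
}
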