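# Shared fixtures: the default (excitable) model and a few canned traces.

default_params <- function() hh_params()

# A synthetic trace object compatible with the analysis functions.
make_trace <- function(v, dt = 0.01) {
  structure(list(t = seq_along(v) * dt - dt, v = v, dt = dt),
            class = "hh_trace")
}

# Gaussian "action potential" bump on a flat baseline.
gaussian_ap_trace <- function(baseline = -70, peak = 20, center = 25,
                              sigma = 0.5, T = 50, dt = 0.01) {
  t <- seq(0, T, by = dt)
  make_trace(baseline + (peak - baseline) * exp(-(t - center)^2 /
                                                  (2 * sigma^2)), dt)
}

# Scale-factor shorthand: a modulation whose sK equals the given factor.
mod_sK <- function(sK) conductance_modulation(beta_K = sK - 1, intensity = 1)

suprathreshold_trace <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_hh(default_params(),
                            protocol = constant_stimulus(1, 300), T = 300)
    cache
  }
})
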