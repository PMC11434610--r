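#' Voltage-clamp step protocols
#'
#' The three step protocols used to characterise sodium, delayed-rectifier
#' potassium and leak potassium currents:
#' \describe{
#'   \item{nav}{holding (command) voltage -100 mV for 20 ms, test pulses
#'     from -80 to -10 mV.}
#'   \item{kv}{holding -100 mV, test pulses of 100 ms from -70 to +130 mV.}
#'   \item{kleak}{test pulses of 400 ms from -120 to -30 mV with a command
#'     voltage of -70 mV.}
#' }
#' Step increments are not part of the printed protocols; the default is
#' 10 mV and must divide the printed range.
#'
#' @param preset `"nav"`, `"kv"` or `"kleak"`.
#' @param step_increment step spacing, mV.
#' @return An object of class `step_protocol` with fields `holding_v`,
#'   `pre_duration`, `step_levels`, `step_duration`, `inter_sweep` (ms).
#' @examples
#' length(make_protocol("kv")$step_levels) # 21
#' @export
make_protocol <- function(preset = c("nav", "kv", "kleak"),
                          step_increment = 10) {
  preset <- match.arg(preset)
  spec <- switch(preset,
    nav = list(holding_v = -100, pre_duration = 20, range = c(-80, -10),
               step_duration = 50),
    kv = list(holding_v = -100, pre_duration = 50, range = c(-70, 130),
              step_duration = 100),
    kleak = list(holding_v = -70, pre_duration = 50, range = c(-120, -30),
                 step_duration = 400))
  span <- diff(spec$range)
  if (span %% step_increment != 0)
    stop("step_increment must divide the protocol range (", span, " mV)")
  structure(list(preset = preset, holding_v = spec$holding_v,
                 pre_duration = spec$pre_duration,
                 step_levels = seq(spec$range[1], spec$range[2],
                                   by = step_increment),
                 step_duration = spec$step_duration, inter_sweep = 0),
            class = "step_protocol")
}

#' Kinetic channel models for synthetic voltage-clamp currents
#'
#' Channel state under clamp relaxes exponentially (the command voltage is
#' piecewise constant, so gate trajectories are closed-form). Steady states
#' are Boltzmann sigmoids; time constants are voltage-independent model
#' parameters. These parameter values are synthetic-generator conventions,
#' not measured values.
#'
#' @param g_max maximal conductance (arbitrary conductance units; currents
#'   come out in g_max * mV).
#' @param E_rev reversal potential, mV.
#' @param act_v_half,act_k activation Boltzmann midpoint and slope, mV.
#' @param tau_act activation time constant, ms.
#' @param inact_v_half,inact_k inactivation Boltzmann midpoint and slope, mV.
#' @param tau_inact inactivation time constant, ms.
#' @param kexp activation-gate exponent.
#' @return An object of class `channel_model`.
#' @name channel_models
NULL

#' @rdname channel_models
#' @export
channel_nav <- function(g_max = 120, E_rev = 50, act_v_half = -30,
                        act_k = 6, tau_act = 0.3, inact_v_half = -60,
                        inact_k = 6.2, tau_inact = 2, kexp = 3) {
  structure(list(type = "nav", g_max = g_max, E_rev = E_rev,
                 act_v_half = act_v_half, act_k = act_k, tau_act = tau_act,
                 inact_v_half = inact_v_half, inact_k = inact_k,
                 tau_inact = tau_inact, kexp = kexp),
            class = "channel_model")
}

#' @rdname channel_models
#' @export
channel_kv <- function(g_max = 36, E_rev = -90, act_v_half = -20,
                       act_k = 12, tau_act = 8, kexp = 1) {
  structure(list(type = "kv", g_max = g_max, E_rev = E_rev,
                 act_v_half = act_v_half, act_k = act_k, tau_act = tau_act,
                 kexp = kexp),
            class = "channel_model")
}

#' @rdname channel_models
#' @param g leak conductance.
#' @export
channel_leak <- function(g = 0.3, E_rev = -90) {
  structure(list(type = "leak", g_max = g, E_rev = E_rev),
            class = "channel_model")
}

boltz <- function(v, v_half, k) 1 / (1 + exp((v_half - v) / k))

# Gate steady states of a channel model at voltage v: activation rises with
# v, inactivation falls with v.
.channel_gates_inf <- function(ch, v) {
  act <- if (ch$type == "leak") 1 else boltz(v, ch$act_v_half, ch$act_k)
  inact <- if (ch$type == "nav")
    1 - boltz(v, ch$inact_v_half, ch$inact_k) else 1
  c(act = act, inact = inact)
}

#' Simulate a voltage-clamp trace set
#'
#' For each step level the command voltage sits at `holding_v` for
#' `pre_duration` ms, then jumps to the step level for `step_duration` ms.
#' Gates start at the holding-potential steady state and relax exponentially
#' toward the step-level steady state; the recorded current is
#' \eqn{I(t) = g_{max}\,a(t)^{kexp}\, i(t)\,(V - E_{rev})} plus optional
#' additive Gaussian noise. Deterministic per seed.
#'
#' @param channel a [channel_models] object.
#' @param protocol a [make_protocol()] step protocol.
#' @param dt sample interval, ms (default 0.1, i.e. 10 kHz).
#' @param noise_sigma additive Gaussian noise standard deviation (current
#'   units).
#' @param seed RNG seed for the noise (ignored when `noise_sigma = 0`).
#' @return A `current_trace_set`: list with `t` (ms, from sweep start),
#'   `i` (time x step matrix), `step_levels`, `step_onset`, `protocol`,
#'   `channel`, `dt`, `noise_sigma`.
#' @export
run_voltage_clamp <- function(channel, protocol, dt = 0.1, noise_sigma = 0,
                              seed = NULL) {
  tmax <- protocol$pre_duration + protocol$step_duration
  t <- seq(0, tmax, by = dt)
  on_step <- t >= protocol$pre_duration
  g0 <- .channel_gates_inf(channel, protocol$holding_v)
  if (noise_sigma > 0 && !is.null(seed)) set.seed(seed)
  imat <- vapply(protocol$step_levels, function(vstep) {
    v <- ifelse(on_step, vstep, protocol$holding_v)
    if (channel$type == "leak") {
      i <- channel$g_max * (v - channel$E_rev)
    } else {
      ginf <- .channel_gates_inf(channel, vstep)
      ts <- pmax(t - protocol$pre_duration, 0)
      act <- ifelse(on_step,
                    ginf[["act"]] + (g0[["act"]] - ginf[["act"]]) *
                      exp(-ts / channel$tau_act),
                    g0[["act"]])
      inact <- if (channel$type == "nav") {
        ifelse(on_step,
               ginf[["inact"]] + (g0[["inact"]] - ginf[["inact"]]) *
                 exp(-ts / channel$tau_inact),
               g0[["inact"]])
      } else 1
      i <- channel$g_max * act^channel$kexp * inact * (v - channel$E_rev)
    }
    if (noise_sigma > 0) i <- i + stats::rnorm(length(i), 0, noise_sigma)
    i
  }, numeric(length(t)))
  structure(list(t = t, i = imat, step_levels = protocol$step_levels,
                 step_onset = protocol$pre_duration, protocol = protocol,
                 channel = channel, dt = dt, noise_sigma = noise_sigma),
            class = "current_trace_set")
}

#' Current-voltage relation from a clamp trace set
#'
#' @param traces a `current_trace_set`.
#' @param mode `"peak"` (signed extremum of largest magnitude within the
#'   step) or `"steady_state"` (mean over a window).
#' @param window window relative to step onset, ms; default for
#'   `"steady_state"` is the last 20 percent of the step, for `"peak"` the
#'   whole step.
#' @return data frame with columns `v` (step level, mV) and `i`, one row per
#'   step; attribute `mode`.
#' @export
iv_curve <- function(traces, mode = c("steady_state", "peak"),
                     window = NULL) {
  mode <- match.arg(mode)
  dur <- traces$protocol$step_duration
  if (is.null(window))
    window <- if (mode == "steady_state") c(0.8 * dur, dur) else c(0, dur)
  if (window[1] < 0 || window[2] > dur || diff(window) <= 0)
    stop("window must lie within the step interval [0, ", dur, "] ms")
  tw <- traces$t - traces$step_onset
  sel <- tw >= window[1] & tw <= window[2]
  vals <- apply(traces$i[sel, , drop = FALSE], 2, function(x) {
    if (mode == "steady_state") mean(x) else x[which.max(abs(x))]
  })
  out <- data.frame(v = traces$step_levels, i = vals)
  attr(out, "mode") <- mode
  out
}

#' Fit a Boltzmann activation or inactivation curve
#'
#' Least-squares fit of \eqn{y(V) = g_{max} / (1 + \exp(\pm(V_{1/2} - V)/k))}
#' (rising with V for activation, falling for inactivation) by
#' Levenberg-Marquardt. Initialisation comes from a logit-linear regression
#' of the normalized response on voltage (which lands in the correct basin
#' even for noisy data); if that fit fails, a coarse heuristic
#' (\eqn{V_{1/2}} at the voltage nearest half response, \eqn{k_0} =
#' range(V)/6) is used. Bounds \eqn{k \in (0.1, 50)} mV. To fit
#' conductance-activation data, transform currents with
#' `G = I / (V - E_rev)` first and normalize by the fitted `g_max` rather
#' than the largest data point.
#'
#' @param v voltages, mV (>= 4 points spanning the transition).
#' @param y response (normalized conductance or current).
#' @param direction `"activation"` or `"inactivation"`.
#' @return An object of class `boltzmann_fit`: list with `v_half`,
#'   `slope_k`, `g_max`, `direction`, `residual_norm`, `fitted`.
#' @export
fit_boltzmann <- function(v, y, direction = c("activation", "inactivation")) {
  direction <- match.arg(direction)
  stopifnot(length(v) == length(y), length(v) >= 4)
  sgn <- if (direction == "activation") 1 else -1
  ymax0 <- max(abs(y))
  # logit-linear initialisation: log(p/(1-p)) = sgn * (v - v_half) / k
  p0 <- pmin(pmax(y / (1.02 * ymax0), 1e-3), 1 - 1e-3)
  lf <- stats::lm(log(p0 / (1 - p0)) ~ v)
  slope <- unname(stats::coef(lf)[2]) * sgn
  # the midpoint is the zero crossing of the logit line for both directions
  v_half0 <- -unname(stats::coef(lf)[1]) / unname(stats::coef(lf)[2])
  k0 <- if (is.finite(slope) && slope > 1e-6) 1 / slope else
    diff(range(v)) / 6
  if (!is.finite(v_half0) || v_half0 < min(v) - 50 || v_half0 > max(v) + 50)
    v_half0 <- v[which.min(abs(y / ymax0 - 0.5))]
  k0 <- min(max(k0, 0.2), 45)
  do_fit <- function(start) minpack.lm::nlsLM(
    y ~ g_max / (1 + exp(sgn * (v_half - v) / k)),
    start = start,
    lower = c(g_max = 0, v_half = min(v) - 50, k = 0.1),
    upper = c(g_max = Inf, v_half = max(v) + 50, k = 50),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  fit <- tryCatch(
    do_fit(list(g_max = ymax0, v_half = v_half0, k = k0)),
    error = function(e1) tryCatch(
      do_fit(list(g_max = ymax0,
                  v_half = v[which.min(abs(y / ymax0 - 0.5))],
                  k = diff(range(v)) / 6)),
      error = function(e2) stop("Boltzmann fit failed to converge: ",
                                conditionMessage(e2))))
  co <- stats::coef(fit)
  structure(list(v_half = unname(co["v_half"]), slope_k = unname(co["k"]),
                 g_max = unname(co["g_max"]), direction = direction,
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 fitted = stats::fitted(fit)),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("<boltzmann_fit %s> v_half=%.3f mV k=%.3f mV g_max=%.4g (rss=%.3g)\n",
              x$direction, x$v_half, x$slope_k, x$g_max, x$residual_norm^2))
  invisible(x)
}

#' Single-exponential time-constant fit
#'
#' Fits \eqn{y(t) = y_\infty + a \exp(-t/\tau)} to a trace segment by
#' Levenberg-Marquardt, initialised from a log-linear regression.
#'
#' @param t time, ms (relative to segment start).
#' @param y trace values.
#' @return list with `tau` (ms), `a`, `y_inf`.
#' @export
fit_exp_tau <- function(t, y) {
  stopifnot(length(t) == length(y), length(t) >= 4)
  y_inf0 <- y[length(y)]
  d0 <- y - y_inf0
  amp0 <- d0[1]
  pos <- which(abs(d0) > 0.05 * abs(amp0))
  tau0 <- if (length(pos) > 2) {
    f <- stats::lm(log(abs(d0[pos])) ~ t[pos])
    max(-1 / stats::coef(f)[2], 1e-3)
  } else diff(range(t)) / 5
  fit <- minpack.lm::nlsLM(y ~ y_inf + a * exp(-t / tau),
                           start = list(y_inf = y_inf0, a = amp0,
                                        tau = tau0),
                           lower = c(-Inf, -Inf, 1e-6),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- stats::coef(fit)
  list(tau = unname(co["tau"]), a = unname(co["a"]),
       y_inf = unname(co["y_inf"]))
}

#' Leak-conductance analysis above a voltage cutoff
#'
#' Ordinary least-squares line through steady-state (V, I) pairs restricted
#' to step levels at or above `v_min` (default -65 mV, the rule for
#' isolating leak potassium current from the kleak protocol). The slope is
#' the leak conductance and the V-axis intercept the reversal potential.
#'
#' @param traces a `current_trace_set` (typically from the kleak preset).
#' @param v_min lowest step level analysed, mV.
#' @param window steady-state window relative to step onset, ms (default
#'   last 20 percent of the step).
#' @return list with `g_leak`, `E_rev`, `levels_used`, `fit` (the `lm`).
#' @export
leak_analysis <- function(traces, v_min = -65, window = NULL) {
  ivd <- iv_curve(traces, "steady_state", window)
  use <- ivd$v >= v_min
  if (sum(use) < 2)
    stop("insufficient data: fewer than 2 step levels at or above v_min")
  fit <- stats::lm(i ~ v, data = ivd[use, ])
  g <- unname(stats::coef(fit)[2])
  e <- -unname(stats::coef(fit)[1]) / g
  list(g_leak = g, E_rev = e, levels_used = ivd$v[use], fit = fit)
}
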