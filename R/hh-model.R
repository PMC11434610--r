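#' Voltage-dependent opening and closing rates of a gating variable
#'
#' Each gating variable y obeys \eqn{dy/dt = \alpha_y(v)(1-y) - \beta_y(v) y}.
#' For the h gate the steady state used throughout the model is the fixed
#' sigmoid \eqn{h_\infty(v) = 1/(1+\exp((v+60)/6.2))} (see
#' [gate_steady_state()]); its \eqn{\alpha_h, \beta_h} only set the time
#' constant \eqn{\tau_h = 1/(\alpha_h+\beta_h)}.
#'
#' @param v membrane potential, mV (finite scalar).
#' @param which gate id: `"m"`, `"h"` or `"n"`.
#' @param rate_set `"traub"` or `"classic"`.
#' @return Named numeric vector `c(alpha, beta)` in 1/ms, both >= 0.
#' @examples
#' gating_rates(-55, "n")
#' @export
gating_rates <- function(v, which, rate_set = c("traub", "classic")) {
  rate_set <- match.arg(rate_set)
  stopifnot(is.finite(v))
  if (!which %in% c("m", "h", "n"))
    stop("unknown gate id '", which, "' (must be one of m, h, n)")
  r <- .hh_gating_rates_cpp(v, if (rate_set == "classic") 0L else 1L)
  c(alpha = unname(r[paste0("alpha_", which)]),
    beta = unname(r[paste0("beta_", which)]))
}

#' Steady state and time constant of a gate
#'
#' For m and n the steady state is \eqn{\alpha/(\alpha+\beta)}; for h it is
#' the fixed sigmoid \eqn{1/(1+\exp((v+60)/6.2))}. The time constant is
#' \eqn{1/(\alpha+\beta)} for all gates.
#'
#' @inheritParams gating_rates
#' @return Named vector `c(inf, tau)` (dimensionless, ms).
#' @examples
#' gate_steady_state(-60, "h")["inf"] # 0.5 by construction
#' @export
gate_steady_state <- function(v, which, rate_set = c("traub", "classic")) {
  rate_set <- match.arg(rate_set)
  r <- gating_rates(v, which, rate_set)
  inf <- if (which == "h") 1 / (1 + exp((v + 60) / 6.2)) else
    r["alpha"] / (r["alpha"] + r["beta"])
  c(inf = unname(inf), tau = unname(1 / (r["alpha"] + r["beta"])))
}

#' Time derivative of the neuron state
#'
#' Reference R implementation of the membrane equation; the compiled
#' integrator used by [simulate_hh()] evaluates the same expressions.
#'
#' @param state named numeric vector `c(v, m, h, n)` with gates in [0, 1].
#' @param params an [hh_params()].
#' @param mod a [conductance_modulation()] (default: no field).
#' @param stim injected current, µA/cm².
#' @return Named vector of derivatives `c(v, m, h, n)` (mV/ms, 1/ms).
#' @export
hh_derivatives <- function(state, params, mod = conductance_modulation(),
                           stim = 0) {
  stopifnot(all(is.finite(state)))
  v <- state[["v"]]; m <- state[["m"]]; h <- state[["h"]]; n <- state[["n"]]
  if (any(c(m, h, n) < 0) || any(c(m, h, n) > 1))
    stop("gating variables must lie in [0, 1]")
  s <- conductance_scaling(mod)
  rm_ <- gating_rates(v, "m", params$rate_set)
  rh <- gating_rates(v, "h", params$rate_set)
  rn <- gating_rates(v, "n", params$rate_set)
  nk <- if (params$k_gate_exponent == 1L) n else n^4
  iNa <- s[["sNa"]] * params$gNa_max * m^3 * h * (v - params$vNa)
  iK <- s[["sK"]] * params$gK_max * nk * (v - params$vK)
  iL <- if (params$leak_gated) params$gL * n * (v - params$vL) else
    params$gL * (v - params$vL)
  h_inf <- 1 / (1 + exp((v + 60) / 6.2))
  c(v = (stim - iNa - iK - iL) / params$C,
    m = rm_[["alpha"]] * (1 - m) - rm_[["beta"]] * m,
    h = (h_inf - h) * (rh[["alpha"]] + rh[["beta"]]),
    n = rn[["alpha"]] * (1 - n) - rn[["beta"]] * n)
}

# Net ionic current balance at voltage v with all gates at steady state;
# roots are membrane equilibria.
.current_balance <- function(v, params, s) {
  m <- gate_steady_state(v, "m", params$rate_set)[["inf"]]
  h <- 1 / (1 + exp((v + 60) / 6.2))
  n <- gate_steady_state(v, "n", params$rate_set)[["inf"]]
  nk <- if (params$k_gate_exponent == 1L) n else n^4
  iL <- if (params$leak_gated) params$gL * n * (v - params$vL) else
    params$gL * (v - params$vL)
  -(s[["sNa"]] * params$gNa_max * m^3 * h * (v - params$vNa) +
      s[["sK"]] * params$gK_max * nk * (v - params$vK) + iL)
}

#' Resting fixed point of the model
#'
#' Scans the membrane equation for zero-current equilibria with all gates at
#' steady state and returns the most hyperpolarized stable one (stability by
#' the eigenvalues of a finite-difference Jacobian of the full 4-dimensional
#' system); if no equilibrium is linearly stable the most hyperpolarized root
#' is returned.
#'
#' @inheritParams hh_derivatives
#' @param v_range search interval for the resting potential, mV.
#' @return Named state vector `c(v, m, h, n)`.
#' @export
resting_state <- function(params, mod = conductance_modulation(),
                          v_range = c(-110, -30)) {
  s <- conductance_scaling(mod)
  vs <- seq(v_range[1], v_range[2], by = 0.5)
  fs <- vapply(vs, .current_balance, numeric(1), params = params, s = s)
  roots <- numeric(0)
  for (i in seq_len(length(vs) - 1)) {
    if (is.finite(fs[i]) && is.finite(fs[i + 1]) && fs[i] * fs[i + 1] < 0) {
      roots <- c(roots, stats::uniroot(.current_balance, c(vs[i], vs[i + 1]),
                                       params = params, s = s,
                                       tol = 1e-10)$root)
    }
  }
  if (!length(roots)) stop("no membrane equilibrium found in v_range")
  state_at <- function(v) {
    c(v = v,
      m = gate_steady_state(v, "m", params$rate_set)[["inf"]],
      h = 1 / (1 + exp((v + 60) / 6.2)),
      n = gate_steady_state(v, "n", params$rate_set)[["inf"]])
  }
  stable <- vapply(roots, function(v) {
    st <- state_at(v)
    J <- matrix(0, 4, 4)
    eps <- c(1e-4, 1e-7, 1e-7, 1e-7)
    for (j in 1:4) {
      up <- st; up[j] <- up[j] + eps[j]
      dn <- st; dn[j] <- dn[j] - eps[j]
      up[2:4] <- pmin(pmax(up[2:4], 0), 1)
      dn[2:4] <- pmin(pmax(dn[2:4], 0), 1)
      J[, j] <- (hh_derivatives(up, params, mod) -
                   hh_derivatives(dn, params, mod)) / (up[j] - dn[j])
    }
    all(Re(eigen(J, only.values = TRUE)$values) < 0)
  }, logical(1))
  v_rest <- if (any(stable)) min(roots[stable]) else min(roots)
  state_at(v_rest)
}

#' Integrate the modified Hodgkin-Huxley model
#'
#' Fixed-step 4th-order Runge-Kutta integration of the membrane equation with
#' terahertz conductance scaling. Deterministic for fixed inputs; gating
#' variables are kept in [0, 1] at every sample. Integration failure
#' (non-finite membrane potential) raises an error naming the time of
#' divergence.
#'
#' @inheritParams hh_derivatives
#' @param protocol a [stimulus_protocol()] for the injected current.
#' @param T total duration, ms (>= dt).
#' @param dt integration and sampling step, ms (> 0; default 0.01).
#' @param init optional initial state `c(v, m, h, n)`; defaults to
#'   [resting_state()].
#' @param record_gating keep the sampled m, h, n alongside v.
#' @return An `hh_trace`: list with fields `t`, `v` (and `m`, `h`, `n` when
#'   recorded), `dt`, and the inputs used.
#' @examples
#' p <- hh_params()
#' tr <- simulate_hh(p, protocol = constant_stimulus(0, 50), T = 50)
#' range(tr$v)
#' @export
simulate_hh <- function(params, mod = conductance_modulation(),
                        protocol = constant_stimulus(0, T), T = 500,
                        dt = 0.01, init = NULL, record_gating = TRUE) {
  stopifnot(dt > 0, T >= dt)
  s <- conductance_scaling(mod)
  if (is.null(init)) init <- resting_state(params, mod)
  stopifnot(length(init) == 4)
  cpars <- list(C = params$C, gNa_max = params$gNa_max,
                gK_max = params$gK_max, gL = params$gL, vNa = params$vNa,
                vK = params$vK, vL = params$vL,
                k_gate_exponent = params$k_gate_exponent,
                leak_gated = params$leak_gated,
                rateset = if (params$rate_set == "classic") 0L else 1L,
                sK = s[["sK"]], sNa = s[["sNa"]])
  seg <- protocol$segments
  m <- .hh_simulate_cpp(as.numeric(init), cpars, seg$start, seg$duration,
                        seg$amplitude, T, dt, record_gating)
  out <- list(t = m[, 1], v = m[, 2], dt = dt, params = params, mod = mod,
              protocol = protocol)
  if (record_gating) {
    out$m <- m[, 3]; out$h <- m[, 4]; out$n <- m[, 5]
  }
  structure(out, class = "hh_trace")
}

#' @export
print.hh_trace <- function(x, ...) {
  cat(sprintf("<hh_trace> %d samples, dt=%g ms, %g ms total, v in [%.2f, %.2f] mV\n",
              length(x$t), x$dt, max(x$t), min(x$v), max(x$v)))
  invisible(x)
}

#' Coerce a membrane-potential trace to a data frame
#'
#' @param x an `hh_trace`.
#' @param ... unused.
#' @return data frame with columns `t_ms`, `v_mV` and, when recorded,
#'   `m`, `h`, `n`.
#' @export
as.data.frame.hh_trace <- function(x, ...) {
  d <- data.frame(t_ms = x$t, v_mV = x$v)
  for (g in c("m", "h", "n")) if (!is.null(x[[g]])) d[[g]] <- x[[g]]
  d
}
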