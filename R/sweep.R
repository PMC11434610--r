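#' Repetitive-firing (DC) threshold of the model
#'
#' Smallest constant injected current sustaining at least one spike in the
#' steady-state window of a constant-stimulus run, found by bisection. This
#' is the reference point for choosing a near-rheobase drive.
#'
#' @inheritParams simulate_hh
#' @param amp_range bisection bracket, µA/cm².
#' @param T,t0 run length and start of the steady-state window, ms.
#' @param tol amplitude tolerance, µA/cm².
#' @return threshold amplitude, µA/cm².
#' @export
dc_firing_threshold <- function(params, mod = conductance_modulation(),
                                amp_range = c(0, 5), T = 500, t0 = 100,
                                tol = 1e-4, dt = 0.01) {
  init <- resting_state(params, mod)
  fires <- function(a) {
    tr <- simulate_hh(params, mod, constant_stimulus(a, T), T = T, dt = dt,
                      init = init, record_gating = FALSE)
    sp <- detect_spikes(tr)
    any(sp$peak_time >= t0)
  }
  # Scan upward for the first sustaining amplitude (very strong drive can
  # fail to fire through depolarization block), then bisect below it.
  grid <- seq(amp_range[1], amp_range[2], length.out = 65)[-1]
  first <- NA_integer_
  for (i in seq_along(grid)) if (fires(grid[i])) { first <- i; break }
  if (is.na(first))
    stop("search bracket error: no amplitude in range sustains firing")
  lo <- if (first == 1) amp_range[1] else grid[first - 1]
  hi <- grid[first]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Sweep the potassium-conductance scale factor
#'
#' For each scale factor sK the model is started from its resting state
#' (recomputed under that scaling) and driven with a constant suprathreshold
#' current; the steady-state firing rate is counted over `[t0, T]` and the
#' FWHM of a representative (median) steady-state action potential is
#' measured under the threshold-baseline convention.
#'
#' @inheritParams simulate_hh
#' @param stim constant drive amplitude, µA/cm².
#' @param sK_grid scale factors to sweep.
#' @param T,t0 run length and steady-state window start, ms.
#' @return data frame with columns `sK`, `rate` (Hz), `fwhm` (ms; NA when no
#'   steady spike exists), `rmp` (resting potential at that scaling, mV).
#' @export
conductance_sweep <- function(params, stim, sK_grid = seq(1, 3, by = 0.01),
                              T = 5000, t0 = 500, dt = 0.01) {
  rows <- lapply(sK_grid, function(sK) {
    mod <- conductance_modulation(beta_K = sK - 1, intensity = 1)
    rest <- resting_state(params, mod)
    tr <- simulate_hh(params, mod, constant_stimulus(stim, T), T = T,
                      dt = dt, init = rest, record_gating = FALSE)
    sp <- detect_spikes(tr)
    steady <- sp[sp$peak_time >= t0, , drop = FALSE]
    fw <- NA_real_
    if (nrow(steady) > 0) {
      md <- steady[ceiling(nrow(steady) / 2), ]
      fw <- ap_features(tr, md)$fwhm
    }
    data.frame(sK = sK, rate = nrow(steady) / ((T - t0) / 1000), fwhm = fw,
               rmp = rest[["v"]])
  })
  do.call(rbind, rows)
}

#' Operating points of a conductance sweep
#'
#' Locates (on the sweep grid, among scale factors that still fire) the
#' point where the firing rate is nearest the target fraction of control and
#' reports the FWHM ratio there, and symmetrically the point where the FWHM
#' ratio is nearest the target percentage and reports the firing-rate
#' reduction there.
#'
#' @param sweep data frame from [conductance_sweep()].
#' @param rate_fraction target steady-rate fraction of control (default 0.30).
#' @param fwhm_percent target FWHM percentage of control (default 95).
#' @return list with `fwhm_percent_at_rate_target`,
#'   `rate_reduction_at_fwhm_target` (both percent), the scale factors
#'   `sK_rate`, `sK_fwhm`, and the control rate/FWHM.
#' @export
operating_points <- function(sweep, rate_fraction = 0.30,
                             fwhm_percent = 95) {
  ctrl_rate <- sweep$rate[1]
  ctrl_fwhm <- sweep$fwhm[1]
  if (ctrl_rate <= 0 || !is.finite(ctrl_fwhm))
    stop("control condition does not fire; choose a suprathreshold stimulus")
  ok <- which(sweep$rate > 0 & is.finite(sweep$fwhm))
  ratio <- sweep$rate / ctrl_rate
  fwr <- sweep$fwhm / ctrl_fwhm * 100
  i_rate <- ok[which.min(abs(ratio[ok] - rate_fraction))]
  i_fwhm <- ok[which.min(abs(fwr[ok] - fwhm_percent))]
  list(fwhm_percent_at_rate_target = fwr[i_rate],
       rate_reduction_at_fwhm_target = 100 * (1 - ratio[i_fwhm]),
       sK_rate = sweep$sK[i_rate], sK_fwhm = sweep$sK[i_fwhm],
       rate_ratio_at_rate_target = ratio[i_rate],
       fwhm_percent_at_fwhm_target = fwr[i_fwhm],
       control_rate = ctrl_rate, control_fwhm = ctrl_fwhm)
}

#' Firing-rate and FWHM operating points across model variants
#'
#' Runs the potassium-scaling sweep for the four readings of the membrane
#' equation (K gate exponent 1 or 4, leak gated or ohmic) under a
#' near-rheobase constant drive (`stim_rel` times each variant's own DC
#' firing threshold), and summarises the two operating points per variant.
#' Variants that are not excitable (no sustained firing at any tested drive)
#' are reported with NA operating points.
#'
#' @param rate_set rate-function family, see [hh_params()].
#' @param stim_rel drive relative to the control DC firing threshold.
#' @param sK_grid scale-factor grid.
#' @param T,t0,dt as in [conductance_sweep()].
#' @return data frame with one row per variant: flags, drive used, control
#'   rate, and the two operating-point percentages.
#' @export
variant_operating_summary <- function(rate_set = "traub", stim_rel = 1.07,
                                      sK_grid = seq(1, 3, by = 0.01),
                                      T = 5000, t0 = 500, dt = 0.01) {
  grid <- expand.grid(k_gate_exponent = c(4L, 1L),
                      leak_gated = c(FALSE, TRUE))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- hh_params(rate_set, k_gate_exponent = grid$k_gate_exponent[i],
                   leak_gated = grid$leak_gated[i])
    base <- data.frame(k_gate_exponent = grid$k_gate_exponent[i],
                       leak_gated = grid$leak_gated[i], stim = NA_real_,
                       control_rate = NA_real_,
                       fwhm_percent_at_rate_target = NA_real_,
                       rate_reduction_at_fwhm_target = NA_real_,
                       sK_rate = NA_real_, sK_fwhm = NA_real_)
    th <- tryCatch(dc_firing_threshold(p, amp_range = c(0, 200), dt = dt),
                   error = function(e) NA_real_)
    if (!is.finite(th)) return(base)
    stim <- stim_rel * th
    sw <- conductance_sweep(p, stim, sK_grid, T = T, t0 = t0, dt = dt)
    op <- tryCatch(operating_points(sw), error = function(e) NULL)
    if (is.null(op)) return(base)
    base$stim <- stim
    base$control_rate <- op$control_rate
    base$fwhm_percent_at_rate_target <- op$fwhm_percent_at_rate_target
    base$rate_reduction_at_fwhm_target <- op$rate_reduction_at_fwhm_target
    base$sK_rate <- op$sK_rate
    base$sK_fwhm <- op$sK_fwhm
    base
  })
  do.call(rbind, rows)
}

#' Select the variant best matching the reported operating point
#'
#' @param summary data frame from [variant_operating_summary()].
#' @param fwhm_target,reduction_target reported FWHM percentage and
#'   firing-rate reduction percentage of control.
#' @return the best-matching row of `summary`.
#' @export
best_variant <- function(summary, fwhm_target = 95, reduction_target = 70) {
  dev <- abs(summary$fwhm_percent_at_rate_target - fwhm_target) +
    abs(summary$rate_reduction_at_fwhm_target - reduction_target)
  if (all(!is.finite(dev))) stop("no excitable variant in summary")
  summary[which.min(dev), ]
}
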