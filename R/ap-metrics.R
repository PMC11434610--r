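#' Detect action potentials in a membrane-potential trace
#'
#' One spike event per upward crossing of `peak_threshold` followed by a
#' local maximum; events closer than `min_interval` to the previous kept
#' event are discarded. For each spike the AP threshold is located by
#' scanning backwards from the peak to the first sample of the upstroke,
#' defined as the contiguous region where dv/dt exceeds `dvdt_criterion`.
#'
#' @param trace an `hh_trace` (or any list with `t`, `v`, `dt`).
#' @param peak_threshold voltage that the upstroke must cross, mV (default 0).
#' @param min_interval minimum separation between spike peaks, ms (>= dt).
#' @param dvdt_criterion AP threshold criterion on dv/dt, mV/ms (default 20).
#' @return data frame with one row per spike: `peak_time`, `peak_v`,
#'   `threshold_time`, `threshold_v` and the sample indices `peak_index`,
#'   `threshold_index`. Zero rows for subthreshold traces.
#' @export
detect_spikes <- function(trace, peak_threshold = 0, min_interval = 2,
                          dvdt_criterion = 20) {
  t <- trace$t; v <- trace$v; dt <- trace$dt
  stopifnot(min_interval >= dt, length(v) >= 2)
  n <- length(v)
  cross <- which(v[-1] >= peak_threshold & v[-n] < peak_threshold)
  empty <- data.frame(peak_time = numeric(0), peak_v = numeric(0),
                      threshold_time = numeric(0), threshold_v = numeric(0),
                      peak_index = integer(0), threshold_index = integer(0))
  if (!length(cross)) return(empty)
  dv <- c(0, diff(v)) / dt
  rows <- lapply(cross, function(i) {
    k <- i
    while (k < n - 1 && v[k + 1] > v[k]) k <- k + 1
    j <- k
    while (j > 1 && dv[j] < dvdt_criterion) j <- j - 1
    while (j > 1 && dv[j] >= dvdt_criterion) j <- j - 1
    data.frame(peak_time = t[k], peak_v = v[k], threshold_time = t[j],
               threshold_v = v[j], peak_index = k, threshold_index = j)
  })
  out <- do.call(rbind, rows)
  keep <- !logical(nrow(out))
  last <- -Inf
  for (i in seq_len(nrow(out))) {
    if (out$peak_time[i] - last < min_interval) keep[i] <- FALSE
    else last <- out$peak_time[i]
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-action-potential waveform features
#'
#' Computes amplitude and width of a single detected AP. Width (FWHM /
#' half-width; the two names denote the same computation here) is the
#' duration the trace spends above the midpoint between a baseline and the
#' spike peak, with linearly interpolated crossing times. The default
#' baseline is the AP threshold voltage; `baseline = "rmp"` instead uses the
#' resting/pre-stimulus level supplied via `rmp_value`.
#'
#' @param trace an `hh_trace`.
#' @param spike one row of the data frame from [detect_spikes()].
#' @param baseline `"threshold"` (default) or `"rmp"`.
#' @param rmp_value resting potential, mV (required when `baseline = "rmp"`).
#' @return list with `fwhm` (ms), `half_width` (alias of `fwhm`), `amplitude`
#'   (mV), `threshold` (mV) and the convention used.
#' @export
ap_features <- function(trace, spike, baseline = c("threshold", "rmp"),
                        rmp_value = NULL) {
  baseline <- match.arg(baseline)
  t <- trace$t; v <- trace$v; dt <- trace$dt
  k <- spike$peak_index
  base_v <- if (baseline == "threshold") spike$threshold_v else {
    if (is.null(rmp_value)) stop("rmp_value required for baseline = 'rmp'")
    rmp_value
  }
  vpk <- spike$peak_v
  if (vpk <= base_v) stop("width undefined: spike peak at or below baseline")
  half <- (base_v + vpk) / 2
  il <- k; while (il > 1 && v[il] > half) il <- il - 1
  ir <- k; while (ir < length(v) && v[ir] > half) ir <- ir + 1
  if (v[il] > half || v[ir] > half)
    stop("width undefined: trace does not return below half level")
  tl <- t[il] + (half - v[il]) / (v[il + 1] - v[il]) * dt
  tr <- t[ir - 1] + (half - v[ir - 1]) / (v[ir] - v[ir - 1]) * dt
  list(fwhm = tr - tl, half_width = tr - tl,
       amplitude = vpk - spike$threshold_v, threshold = spike$threshold_v,
       peak_v = vpk, baseline = baseline, baseline_v = base_v)
}

#' Mean firing rate over a time window
#'
#' @param spike_times spike times, ms.
#' @param window `c(start, end)` in ms, end > start.
#' @return rate in Hz: spike count in the (closed) window divided by its
#'   length.
#' @export
firing_rate <- function(spike_times, window) {
  stopifnot(length(window) == 2, diff(window) > 0)
  sum(spike_times >= window[1] & spike_times <= window[2]) /
    (diff(window) / 1000)
}

#' Resting membrane potential from a pre-stimulus window
#'
#' @param trace an `hh_trace`.
#' @param window `c(start, end)` in ms; must lie inside the trace.
#' @return mean membrane potential over the window, mV.
#' @export
rmp <- function(trace, window) {
  stopifnot(length(window) == 2, diff(window) > 0)
  if (window[1] < min(trace$t) || window[2] > max(trace$t))
    stop("rmp window lies outside the trace")
  sel <- trace$t >= window[1] & trace$t <= window[2]
  mean(trace$v[sel])
}

#' Rheobase by bisection on a current pulse
#'
#' Smallest amplitude (to `resolution`) of a depolarizing current pulse that
#' elicits at least one spike, found by bisection between a subthreshold
#' lower and a suprathreshold upper bracket.
#'
#' @inheritParams simulate_hh
#' @param pulse_duration pulse length, ms (default 30).
#' @param amp_range `c(lo, hi)` bracket, µA/cm²; `hi` must elicit a spike.
#' @param resolution amplitude resolution, µA/cm².
#' @param dt integration step, ms.
#' @return rheobase amplitude, µA/cm².
#' @export
rheobase_search <- function(params, mod = conductance_modulation(),
                            pulse_duration = 30, amp_range = c(0, 5),
                            resolution = 0.005, dt = 0.01) {
  init <- resting_state(params, mod)
  spikes_at <- function(a) {
    pr <- stimulus_protocol(data.frame(start = 5, duration = pulse_duration,
                                       amplitude = a))
    tr <- simulate_hh(params, mod, pr, T = pulse_duration + 25, dt = dt,
                      init = init, record_gating = FALSE)
    nrow(detect_spikes(tr)) >= 1
  }
  lo <- amp_range[1]; hi <- amp_range[2]
  if (!spikes_at(hi))
    stop("search bracket error: upper amplitude elicits no spike")
  if (spikes_at(lo)) return(lo)
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    if (spikes_at(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Input-output (F-I) curve
#'
#' Spike count per step amplitude, each from a fresh deterministic
#' simulation of a constant current step.
#'
#' @inheritParams rheobase_search
#' @param amplitudes step amplitudes, µA/cm², sorted ascending.
#' @param duration step duration, ms.
#' @return data frame with columns `amplitude` and `count`, class
#'   `fi_curve`.
#' @export
fi_curve <- function(params, mod = conductance_modulation(), amplitudes,
                     duration = 500, dt = 0.01) {
  stopifnot(!is.unsorted(amplitudes, strictly = TRUE))
  init <- resting_state(params, mod)
  counts <- vapply(amplitudes, function(a) {
    tr <- simulate_hh(params, mod, constant_stimulus(a, duration),
                      T = duration, dt = dt, init = init,
                      record_gating = FALSE)
    nrow(detect_spikes(tr))
  }, numeric(1))
  structure(data.frame(amplitude = amplitudes, count = counts),
            class = c("fi_curve", "data.frame"))
}

#' Phase plot of a voltage trace
#'
#' Pairs the membrane potential with its central-difference derivative,
#' dropping the first and last samples.
#'
#' @param trace an `hh_trace` with at least 3 samples.
#' @return data frame with columns `v` (mV) and `dvdt` (mV/ms), of length
#'   `length(trace$v) - 2`.
#' @export
phase_plot <- function(trace) {
  v <- trace$v; n <- length(v)
  stopifnot(n >= 3)
  data.frame(v = v[2:(n - 1)],
             dvdt = (v[3:n] - v[1:(n - 2)]) / (2 * trace$dt))
}
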