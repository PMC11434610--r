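#' Poisson spike train with dead time
#'
#' Renewal process whose inter-spike intervals are a fixed refractory period
#' plus an exponential with the given hazard rate, so the expected count over
#' duration `T` is `rate * T / (1 + rate * refractory)`. Deterministic per
#' seed.
#'
#' @param rate hazard rate, Hz (>= 0).
#' @param duration train duration, s.
#' @param refractory dead time, ms.
#' @param seed RNG seed.
#' @return sorted spike times in ms; empty for `rate = 0`.
#' @export
gen_spike_train <- function(rate, duration, refractory = 2, seed = NULL) {
  stopifnot(rate >= 0, duration > 0)
  if (rate == 0) return(numeric(0))
  if (!is.null(seed)) set.seed(seed)
  times <- numeric(0)
  t <- 0
  repeat {
    n_draw <- max(64, ceiling(rate * duration * 1.5))
    isi <- refractory / 1000 + stats::rexp(n_draw, rate)
    tt <- t + cumsum(isi)
    times <- c(times, tt[tt < duration])
    if (tt[length(tt)] >= duration) break
    t <- tt[length(tt)]
  }
  times * 1000
}

#' Synthetic biphasic extracellular unit waveform
#'
#' Sum of a negative and a later positive Gaussian lobe. The trough-lobe
#' standard deviation is set from the requested half-width
#' (`sigma = half_width / (2 sqrt(2 ln 2))`), the positive lobe is placed
#' `trough_to_peak` later with 1.5x the width and 0.4x the depth, so a
#' noise-free round trip through [waveform_features()] recovers both
#' parameters to within one sample interval.
#'
#' @param trough_to_peak target trough-to-peak duration, µs (>= 2 sample
#'   intervals).
#' @param half_width target trough half-width, µs.
#' @param amplitude trough depth (positive number).
#' @param fs sampling rate, Hz (>= 20 kHz).
#' @param noise_sigma additive Gaussian noise sd, same units as amplitude.
#' @param seed RNG seed for the noise.
#' @return a [unit_waveform()].
#' @export
gen_waveform <- function(trough_to_peak = 600, half_width = 250,
                         amplitude = 1, fs = 30000, noise_sigma = 0,
                         seed = NULL) {
  stopifnot(fs >= 20000)
  dt_us <- 1e6 / fs
  if (trough_to_peak < 2 * dt_us)
    stop("resolution error: trough_to_peak below 2 sample intervals at fs")
  sig_t <- half_width / (2 * sqrt(2 * log(2)))
  sig_p <- 1.5 * sig_t
  t_tr <- max(4 * sig_t, 200)
  t_pk <- t_tr + trough_to_peak
  total <- t_pk + 4 * sig_p
  tt <- seq(0, total, by = dt_us)
  x <- -amplitude * exp(-(tt - t_tr)^2 / (2 * sig_t^2)) +
    0.4 * amplitude * exp(-(tt - t_pk)^2 / (2 * sig_p^2))
  if (noise_sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    x <- x + stats::rnorm(length(x), 0, noise_sigma)
  }
  unit_waveform(x, fs)
}

#' Configuration for a synthetic unit population
#'
#' Defaults emulate the recorded population structure: a bimodal
#' trough-to-peak distribution straddling the 430 µs classification
#' boundary (pyramidal mode 600 µs, interneuron mode 250 µs, sd 60 µs each),
#' pyramidal cells firing slower than interneurons, and per-condition
#' fractions of units whose firing rate decreases, increases or stays
#' unchanged after stimulation. The printed population fractions are the
#' defaults: sham 63.4/10.8/25.8 and SNI 61.8/20.3/17.9 percent
#' (decreased/increased/unchanged).
#'
#' @param n_pyr,n_int number of pyramidal / interneuron units.
#' @param condition `"sham"` or `"SNI"` (selects default fractions).
#' @param fractions named numeric `(decreased, increased, unchanged)`
#'   summing to 1; overrides the condition default.
#' @param pyr_rate,int_rate baseline rate distribution (mean, sd), Hz.
#' @param effect_decrease,effect_increase multiplicative post-epoch rate
#'   change for affected units.
#' @param ttp_modes trough-to-peak modes `(INT, PYR)`, µs.
#' @param ttp_sd mode standard deviation, µs.
#' @param epoch_duration pre and post epoch length, s.
#' @param seed RNG seed.
#' @return An object of class `population_config`.
#' @export
population_config <- function(n_pyr = 93, n_int = 15,
                              condition = c("sham", "SNI"),
                              fractions = NULL,
                              pyr_rate = c(mean = 4, sd = 2),
                              int_rate = c(mean = 12, sd = 4),
                              effect_decrease = 0.5, effect_increase = 2,
                              ttp_modes = c(INT = 250, PYR = 600),
                              ttp_sd = 60, epoch_duration = 300, seed = 1) {
  condition <- match.arg(condition)
  if (is.null(fractions)) {
    fractions <- if (condition == "sham")
      c(decreased = 0.634, increased = 0.108, unchanged = 0.258) else
      c(decreased = 0.618, increased = 0.203, unchanged = 0.179)
  }
  stopifnot(all(fractions >= 0), abs(sum(fractions) - 1) < 1e-6,
            all(c("decreased", "increased", "unchanged") %in%
                  names(fractions)))
  structure(list(n_pyr = n_pyr, n_int = n_int, condition = condition,
                 fractions = fractions, pyr_rate = pyr_rate,
                 int_rate = int_rate, effect_decrease = effect_decrease,
                 effect_increase = effect_increase, ttp_modes = ttp_modes,
                 ttp_sd = ttp_sd, epoch_duration = epoch_duration,
                 seed = seed),
            class = "population_config")
}

# Largest-remainder allocation of n units to the named fractions, so the
# population fractions equal the configured ones at any n.
.allocate_directions <- function(n, fractions) {
  if (n == 0) return(character(0))
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  rep(names(fractions), times = base)
}

#' Generate a synthetic unit population with ground truth
#'
#' Draws unit classes, waveform parameters, baseline rates and direction
#' labels from a [population_config()], then produces per-unit waveforms and
#' pre/post spike trains. Direction labels are allocated by largest-remainder
#' rounding of the configured fractions (then shuffled across units), so the
#' realised population fractions match the configuration at any n. Pure
#' function of (config, seed).
#'
#' @param cfg a [population_config()].
#' @return list with `units` (data frame of ground truth: unit_id, class,
#'   direction, true waveform parameters and rates), `waveforms` (list of
#'   [unit_waveform()]), `pre_spikes`, `post_spikes` (lists of ms spike
#'   times), `config`.
#' @export
gen_unit_population <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_pyr + cfg$n_int
  if (n == 0)
    return(list(units = data.frame(), waveforms = list(),
                pre_spikes = list(), post_spikes = list(), config = cfg))
  cls <- c(rep("PYR", cfg$n_pyr), rep("INT", cfg$n_int))
  dir_pyr <- sample(.allocate_directions(cfg$n_pyr, cfg$fractions))
  dir_int <- sample(.allocate_directions(cfg$n_int, cfg$fractions))
  direction <- c(dir_pyr, dir_int)
  is_pyr <- cls == "PYR"
  ttp <- stats::rnorm(n, ifelse(is_pyr, cfg$ttp_modes[["PYR"]],
                                cfg$ttp_modes[["INT"]]), cfg$ttp_sd)
  ttp <- pmax(ttp, 100)
  hw <- pmax(stats::rnorm(n, ifelse(is_pyr, 260, 130), 25), 60)
  base_rate <- pmax(stats::rnorm(n, ifelse(is_pyr, cfg$pyr_rate[["mean"]],
                                           cfg$int_rate[["mean"]]),
                                 ifelse(is_pyr, cfg$pyr_rate[["sd"]],
                                        cfg$int_rate[["sd"]])), 0.5)
  mult <- ifelse(direction == "decreased", cfg$effect_decrease,
                 ifelse(direction == "increased", cfg$effect_increase, 1))
  seeds <- sample.int(.Machine$integer.max %/% 4L, 3 * n)
  waveforms <- vector("list", n)
  pre <- vector("list", n)
  post <- vector("list", n)
  for (i in seq_len(n)) {
    waveforms[[i]] <- gen_waveform(ttp[i], hw[i], amplitude = 1,
                                   noise_sigma = 0.02, seed = seeds[i])
    pre[[i]] <- gen_spike_train(base_rate[i], cfg$epoch_duration,
                                seed = seeds[n + i])
    post[[i]] <- gen_spike_train(base_rate[i] * mult[i], cfg$epoch_duration,
                                 seed = seeds[2 * n + i])
  }
  units <- data.frame(unit_id = seq_len(n), class = cls,
                      direction = direction, ttp_true = ttp, hw_true = hw,
                      base_rate = base_rate, post_rate = base_rate * mult)
  list(units = units, waveforms = waveforms, pre_spikes = pre,
       post_spikes = post, config = cfg)
}

#' Synthetic voltage-clamp trace generation
#'
#' Thin wrapper around [run_voltage_clamp()] pairing a protocol preset with
#' a ground-truth channel model; with `noise_sigma = 0` the output is
#' identical to the noise-free clamp simulation.
#'
#' @param preset `"nav"`, `"kv"` or `"kleak"`.
#' @param channel a [channel_models] object; defaults to the matching
#'   channel type.
#' @param noise_sigma additive Gaussian noise sd.
#' @param seed RNG seed.
#' @param step_increment protocol step spacing, mV.
#' @return a `current_trace_set`.
#' @export
gen_current_traces <- function(preset = c("nav", "kv", "kleak"),
                               channel = NULL, noise_sigma = 0, seed = NULL,
                               step_increment = 10) {
  preset <- match.arg(preset)
  if (is.null(channel))
    channel <- switch(preset, nav = channel_nav(), kv = channel_kv(),
                      kleak = channel_leak())
  run_voltage_clamp(channel, make_protocol(preset, step_increment),
                    noise_sigma = noise_sigma, seed = seed)
}
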