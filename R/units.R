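#' Extracellular unit waveform container
#'
#' @param samples waveform samples (µV or normalized), one trough followed
#'   by one peak.
#' @param fs sampling rate, Hz.
#' @return An object of class `unit_waveform`.
#' @export
unit_waveform <- function(samples, fs) {
  stopifnot(is.numeric(samples), length(samples) >= 4, fs > 0)
  structure(list(samples = as.numeric(samples), fs = fs),
            class = "unit_waveform")
}

#' Waveform features of an extracellular unit
#'
#' The trough-to-peak duration is the time from the global negative trough
#' to the subsequent positive peak; the half-width is the width of the
#' trough lobe at half its depth below the baseline (the waveform median),
#' with linearly interpolated crossings. A waveform whose peak precedes its
#' trough violates the expected biphasic shape and raises an error.
#'
#' @param w a [unit_waveform()].
#' @return list with `trough_to_peak` (µs) and `half_width` (µs).
#' @export
waveform_features <- function(w) {
  x <- w$samples
  itr <- which.min(x)
  if (itr >= length(x)) stop("waveform shape error: no peak after trough")
  ipk <- itr + which.max(x[(itr + 1):length(x)])
  base <- stats::median(x)
  if (x[itr] >= base || x[ipk] <= base)
    stop("waveform shape error: expected a negative trough then a positive peak")
  if (max(x[1:itr]) > x[ipk])
    stop("waveform shape error: dominant peak precedes the trough")
  dt_us <- 1e6 / w$fs
  half <- (base + x[itr]) / 2
  il <- itr; while (il > 1 && x[il] < half) il <- il - 1
  ir <- itr; while (ir < length(x) && x[ir] < half) ir <- ir + 1
  if (x[il] < half || x[ir] < half)
    stop("waveform shape error: trough lobe not resolved at half depth")
  tl <- il + (half - x[il]) / (x[il + 1] - x[il])
  tr <- (ir - 1) + (half - x[ir - 1]) / (x[ir] - x[ir - 1])
  list(trough_to_peak = (ipk - itr) * dt_us, half_width = (tr - tl) * dt_us)
}

#' Classify units into pyramidal cells and interneurons
#'
#' Two methods mirroring standard practice: a fixed duration rule (putative
#' pyramidal cell iff trough-to-peak > 430 µs) and 2-means clustering on the
#' standardized feature triplet (trough-to-peak, half-width, mean rate),
#' labelling the cluster with the larger mean trough-to-peak as PYR (ties
#' broken by comparing cluster means against 430 µs).
#'
#' @param features data frame with columns `trough_to_peak` (µs),
#'   `half_width` (µs), `mean_rate` (Hz).
#' @param method `"threshold"` or `"kmeans"`.
#' @param seed RNG seed for the k-means restarts.
#' @param threshold_us duration rule boundary, µs.
#' @return character vector of labels, `"PYR"` or `"INT"`.
#' @export
classify_units <- function(features, method = c("threshold", "kmeans"),
                           seed = 1, threshold_us = 430) {
  method <- match.arg(method)
  if (method == "threshold")
    return(ifelse(features$trough_to_peak > threshold_us, "PYR", "INT"))
  if (nrow(features) < 2)
    stop("k-means classification requires at least 2 units")
  if (nrow(features) == 2) {
    # 2 points split trivially into one cluster each
    return(unname(ifelse(rank(features$trough_to_peak,
                              ties.method = "first") == 2, "PYR", "INT")))
  }
  x <- scale(as.matrix(features[, c("trough_to_peak", "half_width",
                                    "mean_rate")]))
  x[!is.finite(x)] <- 0 # constant features carry no information
  set.seed(seed)
  km <- stats::kmeans(x, centers = 2, nstart = 10)
  mu <- tapply(features$trough_to_peak, km$cluster, mean)
  pyr_cluster <- if (mu[1] == mu[2]) {
    which(abs(mu - threshold_us) == max(abs(mu - threshold_us)))[1]
  } else which.max(mu)
  unname(ifelse(km$cluster == as.integer(names(mu)[pyr_cluster]),
                "PYR", "INT"))
}

#' Inter-spike-interval histogram and refractory violations
#'
#' @param spike_times sorted spike times, ms.
#' @param bin_width histogram bin width, ms.
#' @param refractory refractory period, ms; intervals shorter than this are
#'   counted as violations.
#' @return list with `breaks`, `counts`, `isi` (the intervals, ms) and
#'   `violations`.
#' @export
isi_histogram <- function(spike_times, bin_width = 1, refractory = 2) {
  if (is.unsorted(spike_times)) stop("spike_times must be sorted")
  isi <- diff(spike_times)
  breaks <- seq(0, max(c(isi, bin_width)) + bin_width, by = bin_width)
  counts <- if (length(isi))
    graphics::hist(isi, breaks = breaks, plot = FALSE)$counts else
      integer(length(breaks) - 1)
  list(breaks = breaks, counts = counts, isi = isi,
       violations = sum(isi < refractory))
}

#' Pre/post stimulation firing-rate change
#'
#' Bins each epoch's spike times into fixed-width count bins and compares
#' the two count samples with a two-sided Wilcoxon rank-sum test. The unit
#' is called `increased` or `decreased` by the sign of the median (falling
#' back to mean) count difference when p < alpha, otherwise `unchanged`.
#'
#' @param pre_spikes,post_spikes spike times within each epoch, ms from
#'   epoch start.
#' @param duration epoch duration, s (same for both epochs).
#' @param bin_width bin width, s (default 1).
#' @param alpha two-sided significance level (default 0.05).
#' @return An object of class `rate_change`: list with `direction`,
#'   `p_value`, `pre_rate`, `post_rate` (Hz).
#' @export
rate_change <- function(pre_spikes, post_spikes, duration, bin_width = 1,
                        alpha = 0.05) {
  nbins <- floor(duration / bin_width)
  if (nbins < 10)
    stop("insufficient data: need at least 10 bins per epoch")
  edges <- seq(0, nbins * bin_width, by = bin_width) * 1000 # ms
  bin_counts <- function(st) {
    st <- st[st >= 0 & st < nbins * bin_width * 1000]
    tabulate(findInterval(st, edges), nbins)
  }
  pre <- bin_counts(pre_spikes)
  post <- bin_counts(post_spikes)
  p <- stats::wilcox.test(pre, post, exact = FALSE, correct = FALSE)$p.value
  if (is.nan(p)) p <- 1 # identical constant samples
  dirn <- "unchanged"
  if (p < alpha) {
    d <- stats::median(post) - stats::median(pre)
    if (d == 0) d <- mean(post) - mean(pre)
    dirn <- if (d > 0) "increased" else if (d < 0) "decreased" else
      "unchanged"
  }
  structure(list(direction = dirn, p_value = p,
                 pre_rate = mean(pre) / bin_width,
                 post_rate = mean(post) / bin_width),
            class = "rate_change")
}

#' @export
print.rate_change <- function(x, ...) {
  cat(sprintf("<rate_change> %s (p=%.3g): %.2f -> %.2f Hz\n",
              x$direction, x$p_value, x$pre_rate, x$post_rate))
  invisible(x)
}
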