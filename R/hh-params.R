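#' Parameters of the modified Hodgkin-Huxley cortical neuron model
#'
#' Bundles the constants of the conductance-based membrane equation
#' \deqn{C\,dv/dt = G_{stim} - s_{Na}\bar g_{Na} m^3 h (v - v_{Na})
#'       - s_K \bar g_K n^k (v - v_K) - I_{leak}}
#' where the leak current is either gated, \eqn{g_L n (v - v_L)}, or ohmic,
#' \eqn{g_L (v - v_L)}, and the potassium gate enters with exponent
#' \eqn{k \in \{1, 4\}}. The terahertz field acts on this model only through
#' the multiplicative scale factors of [conductance_modulation()].
#'
#' Two rate-function families are provided for the m and n gates. The
#' `"traub"` set (Traub-Miles cortical pyramidal cell) is the default: it is
#' type I excitable, i.e. its firing rate falls continuously to zero as drive
#' decreases or potassium conductance rises, which is the regime in which a
#' pure potassium-conductance enhancement can produce a large graded
#' firing-rate reduction. The `"classic"` squid-axon set is type II (firing
#' stops abruptly from a finite rate) and is kept for comparison. In both
#' families the inactivation gate h relaxes toward the fixed steady state
#' \eqn{h_\infty(v) = 1/(1 + \exp((v+60)/6.2))} with time constant
#' \eqn{1/(\alpha_h + \beta_h)} from the family's h rates.
#'
#' Default maximal conductances and reversal potentials are the canonical
#' values of the chosen rate family and may be overridden individually.
#'
#' @param rate_set `"traub"` (default) or `"classic"`.
#' @param C membrane capacitance, µF/cm².
#' @param gNa_max,gK_max,gL maximal conductances, mS/cm².
#' @param vNa,vK,vL reversal potentials (sodium, potassium, leak), mV.
#' @param k_gate_exponent potassium gate exponent, 1 or 4.
#' @param leak_gated logical; if `TRUE` the leak current is gated by n.
#' @return An object of class `hh_params`.
#' @examples
#' p <- hh_params()
#' p$gK_max
#' hh_params("classic", k_gate_exponent = 4)$vK
#' @export
hh_params <- function(rate_set = c("traub", "classic"),
                      C = 0.75,
                      gNa_max = NULL, gK_max = NULL, gL = NULL,
                      vNa = NULL, vK = NULL, vL = NULL,
                      k_gate_exponent = 4,
                      leak_gated = FALSE) {
  rate_set <- match.arg(rate_set)
  def <- if (rate_set == "traub") {
    list(gNa_max = 100, gK_max = 80, gL = 0.1, vNa = 50, vK = -100, vL = -67)
  } else {
    list(gNa_max = 120, gK_max = 36, gL = 0.3, vNa = 50, vK = -77, vL = -54.4)
  }
  p <- list(
    C = C,
    gNa_max = gNa_max %||% def$gNa_max,
    gK_max = gK_max %||% def$gK_max,
    gL = gL %||% def$gL,
    vNa = vNa %||% def$vNa,
    vK = vK %||% def$vK,
    vL = vL %||% def$vL,
    k_gate_exponent = as.integer(k_gate_exponent),
    leak_gated = isTRUE(leak_gated),
    rate_set = rate_set
  )
  if (p$C <= 0) stop("C must be > 0")
  if (p$gNa_max < 0 || p$gK_max < 0 || p$gL < 0)
    stop("conductances must be >= 0")
  if (!(p$vK < p$vL && p$vL < p$vNa))
    stop("reversal potentials must satisfy vK < vL < vNa")
  if (!p$k_gate_exponent %in% c(1L, 4L))
    stop("k_gate_exponent must be 1 or 4")
  structure(p, class = "hh_params")
}

#' @export
print.hh_params <- function(x, ...) {
  cat(sprintf(
    "<hh_params> rate_set=%s C=%g uF/cm2 gNa=%g gK=%g gL=%g mS/cm2\n",
    x$rate_set, x$C, x$gNa_max, x$gK_max, x$gL))
  cat(sprintf("  vNa=%g vK=%g vL=%g mV  K-gate n^%d  leak %s\n",
              x$vNa, x$vK, x$vL, x$k_gate_exponent,
              if (x$leak_gated) "gated (gL*n)" else "ohmic (gL)"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Terahertz-intensity dependent conductance scaling
#'
#' The terahertz field period (~28 fs at 36 THz) is ten orders of magnitude
#' below the membrane time scale, so the field enters the neuron model only
#' through its time-averaged intensity: potassium (and optionally sodium)
#' maximal conductance is multiplied by a scale factor that grows linearly
#' with intensity, `s = 1 + beta * intensity`. Resonant absorption by the
#' potassium channel makes `beta_K > 0` while the sodium conductance is
#' unaffected (`beta_Na = 0` by default). Intensity is in model-relative
#' units; `beta_K` is a calibration parameter.
#'
#' @param beta_K linear potassium scaling coefficient per unit intensity.
#' @param beta_Na linear sodium scaling coefficient (default 0).
#' @param intensity applied field intensity (model units, >= 0).
#' @return An object of class `conductance_modulation`.
#' @examples
#' conductance_scaling(conductance_modulation(beta_K = 0.5, intensity = 1))
#' @export
conductance_modulation <- function(beta_K = 0, beta_Na = 0, intensity = 0) {
  if (intensity < 0) stop("intensity must be >= 0")
  mod <- structure(list(beta_K = beta_K, beta_Na = beta_Na,
                        intensity = intensity),
                   class = "conductance_modulation")
  conductance_scaling(mod) # validates the resulting factors
  mod
}

#' Conductance scale factors implied by a modulation
#'
#' @param mod a [conductance_modulation()].
#' @return Named numeric vector `c(sK, sNa)`, each >= 0; both equal 1 at zero
#'   intensity.
#' @export
conductance_scaling <- function(mod) {
  sK <- 1 + mod$beta_K * mod$intensity
  sNa <- 1 + mod$beta_Na * mod$intensity
  if (sK < 0 || sNa < 0)
    stop("modulation parameters yield a negative conductance scale factor")
  c(sK = sK, sNa = sNa)
}

#' Terahertz field description and waveform
#'
#' The stimulating field is a plane-polarized cosine,
#' \eqn{E(t) = A\,u\,\cos(\omega t + \phi)} with \eqn{\omega = 2\pi\nu}.
#' It is used for reporting and for deriving the (time-averaged) intensity
#' that drives [conductance_modulation()]; it is never injected into the
#' membrane equation as an oscillatory drive.
#'
#' @param A field amplitude (model units).
#' @param nu frequency in THz (> 0); 36 THz is the potassium-channel
#'   resonance.
#' @param phi phase, radians.
#' @param u polarization unit 3-vector.
#' @return An object of class `thz_field`.
#' @examples
#' f <- thz_field(A = 1, nu = 36)
#' thz_field_waveform(f, t = 0)
#' @export
thz_field <- function(A = 1, nu = 36, phi = 0, u = c(0, 0, 1)) {
  if (nu <= 0) stop("nu must be > 0 (THz)")
  if (length(u) != 3 || abs(sqrt(sum(u^2)) - 1) > 1e-8)
    stop("u must be a unit 3-vector")
  structure(list(A = A, nu = nu, phi = phi, u = u), class = "thz_field")
}

#' @rdname thz_field
#' @param field a [thz_field()].
#' @param t time in seconds (finite).
#' @return `thz_field_waveform`: scalar field value along `u`,
#'   `A * cos(2*pi*nu*1e12*t + phi)`.
#' @export
thz_field_waveform <- function(field, t) {
  stopifnot(all(is.finite(t)))
  field$A * cos(2 * pi * field$nu * 1e12 * t + field$phi)
}

#' Angular frequency of a terahertz field
#'
#' @param field a [thz_field()].
#' @return omega = 2*pi*nu in rad/s.
#' @export
thz_angular_frequency <- function(field) 2 * pi * field$nu * 1e12

#' Injected-current stimulus protocol
#'
#' An ordered set of non-overlapping current segments defining
#' \eqn{G_{stim}(t)}; outside all segments the injected current is zero.
#'
#' @param segments data frame with columns `start` (ms), `duration` (ms) and
#'   `amplitude` (µA/cm²).
#' @return An object of class `stimulus_protocol`.
#' @examples
#' stimulus_protocol(data.frame(start = 10, duration = 30, amplitude = 2))
#' constant_stimulus(0.26, 500)
#' @export
stimulus_protocol <- function(segments) {
  stopifnot(is.data.frame(segments),
            all(c("start", "duration", "amplitude") %in% names(segments)))
  if (any(segments$duration < 0)) stop("segment durations must be >= 0")
  if (nrow(segments) > 1) {
    o <- order(segments$start)
    s <- segments[o, ]
    if (any(s$start[-1] < (s$start + s$duration)[-nrow(s)]))
      stop("stimulus segments must not overlap")
  }
  structure(list(segments = segments), class = "stimulus_protocol")
}

#' @rdname stimulus_protocol
#' @param amplitude constant current amplitude, µA/cm².
#' @param T total duration, ms.
#' @export
constant_stimulus <- function(amplitude, T) {
  stimulus_protocol(data.frame(start = 0, duration = T, amplitude = amplitude))
}

#' Stimulus amplitude at given times
#'
#' @param protocol a [stimulus_protocol()].
#' @param t times, ms.
#' @return numeric vector of injected current, µA/cm².
#' @export
stimulus_at <- function(protocol, t) {
  seg <- protocol$segments
  out <- numeric(length(t))
  for (j in seq_len(nrow(seg)))
    out <- out + ifelse(t >= seg$start[j] & t < seg$start[j] + seg$duration[j],
                        seg$amplitude[j], 0)
  out
}
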