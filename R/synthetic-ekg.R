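#' Synthetic EKG trace with known R-peak times
#'
#' Lays one smooth biphasic QRS-like pulse (a Ricker / Mexican-hat template
#' of ~80 ms support) at each cumulative RR time and adds Gaussian noise.
#' The true peak sample indices are returned so detector accuracy can be
#' measured exactly.
#'
#' @param rr_plan vector of inter-beat intervals in seconds (all > 0); beat
#'   `i` occurs at `cumsum(rr_plan)[i]` seconds.
#' @param fs sampling rate in Hz. Must resolve the pulse: `fs > 4 /
#'   qrs_width_s`.
#' @param peak_amplitude peak height in microvolts. The default (12000) sits
#'   comfortably above the conventional 7500 uV detection floor, as real
#'   chest-lead R-peaks do.
#' @param noise_sd additive Gaussian noise SD (uV).
#' @param seed RNG seed for the noise.
#' @param qrs_width_s total support of the QRS template in seconds.
#' @param pad_s silence appended after the last beat (s).
#' @return list with `trace` (an [ekg_trace()]), `peak_indices` (true peak
#'   sample indices) and `peak_times` (seconds).
#' @export
generate_ekg <- function(rr_plan, fs = 250, peak_amplitude = 12000,
                         noise_sd = 0, seed = NULL, qrs_width_s = 0.08,
                         pad_s = 0.5) {
  if (any(rr_plan <= 0)) stop_sub("all RR intervals must be positive")
  if (fs <= 4 / qrs_width_s) {
    stop_sub("`fs` too low to resolve the QRS template (need fs > ",
             4 / qrs_width_s, " Hz)")
  }
  check_seed(seed)
  peak_times <- cumsum(rr_plan)
  peak_idx <- as.integer(round(peak_times * fs)) + 1L
  n <- ceiling((peak_times[length(peak_times)] + pad_s) * fs)
  x <- numeric(n)
  # Ricker pulse: (1 - u^2) exp(-u^2 / 2), u = t/a; support ~ +/- 3a
  a <- qrs_width_s / 6
  half <- ceiling(3 * a * fs)
  u <- ((-half):half) / (a * fs)
  template <- peak_amplitude * (1 - u^2) * exp(-u^2 / 2)
  for (p in peak_idx) {
    lo <- max(1L, p - half)
    hi <- min(n, p + half)
    x[lo:hi] <- x[lo:hi] + template[(lo - p + half + 1L):(hi - p + half + 1L)]
  }
  if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
  list(trace = ekg_trace(x, fs = fs),
       peak_indices = peak_idx,
       peak_times = peak_times)
}

#' Planned RR intervals from a per-volume bpm series
#'
#' Walks through the scan emitting beats whose instantaneous RR equals
#' 60/bpm of the volume the beat falls in; used to turn the cohort's
#' planned heart-rate truth into an EKG beat plan.
#'
#' @param bpm numeric vector, one planned bpm value per fMRI volume.
#' @param tr_seconds volume duration (s).
#' @return numeric vector of RR intervals covering the whole scan.
#' @export
rr_plan_from_bpm <- function(bpm, tr_seconds = 2) {
  if (any(bpm <= 0)) stop_sub("planned bpm must be positive")
  duration <- length(bpm) * tr_seconds
  t <- 0
  rr <- numeric(0)
  while (t < duration) {
    vol <- min(length(bpm), floor(t / tr_seconds) + 1L)
    step <- 60 / bpm[vol]
    rr <- c(rr, step)
    t <- t + step
  }
  rr
}
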