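#' EKG voltage trace
#'
#' @param samples numeric vector of voltages in microvolts.
#' @param fs sampling rate (Hz).
#' @param t0 start time in seconds relative to scan start.
#' @return object of class `ekg_trace`.
#' @export
ekg_trace <- function(samples, fs, t0 = 0) {
  if (fs <= 0) stop_sub("`fs` must be positive")
  if (length(samples) < 2) stop_sub("trace must contain at least 2 samples")
  structure(list(samples = as.numeric(samples), fs = fs, t0 = t0),
            class = "ekg_trace")
}

#' @export
print.ekg_trace <- function(x, ...) {
  cat("<ekg_trace> ", length(x$samples), " samples at ", x$fs, " Hz (",
      round(length(x$samples) / x$fs, 1), " s)\n", sep = "")
  invisible(x)
}

#' Half-wave rectification: clamp negative voltages to zero
#'
#' Improves R-peak detection by discarding the negative deflections of the
#' QRS complex. Idempotent; length and sampling rate unchanged.
#'
#' @param trace an [ekg_trace()].
#' @return rectified [ekg_trace()].
#' @export
rectify_trace <- function(trace) {
  trace$samples <- pmax(trace$samples, 0)
  trace
}

# Squared-magnitude frequency responses of the MODWT-rescaled Daubechies-4
# analysis filters, evaluated at angular frequencies `w`. These satisfy
# |G|^2 + |H|^2 = 1 exactly, which makes the multiresolution band transfer
# telescope to unity over all levels (perfect reconstruction).
d4_sq_responses <- function(w) {
  s3 <- sqrt(3)
  g <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2)) / sqrt(2)
  h <- c(g[4], -g[3], g[2], -g[1])
  E <- exp(-1i * outer(w, 0:3))
  list(G2 = Mod(E %*% g)^2, H2 = Mod(E %*% h)^2)
}

# Zero-phase transfer function of the selected MODWT detail levels (plus
# smooth if it intersects the band), at the N DFT frequencies.
modwt_band_transfer <- function(n, fs, band, max_level = 30L) {
  J <- max(1L, min(max_level, as.integer(ceiling(log2(fs / band[1])) - 1L)))
  wk <- 2 * pi * (seq_len(n) - 1) / n
  # level-j filters are the base filters upsampled by 2^(j-1): response at
  # 2^(j-1) * w (mod 2*pi)
  G2 <- matrix(0, n, J)
  H2 <- matrix(0, n, J)
  for (j in seq_len(J)) {
    r <- d4_sq_responses((2^(j - 1) * wk) %% (2 * pi))
    G2[, j] <- r$G2
    H2[, j] <- r$H2
  }
  transfer <- numeric(n)
  cumG <- rep(1, n)
  for (j in seq_len(J)) {
    lo <- fs / 2^(j + 1)
    hi <- fs / 2^j
    if (lo < band[2] && hi > band[1]) transfer <- transfer + cumG * H2[, j]
    cumG <- cumG * G2[, j]
  }
  if (fs / 2^(J + 1) > band[1]) transfer <- transfer + cumG  # smooth level
  transfer
}

#' Wavelet band enhancement of an EKG trace
#'
#' Reconstructs the trace from the MODWT (Daubechies-4) multiresolution
#' detail levels whose nominal pass-bands intersect `band`, attenuating
#' energy outside the band. The filter is applied as a zero-phase transfer
#' function (squared-magnitude responses), so peak locations of an isolated
#' QRS pulse are preserved exactly. Selecting the full Nyquist range
#' reproduces the input (perfect reconstruction).
#'
#' @param trace an [ekg_trace()].
#' @param band numeric length-2 frequency interval in Hz, within
#'   `(0, fs/2)`. Default 5-32 Hz, the conventional QRS energy band.
#' @return filtered [ekg_trace()] of identical length.
#' @export
wavelet_enhance <- function(trace, band = c(5, 32)) {
  fs <- trace$fs
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1] || band[2] > fs / 2) {
    stop_sub("`band` must satisfy 0 < low < high <= fs/2 = ", fs / 2, " Hz")
  }
  x <- trace$samples
  n <- length(x)
  m <- stats::nextn(n, c(2, 3, 5))  # composite length keeps the FFT fast
  tr <- modwt_band_transfer(m, fs, band)
  xp <- c(x, numeric(m - n))
  trace$samples <- Re(fft(fft(xp) * tr, inverse = TRUE))[seq_len(n)] / m
  trace
}

#' R-peak series
#' @param peak_indices strictly increasing sample indices.
#' @param fs sampling rate of the trace the peaks were detected on.
#' @param t0 trace start time (s).
#' @param min_distance minimum inter-beat distance used at detection (s).
#' @return object of class `r_peaks`.
#' @export
r_peaks <- function(peak_indices, fs, t0 = 0, min_distance = NA_real_) {
  peak_indices <- as.integer(peak_indices)
  if (is.unsorted(peak_indices, strictly = TRUE)) {
    stop_sub("`peak_indices` must be strictly increasing")
  }
  structure(list(peak_indices = peak_indices,
                 peak_times = (peak_indices - 1) / fs + t0,
                 fs = fs, t0 = t0, min_distance = min_distance),
            class = "r_peaks")
}

#' @export
print.r_peaks <- function(x, ...) {
  cat("<r_peaks> ", length(x$peak_indices), " peaks", sep = "")
  if (length(x$peak_times) > 1) {
    cat(", mean RR ", round(mean(diff(x$peak_times)), 3), " s", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Constrained R-peak detection
#'
#' Local maxima at or above `min_height`, pruned so that no two retained
#' peaks are closer than `min_distance`: conflicting peaks are resolved in
#' favor of the larger amplitude, ties in favor of the earlier index
#' (findpeaks-style semantics, made deterministic). The defaults are the
#' conventional values for wavelet-enhanced chest-lead EKG: 7500 uV minimum
#' height and 0.45 s minimum inter-beat distance.
#'
#' @param trace a rectified/enhanced [ekg_trace()].
#' @param min_height minimum peak height (uV).
#' @param min_distance minimum inter-beat distance (s).
#' @return an [r_peaks()] series; empty (with a warning) when no sample
#'   qualifies.
#' @export
detect_r_peaks <- function(trace, min_height = 7500, min_distance = 0.45) {
  x <- trace$samples
  n <- length(x)
  rising <- c(FALSE, diff(x) > 0)
  falling <- c(diff(x) < 0, FALSE)
  # first sample of each plateau-top counts as the peak
  plateau <- c(diff(x) == 0, FALSE)
  cand <- which(rising & (falling | plateau))
  cand <- cand[sapply(cand, function(i) {
    j <- i
    while (j < n && x[j + 1] == x[i]) j <- j + 1
    j == n || x[j + 1] < x[i]
  })]
  cand <- cand[x[cand] >= min_height]
  if (!length(cand)) {
    warning("no R-peaks detected (over-thresholded or flat trace)")
    return(r_peaks(integer(0), fs = trace$fs, t0 = trace$t0,
                   min_distance = min_distance))
  }
  ord <- cand[order(-x[cand], cand)]
  keep <- logical(n)
  min_gap <- min_distance * trace$fs
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= min_gap)) {
      kept <- c(kept, i)
    }
  }
  r_peaks(sort(kept), fs = trace$fs, t0 = trace$t0, min_distance = min_distance)
}

#' Instantaneous heart rate as a step function
#'
#' Between successive R-peaks i and j the instantaneous heart rate is
#' `60 / RR_ij` bpm, where `RR_ij` is the inter-peak interval in seconds.
#' The step function is sampled on a regular grid (default 250 Hz). Before
#' the first and after the last peak the nearest RR value is extended, so
#' the series has no missing values at the scan edges.
#'
#' @param peaks an [r_peaks()] series with at least two peaks.
#' @param fs_out output sampling rate (Hz).
#' @param duration_s duration of the output grid in seconds (default: up to
#'   the last peak).
#' @return list of class `hr_step` with `bpm` and `fs`.
#' @export
instantaneous_hr <- function(peaks, fs_out = 250, duration_s = NULL) {
  tp <- peaks$peak_times
  if (length(tp) < 2) stop_sub("insufficient beats: need at least 2 R-peaks")
  rr <- diff(tp)
  duration_s <- duration_s %||% tp[length(tp)]
  t <- seq(0, duration_s - 1 / fs_out, by = 1 / fs_out)
  iv <- findInterval(t, tp)              # 0 before first peak
  iv <- pmin(pmax(iv, 1L), length(rr))   # extend nearest RR at the edges
  structure(list(bpm = 60 / rr[iv], fs = fs_out), class = "hr_step")
}

#' Resample instantaneous heart rate onto the fMRI volume grid
#'
#' One value per volume: the mean of the instantaneous heart rate within the
#' volume's non-overlapping `tr_seconds` window (0.5 Hz for the default
#' TR = 2 s). A window containing no HR samples is marked missing (`NA`).
#'
#' @param hr an `hr_step` from [instantaneous_hr()].
#' @param tr_seconds repetition time (s).
#' @param n_volumes number of volumes to emit (default: as many full
#'   windows as the series covers).
#' @return list of class `hr_series` with `bpm` (length `n_volumes`),
#'   `volume` and `tr_seconds`.
#' @export
resample_hr <- function(hr, tr_seconds = 2, n_volumes = NULL) {
  spv <- tr_seconds * hr$fs   # samples per volume
  n_volumes <- n_volumes %||% floor(length(hr$bpm) / spv)
  if (n_volumes < 1) stop_sub("HR series does not cover a full TR window")
  vol <- floor((seq_along(hr$bpm) - 1) / spv) + 1
  bpm <- rep(NA_real_, n_volumes)
  means <- tapply(hr$bpm, vol, mean)
  idx <- as.integer(names(means))
  ok <- idx >= 1 & idx <= n_volumes
  bpm[idx[ok]] <- as.numeric(means[ok])
  structure(list(bpm = bpm, volume = seq_len(n_volumes),
                 tr_seconds = tr_seconds),
            class = "hr_series")
}

#' Mean heart rate during a substate
#'
#' Averages the volume-aligned bpm series over the volumes assigned to
#' `state`, restricted to the pre-injection, post-injection, or whole-scan
#' period. Missing volumes are excluded.
#'
#' @param hr an `hr_series` from [resample_hr()].
#' @param affiliation per-volume substate labels (same volume grid).
#' @param state substate label to average over.
#' @param period `"all"`, `"pre"` or `"post"`.
#' @param injection_volume last pre-injection volume (required for
#'   `"pre"`/`"post"`).
#' @return mean bpm (scalar).
#' @export
mean_hr_in_state <- function(hr, affiliation, state,
                             period = c("all", "pre", "post"),
                             injection_volume = NULL) {
  period <- match.arg(period)
  labels <- as.integer(affiliation)
  nv <- min(length(hr$bpm), length(labels))
  vols <- seq_len(nv)
  if (period != "all") {
    if (is.null(injection_volume)) {
      stop_sub("`injection_volume` needed for period '", period, "'")
    }
    vols <- if (period == "pre") vols[vols <= injection_volume] else vols[vols > injection_volume]
  }
  vols <- vols[labels[vols] == state & !is.na(hr$bpm[vols])]
  if (!length(vols)) {
    stop_sub("state ", state, " does not occur in the ", period, " period (empty selection)")
  }
  mean(hr$bpm[vols])
}

#' Full EKG-to-heart-rate chain
#'
#' Decimates the trace to `work_fs` (anti-aliased) when recorded at a higher
#' rate, rectifies, applies the wavelet band enhancement, detects R-peaks
#' with the height/distance constraints, converts inter-beat intervals to
#' instantaneous heart rate, and averages onto the fMRI volume grid.
#'
#' @param trace an [ekg_trace()] at any sampling rate (a rate above
#'   `work_fs` must be an integer multiple of it).
#' @param tr_seconds,n_volumes fMRI volume grid.
#' @param min_height,min_distance peak-detection constraints (uV, s).
#' @param band wavelet enhancement band (Hz).
#' @param work_fs internal detection rate (Hz), default 250.
#' @return list with `hr` (an `hr_series`), `peaks` (the [r_peaks()]) and
#'   `qc` (number of peaks, fraction of missing volumes).
#' @export
derive_heart_rate <- function(trace, tr_seconds = 2, n_volumes = NULL,
                              min_height = 7500, min_distance = 0.45,
                              band = c(5, 32), work_fs = 250) {
  if (trace$fs > work_fs) {
    q <- trace$fs / work_fs
    if (abs(q - round(q)) > 1e-9) {
      stop_sub("`fs` (", trace$fs, ") must be an integer multiple of work_fs (",
               work_fs, ")")
    }
    trace <- ekg_trace(signal::decimate(trace$samples, round(q), ftype = "fir"),
                       fs = work_fs, t0 = trace$t0)
  }
  duration <- length(trace$samples) / trace$fs
  enhanced <- wavelet_enhance(rectify_trace(trace), band = band)
  peaks <- detect_r_peaks(enhanced, min_height = min_height,
                          min_distance = min_distance)
  hr250 <- instantaneous_hr(peaks, fs_out = work_fs, duration_s = duration)
  hr <- resample_hr(hr250, tr_seconds = tr_seconds, n_volumes = n_volumes)
  list(hr = hr, peaks = peaks,
       qc = list(n_peaks = length(peaks$peak_indices),
                 pct_missing = mean(is.na(hr$bpm)) * 100))
}

#' Read an EKG trace from CSV
#'
#' Accepts either two columns `time_s, voltage_uV` (sampling rate inferred
#' from the time grid) or a single `voltage_uV` column with `fs` supplied.
#'
#' @param path CSV file.
#' @param fs sampling rate, required for single-column files.
#' @return an [ekg_trace()].
#' @export
read_ekg_csv <- function(path, fs = NULL) {
  d <- read.csv(path)
  if (all(c("time_s", "voltage_uV") %in% names(d))) {
    dt <- diff(d$time_s)
    if (any(dt <= 0)) stop_sub("time_s must be strictly increasing in ", path)
    ekg_trace(d$voltage_uV, fs = 1 / median(dt), t0 = d$time_s[1])
  } else if ("voltage_uV" %in% names(d)) {
    if (is.null(fs)) stop_sub("`fs` required when ", path, " has no time_s column")
    ekg_trace(d$voltage_uV, fs = fs)
  } else {
    stop_sub(path, ": expected columns (time_s, voltage_uV) or (voltage_uV)")
  }
}

#' Write a volume-aligned heart-rate series to CSV
#' @param hr an `hr_series`.
#' @param path output CSV with columns `volume_index, bpm`.
#' @export
write_hr_csv <- function(hr, path) {
  write.csv(data.frame(volume_index = hr$volume, bpm = hr$bpm),
            path, row.names = FALSE)
  invisible(path)
}
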