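test_that("rectification clamps negatives, is idempotent, matches oracle", {
  tr <- ekg_trace(c(-5, 3, -1), fs = 250)
  expect_equal(rectify_trace(tr)$samples, c(0, 3, 0))
  pos <- ekg_trace(c(0, 2, 5), fs = 250)
  expect_identical(rectify_trace(pos)$samples, pos$samples)
  set.seed(2)
  x <- rnorm(500, sd = 100)
  r1 <- rectify_trace(ekg_trace(x, fs = 250))
  expect_equal(r1$samples, vapply(x, function(v) max(v, 0), numeric(1)))
  expect_identical(rectify_trace(r1)$samples, r1$samples)  # idempotent
})

test_that("wavelet enhancement passes the QRS band and rejects slow drift", {
  fs <- 250
  t <- (0:9999) / fs
  slow <- ekg_trace(sin(2 * pi * 1 * t), fs = fs)
  out <- wavelet_enhance(slow, band = c(5, 32))
  expect_lt(sd(out$samples) / sd(slow$samples), 0.10)
  # isolated QRS pulse: peak location preserved within one sample
  ek <- generate_ekg(5, fs = fs, noise_sd = 0)  # single beat at 5 s
  enh <- wavelet_enhance(ek$trace, band = c(5, 32))
  expect_lte(abs(which.max(enh$samples) - ek$peak_indices[1]), 1)
  # full-band reconstruction is the identity
  full <- wavelet_enhance(slow, band = c(1e-9, fs / 2))
  rms_err <- sqrt(mean((full$samples - slow$samples)^2))
  expect_lt(rms_err / sqrt(mean(slow$samples^2)), 1e-6)
  expect_error(wavelet_enhance(slow, band = c(5, 200)), "fs/2")
  expect_error(wavelet_enhance(slow, band = c(-1, 30)), "band")
})

test_that("peak detection enforces height and inter-beat constraints", {
  fs <- 250
  # two triangular peaks 0.3 s apart, heights 9000 and 8000
  x <- numeric(2 * fs)
  mk_peak <- function(x, at, h) {
    x[(at - 2):(at + 2)] <- h * c(0.2, 0.6, 1, 0.6, 0.2)
    x
  }
  x <- mk_peak(x, 100, 9000)
  x <- mk_peak(x, 100 + 0.3 * fs, 8000)
  pk <- detect_r_peaks(ekg_trace(x, fs = fs))
  expect_identical(pk$peak_indices, 100L)
  # a 7000 uV peak falls below the conventional floor
  x2 <- mk_peak(numeric(fs), 100, 7000)
  expect_warning(pk2 <- detect_r_peaks(ekg_trace(x2, fs = fs)), "no R-peaks")
  expect_length(pk2$peak_indices, 0)
  # exactly at the floor counts
  x3 <- mk_peak(numeric(fs), 100, 7500)
  expect_identical(detect_r_peaks(ekg_trace(x3, fs = fs))$peak_indices, 100L)
  # equal-height conflict resolves to the earlier peak
  x4 <- mk_peak(numeric(fs), 50, 9000)
  x4 <- mk_peak(x4, 50 + 0.3 * fs, 9000)
  expect_identical(detect_r_peaks(ekg_trace(x4, fs = fs))$peak_indices, 50L)
})

test_that("clean synthetic beats are recovered exactly; close beats merge", {
  ek <- generate_ekg(rep(c(0.8, 1.0, 1.2), 20), fs = 250, noise_sd = 0)
  enh <- wavelet_enhance(rectify_trace(ek$trace))
  pk <- detect_r_peaks(enh)
  expect_identical(pk$peak_indices, ek$peak_indices)
  # alternating 1.0 / 0.4 s: each 0.4 s follower is merged away
  ek2 <- generate_ekg(rep(c(1.0, 0.4), 10), fs = 250, noise_sd = 0)
  pk2 <- detect_r_peaks(wavelet_enhance(rectify_trace(ek2$trace)))
  expect_length(pk2$peak_indices, 10)
  expect_true(all(diff(pk2$peak_times) >= 0.45))
  expect_true(all(vapply(pk2$peak_indices, function(i) {
    min(abs(i - ek2$peak_indices)) == 0
  }, logical(1))))
})

test_that("instantaneous heart rate is 60/RR as a step function", {
  mk_pk <- function(times, fs = 250) r_peaks(round(times * fs) + 1L, fs = fs)
  hr1 <- instantaneous_hr(mk_pk(c(1, 2, 3)))
  expect_true(all(hr1$bpm == 60))
  hr2 <- instantaneous_hr(mk_pk(c(1, 1.5, 2)))
  expect_true(all(hr2$bpm == 120))
  # 0.45 s RR lands on the sample grid at 1 kHz
  hr3 <- instantaneous_hr(r_peaks(c(451L, 901L), fs = 1000), duration_s = 0.9)
  expect_equal(unique(hr3$bpm), 60 / 0.45, tolerance = 1e-9)
  expect_error(instantaneous_hr(mk_pk(1)), "insufficient beats")
  # edge extension: samples before the first peak carry the first RR
  hr4 <- instantaneous_hr(mk_pk(c(2, 3)), duration_s = 4)
  expect_true(all(hr4$bpm == 60))
})

test_that("volume resampling averages within non-overlapping TR windows", {
  const <- structure(list(bpm = rep(60, 1000), fs = 250), class = "hr_step")
  rs <- resample_hr(const, tr_seconds = 2)
  expect_equal(rs$bpm, rep(60, 2))
  half <- structure(list(bpm = c(rep(60, 250), rep(120, 250)), fs = 250),
                    class = "hr_step")
  expect_equal(resample_hr(half, tr_seconds = 2)$bpm, 90)
  # full-scan trace covers one value per volume
  rr <- rep(1, 1700)
  ek <- generate_ekg(rr, fs = 250, noise_sd = 0)
  dh <- derive_heart_rate(ek$trace, tr_seconds = 2, n_volumes = 840)
  expect_length(dh$hr$bpm, 840)
  expect_true(all(abs(dh$hr$bpm - 60) < 1e-9))
  expect_equal(dh$qc$pct_missing, 0)
})

test_that("constant-RR chain resamples to a constant 60/RR series", {
  for (rr in c(0.6, 0.75, 1.0)) {
    ek <- generate_ekg(rep(rr, ceiling(120 / rr)), fs = 250, noise_sd = 0)
    dh <- derive_heart_rate(ek$trace, tr_seconds = 2, n_volumes = 55)
    expect_true(all(abs(dh$hr$bpm - 60 / rr) < 0.75),
                label = paste("rr =", rr))
  }
})

test_that("state-restricted heart-rate means match planted modulation", {
  hr <- structure(list(bpm = rep(70, 100), volume = 1:100, tr_seconds = 2),
                  class = "hr_series")
  affl <- rep(c(1L, 2L), 50)
  expect_equal(mean_hr_in_state(hr, affl, 1, "all"), 70)
  hr2 <- structure(list(bpm = c(60, 80, 100, 100), volume = 1:4,
                        tr_seconds = 2), class = "hr_series")
  expect_equal(mean_hr_in_state(hr2, c(1L, 1L, 2L, 2L), 1, "all"), 70)
  expect_error(mean_hr_in_state(hr2, c(1L, 1L, 2L, 2L), 1, "post",
                                injection_volume = 2), "empty selection")
  # planted +12 bpm during post-injection state 4 survives the full chain
  nv <- 120; inj <- 40
  labels <- plan_labels(balanced_substate_plan(nv, inj, 5), nv)
  bpm_dmt <- rep(65, nv)
  bpm_dmt[labels == 4 & seq_len(nv) > inj] <- 65 + 12
  chain <- function(bpm) {
    ek <- generate_ekg(rr_plan_from_bpm(bpm, 2), fs = 250, noise_sd = 0)
    derive_heart_rate(ek$trace, tr_seconds = 2, n_volumes = nv)$hr
  }
  m_dmt <- mean_hr_in_state(chain(bpm_dmt), labels, 4, "post",
                            injection_volume = inj)
  m_pcb <- mean_hr_in_state(chain(rep(65, nv)), labels, 4, "post",
                            injection_volume = inj)
  expect_lt(abs((m_dmt - m_pcb) - 12), 1)
})

test_that("high-rate traces are decimated before detection", {
  ek <- generate_ekg(rep(1, 30), fs = 1000, noise_sd = 0)
  dh <- derive_heart_rate(ek$trace, tr_seconds = 2, n_volumes = 14)
  expect_true(all(abs(dh$hr$bpm - 60) < 0.5))
  expect_error(derive_heart_rate(ekg_trace(rnorm(1000), fs = 333)),
               "integer multiple")
})

test_that("EKG CSV readers handle both layouts and reject malformed files", {
  d <- tempfile(fileext = ".csv")
  write.csv(data.frame(time_s = (0:99) / 250, voltage_uV = rnorm(100)), d,
            row.names = FALSE)
  tr <- read_ekg_csv(d)
  expect_equal(tr$fs, 250, tolerance = 1e-6)
  d2 <- tempfile(fileext = ".csv")
  write.csv(data.frame(voltage_uV = rnorm(50)), d2, row.names = FALSE)
  expect_error(read_ekg_csv(d2), "fs")
  expect_equal(length(read_ekg_csv(d2, fs = 500)$samples), 50)
  d3 <- tempfile(fileext = ".csv")
  write.csv(data.frame(a = 1:5), d3, row.names = FALSE)
  expect_error(read_ekg_csv(d3), "expected columns")
})
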