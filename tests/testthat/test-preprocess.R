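# Nuisance/task regression, the double-gamma HRF, zero-phase bandpass,
# Gaussian smoothing, and motion QC.

mk_ts <- function(values, tr = 1, runs = NULL) {
  nt <- dim(values)[4]
  if (is.null(runs)) runs <- list(c(1, nt))
  bold_timeseries(values, tr, runs)
}

sine_ts <- function(f, n = 660, tr = 1) {
  mk_ts(array(sin(2 * pi * f * (0:(n - 1)) * tr), c(1, 1, 1, n)), tr)
}

rms <- function(x) sqrt(mean(x^2))

zero_conf <- function(nt) {
  confound_set(matrix(0, nt, 6), numeric(nt), numeric(nt), numeric(nt))
}

test_that("double-gamma HRF has canonical shape", {
  h <- hrf_double_gamma(0.1)
  expect_equal(h[1], 0)
  peak_t <- (which.max(h) - 1) * 0.1
  expect_gte(peak_t, 4)
  expect_lte(peak_t, 8)
  expect_equal(max(h), 1)
  auc <- sum(h) * 0.1
  expect_gt(auc, 0)
  expect_lt(auc, max(h) * 32)
})

test_that("confound regression annihilates regressors and evoked signal", {
  set.seed(1)
  nt <- 132
  conf <- confound_set(matrix(rnorm(nt * 6, sd = 0.01), nt, 6),
                       rnorm(nt), rnorm(nt), rnorm(nt))
  task <- default_task_design(n_baseline_runs = 0, n_image_runs = 2)
  # voxel 1 equals the global signal; voxel 2 is evoked + band-limited signal
  h <- hrf_double_gamma(1)
  box <- c(scpm:::run_boxcar(task, 1, 0, 66, 1),
           scpm:::run_boxcar(task, 2, 66, 66, 1))
  evoked <- convolve(c(box, numeric(length(h))), rev(h),
                     type = "open")[seq_len(nt)]
  s_bg <- scpm:::band_limited_signal(nt, 1, c(0.01, 0.1))
  vals <- array(rnorm(4 * nt), c(2, 2, 1, nt))
  vals[1, 1, 1, ] <- conf$global
  vals[2, 1, 1, ] <- evoked + s_bg
  ts <- mk_ts(vals, runs = list(c(1, 66), c(67, 132)))
  res <- confound_regress(ts, conf, task)
  expect_lt(max(abs(res$values[1, 1, 1, ])), 1e-8)
  expect_lt(abs(cor(res$values[2, 1, 1, ], evoked)), 0.01)
  # residuals orthogonal to every regressor within each run
  for (run in 1:2) {
    rows <- if (run == 1) 1:66 else 67:132
    X <- scpm:::build_design(conf, task, run, rows, (run - 1) * 66, 1)
    r <- res$values[2, 2, 1, rows]
    dots <- abs(crossprod(X, r))
    norms <- sqrt(colSums(X^2)) * sqrt(sum(r^2))
    expect_true(all(dots <= 1e-8 * pmax(norms, 1)))
  }
})

test_that("regression followed by bandpass is a linear operator", {
  set.seed(2)
  nt <- 66
  conf <- confound_set(matrix(rnorm(nt * 6, sd = 0.01), nt, 6),
                       rnorm(nt), rnorm(nt), rnorm(nt))
  task <- default_task_design(0, 1)
  stagepair <- function(v) {
    ts <- mk_ts(array(v, c(1, 1, 1, nt)))
    bandpass(confound_regress(ts, conf, task))$values
  }
  a <- rnorm(nt)
  b <- rnorm(nt)
  expect_lt(max(abs(stagepair(a + b) - (stagepair(a) + stagepair(b)))), 1e-8)
})

test_that("bandpass attenuates the stimulus frequency and passes the band", {
  expect_lt(rms(bandpass(sine_ts(0.17))$values) / rms(sine_ts(0.17)$values),
            0.10)
  expect_gt(rms(bandpass(sine_ts(0.05))$values) / rms(sine_ts(0.05)$values),
            0.90)
  const <- mk_ts(array(7, c(1, 1, 1, 66)))
  expect_lt(max(abs(bandpass(const)$values)), 1e-6 * 7)
  short <- mk_ts(array(rnorm(10), c(1, 1, 1, 10)))
  expect_error(bandpass(short), "run 1")
})

test_that("gaussian smoothing hits the target FWHM and respects identities", {
  vol <- array(0, c(31, 31, 31))
  vol[16, 16, 16] <- 1
  sm <- gaussian_smooth_vol(vol, fwhm_mm = 6, voxel_mm = 2)
  prof <- sm[, 16, 16]
  xs_mm <- (1:31 - 16) * 2
  # Gaussian fit via second moment of the (positive) profile
  fwhm_est <- 2 * sqrt(2 * log(2)) * sqrt(sum(prof * xs_mm^2) / sum(prof))
  expect_lt(abs(fwhm_est - 6) / 6, 0.05)

  ts <- mk_ts(array(rnorm(5 * 5 * 5 * 4), c(5, 5, 5, 4)))
  expect_identical(gaussian_smooth(ts, 0)$values, ts$values)
  const <- mk_ts(array(3.5, c(6, 6, 6, 2)))
  expect_equal(gaussian_smooth(const, 6)$values, const$values,
               tolerance = 1e-12)
})

test_that("framewise displacement flags exactly the injected high-motion run", {
  nt <- 8 * 66
  runs <- lapply(1:8, function(r) c((r - 1) * 66 + 1, r * 66))
  mot <- matrix(0, nt, 6)
  expect_equal(framewise_displacement(mot), rep(0, nt))
  mot_off <- mot
  mot_off[, 1] <- 2.5  # constant offset: no frame-to-frame change
  expect_equal(framewise_displacement(mot_off), rep(0, nt))

  # run 4 gets alternating 2.0 mm translation jumps
  mot_bad <- mot
  rows4 <- runs[[4]][1]:runs[[4]][2]
  mot_bad[rows4, 1] <- rep(c(0, 2), length.out = length(rows4))
  conf <- confound_set(mot_bad, numeric(nt), numeric(nt), numeric(nt))
  ts <- mk_ts(array(rnorm(nt), c(1, 1, 1, nt)), runs = runs)
  qc <- suppressMessages(qc_exclude_runs(ts, conf, threshold_mm = 1.5))
  expect_identical(qc$excluded, 4L)
  expect_identical(qc$retained, setdiff(1:8, 4L))

  conf_all_bad <- confound_set(matrix(rep(c(0, 3), length.out = nt), nt, 6),
                               numeric(nt), numeric(nt), numeric(nt))
  expect_error(suppressMessages(
    qc_exclude_runs(ts, conf_all_bad, threshold_mm = 1.5)), "all runs")
})
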