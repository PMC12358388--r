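test_that("extract_aif averages mask voxels at frame mid-times", {
  spec <- phantom_spec(shape = c(16, 16, 6), noise_level = 0, seed = 1)
  ph <- make_phantom(spec)
  study <- simulate_study(ph)
  # uniform study -> constant curve
  ustudy <- study
  ustudy$data[] <- 7.5
  cv <- extract_aif(ustudy, ph$rois$artery)
  expect_equal(cv$activity, rep(7.5, study$schedule$n))
  expect_equal(cv$times_s, study$schedule$mid)
  # single-voxel mask -> that voxel's TAC
  m1 <- array(FALSE, dim(ph$labels))
  idx <- which(ph$rois$artery)[1]
  m1[idx] <- TRUE
  cv1 <- extract_aif(study, m1)
  flat <- matrix(study$data, nrow = prod(dim(ph$labels)))
  expect_equal(cv1$activity, flat[idx, ])
  # phantom artery recovers the generating AIF's frame averages (noiseless)
  cva <- extract_aif(study, ph$rois$artery)
  tg <- seq(0, study$schedule$end[study$schedule$n], by = 1)
  truth <- frame_average(tg, phantom_aif(tg, spec$aif_params), study$schedule)
  expect_equal(cva$activity, truth, tolerance = 1e-10)
  # errors
  expect_error(extract_aif(study, array(FALSE, dim(ph$labels))), "empty")
  expect_error(extract_aif(study, array(TRUE, c(2, 2, 2))), "geometry")
})

test_that("fit_aif recovers a noiseless mono-exponential tail to 0.1%", {
  fs <- default_frame_schedule()
  t_s <- fs$mid
  A <- 5e4; r <- 0.12                      # min^-1; tail anchored at the
  t_pk <- 35                               # peak *sample* (a frame mid-time)
  rise <- pmin(pmax((t_s - 10) / (t_pk - 10), 0), 1)
  tail <- A * exp(-r * pmax(t_s - t_pk, 0) / 60)
  y <- ifelse(t_s < t_pk, rise * A * 0.999, tail)
  fit <- fit_aif(arterial_curve(t_s, y), n_exp = 1)
  expect_equal(sum(fit$A), A, tolerance = 1e-3)
  expect_equal(fit$r, r, tolerance = 1e-3)
})

test_that("fit_aif is deterministic and rejects peakless curves", {
  fs <- default_frame_schedule()
  t_s <- fs$mid
  y <- t_s                                  # monotone: max at last sample
  expect_error(fit_aif(arterial_curve(t_s, y)), "peak")
  tg <- seq(0, fs$end[fs$n], by = 1)
  curve <- arterial_curve(fs$mid, frame_average(tg, phantom_aif(tg), fs))
  f1 <- fit_aif(curve)
  f2 <- fit_aif(curve)
  expect_identical(f1$A, f2$A)
  expect_identical(f1$r, f2$r)
})

test_that("fit_aif on the phantom bi-exponential: AUC within 2% of truth", {
  fs <- default_frame_schedule()
  tg <- seq(0, fs$end[fs$n], by = 1)
  p <- default_aif_params()
  curve <- arterial_curve(fs$mid, frame_average(tg, phantom_aif(tg, p), fs))
  fit <- fit_aif(curve, n_exp = 2)
  # analytic AUC of the generator over the scan window (minutes * Bq/mL)
  peak <- sum(p$A)
  rise_auc <- peak * (p$t_peak_s - p$t_arrival_s) / 2 / 60
  span_min <- (fs$end[fs$n] - p$t_peak_s) / 60
  tail_auc <- sum(p$A / p$r * (1 - exp(-p$r * span_min)))
  truth <- rise_auc + tail_auc
  # fitted model AUC over the same window by fine quadrature
  yy <- predict_aif(fit, tg)
  got <- cumtrapz(tg / 60, yy)[length(tg)]
  expect_equal(got, truth, tolerance = 0.02)
})

test_that("therapy_auc closed forms and identity scaling", {
  # single-exponential fit from t = 0: A/r (1 - exp(-r H)) with no decay
  fit <- structure(list(t_arrival = 0, t_peak = 0, A = 1000, r = 0.05,
                        n_exp = 1, scan_end_s = 1330), class = "aif_fit")
  H <- 3600 * 10
  expect_equal(therapy_auc(fit, 0, 0, 1, 1, H),
               1000 / (0.05 / 60) * (1 - exp(-0.05 / 60 * H)),
               tolerance = 1e-12)
  # identity scaling: lam_diag = lam_ther, equal activities -> plain AUC
  lam <- decay_constant_per_min(6.67)
  expect_equal(therapy_auc(fit, lam, lam, 2, 2, H),
               therapy_auc(fit, 0, 0, 1, 1, H), tolerance = 1e-12)
})

test_that("therapy_auc equals brute-force 1-s quadrature at phantom settings", {
  fs <- default_frame_schedule()
  tg <- seq(0, fs$end[fs$n], by = 1)
  curve <- arterial_curve(fs$mid, frame_average(tg, phantom_aif(tg), fs))
  fit <- fit_aif(curve, n_exp = 2)
  lam_d <- decay_constant_per_min(109.77 / (24 * 60))   # F-18
  lam_t <- decay_constant_per_min(6.67)                 # Lu-177
  H <- 5 * 6.0 * 24 * 3600                              # ~5 eff. half-lives
  got <- therapy_auc(fit, lam_d, lam_t, 0.325, 7.4, H)
  # oracle: evaluate the decay-swapped scaled curve on a 1-s grid
  tg_full <- seq(0, H, by = 1)
  y <- predict_aif(fit, tg_full) *
    exp((lam_d - lam_t) * tg_full / 60) * (7.4 / 0.325)
  oracle <- cumtrapz(tg_full, y)[length(tg_full)]
  expect_equal(got, oracle, tolerance = 1e-3)
  # magnitude matches the clinically reported arterial AUC range
  expect_gt(got, 1.0e8); expect_lt(got, 2.0e8)
})

test_that("therapy_auc is linear in activity and amplitudes, monotone in horizon", {
  fit <- structure(list(t_arrival = 10, t_peak = 30, A = c(2e4, 1.5e3),
                        r = c(0.35, 0.03), n_exp = 2, scan_end_s = 1330),
                   class = "aif_fit")
  lam_d <- decay_constant_per_min(109.77 / (24 * 60))
  lam_t <- decay_constant_per_min(6.67)
  H <- 2e6
  a1 <- therapy_auc(fit, lam_d, lam_t, 0.325, 7.4, H)
  expect_equal(therapy_auc(fit, lam_d, lam_t, 0.325, 14.8, H), 2 * a1)
  fit2 <- fit; fit2$A <- fit$A * 3
  expect_equal(therapy_auc(fit2, lam_d, lam_t, 0.325, 7.4, H), 3 * a1,
               tolerance = 1e-12)
  hs <- c(2e5, 5e5, 1e6, 2e6, Inf)
  aucs <- sapply(hs, function(h) therapy_auc(fit, lam_d, lam_t, 0.325, 7.4, h))
  expect_true(all(diff(aucs) >= 0))
  # horizon at 5 T_eff is within 3% of the infinite-horizon value
  r_bio <- min(fit$r) - lam_d
  t_eff_min <- effective_half_life(log(2) / lam_t, log(2) / r_bio)
  a5 <- therapy_auc(fit, lam_d, lam_t, 0.325, 7.4, 5 * t_eff_min * 60)
  expect_lt((aucs[length(aucs)] - a5) / aucs[length(aucs)], 0.03)
  # population override of the slowest terminal rate changes only the tail
  a_pop <- therapy_auc(fit, lam_d, lam_t, 0.325, 7.4, H, r_pop = 0.06)
  expect_lt(a_pop, a1)
  expect_error(therapy_auc(fit, lam_d, lam_t, 0.325, 7.4, 100), "horizon")
  expect_error(therapy_auc(fit, lam_d, lam_t, 0, 7.4, H), "activities")
})

test_that("arterial curve and fit serialize round-trip", {
  cv <- arterial_curve(c(5, 15, 25), c(0, 100, 80), source = "test")
  f <- tempfile(fileext = ".csv")
  write_arterial_curve(cv, f)
  cv2 <- read_arterial_curve(f)
  expect_equal(cv2$times_s, cv$times_s)
  expect_equal(cv2$activity, cv$activity)
  fit <- structure(list(t_arrival = 10, t_peak = 30, A = c(2e4, 1.5e3),
                        r = c(0.35, 0.03), n_exp = 2, scan_end_s = 1330),
                   class = "aif_fit")
  fj <- tempfile(fileext = ".json")
  write_aif_fit(fit, fj)
  fit2 <- read_aif_fit(fj)
  expect_equal(fit2$A, fit$A)
  expect_equal(fit2$r, fit$r)
  expect_equal(predict_aif(fit2, c(0, 20, 30, 600)),
               predict_aif(fit, c(0, 20, 30, 600)))
  expect_error(arterial_curve(c(1, 1, 2), c(0, 1, 2)), "increasing")
  expect_error(arterial_curve(c(1, 2), c(-1, 1)), ">= 0")
})
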