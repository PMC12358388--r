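#' Arterial input curve container
#'
#' @param times_s sample times, seconds, strictly increasing.
#' @param activity activity concentration, Bq mL^-1, non-negative.
#' @param source free-text provenance (e.g. "right common iliac artery").
#' @return object of class `arterial_curve`.
#' @export
arterial_curve <- function(times_s, activity, source = "unknown") {
  if (length(times_s) != length(activity)) stop("length mismatch")
  if (any(diff(times_s) <= 0)) stop("times must be strictly increasing")
  if (any(activity < 0)) stop("activities must be >= 0")
  structure(list(times_s = as.numeric(times_s),
                 activity = as.numeric(activity),
                 source = source),
            class = "arterial_curve")
}

#' @export
print.arterial_curve <- function(x, ...) {
  cat(sprintf("arterial_curve: %d samples over [%g, %g] s, peak %.3g Bq/mL (%s)\n",
              length(x$times_s), min(x$times_s), max(x$times_s),
              max(x$activity), x$source))
  invisible(x)
}

#' Read/write an arterial curve as two-column CSV
#'
#' Columns `time_s`, `activity_Bq_per_mL`.
#' @param curve an [arterial_curve()].
#' @param path CSV file path.
#' @export
write_arterial_curve <- function(curve, path) {
  stopifnot(inherits(curve, "arterial_curve"))
  utils::write.csv(
    data.frame(time_s = curve$times_s, activity_Bq_per_mL = curve$activity),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_arterial_curve
#' @param source provenance string attached on read.
#' @export
read_arterial_curve <- function(path, source = path) {
  d <- utils::read.csv(path)
  arterial_curve(d$time_s, d$activity_Bq_per_mL, source = source)
}

#' Extract an image-derived arterial input function
#'
#' Averages the time-activity curves of all voxels inside an arterial mask
#' (e.g. the common iliac artery), one sample per frame at the frame
#' mid-time. No partial-volume correction is applied.
#'
#' @param study a `dynamic_study` (see [simulate_study()]).
#' @param artery_mask logical array congruent with the study grid.
#' @return an [arterial_curve()].
#' @export
extract_aif <- function(study, artery_mask) {
  stopifnot(inherits(study, "dynamic_study"))
  dims <- dim(study$data)
  if (!identical(dim(artery_mask), dims[1:3]))
    stop("artery mask geometry does not match the study")
  idx <- which(artery_mask)
  if (length(idx) == 0) stop("artery mask is empty")
  nvox <- prod(dims[1:3])
  mat <- matrix(study$data, nrow = nvox)        # voxels x frames
  vals <- colMeans(mat[idx, , drop = FALSE])
  arterial_curve(study$schedule$mid, vals,
                 source = sprintf("image-derived, %d voxels", length(idx)))
}

# Evaluate the fitted AIF model at times t (seconds):
# 0 before bolus arrival, linear rise to the peak, exponential-sum tail
# A_i exp(-r_i (t - t_peak)) after the peak. Rates r_i are per minute.
.aif_model_eval <- function(fit, t_s) {
  peak_val <- sum(fit$A)
  y <- numeric(length(t_s))
  rise <- t_s > fit$t_arrival & t_s < fit$t_peak
  if (fit$t_peak > fit$t_arrival)
    y[rise] <- peak_val * (t_s[rise] - fit$t_arrival) / (fit$t_peak - fit$t_arrival)
  tail <- t_s >= fit$t_peak
  dt_min <- (t_s[tail] - fit$t_peak) / 60
  y[tail] <- colSums(fit$A * exp(-outer(fit$r, dt_min)))
  y
}

#' Evaluate a fitted AIF at arbitrary times
#'
#' @param fit an `aif_fit` from [fit_aif()].
#' @param t_s times in seconds.
#' @return modeled activity, Bq mL^-1.
#' @export
predict_aif <- function(fit, t_s) {
  stopifnot(inherits(fit, "aif_fit"))
  .aif_model_eval(fit, t_s)
}

#' Fit an exponential-sum model to an arterial curve
#'
#' The model is a linear rise from bolus arrival to the peak sample followed
#' by a sum of `n_exp` decaying exponentials from the peak. Fitting is by
#' multi-start bounded quasi-Newton least squares on the tail (peak to scan
#' end); 16 deterministic starts seeded from log-spaced rate guesses, best
#' residual sum of squares wins, ties broken toward the lower start index.
#'
#' @param curve an [arterial_curve()].
#' @param n_exp number of tail exponentials (1, 2 or 3; default 2 — three is
#'   unidentifiable on a 28-frame 22-min acquisition).
#' @param n_starts multi-start budget (default 16).
#' @return object of class `aif_fit`: `t_arrival`, `t_peak` (s), amplitudes
#'   `A` (Bq mL^-1, summing to the peak value), rates `r` (min^-1, sorted
#'   decreasing), `rss`, `n_tail`.
#' @export
fit_aif <- function(curve, n_exp = 2, n_starts = 16) {
  stopifnot(inherits(curve, "arterial_curve"))
  if (!n_exp %in% 1:3) stop("n_exp must be 1, 2 or 3")
  n <- length(curve$times_s)
  if (n < 2 * n_exp + 2) stop("too few samples for the requested model")
  ipk <- which.max(curve$activity)
  if (ipk == n) stop("no detectable peak: maximum at the last sample")
  t_peak <- curve$times_s[ipk]
  peak_val <- curve$activity[ipk]
  if (peak_val <= 0) stop("curve is identically zero")
  # bolus arrival: last pre-peak sample below 5% of peak, else first sample
  pre <- which(curve$times_s < t_peak & curve$activity <= 0.05 * peak_val)
  t_arrival <- if (length(pre)) max(curve$times_s[pre]) else
    max(0, curve$times_s[1])
  tt <- (curve$times_s[ipk:n] - t_peak) / 60     # tail times, minutes
  yy <- curve$activity[ipk:n]
  if (length(tt) < 2 * n_exp) stop("tail too short for n_exp exponentials")

  obj <- function(p) {
    A <- exp(p[1:n_exp]); r <- exp(p[(n_exp + 1):(2 * n_exp)])
    pred <- colSums(A * exp(-outer(r, tt)))
    sum((pred - yy)^2)
  }
  # deterministic start grid: rates log-spaced over plausible clearance
  # (0.005 - 2 min^-1), amplitudes split the peak value
  base_rates <- exp(seq(log(0.005), log(2), length.out = 8))
  starts <- list()
  for (i in seq_len(n_starts)) {
    ri <- sort(base_rates[((i - 1 + seq_len(n_exp) * 2) %% 8) + 1],
               decreasing = TRUE)
    Ai <- rep(peak_val / n_exp, n_exp) * (0.5 + 0.1 * (i %% 5))
    starts[[i]] <- c(log(pmax(Ai, 1e-9)), log(ri))
  }
  best <- NULL
  for (s in starts) {
    res <- tryCatch(
      stats::optim(s, obj, method = "Nelder-Mead",
                   control = list(maxit = 4000, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(res)) {
      res <- tryCatch(
        stats::optim(res$par, obj, method = "BFGS",
                     control = list(maxit = 1000, reltol = 1e-14)),
        error = function(e) res)
    }
    if (!is.null(res) && (is.null(best) || res$value < best$value - 1e-12))
      best <- res
  }
  if (is.null(best)) stop("AIF fit failed to converge after multi-start budget")
  A <- exp(best$par[1:n_exp]); r <- exp(best$par[(n_exp + 1):(2 * n_exp)])
  o <- order(r, decreasing = TRUE)
  A <- A[o]; r <- r[o]
  # rescale amplitudes so the model is continuous at the peak sample
  A <- A * peak_val / sum(A)
  fit <- structure(list(t_arrival = t_arrival, t_peak = t_peak,
                        A = A, r = r, n_exp = n_exp,
                        rss = best$value, n_tail = length(tt),
                        scan_end_s = max(curve$times_s)),
                   class = "aif_fit")
  fit
}

#' @export
print.aif_fit <- function(x, ...) {
  cat(sprintf("aif_fit: arrival %g s, peak %g s, %d exponentials\n",
              x$t_arrival, x$t_peak, x$n_exp))
  for (i in seq_len(x$n_exp))
    cat(sprintf("  A%d = %.4g Bq/mL, r%d = %.4g min^-1\n", i, x$A[i], i, x$r[i]))
  cat(sprintf("  tail RSS %.4g over %d frames\n", x$rss, x$n_tail))
  invisible(x)
}

#' Serialize an AIF fit to JSON
#' @param fit an `aif_fit`.
#' @param path output path.
#' @export
write_aif_fit <- function(fit, path) {
  stopifnot(inherits(fit, "aif_fit"))
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_aif_fit
#' @export
read_aif_fit <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "aif_fit")
}

# analytic integral of (a + b t) * exp(-q t) over [t0, t1]; q may be 0
.lin_exp_integral <- function(a, b, q, t0, t1) {
  if (abs(q) < 1e-14) {
    return(a * (t1 - t0) + b * (t1^2 - t0^2) / 2)
  }
  F <- function(t) -exp(-q * t) * (a + b * t + b / q) / q
  F(t1) - F(t0)
}

#' Therapy-scaled arterial AUC
#'
#' Converts the fitted diagnostic arterial curve into the predicted
#' therapeutic arterial time-integral: the measured tracer's physical decay
#' is removed (multiply by exp(+lam_diag t)), the therapeutic nuclide's decay
#' applied (exp(-lam_ther t)), and the curve scaled by the ratio of
#' administered activities. Integration is fully analytic, piecewise over
#' the zero segment, the linear rise and the exponential tail, so no
#' numeric quadrature error enters the extrapolation beyond the scan window.
#'
#' @param fit an `aif_fit` from [fit_aif()].
#' @param lam_diag decay constant of the diagnostic nuclide, min^-1.
#' @param lam_ther decay constant of the therapeutic nuclide, min^-1.
#' @param A_diag administered diagnostic activity, GBq.
#' @param A_ther administered therapeutic activity, GBq.
#' @param horizon_s integration horizon, seconds (conventionally five
#'   effective half-lives of the therapeutic radioligand); `Inf` allowed.
#' @param r_pop optional population terminal clearance rate, min^-1,
#'   overriding the slowest fitted rate beyond the scan window (default NULL:
#'   keep the fitted rate).
#' @return AUC in Bq s mL^-1.
#' @export
therapy_auc <- function(fit, lam_diag, lam_ther, A_diag, A_ther,
                        horizon_s, r_pop = NULL) {
  stopifnot(inherits(fit, "aif_fit"))
  if (A_diag <= 0 || A_ther <= 0) stop("administered activities must be > 0")
  if (horizon_s < fit$scan_end_s) stop("horizon must be >= scan span")
  scale <- A_ther / A_diag
  dlam <- (lam_ther - lam_diag) / 60   # net extra decay rate, s^-1
  total <- 0
  peak_val <- sum(fit$A)
  # linear rise segment: y(t) = m (t - t_arrival), times in seconds
  if (fit$t_peak > fit$t_arrival) {
    m <- peak_val / (fit$t_peak - fit$t_arrival)
    total <- total + .lin_exp_integral(-m * fit$t_arrival, m, dlam,
                                       fit$t_arrival, min(fit$t_peak, horizon_s))
  }
  # tail: A_i exp(-r_i (t - tp)) exp(-dlam t), analytic in two pieces so a
  # population rate can replace the slowest fitted rate beyond the scan end
  rates <- fit$r
  if (horizon_s > fit$t_peak) {
    for (i in seq_along(rates)) {
      ri <- rates[i] / 60                        # s^-1
      q <- ri + dlam
      t0 <- fit$t_peak
      t1 <- min(fit$scan_end_s, horizon_s)
      # within-scan piece
      if (q <= 0 && !is.finite(horizon_s))
        stop("non-positive net clearance: infinite-horizon AUC diverges")
      total <- total + fit$A[i] * exp(ri * fit$t_peak) *
        .int_exp(q, t0, t1)
      # beyond-scan piece, possibly with population rate for slowest term
      if (horizon_s > t1) {
        r_beyond <- ri
        if (!is.null(r_pop) && i == which.min(rates)) r_beyond <- r_pop / 60
        # value at scan end under the fitted model
        v_end <- fit$A[i] * exp(-ri * (t1 - fit$t_peak))
        q2 <- r_beyond + dlam
        if (q2 <= 0 && !is.finite(horizon_s))
          stop("non-positive net clearance: infinite-horizon AUC diverges")
        total <- total + v_end * exp(-dlam * t1) * .int_exp(q2, 0, horizon_s - t1)
      }
    }
  }
  if (total < 0) stop("extrapolated therapy curve integrates negative")
  scale * total
}

# integral of exp(-q t) over [t0, t1]; handles q = 0 and t1 = Inf
.int_exp <- function(q, t0, t1) {
  if (abs(q) < 1e-16) {
    if (!is.finite(t1)) stop("divergent integral")
    return(t1 - t0)
  }
  if (!is.finite(t1)) {
    if (q <= 0) stop("divergent integral")
    return(exp(-q * t0) / q)
  }
  (exp(-q * t0) - exp(-q * t1)) / q
}
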