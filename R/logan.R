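#' Logan transform of a tissue curve against an arterial input
#'
#' Maps a time-activity curve into Logan coordinates
#' X_j = (int_0^{t_j} Ca) / TAC(t_j), Y_j = (int_0^{t_j} TAC) / TAC(t_j),
#' both in minutes. At quasi-equilibrium Y is linear in X with slope equal to
#' the distribution volume. Cumulative integrals use the trapezoid rule on
#' each curve's native grid; the arterial integral is linearly interpolated
#' to the frame mid-times.
#'
#' @param tac_times_s frame mid-times, seconds.
#' @param tac tissue activity, Bq mL^-1, one value per frame.
#' @param aif_times_s arterial sample times, seconds.
#' @param aif arterial activity, Bq mL^-1.
#' @param floor positivity floor for the TAC denominator; frames at or below
#'   it are excluded and flagged. Default `max(.Machine$double.eps,
#'   1e-3 * max(tac))`.
#' @return list with `X`, `Y` (minutes), `t_min` (frame mid-times, minutes)
#'   and logical `used` marking frames above the floor.
#' @export
logan_transform <- function(tac_times_s, tac, aif_times_s, aif, floor = NULL) {
  stopifnot(length(tac_times_s) == length(tac),
            length(aif_times_s) == length(aif))
  if (is.null(floor)) floor <- max(.Machine$double.eps, 1e-3 * max(tac))
  cum_aif <- cumtrapz0(aif_times_s / 60, aif)
  cum_aif_at <- stats::approx(aif_times_s / 60, cum_aif,
                              xout = tac_times_s / 60, rule = 2)$y
  cum_tac <- cumtrapz0(tac_times_s / 60, tac)
  used <- tac > floor
  X <- Y <- rep(NA_real_, length(tac))
  X[used] <- cum_aif_at[used] / tac[used]
  Y[used] <- cum_tac[used] / tac[used]
  list(X = X, Y = Y, t_min = tac_times_s / 60, used = used)
}

#' Cumulative trapezoid integral
#' @param x strictly increasing abscissae.
#' @param y values.
#' @return vector of cumulative integrals, same length, starting at 0.
#' @export
cumtrapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(rep(0, n))
  c(0, cumsum(diff(x) * (y[-1] + y[-n]) / 2))
}

# cumulative trapezoid measured from t = 0: when the grid starts after 0 the
# first sample (a frame average over an interval straddling its mid-time) is
# extended back to the origin, so e.g. a constant curve integrates to c * t
# exactly
cumtrapz0 <- function(x, y) {
  lead <- if (x[1] > 0) x[1] * y[1] else 0
  lead + cumtrapz(x, y)
}

#' Default Logan delay grid
#'
#' Candidate quasi-equilibrium start times: the frame mid-times falling
#' inside the configured window (default ~2.33-8 min); the data are
#' frame-discrete so a finer grid adds nothing.
#'
#' @param fs a [frame_schedule()].
#' @param window_min two-element window in minutes.
#' @return delays in minutes.
#' @export
logan_delay_grid <- function(fs, window_min = c(2.33, 8)) {
  mids <- fs$mid / 60
  d <- mids[mids >= window_min[1] & mids <= window_min[2]]
  if (!length(d)) stop("no frame mid-times inside the delay window")
  d
}

#' Logan line fit with quasi-equilibrium delay search
#'
#' For each candidate delay, fits an ordinary least-squares line to the
#' Logan-transformed points with frame mid-time at or after the delay, and
#' returns the fit with the maximum coefficient of determination. Ties are
#' broken toward the earliest delay. With exactly two usable points R^2 is 1
#' by convention and the result is flagged.
#'
#' @param X,Y Logan coordinates (minutes); NA entries are skipped.
#' @param t_min frame mid-times, minutes.
#' @param delay_grid candidate delays, minutes.
#' @return list `slope`, `intercept`, `r2`, `t0`, `n_points`,
#'   `two_point_fit`; or NULL if no delay has two usable frames.
#' @export
fit_delay_search <- function(X, Y, t_min, delay_grid) {
  best <- NULL
  for (d in sort(delay_grid)) {
    sel <- which(t_min >= d & is.finite(X) & is.finite(Y))
    if (length(sel) < 2) next
    f <- .ols(X[sel], Y[sel])
    if (is.null(f)) next
    if (length(sel) == 2) f$r2 <- 1
    if (is.null(best) || f$r2 > best$r2 + 1e-15) {
      best <- c(f, list(t0 = d, n_points = length(sel),
                        two_point_fit = length(sel) == 2))
    }
  }
  best
}

# closed-form OLS; returns NULL when X is degenerate (zero variance)
.ols <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx <= 0) return(NULL)
  sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  intercept <- my - slope * mx
  syy <- sum((y - my)^2)
  r2 <- if (syy <= 0) 1 else sxy^2 / (sxx * syy)
  list(slope = slope, intercept = intercept, r2 = min(r2, 1))
}

#' Voxel-wise Logan parametric maps
#'
#' Applies the Logan transform and delay search to every voxel in a mask,
#' producing distribution-volume, intercept, R-squared and selected-delay
#' maps. The per-voxel slope is in mL of blood per mL of tissue; dividing by
#' the voxel density converts it to mL/g (the field's conventional unit).
#' Voxels where no delay yields two frames above the positivity floor are
#' flagged unanalyzable (NA in all maps, recorded in `unanalyzable`).
#'
#' The delay search is vectorized across voxels: for each candidate delay an
#' OLS line is fitted to every voxel simultaneously with masked sums, then
#' the maximum-R-squared delay is selected per voxel (ties to the earliest
#' delay).
#'
#' @param study a `dynamic_study`.
#' @param aif an [arterial_curve()].
#' @param mask logical array of voxels to analyze.
#' @param density density map, g mL^-1 (scalar or array congruent with mask).
#' @param delay_grid candidate delays in minutes (default
#'   [logan_delay_grid()] of the study schedule).
#' @param divide_by_density logical; convert slope to mL/g using the density
#'   map (default TRUE).
#' @return object of class `parametric_maps`: arrays `ldv`, `intercept`,
#'   `r2`, `t0` (min), logical `mask`, integer vector `unanalyzable`
#'   (flat indices), `delay_grid`.
#' @export
ldv_map <- function(study, aif, mask, density = 1,
                    delay_grid = NULL, divide_by_density = TRUE) {
  stopifnot(inherits(study, "dynamic_study"), inherits(aif, "arterial_curve"))
  dims <- dim(study$data)
  if (!identical(dim(mask), dims[1:3])) stop("mask geometry mismatch")
  if (is.array(density) && !identical(dim(density), dims[1:3]))
    stop("density geometry mismatch")
  fs <- study$schedule
  if (is.null(delay_grid)) delay_grid <- logan_delay_grid(fs)
  delay_grid <- sort(delay_grid)
  t_min <- fs$mid / 60
  if (min(delay_grid) < 0 || max(delay_grid) > max(t_min))
    stop("delay grid outside the scan span")

  idx <- which(mask)
  nvox <- length(idx)
  if (nvox == 0) stop("empty analysis mask")
  nf <- fs$n
  tacm <- matrix(study$data, nrow = prod(dims[1:3]))[idx, , drop = FALSE]

  cum_aif <- cumtrapz0(aif$times_s / 60, aif$activity)
  cum_aif_at <- stats::approx(aif$times_s / 60, cum_aif,
                              xout = t_min, rule = 2)$y
  # voxel-wise cumulative trapezoid of the TAC over frame mid-times,
  # measured from t = 0 (first sample extended back to the origin)
  dt <- diff(t_min)
  cum_tac <- matrix(0, nvox, nf)
  cum_tac[, 1] <- t_min[1] * tacm[, 1]
  for (j in 2:nf)
    cum_tac[, j] <- cum_tac[, j - 1] +
      dt[j - 1] * (tacm[, j] + tacm[, j - 1]) / 2

  floor_v <- pmax(.Machine$double.eps, 1e-3 * apply(tacm, 1, max))
  W <- tacm > floor_v                            # usable frames, voxels x frames
  X <- Y <- matrix(NA_real_, nvox, nf)
  X[W] <- (matrix(cum_aif_at, nvox, nf, byrow = TRUE) / tacm)[W]
  Y[W] <- (cum_tac / tacm)[W]

  best_r2 <- rep(-Inf, nvox)
  best_slope <- best_int <- best_t0 <- rep(NA_real_, nvox)
  Xz <- ifelse(W, X, 0); Yz <- ifelse(W, Y, 0)
  for (d in delay_grid) {
    fsel <- t_min >= d
    Wd <- W[, fsel, drop = FALSE]
    nD <- rowSums(Wd)
    ok <- nD >= 2
    if (!any(ok)) next
    Xd <- Xz[, fsel, drop = FALSE]; Yd <- Yz[, fsel, drop = FALSE]
    sx <- rowSums(Xd); sy <- rowSums(Yd)
    sxx <- rowSums(Xd^2); syy <- rowSums(Yd^2); sxy <- rowSums(Xd * Yd)
    vxx <- sxx - sx^2 / nD
    vyy <- syy - sy^2 / nD
    vxy <- sxy - sx * sy / nD
    ok <- ok & vxx > 0
    slope <- vxy / vxx
    r2 <- ifelse(vyy <= 0, 1, pmin(vxy^2 / (vxx * vyy), 1))
    r2[nD == 2] <- 1                             # two-point convention
    upd <- ok & r2 > best_r2 + 1e-15
    best_r2[upd] <- r2[upd]
    best_slope[upd] <- slope[upd]
    best_int[upd] <- (sy / nD - slope * sx / nD)[upd]
    best_t0[upd] <- d
  }
  bad <- !is.finite(best_slope)
  rho <- if (is.array(density)) density[idx] else rep(density, nvox)
  slope_out <- best_slope
  if (divide_by_density) slope_out <- slope_out / rho

  blank <- array(NA_real_, dims[1:3])
  m_ldv <- m_int <- m_r2 <- m_t0 <- blank
  m_ldv[idx] <- ifelse(bad, NA, slope_out)
  m_int[idx] <- ifelse(bad, NA, best_int)
  m_r2[idx] <- ifelse(bad, NA, best_r2)
  m_t0[idx] <- ifelse(bad, NA, best_t0)
  structure(list(ldv = m_ldv, intercept = m_int, r2 = m_r2, t0 = m_t0,
                 mask = mask, unanalyzable = idx[bad],
                 delay_grid = delay_grid, voxel_mm = study$voxel_mm,
                 divide_by_density = divide_by_density),
            class = "parametric_maps")
}

#' @export
print.parametric_maps <- function(x, ...) {
  n <- sum(x$mask)
  cat(sprintf("parametric_maps: %d voxels analyzed, %d unanalyzable\n",
              n, length(x$unanalyzable)))
  cat(sprintf("  LDV  mean %.3g mL/g, R2 mean %.6f\n",
              mean(x$ldv[x$mask], na.rm = TRUE),
              mean(x$r2[x$mask], na.rm = TRUE)))
  invisible(x)
}

#' Write parametric maps as NIfTI-1 volumes plus a stats CSV
#'
#' @param pm a `parametric_maps` object.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return invisibly, the written paths.
#' @export
write_parametric_maps <- function(pm, dir, prefix = "logan") {
  stopifnot(inherits(pm, "parametric_maps"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in c("ldv", "intercept", "r2", "t0")) {
    p <- file.path(dir, sprintf("%s_%s.nii", prefix, nm))
    write_nifti(pm[[nm]], p, voxel_mm = pm$voxel_mm)
    paths <- c(paths, p)
  }
  invisible(paths)
}
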