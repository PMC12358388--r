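#' Kinetic parameters of the decay-incorporated two-tissue compartment model
#'
#' The standard two-tissue compartment model (S2TCM) describes radioligand
#' exchange between arterial blood, a free tissue compartment and a bound
#' tissue compartment, extended with the physical decay constant of the
#' radionuclide so that the same rate constants describe both a short-lived
#' diagnostic tracer and a long-lived therapeutic one.
#'
#' @param K1 influx rate constant, mL min^-1 g^-1 (blood to tissue).
#' @param k2 efflux rate constant, min^-1 (free tissue to blood).
#' @param k3 binding rate constant, min^-1 (free to bound).
#' @param k4 dissociation rate constant, min^-1 (bound to free).
#' @param lam radionuclide physical decay constant, min^-1.
#' @return An object of class `kinetic_params`.
#' @examples
#' kp <- kinetic_params(K1 = 0.15, k2 = 0.4, k3 = 0.05, k4 = 0.02)
#' ldv(kp)
#' @export
kinetic_params <- function(K1, k2, k3, k4, lam = 0) {
  vals <- c(K1 = K1, k2 = k2, k3 = k3, k4 = k4, lam = lam)
  if (any(!is.finite(vals))) stop("kinetic parameters must be finite")
  if (any(vals < 0)) stop("kinetic parameters must be >= 0")
  structure(as.list(vals), class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf(
    "S2TCM parameters: K1=%g mL/min/g, k2=%g, k3=%g, k4=%g, lambda=%g min^-1\n",
    x$K1, x$k2, x$k3, x$k4, x$lam))
  if (x$k2 > 0 && (x$k3 == 0 || x$k4 > 0))
    cat(sprintf("  LDV = %g mL/g\n", ldv(x)))
  invisible(x)
}

#' Convert a half-life in days to a decay constant in min^-1
#'
#' Half-lives are conventionally tabulated in days for therapeutic nuclides;
#' all kinetics here work in minutes, so the conversion happens once at this
#' boundary.
#'
#' @param half_life_days physical half-life in days.
#' @return decay constant, min^-1.
#' @export
decay_constant_per_min <- function(half_life_days) {
  stopifnot(half_life_days > 0)
  log(2) / (half_life_days * 24 * 60)
}

#' Effective half-life of activity in tissue
#'
#' Combines physical and biological half-lives as
#' 1/T_eff = 1/T_phys + 1/T_bio. The integration horizon for
#' time-integrated activity is conventionally five effective half-lives.
#'
#' @param t_phys physical half-life (any time unit).
#' @param t_bio biological half-life (same unit).
#' @return effective half-life in the same unit.
#' @export
effective_half_life <- function(t_phys, t_bio) {
  stopifnot(t_phys > 0, t_bio > 0)
  1 / (1 / t_phys + 1 / t_bio)
}

# Eigen-rates of the 2TCM system matrix (without decay): theta1 <= theta2,
# theta1*theta2 = k2*k4, theta1+theta2 = k2+k3+k4. Discriminant is
# (k2-k4)^2 + k3^2 + 2 k3 (k2+k4) >= 0 so the rates are always real.
.tcm_eigenrates <- function(k2, k3, k4) {
  s <- k2 + k3 + k4
  disc <- s^2 - 4 * k2 * k4
  disc <- max(disc, 0)
  r <- sqrt(disc)
  c(theta1 = (s - r) / 2, theta2 = (s + r) / 2)
}

#' Macro-rates of the impulse residue function
#'
#' For the decay-incorporated S2TCM the flow-scaled impulse residue function
#' is a biexponential, R(t) = G exp(-alpha t) + H exp(-beta t), where alpha
#' and beta are the decay constant lambda plus the eigen-rates of the
#' two-compartment system and G + H = K1. When the eigen-rates coincide
#' (repeated root) the analytic limit R(t) = (K1 + c t) exp(-alpha t) is
#' returned with the linear coefficient in field `C`.
#'
#' @param kp a [kinetic_params()] object.
#' @return An object of class `macro_rates` with fields `G`, `H`, `alpha`,
#'   `beta` (and `C`, `degenerate` for the repeated-root case).
#' @export
macro_rates <- function(kp) {
  stopifnot(inherits(kp, "kinetic_params"))
  s <- kp$k2 + kp$k3 + kp$k4
  if (s == 0 && kp$lam == 0 && kp$K1 > 0) {
    # no efflux, no decay: R(t) constant at K1
    out <- list(G = kp$K1, H = 0, alpha = 0, beta = 0,
                C = 0, degenerate = FALSE)
    return(structure(out, class = "macro_rates"))
  }
  disc <- s^2 - 4 * kp$k2 * kp$k4
  if (s > 0 && disc < 1e-12 * s^2) {
    # repeated eigenvalue: R(t) = (K1 + C t) e^{-(theta+lam) t}
    theta <- s / 2
    C <- kp$K1 * (kp$k3 + kp$k4 - theta)
    out <- list(G = kp$K1, H = 0, alpha = theta + kp$lam,
                beta = theta + kp$lam, C = C, degenerate = TRUE)
    return(structure(out, class = "macro_rates"))
  }
  th <- .tcm_eigenrates(kp$k2, kp$k3, kp$k4)
  d <- th["theta2"] - th["theta1"]
  G <- kp$K1 * (kp$k3 + kp$k4 - th["theta1"]) / d
  H <- kp$K1 * (th["theta2"] - kp$k3 - kp$k4) / d
  out <- list(G = unname(G), H = unname(H),
              alpha = unname(th["theta1"] + kp$lam),
              beta = unname(th["theta2"] + kp$lam),
              C = 0, degenerate = FALSE)
  structure(out, class = "macro_rates")
}

#' Evaluate the impulse residue function R(t)
#'
#' @param kp a [kinetic_params()] object.
#' @param t_min times in minutes (vector).
#' @return R(t) in min^-1 scaled by K1 (i.e. mL min^-1 g^-1 response to a
#'   unit arterial bolus).
#' @export
residue_function <- function(kp, t_min) {
  mr <- macro_rates(kp)
  if (mr$degenerate) {
    (kp$K1 + mr$C * t_min) * exp(-mr$alpha * t_min)
  } else {
    mr$G * exp(-mr$alpha * t_min) + mr$H * exp(-mr$beta * t_min)
  }
}

#' Closed-form area under the impulse residue function
#'
#' AUC of R(t) over t in [0, Inf):
#' K1 (k4 + k3 + lambda) / (k2 k4 + (k2 + k3 + k4) lambda + lambda^2).
#' For lambda = 0 this reduces to the Logan distribution volume
#' K1/k2 (1 + k3/k4).
#'
#' @param kp a [kinetic_params()] object.
#' @return AUC in mL g^-1.
#' @export
auc_R <- function(kp) {
  stopifnot(inherits(kp, "kinetic_params"))
  den <- kp$k2 * kp$k4 + (kp$k2 + kp$k3 + kp$k4) * kp$lam + kp$lam^2
  if (den <= 0) {
    stop("auc_R is not finite: k2*k4 + (k2+k3+k4)*lambda + lambda^2 must be > 0 ",
         "(irreversible binding with no decay has infinite residence)")
  }
  kp$K1 * (kp$k4 + kp$k3 + kp$lam) / den
}

#' Logan distribution volume
#'
#' LDV = K1/k2 (1 + k3/k4), the zero-decay limit of [auc_R()] and the slope
#' recovered by Logan graphical analysis at quasi-equilibrium. For k3 = 0 the
#' bound compartment drops out and LDV = K1/k2 regardless of k4.
#'
#' @param kp a [kinetic_params()] object.
#' @return distribution volume, mL g^-1.
#' @export
ldv <- function(kp) {
  stopifnot(inherits(kp, "kinetic_params"))
  if (kp$k2 == 0) stop("LDV undefined for k2 = 0")
  if (kp$k3 > 0 && kp$k4 == 0)
    stop("LDV undefined for irreversible binding (k3 > 0, k4 = 0)")
  ratio <- if (kp$k3 == 0) 0 else kp$k3 / kp$k4
  kp$K1 / kp$k2 * (1 + ratio)
}

#' Frame schedule of a dynamic acquisition
#'
#' @param durations_s frame durations in seconds; frames are contiguous
#'   starting at `start_s`.
#' @param start_s acquisition start time, seconds (default 0).
#' @return An object of class `frame_schedule` with `start`, `dur`, `end`,
#'   `mid` (all seconds).
#' @export
frame_schedule <- function(durations_s, start_s = 0) {
  if (any(durations_s <= 0)) stop("frame durations must be > 0")
  start <- start_s + cumsum(c(0, durations_s[-length(durations_s)]))
  end <- start + durations_s
  structure(list(start = start, dur = durations_s, end = end,
                 mid = (start + end) / 2, n = length(durations_s),
                 span = sum(durations_s)),
            class = "frame_schedule")
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("frame_schedule: %d frames, %g s total (%.2f min)\n",
              x$n, x$span, x$span / 60))
  invisible(x)
}

#' Simulate a tissue time-activity curve
#'
#' Forward model TAC(t) = Ca(t) (x) R(t): the arterial input convolved with
#' the flow-scaled impulse residue function, then averaged over each frame
#' interval (instantaneous sampling would bias the long late frames). The
#' convolution is evaluated on a uniform 1-s grid.
#'
#' @param aif_times_s arterial sample times, seconds, on a grid at least as
#'   fine as 1 s spanning the scan.
#' @param aif arterial activity concentration, Bq mL^-1, same length.
#' @param kp a [kinetic_params()] object, or the string `"blood"` for the
#'   pure-blood passthrough (tissue identical to the arterial input).
#' @param fs a [frame_schedule()].
#' @param density_g_ml tissue density used to express the tissue curve per
#'   mL of tissue (TAC = rho * Ca (x) R); default 1.
#' @return numeric vector of per-frame mean activity, Bq mL^-1.
#' @export
simulate_tissue_tac <- function(aif_times_s, aif, kp, fs, density_g_ml = 1) {
  stopifnot(inherits(fs, "frame_schedule"))
  if (length(aif_times_s) != length(aif)) stop("aif grid/value length mismatch")
  scan_end <- fs$end[fs$n]
  if (max(aif_times_s) < scan_end) stop("aif grid shorter than scan span")
  tgrid <- seq(0, scan_end, by = 1)
  ca <- stats::approx(aif_times_s, aif, xout = tgrid, rule = 2)$y
  if (identical(kp, "blood")) {
    tac <- ca
  } else {
    stopifnot(inherits(kp, "kinetic_params"))
    r <- residue_function(kp, tgrid / 60)          # min^-1 units
    full <- convolve_causal(ca, r) * (1 / 60)      # dt = 1 s = 1/60 min
    tac <- density_g_ml * full[seq_along(tgrid)]
  }
  frame_average(tgrid, tac, fs)
}

#' Causal discrete convolution with trapezoid end-weights
#'
#' Approximates the continuous convolution integral int_0^t f(u) g(t-u) du on
#' a shared uniform grid by the trapezoid rule: the plain discrete
#' convolution sum minus half the two endpoint products. Multiply by the
#' grid spacing. The endpoint correction matters here because the residue
#' function has a finite jump R(0) = K1.
#'
#' @param f,g numeric vectors on a common uniform grid.
#' @return vector of length `length(f)`.
#' @export
convolve_causal <- function(f, g) {
  n <- length(f)
  out <- stats::convolve(f, rev(g), type = "open")[seq_len(n)]
  out - (f[1] * g[seq_len(n)] + f[seq_len(n)] * g[1]) / 2
}

#' Average a finely sampled curve over frame intervals
#'
#' @param t_s sample times, seconds (uniform grid).
#' @param y values at `t_s`.
#' @param fs a [frame_schedule()].
#' @return per-frame means.
#' @export
frame_average <- function(t_s, y, fs) {
  vapply(seq_len(fs$n), function(j) {
    sel <- t_s >= fs$start[j] & t_s <= fs$end[j]
    mean(y[sel])
  }, numeric(1))
}

#' Serialize kinetic parameters to a flat key-value list / JSON
#'
#' @param kp a [kinetic_params()] object.
#' @param path optional file path; if given, JSON is written there.
#' @return invisibly, the flat named list (keys `K1`, `k2`, `k3`, `k4`,
#'   `lambda_per_min`).
#' @export
write_kinetic_params <- function(kp, path = NULL) {
  stopifnot(inherits(kp, "kinetic_params"))
  x <- list(K1 = kp$K1, k2 = kp$k2, k3 = kp$k3, k4 = kp$k4,
            lambda_per_min = kp$lam)
  if (!is.null(path))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(x)
}

#' @rdname write_kinetic_params
#' @param x a named list or a JSON file path to read from.
#' @export
read_kinetic_params <- function(x) {
  if (is.character(x)) x <- jsonlite::read_json(x, simplifyVector = TRUE)
  kinetic_params(K1 = x$K1, k2 = x$k2, k3 = x$k3, k4 = x$k4,
                 lam = if (!is.null(x$lambda_per_min)) x$lambda_per_min else 0)
}
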