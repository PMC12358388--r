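test_that("macro_rates reconstructs R(t) and matches the ODE oracle", {
  cases <- list(
    list(kp = kinetic_params(0.15, 0.4, 0.05, 0.02), t_end = 400),
    list(kp = kinetic_params(0.15, 0.4, 0.05, 0.02,
                             lam = decay_constant_per_min(6.67)), t_end = 400),
    list(kp = kinetic_params(1.2, 0.9, 0.3, 0.2, lam = 0.01), t_end = 60),
    list(kp = kinetic_params(0.3, 0.5, 0, 0), t_end = 60))
  for (cs in cases) {
    kp <- cs$kp
    mr <- macro_rates(kp)
    # structural invariants
    expect_lte(mr$alpha, mr$beta)
    expect_gte(mr$alpha, kp$lam)
    expect_gte(mr$G, -1e-12)
    expect_gte(mr$H, -1e-12)
    expect_equal(mr$G + mr$H, kp$K1, tolerance = 1e-12)
    expect_equal(residue_function(kp, 0), kp$K1, tolerance = 1e-12)
    # pointwise agreement with RK4 integration of the compartment system
    orc <- ode_residue_oracle(kp, t_end_min = 5, dt = 1e-3)
    at <- seq(0, 5, by = 0.5)
    expect_equal(residue_function(kp, at),
                 approx(orc$t, orc$r, xout = at)$y, tolerance = 1e-6)
  }
})

test_that("macro_rates trivial reductions and degenerate root", {
  # no efflux, no decay: constant R
  mr0 <- macro_rates(kinetic_params(0.1, 0, 0, 0))
  expect_equal(mr0$G + mr0$H, 0.1)
  expect_equal(max(mr0$alpha, mr0$beta), 0)
  expect_equal(residue_function(kinetic_params(0.1, 0, 0, 0), c(0, 5, 50)),
               rep(0.1, 3))
  # one-compartment reduction
  kp1 <- kinetic_params(0.2, 0.3, 0, 0)
  expect_equal(residue_function(kp1, c(0, 1, 2, 7)),
               0.2 * exp(-0.3 * c(0, 1, 2, 7)), tolerance = 1e-12)
  # K1 = 0 implies R == 0
  expect_equal(residue_function(kinetic_params(0, 0.3, 0.1, 0.05), 0:5),
               rep(0, 6))
  # repeated eigenvalue: k3 = 0, k2 = k4 -> discriminant 0; analytic limit
  kpd <- kinetic_params(0.1, 0.25, 0, 0.25)
  mrd <- macro_rates(kpd)
  expect_true(mrd$degenerate)
  orc <- ode_residue_oracle(kpd, 5, dt = 1e-3)
  at <- seq(0, 5, by = 0.5)
  expect_equal(residue_function(kpd, at),
               approx(orc$t, orc$r, xout = at)$y, tolerance = 1e-6)
})

test_that("auc_R closed form equals quadrature of R(t) and honors limits", {
  # randomized valid parameters, fixed seed
  set.seed(11)
  for (i in 1:25) {
    kp <- kinetic_params(K1 = runif(1, 0.01, 2), k2 = runif(1, 0.05, 2),
                         k3 = runif(1, 0, 1), k4 = runif(1, 0.02, 1),
                         lam = runif(1, 0, 0.05))
    quad <- integrate(function(t) residue_function(kp, t), 0, Inf,
                      rel.tol = 1e-12)$value
    expect_equal(auc_R(kp), quad, tolerance = 1e-8)
  }
  # lam = 0 reduces exactly to the distribution volume
  kp <- kinetic_params(0.15, 0.4, 0.05, 0.02)
  expect_equal(auc_R(kp), ldv(kp), tolerance = 1e-14)
  expect_equal(ldv(kp), 0.375 * 3.5)                 # 1.3125 by hand
  expect_equal(ldv(kinetic_params(0.2, 0.4, 0, 0)), 0.5)
  # 177Lu decay is a < 1% perturbation of the zero-decay limit
  kp_lu <- kinetic_params(0.15, 0.4, 0.05, 0.02,
                          lam = decay_constant_per_min(6.67))
  expect_lt(abs(ldv(kp) - auc_R(kp_lu)) / auc_R(kp_lu), 0.01)
  # RK4 oracle agreement with decay included
  orc <- ode_residue_oracle(kp_lu, t_end_min = 3000, dt = 0.01)
  expect_equal(auc_R(kp_lu), orc$auc, tolerance = 1e-4)
  # divergence: irreversible binding without decay
  expect_error(auc_R(kinetic_params(0.1, 0.3, 0.1, 0)), "not finite")
  expect_error(ldv(kinetic_params(0.1, 0, 0.1, 0.1)), "k2")
  expect_error(ldv(kinetic_params(0.1, 0.3, 0.1, 0)), "irreversible")
})

test_that("auc_R monotonicity properties", {
  base <- list(K1 = 0.2, k2 = 0.4, k3 = 0.1, k4 = 0.05, lam = 0.001)
  val <- function(l) auc_R(do.call(kinetic_params, l))
  bump <- function(nm, d) { l <- base; l[[nm]] <- l[[nm]] + d; val(l) }
  expect_gte(bump("K1", 0.1), val(base))
  expect_gte(bump("k3", 0.1), val(base))
  expect_lte(bump("k2", 0.1), val(base))
  expect_lte(bump("lam", 0.01), val(base))
})

test_that("R(t) is non-negative and non-increasing for valid params", {
  set.seed(3)
  tt <- seq(0, 30, by = 0.1)
  for (i in 1:20) {
    kp <- kinetic_params(runif(1, 0.01, 2), runif(1, 0, 2),
                         runif(1, 0, 1), runif(1, 0, 1),
                         lam = runif(1, 0, 0.02))
    r <- residue_function(kp, tt)
    expect_gte(min(r), -1e-12)
    expect_lte(max(diff(r)), 1e-12)
  }
})

test_that("effective half-life combines physical and biological decay", {
  expect_equal(effective_half_life(6, 3), 2)
  expect_lte(effective_half_life(6.67, 100), min(6.67, 100))
  # harmonic identity
  t_eff <- effective_half_life(6.67, 12)
  expect_equal(1 / t_eff, 1 / 6.67 + 1 / 12)
})

test_that("simulate_tissue_tac: convolution forward model", {
  fs <- frame_schedule(c(rep(10, 6), rep(30, 4)))
  tg <- seq(0, fs$span, by = 1)
  kp <- kinetic_params(0.5, 0.6, 0.2, 0.1)
  # zero input -> zero output
  expect_equal(simulate_tissue_tac(tg, rep(0, length(tg)), kp, fs),
               rep(0, fs$n))
  # 1-s bolus -> TAC proportional to frame-averaged R(t)
  bolus <- c(1, rep(0, length(tg) - 1))
  tac_b <- simulate_tissue_tac(tg, bolus, kp, fs)
  rmean <- frame_average(tg, residue_function(kp, tg / 60), fs)
  # half-weight at the jump sample: compare away from frame 1
  expect_equal(tac_b[-1] / tac_b[2], rmean[-1] / rmean[2], tolerance = 1e-2)
  # pure blood passthrough equals the frame-averaged input exactly
  aif <- phantom_aif(tg)
  expect_equal(simulate_tissue_tac(tg, aif, "blood", fs),
               frame_average(tg, aif, fs))
  # non-negative output, right length
  tac <- simulate_tissue_tac(tg, aif, kp, fs)
  expect_length(tac, fs$n)
  expect_gte(min(tac), 0)
  expect_error(simulate_tissue_tac(tg[1:50], aif[1:50], kp, fs), "shorter")
})

test_that("Fubini factorization: integral of TAC = AUC(aif) * AUC(R)", {
  kp <- kinetic_params(0.8, 1.2, 0.4, 0.3, lam = 0.002)
  # carry both integrals to >= 5 effective half-lives of the slowest rate
  mr <- macro_rates(kp)
  # ">= 5 effective half-lives": carry to 10 so the truncation residual is
  # well inside the 0.5% tolerance
  t_end <- 400 * ceiling(10 * log(2) / min(mr$alpha, 0.05) * 60 / 400)
  fs <- frame_schedule(rep(t_end / 400, 400))
  tg <- seq(0, fs$span, by = 1)
  aif <- 1000 * exp(-0.05 * tg / 60)    # decaying input, AUC analytic
  tac <- simulate_tissue_tac(tg, aif, kp, fs)
  int_tac <- sum(fs$dur / 60 * tac)
  int_aif <- cumtrapz(tg / 60, aif)[length(tg)]
  expect_equal(int_tac, int_aif * auc_R(kp), tolerance = 5e-3)
})

test_that("kinetic params serialize round-trip", {
  kp <- kinetic_params(0.15, 0.4, 0.05, 0.02, lam = 1e-4)
  f <- tempfile(fileext = ".json")
  write_kinetic_params(kp, f)
  kp2 <- read_kinetic_params(f)
  expect_equal(unclass(kp2), unclass(kp))
})
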