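# Shared fixtures: printed per-patient report tables (inputs to the summary
# machinery) and small oracles used across test files.

# Per-cycle absorbed dose (Gy) at 7.4 GBq, six patients
table2 <- data.frame(
  patient = c("IGPC-02-026", "IGPC-02-028", "IGPC-02-029", "IGPC-02-031",
              "IGPC-02-032", "IGPC-02-033"),
  tumor = c(146.3, 57.2, 77.7, 77.4, 50.9, 50.6),
  total_prostate = c(48.0, 35.3, 44.1, 36.8, 39.4, 30.9),
  normal_prostate = c(43.3, 35.0, 43.5, 34.6, 38.9, 30.2),
  femur_r = c(6.7, 7.0, 11.0, 7.7, 7.1, 5.3),
  femur_l = c(6.7, 6.9, 10.9, 7.2, 7.4, 5.4))

# Distribution volumes (mL/g) and arterial AUC (Bq s/mL)
table1 <- data.frame(
  patient = table2$patient,
  tumor_ldv = c(5.38, 2.78, 2.16, 2.72, 2.03, 2.77),
  normal_prostate_ldv = c(1.56, 1.67, 1.17, 1.19, 1.54, 1.63),
  femur_r_ldv = c(0.26, 0.36, 0.32, 0.29, 0.30, 0.32),
  auc_ca = c(1.50, 1.13, 2.00, 1.58, 1.38, 1.00) * 1e8)

# BED per cycle (Gy)
table7 <- data.frame(
  patient = table2$patient,
  tumor = c(230.4, 68.4, 97.7, 99.1, 59.5, 59.1),
  femur_r = c(6.8, 7.1, 11.4, 7.9, 7.3, 5.4))

# fixed-step RK4 integration of the decay-incorporated 2TCM impulse
# response: independent oracle for macro_rates / residue_function
ode_residue_oracle <- function(kp, t_end_min, dt = 1e-3) {
  nt <- ceiling(t_end_min / dt)
  c1 <- kp$K1; c2 <- 0
  deriv <- function(c1, c2) c(
    -(kp$k2 + kp$k3 + kp$lam) * c1 + kp$k4 * c2,
    kp$k3 * c1 - (kp$k4 + kp$lam) * c2)
  out_t <- numeric(nt + 1); out_r <- numeric(nt + 1)
  out_t[1] <- 0; out_r[1] <- c1 + c2
  for (i in seq_len(nt)) {
    k1v <- deriv(c1, c2)
    k2v <- deriv(c1 + dt / 2 * k1v[1], c2 + dt / 2 * k1v[2])
    k3v <- deriv(c1 + dt / 2 * k2v[1], c2 + dt / 2 * k2v[2])
    k4v <- deriv(c1 + dt * k3v[1], c2 + dt * k3v[2])
    c1 <- c1 + dt / 6 * (k1v[1] + 2 * k2v[1] + 2 * k3v[1] + k4v[1])
    c2 <- c2 + dt / 6 * (k1v[2] + 2 * k2v[2] + 2 * k3v[2] + k4v[2])
    out_t[i + 1] <- i * dt
    out_r[i + 1] <- c1 + c2
  }
  list(t = out_t, r = out_r,
       auc = sum(diff(out_t) * (out_r[-1] + out_r[-length(out_r)]) / 2))
}

# small noiseless phantom study shared by slower tests (built once per run)
tiny_noiseless_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- phantom_spec(shape = c(32, 32, 12), noise_level = 0, seed = 42)
      cfg <- pipeline_config(phantom_spec = spec, seed = 42,
                             out_dir = tempfile("tiny_run_"))
      cache <<- run_pipeline(cfg, write = FALSE)
    }
    cache
  }
})
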