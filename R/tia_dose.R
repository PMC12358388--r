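MEV_TO_J <- 1.602176634e-13

#' Nuclide decay and emission data
#'
#' Container for the physical data the dose engine needs. The bundled
#' lutetium-177 defaults use the half-life consistent with the radiobiology
#' parameter set (6.67 days) and per-decay emission energies from the
#' package's versioned constants file (`inst/extdata/lu177_constants.json`):
#' mean electron energy (beta spectrum plus conversion/Auger electrons)
#' 0.1479 MeV and mean photon energy 0.0334 MeV per decay.
#'
#' @param half_life_days physical half-life, days.
#' @param electron_mev mean electron (beta + conversion) energy per decay, MeV.
#' @param photon_mev mean photon energy per decay, MeV.
#' @param kernel optional radial kernel data.frame (`radius_mm`,
#'   `dose_weight`) describing relative local energy deposition density in
#'   water for the electron component.
#' @param name nuclide label.
#' @return object of class `nuclide_data`.
#' @export
nuclide_data <- function(half_life_days, electron_mev, photon_mev = 0,
                         kernel = NULL, name = "custom") {
  stopifnot(half_life_days > 0, electron_mev >= 0, photon_mev >= 0)
  structure(list(half_life_days = half_life_days,
                 electron_mev = electron_mev, photon_mev = photon_mev,
                 kernel = kernel, name = name,
                 lam_per_min = decay_constant_per_min(half_life_days)),
            class = "nuclide_data")
}

#' @rdname nuclide_data
#' @export
lu177_data <- function() {
  consts <- jsonlite::read_json(
    system.file("extdata", "lu177_constants.json", package = "trtdose"),
    simplifyVector = TRUE)
  kern <- utils::read.csv(
    system.file("extdata", "lu177_kernel_synthetic.csv", package = "trtdose"),
    comment.char = "#")
  nuclide_data(consts$half_life_days, consts$electron_mev_per_decay,
               consts$photon_mev_per_decay, kernel = kern, name = "Lu-177")
}

#' @rdname nuclide_data
#' @export
f18_data <- function() {
  nuclide_data(109.77 / (24 * 60), electron_mev = 0.2498,
               photon_mev = 0.9783, name = "F-18")
}

#' Time-integrated activity map
#'
#' TIA per voxel is the product of the Logan distribution volume (mL/g), the
#' voxel density (g/mL), the voxel volume (mL) and the therapy-scaled
#' arterial AUC (Bq s/mL): the factorized time integral of the therapeutic
#' activity in that voxel. Unanalyzable voxels and negative-LDV voxels are
#' set to zero and counted.
#'
#' @param pm a `parametric_maps` object from [ldv_map()].
#' @param density density map, g mL^-1 (scalar or congruent array).
#' @param voxel_volume_ml voxel volume, mL.
#' @param auc_ther therapy arterial AUC, Bq s mL^-1 (from [therapy_auc()]).
#' @return object of class `tia_map`: array `tia` (Bq s), `total` (Bq s),
#'   counts of flagged/clamped voxels, geometry.
#' @export
tia_map <- function(pm, density, voxel_volume_ml, auc_ther) {
  stopifnot(inherits(pm, "parametric_maps"))
  if (auc_ther <= 0) stop("auc_ther must be > 0")
  dims <- dim(pm$ldv)
  if (is.array(density) && !identical(dim(density), dims))
    stop("density geometry mismatch")
  rho <- if (is.array(density)) density else array(density, dims)
  tia <- pm$ldv * rho * voxel_volume_ml * auc_ther
  n_flagged <- sum(pm$mask & !is.finite(tia))
  n_clamped <- sum(tia < 0, na.rm = TRUE)
  tia[!is.finite(tia)] <- 0
  tia[tia < 0] <- 0
  structure(list(tia = tia, total = sum(tia),
                 n_flagged = n_flagged, n_clamped = n_clamped,
                 voxel_mm = pm$voxel_mm, voxel_volume_ml = voxel_volume_ml,
                 auc_ther = auc_ther),
            class = "tia_map")
}

#' @export
print.tia_map <- function(x, ...) {
  cat(sprintf("tia_map: total %.4g Bq s (%d flagged, %d clamped voxels)\n",
              x$total, x$n_flagged, x$n_clamped))
  invisible(x)
}

#' CT number to mass density calibration
#'
#' Two-segment piecewise-linear calibration anchored at air (-1000 HU,
#' 0.001 g/mL), water (0 HU, 1.0 g/mL) and a documented bone segment of
#' 0.0006 g/mL per HU above water (1000 HU -> 1.6 g/mL, compact-bone scale).
#' Output clipped to [0.001, 3.0] g/mL.
#'
#' @param hu Hounsfield units (any numeric array/vector), plausible range
#'   -1024..3000.
#' @return density, g mL^-1, same shape.
#' @export
hu_to_density <- function(hu) {
  rho <- ifelse(hu <= 0, 1 + hu * (0.999 / 1000), 1 + hu * 0.0006)
  pmin(pmax(rho, 0.001), 3.0)
}

# voxelized kernel from a radial table: weight at each voxel-center offset is
# the interpolated radial deposition density times the voxel volume,
# normalized to sum 1 (all electron energy deposited within the support)
.voxelize_kernel <- function(kernel, voxel_mm) {
  rmax <- max(kernel$radius_mm)
  nr <- ceiling(rmax / voxel_mm)
  off <- lapply(1:3, function(i) (-nr[i]):(nr[i]))
  g <- expand.grid(i = off[[1]], j = off[[2]], k = off[[3]])
  r <- sqrt((g$i * voxel_mm[1])^2 + (g$j * voxel_mm[2])^2 +
              (g$k * voxel_mm[3])^2)
  w <- stats::approx(kernel$radius_mm, kernel$dose_weight, xout = r,
                     yleft = kernel$dose_weight[1], yright = 0, rule = 2)$y
  w[r > rmax] <- 0
  g$w <- w / sum(w)
  g[g$w > 0, ]
}

#' Absorbed dose from a TIA map
#'
#' Local mode deposits each voxel's full electron energy in that voxel:
#' D = TIA x E_e (MeV -> J) / voxel mass. Kernel mode spreads the electron
#' energy over neighbours according to a voxelized radial dose-point-kernel
#' (a documented surrogate for full Monte Carlo transport), then divides the
#' imparted energy by the local voxel mass, so denser voxels receive
#' proportionally lower dose (local/reference density scaling). The photon
#' component is ignored in local mode (flagged in provenance).
#'
#' @param tia a `tia_map`.
#' @param density density map, g mL^-1 (scalar or congruent array).
#' @param nd a [nuclide_data()] (kernel mode requires its kernel table).
#' @param mode `"local"` or `"kernel"`.
#' @return object of class `dose_map`: array `dose` (Gy), `total_energy_j`,
#'   provenance list.
#' @export
absorbed_dose <- function(tia, density, nd, mode = c("local", "kernel")) {
  stopifnot(inherits(tia, "tia_map"), inherits(nd, "nuclide_data"))
  mode <- match.arg(mode)
  dims <- dim(tia$tia)
  rho <- if (is.array(density)) density else array(density, dims)
  if (!identical(dim(rho), dims)) stop("density geometry mismatch")
  if (any(rho <= 0)) stop("zero or negative mass voxels in density map")
  mass_kg <- rho * tia$voxel_volume_ml / 1000     # g -> kg via mL * g/mL /1000
  e_j <- nd$electron_mev * MEV_TO_J
  if (mode == "local") {
    energy <- tia$tia * e_j
  } else {
    if (is.null(nd$kernel)) stop("kernel mode requires a kernel table")
    kern <- .voxelize_kernel(nd$kernel, tia$voxel_mm)
    energy <- array(0, dims)
    src <- tia$tia * e_j
    for (q in seq_len(nrow(kern))) {
      di <- kern$i[q]; dj <- kern$j[q]; dk <- kern$k[q]; w <- kern$w[q]
      xs <- max(1, 1 + di):min(dims[1], dims[1] + di)
      ys <- max(1, 1 + dj):min(dims[2], dims[2] + dj)
      zs <- max(1, 1 + dk):min(dims[3], dims[3] + dk)
      energy[xs, ys, zs] <- energy[xs, ys, zs] +
        w * src[xs - di, ys - dj, zs - dk]
    }
  }
  dose <- energy / mass_kg
  structure(list(dose = dose, total_energy_j = sum(energy),
                 voxel_mm = tia$voxel_mm,
                 voxel_volume_ml = tia$voxel_volume_ml,
                 provenance = list(engine = mode, nuclide = nd$name,
                                   electron_mev = nd$electron_mev,
                                   photon_included = FALSE,
                                   administered_gbq = NA_real_)),
            class = "dose_map")
}

#' @export
print.dose_map <- function(x, ...) {
  cat(sprintf("dose_map (%s engine, %s): mean %.3g Gy, total energy %.3g J\n",
              x$provenance$engine, x$provenance$nuclide,
              mean(x$dose), x$total_energy_j))
  invisible(x)
}

#' Normalize a dose map per unit administered activity
#'
#' @param dose a `dose_map` in Gy.
#' @param administered_gbq administered activity, GBq.
#' @return a `dose_map` in Gy/GBq.
#' @export
normalize_per_gbq <- function(dose, administered_gbq) {
  stopifnot(inherits(dose, "dose_map"))
  if (administered_gbq <= 0) stop("administered activity must be > 0")
  dose$dose <- dose$dose / administered_gbq
  dose$total_energy_j <- dose$total_energy_j / administered_gbq
  dose$provenance$administered_gbq <- administered_gbq
  dose$provenance$units <- "Gy/GBq"
  dose
}

#' @rdname normalize_per_gbq
#' @param dose_per_gbq a per-GBq `dose_map`.
#' @param cycle_activity_gbq therapy cycle activity, GBq (e.g. 7.4).
#' @export
scale_to_cycle <- function(dose_per_gbq, cycle_activity_gbq) {
  stopifnot(inherits(dose_per_gbq, "dose_map"))
  if (cycle_activity_gbq <= 0) stop("cycle activity must be > 0")
  dose_per_gbq$dose <- dose_per_gbq$dose * cycle_activity_gbq
  dose_per_gbq$total_energy_j <- dose_per_gbq$total_energy_j * cycle_activity_gbq
  dose_per_gbq$provenance$units <- "Gy"
  dose_per_gbq
}

#' Write a map object (tia/dose/bed) to NIfTI-1 with a JSON provenance sidecar
#'
#' @param map a `tia_map`, `dose_map` or `bed_map`.
#' @param path output `.nii` path; the sidecar gets extension `.json`.
#' @export
write_map <- function(map, path) {
  arr <- if (inherits(map, "tia_map")) map$tia
         else if (inherits(map, "dose_map")) map$dose
         else if (inherits(map, "bed_map")) map$bed
         else stop("unsupported map type")
  write_nifti(arr, path, voxel_mm = map$voxel_mm)
  side <- sub("\\.nii$", ".json", path)
  prov <- if (!is.null(map$provenance)) map$provenance else
    list(total = map$total, auc_ther = map$auc_ther)
  prov$class <- class(map)
  jsonlite::write_json(prov, side, auto_unbox = TRUE, digits = NA)
  invisible(c(path, side))
}
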