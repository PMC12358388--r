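#' Default dynamic acquisition frame schedule
#'
#' The 22-minute pelvic dynamic PET protocol: 11 frames of 10 s, five of
#' 20 s, four of 40 s, four of 60 s and four of 180 s — 28 frames, 1330 s.
#'
#' @return a [frame_schedule()].
#' @export
default_frame_schedule <- function() {
  frame_schedule(c(rep(10, 11), rep(20, 5), rep(40, 4), rep(60, 4),
                   rep(180, 4)))
}

#' Default arterial input model parameters
#'
#' A bolus arriving at 15 s, peaking at 30 s, with a bi-exponential tail
#' (fast vascular mixing component plus slow clearance). Amplitudes are
#' chosen so that for a 325-MBq diagnostic injection the therapy-scaled
#' arterial AUC at 7.4 GBq falls inside the clinically observed
#' (1.0-2.0) x 1e8 Bq s/mL range.
#'
#' @return named list understood by [phantom_aif()].
#' @export
default_aif_params <- function() {
  list(t_arrival_s = 15, t_peak_s = 30,
       A = c(20000, 1500),        # Bq/mL
       r = c(0.35, 0.03))         # min^-1, tissue-clearance incl. F-18 decay
}

#' Evaluate the phantom's ground-truth arterial input function
#'
#' Zero before bolus arrival, linear rise to the peak, exponential-sum tail.
#' This is the generating truth against which image-derived extraction and
#' fitting are validated.
#'
#' @param t_s times, seconds.
#' @param p parameter list as from [default_aif_params()].
#' @return activity, Bq mL^-1.
#' @export
phantom_aif <- function(t_s, p = default_aif_params()) {
  fit <- structure(list(t_arrival = p$t_arrival_s, t_peak = p$t_peak_s,
                        A = p$A, r = p$r), class = "aif_fit")
  .aif_model_eval(fit, t_s)
}

#' Phantom specification
#'
#' Defines the digital pelvis: grid geometry, tissue kinetics and densities,
#' tumor sphere, arterial cylinder and acquisition noise. Default tissue
#' kinetic parameters give distribution volumes of 3.0 (tumor), 1.5
#' (prostate), 0.30 (femoral marrow) and 0.8 (background soft tissue) mL/g,
#' inside the clinically reported per-tissue ranges.
#'
#' @param shape grid dimensions (default 64 x 64 x 20; use
#'   `paper_scale = TRUE` for 128 x 128 x 47).
#' @param voxel_mm voxel size, mm (default 3.27 isotropic).
#' @param tumor_radius_mm tumor sphere radius; 0 for no tumor.
#' @param noise_level Gaussian noise scale; the per-frame standard deviation
#'   is `noise_level * sqrt(TAC / (dur/10 s))`, i.e. variance proportional
#'   to activity and inversely to frame duration. 0 disables noise.
#' @param seed integer seed recorded in provenance and used for all noise.
#' @param aif_params arterial model, see [default_aif_params()].
#' @param paper_scale logical; use the full acquisition matrix.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 20), voxel_mm = c(3.27, 3.27, 3.27),
                         tumor_radius_mm = 8, noise_level = 5, seed = 1,
                         aif_params = default_aif_params(),
                         paper_scale = FALSE) {
  if (paper_scale) shape <- c(128, 128, 47)
  # rate constants fast enough that quasi-equilibrium is reached inside the
  # 2.33-8 min Logan delay window of a 22-min scan (see methods vignette);
  # LDVs are 3.0 / 1.5 / 0.30 / 0.8 mL/g, inside the clinical ranges
  tissues <- list(
    background = list(label = 1L, density = 1.00, avidity = 1,
                      kp = kinetic_params(1.40, 3.50, 0.35, 0.35)),
    prostate   = list(label = 2L, density = 1.02, avidity = 1,
                      kp = kinetic_params(1.68, 2.24, 0.56, 0.56)),
    tumor      = list(label = 3L, density = 1.04, avidity = 4,
                      kp = kinetic_params(3.36, 2.80, 0.84, 0.56)),
    marrow     = list(label = 4L, density = 0.98, avidity = 1,
                      kp = kinetic_params(0.63, 4.20, 0.28, 0.28)),
    artery     = list(label = 5L, density = 1.06, avidity = 1, kp = "blood"))
  structure(list(shape = shape, voxel_mm = voxel_mm,
                 tumor_radius_mm = tumor_radius_mm,
                 noise_level = noise_level, seed = seed,
                 aif_params = aif_params, tissues = tissues),
            class = "phantom_spec")
}

#' Build the labeled digital pelvis phantom
#'
#' Lays out, on the spec's grid: a soft-tissue background, a prostate
#' ellipsoid containing an optional tumor sphere, two femoral-marrow
#' cylinders, and a 12-mm-diameter arterial cylinder (comfortably above PET
#' spatial resolution, so no partial-volume treatment is needed). Returns the
#' label volume, density map, per-tissue ROI masks and the ground-truth LDV
#' map.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `phantom`: `labels` (integer array), `density`,
#'   `rois` (named list of logical arrays), `ldv_truth`, `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dm <- spec$shape; vs <- spec$voxel_mm
  ax <- (seq_len(dm[1]) - 0.5) * vs[1]
  ay <- (seq_len(dm[2]) - 0.5) * vs[2]
  az <- (seq_len(dm[3]) - 0.5) * vs[3]
  X <- array(ax, dm)
  Y <- array(rep(ay, each = dm[1]), dm)
  Z <- array(rep(az, each = dm[1] * dm[2]), dm)
  cx <- max(ax) / 2; cy <- max(ay) / 2; cz <- max(az) / 2

  labels <- array(1L, dm)
  # prostate: ellipsoid, ~20 mm semi-axes
  pr <- ((X - cx) / 20)^2 + ((Y - cy) / 18)^2 + ((Z - cz) / 15)^2 <= 1
  labels[pr] <- 2L
  # tumor: sphere offset inside the prostate
  if (spec$tumor_radius_mm > 0) {
    tu <- (X - (cx + 8))^2 + (Y - (cy + 5))^2 + (Z - cz)^2 <=
      spec$tumor_radius_mm^2
    tu <- tu & pr
    labels[tu] <- 3L
  }
  # femoral marrow: two z-axis cylinders, 8 mm radius, lateral
  for (s in c(-1, 1)) {
    fm <- (X - (cx + s * min(60, cx * 0.8)))^2 + (Y - cy)^2 <= 8^2
    labels[fm & labels == 1L] <- 4L
  }
  # common iliac artery: 6 mm radius z-cylinder, anterior
  ar <- (X - cx)^2 + (Y - (cy - min(40, cy * 0.7)))^2 <= 6^2
  labels[ar & labels == 1L] <- 5L

  density <- array(0, dm); ldv_truth <- array(NA_real_, dm)
  uptake <- array(0, dm)
  rois <- list()
  for (nm in names(spec$tissues)) {
    ts <- spec$tissues[[nm]]
    m <- labels == ts$label
    rois[[nm]] <- m
    density[m] <- ts$density
    if (identical(ts$kp, "blood")) {
      ldv_truth[m] <- NA_real_
      uptake[m] <- 1          # residual blood pool, arbitrary low units
    } else {
      ldv_truth[m] <- ldv(ts$kp)
      # synthetic static PSMA uptake image (clinical ~60-min scan used for
      # tumor segmentation): equilibrium uptake boosted by a binding-avidity
      # factor for the tumor, whose late-time SUV contrast exceeds the
      # 22-min equilibrium contrast (see methods vignette)
      uptake[m] <- ts$density * ldv(ts$kp) * ts$avidity
    }
  }
  structure(list(labels = labels, density = density, rois = rois,
                 ldv_truth = ldv_truth, uptake = uptake, spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("phantom: %s grid, %.3g mm voxels\n",
              paste(x$spec$shape, collapse = "x"),
              x$spec$voxel_mm[1]))
  for (nm in names(x$rois))
    cat(sprintf("  %-10s %6d voxels\n", nm, sum(x$rois[[nm]])))
  invisible(x)
}

#' Forward-simulate a dynamic PET study from a phantom
#'
#' Every voxel receives the frame-averaged tissue curve of its label
#' (arterial voxels carry the input function itself), computed by the
#' convolution forward model of the kinetics module. Optional zero-mean
#' Gaussian noise with variance proportional to activity over frame duration
#' emulates post-reconstruction frame noise; all randomness derives from the
#' spec seed, so equal seeds give bit-identical studies.
#'
#' @param phantom a `phantom` from [make_phantom()].
#' @param fs a [frame_schedule()] (default [default_frame_schedule()]).
#' @return object of class `dynamic_study`: 4D array `data` (Bq mL^-1),
#'   `schedule`, `voxel_mm`, and `truth` (the phantom).
#' @export
simulate_study <- function(phantom, fs = default_frame_schedule()) {
  stopifnot(inherits(phantom, "phantom"), inherits(fs, "frame_schedule"))
  spec <- phantom$spec
  dm <- spec$shape
  tgrid <- seq(0, fs$end[fs$n], by = 1)
  aif <- phantom_aif(tgrid, spec$aif_params)
  data <- array(0, c(dm, fs$n))
  nvox <- prod(dm)
  for (nm in names(spec$tissues)) {
    ts <- spec$tissues[[nm]]
    m <- phantom$rois[[nm]]
    if (!any(m)) next
    tac <- simulate_tissue_tac(tgrid, aif, ts$kp, fs,
                               density_g_ml = ts$density)
    for (j in seq_len(fs$n)) {
      plane <- data[, , , j]
      plane[m] <- tac[j]
      data[, , , j] <- plane
    }
  }
  if (spec$noise_level > 0) {
    set.seed(spec$seed)
    for (j in seq_len(fs$n)) {
      sd_j <- spec$noise_level * sqrt(pmax(data[, , , j], 0) /
                                        (fs$dur[j] / 10))
      data[, , , j] <- data[, , , j] +
        stats::rnorm(nvox, 0, 1) * sd_j
    }
    data[data < 0] <- 0
  }
  structure(list(data = data, schedule = fs, voxel_mm = spec$voxel_mm,
                 truth = phantom, seed = spec$seed),
            class = "dynamic_study")
}

#' @export
print.dynamic_study <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("dynamic_study: %dx%dx%d voxels, %d frames over %g s\n",
              d[1], d[2], d[3], d[4], x$schedule$span))
  invisible(x)
}

#' Write a dynamic study as 4D NIfTI-1 plus a BIDS-style timing sidecar
#'
#' @param study a `dynamic_study`.
#' @param path output `.nii` path; timing JSON written alongside with fields
#'   `FrameTimesStart` and `FrameDuration` (seconds).
#' @export
write_dynamic_study <- function(study, path) {
  stopifnot(inherits(study, "dynamic_study"))
  write_nifti(study$data, path, voxel_mm = study$voxel_mm)
  side <- sub("\\.nii$", ".json", path)
  jsonlite::write_json(list(FrameTimesStart = study$schedule$start,
                            FrameDuration = study$schedule$dur),
                       side, digits = NA)
  invisible(c(path, side))
}

#' Read a dynamic study written by [write_dynamic_study()]
#' @param path `.nii` path with a timing JSON sidecar.
#' @export
read_dynamic_study <- function(path) {
  vol <- read_nifti(path)
  side <- jsonlite::read_json(sub("\\.nii$", ".json", path),
                              simplifyVector = TRUE)
  fs <- frame_schedule(side$FrameDuration, start_s = side$FrameTimesStart[1])
  structure(list(data = vol$data, schedule = fs, voxel_mm = vol$voxel_mm,
                 truth = NULL, seed = NA_integer_),
            class = "dynamic_study")
}
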