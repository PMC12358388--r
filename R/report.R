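#' Threshold segmentation rule
#'
#' @param fraction threshold as a fraction of the parent region's maximum
#'   uptake (default 0.30, the conventional 30 percent SUVmax isocontour).
#' @return object of class `segmentation_rule`.
#' @export
segmentation_rule <- function(fraction = 0.30) {
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)")
  structure(list(fraction = fraction), class = "segmentation_rule")
}

#' Threshold-based tumor segmentation
#'
#' Selects voxels of the parent ROI whose uptake is at or above
#' `fraction * max(uptake in parent)`, the automated analogue of a
#' percent-of-SUVmax isocontour. Also returns the remainder of the parent
#' ("normal" tissue, e.g. prostate minus tumor).
#'
#' @param uptake_map numeric array (static uptake image).
#' @param parent_roi logical array, non-empty.
#' @param rule a [segmentation_rule()].
#' @return list `tumor`, `normal` (logical arrays), `threshold`.
#' @export
segment_tumor <- function(uptake_map, parent_roi, rule = segmentation_rule()) {
  stopifnot(inherits(rule, "segmentation_rule"))
  if (!identical(dim(uptake_map), dim(parent_roi))) stop("geometry mismatch")
  if (!any(parent_roi)) stop("parent ROI is empty")
  thr <- rule$fraction * max(uptake_map[parent_roi])
  tumor <- parent_roi & uptake_map >= thr
  if (!any(tumor)) warning("threshold segmentation selected no voxels")
  list(tumor = tumor, normal = parent_roi & !tumor, threshold = thr)
}

#' Dice similarity coefficient between two masks
#' @param a,b logical arrays of identical shape.
#' @return 2|A n B| / (|A| + |B|).
#' @export
dice <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}

#' Pipeline configuration
#'
#' Bundles everything one pipeline run needs. Defaults reproduce the
#' package's standard scenario: 325 MBq diagnostic F-18 study scaled to a
#' 7.4-GBq Lu-177 therapy cycle.
#'
#' @param phantom_spec a [phantom_spec()] (synthetic input; alternatively set
#'   `study_path` to a 4D NIfTI written by [write_dynamic_study()]).
#' @param study_path optional path to a stored dynamic study.
#' @param a_diag_gbq administered diagnostic activity, GBq.
#' @param a_ther_gbq administered therapeutic activity per cycle, GBq.
#' @param engine dose engine mode, `"local"` or `"kernel"`.
#' @param radiobio a [radiobio_params()].
#' @param delay_window_min Logan delay window, minutes.
#' @param seg_rule a [segmentation_rule()].
#' @param out_dir output directory.
#' @param seed integer; all pipeline randomness derives from it.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(phantom_spec = NULL, study_path = NULL,
                            a_diag_gbq = 0.325, a_ther_gbq = 7.4,
                            engine = "local",
                            radiobio = radiobio_params(),
                            delay_window_min = c(2.33, 8),
                            seg_rule = segmentation_rule(),
                            out_dir = tempfile("trtdose_run_"),
                            seed = 1) {
  if (is.null(phantom_spec) && is.null(study_path))
    stop("provide a phantom_spec or a study_path")
  if (a_diag_gbq <= 0 || a_ther_gbq <= 0) stop("activities must be > 0")
  if (is.null(phantom_spec)) stop("stored-study ingestion requires ROI masks; ",
                                  "only the phantom route is bundled")
  phantom_spec$seed <- seed
  structure(list(phantom_spec = phantom_spec, study_path = study_path,
                 a_diag_gbq = a_diag_gbq, a_ther_gbq = a_ther_gbq,
                 engine = engine, radiobio = radiobio,
                 delay_window_min = delay_window_min, seg_rule = seg_rule,
                 out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

#' Run the full dosimetry pipeline
#'
#' simulate -> extract AIF -> fit/extrapolate -> Logan LDV maps -> TIA ->
#' absorbed dose -> BED -> per-ROI tables and DVHs. Writes per-cycle and
#' per-GBq ROI tables (full precision CSV plus one-decimal display CSV),
#' DVH CSVs, NIfTI maps and a JSON provenance log into `cfg$out_dir`.
#'
#' @param cfg a [pipeline_config()].
#' @param write logical; write output files (default TRUE). The result
#'   object is returned either way.
#' @return list with all intermediate objects and the report tables.
#' @export
run_pipeline <- function(cfg, write = TRUE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  ph <- make_phantom(cfg$phantom_spec)
  study <- simulate_study(ph)
  fs <- study$schedule

  curve <- extract_aif(study, ph$rois$artery)
  fit <- fit_aif(curve, n_exp = 2)
  lu <- lu177_data()
  f18 <- f18_data()
  # horizon: five effective half-lives of the therapy nuclide, biological
  # half-life from the slowest fitted clearance (decay-corrected)
  r_slow <- min(fit$r)                       # min^-1, includes F-18 decay
  r_bio <- max(r_slow - f18$lam_per_min, 1e-6)
  t_eff_min <- effective_half_life(log(2) / lu$lam_per_min, log(2) / r_bio)
  horizon_s <- 5 * t_eff_min * 60
  auc_ther <- therapy_auc(fit, lam_diag = f18$lam_per_min,
                          lam_ther = lu$lam_per_min,
                          A_diag = cfg$a_diag_gbq, A_ther = cfg$a_ther_gbq,
                          horizon_s = horizon_s)

  body_mask <- array(TRUE, dim(ph$labels)) & !ph$rois$artery
  pm <- ldv_map(study, curve, body_mask, density = ph$density,
                delay_grid = logan_delay_grid(fs, cfg$delay_window_min))
  vvol <- prod(study$voxel_mm) / 1000        # mm^3 -> mL
  tia <- tia_map(pm, ph$density, vvol, auc_ther)
  dose <- absorbed_dose(tia, ph$density, lu, mode = cfg$engine)
  dose_per_gbq <- normalize_per_gbq(dose, cfg$a_ther_gbq)
  bedm <- bed_map(dose, cfg$radiobio)

  seg <- segment_tumor(ph$uptake, ph$rois$prostate | ph$rois$tumor,
                       cfg$seg_rule)
  rois <- list(tumor = seg$tumor,
               total_prostate = ph$rois$prostate | ph$rois$tumor,
               normal_prostate = seg$normal,
               marrow = ph$rois$marrow)

  tab <- function(map) {
    do.call(rbind, lapply(names(rois), function(nm) {
      cbind(data.frame(roi = nm), roi_stats(map, rois[[nm]]))
    }))
  }
  tables <- list(ldv = tab(pm), dose_gy = tab(dose),
                 dose_gy_per_gbq = tab(dose_per_gbq), bed_gy = tab(bedm))
  dvhs <- lapply(rois, function(r) dvh(dose, r))

  prov <- list(seed = cfg$seed, engine = cfg$engine,
               a_diag_gbq = cfg$a_diag_gbq, a_ther_gbq = cfg$a_ther_gbq,
               auc_ther_bq_s_per_ml = auc_ther, horizon_s = horizon_s,
               nuclide = lu$name, G = bedm$G,
               package_version = as.character(utils::packageVersion("trtdose")))

  if (write) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(tables)) {
      utils::write.csv(tables[[nm]],
                       file.path(cfg$out_dir, paste0("roi_", nm, ".csv")),
                       row.names = FALSE)
      disp <- tables[[nm]]
      num <- vapply(disp, is.numeric, logical(1))
      disp[num] <- lapply(disp[num], round_half_up, digits = 1)
      utils::write.csv(disp,
                       file.path(cfg$out_dir,
                                 paste0("roi_", nm, "_display.csv")),
                       row.names = FALSE)
    }
    for (nm in names(dvhs))
      utils::write.csv(dvhs[[nm]],
                       file.path(cfg$out_dir, paste0("dvh_", nm, ".csv")),
                       row.names = FALSE)
    write_parametric_maps(pm, cfg$out_dir)
    write_map(tia, file.path(cfg$out_dir, "tia.nii"))
    write_map(dose, file.path(cfg$out_dir, "dose_gy.nii"))
    write_map(bedm, file.path(cfg$out_dir, "bed_gy.nii"))
    jsonlite::write_json(prov, file.path(cfg$out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(phantom = ph, study = study, aif = curve, aif_fit = fit,
                 auc_ther = auc_ther, maps = pm, tia = tia, dose = dose,
                 dose_per_gbq = dose_per_gbq, bed = bedm, rois = rois,
                 tables = tables, dvhs = dvhs, provenance = prov))
}

#' Half-up decimal rounding
#'
#' Report tables round half away from zero at one decimal (matching the
#' field's printed tables), unlike R's banker's rounding.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Cohort summary of per-subject values
#'
#' @param values numeric vector (one value per subject) or a data.frame whose
#'   numeric columns are summarized column-wise.
#' @return data.frame `mean`, `sd` (sample, n-1; NA for a single subject),
#'   `cov_pct`, `median`, `min`, `max`, `n`.
#' @export
summarize_cohort <- function(values) {
  if (is.data.frame(values)) {
    num <- names(values)[vapply(values, is.numeric, logical(1))]
    out <- do.call(rbind, lapply(num, function(nm)
      cbind(data.frame(variable = nm), summarize_cohort(values[[nm]]))))
    return(out)
  }
  if (!length(values)) stop("at least one subject required")
  n <- length(values)
  m <- mean(values)
  s <- if (n > 1) stats::sd(values) else NA_real_
  data.frame(mean = m, sd = s,
             cov_pct = if (is.na(s) || m == 0) NA_real_ else 100 * s / m,
             median = stats::median(values), min = min(values),
             max = max(values), n = n)
}
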