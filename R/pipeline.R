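## End-to-end orchestration: phantom cohort simulation, evaluation of
## predicted against reference volumes, flap extraction + morphometry,
## and mesh export, driven by a flat YAML configuration. All tabular
## outputs are deterministic given the configured seeds.

#' Build or load a run configuration
#'
#' The configuration is a flat YAML file (or an equivalent named list)
#' validated against a small schema. Unknown keys are rejected; defaults
#' fill in everything else. Fields under `phantom` may be scalars or
#' `[min, max]` ranges, sampled uniformly per patient.
#'
#' @param x path to a YAML file, or a named list.
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(x = list()) {
  if (is.character(x)) {
    if (!file.exists(x)) stop_io("config file not found: %s", x)
    x <- yaml::read_yaml(x)
  }
  defaults <- list(
    mode = "full",
    output_dir = "taadmorph_run",
    seed = 1L,
    n_patients = 4L,
    cv_folds = 4L,
    hd_units = "mm",
    slice_range = NULL,
    phantom = list(n_slices = 40L, grid_shape = c(96L, 96L),
                   spacing = c(1.25, 0.8242, 0.8242),
                   outer_diameter = c(40, 55), flap_thickness = c(2, 3),
                   flap_offset = c(3, 9), flap_angle = c(0, pi),
                   centerline_amplitude = 5),
    degradation = list(boundary_shift_mm = 0.9, flip_fraction = 0.05,
                       dropout_slices = 0L),
    contour = list(max_iterations = 50L, smoothing_passes = 2L,
                   convergence_window = 3L, init_dilation_mm = 3,
                   adjacency_required = TRUE, engine = "active_contour"),
    patients = NULL
  )
  unknown <- setdiff(names(x), names(defaults))
  if (length(unknown) > 0L)
    stop_validation("unknown config keys: %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, x)
  if (!cfg$mode %in% c("simulate", "evaluate", "quantify", "full"))
    stop_validation("mode must be one of simulate/evaluate/quantify/full (got %s)",
                    cfg$mode)
  if (!cfg$hd_units %in% c("mm", "voxel"))
    stop_validation("hd_units must be 'mm' or 'voxel'")
  if (cfg$mode %in% c("evaluate", "quantify") && is.null(cfg$patients))
    stop_validation("mode '%s' needs a 'patients' list of gt/pred paths", cfg$mode)
  class(cfg) <- c("run_config", "list")
  cfg
}

pipeline_log <- function(state, level, fmt, ...) {
  line <- sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  level, sprintf(fmt, ...))
  message(line)
  if (!is.null(state$log_path)) cat(line, "\n", file = state$log_path,
                                    append = TRUE, sep = "")
  invisible(NULL)
}

## Sample a scalar-or-range phantom field.
sample_field <- function(v) {
  if (length(v) == 2L && is.numeric(v) && v[2] > v[1]) runif(1, v[1], v[2])
  else v[1]
}

#' Run the post-segmentation analysis pipeline
#'
#' Executes the stage chain requested by `config$mode`:
#' `simulate` generates a phantom cohort (ground truth, full truth and
#' degraded prediction per patient, written as NIfTI); `evaluate`
#' computes per-patient six-metric tables with cross-validation fold
#' assignment and a mean/SD summary; `quantify` extracts the flap from
#' both reference and prediction, computes per-patient morphometry,
#' relative errors and surface meshes; `full` chains all three on the
#' simulated cohort. Every skipped slice or patient is logged with a
#' reason. Deterministic given `config$seed`.
#'
#' @param config a [run_config()], a path to a YAML config, or a list.
#' @return a summary list: output paths per stage plus headline numbers
#'   (mean DSC per label, mean relative errors).
#' @export
run_pipeline <- function(config = run_config()) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  state <- list(log_path = file.path(cfg$output_dir, "run.log"))
  cat("", file = state$log_path)  # truncate
  yaml::write_yaml(unclass(cfg), file.path(cfg$output_dir, "config_used.yaml"))
  params <- do.call(contour_params, cfg$contour)
  summary <- list(output_dir = cfg$output_dir, mode = cfg$mode,
                  paths = list(), headline = list())

  patients <- cfg$patients
  cohort <- NULL
  if (cfg$mode %in% c("simulate", "full")) {
    pipeline_log(state, "INFO", "simulate: generating %d phantom patients",
                 cfg$n_patients)
    pdir <- file.path(cfg$output_dir, "patients")
    dir.create(pdir, showWarnings = FALSE)
    cohort <- list()
    truth_rows <- list()
    for (i in seq_len(cfg$n_patients)) {
      pid <- sprintf("p%02d", i)
      spec <- withr::with_seed(cfg$seed + i, {
        ph <- cfg$phantom
        phantom_spec(n_slices = ph$n_slices, grid_shape = ph$grid_shape,
                     spacing = ph$spacing,
                     outer_diameter = sample_field(ph$outer_diameter),
                     flap_thickness = sample_field(ph$flap_thickness),
                     flap_offset = sample_field(ph$flap_offset),
                     flap_angle = sample_field(ph$flap_angle),
                     centerline_amplitude = sample_field(ph$centerline_amplitude),
                     seed = cfg$seed + i)
      })
      phant <- generate_phantom(spec)
      dspec <- degradation_spec(
        boundary_shift_mm = cfg$degradation$boundary_shift_mm,
        flip_fraction = cfg$degradation$flip_fraction,
        dropout_slices = cfg$degradation$dropout_slices,
        seed = cfg$seed + 1000L + i)
      pred <- degrade_prediction(phant$annotation, dspec)
      gt_path <- file.path(pdir, paste0(pid, "_gt.nii.gz"))
      full_path <- file.path(pdir, paste0(pid, "_fulltruth.nii.gz"))
      pred_path <- file.path(pdir, paste0(pid, "_pred.nii.gz"))
      write_label_volume(phant$annotation, gt_path)
      write_label_volume(phant$full, full_path)
      write_label_volume(pred, pred_path)
      truth_rows[[i]] <- cbind(data.frame(patient_id = pid), phant$truth)
      cohort[[pid]] <- list(id = pid, gt = gt_path, pred = pred_path,
                            full = full_path)
    }
    truth_csv <- file.path(cfg$output_dir, "phantom_truth.csv")
    write.csv(do.call(rbind, truth_rows), truth_csv, row.names = FALSE)
    summary$paths$phantom_truth <- truth_csv
    patients <- cohort
  }
  if (is.null(patients) && cfg$mode %in% c("evaluate", "quantify"))
    patients <- cfg$patients
  if (!is.null(patients) && is.null(names(patients)))
    names(patients) <- vapply(patients, function(p) p$id, character(1))

  load_pair <- function(p, stage) {
    gt <- tryCatch(read_label_volume(p$gt), error = function(e)
      stop(sprintf("%s: patient %s: %s", stage, p$id, conditionMessage(e)),
           call. = FALSE))
    pred <- tryCatch(read_label_volume(p$pred), error = function(e)
      stop(sprintf("%s: patient %s: %s", stage, p$id, conditionMessage(e)),
           call. = FALSE))
    tryCatch(check_matched_volumes(gt, pred), error = function(e)
      stop(sprintf("%s: patient %s: %s", stage, p$id, conditionMessage(e)),
           call. = FALSE))
    list(gt = gt, pred = pred)
  }

  if (cfg$mode %in% c("evaluate", "full")) {
    pipeline_log(state, "INFO", "evaluate: %d patients", length(patients))
    layout <- if (length(patients) >= 2L)
      make_cv_layout(names(patients), k = min(cfg$cv_folds, length(patients)),
                     seed = cfg$seed)
    else data.frame(patient_id = names(patients), fold = NA_integer_)
    rows <- list()
    for (p in patients) {
      pair <- load_pair(p, "evaluate")
      pm <- withCallingHandlers(
        patient_metrics(pair$gt, pair$pred, hd_units = cfg$hd_units),
        warning = function(w) {
          pipeline_log(state, "WARN", "evaluate: patient %s: %s", p$id,
                       conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      pm <- cbind(data.frame(patient_id = p$id), pm)
      rows[[p$id]] <- pm
    }
    metrics <- do.call(rbind, rows)
    metrics$fold <- layout$fold[match(metrics$patient_id, layout$patient_id)]
    rownames(metrics) <- NULL
    metrics_csv <- file.path(cfg$output_dir, "metrics.csv")
    write.csv(metrics, metrics_csv, row.names = FALSE)
    summary_csv <- file.path(cfg$output_dir, "metrics_summary.csv")
    write.csv(summarize_metrics(metrics), summary_csv, row.names = FALSE)
    summary$paths$metrics <- metrics_csv
    summary$paths$metrics_summary <- summary_csv
    for (lb in unique(metrics$label))
      summary$headline[[paste0("mean_dsc_", lb)]] <-
        mean(metrics$dsc[metrics$label == lb], na.rm = TRUE)
  }

  if (cfg$mode %in% c("quantify", "full")) {
    pipeline_log(state, "INFO", "quantify: %d patients", length(patients))
    fdir <- file.path(cfg$output_dir, "flap")
    mdir <- file.path(cfg$output_dir, "meshes")
    dir.create(fdir, showWarnings = FALSE)
    dir.create(mdir, showWarnings = FALSE)
    gt_rows <- list(); pred_rows <- list()
    for (p in patients) {
      pair <- load_pair(p, "quantify")
      srange <- NULL
      if (!is.null(cfg$slice_range)) {
        srange <- if (is.list(cfg$slice_range)) cfg$slice_range[[p$id]]
          else cfg$slice_range
      }
      for (side in c("gt", "pred")) {
        vol <- pair[[side]]
        flapped <- extract_flap_volume(vol, params)
        skip <- attr(flapped, "skip_log")
        if (nrow(skip) > 0L)
          pipeline_log(state, "WARN",
                       "quantify: patient %s (%s): %d slice(s) skipped (%s)",
                       p$id, side, nrow(skip),
                       paste(unique(skip$reason), collapse = "; "))
        write_label_volume(flapped,
                           file.path(fdir, sprintf("%s_%s_flap.nii.gz", p$id, side)))
        morpho <- tryCatch(
          patient_morphometry(flapped, slice_range = srange, patient_id = p$id),
          taadmorph_exclusion = function(e) {
            pipeline_log(state, "WARN", "quantify: %s", conditionMessage(e))
            NULL
          })
        if (side == "gt") gt_rows[[p$id]] <- morpho else pred_rows[[p$id]] <- morpho
        for (lb in c(TL = 1L, FL = 2L)) {
          if (!any(flapped$voxels == lb)) next
          mesh <- stack_to_mesh(flapped, lb)
          write_mesh_stl(mesh, file.path(mdir,
            sprintf("%s_%s_label%d.stl", p$id, side, lb)))
        }
      }
    }
    keep <- intersect(names(gt_rows)[!vapply(gt_rows, is.null, logical(1))],
                      names(pred_rows)[!vapply(pred_rows, is.null, logical(1))])
    if (length(keep) > 0L) {
      gt_df <- do.call(rbind, gt_rows[keep])
      pred_df <- do.call(rbind, pred_rows[keep])
      morpho_csv <- file.path(cfg$output_dir, "morphometry.csv")
      both <- rbind(cbind(data.frame(source = "gt"), as.data.frame(gt_df)),
                    cbind(data.frame(source = "pred"), as.data.frame(pred_df)))
      write.csv(both, morpho_csv, row.names = FALSE)
      cmp <- compare_morphometry(gt_df, pred_df)
      cmp_csv <- file.path(cfg$output_dir, "morphometry_comparison.csv")
      write.csv(as.data.frame(cmp), cmp_csv, row.names = FALSE)
      summary$paths$morphometry <- morpho_csv
      summary$paths$morphometry_comparison <- cmp_csv
      for (i in seq_len(nrow(cmp)))
        summary$headline[[paste0("re_", cmp$field[i])]] <-
          cmp$mean_relative_error[i]
    }
    summary$paths$flap_dir <- fdir
    summary$paths$mesh_dir <- mdir
  }

  pipeline_log(state, "INFO", "done: outputs in %s", cfg$output_dir)
  summary
}
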