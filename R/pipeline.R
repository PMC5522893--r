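#' Read a study configuration file
#'
#' Plain-text `key = value` configuration (one per line, `#` comments).
#' Recognised keys: `hip_landmarks`, `spine_landmarks`, `cohort`, `out_dir`,
#' `tol`, `max_iter`, `n_retained_hip`, `n_retained_spine`, `threshold`,
#' `flag_rule`, `seed`.
#'
#' @param path Path to the configuration file.
#' @return A named list suitable for [run_study()].
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop(glue::glue("config file not found: {path}"), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  cfg <- stats::setNames(
    lapply(kv, function(p) trimws(paste(p[-1], collapse = "="))),
    vapply(kv, function(p) trimws(p[1]), "")
  )
  numeric_keys <- c(
    "tol", "max_iter", "n_retained_hip", "n_retained_spine", "threshold", "seed"
  )
  for (key in intersect(numeric_keys, names(cfg))) {
    cfg[[key]] <- as.numeric(cfg[[key]])
  }
  cfg
}

study_defaults <- function() {
  list(
    tol = 1e-8, max_iter = 100L,
    n_retained_hip = 10L, n_retained_spine = 8L,
    threshold = 0.1, flag_rule = "geq", seed = 1L
  )
}

#' Run the full two-joint shape study
#'
#' Orchestrates the complete flow: read hip and spine landmark files and the
#' cohort table; Procrustes-align and fit a shape model per joint (each model
#' is fitted on every subject with a usable scan of that joint); score;
#' restrict the statistics to the subjects present in hip, spine and cohort
#' inputs simultaneously; and write sex-difference tables, CRF-adjusted
#' covariate correlation tables, the hip x spine cross-correlation table by
#' sex, scree/score CSVs, model JSONs, +/-2 SD mode reconstructions, a
#' cohort-accounting log and a run manifest.
#'
#' @param config A named list (see [read_study_config()]) with at least
#'   `hip_landmarks`, `spine_landmarks`, `cohort` and `out_dir`.
#' @return Invisibly, a list with the fitted models, score tables and all
#'   result tables; everything is also written under `config$out_dir`.
#' @export
run_study <- function(config) {
  cfg <- utils::modifyList(study_defaults(), config)
  for (key in c("hip_landmarks", "spine_landmarks", "cohort", "out_dir")) {
    if (is.null(cfg[[key]])) stop(glue::glue("config key '{key}' is required"), call. = FALSE)
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "study.log")
  log_lines <- character(0)
  say <- function(stage, msg) {
    line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage, msg)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(glue::glue("stage '{stage}' failed: {conditionMessage(e)}"), call. = FALSE)
    })
  }

  hip_tpl <- builtin_template("hip")
  spine_tpl <- builtin_template("spine")
  hip_lmk <- run_stage("read_hip", read_landmarks(cfg$hip_landmarks, hip_tpl))
  spine_lmk <- run_stage("read_spine", read_landmarks(cfg$spine_landmarks, spine_tpl))
  records <- run_stage("read_cohort", read_cohort_table(cfg$cohort))

  hip_ids <- unique(hip_lmk$subject_id)
  spine_ids <- unique(spine_lmk$subject_id)
  say("accounting", sprintf(
    "hip scans: %d; spine scans: %d; cohort records: %d",
    length(hip_ids), length(spine_ids), nrow(records)
  ))
  joint_ids <- intersect(intersect(hip_ids, spine_ids), records$subject_id)
  say("accounting", sprintf("joint analysis set (hip & spine & cohort): %d", length(joint_ids)))
  if (length(joint_ids) == 0L) stop("empty joint subject set", call. = FALSE)

  fit_joint <- function(stage, lmk, n_retained) {
    run_stage(stage, {
      aligned <- gpa(lmk, tol = cfg$tol, max_iter = cfg$max_iter)
      model <- fit_shape_model(aligned, n_retained = n_retained)
      scores <- score_shapes(model, lmk)
      list(aligned = aligned, model = model, scores = scores)
    })
  }
  hip <- fit_joint("hip_model", hip_lmk, cfg$n_retained_hip)
  say("hip_model", sprintf(
    "fitted on %d shapes, %d iterations, retained %d modes (%.1f%% variance)",
    hip$model$n, hip$aligned$n_iterations, hip$model$n_retained,
    sum(hip$model$pct_variance[seq_len(hip$model$n_retained)])
  ))
  spine <- fit_joint("spine_model", spine_lmk, cfg$n_retained_spine)
  say("spine_model", sprintf(
    "fitted on %d shapes, %d iterations, retained %d modes (%.1f%% variance)",
    spine$model$n, spine$aligned$n_iterations, spine$model$n_retained,
    sum(spine$model$pct_variance[seq_len(spine$model$n_retained)])
  ))

  joint_scores <- function(scores) scores[scores$subject_id %in% joint_ids, ]
  hip_scores <- joint_scores(hip$scores)
  spine_scores <- joint_scores(spine$scores)
  joint_records <- records[records$subject_id %in% joint_ids, ]

  sex_hip <- run_stage("sex_tables", sex_difference_table(hip_scores, joint_records))
  sex_spine <- run_stage("sex_tables", sex_difference_table(spine_scores, joint_records))
  corr_hip <- run_stage("correlation_tables", correlation_table(
    hip_scores, joint_records, c("height_m", "weight_kg", "bmi", "hip_bmd"),
    adjust_crf = TRUE, threshold = cfg$threshold, flag_rule = cfg$flag_rule
  ))
  corr_spine <- run_stage("correlation_tables", correlation_table(
    spine_scores, joint_records, c("height_m", "weight_kg", "bmi", "spine_bmd"),
    adjust_crf = TRUE, threshold = cfg$threshold, flag_rule = cfg$flag_rule
  ))
  cross <- run_stage("cross_correlation", cross_correlation_table(
    hip_scores, spine_scores, joint_records,
    adjust_crf = TRUE, threshold = cfg$threshold, flag_rule = cfg$flag_rule
  ))

  out_csv <- function(x, name) {
    readr::write_csv(x, file.path(cfg$out_dir, name), progress = FALSE)
  }
  run_stage("write_outputs", {
    write_shape_model(hip$model, file.path(cfg$out_dir, "hip_model.json"), seed = cfg$seed)
    write_shape_model(spine$model, file.path(cfg$out_dir, "spine_model.json"), seed = cfg$seed)
    out_csv(scree_table(hip$model), "hip_scree.csv")
    out_csv(scree_table(spine$model), "spine_scree.csv")
    out_csv(hip$scores, "hip_scores.csv")
    out_csv(spine$scores, "spine_scores.csv")
    out_csv(sex_hip, "hip_sex_differences.csv")
    out_csv(sex_spine, "spine_sex_differences.csv")
    out_csv(corr_hip, "hip_covariate_correlations.csv")
    out_csv(corr_spine, "spine_covariate_correlations.csv")
    out_csv(cross, "hip_spine_cross_correlations.csv")
    recon <- dplyr::bind_rows(lapply(list(hip$model, spine$model), function(model) {
      purrr::map_dfr(seq_len(model$n_retained), function(mode) {
        dplyr::bind_rows(
          dplyr::mutate(reconstruct_shape(model, mode, -2), k_sd = -2),
          dplyr::mutate(reconstruct_shape(model, mode, 2), k_sd = 2)
        ) |>
          dplyr::mutate(template = model$template, mode = mode)
      })
    }))
    # coordinates use the image pixel convention: origin top-left, x rightward,
    # y downward, consensus-aligned unit-centroid-size units
    out_csv(
      recon[, c("template", "mode", "k_sd", "point", "x", "y")],
      "mode_reconstructions_pm2sd.csv"
    )
    manifest <- list(
      tool = "shapemodes",
      version = as.character(utils::packageVersion("shapemodes")),
      seed = cfg$seed,
      tol = cfg$tol, max_iter = cfg$max_iter,
      n_hip = hip$model$n, n_spine = spine$model$n, n_joint = length(joint_ids),
      n_retained_hip = hip$model$n_retained,
      n_retained_spine = spine$model$n_retained,
      threshold = cfg$threshold, flag_rule = cfg$flag_rule,
      coordinate_convention = "image pixels: origin top-left, x rightward, y downward"
    )
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
      auto_unbox = TRUE, pretty = TRUE
    )
  })
  writeLines(log_lines, log_path)

  invisible(list(
    hip = hip, spine = spine,
    joint_ids = joint_ids,
    sex_hip = sex_hip, sex_spine = sex_spine,
    corr_hip = corr_hip, corr_spine = corr_spine,
    cross = cross
  ))
}
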