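#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

#' Landmark tables
#'
#' Throughout the package a landmark cohort is a tidy tibble with one row per
#' landmark point per subject and columns `subject_id`, `template`, `point`
#' (1-based index in template order), `x`, `y` (pixels, origin top-left,
#' y downward) and optionally `width`, `height` (source image size in pixels).
#'
#' @param landmarks A landmark tibble.
#' @param template A `point_template` (see [builtin_template()]), or `NULL` to
#'   skip the point-count check against a template.
#' @return `validate_landmarks()` returns its input invisibly, erroring if the
#'   table is malformed.
#' @export
validate_landmarks <- function(landmarks, template = NULL) {
  required <- c("subject_id", "template", "point", "x", "y")
  missing_cols <- setdiff(required, names(landmarks))
  if (length(missing_cols) > 0) {
    stop(glue::glue(
      "landmark table is missing column(s): {paste(missing_cols, collapse = ', ')}"
    ), call. = FALSE)
  }
  if (nrow(landmarks) == 0L) stop("landmark table is empty", call. = FALSE)
  if (!all(is.finite(landmarks$x)) || !all(is.finite(landmarks$y))) {
    stop("landmark coordinates must all be finite", call. = FALSE)
  }
  counts <- dplyr::count(landmarks, .data$subject_id)
  if (!is.null(template)) {
    bad <- counts$subject_id[counts$n != template$n_points]
    if (length(bad) > 0) {
      stop(glue::glue(
        "subject(s) {paste(bad, collapse = ', ')} do not have ",
        "{template$n_points} points as required by template '{template$name}'"
      ), call. = FALSE)
    }
  } else if (length(unique(counts$n)) != 1L) {
    stop("subjects have differing point counts", call. = FALSE)
  }
  sizes <- landmarks |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      cs = sqrt(sum((.data$x - mean(.data$x))^2 + (.data$y - mean(.data$y))^2)),
      .groups = "drop"
    )
  degenerate <- sizes$subject_id[sizes$cs <= 0]
  if (length(degenerate) > 0) {
    stop(glue::glue(
      "degenerate configuration (all points coincident) for subject(s): ",
      "{paste(degenerate, collapse = ', ')}"
    ), call. = FALSE)
  }
  invisible(landmarks)
}

#' Read landmark configurations from a landmark TSV file
#'
#' The file format is a plain-text TSV dialect: comment lines start with `#`;
#' each subject block starts with a header line
#' `>subject_id<TAB>template_name[<TAB>width<TAB>height]` followed by one line
#' per point, `index<TAB>x<TAB>y`, with a 0-based index in template order;
#' blocks are separated by blank lines.
#'
#' @param path Path to a landmark TSV file.
#' @param template A `point_template` each block is validated against.
#' @return A landmark tibble (see [validate_landmarks()]), subjects in file
#'   order.
#' @export
read_landmarks <- function(path, template) {
  if (!file.exists(path)) stop(glue::glue("file not found: {path}"), call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^#", lines)
  blocks <- list()
  current <- NULL
  flush_block <- function(current) {
    if (is.null(current)) return(NULL)
    if (length(current$rows) != template$n_points) {
      stop(glue::glue(
        "subject '{current$id}' (header at line {current$line}) has ",
        "{length(current$rows)} points, template '{template$name}' requires ",
        "{template$n_points}"
      ), call. = FALSE)
    }
    current
  }
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    line <- lines[i]
    if (!nzchar(trimws(line))) {
      blk <- flush_block(current)
      if (!is.null(blk)) blocks[[length(blocks) + 1L]] <- blk
      current <- NULL
      next
    }
    if (startsWith(line, ">")) {
      blk <- flush_block(current)
      if (!is.null(blk)) blocks[[length(blocks) + 1L]] <- blk
      fields <- strsplit(sub("^>", "", line), "\t", fixed = TRUE)[[1]]
      if (length(fields) < 2L) {
        stop(glue::glue("malformed block header at line {i}"), call. = FALSE)
      }
      size <- if (length(fields) >= 4L) suppressWarnings(as.numeric(fields[3:4])) else c(NA_real_, NA_real_)
      current <- list(
        id = fields[1], template = fields[2], line = i,
        width = size[1], height = size[2], rows = list()
      )
    } else {
      if (is.null(current)) {
        stop(glue::glue("point line outside any subject block at line {i}"), call. = FALSE)
      }
      fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(fields) != 3L) {
        stop(glue::glue("expected 'index<TAB>x<TAB>y' at line {i}"), call. = FALSE)
      }
      vals <- suppressWarnings(as.numeric(fields))
      if (any(is.na(vals))) {
        stop(glue::glue("non-numeric coordinate at line {i}"), call. = FALSE)
      }
      current$rows[[length(current$rows) + 1L]] <- vals
    }
  }
  blk <- flush_block(current)
  if (!is.null(blk)) blocks[[length(blocks) + 1L]] <- blk
  if (length(blocks) == 0L) stop(glue::glue("no landmark blocks found in {path}"), call. = FALSE)

  ids <- vapply(blocks, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop(glue::glue("duplicate subject id(s): {paste(dup, collapse = ', ')}"), call. = FALSE)
  }
  np <- template$n_points
  out <- purrr::map_dfr(blocks, function(b) {
    m <- do.call(rbind, b$rows)
    ord <- order(m[, 1])
    m <- m[ord, , drop = FALSE]
    if (!identical(as.integer(m[, 1]), 0:(np - 1L))) {
      stop(glue::glue(
        "subject '{b$id}': point indices must be 0..{np - 1} exactly"
      ), call. = FALSE)
    }
    tibble(
      subject_id = b$id, template = b$template,
      point = seq_len(np),
      x = m[, 2], y = m[, 3],
      width = b$width, height = b$height
    )
  })
  validate_landmarks(out, template)
  out
}

#' Write landmark configurations to a landmark TSV file
#'
#' @param landmarks A landmark tibble (homogeneous template).
#' @param path Output path.
#' @param comment Optional character vector written as leading `#` comment
#'   lines (for example a coordinate-convention note).
#' @return `path`, invisibly. Subject blocks are written in order of
#'   `subject_id` so output is stable.
#' @export
write_landmarks <- function(landmarks, path, comment = NULL) {
  if (is.null(landmarks) || nrow(landmarks) == 0L) {
    stop("cannot write an empty landmark table", call. = FALSE)
  }
  validate_landmarks(landmarks)
  if (length(unique(landmarks$template)) != 1L) {
    stop("all configurations must share one template", call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  has_size <- all(c("width", "height") %in% names(landmarks))
  for (id in sort(unique(landmarks$subject_id))) {
    block <- landmarks[landmarks$subject_id == id, ]
    block <- block[order(block$point), ]
    size_ok <- has_size && all(is.finite(c(block$width[1], block$height[1])))
    header <- if (size_ok) {
      sprintf(">%s\t%s\t%g\t%g", id, block$template[1], block$width[1], block$height[1])
    } else {
      sprintf(">%s\t%s", id, block$template[1])
    }
    writeLines(header, con)
    writeLines(
      sprintf("%d\t%.9g\t%.9g", block$point - 1L, block$x, block$y),
      con
    )
    writeLines("", con)
  }
  invisible(path)
}

#' Read a cohort covariate table
#'
#' Reads a participant CSV with required columns
#' `subject_id,sex,age,height_m,weight_kg,crf` and optional
#' `bmi,hip_bmd,spine_bmd`. Sex must be coded `M`/`F`. BMI, when absent, is
#' derived as weight/height^2; when present it must agree with the derived
#' value within 0.1 kg m^-2. Missing numeric cells are preserved as `NA`.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `subject_id`, `sex` (factor `F`/`M`), `age`,
#'   `height_m`, `weight_kg`, `bmi`, `hip_bmd`, `spine_bmd`, `crf` (factor).
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop(glue::glue("file not found: {path}"), call. = FALSE)
  df <- suppressMessages(readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
  if (nrow(df) == 0L) stop(glue::glue("cohort table {path} is empty"), call. = FALSE)
  required <- c("subject_id", "sex", "age", "height_m", "weight_kg", "crf")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop(glue::glue(
      "cohort table is missing required column(s): {paste(missing_cols, collapse = ', ')}"
    ), call. = FALSE)
  }
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id)) stop("duplicate subject ids in cohort table", call. = FALSE)
  sex <- as.character(df$sex)
  bad_sex <- setdiff(unique(sex[!is.na(sex)]), c("M", "F"))
  if (length(bad_sex) > 0) {
    stop(glue::glue("sex must be coded M/F; found: {paste(bad_sex, collapse = ', ')}"),
      call. = FALSE
    )
  }
  num <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  out <- tibble(
    subject_id = df$subject_id,
    sex = factor(sex, levels = c("F", "M")),
    age = num(df$age),
    height_m = num(df$height_m),
    weight_kg = num(df$weight_kg),
    bmi = num(df[["bmi"]]),
    hip_bmd = num(df[["hip_bmd"]]),
    spine_bmd = num(df[["spine_bmd"]]),
    crf = factor(as.character(df$crf))
  )
  if (any(out$height_m <= 0, na.rm = TRUE) || any(out$weight_kg <= 0, na.rm = TRUE)) {
    stop("height and weight must be positive", call. = FALSE)
  }
  derived <- out$weight_kg / out$height_m^2
  mismatch <- !is.na(out$bmi) & !is.na(derived) & abs(out$bmi - derived) > 0.1
  if (any(mismatch)) {
    stop(glue::glue(
      "bmi disagrees with weight/height^2 by more than 0.1 for subject(s): ",
      "{paste(out$subject_id[mismatch], collapse = ', ')}"
    ), call. = FALSE)
  }
  out$bmi <- dplyr::coalesce(out$bmi, derived)
  out
}
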