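# Internal: real coordinate vector layout is (x1, y1, x2, y2, ..., xk, yk).
cpx_to_realvec <- function(z) {
  as.vector(rbind(Re(z), Im(z)))
}

realvec_to_cpx <- function(v) {
  m <- matrix(v, nrow = 2)
  complex(real = m[1, ], imaginary = m[2, ])
}

# Deterministic eigenvector sign convention: the coefficient of largest
# magnitude is made positive; ties resolved by the lowest coordinate index
# (which.max already takes the first maximum).
fix_mode_signs <- function(V) {
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

default_n_retained <- function(template_name, n_modes) {
  suggested <- switch(template_name, hip = 10L, spine = 8L, NULL)
  if (is.null(suggested)) {
    stop("`n_retained` must be given for templates other than 'hip'/'spine'",
      call. = FALSE
    )
  }
  min(suggested, n_modes)
}

#' Fit a point-distribution shape model
#'
#' Builds the PCA shape model from a Procrustes-aligned cohort. Each aligned
#' unit-size shape is first mapped to Kendall tangent coordinates (rescaled by
#' the inverse of its dot product with the consensus), then the model is the
#' eigendecomposition of the sample covariance (n-1 denominator) of the tangent
#' coordinate vectors about their mean. Modes are sorted by decreasing variance
#' and carry a deterministic sign convention (largest-magnitude coefficient
#' positive). Working in the tangent space makes scoring exact: the model mean
#' scores 0 on every mode and the training sample rescored has mean 0 and SD 1
#' per mode by construction.
#'
#' @param alignment A `shape_alignment` from [gpa()].
#' @param n_retained Number of modes retained for scoring/reconstruction.
#'   Defaults to 10 for the hip template and 8 for the spine template.
#' @return An object of class `shape_model` with elements `template`,
#'   `n_points`, `n`, `consensus` (the rotation target, unit preshape),
#'   `mean_shape` (tangent-space mean, the PCA centre), `modes` (2k x m
#'   orthonormal matrix), `variances`, `raw_sds` (`sqrt(variances)`, the
#'   normalisers for raw scores), `pct_variance`, `n_retained`.
#' @export
fit_shape_model <- function(alignment, n_retained = NULL) {
  if (!inherits(alignment, "shape_alignment")) {
    stop("`alignment` must be a shape_alignment from gpa()", call. = FALSE)
  }
  Z <- lmk_complex(alignment$shapes)
  n <- nrow(Z)
  k <- ncol(Z)
  if (n < 3L) stop("need at least 3 shapes to fit a model", call. = FALSE)
  mu <- complex(real = alignment$mean_shape$x, imaginary = alignment$mean_shape$y)

  # tangent projection: shapes are already optimally rotated onto mu, so
  # <z, mu> is real positive; rescale each shape by its inverse.
  dots <- Re(Z %*% Conj(mu))[, 1]
  if (any(dots <= 0)) stop("a shape is orthogonal to the consensus; cannot project", call. = FALSE)
  Zt <- Z / dots

  X <- t(apply(Zt, 1, cpx_to_realvec)) # n x 2k
  m <- colMeans(X)
  Xc <- sweep(X, 2, m)
  total_var <- sum(Xc^2) / (n - 1)
  if (total_var <= 1e-20) {
    stop("all shapes identical: total shape variance is zero", call. = FALSE)
  }
  S <- crossprod(Xc) / (n - 1)
  eg <- eigen(S, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  V <- fix_mode_signs(eg$vectors)
  rank <- sum(vals > max(vals) * 1e-12)

  if (is.null(n_retained)) n_retained <- default_n_retained(alignment$template, rank)
  n_retained <- as.integer(n_retained)
  if (n_retained < 1L || n_retained > rank) {
    stop(glue::glue(
      "n_retained = {n_retained} exceeds the model rank ({rank})"
    ), call. = FALSE)
  }

  structure(
    list(
      template = alignment$template,
      n_points = k,
      n = n,
      consensus = tibble(point = seq_len(k), x = Re(mu), y = Im(mu)),
      mean_shape = tibble(
        point = seq_len(k),
        x = m[seq(1, 2 * k, by = 2)],
        y = m[seq(2, 2 * k, by = 2)]
      ),
      modes = V,
      variances = vals,
      raw_sds = sqrt(vals),
      pct_variance = 100 * vals / sum(vals),
      rank = rank,
      n_retained = n_retained
    ),
    class = "shape_model"
  )
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf(
    "<shape_model '%s': %d points, fitted on %d shapes, %d/%d modes retained>\n",
    x$template, x$n_points, x$n, x$n_retained, x$rank
  ))
  top <- utils::head(x$pct_variance, x$n_retained)
  cat(sprintf(
    "  retained modes explain %.1f%% of variance (mode 1: %.1f%%)\n",
    sum(top), top[1]
  ))
  invisible(x)
}

#' Normalised mode scores for landmark configurations
#'
#' Each configuration is centred, scaled to unit centroid size, optimally
#' rotated onto the model consensus, mapped to tangent coordinates and
#' projected onto the retained modes; raw projections are divided by each
#' mode's raw-score standard deviation so scores are in SD units (0 = the mean
#' shape). Scores are invariant to similarity transforms of the input.
#'
#' @param model A `shape_model`.
#' @param landmarks A landmark tibble with the model's point count.
#' @return A tibble with columns `subject_id`, `mode` (integer) and `score`.
#' @export
score_shapes <- function(model, landmarks) {
  validate_landmarks(landmarks)
  Z <- lmk_complex(landmarks)
  if (ncol(Z) != model$n_points) {
    stop(glue::glue(
      "configurations have {ncol(Z)} points; model '{model$template}' expects {model$n_points}"
    ), call. = FALSE)
  }
  ps <- to_preshape_cpx(Z)
  Z <- ps$Z
  mu <- complex(real = model$consensus$x, imaginary = model$consensus$y)
  inner <- (Z %*% Conj(mu))[, 1]
  theta <- -Arg(inner)
  Zr <- Z * exp(1i * theta)
  dots <- Re(Zr %*% Conj(mu))[, 1]
  if (any(dots <= 0)) {
    stop("a configuration is orthogonal to the model consensus", call. = FALSE)
  }
  Zt <- Zr / dots
  X <- t(apply(Zt, 1, cpx_to_realvec))
  m <- as.vector(t(as.matrix(model$mean_shape[, c("x", "y")])))
  Xc <- sweep(X, 2, m)
  idx <- seq_len(model$n_retained)
  raw <- Xc %*% model$modes[, idx, drop = FALSE]
  scores <- sweep(raw, 2, model$raw_sds[idx], `/`)
  tibble(
    subject_id = rep(rownames(Z), times = length(idx)),
    mode = rep(idx, each = nrow(Z)),
    score = as.vector(scores)
  ) |>
    dplyr::arrange(.data$subject_id, .data$mode)
}

#' Reconstruct the shape at k standard deviations along one mode
#'
#' Returns `mean_shape + k_sd * raw_sd(mode) * mode vector` as a point table,
#' the construction used to visualise what each mode of variation does (for
#' example +/-2 SD outlines). Coordinates follow the image pixel convention
#' (origin top-left, x rightward, y downward) in consensus-aligned
#' unit-centroid-size units.
#'
#' @param model A `shape_model`.
#' @param mode Mode index (1-based), at most `n_retained`.
#' @param k_sd Number of standard deviations along the mode.
#' @return A tibble with columns `point`, `x`, `y`.
#' @export
reconstruct_shape <- function(model, mode, k_sd) {
  mode <- as.integer(mode)
  if (mode < 1L || mode > model$n_retained) {
    stop(glue::glue(
      "mode {mode} out of range; model retains {model$n_retained} mode(s)"
    ), call. = FALSE)
  }
  m <- as.vector(t(as.matrix(model$mean_shape[, c("x", "y")])))
  v <- m + k_sd * model$raw_sds[mode] * model$modes[, mode]
  z <- realvec_to_cpx(v)
  tibble(point = seq_along(z), x = Re(z), y = Im(z))
}

#' Scree table of a shape model
#'
#' Per-mode and cumulative percentage of total shape variance over all modes.
#'
#' @param model A `shape_model`.
#' @return A tibble with columns `mode`, `pct_variance`, `cumulative_pct`.
#' @export
scree_table <- function(model) {
  tibble(
    mode = seq_along(model$pct_variance),
    pct_variance = model$pct_variance,
    cumulative_pct = cumsum(model$pct_variance)
  )
}

#' Choose how many modes to retain from a scree table
#'
#' @param scree A scree table from [scree_table()].
#' @param rule `"fixed"` (take `value` modes), `"per_mode_threshold"` (largest
#'   m such that mode m explains at least `value` percent) or
#'   `"cumulative_target"` (smallest m whose cumulative percentage reaches
#'   `value`).
#' @param value The rule's parameter (a count or a percentage).
#' @return An integer mode count.
#' @export
select_modes <- function(scree, rule = c("fixed", "per_mode_threshold", "cumulative_target"),
                         value) {
  rule <- match.arg(rule)
  n_modes <- nrow(scree)
  switch(rule,
    fixed = {
      m <- as.integer(value)
      if (m < 1L || m > n_modes) {
        stop(glue::glue("fixed mode count {value} outside 1..{n_modes}"), call. = FALSE)
      }
      m
    },
    per_mode_threshold = {
      ok <- which(scree$pct_variance >= value)
      if (length(ok) == 0L) {
        stop(glue::glue("no mode explains at least {value}% of variance"), call. = FALSE)
      }
      max(ok)
    },
    cumulative_target = {
      ok <- which(scree$cumulative_pct >= value - 1e-9)
      if (length(ok) == 0L) {
        stop(glue::glue("cumulative variance never reaches {value}%"), call. = FALSE)
      }
      min(ok)
    }
  )
}

#' Serialise a shape model to JSON
#'
#' Writes the model (template, point count, consensus, tangent mean, retained
#' modes, variances, raw SDs) as a JSON document with 9 significant digits and
#' a provenance block. [read_shape_model()] restores it.
#'
#' @param model A `shape_model`.
#' @param path Output path.
#' @param seed Optional seed recorded in the provenance block.
#' @return `path`, invisibly.
#' @export
write_shape_model <- function(model, path, seed = NULL) {
  doc <- list(
    template = model$template,
    n_points = model$n_points,
    n = model$n,
    consensus = list(x = model$consensus$x, y = model$consensus$y),
    mean_shape = list(x = model$mean_shape$x, y = model$mean_shape$y),
    modes = t(model$modes), # row per mode
    variances = model$variances,
    raw_sds = model$raw_sds,
    pct_variance = model$pct_variance,
    rank = model$rank,
    n_retained = model$n_retained,
    provenance = list(
      tool = "shapemodes",
      version = as.character(utils::packageVersion("shapemodes")),
      n_subjects = model$n,
      seed = seed
    )
  )
  jsonlite::write_json(doc, path, digits = I(9), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_shape_model
#' @export
read_shape_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  k <- doc$n_points
  structure(
    list(
      template = doc$template,
      n_points = k,
      n = doc$n,
      consensus = tibble(point = seq_len(k), x = doc$consensus$x, y = doc$consensus$y),
      mean_shape = tibble(point = seq_len(k), x = doc$mean_shape$x, y = doc$mean_shape$y),
      modes = t(doc$modes),
      variances = doc$variances,
      raw_sds = doc$raw_sds,
      pct_variance = doc$pct_variance,
      rank = doc$rank,
      n_retained = doc$n_retained
    ),
    class = "shape_model"
  )
}

#' @rdname fit_shape_model
#' @param x A `shape_model`.
#' @param ... Unused.
#' @export
tidy.shape_model <- function(x, ...) {
  scree_table(x) |>
    dplyr::mutate(
      variance = x$variances,
      raw_sd = x$raw_sds,
      retained = .data$mode <= x$n_retained
    )
}

#' @rdname fit_shape_model
#' @export
glance.shape_model <- function(x, ...) {
  tibble(
    template = x$template,
    n = x$n,
    n_points = x$n_points,
    rank = x$rank,
    n_retained = x$n_retained,
    total_variance = sum(x$variances),
    pct_retained = sum(x$pct_variance[seq_len(x$n_retained)])
  )
}
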