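# Internal helpers -----------------------------------------------------------

# Landmark tibble -> n x k complex matrix (x + iy), rows named by subject id,
# points in template order. Assumes a validated, homogeneous table.
lmk_complex <- function(landmarks) {
  landmarks <- landmarks[order(landmarks$subject_id, landmarks$point), ]
  ids <- unique(landmarks$subject_id)
  k <- nrow(landmarks) / length(ids)
  Z <- matrix(complex(real = landmarks$x, imaginary = landmarks$y),
    nrow = length(ids), ncol = k, byrow = TRUE
  )
  rownames(Z) <- ids
  Z
}

complex_to_tbl <- function(Z, template_name, ids = rownames(Z)) {
  k <- ncol(Z)
  tibble(
    subject_id = rep(ids, each = k),
    template = template_name,
    point = rep(seq_len(k), times = nrow(Z)),
    x = as.vector(t(Re(Z))),
    y = as.vector(t(Im(Z)))
  )
}

# Single-subject preshape table (point, x, y) -> complex vector
preshape_vec <- function(p) {
  p <- p[order(p$point), ]
  complex(real = p$x, imaginary = p$y)
}

centroid_sizes_cpx <- function(Z) {
  cen <- rowMeans(Z)
  sqrt(rowSums(Mod(Z - cen)^2))
}

# Centre rows at the origin and scale to unit centroid size.
to_preshape_cpx <- function(Z, ids = rownames(Z)) {
  cen <- rowMeans(Z)
  Zc <- Z - cen
  cs <- sqrt(rowSums(Mod(Zc)^2))
  if (any(cs <= 0)) {
    bad <- ids[cs <= 0]
    stop(glue::glue(
      "degenerate configuration (zero centroid size) for subject(s): ",
      "{paste(bad, collapse = ', ')}"
    ), call. = FALSE)
  }
  list(Z = Zc / cs, centroid_size = cs)
}

# Optimal rotation angle of complex preshape b onto a (rotation only, never a
# reflection): maximises Re(e^{-i theta} <a, b>) with <a, b> = sum(a conj(b)).
rotation_angle_cpx <- function(a, b) {
  inner <- sum(a * Conj(b))
  if (Mod(inner) == 0) 0 else Arg(inner)
}

# Residual after optimally rotating b onto a, computed by direct differencing
# (avoids the catastrophic cancellation of the 2 - 2|<a,b>| form near zero).
residual_cpx <- function(a, b) {
  theta <- rotation_angle_cpx(a, b)
  sqrt(sum(Mod(a - exp(1i * theta) * b)^2))
}

# Public operations -----------------------------------------------------------

#' Centre and scale configurations to preshapes
#'
#' Removes location by centring each configuration's centroid at the origin and
#' removes size by scaling to unit centroid size (centroid size = square root
#' of the summed squared distances of the points to their centroid). The
#' removed size is recorded per subject.
#'
#' @param landmarks A landmark tibble (see [validate_landmarks()]).
#' @return A tibble with columns `subject_id`, `template`, `point`, `x`, `y`
#'   (preshape coordinates) and `centroid_size` (the removed size, pixels).
#' @examples
#' sq <- tibble::tibble(
#'   subject_id = "s1", template = "square", point = 1:4,
#'   x = c(1, 1, -1, -1), y = c(1, -1, -1, 1)
#' )
#' center_and_scale(sq)
#' @export
center_and_scale <- function(landmarks) {
  validate_landmarks(landmarks)
  Z <- lmk_complex(landmarks)
  ps <- to_preshape_cpx(Z)
  out <- complex_to_tbl(ps$Z, landmarks$template[1])
  out$centroid_size <- rep(unname(ps$centroid_size), each = ncol(Z))
  out
}

#' Optimal rotation between two preshapes
#'
#' Finds the pure rotation (reflections are never considered) of `b` that
#' minimises the summed squared distance to `a`, returning the angle and the
#' minimised root-sum-of-squares residual.
#'
#' @param a,b Single-subject preshape tables with columns `point`, `x`, `y`
#'   (as produced by [center_and_scale()]), with equal point counts.
#' @return A one-row tibble with columns `angle` (radians, anticlockwise in the
#'   x-right / y-down pixel convention) and `residual`.
#' @export
optimal_rotation <- function(a, b) {
  va <- preshape_vec(a)
  vb <- preshape_vec(b)
  if (length(va) != length(vb)) {
    stop("point counts differ between the two preshapes", call. = FALSE)
  }
  theta <- rotation_angle_cpx(va, vb)
  tibble(angle = theta, residual = residual_cpx(va, vb))
}

#' Procrustes distance between two preshapes
#'
#' Root summed squared distance between `a` and `b` after optimally rotating
#' `b` onto `a` (rotation only). Symmetric in its arguments.
#'
#' @inheritParams optimal_rotation
#' @return A single number.
#' @export
procrustes_distance <- function(a, b) {
  optimal_rotation(a, b)$residual
}

#' Generalized Procrustes alignment of a landmark cohort
#'
#' Superimposes all configurations by removing translation and size
#' ([center_and_scale()]) and then iterating: rotate every preshape onto the
#' current consensus, recompute the consensus as the renormalised mean of the
#' rotated shapes, until the Procrustes distance between successive consensus
#' shapes falls below `tol` or `max_iter` is reached. Reflections are never
#' used, so input configurations are assumed consistently oriented. After
#' convergence the whole set is rigidly rotated so the consensus is optimally
#' aligned with the first subject's preshape, fixing the arbitrary overall
#' rotation deterministically.
#'
#' @param landmarks A landmark tibble; at least two subjects, one template.
#' @param tol Convergence tolerance on the Procrustes distance between
#'   successive consensus shapes.
#' @param max_iter Maximum number of iterations.
#' @return An object of class `shape_alignment`: a list with `shapes` (tibble
#'   of aligned unit-size coordinates), `mean_shape` (tibble, unit centroid
#'   size, zero centroid), `centroid_sizes` (tibble `subject_id`,
#'   `centroid_size` of the original configurations), `residuals` (tibble
#'   `subject_id`, `residual` Procrustes distance to the consensus),
#'   `n_iterations`, `converged`, `template` and `tol`.
#' @export
gpa <- function(landmarks, tol = 1e-8, max_iter = 100L) {
  validate_landmarks(landmarks)
  template_name <- landmarks$template[1]
  Z0 <- lmk_complex(landmarks)
  if (nrow(Z0) < 2L) stop("GPA needs at least 2 configurations", call. = FALSE)
  ps <- to_preshape_cpx(Z0)
  Z <- ps$Z
  input_order <- unique(landmarks[order(landmarks$subject_id), ]$subject_id)

  mu <- Z[1, ]
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    # rotate each preshape onto the consensus
    inner <- Z %*% Conj(mu) # row i: <z_i, mu>* ... see below
    # sum_j z_ij * conj(mu_j) = <z_i, mu>; rotating z_i onto mu uses
    # theta_i = Arg(<mu, z_i>) = -Arg(<z_i, mu>)
    theta <- -Arg(inner[, 1])
    Zr <- Z * exp(1i * theta)
    m_raw <- colMeans(Zr)
    m_raw <- m_raw - mean(m_raw)
    nm <- sqrt(sum(Mod(m_raw)^2))
    if (nm <= 0) stop("degenerate consensus during GPA", call. = FALSE)
    mu_new <- m_raw / nm
    d <- residual_cpx(mu, mu_new)
    mu <- mu_new
    if (d < tol) {
      converged <- TRUE
      break
    }
  }

  # global rotational gauge: consensus optimally aligned to first preshape
  gauge <- rotation_angle_cpx(Z[1, ], mu)
  mu <- mu * exp(1i * gauge)
  # final pass: every preshape exactly optimally rotated onto the consensus
  inner <- Z %*% Conj(mu)
  theta <- -Arg(inner[, 1])
  Za <- Z * exp(1i * theta)
  residuals <- sqrt(rowSums(Mod(Za - matrix(mu, nrow(Za), ncol(Za), byrow = TRUE))^2))

  structure(
    list(
      shapes = complex_to_tbl(Za, template_name),
      mean_shape = tibble(
        point = seq_along(mu), x = Re(mu), y = Im(mu)
      ),
      centroid_sizes = tibble(
        subject_id = input_order, centroid_size = unname(ps$centroid_size)
      ),
      residuals = tibble(subject_id = input_order, residual = unname(residuals)),
      n_iterations = iter,
      converged = converged,
      template = template_name,
      tol = tol
    ),
    class = "shape_alignment"
  )
}

#' @export
print.shape_alignment <- function(x, ...) {
  cat(sprintf(
    "<shape_alignment: %d shapes x %d points ('%s'), %d iteration(s), %s>\n",
    nrow(x$centroid_sizes), max(x$mean_shape$point), x$template,
    x$n_iterations, if (x$converged) "converged" else "NOT converged"
  ))
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' @rdname gpa
#' @param x A `shape_alignment`.
#' @param ... Unused.
#' @export
glance.shape_alignment <- function(x, ...) {
  tibble(
    n_shapes = nrow(x$centroid_sizes),
    n_points = max(x$mean_shape$point),
    n_iterations = x$n_iterations,
    converged = x$converged,
    mean_residual = mean(x$residuals$residual),
    max_residual = max(x$residuals$residual)
  )
}

#' @rdname gpa
#' @export
tidy.shape_alignment <- function(x, ...) {
  dplyr::left_join(x$shapes, x$residuals, by = "subject_id")
}
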