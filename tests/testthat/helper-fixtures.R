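# Shared fixtures built in code. Kept deliberately small; study-scale cohorts
# are generated only where a test needs them.

# random landmark tibble: n subjects, k points, around a ragged polygon
random_landmarks <- function(n, k, seed, template = "toy", noise = 5,
                             base = 100, id_prefix = "s") {
  withr::with_seed(seed, {
    angles <- seq(0, 2 * pi, length.out = k + 1)[-(k + 1)]
    radius <- 40 + 10 * sin(3 * angles)
    base_x <- base + radius * cos(angles)
    base_y <- base + radius * sin(angles)
    purrr::map_dfr(seq_len(n), function(i) {
      tibble::tibble(
        subject_id = sprintf("%s%03d", id_prefix, i),
        template = template,
        point = seq_len(k),
        x = base_x + stats::rnorm(k, sd = noise),
        y = base_y + stats::rnorm(k, sd = noise)
      )
    })
  })
}

one_preshape <- function(landmarks, id) {
  ps <- center_and_scale(landmarks[landmarks$subject_id == id, ])
  ps[, c("point", "x", "y")]
}

# apply a similarity transform (rotation deg, scale, translation) to a
# landmark tibble, independent implementation of the generator's transform
apply_similarity <- function(landmarks, rot_deg = 0, scale = 1, dx = 0, dy = 0) {
  th <- rot_deg * pi / 180
  landmarks |>
    dplyr::mutate(
      x0 = .data$x, y0 = .data$y,
      x = scale * (cos(th) * .data$x0 - sin(th) * .data$y0) + dx,
      y = scale * (sin(th) * .data$x0 + cos(th) * .data$y0) + dy
    ) |>
    dplyr::select(-dplyr::all_of(c("x0", "y0")))
}

# independent residual-after-rotation oracle: summed squared distance when b
# is rotated by theta onto a
rotation_rss <- function(a, b, theta) {
  br_x <- cos(theta) * b$x - sin(theta) * b$y
  br_y <- sin(theta) * b$x + cos(theta) * b$y
  sum((a$x - br_x)^2 + (a$y - br_y)^2)
}

# grid search + local refinement over rotation angles only (no reflection);
# independent oracle for optimal_rotation
grid_search_rotation <- function(a, b) {
  grid <- seq(-pi, pi, length.out = 2001)
  rss <- vapply(grid, function(th) rotation_rss(a, b, th), numeric(1))
  i <- which.min(rss)
  lo <- grid[max(i - 1, 1)]
  hi <- grid[min(i + 1, length(grid))]
  opt <- stats::optimize(function(th) rotation_rss(a, b, th), c(lo, hi), tol = 1e-12)
  list(angle = opt$minimum, residual = sqrt(max(opt$objective, 0)))
}

mirror_landmarks <- function(landmarks) {
  dplyr::mutate(landmarks, x = -.data$x)
}

# small truth without sex/covariate structure, for pure alignment/PCA tests
toy_truth <- function(k_points = 12, m = 2, seed = 5,
                      fractions = c(0.5, 0.3), total = 0.01, noise = 0) {
  tpl <- new_toy_template(k_points)
  make_true_model(tpl, m, fractions,
    smoothness = 1, seed = seed,
    total_variance = total, noise_sd = noise, base_centroid_size = 200,
    image_size = c(200, 200)
  )
}

new_toy_template <- function(k) {
  angles <- seq(0, 2 * pi, length.out = k + 1)[-(k + 1)]
  pts <- cbind(100 + 40 * cos(angles), 100 + 40 * sin(angles))
  structure(
    list(
      name = "toy", n_points = k,
      labels = sprintf("p%02d", seq_len(k)),
      outline_groups = list(outline = seq_len(k)),
      points = pts
    ),
    class = "point_template"
  )
}
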