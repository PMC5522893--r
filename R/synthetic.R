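# Orthonormal basis of the similarity directions at a unit mean preshape mu
# (translation x, translation y, scaling along mu, infinitesimal rotation).
# Real layout (x1, y1, ..., xk, yk). All four are exactly orthonormal when mu
# is centred with unit centroid size.
similarity_basis <- function(mu) {
  k <- length(mu)
  cbind(
    rep(c(1, 0), k) / sqrt(k),
    rep(c(0, 1), k) / sqrt(k),
    cpx_to_realvec(mu),
    cpx_to_realvec(1i * mu)
  )
}

# Gaussian smoothing of a displacement sequence over point index within one
# outline group (non-circular, renormalised kernel at the ends).
smooth_in_group <- function(v, width) {
  if (width <= 0) return(v)
  n <- length(v)
  idx <- seq_len(n)
  vapply(idx, function(i) {
    w <- exp(-0.5 * ((idx - i) / width)^2)
    sum(w * v) / sum(w)
  }, numeric(1))
}

#' Construct a ground-truth synthetic shape model
#'
#' Builds the known-truth model the cohort generator samples from: `m`
#' spatially smooth orthonormal modes of variation around a template's mean
#' shape, a descending variance spectrum given as fractions of a total
#' Procrustes variance, optional per-mode sex offsets and covariate loadings,
#' and a digitisation-noise level in pixels. Modes are drawn as random
#' per-point displacement fields, smoothed along each outline group with a
#' Gaussian kernel of width `smoothness` (in point-index units), made
#' orthogonal to the similarity directions (translation, scaling, rotation)
#' and to each other, and unit-normalised. Everything is deterministic given
#' `seed`.
#'
#' The residual variance not captured by the `m` modes (fraction
#' `1 - sum(variance_fractions)`) is an isotropic floor; the pixel
#' digitisation noise, mapped to preshape units at the nominal centroid size,
#' is counted as part of that floor so that the generated cohort's empirical
#' variance spectrum matches the injected fractions.
#'
#' @param template A `point_template` (see [builtin_template()]).
#' @param m Number of true modes; must be below `2 * n_points - 4`.
#' @param variance_fractions Positive, non-increasing fractions of
#'   `total_variance` carried by each mode; must sum to at most 1.
#' @param smoothness Gaussian kernel width (point-index units) for mode
#'   smoothing.
#' @param seed Integer seed.
#' @param total_variance Total Procrustes (tangent-space) shape variance.
#' @param noise_sd Landmark digitisation noise SD per axis, pixels.
#' @param base_centroid_size Nominal centroid size, pixels, at which shapes
#'   are rendered into image coordinates.
#' @param sex_offsets Per-mode mean score shift (units of that mode's true
#'   SD) applied to male subjects.
#' @param covariate_loadings Optional `m` x p matrix of target within-sex
#'   correlations between mode scores and covariates; column names among
#'   `height_m`, `weight_kg`, `hip_bmd`, `spine_bmd`. Column-wise sums of
#'   squares must stay below 1.
#' @param covariate_profiles Per-sex means/SDs of the generated covariates: a
#'   tibble with columns `covariate`, `mean_f`, `sd_f`, `mean_m`, `sd_m`.
#' @param crf_offsets Optional named list mapping covariate names to length-6
#'   additive offsets, one per scanning centre.
#' @param image_size Nominal `(width, height)` of the source images, pixels.
#' @return An object of class `synthetic_truth`.
#' @export
make_true_model <- function(template, m, variance_fractions, smoothness = 3,
                            seed = 1L,
                            total_variance = 0.015,
                            noise_sd = 0,
                            base_centroid_size = 700,
                            sex_offsets = rep(0, m),
                            covariate_loadings = NULL,
                            covariate_profiles = default_covariate_profiles(),
                            crf_offsets = default_crf_offsets(),
                            image_size = c(300, 252)) {
  k <- template$n_points
  if (m >= 2 * k - 4) {
    stop(glue::glue("m must be below 2 * n_points - 4 = {2 * k - 4}"), call. = FALSE)
  }
  if (length(variance_fractions) != m || any(variance_fractions < 0) ||
    any(diff(variance_fractions) > 1e-12) || sum(variance_fractions) > 1 + 1e-9) {
    stop("variance_fractions must be nonnegative, non-increasing and sum to <= 1",
      call. = FALSE
    )
  }
  if (length(sex_offsets) != m) stop("sex_offsets must have length m", call. = FALSE)
  if (!is.null(covariate_loadings)) {
    covariate_loadings <- as.matrix(covariate_loadings)
    if (nrow(covariate_loadings) != m) {
      stop("covariate_loadings must have one row per mode", call. = FALSE)
    }
    if (any(abs(covariate_loadings) >= 0.9)) {
      stop("individual covariate loadings must stay below 0.9 in magnitude", call. = FALSE)
    }
    ss <- colSums(covariate_loadings^2)
    if (any(ss >= 1)) {
      stop(glue::glue(
        "infeasible correlation targets for: ",
        "{paste(colnames(covariate_loadings)[ss >= 1], collapse = ', ')} ",
        "(squared loadings must sum below 1)"
      ), call. = FALSE)
    }
  }

  # template outline as the unit mean preshape
  pts <- template$points
  zc <- complex(real = pts[, 1], imaginary = pts[, 2])
  zc <- zc - mean(zc)
  mu <- zc / sqrt(sum(Mod(zc)^2))

  B <- similarity_basis(mu)
  modes <- withr::with_seed(seed, {
    V <- matrix(0, 2 * k, m)
    for (j in seq_len(m)) {
      dx <- stats::rnorm(k)
      dy <- stats::rnorm(k)
      for (g in template$outline_groups) {
        dx[g] <- smooth_in_group(dx[g], smoothness)
        dy[g] <- smooth_in_group(dy[g], smoothness)
      }
      v <- as.vector(rbind(dx, dy))
      basis <- cbind(B, V[, seq_len(j - 1), drop = FALSE])
      v <- v - basis %*% crossprod(basis, v)
      nv <- sqrt(sum(v^2))
      if (nv < 1e-8) stop("degenerate random mode draw; change the seed", call. = FALSE)
      V[, j] <- v / nv
    }
    fix_mode_signs(V)
  })

  structure(
    list(
      template = template,
      mean_shape = mu,
      true_modes = modes,
      variance_fractions = variance_fractions,
      true_variances = variance_fractions * total_variance,
      total_variance = total_variance,
      sex_offsets = sex_offsets,
      covariate_loadings = covariate_loadings,
      covariate_profiles = covariate_profiles,
      crf_offsets = crf_offsets,
      noise_sd = noise_sd,
      base_centroid_size = base_centroid_size,
      image_size = image_size,
      smoothness = smoothness,
      seed = seed
    ),
    class = "synthetic_truth"
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_truth: '%s' template, %d modes (%.1f%% of variance), noise %.2g px>\n",
    x$template$name, ncol(x$true_modes), 100 * sum(x$variance_fractions), x$noise_sd
  ))
  invisible(x)
}

#' Realistic per-sex covariate distributions
#'
#' Default means and SDs for the generated covariates, on the scales typical
#' of a British cohort in its early sixties (height in metres, weight in kg,
#' areal BMD in g cm^-2).
#'
#' @return A tibble with columns `covariate`, `mean_f`, `sd_f`, `mean_m`,
#'   `sd_m`.
#' @export
default_covariate_profiles <- function() {
  tibble(
    covariate = c("age", "height_m", "weight_kg", "hip_bmd", "spine_bmd"),
    mean_f = c(63.3, 1.62, 71.5, 0.87, 0.94),
    sd_f = c(1.09, 0.06, 12.4, 0.13, 0.16),
    mean_m = c(63.2, 1.75, 85.2, 1.00, 1.05),
    sd_m = c(1.17, 0.06, 12.8, 0.14, 0.19)
  )
}

#' @rdname default_covariate_profiles
#' @return `default_crf_offsets()`: a named list of length-6 additive centre
#'   offsets (small scanner calibration shifts on BMD).
#' @export
default_crf_offsets <- function() {
  list(
    hip_bmd = c(-0.02, -0.01, 0, 0, 0.01, 0.02),
    spine_bmd = c(-0.02, 0, -0.01, 0.01, 0, 0.02)
  )
}

#' Default hip and spine study scenarios
#'
#' Ready-made `synthetic_truth` objects emulating the statistical structure of
#' a large DXA shape cohort: a 68-point hip model with 10 modes whose variance
#' fractions echo a typical hip scree (mode 1 = 23%, first three = 52.8%,
#' first ten = 80.6%), and an 89-point spine model with 8 modes (mode 1 = 53%,
#' first eight = 84.9%). Sex offsets mirror the magnitudes reported for hip
#' and spine mode scores, covariate loadings the strongest reported
#' mode-covariate correlations, and the digitisation noise the inter-rater
#' placement error (2.6 px hip, 2.2 px spine).
#'
#' @param seed Integer seed for the random mode fields.
#' @return A `synthetic_truth`.
#' @export
default_hip_truth <- function(seed = 101L) {
  loadings <- matrix(0, 10, 3, dimnames = list(NULL, c("height_m", "weight_kg", "hip_bmd")))
  loadings[2, "weight_kg"] <- 0.19
  loadings[6, "height_m"] <- 0.22
  loadings[9, "height_m"] <- -0.11
  loadings[8, "hip_bmd"] <- 0.16
  make_true_model(
    template = builtin_template("hip"),
    m = 10,
    variance_fractions = c(23.0, 17.0, 12.8, 6.9, 5.2, 4.1, 3.5, 3.2, 2.8, 2.1) / 100,
    smoothness = 3,
    seed = seed,
    total_variance = 0.015,
    noise_sd = 2.6,
    base_centroid_size = 700,
    sex_offsets = c(0.40, 0.39, -0.49, 0.44, 0.05, 0.37, 0.00, 0.25, -0.27, -0.71),
    covariate_loadings = loadings,
    image_size = c(300, 252)
  )
}

#' @rdname default_hip_truth
#' @export
default_spine_truth <- function(seed = 202L) {
  loadings <- matrix(0, 8, 3, dimnames = list(NULL, c("height_m", "weight_kg", "spine_bmd")))
  loadings[3, "weight_kg"] <- -0.15
  loadings[6, "weight_kg"] <- -0.12
  loadings[8, "height_m"] <- -0.11
  loadings[3, "spine_bmd"] <- -0.17
  make_true_model(
    template = builtin_template("spine"),
    m = 8,
    variance_fractions = c(53.0, 12.0, 6.5, 4.0, 3.2, 2.7, 2.3, 1.2) / 100,
    smoothness = 3,
    seed = seed,
    total_variance = 0.02,
    noise_sd = 2.2,
    base_centroid_size = 2500,
    sex_offsets = c(-0.15, 0.04, -0.97, 0.09, 0.07, 0.37, 0.06, -0.50),
    covariate_loadings = loadings,
    image_size = c(400, 1200)
  )
}

#' Generate a synthetic landmark cohort with known ground truth
#'
#' Samples a cohort from a `synthetic_truth`: per subject, draws sex, standard
#' mode scores (with the truth's sex offsets added for males), an isotropic
#' residual field orthogonal to the true modes and the similarity directions,
#' covariates as calibrated linear combinations of the sex-centred scores plus
#' centre offsets and independent noise (so that the within-sex population
#' correlation between a loaded covariate and its mode score equals the
#' injected loading), then renders the shape into pixel coordinates under a
#' random similarity transform and adds i.i.d. landmark digitisation noise.
#'
#' @param truth A `synthetic_truth` from [make_true_model()].
#' @param n Number of subjects (at least 10).
#' @param sex_ratio Probability a subject is male.
#' @param transform_ranges Named list with elements `rotation` (degrees,
#'   uniform in +/- range), `log_scale` (uniform in +/- range) and
#'   `translation` (pixels, uniform in +/- range per axis).
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return An object of class `synthetic_cohort`: a list with `landmarks`
#'   (landmark tibble in pixels), `records` (participant tibble),
#'   `true_scores` (tibble `subject_id`, `mode`, `z` standard score, `raw`
#'   raw-unit score) and `truth`.
#' @export
generate_cohort <- function(truth, n, sex_ratio = 0.482,
                            transform_ranges = list(
                              rotation = 10, log_scale = 0.1, translation = 20
                            ),
                            seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (n < 10) stop("n must be at least 10", call. = FALSE)
  k <- truth$template$n_points
  m <- ncol(truth$true_modes)
  leftover <- 1 - sum(truth$variance_fractions)
  n_resid_dims <- 2 * k - 4 - m
  floor_per_dim <- leftover * truth$total_variance / n_resid_dims
  sigma_p <- truth$noise_sd / truth$base_centroid_size
  resid_var <- floor_per_dim - sigma_p^2
  if (resid_var < -1e-15) {
    stop(
      "digitisation noise exceeds the residual variance budget; ",
      "increase total_variance or reduce noise_sd",
      call. = FALSE
    )
  }
  resid_sd <- sqrt(max(resid_var, 0))

  withr::with_seed(seed, {
    ids <- sprintf("S%05d", seq_len(n))
    male <- stats::rbinom(n, 1, sex_ratio) == 1
    z_centred <- matrix(stats::rnorm(n * m), n, m)
    z <- z_centred + outer(as.numeric(male), truth$sex_offsets)
    raw <- sweep(z, 2, sqrt(truth$true_variances), `*`)

    eps <- matrix(stats::rnorm(n * 2 * k, sd = resid_sd), n, 2 * k)
    basis <- cbind(similarity_basis(truth$mean_shape), truth$true_modes)
    eps <- eps - (eps %*% basis) %*% t(basis)

    X <- matrix(rep(cpx_to_realvec(truth$mean_shape), each = n), n, 2 * k)
    X <- X + raw %*% t(truth$true_modes) + eps
    Z <- t(apply(X, 1, realvec_to_cpx)) # n x k complex, tangent coords

    rot <- stats::runif(n, -transform_ranges$rotation, transform_ranges$rotation) * pi / 180
    scl <- truth$base_centroid_size * exp(stats::runif(
      n, -transform_ranges$log_scale, transform_ranges$log_scale
    ))
    ctr <- complex(
      real = truth$image_size[1] / 2 +
        stats::runif(n, -transform_ranges$translation, transform_ranges$translation),
      imaginary = truth$image_size[2] / 2 +
        stats::runif(n, -transform_ranges$translation, transform_ranges$translation)
    )
    Zpx <- Z * scl * exp(1i * rot) + ctr
    Zpx <- Zpx +
      matrix(complex(
        real = stats::rnorm(n * k, sd = truth$noise_sd),
        imaginary = stats::rnorm(n * k, sd = truth$noise_sd)
      ), n, k)
    rownames(Zpx) <- ids

    landmarks <- complex_to_tbl(Zpx, truth$template$name, ids)
    landmarks$width <- truth$image_size[1]
    landmarks$height <- truth$image_size[2]

    records <- generate_records(truth, ids, male, z_centred)

    true_scores <- tibble(
      subject_id = rep(ids, times = m),
      mode = rep(seq_len(m), each = n),
      z = as.vector(z),
      raw = as.vector(raw)
    ) |>
      dplyr::arrange(.data$subject_id, .data$mode)

    structure(
      list(
        landmarks = landmarks, records = records,
        true_scores = true_scores, truth = truth, seed = seed
      ),
      class = "synthetic_cohort"
    )
  })
}

# Covariates as calibrated linear combinations of the sex-centred standard
# scores + CRF offsets + independent noise. Runs inside the cohort's seed.
generate_records <- function(truth, ids, male, z_centred) {
  n <- length(ids)
  profiles <- truth$covariate_profiles
  crf <- factor(
    sample(paste0("CRF", 1:6), n, replace = TRUE),
    levels = paste0("CRF", 1:6)
  )
  L <- truth$covariate_loadings
  gen_cov <- function(name) {
    p <- profiles[profiles$covariate == name, ]
    if (nrow(p) == 0) stop(glue::glue("no covariate profile for '{name}'"), call. = FALSE)
    mu <- ifelse(male, p$mean_m, p$mean_f)
    sdv <- ifelse(male, p$sd_m, p$sd_f)
    rho <- if (!is.null(L) && name %in% colnames(L)) L[, name] else rep(0, ncol(z_centred))
    signal <- as.vector(z_centred %*% rho)
    e <- stats::rnorm(n, sd = sqrt(1 - sum(rho^2)))
    off <- if (name %in% names(truth$crf_offsets)) {
      truth$crf_offsets[[name]][as.integer(crf)]
    } else {
      0
    }
    mu + off + sdv * (signal + e)
  }
  height <- gen_cov("height_m")
  weight <- gen_cov("weight_kg")
  tibble(
    subject_id = ids,
    sex = factor(ifelse(male, "M", "F"), levels = c("F", "M")),
    age = gen_cov("age"),
    height_m = height,
    weight_kg = weight,
    bmi = weight / height^2,
    hip_bmd = gen_cov("hip_bmd"),
    spine_bmd = gen_cov("spine_bmd"),
    crf = crf
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort: %d subjects, '%s' template, seed %d>\n",
    nrow(x$records), x$truth$template$name, x$seed
  ))
  invisible(x)
}

#' Generate paired repeat markings for repeatability analysis
#'
#' Selects subjects without replacement from a synthetic cohort and perturbs
#' each subject's configuration twice with independent Gaussian noise of
#' `rater_sd` pixels per axis, emulating two independent markings of the same
#' image. When both markings carry noise sigma per axis, the expected mean
#' point error is `sigma * sqrt(pi)` (Rayleigh with scale `sigma * sqrt(2)`).
#'
#' @param cohort A `synthetic_cohort`.
#' @param n_subjects Number of subjects to select.
#' @param rater_sd Marking noise SD per axis, pixels.
#' @param comparison Label, `"intra"` or `"inter"`.
#' @param seed Integer seed.
#' @return A pairs tibble for [point_error()].
#' @export
generate_repeatability_pairs <- function(cohort, n_subjects = 50, rater_sd = 1,
                                         comparison = c("intra", "inter"),
                                         seed = 1L) {
  comparison <- match.arg(comparison)
  stopifnot(inherits(cohort, "synthetic_cohort"))
  ids <- unique(cohort$landmarks$subject_id)
  if (n_subjects > length(ids)) {
    stop(glue::glue(
      "requested {n_subjects} subjects but the cohort has only {length(ids)}"
    ), call. = FALSE)
  }
  withr::with_seed(seed, {
    chosen <- sample(ids, n_subjects)
    base <- cohort$landmarks[cohort$landmarks$subject_id %in% chosen, ]
    mark <- function(rater) {
      base |>
        dplyr::mutate(
          rater = rater,
          comparison = comparison,
          x = .data$x + stats::rnorm(dplyr::n(), sd = rater_sd),
          y = .data$y + stats::rnorm(dplyr::n(), sd = rater_sd)
        )
    }
    dplyr::bind_rows(mark("a"), mark("b")) |>
      dplyr::select(dplyr::all_of(c(
        "subject_id", "comparison", "rater", "template", "point", "x", "y"
      )))
  })
}

#' Express a fitted model in a ground-truth frame
#'
#' A fitted model's orientation gauge (consensus rotated onto the first
#' subject) differs from the generator's frame by one global rotation, and
#' eigenvector signs are arbitrary up to the deterministic convention. This
#' helper rotates the fitted consensus and modes into the truth's frame so
#' recovered quantities can be compared like for like.
#'
#' @param model A `shape_model` fitted on a cohort generated from `truth`.
#' @param truth The `synthetic_truth` the cohort came from.
#' @return A list with `mean_distance` (Procrustes distance between the fitted
#'   consensus and the true mean preshape), `modes` (fitted mode matrix rotated
#'   into the truth frame) and `mode_sign` (per-true-mode sign that aligns
#'   fitted mode j with true mode j).
#' @export
align_to_truth <- function(model, truth) {
  stopifnot(inherits(model, "shape_model"), inherits(truth, "synthetic_truth"))
  mu_e <- complex(real = model$consensus$x, imaginary = model$consensus$y)
  mu_t <- truth$mean_shape
  inner <- sum(mu_t * Conj(mu_e))
  gamma <- Arg(inner)
  rot <- apply(model$modes, 2, function(v) {
    cpx_to_realvec(realvec_to_cpx(v) * exp(1i * gamma))
  })
  m <- ncol(truth$true_modes)
  cosines <- diag(crossprod(truth$true_modes, rot[, seq_len(m), drop = FALSE]))
  list(
    mean_distance = sqrt(max(2 - 2 * Mod(inner), 0)),
    modes = rot,
    mode_sign = ifelse(cosines >= 0, 1, -1)
  )
}

#' Largest principal angle between two mode subspaces
#'
#' @param a,b Matrices whose columns span the two subspaces (orthonormal
#'   columns).
#' @return The largest principal angle, degrees.
#' @export
subspace_angle <- function(a, b) {
  sv <- svd(crossprod(a, b))$d
  acos(min(pmin(sv, 1))) * 180 / pi
}
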