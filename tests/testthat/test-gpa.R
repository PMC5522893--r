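test_that("center_and_scale removes location and size and records them", {
  sq <- tibble::tibble(
    subject_id = "sq", template = "square", point = 1:4,
    x = c(1, 1, -1, -1), y = c(1, -1, -1, 1)
  )
  ps <- center_and_scale(sq)
  expect_equal(ps$centroid_size, rep(sqrt(8), 4))
  expect_equal(abs(ps$x), rep(1 / sqrt(8), 4), tolerance = 1e-12)
  expect_equal(abs(ps$y), rep(1 / sqrt(8), 4), tolerance = 1e-12)

  # translation invariance
  shifted <- dplyr::mutate(sq, x = x + 5, y = y + 7)
  ps2 <- center_and_scale(shifted)
  expect_lt(max(abs(ps$x - ps2$x)), 1e-12)
  expect_lt(max(abs(ps$y - ps2$y)), 1e-12)

  # direct recomputation on a random 68-point configuration
  lmk <- random_landmarks(1, 68, seed = 21)
  ps3 <- center_and_scale(lmk)
  expect_lt(abs(mean(ps3$x)), 1e-12)
  expect_lt(abs(mean(ps3$y)), 1e-12)
  expect_equal(sum(ps3$x^2 + ps3$y^2), 1, tolerance = 1e-12)
  expect_equal(
    ps3$centroid_size[1],
    sqrt(sum((lmk$x - mean(lmk$x))^2 + (lmk$y - mean(lmk$y))^2))
  )

  coincident <- tibble::tibble(
    subject_id = "c", template = "t", point = 1:3, x = 2, y = 2
  )
  expect_error(center_and_scale(coincident), "degenerate")
})

test_that("optimal_rotation recovers rotations and matches the grid-search oracle", {
  lmk <- random_landmarks(1, 20, seed = 31)
  a <- one_preshape(lmk, "s001")

  same <- optimal_rotation(a, a)
  expect_equal(same$angle, 0)
  expect_lt(same$residual, 1e-12)

  rotated <- one_preshape(apply_similarity(lmk, rot_deg = 30), "s001")
  rec <- optimal_rotation(a, rotated)
  expect_equal(abs(rec$angle), 30 * pi / 180, tolerance = 1e-8)
  expect_lt(rec$residual, 1e-8)

  # random pair: agree with an independent grid search over angles
  lmk2 <- random_landmarks(2, 20, seed = 32)
  b <- one_preshape(lmk2, "s002")
  fit <- optimal_rotation(a, b)
  oracle <- grid_search_rotation(a, b)
  expect_equal(fit$residual, oracle$residual, tolerance = 1e-6)
  expect_equal(rotation_rss(a, b, fit$angle), oracle$residual^2, tolerance = 1e-6)

  # a mirror image is NOT undone: residual stays positive and equals the best
  # achievable by rotation alone
  m <- one_preshape(mirror_landmarks(lmk), "s001")
  mfit <- optimal_rotation(a, m)
  moracle <- grid_search_rotation(a, m)
  expect_gt(mfit$residual, 0.1)
  expect_equal(mfit$residual, moracle$residual, tolerance = 1e-6)

  expect_error(optimal_rotation(a, b[-1, ]), "point counts")
})

test_that("procrustes_distance is symmetric and consistent with optimal_rotation", {
  withr::with_seed(41, {
    for (i in 1:5) {
      lmk <- random_landmarks(2, 10, seed = 100 + i)
      a <- one_preshape(lmk, "s001")
      b <- one_preshape(lmk, "s002")
      expect_equal(procrustes_distance(a, b), procrustes_distance(b, a),
        tolerance = 1e-10
      )
      expect_equal(procrustes_distance(a, b), optimal_rotation(a, b)$residual)
    }
  })
  lmk <- random_landmarks(1, 10, seed = 50)
  a <- one_preshape(lmk, "s001")
  expect_equal(procrustes_distance(a, a), 0, tolerance = 1e-12)
})

test_that("gpa aligns exact copies perfectly and quickly", {
  base <- random_landmarks(1, 30, seed = 61)
  withr::with_seed(62, {
    copies <- purrr::map_dfr(1:50, function(i) {
      apply_similarity(base,
        rot_deg = stats::runif(1, -180, 180),
        scale = exp(stats::runif(1, -0.5, 0.5)),
        dx = stats::runif(1, -50, 50), dy = stats::runif(1, -50, 50)
      ) |>
        dplyr::mutate(subject_id = sprintf("c%03d", i))
    })
  })
  fit <- gpa(copies)
  expect_true(fit$converged)
  expect_lte(fit$n_iterations, 2)
  expect_lt(max(fit$residuals$residual), 1e-8)
})

test_that("with two shapes each residual to the consensus is half the pairwise residual", {
  # small-variation regime
  base <- random_landmarks(1, 25, seed = 71, noise = 0)
  two <- dplyr::bind_rows(
    dplyr::mutate(base, subject_id = "a"),
    withr::with_seed(72, dplyr::mutate(base,
      subject_id = "b",
      x = x + stats::rnorm(25, sd = 0.15), y = y + stats::rnorm(25, sd = 0.15)
    ))
  )
  fit <- gpa(two)
  pa <- one_preshape(two, "a")
  pb <- one_preshape(two, "b")
  pairwise <- optimal_rotation(pa, pb)$residual
  expect_equal(fit$residuals$residual, rep(pairwise / 2, 2), tolerance = 1e-6)
})

test_that("gpa recovers the generator's mean shape", {
  tr <- toy_truth(k_points = 20, m = 3, seed = 81, fractions = c(0.4, 0.2, 0.1))
  tr$noise_sd <- 0.5
  co <- generate_cohort(tr, n = 500, seed = 82)
  fit <- gpa(co$landmarks)
  mu_hat <- one_preshape(
    dplyr::mutate(fit$mean_shape, subject_id = "m", template = "toy"), "m"
  )
  mu_true <- tibble::tibble(
    point = seq_along(tr$mean_shape),
    x = Re(tr$mean_shape), y = Im(tr$mean_shape)
  )
  expect_lt(procrustes_distance(mu_true, mu_hat), 0.01)
})

test_that("aligned output is invariant to similarity transforms of the input", {
  lmk <- random_landmarks(20, 15, seed = 91)
  fit1 <- gpa(lmk)
  withr::with_seed(92, {
    transformed <- lmk |>
      dplyr::group_by(subject_id) |>
      dplyr::group_modify(function(d, key) {
        apply_similarity(d,
          rot_deg = stats::runif(1, -180, 180),
          scale = exp(stats::runif(1, -1, 1)),
          dx = stats::runif(1, -100, 100), dy = stats::runif(1, -100, 100)
        )
      }) |>
      dplyr::ungroup() |>
      dplyr::relocate(subject_id)
  })
  fit2 <- gpa(transformed)
  # remove the one global rotation: rotate consensus 2 onto consensus 1
  gauge <- optimal_rotation(
    dplyr::select(fit1$mean_shape, point, x, y),
    dplyr::select(fit2$mean_shape, point, x, y)
  )$angle
  s2 <- fit2$shapes |>
    dplyr::mutate(
      xr = cos(gauge) * x - sin(gauge) * y,
      yr = sin(gauge) * x + cos(gauge) * y
    )
  cmp <- dplyr::inner_join(fit1$shapes, s2, by = c("subject_id", "point"))
  expect_lt(max(abs(cmp$x.x - cmp$xr)), 1e-6)
  expect_lt(max(abs(cmp$y.x - cmp$yr)), 1e-6)
})

test_that("gpa is stable on its own output and keeps original centroid sizes", {
  lmk <- random_landmarks(15, 12, seed = 95)
  fit <- gpa(lmk)
  refit <- gpa(fit$shapes)
  d <- procrustes_distance(
    dplyr::select(fit$mean_shape, point, x, y),
    dplyr::select(refit$mean_shape, point, x, y)
  )
  expect_lt(d, fit$tol * 10)
  # centroid sizes equal input sizes exactly
  orig <- lmk |>
    dplyr::group_by(subject_id) |>
    dplyr::summarise(
      cs = sqrt(sum((x - mean(x))^2 + (y - mean(y))^2)), .groups = "drop"
    )
  expect_equal(fit$centroid_sizes$centroid_size, orig$cs)
  # consensus invariants
  expect_lt(abs(mean(fit$mean_shape$x)), 1e-10)
  expect_lt(abs(mean(fit$mean_shape$y)), 1e-10)
  expect_equal(sum(fit$mean_shape$x^2 + fit$mean_shape$y^2), 1, tolerance = 1e-10)
})

test_that("gpa converges within 100 iterations at 1e-8 on a large noisy cohort", {
  tr <- default_hip_truth()
  co <- generate_cohort(tr, n = 2000, seed = 96)
  fit <- gpa(co$landmarks, tol = 1e-8, max_iter = 100)
  expect_true(fit$converged)
  expect_lte(fit$n_iterations, 100)
})

test_that("gpa reports the offending subject for degenerate input", {
  lmk <- random_landmarks(3, 8, seed = 97)
  bad <- dplyr::mutate(lmk, x = ifelse(subject_id == "s002", 1, x),
    y = ifelse(subject_id == "s002", 1, y)
  )
  expect_error(gpa(bad), "s002")
})
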