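test_that("ttest_raw reproduces a hand-computed case and the t.test oracle", {
  res <- ttest_raw(c(1, 2, 3), c(4, 5, 6))
  # pooled sd = 1, SE = sqrt(2/3)
  expect_equal(res$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res$t, -3.674, tolerance = 1e-3)
  expect_equal(res$df, 4)
  expect_equal(res$p, 0.0213, tolerance = 1e-2)
  expect_equal(res$mean_difference, -3)

  # identical groups
  same <- ttest_raw(c(1, 2, 3), c(3, 2, 1))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # independent oracle: stats::t.test with pooled variance
  withr::with_seed(411, {
    for (i in 1:10) {
      a <- stats::rnorm(sample(5:40, 1), mean = stats::runif(1, -1, 1))
      b <- stats::rnorm(sample(5:40, 1), sd = stats::runif(1, 0.5, 2))
      mine <- ttest_raw(a, b)
      ref <- stats::t.test(a, b, var.equal = TRUE)
      expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    }
  })

  expect_error(ttest_raw(c(1, 1), c(1, 1)), "pooled variance")
  expect_error(ttest_raw(1, c(1, 2)), "n >= 2")
})

test_that("ttest_summary equals ttest_raw on the groups' own summaries", {
  withr::with_seed(421, {
    for (i in 1:10) {
      a <- stats::rnorm(sample(5:50, 1), mean = stats::runif(1, -2, 2))
      b <- stats::rnorm(sample(5:50, 1), sd = stats::runif(1, 0.2, 3))
      raw <- ttest_raw(a, b)
      summ <- ttest_summary(
        list(n = length(a), mean = mean(a), sd = stats::sd(a)),
        list(n = length(b), mean = mean(b), sd = stats::sd(b))
      )
      expect_equal(raw$t, summ$t, tolerance = 1e-10)
      expect_equal(raw$p, summ$p, tolerance = 1e-10)
    }
  })
  eq <- ttest_summary(list(n = 10, mean = 1, sd = 2), list(n = 8, mean = 1, sd = 2))
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
})

test_that("published-style summary rows give the printed significance levels", {
  # male vs female mode-score rows: strong separations are < 0.001
  hm1 <- ttest_summary(
    list(n = 729, mean = 0.22, sd = 1.01),
    list(n = 782, mean = -0.18, sd = 0.95)
  )
  expect_lt(hm1$p, 0.001)
  expect_gt(hm1$t, 0)
  sm3 <- ttest_summary(
    list(n = 729, mean = -0.50, sd = 0.98),
    list(n = 782, mean = 0.47, sd = 0.77)
  )
  expect_lt(sm3$p, 0.001)
  expect_lt(sm3$t, 0)
})

test_that("pearson computes r, drops incomplete pairs and flags by threshold", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson(x, 2 * x + 1)$r, 1, tolerance = 1e-12)

  # missing pairs dropped
  res <- pearson(c(x, NA), c(2 * x + 1, 4))
  expect_equal(res$n_used, 5)

  # independence bound at large n
  withr::with_seed(431, {
    x <- stats::rnorm(1e5)
    y <- stats::rnorm(1e5)
  })
  expect_lt(abs(pearson(x, y)$r), 0.02)

  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson(c(1, 2), c(1, 2)), "at least 3")
})

test_that("the |r| reporting threshold flags as printed tables do", {
  base <- c(-0.3, 0.1, 0.4, -0.2, 0.25, 0.05, -0.15)
  mk <- function(r_target) {
    # construct a pair with exactly the wanted correlation via rotation trick
    x <- scale(base)[, 1]
    e <- scale(stats::residuals(stats::lm(rev(x) ~ x)))[, 1]
    y <- r_target * x + sqrt(1 - r_target^2) * e
    list(x = x, y = y)
  }
  withr::with_seed(441, {
    d13 <- mk(0.13)
    expect_equal(pearson(d13$x, d13$y)$r, 0.13, tolerance = 1e-10)
    expect_true(pearson(d13$x, d13$y)$flagged)
    d09 <- mk(0.09)
    expect_false(pearson(d09$x, d09$y)$flagged)
    # boundary: default rule is >= (as bolded in tables), "gt" is strict
    d10 <- mk(0.10)
    expect_true(pearson(d10$x, d10$y)$flagged)
    expect_false(pearson(d10$x, d10$y, flag_rule = "gt")$flagged)
  })
})

test_that("partial_correlation removes level-mean confounding and matches the oracle", {
  # single level: equals plain pearson
  withr::with_seed(451, {
    x <- stats::rnorm(50)
    y <- 0.5 * x + stats::rnorm(50)
  })
  g1 <- rep("only", 50)
  expect_equal(partial_correlation(x, y, g1)$r, pearson(x, y)$r, tolerance = 1e-10)

  # pure level shifts: plain r large, partial r near zero
  withr::with_seed(452, {
    lev <- sample(c("A", "B"), 1e5, replace = TRUE)
    shift <- ifelse(lev == "A", 1, -1)
    x <- shift + stats::rnorm(1e5)
    y <- shift + stats::rnorm(1e5)
  })
  expect_gt(abs(pearson(x, y)$r), 0.3)
  expect_lt(abs(partial_correlation(x, y, lev)$r), 0.02)

  # normal-equations oracle on random small data
  withr::with_seed(453, {
    for (i in 1:10) {
      n <- sample(30:80, 1)
      g <- sample(c("C1", "C2", "C3"), n, replace = TRUE)
      x <- stats::rnorm(n) + as.integer(factor(g))
      y <- stats::rnorm(n) - as.integer(factor(g))
      mine <- partial_correlation(x, y, g)$r
      oracle <- stats::cor(
        normal_equations_residuals(x, g),
        normal_equations_residuals(y, g)
      )
      expect_equal(mine, oracle, tolerance = 1e-10)
      # symmetry
      expect_equal(mine, partial_correlation(y, x, g)$r, tolerance = 1e-10)
    }
  })

  expect_error(
    partial_correlation(stats::rnorm(10), stats::rnorm(10), c(rep("A", 9), "B")),
    "fewer than 2"
  )
})

test_that("adjusted_sex_association equals the t-test unadjusted and shrinks under mediation", {
  withr::with_seed(461, {
    sex <- factor(sample(c("F", "M"), 200, replace = TRUE))
    score <- stats::rnorm(200) + 0.5 * (sex == "M")
  })
  unadj <- adjusted_sex_association(score, sex)
  tt <- ttest_raw(score[sex == "M"], score[sex == "F"])
  expect_equal(unadj$estimate, tt$mean_difference, tolerance = 1e-10)
  expect_equal(unadj$p, tt$p, tolerance = 1e-10)

  # mediation: the score is a pure function of height, and height differs by
  # sex; adjusting for height removes the sex association
  withr::with_seed(462, {
    sex <- factor(rep(c("F", "M"), each = 300))
    height <- ifelse(sex == "M", 1.75, 1.62) + stats::rnorm(600, sd = 0.06)
    score <- 8 * (height - 1.68) + stats::rnorm(600, sd = 0.05)
  })
  raw <- adjusted_sex_association(score, sex)
  adj <- adjusted_sex_association(score, sex, data.frame(height = height))
  expect_lt(abs(adj$estimate), 0.1 * abs(raw$estimate))

  # normal-equations oracle for the adjusted coefficient
  X <- cbind(1, sex == "M", height)
  beta <- solve(t(X) %*% X, t(X) %*% score)
  expect_equal(adj$estimate, beta[2], tolerance = 1e-8)

  expect_error(
    adjusted_sex_association(score, sex, data.frame(h2 = height, h3 = height)),
    "collinear"
  )
})

test_that("sex_difference_table detects an injected offset and is calibrated under the null", {
  mk_scores <- function(n, delta, seed) {
    withr::with_seed(seed, {
      sex <- factor(sample(c("F", "M"), n, replace = TRUE), levels = c("F", "M"))
      rec <- tibble::tibble(
        subject_id = sprintf("p%04d", 1:n), sex = sex, crf = "CRF1"
      )
      sc <- purrr::map_dfr(1:3, function(mode) {
        tibble::tibble(
          subject_id = rec$subject_id, mode = mode,
          score = stats::rnorm(n) + ifelse(mode == 1, delta * (sex == "M"), 0)
        )
      })
      list(scores = sc, records = rec)
    })
  }
  d <- mk_scores(1500, 0.4, seed = 471)
  tab <- sex_difference_table(d$scores, d$records)
  expect_equal(nrow(tab), 3)
  expect_lt(tab$p[tab$mode == 1], 0.001)
  expect_gt(tab$mean_difference[tab$mode == 1], 0)

  # null calibration: p uniform over 200 replicates (KS)
  pvals <- vapply(1:200, function(i) {
    d0 <- mk_scores(120, 0, seed = 5000 + i)
    sex_difference_table(d0$scores[d0$scores$mode == 1, ], d0$records)$p
  }, numeric(1))
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)

  # identically distributed sexes: bounded standardised differences
  d0 <- mk_scores(2000, 0, seed = 481)
  tab0 <- sex_difference_table(d0$scores, d0$records)
  expect_true(all(abs(tab0$mean_difference) < 3 * sqrt(2 / 1000)))

  # single-mode table has one row
  tab1 <- sex_difference_table(d$scores[d$scores$mode == 2, ], d$records)
  expect_equal(nrow(tab1), 1)
})

test_that("correlation_table is consistent with element-wise calls and honours adjust_crf", {
  withr::with_seed(491, {
    n <- 400
    rec <- tibble::tibble(
      subject_id = sprintf("q%04d", 1:n),
      sex = factor(sample(c("F", "M"), n, replace = TRUE), levels = c("F", "M")),
      height_m = stats::rnorm(n, 1.7, 0.08),
      weight_kg = stats::rnorm(n, 78, 12),
      crf = factor(sample(paste0("CRF", 1:3), n, replace = TRUE))
    )
    sc <- purrr::map_dfr(1:2, function(mode) {
      tibble::tibble(
        subject_id = rec$subject_id, mode = mode,
        score = stats::rnorm(n) + ifelse(mode == 1, 0.05 * (rec$weight_kg - 78), 0)
      )
    })
  })
  tab <- correlation_table(sc, rec, c("height_m", "weight_kg"), adjust_crf = TRUE)
  expect_equal(nrow(tab), 2 * 2 * 2) # sex x mode x variable
  one <- tab[tab$sex == "F" & tab$mode == 1 & tab$variable == "weight_kg", ]
  d <- dplyr::inner_join(sc[sc$mode == 1, ], rec[rec$sex == "F", ], by = "subject_id")
  expect_equal(one$r, partial_correlation(d$score, d$weight_kg, d$crf)$r)
  expect_true(one$flagged)

  # no CRF structure: adjusted and plain tables agree
  rec1 <- dplyr::mutate(rec, crf = factor("CRF1"))
  t_adj <- correlation_table(sc, rec1, "weight_kg", adjust_crf = TRUE)
  t_plain <- correlation_table(sc, rec1, "weight_kg", adjust_crf = FALSE)
  expect_equal(t_adj$r, t_plain$r, tolerance = 1e-10)

  expect_error(correlation_table(sc, rec, "nope"), "unknown variable")
})
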