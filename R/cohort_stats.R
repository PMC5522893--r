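#' Pooled-variance Student's t-test
#'
#' Two-sided Student's t-test with the pooled variance estimate,
#' `df = n_a + n_b - 2`. `ttest_raw()` takes the raw samples; [ttest_summary()]
#' computes the identical statistic from group summaries (n, mean, SD) alone,
#' which is how printed cohort tables can be re-tested.
#'
#' @param a,b Numeric vectors (missing values dropped), each with at least two
#'   observations and a positive pooled variance.
#' @return A one-row tibble with columns `t`, `df`, `p` and `mean_difference`
#'   (`mean(a) - mean(b)`).
#' @examples
#' ttest_raw(c(1, 2, 3), c(4, 5, 6))
#' @export
ttest_raw <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  summarise_group <- function(v) {
    tibble(n = length(v), mean = mean(v), sd = stats::sd(v))
  }
  ttest_summary(summarise_group(a), summarise_group(b))
}

#' Pooled Student's t-test from group summaries
#'
#' Computes the identical statistic to [ttest_raw()] from per-group summaries
#' alone, so printed "mean (SD)" table rows can be re-tested.
#'
#' @param a,b Group summaries, each a list or one-row data frame with elements
#'   `n`, `mean`, `sd`.
#' @return A one-row tibble with columns `t`, `df`, `p` and `mean_difference`.
#' @examples
#' men <- list(n = 729, mean = 0.22, sd = 1.01)
#' women <- list(n = 782, mean = -0.18, sd = 0.95)
#' ttest_summary(men, women)
#' @export
ttest_summary <- function(a, b) {
  n1 <- a$n
  n2 <- b$n
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2", call. = FALSE)
  df <- n1 + n2 - 2
  pooled_var <- ((n1 - 1) * a$sd^2 + (n2 - 1) * b$sd^2) / df
  if (pooled_var <= 0) stop("pooled variance is zero", call. = FALSE)
  diff <- a$mean - b$mean
  se <- sqrt(pooled_var * (1 / n1 + 1 / n2))
  t <- diff / se
  tibble(
    t = t, df = df,
    p = 2 * stats::pt(-abs(t), df),
    mean_difference = diff
  )
}

#' Pearson correlation with reporting flag
#'
#' Product-moment correlation between paired samples; pairs with any missing
#' value are dropped. The `flagged` column marks coefficients whose magnitude
#' reaches the interpretation threshold (default 0.1, the conventional cut-off
#' used when p-values are uninformative at large n).
#'
#' @param x,y Paired numeric vectors.
#' @param threshold Reporting threshold on `|r|`.
#' @param flag_rule `"geq"` flags `|r| >= threshold` (as bolded in printed
#'   correlation tables); `"gt"` flags strictly greater.
#' @return A one-row tibble with columns `r`, `n_used`, `adjusted_for` (empty
#'   string) and `flagged`.
#' @export
pearson <- function(x, y, threshold = 0.1, flag_rule = c("geq", "gt")) {
  flag_rule <- match.arg(flag_rule)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::var(x) <= 0 || stats::var(y) <= 0) {
    stop("zero variance in x or y", call. = FALSE)
  }
  r <- stats::cor(x, y)
  tibble(
    r = r, n_used = length(x), adjusted_for = "",
    flagged = flag_hit(r, threshold, flag_rule)
  )
}

flag_hit <- function(r, threshold, flag_rule) {
  if (flag_rule == "geq") abs(r) >= threshold else abs(r) > threshold
}

# Residualise v on an intercept + dummy-coded factor by least squares.
# A single-level factor residualises on the intercept alone (centring).
residualise_on_factor <- function(v, f) {
  X <- if (nlevels(f) < 2) matrix(1, length(v), 1) else stats::model.matrix(~f)
  fit <- stats::lm.fit(X, v)
  if (fit$rank < ncol(X)) stop("singular adjustment design", call. = FALSE)
  fit$residuals
}

#' Partial correlation adjusting for a categorical covariate
#'
#' Residualises `x` and `y` separately on an intercept plus dummy indicators
#' for the levels of `group` (reference level = first factor level,
#' lexicographic for character input) and returns the Pearson correlation of
#' the residuals. This is the centre-adjusted ("partial, adjusted for CRF")
#' correlation used when scans come from several facilities.
#'
#' @inheritParams pearson
#' @param group Categorical covariate (factor or character), same length.
#' @return A one-row tibble with columns `r`, `n_used`, `adjusted_for`
#'   (`"crf"`) and `flagged`.
#' @export
partial_correlation <- function(x, y, group, threshold = 0.1,
                                flag_rule = c("geq", "gt")) {
  flag_rule <- match.arg(flag_rule)
  ok <- stats::complete.cases(x, y, group)
  x <- x[ok]
  y <- y[ok]
  f <- factor(as.character(group[ok]))
  if (any(table(f) < 2)) {
    small <- names(which(table(f) < 2))
    stop(glue::glue(
      "adjustment level(s) with fewer than 2 members: {paste(small, collapse = ', ')}"
    ), call. = FALSE)
  }
  if (length(x) <= nlevels(f) + 2) {
    stop("too few complete cases for the adjustment", call. = FALSE)
  }
  rx <- residualise_on_factor(x, f)
  ry <- residualise_on_factor(y, f)
  if (stats::var(rx) <= 0 || stats::var(ry) <= 0) {
    stop("zero residual variance after adjustment", call. = FALSE)
  }
  r <- stats::cor(rx, ry)
  tibble(
    r = r, n_used = length(x), adjusted_for = "crf",
    flagged = flag_hit(r, threshold, flag_rule)
  )
}

#' Covariate-adjusted sex association with a mode score
#'
#' Ordinary least squares of the score on an intercept, a sex indicator
#' (male = 1, so the coefficient is the male minus female difference) and any
#' further covariates; used to ask whether a sex difference in a shape mode
#' survives adjustment for, say, height. With no covariates the coefficient
#' equals the raw group mean difference and the p-value equals the pooled
#' t-test's.
#'
#' @param scores Numeric score vector.
#' @param sex Factor or character with levels `F`/`M` (or any two levels; the
#'   second level after `factor()` is the indicator).
#' @param covariates Optional data frame of numeric covariates.
#' @return A one-row tibble with columns `estimate` (sex coefficient), `se`,
#'   `p` and `n_used`.
#' @export
adjusted_sex_association <- function(scores, sex, covariates = NULL) {
  sex <- factor(as.character(sex))
  if (nlevels(sex) != 2) stop("sex must have exactly two levels", call. = FALSE)
  df <- data.frame(score = scores, sex = sex)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    df <- cbind(df, covariates)
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) <= ncol(df) + 2) stop("too few complete cases", call. = FALSE)
  fit <- stats::lm(score ~ ., data = df)
  if (any(is.na(stats::coef(fit)))) stop("collinear design", call. = FALSE)
  cf <- summary(fit)$coefficients
  row <- grep("^sex", rownames(cf))[1]
  tibble(
    estimate = cf[row, 1], se = cf[row, 2], p = cf[row, 4],
    n_used = nrow(df)
  )
}

join_scores_records <- function(scores, records) {
  joined <- dplyr::inner_join(scores, records, by = "subject_id")
  if (nrow(joined) == 0L) {
    stop("no subjects shared between scores and records", call. = FALSE)
  }
  joined
}

#' Sex-difference table for mode scores
#'
#' One row per mode with male and female summaries (n, mean, SD) and the
#' pooled Student's t-test of the sex difference — the layout used for
#' "sex differences in shape modes" tables.
#'
#' @param scores A score tibble (`subject_id`, `mode`, `score`) from
#'   [score_shapes()].
#' @param records A participant tibble from [read_cohort_table()] (needs
#'   `subject_id` and `sex`).
#' @return A tibble with columns `mode`, `n_m`, `mean_m`, `sd_m`, `n_f`,
#'   `mean_f`, `sd_f`, `mean_difference` (male - female), `t`, `df`, `p`.
#' @export
sex_difference_table <- function(scores, records) {
  joined <- join_scores_records(scores, records)
  if (length(unique(stats::na.omit(joined$sex))) < 2) {
    stop("both sexes must be present", call. = FALSE)
  }
  joined |>
    dplyr::filter(!is.na(.data$sex)) |>
    dplyr::group_by(.data$mode) |>
    dplyr::group_modify(function(d, key) {
      a <- d$score[d$sex == "M"]
      b <- d$score[d$sex == "F"]
      if (length(a) < 2 || length(b) < 2) {
        stop("a sex group is empty or too small for a mode", call. = FALSE)
      }
      tt <- ttest_raw(a, b)
      tibble(
        n_m = length(a), mean_m = mean(a), sd_m = stats::sd(a),
        n_f = length(b), mean_f = mean(b), sd_f = stats::sd(b),
        mean_difference = tt$mean_difference, t = tt$t, df = tt$df, p = tt$p
      )
    }) |>
    dplyr::ungroup()
}

#' Mode-covariate correlation table
#'
#' Correlations between each retained mode's scores and each named covariate,
#' optionally adjusted for scanning centre (CRF) by partial correlation and
#' stratified by sex — the layout of printed "partial correlations between
#' modes and height, weight, BMI, BMD" tables. Complete cases are used per
#' mode-covariate cell.
#'
#' @inheritParams sex_difference_table
#' @param variables Character vector of covariate column names in `records`.
#' @param adjust_crf Adjust for the `crf` column via [partial_correlation()]?
#' @param stratify_by_sex Compute separately within each sex?
#' @param threshold,flag_rule Passed to [pearson()]/[partial_correlation()].
#' @return A tibble with columns `sex` (if stratified), `mode`, `variable`,
#'   `r`, `n_used`, `adjusted_for`, `flagged`.
#' @export
correlation_table <- function(scores, records, variables,
                              adjust_crf = TRUE, stratify_by_sex = TRUE,
                              threshold = 0.1, flag_rule = c("geq", "gt")) {
  flag_rule <- match.arg(flag_rule)
  unknown <- setdiff(variables, names(records))
  if (length(unknown) > 0) {
    stop(glue::glue("unknown variable(s): {paste(unknown, collapse = ', ')}"),
      call. = FALSE
    )
  }
  joined <- join_scores_records(scores, records)
  strata <- if (stratify_by_sex) split(joined, joined$sex) else list(all = joined)
  purrr::imap_dfr(strata, function(d, sex_label) {
    grid <- tidyr::expand_grid(mode = sort(unique(d$mode)), variable = variables)
    purrr::pmap_dfr(grid, function(mode, variable) {
      cell <- d[d$mode == mode, ]
      res <- if (adjust_crf) {
        partial_correlation(cell$score, cell[[variable]], cell$crf,
          threshold = threshold, flag_rule = flag_rule
        )
      } else {
        pearson(cell$score, cell[[variable]],
          threshold = threshold, flag_rule = flag_rule
        )
      }
      dplyr::bind_cols(tibble(sex = sex_label, mode = mode, variable = variable), res)
    })
  })
}

#' Cross-correlation table between two sets of mode scores
#'
#' Pairwise correlations between every mode of one joint's model and every
#' mode of another's (for example hip modes x spine modes), CRF-adjusted and
#' sex-stratified by default. Only subjects present in both score tables and
#' the records are used.
#'
#' @param scores_a,scores_b Score tibbles from [score_shapes()]; mode columns
#'   are prefixed in the output as `mode_a`/`mode_b`.
#' @inheritParams correlation_table
#' @return A tibble with columns `sex`, `mode_a`, `mode_b`, `r`, `n_used`,
#'   `adjusted_for`, `flagged`.
#' @export
cross_correlation_table <- function(scores_a, scores_b, records,
                                    adjust_crf = TRUE, stratify_by_sex = TRUE,
                                    threshold = 0.1, flag_rule = c("geq", "gt")) {
  flag_rule <- match.arg(flag_rule)
  wide_a <- tidyr::pivot_wider(scores_a,
    names_from = "mode", values_from = "score", names_prefix = "a"
  )
  wide_b <- tidyr::pivot_wider(scores_b,
    names_from = "mode", values_from = "score", names_prefix = "b"
  )
  joined <- wide_a |>
    dplyr::inner_join(wide_b, by = "subject_id") |>
    dplyr::inner_join(records, by = "subject_id")
  if (nrow(joined) == 0L) stop("empty joint subject set", call. = FALSE)
  modes_a <- sort(unique(scores_a$mode))
  modes_b <- sort(unique(scores_b$mode))
  strata <- if (stratify_by_sex) split(joined, joined$sex) else list(all = joined)
  purrr::imap_dfr(strata, function(d, sex_label) {
    grid <- tidyr::expand_grid(mode_a = modes_a, mode_b = modes_b)
    purrr::pmap_dfr(grid, function(mode_a, mode_b) {
      xa <- d[[paste0("a", mode_a)]]
      xb <- d[[paste0("b", mode_b)]]
      res <- if (adjust_crf) {
        partial_correlation(xa, xb, d$crf, threshold = threshold, flag_rule = flag_rule)
      } else {
        pearson(xa, xb, threshold = threshold, flag_rule = flag_rule)
      }
      dplyr::bind_cols(
        tibble(sex = sex_label, mode_a = mode_a, mode_b = mode_b), res
      )
    })
  })
}
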