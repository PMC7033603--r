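#' Bonferroni-adjusted significance threshold
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param m number of comparisons (at least 1; vectorized).
#' @return the per-comparison threshold `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  assert_that(length(m) >= 1 && all(m >= 1), "m must be at least 1")
  alpha / m
}

#' Compare retained features between conditions
#'
#' For every retained feature: a Welch independent t-test between conditions
#' on the training rows and a paired t-test on the testing rows (paired by
#' participant). Significance is flagged at the Bonferroni-adjusted threshold
#' `alpha / m` with `m = 2 * length(features)` comparisons. A Shapiro-Wilk
#' normality p-value is reported per test for inspection (no automatic
#' nonparametric fallback).
#'
#' @param train_table,test_table feature tables; every testing participant
#'   must have exactly one row per condition.
#' @param features retained feature names.
#' @param alpha family-wise alpha.
#' @return a `comparison_table` tibble: one row per (feature, dataset) with
#'   group means/SDs, t statistic, p-value and significance flag; the
#'   adjusted threshold is in attribute `threshold`.
#' @export
compare_selected_features <- function(train_table, test_table, features,
                                      alpha = 0.05) {
  assert_that(length(features) >= 1, "retained feature set is empty")
  conds <- sort(unique(c(train_table$condition, test_table$condition)))
  assert_that(length(conds) == 2, "exactly two conditions are required")
  pair_check <- test_table |>
    dplyr::count(.data$participant) |>
    dplyr::filter(.data$n != 2)
  if (nrow(pair_check) > 0) {
    abort(sprintf(
      "unpaired testing participant(s): %s",
      paste(pair_check$participant, collapse = ", ")
    ), class = "gaitenv_unpaired")
  }
  m <- 2L * length(features)
  thr <- bonferroni_threshold(alpha, m)
  test_wide <- test_table |> dplyr::arrange(.data$participant)
  rows <- purrr::map_dfr(features, function(f) {
    a_tr <- train_table[[f]][train_table$condition == conds[1]]
    b_tr <- train_table[[f]][train_table$condition == conds[2]]
    tt <- t.test(a_tr, b_tr, var.equal = FALSE)
    a_te <- test_wide[[f]][test_wide$condition == conds[1]]
    b_te <- test_wide[[f]][test_wide$condition == conds[2]]
    d <- a_te - b_te
    pt <- if (sd(d) == 0) {
      list(statistic = c(t = 0), p.value = 1)
    } else {
      t.test(a_te, b_te, paired = TRUE)
    }
    sw_p <- function(x) {
      if (length(unique(x)) < 3) return(NA_real_)
      tryCatch(shapiro.test(x)$p.value, error = function(e) NA_real_)
    }
    tibble::tibble(
      feature = f,
      dataset = c("training", "testing"),
      test = c("welch_independent_t", "paired_t"),
      mean_1 = c(mean(a_tr), mean(a_te)), sd_1 = c(sd(a_tr), sd(a_te)),
      mean_2 = c(mean(b_tr), mean(b_te)), sd_2 = c(sd(b_tr), sd(b_te)),
      statistic = c(unname(tt$statistic), unname(pt$statistic)),
      p_value = c(tt$p.value, pt$p.value),
      shapiro_p = c(sw_p(c(a_tr, b_tr)), sw_p(d)),
      significant = .data$p_value < thr
    )
  })
  rows <- rows |>
    dplyr::rename_with(
      ~ sub("_1$", paste0("_", conds[1]), sub("_2$", paste0("_", conds[2]), .x)),
      dplyr::matches("_[12]$")
    )
  attr(rows, "threshold") <- thr
  attr(rows, "m") <- m
  class(rows) <- c("comparison_table", class(rows))
  rows
}

#' Protocol-level cohort descriptives
#'
#' One-way ANOVA of each descriptive variable (height, mass, age, per-
#' condition speed) across the protocol groups, a paired t-test on the
#' both-conditions group's speeds, and a protocol-by-variable mean (SD)
#' summary.
#'
#' @param dataset a `gait_dataset` (its manifest carries the demographics).
#' @return list with `summary` (mean/SD tibble), `anova` (variable, F,
#'   p-value) and `paired_speed` (t, p-value, means).
#' @export
cohort_descriptives <- function(dataset) {
  stopifnot(inherits(dataset, "gait_dataset"))
  man <- dataset$manifest
  sizes <- man |>
    dplyr::distinct(.data$participant, .data$protocol) |>
    dplyr::count(.data$protocol)
  assert_that(nrow(sizes) >= 2 && all(sizes$n >= 2),
    "need at least 2 protocols with at least 2 participants each")
  per_part <- man |>
    dplyr::distinct(.data$participant, .data$protocol, .data$height_m,
      .data$mass_kg, .data$age_yr)
  speed_tbl <- man |>
    dplyr::select("participant", "protocol", "condition", "speed_mps")

  anova_p <- function(value, group) {
    if (sd(value) == 0) return(tibble::tibble(f_statistic = 0, p_value = 1))
    fit <- aov(value ~ factor(group))
    s <- summary(fit)[[1]]
    tibble::tibble(f_statistic = s$`F value`[1], p_value = s$`Pr(>F)`[1])
  }
  anova_rows <- dplyr::bind_rows(
    dplyr::bind_cols(tibble::tibble(variable = "height_m"),
      anova_p(per_part$height_m, per_part$protocol)),
    dplyr::bind_cols(tibble::tibble(variable = "mass_kg"),
      anova_p(per_part$mass_kg, per_part$protocol)),
    dplyr::bind_cols(tibble::tibble(variable = "age_yr"),
      anova_p(per_part$age_yr, per_part$protocol)),
    purrr::map_dfr(unique(speed_tbl$condition), function(cond) {
      sub <- speed_tbl |> dplyr::filter(.data$condition == cond)
      if (dplyr::n_distinct(sub$protocol) < 2) return(NULL)
      dplyr::bind_cols(
        tibble::tibble(variable = paste0("speed_", cond)),
        anova_p(sub$speed_mps, sub$protocol)
      )
    })
  )
  p3 <- speed_tbl |>
    dplyr::filter(.data$protocol == max(.data$protocol)) |>
    tidyr::pivot_wider(names_from = "condition", values_from = "speed_mps")
  paired_speed <- NULL
  if (nrow(p3) >= 2 && ncol(p3) >= 4) {
    conds <- setdiff(names(p3), c("participant", "protocol"))
    d <- p3[[conds[1]]] - p3[[conds[2]]]
    pt <- if (sd(d) == 0) list(statistic = c(t = 0), p.value = 1) else
      t.test(p3[[conds[1]]], p3[[conds[2]]], paired = TRUE)
    paired_speed <- tibble::tibble(
      condition_1 = conds[1], condition_2 = conds[2],
      mean_1 = mean(p3[[conds[1]]]), mean_2 = mean(p3[[conds[2]]]),
      statistic = unname(pt$statistic), p_value = pt$p.value
    )
  }
  summary_tbl <- per_part |>
    dplyr::group_by(.data$protocol) |>
    dplyr::summarise(
      n = dplyr::n(),
      dplyr::across(c("height_m", "mass_kg", "age_yr"),
        list(mean = mean, sd = sd)),
      .groups = "drop"
    )
  list(summary = summary_tbl, anova = anova_rows, paired_speed = paired_speed)
}
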