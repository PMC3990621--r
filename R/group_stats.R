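#' Holm-Bonferroni step-down procedure
#'
#' Orders the m p-values of a contrast family ascending and compares the
#' k-th smallest against alpha / (m - k + 1), rejecting while p <= alpha_crit
#' and stopping at the first failure (all later hypotheses are retained).
#' Controls the family-wise error rate at alpha without Bonferroni's full
#' conservatism. For a family of six contrasts at alpha = .05 the first four
#' thresholds are .008, .010, .013 and .017 (3 dp, rounded half away from
#' zero).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param alpha Family-wise error level in (0, 1), default `.05`.
#' @param labels Optional contrast labels carried into the output.
#' @return A tibble ordered by ascending p with columns `label` (if given),
#'   `rank`, `p`, `alpha_crit` (full precision), `alpha_crit_3dp` (rounded
#'   half away from zero) and `reject`.
#' @examples
#' holm_step_down(c(.005, .009, .032, .052, .2, .3))
#' @export
holm_step_down <- function(p_values, alpha = 0.05, labels = NULL) {
  if (length(p_values) < 1L || any(p_values < 0 | p_values > 1)) {
    rlang::abort("p-values must lie in [0, 1]",
                 class = "mentalrep_domain_error")
  }
  if (alpha <= 0 || alpha >= 1) {
    rlang::abort("alpha must lie in (0, 1)",
                 class = "mentalrep_domain_error")
  }
  m <- length(p_values)
  ord <- order(p_values)
  p_sorted <- p_values[ord]
  alpha_crit <- alpha / (m - seq_len(m) + 1L)
  passes <- p_sorted <= alpha_crit
  first_fail <- match(FALSE, passes, nomatch = m + 1L)
  out <- tibble::tibble(
    rank = seq_len(m),
    p = p_sorted,
    alpha_crit = alpha_crit,
    alpha_crit_3dp = round_half_away(alpha_crit, 3),
    reject = seq_len(m) < first_fail
  )
  if (!is.null(labels)) {
    out <- dplyr::bind_cols(tibble::tibble(label = labels[ord]), out)
  }
  out
}

#' Cohen's d from summary statistics
#'
#' Standardised mean difference using the pooled standard deviation
#' \eqn{s_p = \sqrt{((n_1-1)s_1^2 + (n_2-1)s_2^2)/(n_1+n_2-2)}}.
#'
#' @param mean1,sd1,n1 Mean, SD and size of group 1.
#' @param mean2,sd2,n2 Mean, SD and size of group 2.
#' @return Cohen's d (positive when group 1 exceeds group 2).
#' @examples
#' cohens_d(10, 2, 13, 8, 2, 13)  # 1
#' @export
cohens_d <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (any(c(sd1, sd2) <= 0)) {
    rlang::abort("standard deviations must be positive",
                 class = "mentalrep_domain_error")
  }
  if (any(c(n1, n2) < 2)) {
    rlang::abort("group sizes must be at least 2",
                 class = "mentalrep_domain_error")
  }
  s_pooled <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  (mean1 - mean2) / s_pooled
}

#' Score the revised Movement Imagery Questionnaire (MIQ-R)
#'
#' The MIQ-R rates the ease of imagining four movements on a 7-point Likert
#' scale, separately for visual and kinesthetic imagery (8 items total).
#' Scoring is a per-scale total (range 4-28) plus the per-item mean
#' (total / 4, 2 dp); around 5 per item is read as "somewhat easy to
#' see/feel", i.e. sufficient imagery ability.
#'
#' @param items Tibble with columns `scale` (`"visual"` or `"kinesthetic"`),
#'   `rating` (integer 1-7) and optionally `participant`.
#' @return A tibble with one row per (participant x) scale: `n_items`,
#'   `total`, `per_item` (2 dp).
#' @examples
#' miq_scores(tibble::tibble(scale = rep(c("visual", "kinesthetic"), each = 4),
#'                           rating = c(7, 7, 7, 7, 5, 5, 5, 5)))
#' @export
miq_scores <- function(items) {
  if (!all(c("scale", "rating") %in% names(items))) {
    rlang::abort("items need columns scale and rating",
                 class = "mentalrep_validation_error")
  }
  if (!all(items$scale %in% c("visual", "kinesthetic"))) {
    rlang::abort("scale must be visual or kinesthetic",
                 class = "mentalrep_validation_error")
  }
  if (!all(items$rating %in% 1:7)) {
    rlang::abort("ratings must be integers 1..7",
                 class = "mentalrep_validation_error")
  }
  keys <- intersect(c("participant", "scale"), names(items))
  out <- items |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(n_items = dplyr::n(), total = sum(.data$rating),
                     .groups = "drop") |>
    dplyr::mutate(per_item = round_half_away(.data$total / 4, 2))
  if (any(out$n_items != 4L)) {
    rlang::abort("each scale needs exactly 4 items",
                 class = "mentalrep_validation_error")
  }
  out
}

#' Group-level means and standard errors of the outcome scores
#'
#' @param perf Per-participant summary from [summarize_putts()] with a
#'   `group` column.
#' @return A tidy tibble with one row per group x test day x score
#'   (`mre`, `bve`): `n`, `mean`, `sd`, `se` (`sd/sqrt(n)`; `NA` with a
#'   message when n = 1).
#' @export
group_summary <- function(perf) {
  if (nrow(perf) == 0L || !all(c("group", "test_day") %in% names(perf))) {
    rlang::abort("perf must be non-empty with group and test_day columns",
                 class = "mentalrep_validation_error")
  }
  out <- perf |>
    tidyr::pivot_longer(dplyr::all_of(c("mre", "bve")), names_to = "score",
                        values_to = "value") |>
    dplyr::group_by(.data$group, .data$test_day, .data$score) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = ifelse(dplyr::n() > 1L, stats::sd(.data$value), NA_real_),
      .groups = "drop"
    ) |>
    dplyr::mutate(se = .data$sd / sqrt(.data$n))
  if (anyNA(out$se)) {
    rlang::inform("groups of size 1 have no standard error")
  }
  out
}

#' Holm-corrected pairwise group contrasts of the outcome scores
#'
#' Builds the contrast family the four-group design implies: all six
#' pairwise group comparisons per dependent variable at one test day, with
#' Welch two-sample one-tailed p-values (direction taken from the observed
#' means, smaller score = better), Holm step-down correction within each
#' dependent variable's family, and Cohen's d effect sizes.
#'
#' This is a descriptive convenience for synthetic or exploratory cohorts;
#' covariate-adjusted omnibus modelling belongs in dedicated statistical
#' software and the per-participant table from [summarize_putts()] exports
#' cleanly for that purpose.
#'
#' @param perf Per-participant summary from [summarize_putts()].
#' @param test_day Which test day to contrast (default `"post"`).
#' @param alpha Family-wise level, default `.05`.
#' @return A tibble with columns `dv`, `contrast`, `rank`, `p`,
#'   `alpha_crit`, `alpha_crit_3dp`, `reject`, `cohens_d`.
#' @export
pairwise_group_contrasts <- function(perf, test_day = "post", alpha = 0.05) {
  day <- perf[perf$test_day == test_day, , drop = FALSE]
  if (dplyr::n_distinct(day$group) < 2L) {
    rlang::abort("need at least two groups at the chosen test day",
                 class = "mentalrep_domain_error")
  }
  groups <- sort(unique(as.character(day$group)))
  pairs <- utils::combn(groups, 2L)
  purrr::map_dfr(c("mre", "bve"), function(dv) {
    tests <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
      g1 <- day[[dv]][day$group == pairs[1, i]]
      g2 <- day[[dv]][day$group == pairs[2, i]]
      tt <- stats::t.test(g1, g2,
                          alternative = if (mean(g1) <= mean(g2)) "less"
                                        else "greater")
      tibble::tibble(
        contrast = paste(pairs[1, i], "vs", pairs[2, i]),
        p = tt$p.value,
        cohens_d = cohens_d(mean(g1), stats::sd(g1), length(g1),
                            mean(g2), stats::sd(g2), length(g2))
      )
    })
    holm_step_down(tests$p, alpha = alpha, labels = tests$contrast) |>
      dplyr::left_join(tests, by = c("label" = "contrast", "p")) |>
      dplyr::rename(contrast = "label") |>
      dplyr::mutate(dv = dv, .before = 1L)
  })
}
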