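#' Centroid of a set of putts
#'
#' The positionally typical shot: the per-axis mean landing position, in cm,
#' with the target centre as origin.
#'
#' @param x,y Numeric vectors of signed offsets from the target centre (cm);
#'   `x` lateral, `y` along the target line.
#' @return A named numeric vector `c(x = , y = )`.
#' @export
putt_centroid <- function(x, y) {
  check_putt_coords(x, y)
  c(x = mean(x), y = mean(y))
}

#' Mean radial error (accuracy)
#'
#' Average distance of the putts from the target centre:
#' \eqn{MRE = \frac{1}{k}\sum_i \sqrt{x_i^2 + y_i^2}} (cm). Lower is more
#' accurate. Invariant under rotations about the origin and axis
#' reflections.
#'
#' @inheritParams putt_centroid
#' @return MRE in cm.
#' @examples
#' mean_radial_error(c(3, -3), c(4, -4))  # 5
#' @export
mean_radial_error <- function(x, y) {
  check_putt_coords(x, y)
  mean(sqrt(x^2 + y^2))
}

#' Bivariate variable error (consistency)
#'
#' Root mean squared distance of the putts from their own centroid:
#' \eqn{BVE = \sqrt{\frac{1}{k}\sum_i \left[(x_i-\bar x)^2 +
#' (y_i-\bar y)^2\right]}} (cm). Lower is more consistent. Invariant under
#' translation of the whole set (it ignores bias); BVE^2 equals the sum of
#' the per-axis population variances.
#'
#' @inheritParams putt_centroid
#' @param divisor `"k"` (default; literal mean over shots) or `"k-1"`.
#' @return BVE in cm; 0 when there is a single putt.
#' @examples
#' bivariate_variable_error(c(3, -3), c(4, -4))  # 5
#' @export
bivariate_variable_error <- function(x, y, divisor = c("k", "k-1")) {
  divisor <- match.arg(divisor)
  check_putt_coords(x, y)
  k <- length(x)
  if (k == 1L) return(0)
  ss <- sum((x - mean(x))^2 + (y - mean(y))^2)
  sqrt(ss / if (divisor == "k") k else k - 1L)
}

check_putt_coords <- function(x, y) {
  if (length(x) == 0L) {
    rlang::abort("need at least one putt", class = "mentalrep_domain_error")
  }
  if (length(x) != length(y) || !all(is.finite(x)) || !all(is.finite(y))) {
    rlang::abort("x and y must be finite and of equal length",
                 class = "mentalrep_validation_error")
  }
  invisible(TRUE)
}

#' Per-participant performance summaries
#'
#' Collapses a long putt table into one row of outcome scores per grouping
#' cell: putt count k, centroid coordinates, mean radial error and bivariate
#' variable error, all in cm. The default grouping is participant x test day
#' (all putts of a test day pooled across blocks); pass e.g.
#' `c("participant", "test_day", "block")` to score blocks separately.
#'
#' @param putts Tibble with columns `participant`, `test_day`, `x_cm`,
#'   `y_cm`, optionally `group` and `block`.
#' @param by Character vector of grouping columns.
#' @param expected_k Expected putt count per cell (default `NULL`, i.e. no
#'   check); cells with fewer putts are kept but counted in a message, so
#'   real-world trial loss is tolerated and visible.
#' @param divisor Passed to [bivariate_variable_error()].
#' @return A tibble with the grouping columns (plus `group` when present)
#'   and `k`, `cx`, `cy`, `mre`, `bve`, ordered by the grouping keys.
#' @export
summarize_putts <- function(putts, by = c("participant", "test_day"),
                            expected_k = NULL, divisor = c("k", "k-1")) {
  divisor <- match.arg(divisor)
  missing_keys <- setdiff(by, names(putts))
  if (length(missing_keys) > 0L) {
    rlang::abort(paste("unknown grouping column(s):",
                       paste(missing_keys, collapse = ", ")),
                 class = "mentalrep_config_error")
  }
  carry <- intersect("group", names(putts))
  out <- putts |>
    dplyr::group_by(dplyr::across(dplyr::all_of(union(carry, by)))) |>
    dplyr::summarise(
      k = dplyr::n(),
      cx = mean(.data$x_cm),
      cy = mean(.data$y_cm),
      mre = mean_radial_error(.data$x_cm, .data$y_cm),
      bve = bivariate_variable_error(.data$x_cm, .data$y_cm,
                                     divisor = divisor),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(by)))
  if (!is.null(expected_k)) {
    short <- sum(out$k < expected_k)
    if (short > 0L) {
      rlang::inform(sprintf("%d cell(s) have fewer than %d putts", short,
                            expected_k))
    }
  }
  out
}

#' Plot group learning curves of an outcome score
#'
#' Group means of MRE or BVE across test days with standard-error bars, the
#' conventional display of putting accuracy/consistency over a practice
#' study.
#'
#' @param perf Per-participant summary from [summarize_putts()] (needs a
#'   `group` column).
#' @param score `"mre"` or `"bve"`.
#' @return A ggplot object.
#' @export
plot_performance <- function(perf, score = c("mre", "bve")) {
  score <- match.arg(score)
  gs <- group_summary(perf) |>
    dplyr::filter(.data$score == !!score)
  ggplot2::ggplot(gs, ggplot2::aes(x = .data$test_day, y = .data$mean,
                                   group = .data$group,
                                   colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.1) +
    ggplot2::labs(x = NULL, y = paste(toupper(score), "(cm)"),
                  colour = "Group") +
    ggplot2::theme_minimal()
}
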