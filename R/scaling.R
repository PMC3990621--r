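#' Assemble a decision matrix from splitting-task judgments
#'
#' In the splitting task each concept in turn serves as the anchor while all
#' remaining concepts are judged "related" (1) or "not related" (0) to it.
#' One participant x test day therefore yields N*(N-1) ordered judgments,
#' collected here into an N x N binary decision matrix with rows = anchors,
#' columns = probes. The diagonal is fixed to 1 by convention and is never
#' used downstream.
#'
#' @param judgments A data frame with columns `anchor_id`, `probe_id`,
#'   `judgment` (0/1), covering every ordered pair exactly once for a single
#'   participant and test day. Extra columns are ignored.
#' @param catalog Catalog tibble, see [bac_catalog()].
#' @return An N x N integer matrix with dimnames set to the concept ids.
#' @examples
#' cat16 <- bac_catalog()
#' judg <- tidyr::crossing(anchor_id = 1:16, probe_id = 1:16) |>
#'   dplyr::filter(anchor_id != probe_id) |>
#'   dplyr::mutate(judgment = 1L)
#' D <- assemble_decision_matrix(judg, cat16)
#' all(D == 1L)
#' @export
assemble_decision_matrix <- function(judgments, catalog = bac_catalog()) {
  catalog <- validate_catalog(catalog)
  n <- nrow(catalog)
  req <- c("anchor_id", "probe_id", "judgment")
  if (!all(req %in% names(judgments))) {
    rlang::abort("judgments need columns anchor_id, probe_id, judgment",
                 class = "mentalrep_validation_error")
  }
  j <- dplyr::as_tibble(judgments[req])
  if (any(j$anchor_id == j$probe_id)) {
    rlang::abort("anchor and probe must differ",
                 class = "mentalrep_validation_error")
  }
  if (!all(j$judgment %in% c(0L, 1L))) {
    rlang::abort("judgment values must be 0 or 1",
                 class = "mentalrep_validation_error")
  }
  dup <- j |>
    dplyr::count(.data$anchor_id, .data$probe_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    rlang::abort(
      sprintf("duplicate judgment for pair (%d,%d)",
              dup$anchor_id[1], dup$probe_id[1]),
      class = "mentalrep_consistency_error"
    )
  }
  D <- matrix(NA_integer_, n, n, dimnames = list(catalog$id, catalog$id))
  D[cbind(match(j$anchor_id, catalog$id), match(j$probe_id, catalog$id))] <-
    as.integer(j$judgment)
  diag(D) <- 1L
  if (anyNA(D)) {
    miss <- which(is.na(D), arr.ind = TRUE)[1, ]
    rlang::abort(
      sprintf("missing judgment for pair (%d,%d)",
              catalog$id[miss[1]], catalog$id[miss[2]]),
      class = "mentalrep_incomplete_data_error"
    )
  }
  D
}

#' Pairwise anchor-profile correlations (SDA-M distance scaling, step 1)
#'
#' For each pair of concepts (i, j) the two anchor rows of the decision
#' matrix are compared on the m = N - 2 probe columns both share (columns i
#' and j themselves are excluded, so each profile is judged on the same
#' third-party concepts). The Pearson correlation of these restricted rows
#' measures how similarly the participant related the two concepts to the
#' rest of the set.
#'
#' A restricted row with zero variance (the participant judged every shared
#' probe identically for that anchor) leaves Pearson's r undefined. Two
#' cases are distinguished: if both restricted rows are constant and
#' identical the profiles agree perfectly and r = 1 (this is what happens to
#' a two-concept cluster whose members relate to nothing else: their mutual
#' columns are excluded, leaving two equal all-zero profiles); any other
#' zero-variance pair carries no usable signal and gets r = 0 with a
#' warning rather than an error, so that group aggregation stays well
#' defined.
#'
#' @param D Binary decision matrix from [assemble_decision_matrix()].
#' @return A symmetric N x N correlation matrix with unit diagonal.
#' @export
pairwise_correlations <- function(D) {
  n <- nrow(D)
  if (n != ncol(D)) {
    rlang::abort("decision matrix must be square",
                 class = "mentalrep_validation_error")
  }
  R <- diag(1, n)
  dimnames(R) <- dimnames(D)
  degenerate <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      keep <- setdiff(seq_len(n), c(i, j))
      xi <- D[i, keep]
      xj <- D[j, keep]
      if (stats::sd(xi) == 0 || stats::sd(xj) == 0) {
        if (stats::sd(xi) == 0 && stats::sd(xj) == 0 && all(xi == xj)) {
          r <- 1          # equal constant profiles: perfect agreement
        } else {
          r <- 0
          degenerate <- degenerate + 1L
        }
      } else {
        r <- stats::cor(xi, xj)
      }
      R[i, j] <- R[j, i] <- r
    }
  }
  if (degenerate > 0L) {
    rlang::warn(sprintf(
      "%d concept pair(s) had a zero-variance judgment profile; r set to 0",
      degenerate
    ))
  }
  R
}

#' Map a correlation to a Euclidean distance
#'
#' The scaling d = sqrt(2 m (1 - r)) is the exact Euclidean distance between
#' two z-standardised vectors of length m whose correlation is r. It is
#' strictly decreasing in r, with d(1) = 0 and d(-1) = sqrt(4 m). With the
#' default 16-concept catalog m = 14, so distances live on [0, sqrt(56)] and
#' the critical value d_crit = 3.41 corresponds to r = 1 - 3.41^2/28.
#'
#' @param r Correlation(s) in `[-1, 1]` (vectorised).
#' @param m Number of shared probe positions (default `14`, i.e. N - 2 for
#'   the 16-concept set).
#' @return Distance(s), same shape as `r`.
#' @examples
#' correlation_to_distance(0, m = 14)   # sqrt(28)
#' @export
correlation_to_distance <- function(r, m = 14L) {
  if (m < 2) {
    rlang::abort("m must be at least 2", class = "mentalrep_domain_error")
  }
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) {
    rlang::abort("correlations must lie in [-1, 1]",
                 class = "mentalrep_domain_error")
  }
  sqrt(pmax(2 * m * (1 - pmin(r, 1)), 0))
}

#' Average correlation matrices across participants
#'
#' Mean-group structures are built by averaging the per-participant
#' correlation matrices entrywise on Fisher's z scale (variance-stabilised),
#' then transforming back. Correlations are clamped to |r| <= 1 - 1e-6
#' before the transform so perfect agreement does not map to infinity.
#'
#' @param mats List of correlation matrices of identical dimension.
#' @param method `"fisher"` (default) or `"linear"` (plain arithmetic mean).
#' @return One correlation matrix of the common dimension.
#' @export
group_mean_correlations <- function(mats, method = c("fisher", "linear")) {
  method <- match.arg(method)
  if (length(mats) == 0L) {
    rlang::abort("need at least one correlation matrix",
                 class = "mentalrep_domain_error")
  }
  dims <- vapply(mats, function(m) dim(m), integer(2))
  if (any(dims != dims[1, 1])) {
    rlang::abort("correlation matrices must share one dimension",
                 class = "mentalrep_domain_error")
  }
  if (method == "linear") {
    out <- Reduce(`+`, mats) / length(mats)
  } else {
    zs <- lapply(mats, function(m) atanh(pmin(pmax(m, -1 + 1e-6), 1 - 1e-6)))
    out <- tanh(Reduce(`+`, zs) / length(zs))
  }
  diag(out) <- 1
  dimnames(out) <- dimnames(mats[[1]])
  out
}

#' Distance matrix from a correlation matrix
#'
#' Applies [correlation_to_distance()] entrywise and zeroes the diagonal.
#'
#' @param R Correlation matrix.
#' @param m Shared probe count, see [correlation_to_distance()].
#' @return Symmetric distance matrix with zero diagonal and attribute `m`.
#' @export
distances_from_correlations <- function(R, m = nrow(R) - 2L) {
  D <- correlation_to_distance(R, m = m)
  diag(D) <- 0
  attr(D, "m") <- as.integer(m)
  D
}

#' Per-participant and mean-group distance scaling in one call
#'
#' Tidy front door for the scaling step: takes a long judgment table for any
#' number of participants and test days, builds each decision matrix, the
#' per-participant correlations, and the Fisher-averaged group correlation
#' and distance matrix per grouping cell.
#'
#' @param judgments Long judgment tibble with columns `participant`,
#'   `test_day`, `anchor_id`, `probe_id`, `judgment`, and optionally `group`.
#' @param catalog Catalog tibble.
#' @param m Shared probe count passed to the distance map.
#' @param average `"fisher"` or `"linear"`, see [group_mean_correlations()].
#' @return A tibble with one row per group x test day (or test day only when
#'   no `group` column is present) and list-columns `correlations`
#'   (per-participant list), `mean_correlation`, `distances`, plus
#'   `n_participants`.
#' @export
scale_judgments <- function(judgments, catalog = bac_catalog(),
                            m = nrow(catalog) - 2L,
                            average = c("fisher", "linear")) {
  average <- match.arg(average)
  catalog <- validate_catalog(catalog)
  keys <- intersect(c("group", "test_day"), names(judgments))
  judgments |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(cell, key) {
      per_part <- cell |>
        dplyr::group_by(.data$participant) |>
        dplyr::group_map(function(rows, pkey) {
          pairwise_correlations(assemble_decision_matrix(rows, catalog))
        })
      Rbar <- group_mean_correlations(per_part, method = average)
      tibble::tibble(
        n_participants = length(per_part),
        correlations = list(per_part),
        mean_correlation = list(Rbar),
        distances = list(distances_from_correlations(Rbar, m = m))
      )
    }) |>
    dplyr::ungroup()
}
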