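#' Read a splitting-task judgment CSV
#'
#' Long format, one row per ordered (anchor, probe) judgment:
#' `participant,test_day,anchor_id,probe_id,judgment` with an optional
#' `group` column; `judgment` strictly 0/1.
#'
#' @param path CSV path.
#' @return A validated tibble.
#' @export
read_judgments <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("participant", "test_day", "anchor_id", "probe_id", "judgment")
  if (!all(req %in% names(x))) {
    rlang::abort(paste0("judgment file ", path, " must have columns ",
                        paste(req, collapse = ",")),
                 class = "mentalrep_validation_error")
  }
  if (!all(x$judgment %in% c(0L, 1L))) {
    bad <- which(!(x$judgment %in% c(0L, 1L)))[1]
    rlang::abort(sprintf("%s row %d: judgment must be 0 or 1", path, bad),
                 class = "mentalrep_validation_error")
  }
  x
}

#' Read a putt outcome CSV
#'
#' Columns `participant,group,test_day,block,trial,x_cm,y_cm`; coordinates
#' are signed offsets in cm from the target centre (x lateral, y along the
#' target line).
#'
#' @param path CSV path.
#' @return A validated tibble.
#' @export
read_putts <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("participant", "group", "test_day", "block", "trial",
           "x_cm", "y_cm")
  if (!all(req %in% names(x))) {
    rlang::abort(paste0("putt file ", path, " must have columns ",
                        paste(req, collapse = ",")),
                 class = "mentalrep_validation_error")
  }
  if (!all(is.finite(x$x_cm)) || !all(is.finite(x$y_cm))) {
    rlang::abort(paste(path, "has non-finite coordinates"),
                 class = "mentalrep_validation_error")
  }
  x
}

#' Run the full mental-representation / performance analysis
#'
#' The end-to-end pipeline: per group x test day, per-participant decision
#' matrices are scaled into correlations, Fisher-averaged into a mean-group
#' correlation matrix, mapped to Euclidean distances, clustered by UPGMA and
#' cut at the critical value; the resulting cluster solution is compared to
#' the movement-phase reference (Adjusted Rand Index) and to the group's
#' other test days (invariance lambda). When putt data are supplied,
#' per-participant MRE/BVE summaries, group means with standard errors, and
#' Holm-corrected pairwise contrasts at post-test are added.
#'
#' @param judgments Judgment tibble (see [read_judgments()]).
#' @param putts Optional putt tibble (see [read_putts()]); `NULL` skips the
#'   performance sections.
#' @param catalog Concept catalog, default [bac_catalog()].
#' @param d_crit Critical cut value, default `3.41` (the conventional value
#'   for the 16-concept set at alpha = .05). The string `"midpoint"`
#'   selects the data-driven [d_crit_midpoint()] policy per cell.
#' @param alpha Alpha level for the contrast family, default `.05`.
#' @param average Correlation averaging method, see
#'   [group_mean_correlations()].
#' @return An object of class `sdam_report`: a list with tibbles
#'   `structure` (one row per group x test day with list-columns for the
#'   distance matrix, dendrogram, partition, plus `newick`,
#'   `ari_vs_reference`, `ari_2dp`), `invariance` (lambda + verdict per
#'   within-group day pair), `ari_changes`, and — when putts are given —
#'   `performance`, `group_summary`, `contrasts`; plus `meta`.
#' @export
run_analysis <- function(judgments, putts = NULL, catalog = bac_catalog(),
                         d_crit = 3.41, alpha = 0.05,
                         average = c("fisher", "linear")) {
  average <- match.arg(average)
  catalog <- validate_catalog(catalog)
  ref <- reference_partition(catalog)
  day_levels <- c("pre", "post", "retention")

  scaled <- scale_judgments(judgments, catalog = catalog, average = average)
  structure_tbl <- scaled |>
    dplyr::mutate(
      dendrogram = purrr::map(.data$distances, upgma),
      d_crit = purrr::map_dbl(.data$distances, function(D) {
        if (identical(d_crit, "midpoint")) d_crit_midpoint(D)
        else as.numeric(d_crit)
      }),
      partition = purrr::map2(.data$dendrogram, .data$d_crit, cut_at),
      newick = purrr::map_chr(.data$dendrogram, to_newick),
      ari_vs_reference = purrr::map_dbl(.data$partition,
                                        adjusted_rand_index, q = ref),
      ari_2dp = round_half_away(.data$ari_vs_reference, 2)
    )
  day_idx <- match(structure_tbl$test_day, day_levels)
  if (!anyNA(day_idx)) {
    grp <- if ("group" %in% names(structure_tbl)) {
      as.character(structure_tbl$group)
    } else {
      ""
    }
    structure_tbl <- structure_tbl[order(grp, day_idx), ]
  }

  keys <- intersect("group", names(structure_tbl))
  invariance <- structure_tbl |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(cell, key) {
      if (nrow(cell) < 2L) return(tibble::tibble())
      pairs <- utils::combn(seq_len(nrow(cell)), 2L)
      purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
        a <- pairs[1, i]; b <- pairs[2, i]
        lam <- invariance_lambda(cell$partition[[a]], cell$partition[[b]])
        tibble::tibble(from = as.character(cell$test_day[a]),
                       to = as.character(cell$test_day[b]),
                       lambda = lam$lambda, verdict = lam$verdict)
      })
    }) |>
    dplyr::ungroup()

  ari_changes <- structure_tbl |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(cell, key) {
      if (nrow(cell) < 2L) return(tibble::tibble())
      ari_change_table(stats::setNames(cell$ari_vs_reference,
                                       as.character(cell$test_day)))
    }) |>
    dplyr::ungroup()

  report <- list(structure = structure_tbl, invariance = invariance,
                 ari_changes = ari_changes,
                 meta = list(d_crit = d_crit, alpha = alpha,
                             average = average,
                             n_concepts = nrow(catalog),
                             version = as.character(
                               utils::packageVersion("mentalrep"))))

  if (!is.null(putts)) {
    perf <- summarize_putts(putts, expected_k = NULL)
    report$performance <- perf
    report$group_summary <- group_summary(perf)
    if ("post" %in% perf$test_day &&
        dplyr::n_distinct(perf$group) >= 2L) {
      report$contrasts <- pairwise_group_contrasts(perf, "post",
                                                   alpha = alpha)
    }
  }
  structure(report, class = "sdam_report")
}

#' @export
print.sdam_report <- function(x, ...) {
  cat("SDA-M analysis report\n")
  cat("  structure cells:", nrow(x$structure), "\n")
  st <- x$structure
  keys <- intersect(c("group", "test_day"), names(st))
  for (i in seq_len(nrow(st))) {
    blocks <- nontrivial_blocks(st$partition[[i]])
    cat(sprintf("  %-14s ARI vs reference = %.2f; clusters: %s\n",
                paste(unlist(st[i, keys]), collapse = " "),
                st$ari_2dp[i],
                if (length(blocks) == 0L) "none"
                else paste(vapply(blocks, function(b)
                  paste0("{", paste(b, collapse = ","), "}"),
                  character(1)), collapse = " ")))
  }
  if (!is.null(x$contrasts)) {
    rej <- sum(x$contrasts$reject)
    cat("  post-test contrasts:", nrow(x$contrasts), "tested,",
        rej, "rejected (Holm)\n")
  }
  invisible(x)
}

#' Tidy and glance methods for analysis reports
#'
#' `tidy()` returns the per group x test day structure table (cluster
#' blocks, ARI vs reference, critical value); `glance()` one row of run-level
#' counts.
#'
#' @param x An `sdam_report`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy sdam_report
#' @export
tidy.sdam_report <- function(x, ...) {
  x$structure |>
    dplyr::mutate(clusters = purrr::map(.data$partition, nontrivial_blocks),
                  n_clusters = purrr::map_int(.data$clusters, length)) |>
    dplyr::select(-dplyr::any_of(c("correlations", "mean_correlation",
                                   "distances", "dendrogram", "partition")))
}

#' @rdname tidy.sdam_report
#' @method glance sdam_report
#' @export
glance.sdam_report <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$structure),
    n_participants = sum(x$structure$n_participants),
    n_concepts = x$meta$n_concepts,
    alpha = x$meta$alpha,
    has_performance = !is.null(x$performance)
  )
}

report_payload <- function(report) {
  st <- report$structure
  keys <- intersect(c("group", "test_day"), names(st))
  cells <- purrr::map(seq_len(nrow(st)), function(i) {
    c(as.list(st[i, keys]),
      list(n_participants = st$n_participants[i],
           d_crit = st$d_crit[i],
           newick = st$newick[i],
           partition = st$partition[[i]]$blocks,
           ari_vs_reference = st$ari_vs_reference[i],
           ari_2dp = st$ari_2dp[i]))
  })
  payload <- list(meta = report$meta, structure = cells,
                  invariance = report$invariance,
                  ari_changes = report$ari_changes)
  if (!is.null(report$performance)) {
    payload$group_summary <- report$group_summary
    payload$contrasts <- report$contrasts
  }
  payload
}

#' Write an analysis report to disk
#'
#' Produces `report.json` (full precision, deterministic byte-for-byte for
#' identical inputs) plus CSV side-tables (`performance.csv`,
#' `group_summary.csv`, `contrasts.csv` when present) and one Newick file
#' per structure cell.
#'
#' @param report An `sdam_report` from [run_analysis()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the path of `report.json`.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(report_payload(report), json_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  st <- report$structure
  keys <- intersect(c("group", "test_day"), names(st))
  for (i in seq_len(nrow(st))) {
    stem <- paste(unlist(st[i, keys]), collapse = "_")
    writeLines(st$newick[i], file.path(dir, paste0("dendrogram_", stem,
                                                   ".nwk")))
  }
  if (!is.null(report$performance)) {
    readr::write_csv(report$performance, file.path(dir, "performance.csv"))
    readr::write_csv(report$group_summary,
                     file.path(dir, "group_summary.csv"))
    if (!is.null(report$contrasts)) {
      readr::write_csv(report$contrasts, file.path(dir, "contrasts.csv"))
    }
  }
  invisible(json_path)
}
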