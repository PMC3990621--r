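#' Unweighted average-linkage (UPGMA) clustering of a distance matrix
#'
#' Builds the merge tree used to display a mental representation structure:
#' at every step the two clusters with the smallest average pairwise leaf
#' distance are joined, and the merge height is that average. Ties are broken
#' by the lexicographically smallest pair of cluster indices (clusters
#' indexed by their smallest leaf), so results are identical across
#' platforms. UPGMA heights can never decrease, so the tree has no
#' inversions.
#'
#' @param D Symmetric non-negative distance matrix with zero diagonal.
#' @param labels Leaf labels; defaults to `rownames(D)` or `1..n`.
#' @return An object of class `sdam_dendrogram`: a list with `merge`
#'   (hclust-style n-1 x 2 matrix, negative entries are leaves), `height`
#'   (merge heights), `order` (leaf ordering for plotting), `labels`, and
#'   `n_leaves`.
#' @examples
#' D <- as.matrix(dist(c(0, 0.1, 4, 4.2)))
#' upgma(D)
#' @export
upgma <- function(D, labels = NULL) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n != ncol(D) || any(abs(D - t(D)) > 1e-8) || any(D < 0)) {
    rlang::abort("distance matrix must be symmetric and non-negative",
                 class = "mentalrep_validation_error")
  }
  if (is.null(labels)) {
    labels <- rownames(D)
    if (is.null(labels)) labels <- as.character(seq_len(n))
  }

  # active clusters keyed by smallest leaf id; d holds average leaf-pair
  # distances between active clusters
  d <- D
  diag(d) <- Inf
  active <- seq_len(n)          # column indices still in play
  size <- rep(1L, n)
  node <- -seq_len(n)           # hclust merge code of each active cluster
  min_leaf <- seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    sub <- d[active, active, drop = FALSE]
    best <- min(sub)
    idx <- which(sub <= best + 0, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    # lexicographic tie-break on (smallest-leaf of i, smallest-leaf of j)
    ml <- cbind(min_leaf[active[idx[, 1]]], min_leaf[active[idx[, 2]]])
    pick <- order(pmin(ml[, 1], ml[, 2]), pmax(ml[, 1], ml[, 2]))[1]
    ai <- active[idx[pick, 1]]
    aj <- active[idx[pick, 2]]
    if (min_leaf[aj] < min_leaf[ai]) { tmp <- ai; ai <- aj; aj <- tmp }

    merge[step, ] <- c(node[ai], node[aj])
    height[step] <- d[ai, aj]
    # unweighted average update: weight by leaf counts
    new_d <- (size[ai] * d[ai, ] + size[aj] * d[aj, ]) /
      (size[ai] + size[aj])
    d[ai, ] <- new_d
    d[, ai] <- new_d
    d[ai, ai] <- Inf
    size[ai] <- size[ai] + size[aj]
    node[ai] <- step
    active <- setdiff(active, aj)
  }

  structure(
    list(merge = merge, height = height,
         order = dendrogram_order(merge, n),
         labels = as.character(labels), n_leaves = n),
    class = "sdam_dendrogram"
  )
}

# leaf ordering by depth-first walk of the merge tree (for plotting)
dendrogram_order <- function(merge, n) {
  walk <- function(code) {
    if (code < 0L) return(-code)
    c(walk(merge[code, 1]), walk(merge[code, 2]))
  }
  if (n == 1L) return(1L)
  walk(nrow(merge))
}

#' @export
print.sdam_dendrogram <- function(x, ...) {
  cat("UPGMA dendrogram,", x$n_leaves, "leaves; merge heights",
      sprintf("%.3f", min(x$height)), "to", sprintf("%.3f", max(x$height)),
      "\n")
  invisible(x)
}

#' Convert to a base-R hclust object
#' @param x An `sdam_dendrogram`.
#' @param ... Unused.
#' @return An object of class `hclust`.
#' @export
as.hclust.sdam_dendrogram <- function(x, ...) {
  structure(
    list(merge = x$merge, height = x$height, order = x$order,
         labels = x$labels, method = "average",
         call = match.call(), dist.method = "euclidean"),
    class = "hclust"
  )
}

#' Members of every merge node
#' @param dendro An `sdam_dendrogram`.
#' @return A tibble with one row per merge: `step`, `height`, and the
#'   list-column `members` of leaf indices under that node.
#' @export
merge_members <- function(dendro) {
  n <- dendro$n_leaves
  members <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    take <- function(code) if (code < 0L) -code else members[[code]]
    members[[k]] <- sort(c(take(dendro$merge[k, 1]),
                           take(dendro$merge[k, 2])))
  }
  tibble::tibble(step = seq_len(n - 1L), height = dendro$height,
                 members = members)
}

#' Cut a dendrogram at the critical value
#'
#' Concepts linked strictly below `d_crit` form a cluster; every concept not
#' linked below it stays a singleton. A merge at exactly `d_crit` does not
#' form a cluster (the cut implements "linked below this value"). Raising
#' `d_crit` can only coarsen the partition, never split a block.
#'
#' @param dendro An `sdam_dendrogram`.
#' @param d_crit Positive cut height. The conventional critical value for
#'   the 16-concept putt set at alpha = .05 is `3.41`.
#' @return A `partition` of the leaves.
#' @examples
#' D <- as.matrix(dist(c(0, 0.1, 4, 4.2)))
#' cut_at(upgma(D), d_crit = 1)
#' @export
cut_at <- function(dendro, d_crit = 3.41) {
  if (!inherits(dendro, "sdam_dendrogram")) {
    rlang::abort("dendro must be an sdam_dendrogram",
                 class = "mentalrep_validation_error")
  }
  if (d_crit <= 0) {
    rlang::abort("d_crit must be positive",
                 class = "mentalrep_domain_error")
  }
  n <- dendro$n_leaves
  memb <- seq_len(n)
  cluster_of <- integer(n - 1L)   # membership label of each merge node
  for (k in seq_len(n - 1L)) {
    if (dendro$height[k] < d_crit) {
      lab <- function(code) if (code < 0L) memb[-code] else cluster_of[code]
      a <- lab(dendro$merge[k, 1]); b <- lab(dendro$merge[k, 2])
      memb[memb == b] <- a
      cluster_of[k] <- a
    } else {
      cluster_of[k] <- 0L
    }
  }
  partition_from_membership(memb)
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths follow the ultrametric convention in which a merge at
#' height h places its two children at depth h/2, so a two-leaf tree at
#' height h is written `(A:h/2,B:h/2);` and leaf-to-ancestor path lengths
#' reproduce half the merge heights exactly.
#'
#' @param dendro An `sdam_dendrogram`.
#' @param file Optional path; when given, the string is also written there.
#' @return The Newick string, invisibly when `file` is given.
#' @export
to_newick <- function(dendro, file = NULL) {
  phy <- ape::as.phylo(as.hclust.sdam_dendrogram(dendro))
  txt <- ape::write.tree(phy, digits = 12)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Parse a Newick string back into a dendrogram
#'
#' The inverse of [to_newick()] for ultrametric binary trees: merge heights
#' are recovered as twice the node depths. Topology round-trips exactly and
#' heights to better than 1e-9.
#'
#' @param text Newick string (or a path via `file`).
#' @param file Optional path to read instead of `text`.
#' @return An `sdam_dendrogram`.
#' @export
from_newick <- function(text = NULL, file = NULL) {
  phy <- tryCatch(
    if (is.null(file)) ape::read.tree(text = text) else ape::read.tree(file),
    error = function(e) NULL
  )
  if (is.null(phy) || !inherits(phy, "phylo")) {
    rlang::abort("malformed Newick string",
                 class = "mentalrep_parse_error")
  }
  hc <- tryCatch(ape::as.hclust.phylo(phy), error = function(e) {
    rlang::abort(paste("Newick tree is not an ultrametric binary tree:",
                       conditionMessage(e)),
                 class = "mentalrep_parse_error")
  })
  structure(
    list(merge = hc$merge, height = hc$height, order = hc$order,
         labels = hc$labels, n_leaves = length(hc$labels)),
    class = "sdam_dendrogram"
  )
}

#' Dendrogram plot with the critical-value line
#'
#' Draws the merge tree with leaves on the x axis and Euclidean distance on
#' the y axis, the way mean-group mental representation structures are
#' conventionally displayed: a dashed horizontal line marks `d_crit`, and
#' links above it are read as "not related".
#'
#' @param object An `sdam_dendrogram`.
#' @param d_crit Critical value drawn as a dashed line (`NULL` to omit).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sdam_dendrogram
#' @export
autoplot.sdam_dendrogram <- function(object, d_crit = 3.41, ...) {
  n <- object$n_leaves
  xpos <- numeric(2L * n - 1L)              # leaves 1..n, merges n+1..2n-1
  xpos[object$order] <- seq_len(n)
  xpos <- c(xpos[seq_len(n)], rep(NA_real_, n - 1L))
  ypos <- c(rep(0, n), object$height)
  at <- function(code) if (code < 0L) -code else n + code
  segs <- purrr::map_dfr(seq_len(n - 1L), function(k) {
    a <- at(object$merge[k, 1]); b <- at(object$merge[k, 2])
    xpos[n + k] <<- (xpos[a] + xpos[b]) / 2
    tibble::tibble(
      x    = c(xpos[a], xpos[a], xpos[b]),
      xend = c(xpos[a], xpos[b], xpos[b]),
      y    = c(ypos[a], object$height[k], ypos[b]),
      yend = c(object$height[k], object$height[k], object$height[k])
    )
  })
  p <- ggplot2::ggplot(segs) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend,
                                       yend = .data$yend)) +
    ggplot2::scale_x_continuous(breaks = seq_len(n),
                                labels = object$labels[object$order]) +
    ggplot2::labs(x = NULL, y = "Euclidean distance") +
    ggplot2::theme_minimal()
  if (!is.null(d_crit)) {
    p <- p + ggplot2::geom_hline(yintercept = d_crit, linetype = "dashed")
  }
  p
}

#' Tidy the merge table of a dendrogram
#' @param x An `sdam_dendrogram`.
#' @param ... Unused.
#' @return A tibble with `step`, `height` and the member leaf labels of each
#'   merge node.
#' @method tidy sdam_dendrogram
#' @export
tidy.sdam_dendrogram <- function(x, ...) {
  merge_members(x) |>
    dplyr::mutate(members = purrr::map(.data$members,
                                       function(m) x$labels[m]))
}
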