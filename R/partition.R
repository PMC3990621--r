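#' Construct a flat partition of concept ids
#'
#' A partition is a set of disjoint blocks of integer item ids whose union is
#' `1..n_items`. Items not named in any block become singleton blocks, which
#' is the convention used throughout: a concept that joined no cluster below
#' the critical value stays a cluster of its own.
#'
#' @param blocks List of integer vectors (the non-trivial blocks; may be an
#'   empty list).
#' @param n_items Total number of items.
#' @return An object of class `partition` with elements `blocks` (list of
#'   sorted integer vectors, sorted by smallest member) and `n_items`.
#' @examples
#' new_partition(list(c(2, 3), c(14, 16)), n_items = 16)
#' @export
new_partition <- function(blocks, n_items) {
  n_items <- as.integer(n_items)
  blocks <- lapply(blocks, function(b) sort(as.integer(b)))
  ids <- unlist(blocks)
  if (anyDuplicated(ids) > 0L) {
    rlang::abort("partition blocks must be disjoint",
                 class = "mentalrep_validation_error")
  }
  if (length(ids) > 0L && (min(ids) < 1L || max(ids) > n_items)) {
    rlang::abort("block members must lie in 1..n_items",
                 class = "mentalrep_validation_error")
  }
  singletons <- setdiff(seq_len(n_items), ids)
  blocks <- c(blocks, lapply(singletons, identity))
  blocks <- blocks[order(vapply(blocks, min, integer(1)))]
  structure(list(blocks = blocks, n_items = n_items), class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat("Partition of", x$n_items, "items into", length(x$blocks), "blocks\n")
  for (b in x$blocks) {
    cat(if (length(b) > 1L) "  {" else "  {", paste(b, collapse = ","),
        "}\n", sep = "")
  }
  invisible(x)
}

#' Membership vector of a partition
#'
#' @param partition A `partition` object.
#' @return Integer vector of length `n_items`; entry i is the index of the
#'   block containing item i.
#' @export
partition_membership <- function(partition) {
  stopifnot(inherits(partition, "partition"))
  memb <- integer(partition$n_items)
  for (k in seq_along(partition$blocks)) memb[partition$blocks[[k]]] <- k
  memb
}

#' Convert a membership vector to a partition
#'
#' @param membership Vector of block labels, one per item (items are
#'   `1..length(membership)`).
#' @return A `partition` object.
#' @export
partition_from_membership <- function(membership) {
  blocks <- unname(split(seq_along(membership), membership))
  new_partition(blocks, n_items = length(membership))
}

partitions_same_items <- function(p, q) {
  inherits(p, "partition") && inherits(q, "partition") &&
    p$n_items == q$n_items
}

#' Non-singleton blocks of a partition
#' @param partition A `partition` object.
#' @return List of blocks with at least two members (possibly empty).
#' @export
nontrivial_blocks <- function(partition) {
  Filter(function(b) length(b) > 1L, partition$blocks)
}

#' Write / read a partition as JSON
#'
#' The JSON form is `{"blocks": [[ids...], ...], "n_items": n}` plus any
#' extra scalar fields passed through `...` (e.g. the `d_crit` the cut used).
#'
#' @param partition A `partition` object.
#' @param path File path.
#' @param ... Extra scalar fields stored alongside the blocks.
#' @return `partition_to_json()` returns `path` invisibly;
#'   `partition_from_json()` returns a `partition`.
#' @export
partition_to_json <- function(partition, path, ...) {
  payload <- c(list(blocks = partition$blocks, n_items = partition$n_items),
               list(...))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname partition_to_json
#' @export
partition_from_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  blocks <- payload$blocks
  if (is.matrix(blocks)) blocks <- split(blocks, seq_len(nrow(blocks)))
  if (!is.list(blocks)) blocks <- as.list(blocks)
  new_partition(blocks, n_items = payload$n_items)
}
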