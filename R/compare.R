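#' Hubert-Arabie Adjusted Rand Index between two partitions
#'
#' Chance-corrected agreement between two flat cluster solutions over the
#' same items, computed from the block-overlap contingency table
#' \eqn{n_{ij}}:
#' \deqn{ARI = \frac{\sum_{ij} \binom{n_{ij}}{2} - E}{\tfrac12\left[\sum_i
#'   \binom{a_i}{2} + \sum_j \binom{b_j}{2}\right] - E}, \quad
#'   E = \sum_i \binom{a_i}{2} \sum_j \binom{b_j}{2} / \binom{n}{2}.}
#' ARI is 1 iff the partitions are identical, about 0 for independent random
#' partitions, and can go (slightly) negative for worse-than-chance
#' agreement. Unclustered items enter as singleton blocks, which is exactly
#' how a cut dendrogram's solution is compared against the movement-phase
#' reference.
#'
#' @param p,q `partition` objects over the same item set.
#' @return A single number in `[-1, 1]`.
#' @examples
#' ref <- reference_partition(bac_catalog())
#' post <- new_partition(list(c(2, 3), c(8, 9), c(10, 11, 13), c(14, 16)), 16)
#' round(adjusted_rand_index(post, ref), 2)  # 0.44
#' @export
adjusted_rand_index <- function(p, q) {
  if (!partitions_same_items(p, q)) {
    rlang::abort("partitions must cover the same item set",
                 class = "mentalrep_domain_error")
  }
  n <- p$n_items
  tab <- table(partition_membership(p), partition_membership(q))
  comb2 <- function(x) x * (x - 1) / 2
  index <- sum(comb2(tab))
  a <- sum(comb2(rowSums(tab)))
  b <- sum(comb2(colSums(tab)))
  expected <- a * b / comb2(n)
  max_index <- (a + b) / 2
  if (max_index == expected) return(1)   # both all-singletons or one block
  (index - expected) / (max_index - expected)
}

#' Invariance measure lambda between two cluster solutions
#'
#' Classifies two cluster solutions as invariant (structurally the same) or
#' variant. The similarity is computed over the non-singleton blocks of the
#' two partitions: for blocks \eqn{A_i} and \eqn{B_j},
#' \eqn{\sigma_{ij} = |A_i \cap B_j| / \sqrt{|A_i||B_j|}}, and
#' \deqn{\lambda = \frac{\sum_i \max_j \sigma_{ij} + \sum_j \max_i
#'   \sigma_{ij}}{p + q}}
#' where p and q count the non-singleton blocks. When neither solution has a
#' non-singleton block the solutions are trivially identical (lambda = 1);
#' when exactly one has none, lambda = 0. Solutions with
#' lambda >= 0.68 are classified invariant, below it variant.
#'
#' @param p,q `partition` objects over the same item set.
#' @param threshold Invariance threshold, default `0.68`.
#' @return A list with `lambda` (in `[0, 1]`) and `verdict`
#'   (`"invariant"` or `"variant"`).
#' @examples
#' a <- new_partition(list(c(1, 2), c(3, 4)), 4)
#' b <- new_partition(list(c(1, 3), c(2, 4)), 4)
#' invariance_lambda(a, b)   # lambda = 0.5, variant
#' @export
invariance_lambda <- function(p, q, threshold = 0.68) {
  if (!partitions_same_items(p, q)) {
    rlang::abort("partitions must cover the same item set",
                 class = "mentalrep_domain_error")
  }
  A <- nontrivial_blocks(p)
  B <- nontrivial_blocks(q)
  if (length(A) == 0L || length(B) == 0L) {
    lambda <- if (length(A) == 0L && length(B) == 0L) 1 else 0
  } else {
    sig <- outer(seq_along(A), seq_along(B),
                 Vectorize(function(i, j) {
                   length(intersect(A[[i]], B[[j]])) /
                     sqrt(length(A[[i]]) * length(B[[j]]))
                 }))
    lambda <- (sum(apply(sig, 1, max)) + sum(apply(sig, 2, max))) /
      (length(A) + length(B))
  }
  list(lambda = lambda,
       verdict = if (lambda >= threshold) "invariant" else "variant")
}

#' Changes in adjusted Rand indices across test days
#'
#' Given the per-test-day ARI of a group's mean structure against the
#' reference, tabulates how much the similarity changed from pre- to
#' post-test, pre- to retention-test, and post- to retention-test.
#'
#' @param per_test_aris Named numeric vector or list with entries `pre`,
#'   `post` and `retention` (at least two of them).
#' @param digits Decimal places for the reported change (default 2).
#' @return A tibble with columns `from`, `to`, `change`.
#' @export
ari_change_table <- function(per_test_aris, digits = 2) {
  aris <- unlist(per_test_aris)
  days <- c("pre", "post", "retention")
  have <- days[days %in% names(aris)]
  if (length(have) < 2L) {
    rlang::abort("need ARIs for at least two test days",
                 class = "mentalrep_domain_error")
  }
  pairs <- utils::combn(have, 2L)
  tibble::tibble(
    from = pairs[1, ],
    to = pairs[2, ],
    change = unname(round_half_away(aris[pairs[2, ]] - aris[pairs[1, ]],
                                    digits))
  )
}

# round half away from zero (matches the convention used in printed tables,
# unlike base round()'s round-half-even)
round_half_away <- function(x, digits = 0) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}
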