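test_that("UPGMA merges identical leaves first and at height zero", {
  D <- as.matrix(dist(c(0, 0, 5, 9)))
  den <- upgma(D)
  expect_equal(den$height[1], 0)
  expect_equal(sort(merge_members(den)$members[[1]]), c(1L, 2L))
  # last merge height is the maximum of the sequence (no inversions)
  expect_equal(den$height[length(den$height)], max(den$height))
})

test_that("UPGMA equals the naive exhaustive average-linkage oracle", {
  set.seed(21)
  for (rep in 1:40) {
    n <- sample(4:8, 1)
    pts <- matrix(rnorm(n * 2), n, 2)
    D <- as.matrix(dist(pts))
    den <- upgma(D)
    oracle <- upgma_naive(D)
    expect_equal(den$height, oracle$heights, tolerance = 1e-10)
    expect_equal(merge_members(den)$members, oracle$merges)
  }
})

test_that("UPGMA heights agree with stats::hclust average linkage", {
  set.seed(9)
  D <- as.matrix(dist(matrix(rnorm(20), 10, 2)))
  den <- upgma(D)
  hc <- hclust(as.dist(D), method = "average")
  expect_equal(sort(den$height), sort(hc$height), tolerance = 1e-10)
})

test_that("UPGMA rejects invalid distance matrices", {
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(upgma(bad), class = "mentalrep_validation_error")
  neg <- matrix(c(0, -1, -1, 0), 2, 2)
  expect_error(upgma(neg), class = "mentalrep_validation_error")
})

test_that("the critical-value cut keeps only merges strictly below d_crit", {
  D <- as.matrix(dist(c(0, 0.5, 4, 4.3, 10)))
  den <- upgma(D)
  # cut above everything -> one block
  all_one <- cut_at(den, max(den$height) + 1)
  expect_equal(length(all_one$blocks), 1L)
  # cut at/below the smallest merge -> all singletons (strict inequality)
  singles <- cut_at(den, min(den$height))
  expect_equal(length(singles$blocks), 5L)
  # intermediate cut recovers the two planted pairs
  mid <- cut_at(den, 2)
  expect_equal(Filter(function(b) length(b) > 1, mid$blocks),
               list(c(1L, 2L), c(3L, 4L)))
})

test_that("cutting is monotone in d_crit and always yields a partition", {
  set.seed(33)
  for (rep in 1:20) {
    n <- sample(5:12, 1)
    D <- as.matrix(dist(matrix(rnorm(n * 2), n, 2)))
    den <- upgma(D)
    expect_true(all(diff(den$height) >= -1e-12))   # no inversions
    cuts <- sort(runif(4, 0, max(den$height) * 1.2))
    prev <- NULL
    for (h in cuts) {
      part <- cut_at(den, h)
      ids <- sort(unlist(part$blocks))
      expect_equal(ids, seq_len(n))               # exhaustive and disjoint
      if (!is.null(prev)) {
        # raising d_crit must never split a block: every previous block is
        # contained in some current block
        memb <- partition_membership(part)
        for (b in prev$blocks) {
          expect_equal(length(unique(memb[b])), 1L)
        }
      }
      prev <- part
    }
  }
})

test_that("Newick export follows the (A:h/2,B:h/2) convention", {
  D <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("A", "B"),
                                                   c("A", "B")))
  nw <- to_newick(upgma(D))
  expect_match(nw, "^\\(A:1\\.5,B:1\\.5\\);$")
})

test_that("Newick round-trip preserves topology and heights", {
  set.seed(14)
  D <- as.matrix(dist(matrix(rnorm(32), 16, 2)))
  rownames(D) <- colnames(D) <- paste0("c", 1:16)
  den <- upgma(D)
  back <- from_newick(to_newick(den))
  # heights to 1e-9 and identical member sets at every merge
  expect_equal(sort(back$height), sort(den$height), tolerance = 1e-9)
  canon <- function(d) {
    mm <- merge_members(d)$members
    mm <- lapply(mm, function(m) sort(d$labels[m]))
    mm[order(vapply(mm, paste, character(1), collapse = ","))]
  }
  expect_equal(canon(back), canon(den))
})

test_that("hand-written 3-leaf Newick parses to the known merge list", {
  den <- from_newick("((A:1,B:1):2,C:3);")
  expect_equal(den$n_leaves, 3L)
  expect_equal(sort(den$height), c(2, 6))   # heights are twice node depths
  mm <- merge_members(den)
  first <- sort(den$labels[mm$members[[1]]])
  expect_equal(first, c("A", "B"))
})

test_that("malformed Newick raises a parse error", {
  expect_error(from_newick("((A:1,B:1:2,C;"), class = "mentalrep_parse_error")
})

test_that("dendrogram plot and tidier run on a 16-leaf tree", {
  D <- as.matrix(dist(matrix(rnorm(32), 16, 2)))
  den <- upgma(D)
  p <- ggplot2::autoplot(den, d_crit = 1)
  expect_s3_class(p, "ggplot")
  td <- tidy(den)
  expect_equal(nrow(td), 15L)
})
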