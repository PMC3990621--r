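test_that("decision matrix assembly honours the saturated-design contract", {
  cat16 <- bac_catalog()
  sat <- judgments_from_matrix(matrix(1L, 16, 16))
  D <- assemble_decision_matrix(sat, cat16)
  expect_true(all(D == 1L))
  expect_equal(dim(D), c(16L, 16L))

  miss <- sat[!(sat$anchor_id == 3 & sat$probe_id == 7), ]
  expect_error(assemble_decision_matrix(miss, cat16),
               "\\(3,7\\)", class = "mentalrep_incomplete_data_error")

  dup <- rbind(sat, sat[1, ])
  dup$judgment[nrow(dup)] <- 0L
  expect_error(assemble_decision_matrix(dup, cat16),
               class = "mentalrep_consistency_error")
})

test_that("a hand-written 4-concept judgment set is transcribed exactly", {
  cat4 <- toy_catalog(4)
  # anchor 1 relates to 2 only; anchor 2 to 1 and 3; anchor 3 to 2; anchor 4
  # to nothing
  D_hand <- rbind(c(1L, 1L, 0L, 0L),
                  c(1L, 1L, 1L, 0L),
                  c(0L, 1L, 1L, 0L),
                  c(0L, 0L, 0L, 1L))
  j <- judgments_from_matrix(D_hand)
  expect_equal(unname(assemble_decision_matrix(j, cat4)), D_hand)
})

test_that("pairwise correlations equal brute-force Pearson on restricted rows", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 5L
    D <- matrix(rbinom(n * n, 1L, 0.5), n, n)
    diag(D) <- 1L
    R <- suppressWarnings(pairwise_correlations(D))
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        keep <- setdiff(1:n, c(i, j))
        xi <- D[i, keep]; xj <- D[j, keep]
        expected <- if (sd(xi) == 0 && sd(xj) == 0 && all(xi == xj)) 1
          else if (sd(xi) == 0 || sd(xj) == 0) 0
          else
          sum((xi - mean(xi)) * (xj - mean(xj))) /
            sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
        expect_equal(R[i, j], expected, tolerance = 1e-12)
        expect_equal(R[i, j], R[j, i])
      }
    }
  }
})

test_that("identical and complementary restricted rows give r = +/-1", {
  D <- matrix(0L, 4, 4)
  D[1, ] <- c(1L, 1L, 1L, 0L)
  D[2, ] <- c(1L, 1L, 1L, 0L)   # rows 1,2 identical on shared cols {3,4}
  D[3, ] <- c(1L, 0L, 1L, 0L)
  D[4, ] <- c(0L, 1L, 0L, 1L)   # rows 3,4 complementary on shared cols {1,2}
  R <- suppressWarnings(pairwise_correlations(D))
  expect_equal(R[1, 2], 1)
  expect_equal(R[3, 4], -1)
})

test_that("degenerate profiles split into perfect-agreement and no-signal", {
  # everything judged related: all restricted rows equal constants -> r = 1
  ones <- matrix(1L, 5, 5)
  R1 <- pairwise_correlations(ones)
  expect_true(all(R1[upper.tri(R1)] == 1))
  # one constant row against a varying one: no usable signal -> r = 0 + warn
  D <- rbind(c(1L, 1L, 1L, 1L, 1L),
             c(0L, 1L, 1L, 0L, 1L),
             c(1L, 0L, 1L, 1L, 0L),
             c(0L, 1L, 0L, 1L, 1L),
             c(1L, 0L, 1L, 0L, 1L))
  expect_warning(R <- pairwise_correlations(D), "zero-variance")
  expect_true(all(R[1, 2:5] == 0))
})

test_that("correlation-to-distance scaling matches its closed form", {
  expect_equal(correlation_to_distance(1, 14), 0)
  expect_equal(correlation_to_distance(-1, 14), sqrt(56))
  expect_equal(correlation_to_distance(0, 14), sqrt(28))
  # strictly decreasing in r for fixed m
  rs <- seq(-1, 1, by = 0.05)
  ds <- correlation_to_distance(rs, 14)
  expect_true(all(diff(ds) < 0))
  expect_error(correlation_to_distance(0.5, m = 1),
               class = "mentalrep_domain_error")
  expect_error(correlation_to_distance(1.5, m = 14),
               class = "mentalrep_domain_error")
})

test_that("group mean correlations average on the Fisher-z scale", {
  M <- matrix(c(1, .5, .5, 1), 2, 2)
  # idempotence: mean of identical matrices is the matrix itself
  expect_equal(group_mean_correlations(list(M, M, M)), M)
  # odd symmetry: +r and -r average to zero
  M2 <- matrix(c(1, -.5, -.5, 1), 2, 2)
  expect_equal(group_mean_correlations(list(M, M2))[1, 2], 0)
  # three random matrices against a per-cell scalar z-mean oracle
  set.seed(7)
  mats <- replicate(3, {
    A <- matrix(runif(16, -0.9, 0.9), 4, 4)
    A <- (A + t(A)) / 2; diag(A) <- 1; A
  }, simplify = FALSE)
  got <- group_mean_correlations(mats)
  for (i in 1:3) {
    for (j in (i + 1):4) {
      zbar <- mean(vapply(mats, function(m) atanh(m[i, j]), numeric(1)))
      expect_equal(got[i, j], tanh(zbar), tolerance = 1e-12)
    }
  }
  expect_error(group_mean_correlations(list()),
               class = "mentalrep_domain_error")
})

test_that("distance matrices invert back to correlations (round trip)", {
  set.seed(3)
  R <- matrix(runif(25, -0.8, 0.8), 5, 5)
  R <- (R + t(R)) / 2; diag(R) <- 1
  D <- distances_from_correlations(R, m = 14)
  expect_equal(diag(D), rep(0, 5))
  r_back <- 1 - D^2 / (2 * 14)
  diag(r_back) <- 1
  expect_equal(r_back, R, ignore_attr = TRUE, tolerance = 1e-12)
  # all-zero off-diagonal correlations give the constant distance sqrt(2m)
  D0 <- distances_from_correlations(diag(5), m = 14)
  expect_true(all(abs(D0[upper.tri(D0)] - sqrt(28)) < 1e-12))
})

test_that("scaling is invariant to participant relabeling and probe order", {
  cat8 <- toy_catalog(8)
  cfg <- split_sim_config(planted = new_partition(list(1:4, 5:8), 8),
                          n_participants = 4)
  j <- simulate_split_judgments(cfg, 5)
  base <- scale_judgments(j, cat8, m = 6)
  # permute row order of the long table (probe presentation order)
  jperm <- j[sample.int(nrow(j)), ]
  perm <- scale_judgments(jperm, cat8, m = 6)
  expect_equal(perm$mean_correlation[[1]], base$mean_correlation[[1]])
  # relabel participants
  jrel <- dplyr::mutate(j, participant = paste0("X", participant))
  rel <- scale_judgments(jrel, cat8, m = 6)
  expect_equal(rel$mean_correlation[[1]], base$mean_correlation[[1]])
})
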