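test_that("judgment simulation is a pure function of config and seed", {
  cfg <- split_sim_config(n_participants = 3)
  a <- simulate_split_judgments(cfg, 42)
  b <- simulate_split_judgments(cfg, 42)
  expect_identical(a, b)
  c_ <- simulate_split_judgments(cfg, 43)
  expect_false(identical(a, c_))
  # full design per participant: 16 x 15 ordered pairs
  expect_equal(nrow(a), 3L * 16L * 15L)
  expect_true(all(a$judgment %in% 0:1))
})

test_that("the noiseless limit recovers the planted partition exactly", {
  planted <- reference_partition()
  cfg <- split_sim_config(planted, n_participants = 5,
                          p_within = 1, p_between = 0)
  j <- simulate_split_judgments(cfg, 7)
  sc <- scale_judgments(j)
  den <- upgma(sc$distances[[1]])
  part <- cut_at(den, d_crit_midpoint(sc$distances[[1]]))
  expect_equal(adjusted_rand_index(part, planted), 1)
  # within-planted-cluster distances collapse (up to the Fisher clamp),
  # between-cluster distances stay large
  D <- sc$distances[[1]]
  memb <- partition_membership(planted)
  same <- outer(memb, memb, "==") & upper.tri(D)
  expect_true(all(D[same] < 0.01))
  expect_true(all(D[!same & upper.tri(D)] > 1))
})

test_that("equal within/between probabilities give chance-level recovery", {
  planted <- reference_partition()
  cfg <- split_sim_config(planted, n_participants = 1,
                          p_within = 0.5, p_between = 0.5)
  aris <- vapply(1:200, function(s) {
    j <- simulate_split_judgments(cfg, s)
    sc <- suppressWarnings(scale_judgments(j))
    part <- cut_at(upgma(sc$distances[[1]]), 3.41)
    adjusted_rand_index(part, planted)
  }, numeric(1))
  # null model: mean ARI vs planted ~ 0 over replicates
  expect_lt(abs(mean(aris)), 0.05)
})

test_that("recovery degrades as the within/between separation shrinks", {
  planted <- reference_partition()
  seps <- list(c(.95, .05), c(.75, .25), c(.6, .4))
  means <- vapply(seq_along(seps), function(i) {
    mean(vapply(1:10, function(s) {
      cfg <- split_sim_config(planted, n_participants = 6,
                              p_within = seps[[i]][1],
                              p_between = seps[[i]][2])
      j <- simulate_split_judgments(cfg, 1000 + 31 * i + s)
      sc <- suppressWarnings(scale_judgments(j))
      D <- sc$distances[[1]]
      adjusted_rand_index(cut_at(upgma(D), d_crit_midpoint(D)), planted)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) <= 0.05))   # non-increasing up to noise
  expect_gt(means[1], means[3])
})

test_that("putt simulation is reproducible and shaped by the design", {
  cfg <- putt_sim_config(n_per_group = 2)
  a <- simulate_putts(cfg, 5)
  b <- simulate_putts(cfg, 5)
  expect_identical(a, b)
  expect_equal(nrow(a), 4 * 2 * 3 * 60)
  expect_equal(sort(unique(as.character(a$group))),
               c("CP", "MP", "NP", "PP"))
})

test_that("no learning means statistically flat dispersion across days", {
  cfg <- putt_sim_config(n_per_group = 1,
                         kappa = c(CP = 0, PP = 0, MP = 0, NP = 0),
                         mu0 = c(x = 0, y = 0))
  # with kappa 0 the generator draws pre/post from the same distribution;
  # compare pooled BVEs across many replicates
  bves <- purrr::map_dfr(1:200, function(s) {
    p <- simulate_putts(cfg, s)
    one <- p[p$participant == "CP01" & p$block == 1, ]
    s1 <- one[one$test_day == "pre", ]
    s2 <- one[one$test_day == "post", ]
    tibble::tibble(
      pre = bivariate_variable_error(s1$x_cm, s1$y_cm),
      post = bivariate_variable_error(s2$x_cm, s2$y_cm)
    )
  })
  expect_gt(t.test(bves$pre, bves$post, paired = TRUE)$p.value, 0.01)
})

test_that("faster learners end with smaller post-test dispersion", {
  cfg <- putt_sim_config(n_per_group = 13)
  p <- simulate_putts(cfg, 11)
  s <- summarize_putts(p)
  post <- s[s$test_day == "post", ]
  means <- tapply(post$bve, as.character(post$group), mean)
  expect_lt(means[["CP"]], means[["NP"]])
  expect_lt(means[["PP"]], means[["NP"]])
  # sigma -> 0 limit: both scores collapse to zero
  tiny <- putt_sim_config(n_per_group = 1, sigma0 = 1e-6,
                          sigma_min = 1e-7, mu0 = c(x = 0, y = 0))
  tp <- simulate_putts(tiny, 3)
  ts <- summarize_putts(tp)
  expect_true(all(ts$mre < 1e-5) && all(ts$bve < 1e-5))
})

test_that("the demo cohort has the full four-group design shape", {
  dir <- tempfile("demo")
  out <- make_demo_cohort(3, dir = dir)
  expect_equal(nrow(out$judgments), 4 * 13 * 3 * 16 * 15)
  expect_equal(nrow(out$putts), 4 * 13 * 3 * 60)
  expect_true(file.exists(out$judgments_csv) && file.exists(out$putts_csv))
  # seed change: same shape, different content
  out2 <- make_demo_cohort(4, dir = tempfile("demo"))
  expect_equal(dim(out2$judgments), dim(out$judgments))
  expect_false(identical(out$judgments$judgment, out2$judgments$judgment))
})

test_that("mental-practice groups recover more reference structure than NP", {
  # post-test ARI vs reference averaged over replicate cohorts
  aris <- purrr::map_dfr(1:8, function(s) {
    sched <- demo_split_schedule()
    sched <- sched[sched$test_day == "post", ]
    purrr::pmap_dfr(sched, function(group, test_day, p_within, p_between) {
      cfg <- split_sim_config(n_participants = 13,
                              p_within = p_within, p_between = p_between)
      j <- simulate_split_judgments(cfg, 500 + 7 * s +
                                      match(group, c("CP", "PP", "MP", "NP")))
      sc <- suppressWarnings(scale_judgments(j))
      part <- cut_at(upgma(sc$distances[[1]]), 3.41)
      tibble::tibble(group = group,
                     ari = adjusted_rand_index(part,
                                               reference_partition()))
    })
  })
  m <- tapply(aris$ari, aris$group, mean)
  expect_gt(m[["MP"]], m[["NP"]])
  expect_gt(m[["CP"]], m[["NP"]])
})
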