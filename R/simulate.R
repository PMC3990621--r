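#' Configuration for simulating splitting-task judgments
#'
#' The generator plants a partition in memory: for every ordered
#' (anchor, probe) pair a participant judges "related" with probability
#' `p_within` if the two concepts share a planted block and `p_between`
#' otherwise, independently across pairs and participants. This emulates the
#' splitting task of a cohort whose mental representation carries the
#' planted structure with a controllable amount of judgment noise.
#'
#' @param planted A `partition` giving the structure participants "hold in
#'   memory"; defaults to the movement-phase reference of the putt catalog.
#' @param n_participants Number of participants, default 13 (one group of
#'   the four-group design).
#' @param p_within,p_between Relatedness probabilities for same-block and
#'   cross-block pairs; must satisfy `0 <= p_between <= p_within <= 1`.
#' @param symmetric When `TRUE`, the judgment for (a, b) is copied to
#'   (b, a) instead of drawn independently; the real task presents ordered
#'   pairs, so the default is `FALSE`.
#' @return A list of class `split_sim_config`.
#' @export
split_sim_config <- function(planted = reference_partition(),
                             n_participants = 13L,
                             p_within = 0.9, p_between = 0.1,
                             symmetric = FALSE) {
  if (!(p_between >= 0 && p_within <= 1 && p_between <= p_within)) {
    rlang::abort("need 0 <= p_between <= p_within <= 1",
                 class = "mentalrep_validation_error")
  }
  structure(list(planted = planted,
                 n_participants = as.integer(n_participants),
                 p_within = p_within, p_between = p_between,
                 symmetric = symmetric),
            class = "split_sim_config")
}

#' Simulate splitting-task judgments from a planted partition
#'
#' @param cfg A [split_sim_config()].
#' @param seed Integer seed; the output is a pure function of (cfg, seed).
#' @param test_day Label stored in the `test_day` column (default `"post"`).
#' @param participants Optional participant ids (default `P01`, `P02`, ...).
#' @return A tibble with columns `participant`, `test_day`, `anchor_id`,
#'   `probe_id`, `judgment`.
#' @examples
#' head(simulate_split_judgments(split_sim_config(n_participants = 2), 1))
#' @export
simulate_split_judgments <- function(cfg, seed, test_day = "post",
                                     participants = NULL) {
  stopifnot(inherits(cfg, "split_sim_config"))
  set.seed(seed)
  n <- cfg$planted$n_items
  memb <- partition_membership(cfg$planted)
  if (is.null(participants)) {
    participants <- sprintf("P%02d", seq_len(cfg$n_participants))
  }
  grid <- tidyr::crossing(anchor_id = seq_len(n), probe_id = seq_len(n)) |>
    dplyr::filter(.data$anchor_id != .data$probe_id)
  same <- memb[grid$anchor_id] == memb[grid$probe_id]
  prob <- ifelse(same, cfg$p_within, cfg$p_between)
  out <- purrr::map_dfr(participants, function(pid) {
    j <- stats::rbinom(nrow(grid), 1L, prob)
    dplyr::mutate(grid, participant = pid, judgment = j)
  })
  if (cfg$symmetric) {
    lower <- out$anchor_id > out$probe_id
    key <- function(a, p, id) paste(id, pmin(a, p), pmax(a, p))
    mirror <- out[!lower, ]
    idx <- match(key(out$anchor_id, out$probe_id, out$participant)[lower],
                 key(mirror$anchor_id, mirror$probe_id, mirror$participant))
    out$judgment[lower] <- mirror$judgment[idx]
  }
  dplyr::transmute(out, participant = .data$participant,
                   test_day = test_day,
                   anchor_id = .data$anchor_id, probe_id = .data$probe_id,
                   judgment = as.integer(.data$judgment))
}

#' Configuration for simulating putt outcomes
#'
#' Putt landing positions are bivariate normal around a bias vector, with
#' isotropic per-axis dispersion that decays exponentially with practice:
#' \eqn{\sigma_t = \sigma_{min} + (\sigma_0 - \sigma_{min}) e^{-\kappa t}}
#' and bias \eqn{\mu_t = \mu_0 e^{-\rho t}}, where t counts completed
#' practice days. Group-specific learning rates default to the ordering
#' combined >= physical >= mental >= none, the standard prediction for
#' mental-practice designs.
#'
#' @param groups Group labels, default `c("CP", "PP", "MP", "NP")`.
#' @param n_per_group Participants per group, default 13.
#' @param sigma0 Initial per-axis dispersion in cm (default 35, a realistic
#'   novice putting to a 3 m target).
#' @param sigma_min Dispersion floor in cm (default 12).
#' @param kappa Named learning rates per practice day, one per group.
#' @param mu0 Initial bias vector in cm (default 15 cm overshoot along the
#'   target line).
#' @param bias_decay Named bias-decay rates; defaults to `kappa`.
#' @param practice_days Cumulative practice days at each test day; default
#'   `c(pre = 0, post = 3, retention = 3)` (nothing decays over the
#'   retention interval itself).
#' @param n_blocks,n_trials Blocks per test day and trials per block
#'   (default 3 x 20).
#' @return A list of class `putt_sim_config`.
#' @export
putt_sim_config <- function(groups = c("CP", "PP", "MP", "NP"),
                            n_per_group = 13L,
                            sigma0 = 35, sigma_min = 12,
                            kappa = c(CP = 0.45, PP = 0.40, MP = 0.25,
                                      NP = 0.08),
                            mu0 = c(x = 0, y = 15),
                            bias_decay = kappa,
                            practice_days = c(pre = 0, post = 3,
                                              retention = 3),
                            n_blocks = 3L, n_trials = 20L) {
  if (sigma_min <= 0 || sigma0 < sigma_min) {
    rlang::abort("need sigma0 >= sigma_min > 0",
                 class = "mentalrep_validation_error")
  }
  if (!all(groups %in% names(kappa)) || any(kappa < 0)) {
    rlang::abort("kappa must name every group and be non-negative",
                 class = "mentalrep_validation_error")
  }
  structure(list(groups = groups, n_per_group = as.integer(n_per_group),
                 sigma0 = sigma0, sigma_min = sigma_min, kappa = kappa,
                 mu0 = mu0, bias_decay = bias_decay,
                 practice_days = practice_days,
                 n_blocks = as.integer(n_blocks),
                 n_trials = as.integer(n_trials)),
            class = "putt_sim_config")
}

#' Simulate putt outcome coordinates
#'
#' @param cfg A [putt_sim_config()].
#' @param seed Integer seed; the output is a pure function of (cfg, seed).
#' @return A tibble with columns `participant`, `group`, `test_day`,
#'   `block`, `trial`, `x_cm`, `y_cm`.
#' @export
simulate_putts <- function(cfg, seed) {
  stopifnot(inherits(cfg, "putt_sim_config"))
  set.seed(seed)
  days <- names(cfg$practice_days)
  design <- tidyr::crossing(
    group = factor(cfg$groups, levels = cfg$groups),
    subject = seq_len(cfg$n_per_group),
    test_day = factor(days, levels = days),
    block = seq_len(cfg$n_blocks),
    trial = seq_len(cfg$n_trials)
  )
  t_practice <- cfg$practice_days[as.character(design$test_day)]
  kap <- cfg$kappa[as.character(design$group)]
  rho <- cfg$bias_decay[as.character(design$group)]
  sigma <- cfg$sigma_min + (cfg$sigma0 - cfg$sigma_min) *
    exp(-kap * t_practice)
  decay <- exp(-rho * t_practice)
  design |>
    dplyr::mutate(
      participant = sprintf("%s%02d", .data$group, .data$subject),
      x_cm = stats::rnorm(dplyr::n(), cfg$mu0[["x"]] * decay, sigma),
      y_cm = stats::rnorm(dplyr::n(), cfg$mu0[["y"]] * decay, sigma)
    ) |>
    dplyr::select(dplyr::all_of(c("participant", "group", "test_day",
                                  "block", "trial", "x_cm", "y_cm")))
}

# per-group relatedness schedule of the demo cohort: structure emerges with
# practice, most for the groups that practice mentally; pre-test is
# unstructured for everyone
demo_split_schedule <- function() {
  tibble::tribble(
    ~group, ~test_day,   ~p_within, ~p_between,
    "CP",   "pre",       0.15,      0.15,
    "CP",   "post",      0.80,      0.10,
    "CP",   "retention", 0.85,      0.10,
    "PP",   "pre",       0.15,      0.15,
    "PP",   "post",      0.40,      0.12,
    "PP",   "retention", 0.50,      0.12,
    "MP",   "pre",       0.15,      0.15,
    "MP",   "post",      0.80,      0.10,
    "MP",   "retention", 0.80,      0.10,
    "NP",   "pre",       0.15,      0.15,
    "NP",   "post",      0.25,      0.12,
    "NP",   "retention", 0.30,      0.12
  )
}

#' Generate a complete demo cohort on disk
#'
#' Emulates the four-group pre/post/retention design: 4 groups x 13
#' participants, each contributing a full splitting task (16 x 15 ordered
#' judgments) and 3 blocks x 20 putts per test day. Judgment structure
#' emerges over the study at group-specific rates (most for the groups that
#' practice mentally), and putt dispersion shrinks at group-specific
#' learning rates.
#'
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @param split_schedule Per group x test day relatedness probabilities; the
#'   default is [demo_split_schedule()].
#' @param putt_cfg A [putt_sim_config()].
#' @param planted Planted partition for the structured cells; default the
#'   phase reference.
#' @return Invisibly, a list with the two tibbles (`judgments`, `putts`)
#'   and the file paths (`judgments_csv`, `putts_csv`).
#' @export
make_demo_cohort <- function(seed, dir = tempfile("cohort"),
                             split_schedule = demo_split_schedule(),
                             putt_cfg = putt_sim_config(),
                             planted = reference_partition()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  judgments <- purrr::pmap_dfr(
    split_schedule,
    function(group, test_day, p_within, p_between) {
      cell_seed <- (seed * 97L +
                      match(group, c("CP", "PP", "MP", "NP")) * 13L +
                      match(test_day, c("pre", "post", "retention"))) %%
        .Machine$integer.max
      cfg <- split_sim_config(planted = planted,
                              n_participants = 13L,
                              p_within = p_within, p_between = p_between)
      simulate_split_judgments(cfg, seed = cell_seed, test_day = test_day,
                               participants = sprintf("%s%02d", group,
                                                      1:13)) |>
        dplyr::mutate(group = group, .after = "participant")
    }
  )
  putts <- simulate_putts(putt_cfg, seed = (seed * 101L + 7L) %%
                            .Machine$integer.max)
  judgments_csv <- file.path(dir, "judgments.csv")
  putts_csv <- file.path(dir, "putts.csv")
  readr::write_csv(judgments, judgments_csv)
  readr::write_csv(putts, putts_csv)
  invisible(list(judgments = judgments, putts = putts,
                 judgments_csv = judgments_csv, putts_csv = putts_csv))
}

#' Data-driven critical value for synthetic cohorts
#'
#' The conventional critical value 3.41 is calibrated to the original
#' instrument; for synthetic cohorts the natural cut lies between the two
#' modes of the bimodal within/between distance distribution. The
#' off-diagonal distances are split into two classes by the exact 1-D
#' two-means partition (the split of the sorted values minimising the
#' within-class sum of squares), and the cut is the midpoint of the two
#' class means. Deterministic, and independent of any planted labels.
#'
#' @param D Distance matrix.
#' @return A single cut height.
#' @export
d_crit_midpoint <- function(D) {
  v <- sort(D[upper.tri(D)])
  n <- length(v)
  if (n < 2L || max(v) == min(v)) return(max(v))
  css <- function(x) sum((x - mean(x))^2)
  ss <- vapply(seq_len(n - 1L),
               function(k) css(v[1:k]) + css(v[(k + 1):n]),
               numeric(1))
  k <- which.min(ss)
  (mean(v[1:k]) + mean(v[(k + 1):n])) / 2
}
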