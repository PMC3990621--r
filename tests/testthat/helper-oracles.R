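# Independent brute-force oracles, deliberately naive and kept separate from
# the implementation paths they check.

# ARI by exhaustive pair counting over all C(n,2) item pairs
ari_pair_counting <- function(p, q) {
  mp <- partition_membership(p)
  mq <- partition_membership(q)
  n <- length(mp)
  a <- b <- c_ <- d <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sp <- mp[i] == mp[j]
      sq <- mq[i] == mq[j]
      if (sp && sq) a <- a + 1
      else if (sp && !sq) b <- b + 1
      else if (!sp && sq) c_ <- c_ + 1
      else d <- d + 1
    }
  }
  tot <- a + b + c_ + d
  expected <- (a + b) * (a + c_) / tot
  max_index <- ((a + b) + (a + c_)) / 2
  if (max_index == expected) return(1)
  (a - expected) / (max_index - expected)
}

# average linkage by exhaustive bookkeeping: clusters as explicit leaf sets,
# inter-cluster distance recomputed from the original matrix each step
upgma_naive <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  merges <- list()
  while (length(clusters) > 1L) {
    best <- Inf
    bi <- bj <- NA
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        dij <- mean(D[clusters[[i]], clusters[[j]]])
        key_new <- c(min(clusters[[i]]), min(clusters[[j]]))
        if (dij < best - 1e-12) {
          best <- dij; bi <- i; bj <- j
        } else if (abs(dij - best) <= 1e-12 && !is.na(bi)) {
          key_old <- sort(c(min(clusters[[bi]]), min(clusters[[bj]])))
          key_new <- sort(key_new)
          if (key_new[1] < key_old[1] ||
              (key_new[1] == key_old[1] && key_new[2] < key_old[2])) {
            bi <- i; bj <- j
          }
        }
      }
    }
    merges <- c(merges, list(sort(c(clusters[[bi]], clusters[[bj]]))))
    heights <- c(heights, best)
    clusters[[bi]] <- sort(c(clusters[[bi]], clusters[[bj]]))
    clusters[[bj]] <- NULL
  }
  list(heights = heights, merges = merges)
}

# Holm rejections by testing every prefix of the sorted p-values
holm_prefix_oracle <- function(p, alpha) {
  m <- length(p)
  ps <- sort(p)
  best <- 0L
  for (k in seq_len(m)) {
    ok <- all(ps[seq_len(k)] <= alpha / (m - seq_len(k) + 1L))
    if (ok) best <- k else break
  }
  rejected_sorted <- seq_len(m) <= best
  rejected_sorted
}

random_partition <- function(n, max_blocks = n) {
  memb <- sample.int(sample.int(max_blocks, 1), n, replace = TRUE)
  partition_from_membership(memb)
}

# complete saturated-design judgment tibble from a decision matrix
judgments_from_matrix <- function(D, participant = "P1", test_day = "pre") {
  n <- nrow(D)
  grid <- expand.grid(anchor_id = seq_len(n), probe_id = seq_len(n))
  grid <- grid[grid$anchor_id != grid$probe_id, ]
  tibble::tibble(
    participant = participant, test_day = test_day,
    anchor_id = grid$anchor_id, probe_id = grid$probe_id,
    judgment = D[cbind(grid$anchor_id, grid$probe_id)]
  )
}

toy_catalog <- function(n, phases = NULL) {
  tibble::tibble(
    id = seq_len(n),
    label = paste0("concept ", seq_len(n)),
    phase = if (is.null(phases)) rep("preparation", n) else phases
  )
}
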