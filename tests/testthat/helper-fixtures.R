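# Shared fixtures and independent oracles used across the suite.

tiny_config <- function(...) {
  args <- list(n_subjects = 4, n_frames = 120, n_rois = 32)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(cohort_config, args)
}

make_seq <- function(states, tr = 1, gaps = NULL) {
  gap_after <- rep(FALSE, length(states))
  if (!is.null(gaps)) gap_after[gaps] <- TRUE
  state_sequence(states, tr_seconds = tr, gap_after = gap_after)
}

# --- naive counting oracles for the dynamic metrics --------------------------

naive_runs <- function(states, gap_after) {
  runs <- list()
  cur <- states[1]
  len <- 1
  for (t in seq_along(states)[-1]) {
    if (states[t] == cur && !gap_after[t - 1]) {
      len <- len + 1
    } else {
      runs[[length(runs) + 1]] <- c(cur, len)
      cur <- states[t]
      len <- 1
    }
  }
  runs[[length(runs) + 1]] <- c(cur, len)
  do.call(rbind, runs)
}

naive_fo <- function(states, k) {
  vapply(seq_len(k), function(s) sum(states == s), numeric(1)) / length(states)
}

naive_dwell <- function(states, gap_after, k, tr) {
  runs <- naive_runs(states, gap_after)
  vapply(seq_len(k), function(s) {
    len <- runs[runs[, 1] == s, 2]
    if (length(len) == 0) 0 else mean(len) * tr
  }, numeric(1))
}

naive_rate <- function(states, gap_after, k, tr) {
  runs <- naive_runs(states, gap_after)
  vapply(seq_len(k), function(s) sum(runs[, 1] == s), numeric(1)) /
    (length(states) * tr / 60)
}

naive_transition <- function(states, gap_after, k) {
  counts <- matrix(0, k, k)
  for (t in seq_len(length(states) - 1)) {
    if (!gap_after[t]) {
      counts[states[t], states[t + 1]] <- counts[states[t], states[t + 1]] + 1
    }
  }
  P <- counts
  for (i in seq_len(k)) {
    if (sum(counts[i, ]) > 0) P[i, ] <- counts[i, ] / sum(counts[i, ])
  }
  P
}

# --- brute-force correlation k-means for tiny problems -----------------------

corr_dist <- function(x, y) 1 - stats::cor(x, y)

brute_force_kmeans2 <- function(X) {
  n <- nrow(X)
  best <- NULL
  for (code in 0:(2^n - 1)) {
    lab <- as.integer(intToBits(code))[1:n] + 1L
    if (length(unique(lab)) < 2) next
    total <- 0
    for (g in 1:2) {
      member <- X[lab == g, , drop = FALSE]
      member_std <- t(apply(member, 1, function(r) {
        rc <- r - mean(r)
        rc / sqrt(sum(rc^2))
      }))
      cent <- colMeans(member_std)
      cent <- cent - mean(cent)
      total <- total + sum(apply(member, 1, corr_dist, y = cent))
    }
    if (is.null(best) || total < best$total) {
      best <- list(labels = lab, total = total)
    }
  }
  best
}

# Tidy per-scan metrics straight from a cohort's ground-truth sequences,
# shaped like dynamic_metrics() output (for inference-stage simulations).
truth_metrics_tidy <- function(cohort) {
  out <- tidyr::pivot_longer(cohort$truth$metrics,
                             c("fractional_occupancy", "dwell_time"),
                             names_to = "metric", values_to = "value")
  out$state_name <- out$state
  out$state <- match(out$state_name, rownames(cohort$centroids))
  out
}

expect_same_partition <- function(a, b) {
  expect_equal(length(a), length(b))
  expect_equal(adjusted_mutual_information(a, b), 1, tolerance = 1e-10)
}

strip_tm <- function(m) {
  attr(m, "undefined_rows") <- NULL
  unname(m)
}
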