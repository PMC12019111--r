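make_metrics_pair <- function(n = 10, k = 3, seed = 1, delta = 0) {
  set.seed(seed)
  ids <- sprintf("S%02d", 1:n)
  base <- expand.grid(subject = ids, state = 1:k,
                      metric = c("fractional_occupancy", "dwell_time"),
                      stringsAsFactors = FALSE)
  pl <- mp <- base
  pl$condition <- "PL"; mp$condition <- "MP"
  pl$value <- rnorm(nrow(pl), 10, 2)
  mp$value <- pl$value + rnorm(nrow(pl), delta, 1)
  out <- tibble::as_tibble(rbind(pl, mp))
  out$state_name <- paste0("St", out$state)
  out
}

test_that("identical conditions yield null paired contrasts", {
  md <- make_metrics_pair(8)
  md$value[md$condition == "MP"] <- md$value[md$condition == "PL"]
  ct <- paired_contrast(md)
  expect_true(all(ct$t_statistic == 0))
  expect_true(all(ct$p_value == 1))
  expect_false(any(ct$significant_bh))
})

test_that("zero-variance nonzero-mean differences are flagged, not NaN", {
  md <- make_metrics_pair(6, k = 1)
  md$value[md$condition == "MP"] <- md$value[md$condition == "PL"] + 1
  expect_warning(ct <- paired_contrast(md), "zero-variance")
  expect_true(all(ct$p_value == 0))
})

test_that("paired t equals the textbook one-sample t on differences", {
  md <- make_metrics_pair(12, seed = 3, delta = 0.8)
  ct <- paired_contrast(md)
  wide <- tidyr::pivot_wider(md[, c("subject", "condition", "state",
                                    "metric", "value")],
                             names_from = "condition", values_from = "value")
  for (i in seq_len(nrow(ct))) {
    d <- wide$MP[wide$state == ct$state[i] & wide$metric == ct$metric[i]] -
      wide$PL[wide$state == ct$state[i] & wide$metric == ct$metric[i]]
    n <- length(d)
    t_oracle <- mean(d) / (sd(d) / sqrt(n))
    p_oracle <- 2 * stats::pt(-abs(t_oracle), n - 1)
    expect_equal(ct$t_statistic[i], t_oracle, tolerance = 1e-10)
    expect_equal(ct$p_value[i], p_oracle, tolerance = 1e-10)
  }
})

test_that("subjects missing a condition are reported by name", {
  md <- make_metrics_pair(6)
  md <- md[!(md$subject == "S03" & md$condition == "MP"), ]
  expect_error(paired_contrast(md), "S03")
})

test_that("BH correction reproduces the hand-computed step-up", {
  out <- bh_correct(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(out$p_adjusted, rep(0.04, 4))
  expect_true(all(out$significant))
  expect_equal(bh_correct(0.03)$p_adjusted, 0.03)
  expect_false(any(bh_correct(rep(1, 5))$significant))
  expect_error(bh_correct(c(0.5, 1.2)), "\\[0, 1\\]")
  # independent step-up oracle on random p-values + monotonicity
  set.seed(9)
  p <- runif(20)
  m <- length(p)
  ord <- order(p)
  stepup <- numeric(m)
  stepup[ord] <- rev(cummin(rev(m * p[ord] / seq_len(m))))
  stepup <- pmin(stepup, 1)
  expect_equal(bh_correct(p)$p_adjusted, stepup, tolerance = 1e-12)
  expect_true(all(diff(bh_correct(p)$p_adjusted[ord]) >= -1e-15))
  expect_true(all(bh_correct(p)$p_adjusted >= p))
})

test_that("pearson_with_p matches cor.test", {
  expect_equal(pearson_with_p(1:10, 2 * (1:10))$estimate, 1)
  expect_equal(pearson_with_p(1:10, -(1:10))$estimate, -1)
  set.seed(12)
  x <- rnorm(20); y <- 0.4 * x + rnorm(20)
  got <- pearson_with_p(x, y)
  ref <- stats::cor.test(x, y)
  expect_equal(got$estimate, unname(ref$estimate), tolerance = 1e-10)
  expect_equal(got$p.value, ref$p.value, tolerance = 1e-10)
  expect_error(pearson_with_p(rep(1, 5), 1:5), "constant")
})

test_that("covariate adjustment behaves as a partial correlation", {
  set.seed(14)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  z_orth <- stats::residuals(stats::lm(rnorm(30) ~ x + y))
  raw <- pearson_with_p(x, y)
  adj <- adjust_for_covariate(x, y, z_orth)
  expect_equal(adj$estimate, raw$estimate, tolerance = 1e-10)
  # y equal to the covariate is fully explained away
  adj2 <- adjust_for_covariate(x, y, y)
  expect_lt(abs(adj2$estimate), 1e-8)
  expect_warning(adj3 <- adjust_for_covariate(x, y, rep(2, 30)), "constant")
  expect_equal(adj3$estimate, raw$estimate)
  # planted confound: adjustment shrinks the correlation on average
  shrink <- replicate(100, {
    cv <- rnorm(25)
    xx <- cv + rnorm(25, sd = 0.5)
    yy <- cv + rnorm(25, sd = 0.5)
    abs(pearson_with_p(xx, yy)$estimate) -
      abs(adjust_for_covariate(xx, yy, cv)$estimate)
  })
  expect_gt(mean(shrink), 0)
})

test_that("ROI correlation tables have full layout and planted signs", {
  cfg <- cohort_config(n_subjects = 30, n_frames = 260)
  coh <- generate_cohort(cfg, timeseries = FALSE)
  deltas <- tibble::tibble(subject = coh$subjects$subject,
                           metric = "dwell_time", state_name = "FPN+",
                           delta = unname(coh$truth$ddwell_fpn))
  tab <- roi_correlation_table(deltas, coh$d1r_roi)
  expect_equal(nrow(tab), ncol(coh$d1r_roi))
  expect_gt(mean(tab$r > 0), 0.9)  # planted positive coupling
  expect_true(all(tab$n == 30))
  # missing subjects are dropped pairwise with the count reported
  deltas2 <- deltas[-(1:5), ]
  tab2 <- roi_correlation_table(deltas2, coh$d1r_roi)
  expect_true(all(tab2$n == 25))
})

test_that("26-connectivity component labelling joins corner neighbours", {
  m <- array(FALSE, c(4, 4, 4))
  m[1, 1, 1] <- TRUE; m[2, 2, 2] <- TRUE  # corner-adjacent
  lab <- label_components(m, 26)
  expect_equal(lab[1, 1, 1], lab[2, 2, 2])
  lab6 <- label_components(m, 6)
  expect_true(lab6[1, 1, 1] != lab6[2, 2, 2])
})

test_that("cluster-extent filtering keeps a 64-voxel block and drops 27", {
  dims <- c(10, 10, 10)
  n <- 24
  set.seed(33)
  target <- rnorm(n)
  backdrop <- array(rnorm(prod(dims)), dims)  # identical across subjects
  build_maps <- function(block_idx) {
    lapply(seq_len(n), function(i) {
      m <- backdrop
      m[block_idx] <- target[i] + rnorm(length(block_idx[, 1]), sd = 0.05)
      m
    })
  }
  block64 <- as.matrix(expand.grid(3:6, 3:6, 3:6))
  res <- voxelwise_correlation_clusters(build_maps(block64), target)
  expect_equal(nrow(res$clusters), 1)
  expect_equal(res$clusters$n_voxels, 64)
  expect_setequal(which(res$cluster_map > 0),
                  block64[, 1] + (block64[, 2] - 1) * 10 +
                    (block64[, 3] - 1) * 100)
  block27 <- as.matrix(expand.grid(3:5, 3:5, 3:5))
  res27 <- voxelwise_correlation_clusters(build_maps(block27), target)
  expect_equal(nrow(res27$clusters), 0)
  expect_true(all(res27$cluster_map == 0))
})

test_that("voxelwise false-positive rate sits near the nominal level", {
  set.seed(44)
  dims <- c(10, 10, 5)
  n <- 30
  target <- rnorm(n)
  maps <- lapply(seq_len(n), function(i) array(rnorm(prod(dims)), dims))
  res <- voxelwise_correlation_clusters(maps, target)
  fp <- mean(res$p_map < 0.05)
  expect_lt(abs(fp - 0.05), 3 * sqrt(0.05 * 0.95 / prod(dims)))
  # all-zero maps: no clusters, no error
  zero <- lapply(seq_len(n), function(i) array(0, dims))
  res0 <- voxelwise_correlation_clusters(zero, target)
  expect_equal(nrow(res0$clusters), 0)
})

test_that("metric_deltas extracts the five canonical change scores", {
  cfg <- tiny_config()
  coh <- generate_cohort(cfg)
  post <- lapply(coh$scans, postprocess)
  cc <- concatenate_scans(post)
  fit <- cluster_states(cc$data, cfg$k_true, coh$templates, n_restarts = 4,
                        n_replicates = 2, seed = 3, scan_index = cc$scan_index)
  md <- dynamic_metrics(fit, cfg$tr_seconds)
  dl <- metric_deltas(md)
  expect_setequal(unique(paste(dl$metric, dl$state_name)),
                  c("dwell_time FPN+", "fractional_occupancy FPN+",
                    "dwell_time VIS-", "fractional_occupancy VIS-",
                    "fractional_occupancy SOM+"))
  expect_equal(nrow(dl), 5 * cfg$n_subjects)
})
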