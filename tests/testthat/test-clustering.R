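test_that("concatenation stacks kept frames and round-trips the index", {
  cfg <- tiny_config()
  tp <- generate_network_templates(cfg$n_rois)
  ce <- generate_centroids(tp, cfg$k_true)
  mk <- function(seed, censor = NULL, id = "S01", cond = "PL") {
    s <- simulate_state_sequence(1, cond, cfg, seed)
    ts <- simulate_roi_timeseries(s, ce, cfg, seed + 1, id, cond)
    if (!is.null(censor)) ts$censor_mask <- censor
    ts
  }
  full <- list(a = mk(1), b = mk(2, id = "S02"))
  cc <- concatenate_scans(full)
  expect_equal(nrow(cc$data), 2 * cfg$n_frames)

  censor <- rep(TRUE, cfg$n_frames); censor[11:30] <- FALSE
  part <- list(a = mk(1, censor), b = mk(2, id = "S02"))
  cc2 <- concatenate_scans(part)
  expect_equal(nrow(cc2$data), 2 * cfg$n_frames - 20)
  expect_false(any(cc2$scan_index$frame[cc2$scan_index$scan == "a"] %in% 11:30))
  # round trip: splitting by scan_index reproduces each scan's kept frames
  for (sid in c("a", "b")) {
    rows <- cc2$scan_index$row[cc2$scan_index$scan == sid]
    frames <- cc2$scan_index$frame[cc2$scan_index$scan == sid]
    expect_equal(cc2$data[rows, ], part[[sid]]$data[frames, ],
                 ignore_attr = TRUE)
  }
  bad <- list(a = mk(1), b = mk(2))
  bad$b$data <- bad$b$data[, 1:10]
  expect_error(concatenate_scans(bad), "mixed ROI")
})

test_that("k-means recovers a perfectly separable +/- pattern exactly", {
  set.seed(5)
  p1 <- rnorm(40); p1 <- p1 - mean(p1)
  p2 <- rnorm(40); p2 <- p2 - mean(p2)
  p2 <- p2 - p1 * sum(p1 * p2) / sum(p1^2)  # orthogonal patterns
  X <- rbind(p1, p1, -p1, p2, p2, -p2, p1, -p2)
  truth <- c(1, 1, 1, 2, 2, 2, 1, 2)  # sign-flips stay maximally anticorrelated
  fit <- kmeans_correlation(X, 2, n_restarts = 10, seed = 3)
  # up to sign, the partition separates the two patterns
  part <- fit$labels
  expect_true(length(unique(part[truth == 1])) <= 2)
  # with pure +1 copies only, recovery is exact and EV = 1
  X2 <- rbind(p1, p1, p1, p2, p2, p2)
  fit2 <- kmeans_correlation(X2, 2, n_restarts = 10, seed = 3)
  expect_equal(fit2$explained_variance, 1, tolerance = 1e-12)
  expect_equal(fit2$inertia, 0, tolerance = 1e-12)
  expect_same_partition(fit2$labels, c(1, 1, 1, 2, 2, 2))
})

test_that("correlation distance attains its 0 and 2 extremes", {
  set.seed(8)
  x <- rnorm(20)
  fit <- kmeans_correlation(rbind(x, x, -x, -x), 2, n_restarts = 5, seed = 2)
  expect_equal(fit$inertia, 0, tolerance = 1e-12)  # d(x, x) = 0
  # the two centroids are exact negations: d(x, -x) = 2
  cs <- fit$centroids / sqrt(rowSums(fit$centroids^2))
  expect_equal(1 - sum(cs[1, ] * cs[2, ]), 2, tolerance = 1e-10)
})

test_that("a 6-frame toy matches the exhaustive-search optimum", {
  set.seed(17)
  a <- c(1, -1, 2, -2); b <- c(-1.5, 2, -1, 0.5)
  X <- rbind(a, a, a, b, b, b) + matrix(rnorm(24, sd = 0.05), 6, 4)
  fit <- kmeans_correlation(X, 2, n_restarts = 20, seed = 4)
  brute <- brute_force_kmeans2(X)
  expect_same_partition(fit$labels, brute$labels)
  expect_equal(fit$inertia, brute$total, tolerance = 1e-8)
})

test_that("explained variance is bounded, saturates on planted data, and elbows", {
  set.seed(23)
  pats <- matrix(rnorm(4 * 30), 4, 30)
  X <- pats[rep(1:4, each = 12), ]
  curve <- explained_variance_curve(X, 2, 6, n_restarts = 10, seed = 9)
  expect_true(all(curve$explained_variance >= 0 &
                    curve$explained_variance <= 1))
  expect_equal(curve$explained_variance[curve$k == 4], 1, tolerance = 1e-10)
  run_max <- cummax(curve$explained_variance)
  expect_true(all(curve$explained_variance >= run_max - 1e-8))
  expect_equal(select_k_elbow(curve), 4L, ignore_attr = TRUE)
})

test_that("elbow selection follows the sub-threshold-gain rule", {
  curve <- tibble::tibble(k = 3:7,
                          explained_variance = c(.80, .90, .95, .955, .957))
  expect_equal(select_k_elbow(curve), 5L)
  steep <- tibble::tibble(k = 3:6,
                          explained_variance = c(.1, .3, .5, .7))
  expect_warning(k_sel <- select_k_elbow(steep), "k_max")
  expect_equal(as.integer(k_sel), 6L)
  expect_true(attr(k_sel, "elbow_fallback"))
})

test_that("AMI matches its reference values and statistical properties", {
  a <- c(1, 1, 2, 2, 3, 3, 1, 2, 3, 1)
  b <- c(2, 2, 3, 3, 1, 1, 1, 3, 1, 2)
  cc <- c(1, 2, 1, 2, 1, 2, 1, 2, 1, 2)
  # frozen reference values (scikit-learn adjusted_mutual_info_score)
  expect_equal(adjusted_mutual_information(a, b), 0.7172912023015783,
               tolerance = 1e-10)
  expect_equal(adjusted_mutual_information(a, cc), -0.13474704154572212,
               tolerance = 1e-10)
  expect_equal(adjusted_mutual_information(c(1, 1, 1, 2, 2, 3),
                                           c(1, 1, 2, 2, 3, 3)),
               0.08372678378671243, tolerance = 1e-10)
  # identity, permutation invariance, symmetry
  expect_equal(adjusted_mutual_information(a, a), 1)
  perm <- c(3, 1, 2)[a]
  expect_equal(adjusted_mutual_information(a, perm), 1)
  expect_equal(adjusted_mutual_information(a, b),
               adjusted_mutual_information(b, a))
  # chance level for independent labelings
  set.seed(77)
  p1 <- sample.int(4, 1000, replace = TRUE)
  p2 <- sample.int(4, 1000, replace = TRUE)
  expect_lt(abs(adjusted_mutual_information(p1, p2)), 0.05)
  expect_error(adjusted_mutual_information(1:5, 1:4), "length")
})

test_that("replicate selection maximizes cumulative AMI with stable ties", {
  set.seed(13)
  X <- matrix(rnorm(60 * 12), 60, 12)
  f1 <- kmeans_correlation(X, 3, n_restarts = 5, seed = 1)
  f_rand <- f1
  f_rand$labels <- sample.int(3, 60, replace = TRUE)
  picked <- select_partition_ami(list(f1, f1, f_rand))
  expect_same_partition(picked$labels, f1$labels)
  # all identical: the first replicate wins the tie
  picked2 <- select_partition_ami(list(f1, f1, f1))
  expect_equal(attr(picked2, "replicate"), 1L)
  # definition re-check: picked cumulative AMI is maximal
  f2 <- kmeans_correlation(X, 3, n_restarts = 5, seed = 2)
  f3 <- kmeans_correlation(X, 3, n_restarts = 5, seed = 3)
  reps <- list(f1, f2, f3, f_rand)
  picked3 <- select_partition_ami(reps)
  cums <- attr(picked3, "ami_total")
  expect_gte(max(cums) + 1e-12, cums[attr(picked3, "replicate")])
  expect_equal(cums[attr(picked3, "replicate")], max(cums))
  f_badk <- kmeans_correlation(X, 4, n_restarts = 2, seed = 1)
  expect_error(select_partition_ami(list(f1, f_badk)), "mismatched k")
})

test_that("state naming follows the dominant signed network part", {
  tp <- generate_network_templates(64)
  fpn <- as.numeric(tp$network == "FPN")
  vis <- as.numeric(tp$network == "VIS")
  cat1 <- name_states(rbind(fpn, -vis), tp)
  expect_equal(cat1$names, c("FPN+", "VIS-"))
  # negation flips the sign suffix
  set.seed(41)
  for (i in 1:10) {
    cvec <- rnorm(64)
    nm <- name_states(rbind(cvec, -cvec), tp)$names
    flip <- function(x) chartr("+-", "-+", x)
    expect_equal(nm[2], flip(nm[1]))
  }
  expect_error(name_states(rbind(rep(0, 64)), tp), "all-zero")
})

test_that("the centroid dendrogram splits association from sensorimotor states", {
  tp <- generate_network_templates(232)
  ce <- generate_centroids(tp, 6)
  dg <- centroid_dendrogram(ce)
  g_fpn <- dg$groups[["FPN+"]]
  expect_setequal(names(dg$groups)[dg$groups == g_fpn],
                  c("FPN+", "SOM-", "VIS-"))
  expect_setequal(names(dg$groups)[dg$groups != g_fpn],
                  c("FPN-", "SOM+", "VIS+"))
  expect_equal(dg$cor_matrix, t(dg$cor_matrix))
  expect_equal(unname(diag(dg$cor_matrix)), rep(1, 6))
  two <- centroid_dendrogram(ce[1:2, ])
  expect_equal(sort(unname(two$groups)), c(1, 2))
})

test_that("clustering is reproducible and invariant to label permutation", {
  set.seed(19)
  X <- matrix(rnorm(200 * 16), 200, 16)
  f1 <- kmeans_correlation(X, 4, n_restarts = 8, seed = 55)
  f2 <- kmeans_correlation(X, 4, n_restarts = 8, seed = 55)
  expect_identical(f1$labels, f2$labels)
  expect_identical(f1$inertia, f2$inertia)
  # permuting cluster identities changes no summary
  perm <- c(3, 4, 1, 2)
  f_perm <- f1
  f_perm$labels <- perm[f1$labels]
  f_perm$centroids <- f1$centroids[order(perm), ]
  expect_equal(adjusted_mutual_information(f1$labels, f_perm$labels), 1)
  sim_own <- function(f) {
    Xn <- statedyn:::row_standardize(X)
    Cn <- statedyn:::centroid_standardize(f$centroids)
    sum(1 - tcrossprod(Xn, Cn)[cbind(seq_len(nrow(X)), f$labels)])
  }
  expect_equal(sim_own(f_perm), f1$inertia, tolerance = 1e-10)
})
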