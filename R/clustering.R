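#' Concatenate postprocessed scans into one frames x ROIs matrix
#'
#' Stacks the kept (non-censored) frames of every scan, in scan order, and
#' returns an invertible index mapping each concatenated row back to its
#' (subject, condition, original frame).
#'
#' @param scans A list of [roi_timeseries()] scans sharing the same ROI count.
#' @return A list with `data` (kept-frames x N matrix) and `scan_index`
#'   (tibble: `row`, `scan`, `subject`, `condition`, `frame`).
#' @export
concatenate_scans <- function(scans) {
  assert_that(length(scans) >= 1, "need at least one scan")
  ns <- vapply(scans, function(s) ncol(s$data), integer(1))
  if (length(unique(ns)) != 1) {
    abort("scans have mixed ROI counts and cannot be concatenated")
  }
  scan_ids <- names(scans) %||% as.character(seq_along(scans))
  blocks <- vector("list", length(scans))
  idx <- vector("list", length(scans))
  for (i in seq_along(scans)) {
    s <- scans[[i]]
    keep <- which(s$censor_mask)
    blocks[[i]] <- s$data[keep, , drop = FALSE]
    idx[[i]] <- tibble::tibble(
      scan = scan_ids[i], subject = s$subject_id, condition = s$condition,
      frame = keep
    )
  }
  scan_index <- dplyr::bind_rows(idx)
  scan_index$row <- seq_len(nrow(scan_index))
  list(data = do.call(rbind, blocks),
       scan_index = dplyr::relocate(scan_index, "row"))
}

# Center rows to zero mean and scale to unit norm; errors on constant rows.
row_standardize <- function(X) {
  Xc <- X - rowMeans(X)
  nrm <- sqrt(rowSums(Xc^2))
  bad <- which(nrm == 0)
  if (length(bad) > 0) {
    abort(paste0("zero-variance frame(s): ",
                 paste(head(bad, 5), collapse = ", "),
                 if (length(bad) > 5) ", ..." else ""))
  }
  Xc / nrm
}

# Normalize centroid rows for correlation computation.
centroid_standardize <- function(C) {
  Cc <- C - rowMeans(C)
  nrm <- sqrt(rowSums(Cc^2))
  nrm[nrm == 0] <- 1
  Cc / nrm
}

#' k-means clustering with correlation distance
#'
#' Lloyd iterations under the distance `d(x, c) = 1 - cor(x, c)` across
#' ROIs: frames are assigned to the maximum-correlation centroid, and each
#' centroid is recomputed as the mean of its members (on row-standardized
#' data) re-centered to zero mean. Each restart is initialized with `k`
#' distinct frames sampled uniformly without replacement; the restart with
#' the lowest total within-cluster distance wins. An emptied cluster is
#' reseeded with the frame farthest from its current centroid. Ties (equal
#' correlation to two centroids) resolve to the lowest centroid index.
#'
#' @param X Frames x ROIs matrix; every row must vary across ROIs.
#' @param k Number of clusters (>= 2).
#' @param n_restarts Random restarts.
#' @param seed Integer seed making the run deterministic.
#' @param max_iter Iteration cap per restart.
#' @param tol Convergence is declared when assignments stop changing or the
#'   total distance improves by less than `tol` relative per iteration.
#' @param scan_index Optional frame index (from [concatenate_scans()])
#'   carried into the result.
#' @return An object of class `state_kmeans`: `k`, `centroids` (k x N,
#'   zero-mean rows), `labels`, `inertia`, `explained_variance`,
#'   `scan_index`, `n_iter`, `converged`. Labels are always an exact argmax
#'   fixed point of the returned centroids.
#' @export
kmeans_correlation <- function(X, k, n_restarts = 50, seed = NULL,
                               max_iter = 50, tol = 1e-5,
                               scan_index = NULL) {
  X <- as.matrix(X)
  assert_that(k >= 2, "k must be >= 2")
  assert_that(k < nrow(X), "k must be below the number of frames")
  Xn <- row_standardize(X)
  n <- nrow(Xn)

  run_once <- function(init_rows) {
    C <- Xn[init_rows, , drop = FALSE]
    labels <- integer(n)
    inertia <- Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      sim <- tcrossprod(Xn, centroid_standardize(C))
      new_labels <- max.col(sim, ties.method = "first")
      # reseed empty clusters with the farthest-from-centroid frame, which
      # is claimed outright so duplicated patterns cannot starve the cluster
      empty <- setdiff(seq_len(k), unique(new_labels))
      guard <- 0L
      while (length(empty) > 0 && guard < 2L * k) {
        guard <- guard + 1L
        own <- sim[cbind(seq_len(n), new_labels)]
        sizes <- tabulate(new_labels, nbins = k)
        cand <- which(sizes[new_labels] >= 2L)
        far <- cand[which.min(own[cand])]
        C[empty[1], ] <- Xn[far, , drop = FALSE]
        sim[, empty[1]] <- tcrossprod(Xn, centroid_standardize(
          C[empty[1], , drop = FALSE]))
        new_labels[far] <- empty[1]
        empty <- setdiff(seq_len(k), unique(new_labels))
      }
      if (length(empty) > 0) abort("could not populate all clusters")
      new_inertia <- sum(1 - sim[cbind(seq_len(n), new_labels)])
      converged <- identical(new_labels, labels) ||
        (is.finite(inertia) && inertia - new_inertia < tol * inertia)
      labels <- new_labels
      inertia <- new_inertia
      C <- rowsum(Xn, labels, reorder = TRUE) /
        tabulate(labels, nbins = k)
      C <- C - rowMeans(C)
      if (converged) break
    }
    # final assignment so labels are an argmax fixed point of the centroids
    sim <- tcrossprod(Xn, centroid_standardize(C))
    labels <- max.col(sim, ties.method = "first")
    empty <- setdiff(seq_len(k), unique(labels))
    guard <- 0L
    while (length(empty) > 0 && guard < 2L * k) {
      guard <- guard + 1L
      own <- sim[cbind(seq_len(n), labels)]
      sizes <- tabulate(labels, nbins = k)
      cand <- which(sizes[labels] >= 2L)
      far <- cand[which.min(own[cand])]
      C[empty[1], ] <- Xn[far, , drop = FALSE]
      sim[, empty[1]] <- tcrossprod(Xn, centroid_standardize(
        C[empty[1], , drop = FALSE]))
      labels[far] <- empty[1]
      empty <- setdiff(seq_len(k), unique(labels))
    }
    if (length(empty) > 0) abort("could not populate all clusters")
    inertia <- max(sum(1 - sim[cbind(seq_len(n), labels)]), 0)
    list(centroids = C, labels = labels, inertia = inertia, n_iter = it,
         converged = converged)
  }

  inits <- with_seed(seed, {
    lapply(seq_len(n_restarts), function(i) sample.int(n, k))
  })
  best <- NULL
  for (init in inits) {
    fit <- run_once(init)
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }

  gc_vec <- colMeans(Xn)
  gc_vec <- gc_vec - mean(gc_vec)
  total <- sum(1 - as.numeric(tcrossprod(Xn, centroid_standardize(
    matrix(gc_vec, 1)))))
  ev <- min(max(1 - best$inertia / total, 0), 1)

  structure(list(
    k = as.integer(k), centroids = best$centroids, labels = best$labels,
    inertia = best$inertia, explained_variance = ev,
    scan_index = scan_index, n_iter = best$n_iter,
    converged = best$converged
  ), class = "state_kmeans")
}

#' @export
print.state_kmeans <- function(x, ...) {
  cat("<state_kmeans> k = ", x$k, ", ", length(x$labels), " frames, ",
      "inertia = ", signif(x$inertia, 6), ", EV = ",
      signif(x$explained_variance, 4), "\n", sep = "")
  invisible(x)
}

#' Explained-variance curve over a range of k
#'
#' For each k, runs [kmeans_correlation()] and records
#' `EV(k) = 1 - sum d(frame, own centroid) / sum d(frame, global centroid)`.
#' The curve is nondecreasing in k up to restart noise.
#'
#' @param X Frames x ROIs matrix.
#' @param k_min,k_max Range of cluster counts (inclusive).
#' @param n_restarts Restarts per k.
#' @param seed Root seed (one child seed per k).
#' @param max_iter Lloyd iteration cap.
#' @return A tibble with columns `k`, `explained_variance`, `inertia`.
#' @export
explained_variance_curve <- function(X, k_min = 3, k_max = 22,
                                     n_restarts = 50, seed = NULL,
                                     max_iter = 50) {
  assert_that(k_min >= 2 && k_max >= k_min, "need 2 <= k_min <= k_max")
  assert_that(k_max < nrow(X), "k_max must be below the number of frames")
  ks <- seq.int(k_min, k_max)
  seeds <- if (is.null(seed)) rep(list(NULL), length(ks)) else
    as.list(split_seed(seed, length(ks)))
  rows <- lapply(seq_along(ks), function(i) {
    fit <- kmeans_correlation(X, ks[i], n_restarts = n_restarts,
                              seed = seeds[[i]], max_iter = max_iter)
    tibble::tibble(k = ks[i], explained_variance = fit$explained_variance,
                   inertia = fit$inertia)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("statedyn_ev", class(out))
  out
}

#' Select k by the elbow criterion
#'
#' Returns the smallest k whose explained-variance gain to the next k falls
#' below `gain_threshold` (default 0.01, i.e. under one percentage point).
#' If no gain drops below the threshold the largest k is returned with a
#' warning, flagged in the `"elbow_fallback"` attribute.
#'
#' @param curve Tibble from [explained_variance_curve()] (columns `k`,
#'   `explained_variance`), at least 3 points.
#' @param gain_threshold Absolute EV gain threshold.
#' @return The selected k (integer).
#' @export
select_k_elbow <- function(curve, gain_threshold = 0.01) {
  assert_that(nrow(curve) >= 3, "elbow selection needs at least 3 curve points")
  curve <- dplyr::arrange(curve, .data$k)
  gains <- diff(curve$explained_variance)
  hit <- which(gains < gain_threshold)
  if (length(hit) == 0) {
    warn("no explained-variance gain fell below the threshold; returning k_max")
    return(structure(as.integer(max(curve$k)), elbow_fallback = TRUE))
  }
  as.integer(curve$k[hit[1]])
}

#' Adjusted mutual information between two labelings
#'
#' Chance-corrected agreement:
#' `AMI = (MI - E[MI]) / (mean(H1, H2) - E[MI])`, where `E[MI]` is the
#' expected mutual information under the hypergeometric model of random
#' labelings with fixed marginals. Symmetric and invariant to label
#' permutation; 1 for identical partitions, ~0 at chance.
#'
#' @param p1,p2 Equal-length label vectors.
#' @return A scalar in (-1, 1].
#' @export
adjusted_mutual_information <- function(p1, p2) {
  assert_that(length(p1) == length(p2),
              "labelings must have the same length")
  n <- length(p1)
  tab <- table(p1, p2)
  a <- rowSums(tab)
  b <- colSums(tab)

  nij <- as.numeric(tab)
  nz <- nij > 0
  ai <- rep(a, times = ncol(tab))[nz]
  bj <- rep(b, each = nrow(tab))[nz]
  mi <- sum(nij[nz] / n * log(n * nij[nz] / (ai * bj)))

  h1 <- -sum(a / n * log(a / n))
  h2 <- -sum(b / n * log(b / n))
  if (h1 == 0 && h2 == 0) return(1)

  emi <- 0
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      lo <- max(1, a[i] + b[j] - n)
      hi <- min(a[i], b[j])
      if (hi < lo) next
      v <- lo:hi
      logp <- lchoose(a[i], v) + lchoose(n - a[i], b[j] - v) - lchoose(n, b[j])
      emi <- emi + sum(exp(logp) * v / n * log(n * v / (a[i] * b[j])))
    }
  }
  denom <- (h1 + h2) / 2 - emi
  if (denom == 0) return(0)
  (mi - emi) / denom
}

#' Select the most representative partition by cumulative AMI
#'
#' Among clustering replicates of the same k, returns the one with the
#' highest summed AMI to all the others; ties break to the lowest inertia,
#' then to the lowest replicate index.
#'
#' @param replicates List (>= 2) of `state_kmeans` fits with identical k
#'   and frame count.
#' @return The selected `state_kmeans`, with attributes `"ami_total"`
#'   (per-replicate cumulative AMI) and `"replicate"` (chosen index).
#' @export
select_partition_ami <- function(replicates) {
  assert_that(length(replicates) >= 2, "need at least 2 replicates")
  ks <- vapply(replicates, function(r) r$k, integer(1))
  if (length(unique(ks)) != 1) abort("replicates have mismatched k")
  lens <- vapply(replicates, function(r) length(r$labels), integer(1))
  if (length(unique(lens)) != 1) abort("replicates have mismatched frame counts")

  m <- length(replicates)
  ami <- matrix(0, m, m)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      ami[i, j] <- ami[j, i] <- adjusted_mutual_information(
        replicates[[i]]$labels, replicates[[j]]$labels)
    }
  }
  cum <- rowSums(ami)
  inertia <- vapply(replicates, function(r) r$inertia, numeric(1))
  ord <- order(-cum, inertia, seq_len(m))
  best <- ord[1]
  out <- replicates[[best]]
  attr(out, "ami_total") <- cum
  attr(out, "replicate") <- best
  out
}

#' Name states by cosine similarity to network templates
#'
#' Splits each centroid into its positive part `max(c, 0)` and negative part
#' `max(-c, 0)` and computes the cosine similarity of each part with each
#' network's indicator vector. The state is named after the single largest
#' similarity: `"NET+"` when it comes from the positive part, `"NET-"` from
#' the negative part. `parts = "whole"` instead compares the full centroid
#' with `+/-` indicator vectors.
#'
#' @param centroids k x N matrix.
#' @param templates Tibble from [generate_network_templates()] (or any with
#'   columns `roi`/`network` matching the centroid columns).
#' @param parts `"signed"` (default) or `"whole"`.
#' @return A list of class `state_catalog`: `names` (length-k character) and
#'   `similarity` (tibble: `state`, `network`, `part`, `cosine`).
#' @export
name_states <- function(centroids, templates, parts = c("signed", "whole")) {
  parts <- match.arg(parts)
  centroids <- as.matrix(centroids)
  assert_that(ncol(centroids) == nrow(templates),
              "centroid length must equal the number of templated ROIs")
  nets <- sort(unique(templates$network))
  ind <- sapply(nets, function(nm) as.numeric(templates$network == nm))

  cosine <- function(u, v) {
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    if (nu == 0 || nv == 0) return(0)
    sum(u * v) / (nu * nv)
  }

  rows <- list()
  nm_out <- character(nrow(centroids))
  for (s in seq_len(nrow(centroids))) {
    cvec <- centroids[s, ]
    if (all(cvec == 0)) abort(sprintf("state %d has an all-zero centroid and cannot be named", s))
    if (parts == "signed") {
      up <- pmax(cvec, 0); dn <- pmax(-cvec, 0)
      sim_pos <- apply(ind, 2, function(v) cosine(up, v))
      sim_neg <- apply(ind, 2, function(v) cosine(dn, v))
    } else {
      sim_pos <- apply(ind, 2, function(v) cosine(cvec, v))
      sim_neg <- apply(ind, 2, function(v) cosine(-cvec, v))
    }
    rows[[s]] <- tibble::tibble(
      state = s,
      network = rep(nets, 2),
      part = rep(c("+", "-"), each = length(nets)),
      cosine = c(sim_pos, sim_neg)
    )
    all_sim <- c(sim_pos, sim_neg)
    top <- which.max(all_sim)
    net <- nets[(top - 1) %% length(nets) + 1]
    sign_sfx <- if (top <= length(nets)) "+" else "-"
    nm_out[s] <- paste0(net, sign_sfx)
  }
  structure(list(names = nm_out, similarity = dplyr::bind_rows(rows)),
            class = "state_catalog")
}

#' @export
print.state_catalog <- function(x, ...) {
  cat("<state_catalog> ", paste(x$names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Two-group split of state centroids
#'
#' Average-linkage hierarchical clustering of the centroids under distance
#' `1 - cor`, cut at two groups; the two-group structure separates
#' association-dominant from sensorimotor-dominant co-activation patterns.
#'
#' @param centroids k x N matrix (k >= 2); rownames, if present, label states.
#' @return A list: `groups` (named integer vector in {1,2}), `cor_matrix`
#'   (k x k Pearson correlations), `hclust` (the tree).
#' @export
centroid_dendrogram <- function(centroids) {
  centroids <- as.matrix(centroids)
  assert_that(nrow(centroids) >= 2, "need at least 2 centroids")
  cm <- stats::cor(t(centroids))
  hc <- hclust(as.dist(1 - cm), method = "average")
  groups <- cutree(hc, k = 2)
  list(groups = groups, cor_matrix = cm, hclust = hc)
}

#' Cluster brain states with replicate selection and naming
#'
#' Convenience front-end for the full discovery stage: runs
#' `n_replicates` independent [kmeans_correlation()] fits at a given k,
#' selects the most representative one by cumulative AMI
#' ([select_partition_ami()]), and names its states against the network
#' templates.
#'
#' @param X Frames x ROIs matrix (concatenated kept frames).
#' @param k Number of states.
#' @param templates Network templates for naming (or `NULL` to skip).
#' @param n_restarts Restarts per replicate.
#' @param n_replicates Independent replicates entering AMI selection.
#' @param seed Root seed.
#' @param scan_index Optional frame index carried into the result.
#' @return A `state_kmeans` fit with `state_names` and `catalog` fields
#'   filled in (when templates are supplied).
#' @export
cluster_states <- function(X, k, templates = NULL, n_restarts = 50,
                           n_replicates = 10, seed = NULL,
                           scan_index = NULL) {
  seeds <- if (is.null(seed)) rep(list(NULL), n_replicates) else
    as.list(split_seed(seed, n_replicates))
  reps <- lapply(seeds, function(s) {
    kmeans_correlation(X, k, n_restarts = n_restarts, seed = s,
                       scan_index = scan_index)
  })
  fit <- if (n_replicates >= 2) select_partition_ami(reps) else reps[[1]]
  if (!is.null(templates)) {
    catalog <- name_states(fit$centroids, templates)
    fit$state_names <- catalog$names
    fit$catalog <- catalog
    rownames(fit$centroids) <- catalog$names
  }
  fit
}
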