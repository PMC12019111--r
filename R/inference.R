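#' Benjamini-Hochberg correction with rejection flags
#'
#' Step-up adjusted p-values (via [stats::p.adjust()] with
#' `method = "BH"`) plus the rejections at level `alpha`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR level.
#' @return A tibble with columns `p_value`, `p_adjusted`, `significant`.
#' @export
bh_correct <- function(p_values, alpha = 0.05) {
  assert_that(all(p_values >= 0 & p_values <= 1),
              "p-values must lie in [0, 1]")
  adj <- p.adjust(p_values, method = "BH")
  tibble::tibble(p_value = p_values, p_adjusted = adj,
                 significant = adj <= alpha)
}

# Paired t on a vector of differences; degenerate zero-variance cases are
# resolved explicitly instead of erroring.
paired_t_stats <- function(d) {
  n <- length(d)
  if (sd(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, p = 1, degenerate = FALSE))
    warn("zero-variance nonzero-mean differences; reporting p as the 0 limit")
    return(list(t = sign(mean(d)) * Inf, p = 0, degenerate = TRUE))
  }
  tt <- t.test(d)
  list(t = unname(tt$statistic), p = tt$p.value, degenerate = FALSE)
}

#' Paired condition contrasts on dynamic metrics
#'
#' Two-sided paired t tests of MP versus PL for each metric x state, on the
#' per-subject differences (MP - PL), with Benjamini-Hochberg correction
#' applied within each metric family (all states of one metric) by default,
#' or globally across the whole table.
#'
#' @param metrics Tidy tibble from [dynamic_metrics()] (columns `subject`,
#'   `condition`, `state`, `state_name`, `metric`, `value`) with both
#'   conditions present for every subject.
#' @param which Optional tibble with columns `metric` and `state_name`
#'   restricting the tested pairs.
#' @param alpha FDR level for the BH flags.
#' @param family `"metric"` (default, per-metric BH families) or `"global"`.
#' @return A tibble of class `contrast_table`: `metric`, `state`,
#'   `state_name`, `n`, `mean_diff`, `t_statistic`, `p_value`, `p_adjusted`,
#'   `significant_uncorrected`, `significant_bh`.
#' @export
paired_contrast <- function(metrics, which = NULL, alpha = 0.05,
                            family = c("metric", "global")) {
  family <- match.arg(family)
  wide <- metrics |>
    dplyr::select("subject", "condition", "state", "state_name",
                  "metric", "value") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "value")
  if (!all(c("PL", "MP") %in% names(wide))) {
    abort("metrics must contain both PL and MP conditions")
  }
  miss <- wide$subject[is.na(wide$PL) | is.na(wide$MP)]
  if (length(miss) > 0) {
    abort(paste0("subjects without both conditions: ",
                 paste(unique(miss), collapse = ", ")))
  }
  if (!is.null(which)) {
    wide <- dplyr::semi_join(wide, which, by = intersect(
      names(which), c("metric", "state_name", "state")))
  }
  grp <- wide |>
    dplyr::group_by(.data$metric, .data$state, .data$state_name) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_diff = mean(.data$MP - .data$PL),
      stats = list(paired_t_stats(.data$MP - .data$PL)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      t_statistic = vapply(.data$stats, function(s) s$t, numeric(1)),
      p_value = vapply(.data$stats, function(s) s$p, numeric(1))
    ) |>
    dplyr::select(-"stats")
  assert_that(all(grp$n >= 3), "paired contrast needs n >= 3 matched subjects")
  fam <- if (family == "metric") grp$metric else rep("all", nrow(grp))
  grp$p_adjusted <- unsplit(
    lapply(split(grp$p_value, fam), function(p) p.adjust(p, "BH")), fam)
  grp$significant_uncorrected <- grp$p_value < 0.05
  grp$significant_bh <- grp$p_adjusted <= alpha
  class(grp) <- c("contrast_table", class(grp))
  grp
}

#' Pearson correlation with a two-sided p-value
#'
#' `r` with the exact t transform `t = r * sqrt((n-2)/(1-r^2))` on `n - 2`
#' degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors (n >= 3, both nonconstant);
#'   incomplete pairs are dropped.
#' @return A one-row tibble: `estimate`, `statistic`, `p.value`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  assert_that(n >= 3, "correlation needs at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined: an input is constant")
  }
  r <- cor(x, y)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  tibble::tibble(estimate = r, statistic = tstat,
                 p.value = 2 * pt(-abs(tstat), df = n - 2), n = n)
}

#' Partial correlation adjusting for one covariate
#'
#' Residualizes `x` and `y` on an intercept plus the covariate by OLS and
#' correlates the residuals, with the t test on `n - 3` degrees of freedom.
#' A constant covariate falls back to the plain Pearson correlation with a
#' warning.
#'
#' @param x,y Numeric vectors.
#' @param covariate Numeric vector (e.g. IQ).
#' @return A one-row tibble: `estimate`, `statistic`, `p.value`, `n`.
#' @export
adjust_for_covariate <- function(x, y, covariate) {
  ok <- complete.cases(x, y, covariate)
  x <- x[ok]; y <- y[ok]; covariate <- covariate[ok]
  n <- length(x)
  assert_that(n >= 4, "partial correlation needs at least 4 complete cases")
  if (sd(covariate) == 0) {
    warn("covariate is constant; falling back to the plain correlation")
    return(pearson_with_p(x, y))
  }
  Z <- cbind(1, covariate)
  rx <- x - Z %*% qr.solve(Z, x)
  ry <- y - Z %*% qr.solve(Z, y)
  # a variable fully explained by the covariate has nothing left to correlate
  if (sd(rx) < 1e-10 * max(sd(x), 1) || sd(ry) < 1e-10 * max(sd(y), 1)) {
    return(tibble::tibble(estimate = 0, statistic = 0, p.value = 1, n = n))
  }
  r <- cor(rx, ry)[1]
  tstat <- r * sqrt((n - 3) / max(1 - r^2, .Machine$double.eps))
  tibble::tibble(estimate = r, statistic = tstat,
                 p.value = 2 * pt(-abs(tstat), df = n - 3), n = n)
}

#' Per-subject MP - PL changes of selected metric x state pairs
#'
#' @param metrics Tidy tibble from [dynamic_metrics()].
#' @param which Tibble with columns `metric`, `state_name`; defaults to the
#'   five pairs of interest: FPN+ dwell time and fractional occupancy, VIS-
#'   dwell time and fractional occupancy, SOM+ fractional occupancy.
#' @return Tibble: `subject`, `metric`, `state_name`, `delta`.
#' @export
metric_deltas <- function(metrics, which = NULL) {
  which <- which %||% tibble::tibble(
    metric = c("dwell_time", "fractional_occupancy", "dwell_time",
               "fractional_occupancy", "fractional_occupancy"),
    state_name = c("FPN+", "FPN+", "VIS-", "VIS-", "SOM+")
  )
  metrics |>
    dplyr::semi_join(which, by = c("metric", "state_name")) |>
    dplyr::select("subject", "condition", "metric", "state_name", "value") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "value") |>
    dplyr::mutate(delta = .data$MP - .data$PL) |>
    dplyr::select("subject", "metric", "state_name", "delta")
}

#' ROI-level correlations between receptor availability and metric changes
#'
#' Pearson correlation (with p) of each receptor ROI column against each
#' metric change, matching subjects by name and dropping incomplete pairs
#' pairwise (the per-cell `n` records how many entered).
#'
#' @param deltas Tibble from [metric_deltas()] (columns `subject`, `metric`,
#'   `state_name`, `delta`).
#' @param receptors Subjects x ROIs numeric matrix with subject rownames
#'   (e.g. the cohort's `d1r_roi`).
#' @return Tibble: `roi`, `metric`, `state_name`, `r`, `p`, `n`.
#' @export
roi_correlation_table <- function(deltas, receptors) {
  receptors <- as.matrix(receptors)
  assert_that(!is.null(rownames(receptors)),
              "receptors must carry subject rownames")
  combos <- dplyr::distinct(deltas, .data$metric, .data$state_name)
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    d <- deltas |>
      dplyr::filter(.data$metric == combos$metric[i],
                    .data$state_name == combos$state_name[i])
    v <- stats::setNames(d$delta, d$subject)[rownames(receptors)]
    for (roi in colnames(receptors)) {
      ct <- pearson_with_p(receptors[, roi], v)
      rows[[length(rows) + 1]] <- tibble::tibble(
        roi = roi, metric = combos$metric[i],
        state_name = combos$state_name[i],
        r = ct$estimate, p = ct$p.value, n = ct$n
      )
    }
  }
  dplyr::bind_rows(rows)
}

# 26-connectivity neighbor offsets (faces + edges + corners).
connectivity_offsets <- function(connectivity = 26) {
  g <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  g <- g[!(g$di == 0 & g$dj == 0 & g$dk == 0), ]
  if (connectivity == 6) g <- g[rowSums(abs(g)) == 1, ]
  as.matrix(g)
}

#' Label connected components of a 3D logical array
#'
#' Flood fill under 26-connectivity (faces, edges and corners count as
#' contiguous) or 6-connectivity.
#'
#' @param mask 3D logical array.
#' @param connectivity 26 (default) or 6.
#' @return Integer array of the same dimension; 0 outside components.
#' @export
label_components <- function(mask, connectivity = 26) {
  dm <- dim(mask)
  assert_that(length(dm) == 3, "mask must be a 3D array")
  offs <- connectivity_offsets(connectivity)
  lab <- array(0L, dm)
  nxt <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue) > 0) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      co <- arrayInd(v, dm)
      nb <- sweep(offs, 2, as.integer(co), `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] &
        nb[, 2] >= 1 & nb[, 2] <= dm[2] &
        nb[, 3] >= 1 & nb[, 3] <= dm[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1L) * dm[1] + (nb[, 3] - 1L) * dm[1] * dm[2]
      lin <- lin[mask[lin] & lab[lin] == 0L]
      if (length(lin) > 0) {
        lab[lin] <- nxt
        queue <- c(queue, lin)
      }
    }
  }
  lab
}

#' Voxelwise correlation with cluster-extent filtering
#'
#' Correlates each in-mask voxel across subjects with a target scalar,
#' binarizes at `p < p_thresh` separately for positive and negative
#' correlations, labels 26-connected components per sign, and keeps only
#' components of at least `min_cluster` voxels.
#'
#' @param maps List of per-subject 3D arrays sharing one grid.
#' @param target Per-subject scalar (same length/order as `maps`).
#' @param mask Optional 3D logical array of analyzable voxels.
#' @param p_thresh Uncorrected voxel-level p threshold.
#' @param min_cluster Minimum component size in voxels.
#' @param connectivity Component connectivity (26 or 6).
#' @return A list: `cluster_map` (integer array, 0 = no surviving cluster),
#'   `clusters` (tibble: `cluster`, `sign`, `n_voxels`, `peak_r`), `r_map`,
#'   `p_map`.
#' @export
voxelwise_correlation_clusters <- function(maps, target, mask = NULL,
                                           p_thresh = 0.05, min_cluster = 30,
                                           connectivity = 26) {
  assert_that(length(maps) == length(target),
              "one map per target value is required")
  assert_that(length(maps) >= 3, "voxelwise correlation needs n >= 3")
  dm <- dim(maps[[1]])
  assert_that(length(dm) == 3, "maps must be 3D arrays")
  same <- vapply(maps, function(m) identical(dim(m), dm), logical(1))
  if (!all(same)) abort("maps are not on a shared grid")
  mask <- mask %||% array(TRUE, dm)
  assert_that(identical(dim(mask), dm), "mask grid mismatch")
  assert_that(any(mask), "mask is empty")

  n <- length(maps)
  Y <- vapply(maps, function(m) as.numeric(m), numeric(prod(dm)))
  Y <- t(Y)                                 # subjects x voxels
  tc <- target - mean(target)
  assert_that(sum(tc^2) > 0, "target is constant")
  Yc <- sweep(Y, 2, colMeans(Y))
  den <- sqrt(colSums(Yc^2)) * sqrt(sum(tc^2))
  r <- as.numeric(crossprod(tc, Yc))
  r <- ifelse(den > 0, r / den, NA_real_)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)

  r_map <- array(r, dm)
  p_map <- array(p, dm)
  sig <- !is.na(p) & p < p_thresh & as.logical(mask)

  cluster_map <- array(0L, dm)
  rows <- list()
  nxt <- 0L
  for (sgn in c(1, -1)) {
    m <- array(sig & !is.na(r) & sign(r) == sgn, dm)
    if (!any(m)) next
    lab <- label_components(m, connectivity)
    for (cl in setdiff(unique(as.integer(lab)), 0L)) {
      vox <- which(lab == cl)
      if (length(vox) < min_cluster) next
      nxt <- nxt + 1L
      cluster_map[vox] <- nxt
      rows[[nxt]] <- tibble::tibble(
        cluster = nxt, sign = if (sgn > 0) "positive" else "negative",
        n_voxels = length(vox), peak_r = r_map[vox][which.max(abs(r_map[vox]))]
      )
    }
  }
  list(
    cluster_map = cluster_map,
    clusters = if (length(rows) > 0) dplyr::bind_rows(rows) else
      tibble::tibble(cluster = integer(), sign = character(),
                     n_voxels = integer(), peak_r = numeric()),
    r_map = r_map, p_map = p_map
  )
}
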