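#' Tidy state centroids into a long tibble
#'
#' @param x A `state_kmeans` fit.
#' @param templates Optional network templates to attach each ROI's network.
#' @param ... Unused.
#' @return A tibble with columns `state`, `state_name`, `roi`, `value`
#'   (+ `network` when templates are given).
#' @method tidy state_kmeans
#' @export
tidy.state_kmeans <- function(x, templates = NULL, ...) {
  k <- x$k
  p <- ncol(x$centroids)
  rois <- colnames(x$centroids) %||% as.character(seq_len(p))
  nm <- x$state_names %||% as.character(seq_len(k))
  out <- tibble::tibble(
    state = rep(seq_len(k), each = p),
    state_name = rep(nm, each = p),
    roi = rep(rois, k),
    value = as.numeric(t(x$centroids))
  )
  if (!is.null(templates)) {
    out$network <- rep(templates$network, k)
  }
  out
}

#' One-row summary of a clustering fit
#'
#' @param x A `state_kmeans` fit.
#' @param ... Unused.
#' @return A one-row tibble: `k`, `n_frames`, `inertia`,
#'   `explained_variance`, `n_iter`, `converged`.
#' @method glance state_kmeans
#' @export
glance.state_kmeans <- function(x, ...) {
  tibble::tibble(
    k = x$k, n_frames = length(x$labels), inertia = x$inertia,
    explained_variance = x$explained_variance, n_iter = x$n_iter,
    converged = x$converged
  )
}

#' Tidy a synthetic cohort's ground truth metrics
#'
#' @param x A `synthetic_cohort`.
#' @param ... Unused.
#' @return The truth metrics tibble (`subject`, `condition`, `state`,
#'   `fractional_occupancy`, `dwell_time`).
#' @method tidy synthetic_cohort
#' @export
tidy.synthetic_cohort <- function(x, ...) {
  x$truth$metrics
}
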