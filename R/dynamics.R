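#' Construct a per-scan state sequence
#'
#' Kept-frame state labels for one scan plus gap markers: `gap_after[t]` is
#' `TRUE` when the next kept frame was not temporally adjacent in the
#' original scan (a censoring gap), so no transition or run may bridge it.
#'
#' @param states Integer labels in `1..k`.
#' @param tr_seconds Repetition time (seconds).
#' @param gap_after Logical, same length (last element ignored).
#' @param subject,condition,scan Identity labels.
#' @return An object of class `state_sequence`.
#' @export
state_sequence <- function(states, tr_seconds, gap_after = NULL,
                           subject = NA_character_, condition = NA_character_,
                           scan = NA_character_) {
  states <- as.integer(states)
  assert_that(length(states) >= 1, "state sequence must be nonempty")
  assert_that(all(states >= 1), "state labels must be positive integers")
  gap_after <- gap_after %||% rep(FALSE, length(states))
  assert_that(length(gap_after) == length(states),
              "gap_after must match the sequence length")
  structure(list(states = states, tr_seconds = tr_seconds,
                 gap_after = as.logical(gap_after), subject = subject,
                 condition = condition, scan = scan),
            class = "state_sequence")
}

#' Split concatenated frame labels back into per-scan sequences
#'
#' Inverts [concatenate_scans()]: groups the fitted labels by scan and marks
#' censoring gaps (non-adjacent original frames) so downstream run/transition
#' counting never bridges them.
#'
#' @param fit A `state_kmeans` with a `scan_index`.
#' @param tr_seconds Repetition time attached to every sequence.
#' @return A named list of [state_sequence()] objects, one per scan.
#' @export
split_labels_by_scan <- function(fit, tr_seconds) {
  assert_that(!is.null(fit$scan_index), "fit carries no scan_index")
  idx <- fit$scan_index
  assert_that(nrow(idx) == length(fit$labels),
              "scan_index does not cover all labels")
  out <- list()
  for (sid in unique(idx$scan)) {
    sub <- idx[idx$scan == sid, ]
    sub <- sub[order(sub$frame), ]
    gaps <- c(diff(sub$frame) > 1, FALSE)
    out[[sid]] <- state_sequence(
      fit$labels[sub$row], tr_seconds = tr_seconds, gap_after = gaps,
      subject = sub$subject[1], condition = sub$condition[1], scan = sid
    )
  }
  out
}

# Maximal runs of each state, broken (never bridged) at censoring gaps.
# Returns a list with values (state per run) and lengths (frames per run).
state_runs <- function(seq) {
  s <- seq$states
  gap <- seq$gap_after
  n <- length(s)
  if (n == 1) return(list(values = s, lengths = 1L))
  brk <- s[-1] != s[-n] | gap[-n]
  run_id <- cumsum(c(1L, as.integer(brk)))
  list(values = s[!duplicated(run_id)],
       lengths = as.integer(tabulate(run_id)))
}

#' Fractional occupancy per state
#'
#' Fraction of kept frames spent in each state; sums to 1.
#'
#' @param seq A [state_sequence()].
#' @param k Number of states.
#' @return Numeric length-k vector.
#' @export
fractional_occupancy <- function(seq, k) {
  tabulate(seq$states, nbins = k) / length(seq$states)
}

#' Mean dwell time per state (seconds)
#'
#' Mean length of the maximal consecutive runs of each state (runs are broken
#' by censoring gaps) multiplied by the TR; 0 for states that never appear.
#'
#' @param seq A [state_sequence()].
#' @param k Number of states.
#' @return Numeric length-k vector of durations in seconds.
#' @export
dwell_time <- function(seq, k) {
  r <- state_runs(seq)
  vapply(seq_len(k), function(s) {
    len <- r$lengths[r$values == s]
    if (length(len) == 0) 0 else mean(len) * seq$tr_seconds
  }, numeric(1))
}

#' Appearance rate per state (visits per minute)
#'
#' Number of maximal runs of each state divided by the kept observation time
#' in minutes.
#'
#' @param seq A [state_sequence()].
#' @param k Number of states.
#' @return Numeric length-k vector of rates per minute.
#' @export
appearance_rate <- function(seq, k) {
  r <- state_runs(seq)
  minutes <- length(seq$states) * seq$tr_seconds / 60
  assert_that(minutes > 0, "observation span must be positive")
  vapply(seq_len(k), function(s) sum(r$values == s), numeric(1)) / minutes
}

#' Frame-to-frame transition probability matrix
#'
#' Counts ordered adjacent state pairs (excluding pairs spanning a censoring
#' gap) and row-normalizes. Self-transitions (persistence) stay on the
#' diagonal; `offdiagonal = TRUE` instead renormalizes each row over exits
#' only. Rows with no observed departures are zero and flagged in the
#' `"undefined_rows"` attribute rather than propagating NaN.
#'
#' @param seq A [state_sequence()] with at least 2 kept frames.
#' @param k Number of states.
#' @param offdiagonal Renormalize over off-diagonal exits only.
#' @return A k x k row-stochastic matrix (up to undefined rows).
#' @export
transition_matrix <- function(seq, k, offdiagonal = FALSE) {
  s <- seq$states
  assert_that(length(s) >= 2, "need at least 2 kept frames")
  from <- s[-length(s)]
  to <- s[-1]
  ok <- !seq$gap_after[-length(s)]
  counts <- matrix(0, k, k)
  for (i in which(ok)) counts[from[i], to[i]] <- counts[from[i], to[i]] + 1
  if (offdiagonal) diag(counts) <- 0
  dep <- rowSums(counts)
  P <- counts
  P[dep > 0, ] <- counts[dep > 0, , drop = FALSE] / dep[dep > 0]
  attr(P, "undefined_rows") <- which(dep == 0)
  P
}

#' Dynamic metrics for every scan of a clustering fit
#'
#' Splits the fitted labels by scan and computes fractional occupancy, mean
#' dwell time, appearance rate and the transition matrix for each scan,
#' returned as one tidy tibble (plus the transition matrices as an
#' attribute).
#'
#' @param fit A `state_kmeans` with `scan_index` (and optionally
#'   `state_names`).
#' @param tr_seconds Repetition time.
#' @return A tibble with columns `scan`, `subject`, `condition`, `state`,
#'   `state_name`, `metric`, `value`, `n_frames_kept`; transition matrices
#'   in `attr(, "transition_matrices")`.
#' @export
dynamic_metrics <- function(fit, tr_seconds) {
  seqs <- split_labels_by_scan(fit, tr_seconds)
  k <- fit$k
  nm <- fit$state_names %||% as.character(seq_len(k))
  tmats <- list()
  rows <- lapply(names(seqs), function(sid) {
    sq <- seqs[[sid]]
    tmats[[sid]] <<- transition_matrix(sq, k)
    tibble::tibble(
      scan = sid, subject = sq$subject, condition = sq$condition,
      state = rep(seq_len(k), 3),
      state_name = rep(nm, 3),
      metric = rep(c("fractional_occupancy", "dwell_time", "appearance_rate"),
                   each = k),
      value = c(fractional_occupancy(sq, k), dwell_time(sq, k),
                appearance_rate(sq, k)),
      n_frames_kept = length(sq$states)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "transition_matrices") <- tmats
  out
}
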