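#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the synthetic study: cohort size, scan geometry,
#' the latent Markov state structure, the pharmacological persistence effect
#' and its receptor-driven heterogeneity, the noise model, and the planted
#' mediation path linking receptor availability to behavior through state
#' dwell time.
#'
#' Defaults mirror the study conditions the generator emulates: 37 subjects
#' scanned under placebo (PL) and methylphenidate (MP), 520 frames at
#' TR = 0.891 s over 232 ROIs (200 cortical + 32 subcortical), six latent
#' co-activation states. Signal amplitude is ~100 arbitrary BOLD units so
#' that a DVARS threshold of 150 is meaningful on the synthetic series.
#'
#' @param n_subjects Number of subjects (each contributes one PL and one MP scan).
#' @param n_rois Number of ROIs per scan.
#' @param n_frames Frames per scan.
#' @param tr_seconds Repetition time in seconds.
#' @param k_true Number of latent states (must be even; states come in
#'   network +/- pairs).
#' @param base_persistence Self-transition probability of every state under
#'   placebo, in (0,1).
#' @param mp_persistence_boost Additive self-transition increase for the
#'   FPN+ and VIS- states under MP (scaled per subject by sensitivity).
#' @param sensitivity_slope Spread of the subject-level sensitivity scalar
#'   around 1 (sensitivity = 1 + slope * latent z).
#' @param mediation_a Correlation in (0,1) between standardized mean D1R and
#'   the latent sensitivity z; path "a" of the planted mediation.
#' @param mediation_b Seconds of 2-ball response-time reduction per second of
#'   true MP-PL FPN+ dwell-time increase; path "b" (entered with a negative
#'   sign so higher dwell gain means faster responses).
#' @param amplitude State-signal amplitude (arbitrary BOLD units).
#' @param noise_sd Stationary SD of the additive AR(1) noise per ROI.
#' @param drift_amp Amplitude of the shared slow sinusoidal drift.
#' @param ar_coeff AR(1) coefficient of the noise.
#' @param spike_rate Per-frame probability of a motion-spike artifact.
#' @param seed Root seed; all child randomness is derived from it via
#'   [split_seed()].
#' @return A list of class `statedyn_config`.
#' @export
cohort_config <- function(n_subjects = 37,
                          n_rois = 232,
                          n_frames = 520,
                          tr_seconds = 0.891,
                          k_true = 6,
                          base_persistence = 0.90,
                          mp_persistence_boost = 0.03,
                          sensitivity_slope = 0.5,
                          mediation_a = 0.6,
                          mediation_b = 0.02,
                          amplitude = 100,
                          noise_sd = 40,
                          drift_amp = 50,
                          ar_coeff = 0.3,
                          spike_rate = 0.02,
                          seed = 7) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_rois = as.integer(n_rois),
    n_frames = as.integer(n_frames), tr_seconds = tr_seconds,
    k_true = as.integer(k_true), base_persistence = base_persistence,
    mp_persistence_boost = mp_persistence_boost,
    sensitivity_slope = sensitivity_slope,
    mediation_a = mediation_a, mediation_b = mediation_b,
    amplitude = amplitude, noise_sd = noise_sd, drift_amp = drift_amp,
    ar_coeff = ar_coeff, spike_rate = spike_rate, seed = as.integer(seed)
  )
  validate_config(cfg)
  structure(cfg, class = "statedyn_config")
}

validate_config <- function(cfg) {
  assert_that(cfg$n_subjects >= 1, "n_subjects must be >= 1")
  assert_that(cfg$n_rois >= 16, "n_rois must be >= 16")
  assert_that(cfg$k_true %% 2 == 0 && cfg$k_true >= 2,
              "k_true must be an even count >= 2")
  assert_that(cfg$base_persistence > 0 && cfg$base_persistence < 1,
              "base_persistence must lie in (0,1)")
  assert_that(cfg$mp_persistence_boost >= 0 &&
                cfg$base_persistence + cfg$mp_persistence_boost < 1,
              "base_persistence + mp_persistence_boost must be < 1")
  assert_that(cfg$spike_rate >= 0 && cfg$spike_rate < 1,
              "spike_rate must lie in [0,1)")
  assert_that(cfg$mediation_a >= 0 && cfg$mediation_a <= 1,
              "mediation_a must lie in [0,1]")
  assert_that(cfg$n_frames * cfg$tr_seconds > 60,
              "scan must span more than 60 s (appearance rate is per minute)")
  invisible(cfg)
}

# Canonical network labels; the 7 cortical networks precede the subcortical.
statedyn_networks <- function() {
  c("FPN", "LIM", "VAT", "DAT", "SOM", "VIS", "DMN", "SUB")
}

#' Assign ROIs to the eight canonical resting-state networks
#'
#' Produces an atlas-like template: contiguous blocks of ROIs labelled with
#' the seven cortical networks (FPN, LIM, VAT, DAT, SOM, VIS, DMN) followed
#' by the subcortical network (SUB). For the default 232-ROI layout the SUB
#' block has exactly 32 ROIs, mirroring a 200 + 32 cortical/subcortical atlas.
#'
#' @param n_rois Number of ROIs (at least 16 so all 8 networks get >= 2 ROIs).
#' @param seed Unused source of randomness kept for interface stability; the
#'   assignment is deterministic.
#' @return A tibble with columns `roi` (index), `roi_name`, `network`.
#' @export
generate_network_templates <- function(n_rois = 232, seed = 1) {
  assert_that(n_rois >= 16, "n_rois must be >= 16 to populate 8 networks with >= 2 ROIs")
  nets <- statedyn_networks()
  n_sub <- max(2L, round(n_rois * 32 / 232))
  n_cort <- n_rois - n_sub
  base <- n_cort %/% 7L
  extra <- n_cort %% 7L
  sizes <- c(rep(base, 7L) + c(rep(1L, extra), rep(0L, 7L - extra)), n_sub)
  names(sizes) <- nets
  assert_that(all(sizes >= 2), "n_rois too small for 8 networks of >= 2 ROIs")
  network <- rep(nets, times = sizes)
  tibble::tibble(
    roi = seq_len(n_rois),
    roi_name = sprintf("%s_%03d", network, unlist(lapply(sizes, seq_len))),
    network = network
  )
}

#' Build latent state centroids as network +/- pairs
#'
#' Each chosen network yields two centroids: one with elevated amplitude on
#' that network's ROIs (the "+" state) and its exact negation (the "-"
#' state). Centroids have zero mean across ROIs, matching demeaned BOLD
#' where positive values mean above-average amplitude. The three canonical
#' states carry their characteristic secondary loadings: FPN+ also elevates
#' the dorsal attention network and suppresses the visual network, while
#' SOM+ and VIS+ suppress the default mode network — which is what groups
#' {FPN+, SOM-, VIS-} (association-dominant) against {FPN-, SOM+, VIS+}
#' (sensorimotor-dominant) in the centroid dendrogram.
#'
#' @param templates Output of [generate_network_templates()].
#' @param k_true Even number of states; `k_true/2` networks are used, in the
#'   order FPN, SOM, VIS, DMN, DAT, VAT, LIM, SUB.
#' @return A `k_true` x `n_rois` matrix with rownames like `"FPN+"`, `"FPN-"`.
#' @export
generate_centroids <- function(templates, k_true = 6) {
  assert_that(k_true %% 2 == 0, "k_true must be even (states come in +/- pairs)")
  order_pref <- c("FPN", "SOM", "VIS", "DMN", "DAT", "VAT", "LIM", "SUB")
  assert_that(k_true <= 2 * length(unique(templates$network)),
              "k_true exceeds twice the number of networks")
  nets <- order_pref[seq_len(k_true / 2)]
  # secondary loadings: primary network +1, listed networks at half weight
  secondary <- list(
    FPN = c(DAT = 0.5, VIS = -0.5),
    SOM = c(DMN = -0.5),
    VIS = c(DMN = -0.5)
  )
  n <- nrow(templates)
  cent <- matrix(0, nrow = k_true, ncol = n)
  rn <- character(k_true)
  for (i in seq_along(nets)) {
    v <- as.numeric(templates$network == nets[i])
    sec <- secondary[[nets[i]]]
    for (nm in names(sec)) {
      v <- v + sec[[nm]] * as.numeric(templates$network == nm)
    }
    v <- v - mean(v)
    cent[2 * i - 1, ] <- v
    cent[2 * i, ] <- -v
    rn[2 * i - 1] <- paste0(nets[i], "+")
    rn[2 * i] <- paste0(nets[i], "-")
  }
  rownames(cent) <- rn
  colnames(cent) <- templates$roi_name
  cent
}

#' Transition kernel of the latent state chain
#'
#' Under placebo every state has self-transition `base_persistence` and
#' uniform exits. Under MP the FPN+ and VIS- states gain
#' `sensitivity * mp_persistence_boost` self-transition probability, with the
#' off-diagonal mass of those rows (including entries into SOM+) shrunk
#' proportionally.
#'
#' @param condition `"PL"` or `"MP"`.
#' @param sensitivity Subject-level scalar multiplying the boost.
#' @param config A [cohort_config()].
#' @param state_names Optional state names used to locate FPN+ / VIS-.
#' @return A row-stochastic `k_true` x `k_true` matrix.
#' @export
transition_kernel <- function(condition, sensitivity, config,
                              state_names = NULL) {
  condition <- match.arg(condition, c("PL", "MP"))
  k <- config$k_true
  p0 <- config$base_persistence
  P <- matrix((1 - p0) / (k - 1), k, k)
  diag(P) <- p0
  if (is.null(state_names)) {
    state_names <- rownames(generate_centroids(
      generate_network_templates(16), k
    ))
  }
  dimnames(P) <- list(state_names, state_names)
  if (condition == "MP" && config$mp_persistence_boost > 0) {
    boosted <- intersect(c("FPN+", "VIS-"), state_names)
    for (s in boosted) {
      pnew <- p0 + sensitivity * config$mp_persistence_boost
      if (pnew >= 1) {
        abort("subject sensitivity too large: self-transition would reach 1")
      }
      i <- match(s, state_names)
      P[i, -i] <- P[i, -i] * (1 - pnew) / (1 - p0)
      P[i, i] <- pnew
    }
  }
  P
}

#' Simulate one scan's latent state sequence
#'
#' First-order Markov chain over `1..k_true` with the condition- and
#' subject-specific kernel of [transition_kernel()]; the initial state is
#' uniform.
#'
#' @param subject_sensitivity Subject-level sensitivity scalar.
#' @param condition `"PL"` or `"MP"`.
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return An integer vector of length `config$n_frames` with values in
#'   `1..k_true`; the realized kernel is attached as attribute `"kernel"`.
#' @export
simulate_state_sequence <- function(subject_sensitivity, condition, config,
                                    seed = 1) {
  P <- transition_kernel(condition, subject_sensitivity, config)
  k <- config$k_true
  n <- config$n_frames
  cum <- t(apply(P, 1, cumsum))
  s <- integer(n)
  with_seed(seed, {
    s[1] <- sample.int(k, 1)
    u <- runif(n - 1)
    for (t in seq_len(n - 1)) {
      s[t + 1] <- 1L + sum(u[t] > cum[s[t], ])
    }
  })
  attr(s, "kernel") <- P
  s
}

#' Synthesize a ROI time series from a latent state sequence
#'
#' Frame t is `amplitude * centroid[state_t]` plus per-ROI AR(1) noise, a
#' shared slow sinusoidal drift (period 128 s), and motion-spike artifacts at
#' Bernoulli(`spike_rate`) frames. The scan carries six motion regressors
#' (injected spikes appear as >0.5 mm translation steps, so spike frames have
#' FD > 0.5) and three tissue regressors (CSF, WM, global) whose global
#' column tracks the injected drift and spikes.
#'
#' @param sequence Integer state sequence (values index `centroids` rows).
#' @param centroids State centroid matrix (`k` x `n_rois`).
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @param subject_id,condition Labels attached to the scan.
#' @return A [roi_timeseries()] object; the spike frames are attached as
#'   attribute `"spike_frames"`.
#' @export
simulate_roi_timeseries <- function(sequence, centroids, config, seed = 1,
                                    subject_id = "S01", condition = "PL") {
  assert_that(all(sequence >= 1 & sequence <= nrow(centroids)),
              "sequence values must index centroid rows")
  n <- length(sequence)
  p <- ncol(centroids)
  tr <- config$tr_seconds
  with_seed(seed, {
    signal_mat <- config$amplitude * centroids[sequence, , drop = FALSE]

    innov <- matrix(
      rnorm(n * p, sd = config$noise_sd * sqrt(1 - config$ar_coeff^2)), n, p
    )
    noise <- if (config$ar_coeff != 0) {
      apply(innov, 2, function(x) {
        as.numeric(stats::filter(x, config$ar_coeff, method = "recursive"))
      })
    } else {
      innov
    }

    phase <- runif(1, 0, 2 * pi)
    drift <- config$drift_amp * sin(2 * pi * (seq_len(n) * tr) / 128 + phase)

    spike <- runif(n) < config$spike_rate
    spike_mat <- matrix(0, n, p)
    if (any(spike)) {
      spike_mat[spike, ] <- rnorm(sum(spike) * p, sd = 4 * config$amplitude)
    }

    data <- signal_mat + noise + drift + spike_mat
    dimnames(data) <- list(NULL, colnames(centroids))

    trans <- apply(matrix(rnorm(n * 3, sd = 0.005), n, 3), 2, cumsum)
    rot <- apply(matrix(rnorm(n * 3, sd = 1e-4), n, 3), 2, cumsum)
    if (any(spike)) {
      trans[spike, 1] <- trans[spike, 1] +
        (0.6 + abs(rnorm(sum(spike), sd = 0.2))) * sign(rnorm(sum(spike)) + 0.5)
    }
    tissue_ar <- function() {
      as.numeric(stats::filter(rnorm(n, sd = 5), 0.8, method = "recursive"))
    }
    glob <- drift + rowMeans(spike_mat) + rnorm(n, sd = 1)
    confounds <- cbind(trans, rot, tissue_ar(), tissue_ar(), glob)
    colnames(confounds) <- c("trans_x", "trans_y", "trans_z",
                             "rot_x", "rot_y", "rot_z",
                             "csf", "wm", "global")

    ts <- roi_timeseries(data, tr_seconds = tr, subject_id = subject_id,
                         condition = condition, confounds = confounds)
    attr(ts, "spike_frames") <- which(spike)
    ts
  })
}

# Ground-truth per-scan metrics straight from a latent sequence (no gaps).
truth_metrics <- function(sequence, k, tr_seconds) {
  r <- rle(as.integer(sequence))
  fo <- tabulate(sequence, nbins = k) / length(sequence)
  dwell <- vapply(seq_len(k), function(s) {
    len <- r$lengths[r$values == s]
    if (length(len) == 0) 0 else mean(len) * tr_seconds
  }, numeric(1))
  list(fractional_occupancy = fo, dwell_time = dwell)
}

#' Generate a full synthetic cohort
#'
#' Draws, for each subject: per-striatal-ROI D1R availability (and D2R under
#' both conditions), a receptor-linked sensitivity scalar, one PL and one MP
#' latent state sequence, optionally the corresponding ROI time series, and
#' behavior. The mediation path is planted as
#' D1R -> sensitivity -> MP persistence boost -> FPN+ dwell-time gain ->
#' 2-ball response-time reduction; IQ is drawn independently of that path.
#' Ball-track accuracy is simulated as 15 Bernoulli probe responses per scan
#' (3 cycles x 5 response intervals), so observed accuracies lie on the grid
#' `{0, 1/15, ..., 1}`.
#'
#' @param config A [cohort_config()].
#' @param timeseries If `FALSE`, skip BOLD synthesis and return only latent
#'   sequences, receptor values and behavior (useful for large simulation
#'   studies of the inference stages).
#' @return A list of class `synthetic_cohort` with elements `scans`,
#'   `templates`, `centroids`, `subjects`, `d1r_roi`, `d2r_pl_roi`,
#'   `d2r_mp_roi`, `truth`, `config`.
#' @export
generate_cohort <- function(config = cohort_config(), timeseries = TRUE) {
  validate_config(config)
  n <- config$n_subjects
  k <- config$k_true
  tr <- config$tr_seconds
  seeds <- split_seed(config$seed, 4 + n)

  templates <- generate_network_templates(config$n_rois, seeds[1])
  centroids <- generate_centroids(templates, k)
  striatal <- templates$roi_name[templates$network == "SUB"]
  ids <- sprintf("S%02d", seq_len(n))

  receptors <- with_seed(seeds[2], {
    mu1 <- rnorm(n, 2.0, 0.3)
    d1r <- mu1 + matrix(rnorm(n * length(striatal), sd = 0.15),
                        n, length(striatal))
    mu2 <- rnorm(n, 2.5, 0.35)
    d2r_pl <- mu2 + matrix(rnorm(n * length(striatal), sd = 0.15),
                           n, length(striatal))
    occ <- pmin(pmax(rnorm(n, 0.2, 0.03), 0.05), 0.5)
    d2r_mp <- d2r_pl * (1 - occ)
    list(d1r = d1r, d2r_pl = d2r_pl, d2r_mp = d2r_mp)
  })
  dimnames(receptors$d1r) <- list(ids, striatal)
  dimnames(receptors$d2r_pl) <- list(ids, striatal)
  dimnames(receptors$d2r_mp) <- list(ids, striatal)

  d1r_mean <- rowMeans(receptors$d1r)
  sensitivity <- with_seed(seeds[3], {
    z_d1r <- as.numeric(scale(d1r_mean))
    z <- config$mediation_a * z_d1r +
      sqrt(max(0, 1 - config$mediation_a^2)) * rnorm(n)
    1 + config$sensitivity_slope * z
  })

  scans <- list()
  truth_seq <- list()
  truth_kernels <- list()
  dwell_rows <- list()
  for (i in seq_len(n)) {
    for (cond in c("PL", "MP")) {
      scan_id <- paste(ids[i], cond, sep = "_")
      sseed <- split_seed(seeds[4 + i], 4)
      off <- if (cond == "PL") 0 else 2
      seq_i <- simulate_state_sequence(sensitivity[i], cond, config,
                                       seed = sseed[1 + off])
      truth_seq[[scan_id]] <- as.integer(seq_i)
      truth_kernels[[scan_id]] <- attr(seq_i, "kernel")
      tm <- truth_metrics(seq_i, k, tr)
      dwell_rows[[scan_id]] <- tibble::tibble(
        subject = ids[i], condition = cond, state = rownames(centroids),
        fractional_occupancy = tm$fractional_occupancy,
        dwell_time = tm$dwell_time
      )
      if (timeseries) {
        scans[[scan_id]] <- simulate_roi_timeseries(
          seq_i, centroids, config, seed = sseed[2 + off],
          subject_id = ids[i], condition = cond
        )
      }
    }
  }
  truth_tbl <- dplyr::bind_rows(dwell_rows)

  fpn_delta <- truth_tbl |>
    dplyr::filter(.data$state == "FPN+") |>
    dplyr::select("subject", "condition", "dwell_time") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "dwell_time") |>
    dplyr::mutate(ddwell = .data$MP - .data$PL)
  ddwell <- fpn_delta$ddwell[match(ids, fpn_delta$subject)]

  subjects <- with_seed(seeds[4], {
    rt2_pl <- rnorm(n, 0.65, 0.08)
    rt2_mp <- pmax(0.2, rt2_pl - config$mediation_b * ddwell +
                     rnorm(n, sd = 0.05))
    rt3_pl <- rnorm(n, 0.75, 0.09)
    rt3_mp <- pmax(0.2, rt3_pl + rnorm(n, sd = 0.05))
    tibble::tibble(
      subject = ids,
      d1r_mean = d1r_mean,
      rt_2ball_pl = rt2_pl, rt_2ball_mp = rt2_mp,
      rt_3ball_pl = rt3_pl, rt_3ball_mp = rt3_mp,
      acc_2ball_pl = rbinom(n, 15, 0.903) / 15,
      acc_2ball_mp = rbinom(n, 15, 0.970) / 15,
      acc_3ball_pl = rbinom(n, 15, 0.890) / 15,
      acc_3ball_mp = rbinom(n, 15, 0.948) / 15,
      iq = rnorm(n, 110, 12)
    )
  })

  structure(list(
    scans = if (timeseries) scans else NULL,
    templates = templates,
    centroids = centroids,
    subjects = subjects,
    d1r_roi = receptors$d1r,
    d2r_pl_roi = receptors$d2r_pl,
    d2r_mp_roi = receptors$d2r_mp,
    truth = list(
      sequences = truth_seq,
      kernels = truth_kernels,
      sensitivity = stats::setNames(sensitivity, ids),
      metrics = truth_tbl,
      ddwell_fpn = stats::setNames(ddwell, ids)
    ),
    config = config
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cfg <- x$config
  cat("<synthetic_cohort> ", cfg$n_subjects, " subjects x 2 conditions, ",
      cfg$n_frames, " frames x ", cfg$n_rois, " ROIs, k_true = ",
      cfg$k_true, "\n", sep = "")
  cat("  scans: ", if (is.null(x$scans)) "not synthesized" else
    length(x$scans), "\n", sep = "")
  invisible(x)
}
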