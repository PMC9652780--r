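# Synthetic-data generators for a lateralized visual-working-memory study:
# delayed-recognition trials, delayed-recall (estimation) trials, Likert
# similarity trials, and epoched EEG with an injected contralateral delay
# component. All generators store ground truth so downstream estimators can
# be validated by parameter recovery.

#' Printed Likert offset sets per stimulus domain
#'
#' The offset grids (in each domain's native units) at which similarity
#' judgements are sampled: orientation offsets up to 90 degrees, colour-wheel
#' offsets up to 180 degrees, luminance offsets up to 128 RGB steps.
#'
#' @param domain one of `"orientation"`, `"color"`, `"luminance"`.
#' @return Numeric vector of offsets.
#' @export
likert_offsets <- function(domain = c("orientation", "color", "luminance")) {
  domain <- match.arg(domain)
  switch(domain,
    orientation = c(0, 2.5, 5, 10, 15, 20, 25, 30, 35, 40, 45, 60, 75, 90),
    color       = c(0, 5, 10, 20, 30, 40, 50, 60, 70, 80, 90, 120, 150, 180),
    luminance   = c(0, 3, 7, 14, 21, 28, 35, 42, 49, 56, 64, 85, 106, 128)
  )
}

default_cluster_map <- function() {
  c(P3 = "left", P5 = "left", P7 = "left", PO3 = "left", PO7 = "left", O1 = "left",
    P4 = "right", P6 = "right", P8 = "right", PO4 = "right", PO8 = "right", O2 = "right",
    Pz = "midline", Oz = "midline",
    Fp1 = "midline", Fp2 = "midline", HEOG = "midline")
}

#' Trial timing specification
#'
#' Event timing of a trial: cue, jittered cue-stimulus interval (CSI),
#' bilateral sample array, unfilled delay, probe. All times in seconds.
#' Epochs are locked to sample-array onset; the probe appears at
#' `sample_dur + delay_dur` after sample onset.
#'
#' @param cue_dur cue duration.
#' @param csi_range two-element range of the jittered CSI.
#' @param csi_step jitter step; `csi_range` must be multiples of it.
#' @param sample_dur sample-array duration.
#' @param delay_dur unfilled delay duration.
#' @param probe_window response window after probe onset.
#' @param epoch_window epoch limits relative to sample onset.
#' @param baseline_window baseline interval relative to sample onset.
#' @return An object of class `timing_spec`.
#' @export
timing_spec <- function(cue_dur = 0.200,
                        csi_range = c(0.400, 0.600),
                        csi_step = 0.050,
                        sample_dur = 0.750,
                        delay_dur = 0.900,
                        probe_window = 2.000,
                        epoch_window = c(-1.5, 2.5),
                        baseline_window = c(-0.200, 0)) {
  stopifnot(length(csi_range) == 2, csi_range[1] <= csi_range[2],
            csi_step > 0, sample_dur > 0, delay_dur > 0,
            length(epoch_window) == 2, epoch_window[1] < epoch_window[2],
            length(baseline_window) == 2, baseline_window[1] < baseline_window[2])
  if (any(abs(csi_range / csi_step - round(csi_range / csi_step)) > 1e-9))
    stop("csi_range values must be multiples of csi_step")
  structure(list(cue_dur = cue_dur, csi_range = csi_range, csi_step = csi_step,
                 sample_dur = sample_dur, delay_dur = delay_dur,
                 probe_window = probe_window, epoch_window = epoch_window,
                 baseline_window = baseline_window,
                 probe_onset = sample_dur + delay_dur),
            class = "timing_spec")
}

#' Generator configuration
#'
#' Bundles every ground-truth parameter the synthetic study uses. Defaults
#' describe a plausible mid-sized lateralized change-detection /
#' delayed-estimation study; see the methods vignette for the rationale of
#' each default.
#'
#' @param seed integer RNG seed used by the generators.
#' @param n_subjects number of simulated subjects (default 28, a typical
#'   enrolled sample for studies of the CDA).
#' @param trials_per_cell trials per subject x condition x load cell
#'   (default 180, matching common per-load trial counts; must be even so
#'   match/nonmatch probes can be balanced).
#' @param capacity_k item capacity; a single value or a named vector with
#'   elements `homogeneous` and `heterogeneous`.
#' @param capacity_sd between-subject SD of capacity (items).
#' @param guess_rate_recognition probability of responding "match" when the
#'   probed item is not in memory.
#' @param mixture_truth list with `pT`, `pN`, `pU` (summing to 1) and `kappa`
#'   (von Mises concentration on the doubled circle) for recall generation.
#' @param tcc_truth list with `dprime` and `swap_prob` for TCC-generated data.
#' @param similarity_shape list describing the generative similarity decay;
#'   `scale_deg` is the exponential decay constant in degrees of the common
#'   180-degree space (offsets are scaled so each domain spans 0--90).
#' @param likert_noise_sd SD of the Gaussian rating noise (rating units).
#' @param rt list of lognormal RT parameters (`meanlog`, `sdlog`,
#'   `load_slope`, `condition_shift`).
#' @param eeg list of EEG-generator parameters: `sfreq` (Hz), `cluster_map`
#'   (named channel -> side vector), `cda_amp_by_load` (muV, negative, named
#'   by load), `bilateral_effect_amp` (muV added to BOTH hemispheres on
#'   homogeneous trials), `noise_sd` (muV), `pink_noise_frac`,
#'   `saccade_rate`, `saccade_amp` (muV), `blink_rate`, `blink_amp` (muV).
#' @return An object of class `gen_config`.
#' @export
gen_config <- function(seed = 1L,
                       n_subjects = 28L,
                       trials_per_cell = 180L,
                       capacity_k = c(homogeneous = 2.2, heterogeneous = 2.8),
                       capacity_sd = 0.4,
                       guess_rate_recognition = 0.5,
                       mixture_truth = list(pT = 0.7, pN = 0.15, pU = 0.15, kappa = 12),
                       tcc_truth = list(dprime = 2, swap_prob = 0.1),
                       similarity_shape = list(type = "exponential", scale_deg = 20),
                       likert_noise_sd = 0.5,
                       rt = list(meanlog = log(0.6), sdlog = 0.25,
                                 load_slope = 0.04, condition_shift = 0.04),
                       eeg = list()) {
  eeg_defaults <- list(
    sfreq = 250,
    cluster_map = default_cluster_map(),
    cda_amp_by_load = c(`1` = -0.9, `3` = -1.8, `5` = -1.8),
    bilateral_effect_amp = -1.0,
    noise_sd = 10,
    pink_noise_frac = 0.6,
    saccade_rate = 0.05,
    saccade_amp = 40,
    blink_rate = 0.05,
    blink_amp = 150)
  eeg <- utils::modifyList(eeg_defaults, eeg)

  if (length(capacity_k) == 1L)
    capacity_k <- c(homogeneous = unname(capacity_k), heterogeneous = unname(capacity_k))
  stopifnot(all(c("homogeneous", "heterogeneous") %in% names(capacity_k)),
            all(capacity_k >= 0), capacity_sd >= 0)

  mt <- mixture_truth
  if (abs(mt$pT + mt$pN + mt$pU - 1) > 1e-9)
    stop("mixture_truth probabilities must sum to 1 (within 1e-9)")
  probs <- c(mt$pT, mt$pN, mt$pU, guess_rate_recognition,
             tcc_truth$swap_prob, eeg$pink_noise_frac,
             eeg$saccade_rate, eeg$blink_rate)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (mt$kappa <= 0) stop("mixture_truth$kappa must be > 0")
  if (eeg$sfreq <= 0) stop("eeg$sfreq must be > 0")
  if (tcc_truth$dprime < 0) stop("tcc_truth$dprime must be >= 0")
  if (!all(c("left", "right") %in% eeg$cluster_map))
    stop("cluster_map must contain left and right cluster channels")

  # Saturation: beyond capacity the contralateral component stops growing --
  # its magnitude must not increase between loads that both exceed capacity.
  amp <- eeg$cda_amp_by_load
  if (is.null(names(amp))) stop("cda_amp_by_load must be named by load")
  loads <- as.numeric(names(amp))
  kmax <- max(capacity_k)
  ord <- order(loads)
  loads <- loads[ord]; amp <- amp[ord]
  for (i in seq_along(loads)[-1]) {
    if (loads[i - 1] >= kmax && loads[i] >= kmax &&
        abs(amp[i]) > abs(amp[i - 1]) + 1e-9)
      stop("cda_amp_by_load must saturate: magnitude may not grow between loads beyond capacity_k")
  }
  eeg$cda_amp_by_load <- amp

  structure(list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
                 trials_per_cell = as.integer(trials_per_cell),
                 capacity_k = capacity_k, capacity_sd = capacity_sd,
                 guess_rate_recognition = guess_rate_recognition,
                 mixture_truth = mt, tcc_truth = tcc_truth,
                 similarity_shape = similarity_shape,
                 likert_noise_sd = likert_noise_sd,
                 rt = rt, eeg = eeg),
            class = "gen_config")
}

#' @export
print.gen_config <- function(x, ...) {
  cat("<gen_config> seed", x$seed, "|", x$n_subjects, "subjects x",
      x$trials_per_cell, "trials/cell\n")
  cat("  capacity k:", paste(sprintf("%s=%.2f", names(x$capacity_k), x$capacity_k),
                             collapse = ", "),
      sprintf("(between-subject sd %.2f)\n", x$capacity_sd))
  mt <- x$mixture_truth
  cat(sprintf("  mixture truth: pT=%.2f pN=%.2f pU=%.2f kappa=%.1f\n",
              mt$pT, mt$pN, mt$pU, mt$kappa))
  cat(sprintf("  tcc truth: d'=%.2f swap=%.2f\n",
              x$tcc_truth$dprime, x$tcc_truth$swap_prob))
  cat(sprintf("  eeg: %g Hz, noise sd %g uV (pink frac %g), CDA %s uV\n",
              x$eeg$sfreq, x$eeg$noise_sd, x$eeg$pink_noise_frac,
              paste(sprintf("%s:%g", names(x$eeg$cda_amp_by_load),
                            x$eeg$cda_amp_by_load), collapse = " ")))
  invisible(x)
}

# Per-subject capacities for one condition, truncated at zero.
subject_capacities <- function(cfg, condition) {
  pmax(stats::rnorm(cfg$n_subjects, cfg$capacity_k[[condition]], cfg$capacity_sd), 0)
}

#' Generate delayed-recognition (change-detection) trials
#'
#' Simulates lateralized change-detection behaviour under a slot-style
#' capacity model: with probability `min(k / load, 1)` the probed item is in
#' memory and the response is correct; otherwise the subject responds
#' "match" with probability `guess_rate_recognition`. Match/nonmatch probes
#' and cue sides are balanced within every subject x condition x load cell.
#'
#' @param cfg a [gen_config()].
#' @param timing a [timing_spec()].
#' @param loads set sizes to simulate (subset of 1, 3, 5).
#' @return A data.frame of trials in the behavioural table dialect (one row
#'   per trial), including the latent `in_memory` truth column.
#' @export
gen_recognition_trials <- function(cfg, timing = timing_spec(), loads = c(1, 3, 5)) {
  stopifnot(inherits(cfg, "gen_config"))
  if (!all(loads %in% c(1, 3, 5))) stop("loads must be a subset of {1, 3, 5}")
  if (cfg$trials_per_cell %% 2L != 0L)
    stop("trials_per_cell must be even to balance match/nonmatch probes")
  with_seed(cfg$seed, {
    conditions <- c("homogeneous", "heterogeneous")
    caps <- sapply(conditions, function(cond) subject_capacities(cfg, cond))
    if (!is.matrix(caps))
      caps <- matrix(caps, nrow = cfg$n_subjects, dimnames = list(NULL, conditions))
    rows <- list()
    for (s in seq_len(cfg$n_subjects)) {
      for (cond in conditions) {
        k_s <- unname(caps[s, cond])
        for (load in loads) {
          n <- cfg$trials_per_cell
          is_match <- sample(rep(c(TRUE, FALSE), n / 2))
          cue_side <- sample(rep(c("left", "right"), n / 2))
          probe_domain <- if (cond == "homogeneous") rep("orientation", n)
                          else sample(c("orientation", "color", "luminance"), n, replace = TRUE)
          trial_type <- if (cond == "homogeneous") sprintf("%dO", load) else {
            switch(as.character(load),
                   `1` = paste0("1", toupper(substr(probe_domain, 1, 1))),
                   `3` = rep("1O1C1L", n),
                   `5` = sample(c("1O1C2L", "1O2C1L", "2O1C1L"), n, replace = TRUE))
          }
          p_mem <- min(k_s / load, 1)
          in_memory <- stats::runif(n) < p_mem
          guess_match <- stats::runif(n) < cfg$guess_rate_recognition
          response <- ifelse(in_memory,
                             ifelse(is_match, "match", "nonmatch"),
                             ifelse(guess_match, "match", "nonmatch"))
          rt <- stats::rlnorm(n, cfg$rt$meanlog + cfg$rt$load_slope * (load - 1) +
                                   cfg$rt$condition_shift * (cond == "homogeneous"),
                              cfg$rt$sdlog)
          timeout <- rt > timing$probe_window
          response[timeout] <- NA
          rt[timeout] <- NA
          rows[[length(rows) + 1L]] <- data.frame(
            subject = sprintf("S%02d", s), experiment = "recognition",
            block = NA_integer_, condition = cond, trial_type = trial_type,
            load = load, cue_side = cue_side, probe_domain = probe_domain,
            is_match = is_match, response = response, rt_s = rt,
            in_memory = in_memory, capacity_true = k_s,
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Generate delayed-recall (estimation) trials
#'
#' Responses follow a target/nontarget/guess mixture: with probability `pT`
#' the response is the target plus von Mises noise (concentration `kappa` on
#' the doubled circle), with `pN` a randomly chosen nontarget plus the same
#' noise, and with `pU` a uniform draw over the 180-unit space. Trial types
#' without nontargets (`1O`, `1O1C1L`) cannot produce swap responses, so
#' their `pN` mass is folded into the target/guess components by
#' renormalization. The generating component of every trial is stored in
#' `truth_component`.
#'
#' @param cfg a [gen_config()].
#' @param trial_types recall trial types to simulate.
#' @param n_trials trials per subject per trial type (default
#'   `cfg$trials_per_cell`).
#' @return A data.frame of recall trials with ground-truth labels.
#' @export
gen_recall_trials <- function(cfg, trial_types = c("1O", "3O", "1O1C1L"),
                              n_trials = NULL) {
  stopifnot(inherits(cfg, "gen_config"))
  bad <- setdiff(trial_types, c("1O", "1C", "1L", "3O", "1O1C1L"))
  if (length(bad)) stop("unknown trial types: ", paste(bad, collapse = ", "))
  if (is.null(n_trials)) n_trials <- cfg$trials_per_cell
  mt <- cfg$mixture_truth
  with_seed(cfg$seed + 1L, {
    rows <- list()
    for (s in seq_len(cfg$n_subjects)) {
      for (tt in trial_types) {
        has_nt <- tt == "3O"
        n <- n_trials
        target <- stats::runif(n, 0, 180)
        if (has_nt) {
          nt1 <- wrap180(target + stats::runif(n, 20, 160))
          nt2 <- wrap180(target - stats::runif(n, 20, 160))
          w <- c(mt$pT, mt$pN, mt$pU)
        } else {
          nt1 <- nt2 <- rep(NA_real_, n)
          # no nontargets: swap mass is impossible, renormalize over (pT, pU)
          w <- c(mt$pT, 0, mt$pU) / (mt$pT + mt$pU)
        }
        comp <- sample(c("target", "nontarget", "guess"), n, replace = TRUE, prob = w)
        eps <- rvm_deg180(n, mt$kappa)
        center <- target
        if (has_nt) {
          pick2 <- stats::runif(n) < 0.5
          center[comp == "nontarget"] <- ifelse(pick2, nt2, nt1)[comp == "nontarget"]
        }
        response <- wrap180(center + eps)
        response[comp == "guess"] <- stats::runif(sum(comp == "guess"), 0, 180)
        rt <- stats::rlnorm(n, cfg$rt$meanlog + 0.4, cfg$rt$sdlog)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = sprintf("S%02d", s), experiment = "recall",
          block = NA_integer_, condition = NA_character_, trial_type = tt,
          load = if (has_nt || tt == "1O1C1L") 3L else 1L,
          probe_domain = "orientation",
          target_deg = target, nontarget1_deg = nt1, nontarget2_deg = nt2,
          probed_location = sample.int(if (has_nt) 3L else 1L, n, replace = TRUE),
          response_deg = response, rt_s = rt, truth_component = comp,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

# Generative similarity: exponential decay over offsets scaled to the common
# 180-degree space (so every domain's maximum offset maps to 90 degrees).
similarity_truth <- function(cfg, offset, domain) {
  grid <- likert_offsets(domain)
  off90 <- offset / max(grid) * 90
  switch(cfg$similarity_shape$type,
    exponential = exp(-off90 / cfg$similarity_shape$scale_deg),
    stop("unknown similarity_shape type"))
}

#' Generate Likert similarity trials
#'
#' Ratings are `clip(round(1 + 6 * s(offset) + noise), 1, 7)` where `s` is
#' the configured decaying similarity shape; identical pairs (offset 0) have
#' modal rating 7 and maximally dissimilar pairs modal rating 1.
#'
#' @param cfg a [gen_config()].
#' @param domain stimulus domain.
#' @param reps repetitions per offset per subject.
#' @return A data.frame of Likert trials (`domain`, `offset`, `rating`).
#' @export
gen_likert_trials <- function(cfg, domain = c("orientation", "color", "luminance"),
                              reps = 10L) {
  stopifnot(inherits(cfg, "gen_config"))
  domain <- match.arg(domain)
  offs <- likert_offsets(domain)
  with_seed(cfg$seed + 2L, {
    rows <- lapply(seq_len(cfg$n_subjects), function(s) {
      offset <- rep(offs, each = reps)
      s_true <- similarity_truth(cfg, offset, domain)
      rating <- round(1 + 6 * s_true + stats::rnorm(length(offset), 0, cfg$likert_noise_sd))
      data.frame(subject = sprintf("S%02d", s), domain = domain,
                 offset = offset, rating = pmin(pmax(rating, 1), 7),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

# Pink (1/f) noise, unit variance, columns independent: shape white noise in
# the frequency domain with amplitude 1/sqrt(f). Computed at the next power
# of two (then truncated) so the FFTs stay cheap; the scalar normalization
# follows from Parseval's identity.
pink_noise <- function(n_samples, n_series) {
  nfft <- 2^ceiling(log2(n_samples))
  x <- matrix(stats::rnorm(nfft * n_series), nfft, n_series)
  X <- stats::mvfft(x)
  k <- c(1, seq_len(nfft - 1))            # avoid dividing by zero at DC
  k <- pmin(k, nfft - k + 1)              # two-sided spectrum symmetry
  w <- 1 / sqrt(k)
  p <- Re(stats::mvfft(X * w, inverse = TRUE)) / nfft
  p[seq_len(n_samples), , drop = FALSE] / sqrt(mean(w^2))
}

#' Generate epoched EEG for a table of lateralized trials
#'
#' Injects, per trial, a sustained negative deflection over the sample and
#' delay periods into the posterior cluster channels of the hemisphere
#' contralateral to the cued side (`cda_amp_by_load[load]` muV) and, on
#' homogeneous trials, an additional bilateral component
#' (`bilateral_effect_amp` muV) into both hemispheres; adds pink + white
#' noise, step-like HEOG saccade artifacts held to the epoch end, and
#' high-amplitude blink transients on frontal channels. Ground-truth
#' artifact annotations are stored in the returned [epoch_set()].
#'
#' @param cfg a [gen_config()].
#' @param timing a [timing_spec()].
#' @param trials data.frame with at least `subject`, `condition`, `load`,
#'   `cue_side` and `trial_type` columns.
#' @param seed optional RNG seed overriding `cfg$seed + 3`.
#' @return An [epoch_set()] with `meta = trials` and artifact annotations.
#' @export
gen_eeg_epochs <- function(cfg, timing = timing_spec(), trials, seed = NULL) {
  stopifnot(inherits(cfg, "gen_config"), inherits(timing, "timing_spec"))
  eeg <- cfg$eeg
  cl <- eeg$cluster_map
  ch_names <- names(cl)
  if (!all(c("left", "right") %in% cl))
    stop("cluster_map must define left and right cluster channels")
  sig_end <- timing$sample_dur + timing$delay_dur
  if (timing$epoch_window[2] < sig_end)
    stop("epoch window ends before the sample + delay interval")
  sfreq <- eeg$sfreq
  times <- seq(timing$epoch_window[1], timing$epoch_window[2], by = 1 / sfreq)
  n_samp <- length(times)
  n_ch <- length(ch_names)
  n_tr <- nrow(trials)
  left_cluster <- which(cl == "left" & !ch_names %in% c("Fp1", "Fp2", "HEOG"))
  right_cluster <- which(cl == "right" & !ch_names %in% c("Fp1", "Fp2", "HEOG"))
  frontal <- which(ch_names %in% c("Fp1", "Fp2"))
  heog <- which(ch_names == "HEOG")
  if (length(heog) != 1L) stop("cluster_map must contain exactly one HEOG channel")

  with_seed(if (is.null(seed)) cfg$seed + 3L else seed, {
    sig_idx <- which(times >= 0 & times < sig_end)
    data <- array(0, dim = c(n_tr, n_ch, n_samp))
    if (eeg$noise_sd > 0) {
      frac <- eeg$pink_noise_frac
      noise <- matrix(0, n_samp, n_tr * n_ch)
      if (frac > 0) noise <- noise + sqrt(frac) * pink_noise(n_samp, n_tr * n_ch)
      if (frac < 1) noise <- noise + sqrt(1 - frac) *
          matrix(stats::rnorm(n_samp * n_tr * n_ch), n_samp, n_tr * n_ch)
      data <- aperm(array(noise * eeg$noise_sd, dim = c(n_samp, n_tr, n_ch)), c(2, 3, 1))
    }

    amp_lookup <- eeg$cda_amp_by_load
    amp_tr <- amp_lookup[as.character(trials$load)]
    amp_tr[is.na(amp_tr)] <- 0
    bil_tr <- if (is.null(trials$condition)) rep(0, n_tr) else
      eeg$bilateral_effect_amp * (trials$condition %in% "homogeneous")
    # contralateral component goes to the hemisphere opposite the cued side;
    # the bilateral component to both clusters (trial index varies fastest,
    # so a length-n_tr vector recycles correctly over channels and samples)
    add_left <- ifelse(trials$cue_side == "right", amp_tr, 0) + bil_tr
    add_right <- ifelse(trials$cue_side == "left", amp_tr, 0) + bil_tr
    data[, left_cluster, sig_idx] <- data[, left_cluster, sig_idx] + add_left
    data[, right_cluster, sig_idx] <- data[, right_cluster, sig_idx] + add_right

    sacc <- stats::runif(n_tr) < eeg$saccade_rate
    sacc_lat <- rep(NA_real_, n_tr)
    if (any(sacc)) {
      lat <- stats::runif(sum(sacc), times[1] + 0.1, sig_end)
      sacc_lat[sacc] <- lat
      sgn <- sample(c(-1, 1), sum(sacc), replace = TRUE)
      for (j in seq_along(lat)) {
        i <- which(sacc)[j]
        idx <- which(times >= lat[j])
        data[i, heog, idx] <- data[i, heog, idx] + sgn[j] * eeg$saccade_amp
      }
    }

    blink <- stats::runif(n_tr) < eeg$blink_rate
    blink_lat <- rep(NA_real_, n_tr)
    if (any(blink)) {
      lat <- stats::runif(sum(blink), times[1] + 0.2, times[n_samp] - 0.2)
      blink_lat[blink] <- lat
      width <- 0.3
      peak <- eeg$blink_amp * stats::runif(sum(blink), 1.05, 1.4)
      for (j in seq_along(lat)) {
        i <- which(blink)[j]
        idx <- which(abs(times - lat[j]) <= width / 2)
        shape <- cos(pi * (times[idx] - lat[j]) / width)^2
        for (ch in frontal)
          data[i, ch, idx] <- data[i, ch, idx] + peak[j] * shape
      }
    }

    epoch_set(data = data, sfreq = sfreq, t0 = times[1], ch_names = ch_names,
              ch_side = unname(cl), heog_ch = "HEOG", meta = trials,
              annotations = data.frame(trial = seq_len(n_tr), saccade = sacc,
                                       saccade_latency_s = sacc_lat,
                                       blink = blink, blink_latency_s = blink_lat))
  })
}
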