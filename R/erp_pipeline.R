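# ERP pipeline: epoch container, baseline correction, amplitude and
# sliding-window HEOG artifact rejection, subject exclusion, contralateral /
# ipsilateral cluster averaging, and window means (the CDA).

#' Epoched EEG container
#'
#' Holds a trials x channels x samples voltage array (microvolts) together
#' with channel geometry and per-trial metadata.
#'
#' @param data numeric array `[trials, channels, samples]` in muV.
#' @param sfreq sampling rate in Hz.
#' @param t0 time of the first sample relative to sample-array onset (s).
#' @param ch_names channel labels.
#' @param ch_side `"left"`, `"right"` or `"midline"` per channel.
#' @param cluster_mask logical per channel: belongs to a lateralized
#'   posterior cluster. Defaults to all non-midline channels.
#' @param heog_ch label of the horizontal-EOG channel (or `NA`).
#' @param meta data.frame of per-trial metadata (one row per trial).
#' @param annotations optional per-trial artifact ground truth (synthetic
#'   data only).
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, sfreq, t0, ch_names, ch_side,
                      cluster_mask = NULL, heog_ch = NA_character_,
                      meta = NULL, annotations = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3, sfreq > 0)
  if (any(!is.finite(data))) stop("epoch data must be finite")
  n_ch <- dim(data)[2]
  stopifnot(length(ch_names) == n_ch, length(ch_side) == n_ch,
            all(ch_side %in% c("left", "right", "midline")))
  if (is.null(cluster_mask)) cluster_mask <- ch_side %in% c("left", "right")
  if (!any(cluster_mask & ch_side == "left") || !any(cluster_mask & ch_side == "right"))
    stop("need at least one left-cluster and one right-cluster channel")
  if (!is.null(meta) && nrow(meta) != dim(data)[1])
    stop("meta must have one row per trial")
  structure(list(data = data, sfreq = sfreq, t0 = t0, ch_names = ch_names,
                 ch_side = ch_side, cluster_mask = cluster_mask,
                 heog_ch = heog_ch, meta = meta, annotations = annotations),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz, t = [%.3f, %.3f] s\n",
              d[1], d[2], d[3], x$sfreq, x$t0, x$t0 + (d[3] - 1) / x$sfreq))
  cat("  clusters: left {", paste(x$ch_names[x$cluster_mask & x$ch_side == "left"], collapse = " "),
      "} right {", paste(x$ch_names[x$cluster_mask & x$ch_side == "right"], collapse = " "), "}\n")
  invisible(x)
}

#' Epoch time axis
#' @param epochs an [epoch_set()].
#' @return Numeric vector of sample times (s) relative to sample onset.
#' @export
epoch_times <- function(epochs) {
  epochs$t0 + (seq_len(dim(epochs$data)[3]) - 1) / epochs$sfreq
}

#' Subset an epoch_set by trial
#' @param epochs an [epoch_set()].
#' @param keep logical or integer trial index.
#' @return The subsetted `epoch_set`.
#' @export
subset_epochs <- function(epochs, keep) {
  epochs$data <- epochs$data[keep, , , drop = FALSE]
  if (!is.null(epochs$meta)) epochs$meta <- epochs$meta[keep, , drop = FALSE]
  if (!is.null(epochs$annotations))
    epochs$annotations <- epochs$annotations[keep, , drop = FALSE]
  epochs
}

#' Analysis window specification
#'
#' @param name window label.
#' @param start,stop window limits in seconds relative to sample onset.
#'   Windows are half-open: samples with `start <= t < stop` are included.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(name, start, stop) {
  stopifnot(start < stop)
  structure(list(name = name, start = start, stop = stop), class = "window_spec")
}

#' Default analysis windows derived from the trial timing
#'
#' The sample window is a 500 ms interval beginning 200 ms after sample
#' onset; the delay window extends from 200 ms after sample offset to 50 ms
#' before probe onset (650 ms with the default timing); the baseline is the
#' 200 ms prestimulus interval.
#'
#' @param timing a [timing_spec()].
#' @return Named list of [window_spec()] objects (baseline, sample, delay).
#' @export
default_windows <- function(timing = timing_spec()) {
  list(baseline = window_spec("baseline", timing$baseline_window[1], timing$baseline_window[2]),
       sample = window_spec("sample", 0.200, 0.700),
       delay = window_spec("delay", timing$sample_dur + 0.200, timing$probe_onset - 0.050))
}

window_index <- function(epochs, window) {
  t <- epoch_times(epochs)
  idx <- which(t >= window$start - 1e-9 & t < window$stop - 1e-9)
  if (length(idx) == 0L)
    stop("window [", window$start, ", ", window$stop, ") outside the epoch span")
  if (window$start < t[1] - 1e-9 || window$stop > t[length(t)] + 1 / epochs$sfreq + 1e-9)
    stop("window [", window$start, ", ", window$stop, ") outside the epoch span")
  idx
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean voltage over the baseline
#' window.
#'
#' @param epochs an [epoch_set()].
#' @param window a [window_spec()]; default the 200 ms prestimulus interval.
#' @return The baseline-corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, window = default_windows()$baseline) {
  idx <- window_index(epochs, window)
  bl <- apply(epochs$data[, , idx, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(bl)  # recycles over the samples axis
  epochs
}

#' Flag trials exceeding an absolute amplitude threshold
#'
#' A trial is flagged when any sample on any channel strictly exceeds the
#' threshold in absolute value.
#'
#' @param epochs an [epoch_set()] (baseline-corrected).
#' @param threshold rejection threshold in muV.
#' @return Logical vector, `TRUE` for rejected trials.
#' @export
reject_amplitude <- function(epochs, threshold = 100) {
  apply(abs(epochs$data), 1, max) > threshold
}

#' Detect step-like HEOG deflections with a split-half sliding window
#'
#' A window of `win_s` seconds slides along the HEOG trace in steps of
#' `step_s`; within each window the difference mean(second half) -
#' mean(first half) is computed, and the trial is flagged if any absolute
#' difference strictly exceeds `thresh_uv` (the signature of a lateral
#' saccade).
#'
#' @param heog numeric matrix `[trials, samples]` of HEOG voltage (muV), or
#'   an [epoch_set()] with a designated HEOG channel.
#' @param sfreq sampling rate in Hz (taken from the epoch_set if given).
#' @param win_s sliding window length (s); must contain an even number of
#'   samples.
#' @param step_s step between window onsets (s).
#' @param thresh_uv rejection threshold (muV).
#' @return Logical vector, `TRUE` for flagged trials, with attribute
#'   `max_step` giving each trial's maximal absolute half-difference.
#' @export
detect_heog_steps <- function(heog, sfreq = NULL, win_s = 0.200,
                              step_s = 0.020, thresh_uv = 20) {
  if (inherits(heog, "epoch_set")) {
    ch <- match(heog$heog_ch, heog$ch_names)
    if (is.na(ch)) stop("epoch_set has no HEOG channel")
    sfreq <- heog$sfreq
    heog <- heog$data[, ch, , drop = TRUE]
    if (is.null(dim(heog))) heog <- matrix(heog, nrow = 1)
  }
  stopifnot(is.matrix(heog), !is.null(sfreq))
  w <- round(win_s * sfreq)
  if (w %% 2L != 0L) stop("window must contain an even number of samples")
  h <- w %/% 2L
  step <- max(1L, round(step_s * sfreq))
  n <- ncol(heog)
  if (n < w) stop("epoch shorter than the sliding window")
  starts <- seq(1L, n - w + 1L, by = step)
  cs <- cbind(0, t(apply(heog, 1, cumsum)))
  first_half <- (cs[, starts + h] - cs[, starts]) / h
  second_half <- (cs[, starts + w] - cs[, starts + h]) / h
  d <- abs(second_half - first_half)
  if (is.null(dim(d))) d <- matrix(d, nrow = nrow(heog))
  max_step <- apply(d, 1, max)
  structure(max_step > thresh_uv, max_step = max_step)
}

#' Exclude subjects with too few surviving trials
#'
#' A subject is excluded when any trial type retains fewer than `min_trials`
#' epochs after artifact rejection.
#'
#' @param meta per-trial metadata with `subject` and a trial-type column.
#' @param keep logical vector, `TRUE` for surviving trials.
#' @param min_trials minimum surviving trials per trial type.
#' @param type_col name of the trial-type column.
#' @return List with `excluded`, `retained` (subject ids) and the
#'   subject x trial-type `counts` table.
#' @export
exclude_low_trial_subjects <- function(meta, keep, min_trials = 75,
                                       type_col = "trial_type") {
  stopifnot(nrow(meta) == length(keep), type_col %in% names(meta))
  counts <- table(meta$subject[keep], meta[[type_col]][keep])
  all_types <- sort(unique(meta[[type_col]]))
  all_subj <- sort(unique(meta$subject))
  full <- matrix(0L, length(all_subj), length(all_types),
                 dimnames = list(all_subj, all_types))
  full[rownames(counts), colnames(counts)] <- counts
  bad <- apply(full, 1, function(r) any(r < min_trials))
  list(excluded = all_subj[bad], retained = all_subj[!bad], counts = full)
}

#' Contralateral and ipsilateral cluster waveforms
#'
#' Averages the left- and right-hemisphere posterior cluster channels and
#' assigns them, per trial, as contralateral or ipsilateral to the cued
#' side (right cluster is contralateral on left-cue trials and vice versa);
#' midline channels are never included. Waveforms are then trial-averaged
#' within each grouping cell.
#'
#' @param epochs an [epoch_set()] whose `meta` contains `cue_side` and the
#'   grouping columns.
#' @param by metadata columns defining the averaging cells.
#' @return An object of class `lateralized` with matrices `contra` and
#'   `ipsi` (cells x samples), the cell table, and `n_trials` per cell.
#' @export
lateralize <- function(epochs, by = c("subject", "condition", "load")) {
  meta <- epochs$meta
  stopifnot(!is.null(meta), "cue_side" %in% names(meta), all(by %in% names(meta)))
  left_ch <- which(epochs$cluster_mask & epochs$ch_side == "left")
  right_ch <- which(epochs$cluster_mask & epochs$ch_side == "right")
  if (!length(left_ch) || !length(right_ch)) stop("empty hemisphere cluster")
  cluster_mean <- function(idx) {
    acc <- epochs$data[, idx[1], ]
    for (j in idx[-1]) acc <- acc + epochs$data[, j, ]
    m <- acc / length(idx)
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    m
  }
  left_wave <- cluster_mean(left_ch)
  right_wave <- cluster_mean(right_ch)
  cue_left <- meta$cue_side == "left"
  contra_tr <- ifelse(cue_left, 1, 0) * right_wave + ifelse(cue_left, 0, 1) * left_wave
  ipsi_tr <- ifelse(cue_left, 1, 0) * left_wave + ifelse(cue_left, 0, 1) * right_wave
  cells <- interaction(meta[by], drop = TRUE, lex.order = TRUE)
  cell_levels <- levels(cells)
  agg <- function(m) t(sapply(cell_levels, function(cl) colMeans(m[cells == cl, , drop = FALSE])))
  first <- !duplicated(cells)
  info <- meta[first, by, drop = FALSE][match(cell_levels, cells[first]), , drop = FALSE]
  rownames(info) <- NULL
  structure(list(contra = agg(contra_tr), ipsi = agg(ipsi_tr),
                 cells = info, n_trials = as.integer(table(cells)[cell_levels]),
                 times = epoch_times(epochs), sfreq = epochs$sfreq),
            class = "lateralized")
}

#' @export
print.lateralized <- function(x, ...) {
  cat(sprintf("<lateralized> %d cells (%s) x %d samples\n",
              nrow(x$contra), paste(names(x$cells), collapse = " x "),
              ncol(x$contra)))
  invisible(x)
}

#' Window means of lateralized waveforms (the CDA)
#'
#' Time-averages the contralateral and ipsilateral waveforms over each
#' analysis window; the difference (contra - ipsi) over the delay window is
#' the contralateral delay activity.
#'
#' @param lat a [lateralize()] result.
#' @param windows list of [window_spec()] objects (default sample + delay).
#' @return A data.frame with one row per cell x window: `contra_mean`,
#'   `ipsi_mean`, `diff_mean` (muV), `window`, `n_trials_used`.
#' @export
window_means <- function(lat, windows = default_windows()[c("sample", "delay")]) {
  out <- list()
  for (w in windows) {
    idx <- which(lat$times >= w$start - 1e-9 & lat$times < w$stop - 1e-9)
    if (!length(idx)) stop("window '", w$name, "' outside the epoch span")
    contra <- rowMeans(lat$contra[, idx, drop = FALSE])
    ipsi <- rowMeans(lat$ipsi[, idx, drop = FALSE])
    out[[w$name]] <- cbind(lat$cells,
                           data.frame(window = w$name, contra_mean = contra,
                                      ipsi_mean = ipsi, diff_mean = contra - ipsi,
                                      n_trials_used = lat$n_trials))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Optional zero-phase band-pass filter
#'
#' Forward-backward Butterworth filtering per trial and channel. Synthetic
#' data is generated at its analysis rate, so this step is off the default
#' path.
#'
#' @param epochs an [epoch_set()].
#' @param l_freq,h_freq band edges in Hz.
#' @param order filter order.
#' @return The filtered `epoch_set`.
#' @export
filter_epochs <- function(epochs, l_freq = 0.1, h_freq = 30, order = 2) {
  ny <- epochs$sfreq / 2
  bf <- signal::butter(order, c(l_freq, h_freq) / ny, type = "pass")
  d <- epochs$data
  for (i in seq_len(dim(d)[1]))
    for (j in seq_len(dim(d)[2]))
      d[i, j, ] <- signal::filtfilt(bf, d[i, j, ])
  epochs$data <- d
  epochs
}

#' Optional integer-factor downsampling
#'
#' @param epochs an [epoch_set()].
#' @param sfreq_new target rate; `sfreq / sfreq_new` must be an integer.
#' @return The decimated `epoch_set`.
#' @export
downsample_epochs <- function(epochs, sfreq_new = 250) {
  fac <- epochs$sfreq / sfreq_new
  if (abs(fac - round(fac)) > 1e-9) stop("sfreq must be an integer multiple of sfreq_new")
  fac <- as.integer(round(fac))
  if (fac == 1L) return(epochs)
  keep <- seq(1L, dim(epochs$data)[3], by = fac)
  epochs$data <- epochs$data[, , keep, drop = FALSE]
  epochs$sfreq <- sfreq_new
  epochs
}

#' Bad-channel interpolation hook
#'
#' Spherical-spline interpolation requires real electrode geometry, which
#' synthetic data does not carry; this hook validates its arguments and
#' returns the data unchanged.
#'
#' @param epochs an [epoch_set()].
#' @param bad character vector of channel labels.
#' @return `epochs`, unchanged.
#' @export
interpolate_bad_channels <- function(epochs, bad = character()) {
  stopifnot(all(bad %in% epochs$ch_names))
  epochs
}
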