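# Behavioural estimators for delayed recognition (Cowan's k) and delayed
# recall (circular response error).

#' Cowan's k capacity estimate
#'
#' `k = set_size * (hit_rate - fa_rate)`, where the hit rate is the
#' proportion of correct responses on nonmatch trials and the false-alarm
#' rate the proportion of incorrect responses on match trials. Negative k is
#' returned as computed (the formula permits it).
#'
#' @param hit_rate,fa_rate rates in `[0, 1]`.
#' @param set_size memory-array set size (>= 1).
#' @return Capacity in items, in `[-set_size, set_size]`.
#' @export
#' @examples
#' cowans_k(0.9, 0.1, 5)  # 4 items
cowans_k <- function(hit_rate, fa_rate, set_size) {
  if (any(hit_rate < 0 | hit_rate > 1, na.rm = TRUE) ||
      any(fa_rate < 0 | fa_rate > 1, na.rm = TRUE))
    stop("hit_rate and fa_rate must lie in [0, 1]")
  if (any(set_size < 1)) stop("set_size must be >= 1")
  set_size * (hit_rate - fa_rate)
}

#' Circular recall error on the 180-degree space
#'
#' Minimal distance, in degrees, between response and target on the
#' 180-periodic stimulus space; the maximal possible error is 90 degrees
#' (the offset used for nonmatch probes).
#'
#' @param response_deg,target_deg angles in `[0, 180)`.
#' @return Absolute error in `[0, 90]`.
#' @export
#' @examples
#' recall_error(175, 5)  # 10: wraps around the 180-degree circle
recall_error <- function(response_deg, target_deg) {
  if (any(response_deg < 0 | response_deg >= 180, na.rm = TRUE) ||
      any(target_deg < 0 | target_deg >= 180, na.rm = TRUE))
    stop("angles must lie in [0, 180)")
  abs(circ_diff180(response_deg, target_deg))
}

#' Per-cell recognition summary and capacity estimates
#'
#' Computes hit rate, false-alarm rate and Cowan's k per subject x
#' condition x load. Timeout trials (missing response) are excluded. When
#' `orientation_probes_only = TRUE` (the default), heterogeneous cells use
#' only trials probing an orientation, so that homogeneous and heterogeneous
#' cells are compared on physically identical probes.
#'
#' @param trials data.frame of recognition trials (columns `subject`,
#'   `condition`, `load`, `is_match`, `response`, and `probe_domain` when
#'   the filter is used).
#' @param orientation_probes_only restrict heterogeneous cells to
#'   orientation probes.
#' @return A data.frame with one row per cell: `hit_rate`, `fa_rate`, `k`,
#'   `n_trials`. Cells left empty after filtering get `NA` estimates.
#' @export
recognition_summary <- function(trials, orientation_probes_only = TRUE) {
  stopifnot(all(c("subject", "condition", "load", "is_match", "response") %in% names(trials)))
  trials <- trials[!is.na(trials$response), , drop = FALSE]
  if (orientation_probes_only) {
    stopifnot("probe_domain" %in% names(trials))
    trials <- trials[trials$condition != "heterogeneous" |
                       trials$probe_domain == "orientation", , drop = FALSE]
  }
  cells <- expand.grid(subject = sort(unique(trials$subject)),
                       condition = sort(unique(trials$condition)),
                       load = sort(unique(trials$load)),
                       stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- trials[trials$subject == cells$subject[i] &
                     trials$condition == cells$condition[i] &
                     trials$load == cells$load[i], , drop = FALSE]
    nm <- cell[!cell$is_match, , drop = FALSE]
    mm <- cell[cell$is_match, , drop = FALSE]
    if (nrow(nm) == 0L || nrow(mm) == 0L)
      return(data.frame(hit_rate = NA_real_, fa_rate = NA_real_, k = NA_real_,
                        n_trials = nrow(cell)))
    hit <- mean(nm$response == "nonmatch")
    fa <- mean(mm$response == "nonmatch")
    data.frame(hit_rate = hit, fa_rate = fa,
               k = cowans_k(hit, fa, cells$load[i]), n_trials = nrow(cell))
  })
  cbind(cells, do.call(rbind, res))
}
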