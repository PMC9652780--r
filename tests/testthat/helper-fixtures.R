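# Shared fixtures built in code.

# Small, quiet configuration for fast structural tests.
tiny_config <- function(seed = 1, ...) {
  gen_config(seed = seed, n_subjects = 2L, trials_per_cell = 20L, ...)
}

# A clean exponential similarity function (no measurement noise).
exp_similarity <- function(scale_deg = 20) {
  offs <- likert_offsets("orientation")
  similarity_function(offs, exp(-offs / scale_deg), domain = "orientation")
}

# Symmetric triangular similarity on [0, 90].
tri_similarity <- function() {
  similarity_function(c(0, 45, 90), c(1, 0.5, 0), domain = "orientation")
}

# Noise-free epoch_set with a hand-set signal; 4 channels (L, R, midline,
# HEOG), sampling at 250 Hz over [-1.5, 2.5] s.
flat_epochs <- function(n_trials = 2, value = 0, meta = NULL, sfreq = 250) {
  times <- seq(-1.5, 2.5, by = 1 / sfreq)
  data <- array(value, dim = c(n_trials, 4, length(times)))
  if (is.null(meta))
    meta <- data.frame(subject = "S01", condition = "homogeneous", load = 1,
                       cue_side = rep(c("left", "right"), length.out = n_trials),
                       trial_type = "1O")
  epoch_set(data, sfreq = sfreq, t0 = -1.5,
            ch_names = c("P3", "P4", "Pz", "HEOG"),
            ch_side = c("left", "right", "midline", "midline"),
            heog_ch = "HEOG", meta = meta)
}

# Recall-trial table from explicit errors (target fixed at 90 degrees).
trials_from_errors <- function(err, nontargets = NULL) {
  d <- data.frame(target_deg = 90, response_deg = wrap180(90 + err))
  if (!is.null(nontargets)) {
    d$nontarget1_deg <- wrap180(90 + nontargets[, 1])
    d$nontarget2_deg <- wrap180(90 + nontargets[, 2])
  }
  d
}
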