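test_that("baseline correction removes the prestimulus mean exactly", {
  ep <- flat_epochs(2, value = 5)
  bc <- baseline_correct(ep)
  expect_true(all(bc$data == 0))

  # 2 uV baseline then 7 uV signal -> 5 uV after correction
  ep <- flat_epochs(1)
  t <- epoch_times(ep)
  ep$data[1, , ] <- rep(ifelse(t < 0, 2, 7), each = 4)
  bc <- baseline_correct(ep)
  expect_equal(unique(as.vector(bc$data[1, , t >= 0])), 5)

  set.seed(8)
  ep <- flat_epochs(5)
  ep$data[] <- rnorm(length(ep$data), 3, 10)
  bc <- baseline_correct(ep)
  idx <- which(t >= -0.2 & t < 0)
  expect_lt(max(abs(apply(bc$data[, , idx], c(1, 2), mean))), 1e-9)

  expect_error(baseline_correct(ep, window_spec("bad", -5, -4)), "outside")
})

test_that("amplitude rejection uses a strict threshold on any channel", {
  ep <- flat_epochs(3)
  ep$data[1, 2, 500] <- 150    # blink-sized transient
  ep$data[2, 1, ] <- 99.9      # large but below threshold everywhere
  mask <- reject_amplitude(ep, 100)
  expect_identical(unname(mask), c(TRUE, FALSE, FALSE))
  ep$data[3, 4, 10] <- -100    # exactly at threshold: "exceeding" is strict
  expect_false(reject_amplitude(ep, 100)[3])
})

test_that("the split-half sliding window flags steps above 20 uV only", {
  n <- 1001
  h <- matrix(0, 3, n)
  h[1, 500:n] <- 30
  h[2, 500:n] <- 15
  mask <- detect_heog_steps(h, sfreq = 250)
  expect_identical(as.vector(mask), c(TRUE, FALSE, FALSE))
  # the maximal half-difference is attained where the window straddles the step
  ms <- attr(mask, "max_step")
  expect_gt(ms[1], 25)
  expect_lt(ms[2], 15 + 1e-9)
  expect_equal(ms[3], 0)
  expect_error(detect_heog_steps(h[, 1:30, drop = FALSE], sfreq = 250), "shorter")
})

test_that("HEOG false alarms on pure noise are rare", {
  set.seed(12)
  h <- matrix(rnorm(300 * 1001, 0, 5), 300, 1001)
  expect_lt(mean(detect_heog_steps(h, sfreq = 250)), 0.05)
})

test_that("subjects are excluded when any trial type dips below the minimum", {
  meta <- data.frame(subject = rep(c("A", "B", "C"), each = 150),
                     trial_type = rep(rep(c("x", "y"), each = 75), 3))
  keep <- rep(TRUE, nrow(meta))
  keep[meta$subject == "B" & meta$trial_type == "y"][1] <- FALSE  # 74 survive
  res <- exclude_low_trial_subjects(meta, keep, min_trials = 75)
  expect_identical(res$excluded, "B")
  expect_identical(res$retained, c("A", "C"))
  expect_equal(res$counts["B", "y"], 74)

  # constructed 2-of-10 exclusion
  meta <- data.frame(subject = rep(sprintf("S%02d", 1:10), each = 100),
                     trial_type = "3O")
  keep <- rep(TRUE, 1000)
  for (s in c("S03", "S08"))
    keep[meta$subject == s][1:30] <- FALSE
  res <- exclude_low_trial_subjects(meta, keep, min_trials = 75)
  expect_identical(res$excluded, c("S03", "S08"))
})

test_that("lateralize assigns clusters contralaterally and skips the midline", {
  meta <- data.frame(subject = "S01", condition = "homogeneous", load = 1,
                     cue_side = c("left", "left"), trial_type = "1O")
  ep <- flat_epochs(2, meta = meta)
  ep$data[, 2, ] <- -1    # right cluster (contralateral to left cue)
  ep$data[, 3, ] <- 99    # midline: must never contribute
  lat <- lateralize(ep, by = "subject")
  expect_true(all(lat$contra == -1))
  expect_true(all(lat$ipsi == 0))

  wm <- window_means(lat)
  expect_equal(wm$contra_mean, c(-1, -1))
  expect_equal(wm$ipsi_mean, c(0, 0))
  expect_equal(wm$diff_mean, c(-1, -1))
})

test_that("contra/ipsi assignment is invariant to swapping cues and hemispheres together", {
  set.seed(9)
  meta <- data.frame(subject = "S01", condition = "homogeneous", load = 3,
                     cue_side = rep(c("left", "right"), 5), trial_type = "3O")
  ep <- flat_epochs(10, meta = meta)
  ep$data[] <- rnorm(length(ep$data))
  lat <- lateralize(ep, by = "subject")

  flipped <- ep
  flipped$meta$cue_side <- ifelse(meta$cue_side == "left", "right", "left")
  flipped$ch_side <- c("right", "left", "midline", "midline")
  lat2 <- lateralize(flipped, by = "subject")
  expect_equal(lat2$contra, lat$contra)
  expect_equal(lat2$ipsi, lat$ipsi)
})

test_that("window means report contra - ipsi differences per window", {
  meta <- data.frame(subject = "S01", condition = "homogeneous", load = 1,
                     cue_side = "left", trial_type = "1O")
  ep <- flat_epochs(1, meta = meta)
  ep$data[, 2, ] <- -2   # contra for a left cue
  ep$data[, 1, ] <- -1   # ipsi
  wm <- window_means(lateralize(ep, by = "subject"))
  expect_equal(wm$diff_mean, rep(-1, 2))
  expect_true(all(abs(wm$diff_mean - (wm$contra_mean - wm$ipsi_mean)) < 1e-9))
})

test_that("the pipeline recovers noiseless injected amplitudes exactly", {
  tm <- timing_spec()
  cfg <- gen_config(seed = 5, n_subjects = 1, trials_per_cell = 4,
                    eeg = list(noise_sd = 0, saccade_rate = 0, blink_rate = 0,
                               cda_amp_by_load = c(`1` = -1.0), bilateral_effect_amp = 0))
  tr <- gen_recognition_trials(cfg, tm, loads = 1)
  tr <- tr[tr$condition == "heterogeneous", ]
  wm <- window_means(lateralize(baseline_correct(gen_eeg_epochs(cfg, tm, tr)),
                                by = c("subject", "load")))
  expect_lt(max(abs(wm$diff_mean - (-1))), 1e-9)
  expect_lt(max(abs(wm$ipsi_mean)), 1e-9)

  # a purely bilateral component cancels in the subtraction
  cfg2 <- gen_config(seed = 5, n_subjects = 1, trials_per_cell = 4,
                     eeg = list(noise_sd = 0, saccade_rate = 0, blink_rate = 0,
                                cda_amp_by_load = c(`1` = 0), bilateral_effect_amp = -1))
  tr2 <- gen_recognition_trials(cfg2, tm, loads = 1)
  tr2 <- tr2[tr2$condition == "homogeneous", ]
  wm2 <- window_means(lateralize(baseline_correct(gen_eeg_epochs(cfg2, tm, tr2)),
                                 by = c("subject", "load")))
  expect_lt(max(abs(wm2$contra_mean - (-1))), 1e-9)
  expect_lt(max(abs(wm2$ipsi_mean - (-1))), 1e-9)
  expect_lt(max(abs(wm2$diff_mean)), 1e-9)
})

test_that("amplitude and HEOG rejection masks combine order-independently", {
  tm <- timing_spec()
  cfg <- gen_config(seed = 6, n_subjects = 1, trials_per_cell = 40,
                    eeg = list(saccade_rate = 0.15, blink_rate = 0.15))
  tr <- gen_recognition_trials(cfg, tm, loads = 3)
  ep <- baseline_correct(gen_eeg_epochs(cfg, tm, tr))
  m1 <- reject_amplitude(ep) | detect_heog_steps(ep)
  m2 <- detect_heog_steps(ep) | reject_amplitude(ep)
  expect_identical(unname(m1), unname(m2))
  expect_gt(sum(m1), 0)
})

test_that("optional preprocessing steps preserve the epoch structure", {
  ep <- flat_epochs(2, value = 1)
  f <- filter_epochs(ep, 0.5, 40)
  expect_equal(dim(f$data), dim(ep$data))
  d <- downsample_epochs(flat_epochs(2, sfreq = 500), 250)
  expect_equal(d$sfreq, 250)
  expect_equal(dim(d$data)[3], ceiling(dim(flat_epochs(2, sfreq = 500)$data)[3] / 2))
  expect_identical(interpolate_bad_channels(ep, "P3"), ep)
  expect_error(interpolate_bad_channels(ep, "nope"))
})
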