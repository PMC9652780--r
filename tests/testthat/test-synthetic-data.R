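test_that("gen_config enforces its invariants at construction", {
  expect_error(gen_config(mixture_truth = list(pT = 0.7, pN = 0.2, pU = 0.2, kappa = 5)),
               "sum to 1")
  expect_error(gen_config(guess_rate_recognition = 1.2), "probabilities")
  expect_error(gen_config(mixture_truth = list(pT = 0.7, pN = 0.15, pU = 0.15, kappa = 0)),
               "kappa")
  expect_error(gen_config(eeg = list(sfreq = 0)), "sfreq")
  # CDA magnitude may not grow between loads that both exceed capacity
  expect_error(gen_config(capacity_k = 2.5,
                          eeg = list(cda_amp_by_load = c(`1` = -1, `3` = -2, `5` = -3))),
               "saturate")
  expect_s3_class(gen_config(capacity_k = 2.5,
                             eeg = list(cda_amp_by_load = c(`1` = -1, `3` = -2, `5` = -2))),
                  "gen_config")
})

test_that("timing_spec validates the CSI jitter grid", {
  expect_error(timing_spec(csi_range = c(0.4, 0.57)), "multiples")
  tm <- timing_spec()
  expect_equal(tm$probe_onset, 1.650)
})

test_that("identical seeds reproduce identical datasets; different seeds differ", {
  a <- gen_recognition_trials(tiny_config(seed = 5))
  b <- gen_recognition_trials(tiny_config(seed = 5))
  c <- gen_recognition_trials(tiny_config(seed = 6))
  expect_identical(a, b)
  expect_false(identical(a, c))
  ra <- gen_recall_trials(tiny_config(seed = 5))
  rb <- gen_recall_trials(tiny_config(seed = 5))
  expect_identical(ra, rb)
})

test_that("recognition generator matches its capacity model expectations", {
  # load 1 with ample capacity: probed item always in memory -> k = 1
  cfg <- gen_config(seed = 2, n_subjects = 1, trials_per_cell = 2000,
                    capacity_k = 3, capacity_sd = 0)
  ks <- recognition_summary(gen_recognition_trials(cfg, loads = 1))
  expect_true(all(ks$hit_rate == 1 & ks$fa_rate == 0 & ks$k == 1))

  # zero capacity: pure guessing, k ~ 0
  cfg0 <- gen_config(seed = 3, n_subjects = 1, trials_per_cell = 10000,
                     capacity_k = 0, capacity_sd = 0,
                     eeg = list(cda_amp_by_load = c(`1` = 0, `3` = 0, `5` = 0)))
  ks0 <- recognition_summary(gen_recognition_trials(cfg0, loads = 3))
  expect_true(all(abs(ks0$hit_rate - 0.5) < 0.05))
  expect_true(all(abs(ks0$k) < 0.2))
})

test_that("recognition accuracy does not increase with load (capacity saturation)", {
  cfg <- gen_config(seed = 4, n_subjects = 4, trials_per_cell = 400)
  tr <- gen_recognition_trials(cfg)
  tr <- tr[!is.na(tr$response), ]
  correct <- with(tr, (is_match & response == "match") | (!is_match & response == "nonmatch"))
  acc <- tapply(correct, list(tr$subject, tr$load), mean)
  expect_true(all(acc[, "1"] >= acc[, "5"]))
})

test_that("recall generator respects the mixture ground truth", {
  # noiseless target recall
  cfg <- gen_config(seed = 1, n_subjects = 1, trials_per_cell = 200,
                    mixture_truth = list(pT = 1, pN = 0, pU = 0, kappa = 1e4))
  tr <- gen_recall_trials(cfg, trial_types = "1O")
  expect_true(all(recall_error(tr$response_deg, tr$target_deg) < 2))
  expect_true(all(tr$truth_component == "target"))

  # pure guessing is uniform on the 180-unit space
  cfg <- gen_config(seed = 2, n_subjects = 1, trials_per_cell = 10000,
                    mixture_truth = list(pT = 0, pN = 0, pU = 1, kappa = 12))
  tr <- gen_recall_trials(cfg, trial_types = "1O")
  h <- table(cut(tr$response_deg, seq(0, 180, by = 10)))
  expect_gt(chisq.test(h)$p.value, 0.01)

  # component labels converge to the configured weights
  cfg <- gen_config(seed = 7, n_subjects = 1, trials_per_cell = 5000)
  tr <- gen_recall_trials(cfg, trial_types = "3O")
  freq <- table(tr$truth_component) / nrow(tr)
  expect_lt(abs(freq[["target"]] - 0.7), 0.02)
  expect_lt(abs(freq[["nontarget"]] - 0.15), 0.02)
  expect_lt(abs(freq[["guess"]] - 0.15), 0.02)
})

test_that("trial types without nontargets carry no swap mass", {
  cfg <- tiny_config(seed = 3)
  tr <- gen_recall_trials(cfg, trial_types = c("1O", "1O1C1L"))
  expect_true(all(is.na(tr$nontarget1_deg)))
  expect_false(any(tr$truth_component == "nontarget"))
})

test_that("Likert generator anchors the scale ends and decays monotonically", {
  cfg <- gen_config(seed = 1, n_subjects = 4, likert_noise_sd = 0)
  lik <- gen_likert_trials(cfg, "orientation")
  expect_true(all(lik$rating[lik$offset == 0] == 7))
  expect_true(all(lik$rating[lik$offset == 90] == 1))

  cfg <- gen_config(seed = 2, n_subjects = 10, likert_noise_sd = 0.5)
  lik <- gen_likert_trials(cfg, "orientation")
  m <- tapply(lik$rating, lik$offset, mean)[as.character(c(0, 20, 90))]
  expect_true(all(diff(m) < 0))
  expect_error(gen_likert_trials(cfg, "hue"))
})

test_that("EEG generator injects recoverable amplitudes and artifacts", {
  tm <- timing_spec()
  # saccade annotations occur at the configured rate
  cfg <- gen_config(seed = 3, n_subjects = 1, trials_per_cell = 500,
                    eeg = list(noise_sd = 0, blink_rate = 0, saccade_rate = 0.1))
  tr <- gen_recognition_trials(cfg, tm, loads = 1)  # 1000 trials over 2 conditions
  ep <- gen_eeg_epochs(cfg, tm, tr)
  expect_lt(abs(mean(ep$annotations$saccade) - 0.1), 0.02)
  # every annotated saccade is a detectable step on the HEOG trace
  expect_true(all(detect_heog_steps(ep)[ep$annotations$saccade]))

  # blink transients exceed the amplitude-rejection threshold
  cfg <- gen_config(seed = 4, n_subjects = 1, trials_per_cell = 100,
                    eeg = list(noise_sd = 0, saccade_rate = 0, blink_rate = 0.2))
  tr <- gen_recognition_trials(cfg, tm, loads = 1)
  ep <- baseline_correct(gen_eeg_epochs(cfg, tm, tr))
  flagged <- reject_amplitude(ep, 100)
  # blinks overlapping the baseline window can partially self-cancel after
  # baseline removal; all others must be caught
  clear <- ep$annotations$blink &
    (ep$annotations$blink_latency_s < -0.7 | ep$annotations$blink_latency_s > 0.3)
  expect_true(all(flagged[clear]))
  expect_false(any(flagged[!ep$annotations$blink]))
})
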