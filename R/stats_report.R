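# Within-subject factorial statistics and the end-to-end synthetic study:
# repeated-measures ANOVA (aov with subject error strata), paired t tests,
# and an orchestrator that runs simulation -> preprocessing -> model fits ->
# window means -> statistics and checks the qualitative comparison pattern.

#' Repeated-measures ANOVA for fully within-subject designs
#'
#' Standard within-subject sums-of-squares partition (subject as a random
#' blocking factor), fitted with `stats::aov` using an
#' `Error(subject/(A*B*...))` stratum structure. The design must be fully
#' crossed and balanced with exactly one value per subject x cell.
#' Uncorrected degrees of freedom are reported by default; Greenhouse-
#' Geisser correction is available behind a flag.
#'
#' @param data long-format data.frame.
#' @param dv name of the numeric response column.
#' @param within character vector of within-subject factor columns.
#' @param subject name of the subject id column.
#' @param gg also report Greenhouse-Geisser epsilon and corrected p-values.
#' @return A data.frame with one row per effect: `effect`, `df_num`,
#'   `df_den`, `F`, `p` (plus `gg_eps`, `p_gg` when requested).
#' @export
rm_anova <- function(data, dv, within, subject = "subject", gg = FALSE) {
  stopifnot(all(c(dv, within, subject) %in% names(data)))
  d <- data.frame(.y = data[[dv]], .subj = factor(data[[subject]]))
  for (w in within) d[[w]] <- factor(data[[w]])
  if (nlevels(d$.subj) < 3) stop("need at least 3 subjects")
  tab <- table(d[c(".subj", within)])
  if (any(tab != 1L))
    stop("design must be fully crossed and balanced (one value per subject x cell)")
  if (anyNA(d$.y)) stop("missing values are not imputed")

  rhs <- paste(within, collapse = " * ")
  form <- stats::as.formula(paste0(".y ~ ", rhs, " + Error(.subj/(", rhs, "))"))
  fit <- stats::aov(form, data = d)
  sm <- summary(fit)
  rows <- list()
  for (stratum in sm) {
    st <- stratum[[1]]
    terms <- rownames(st)
    for (i in seq_along(terms)) {
      nm <- trimws(terms[i])
      if (nm %in% c("Residuals", "")) next
      resid_row <- which(trimws(terms) == "Residuals")
      rows[[length(rows) + 1L]] <- data.frame(
        effect = nm, df_num = st$Df[i], df_den = st$Df[resid_row],
        F = st$`F value`[i], p = st$`Pr(>F)`[i])
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  if (gg) {
    res$gg_eps <- NA_real_
    res$p_gg <- NA_real_
    for (i in seq_len(nrow(res))) {
      facs <- strsplit(res$effect[i], ":", fixed = TRUE)[[1]]
      eps <- gg_epsilon(d, facs, within)
      res$gg_eps[i] <- eps
      res$p_gg[i] <- stats::pf(res$F[i], res$df_num[i] * eps,
                               res$df_den[i] * eps, lower.tail = FALSE)
    }
  }
  res
}

# Greenhouse-Geisser epsilon for one within-subject effect: collapse to
# subject x involved-cell means, project onto the effect's orthonormal
# contrasts, epsilon = tr(S)^2 / (d * tr(S^2)).
gg_epsilon <- function(d, facs, within) {
  cells <- interaction(d[facs], lex.order = TRUE)
  Y <- tapply(d$.y, list(d$.subj, cells), mean)
  Cmats <- lapply(facs, function(f) {
    k <- nlevels(d[[f]])
    qr.Q(qr(stats::contr.helmert(k)))
  })
  C <- Reduce(kronecker, Cmats)
  if (is.null(dim(C))) C <- matrix(C, ncol = 1)
  scores <- Y %*% C
  S <- stats::cov(scores)
  dd <- ncol(S)
  (sum(diag(S))^2) / (dd * sum(S^2))
}

#' Paired t test with degenerate-case flagging
#'
#' @param values_a,values_b numeric vectors paired by subject (length >= 3).
#' @return List with `t`, `df`, `p`, `mean_diff`, and `degenerate` (`TRUE`
#'   when the paired differences have zero variance; `t` is then 0 or
#'   signed infinity).
#' @export
paired_t <- function(values_a, values_b) {
  stopifnot(length(values_a) == length(values_b), length(values_a) >= 3)
  dif <- values_a - values_b
  if (stats::sd(dif) == 0) {
    md <- mean(dif)
    return(list(t = if (md == 0) 0 else sign(md) * Inf, df = length(dif) - 1L,
                p = if (md == 0) 1 else 0, mean_diff = md, degenerate = TRUE))
  }
  tt <- stats::t.test(values_a, values_b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_diff = unname(tt$estimate), degenerate = FALSE)
}

#' Run the complete synthetic study end to end
#'
#' Simulates the behavioural and EEG datasets, preprocesses the epochs
#' (baseline correction, amplitude and HEOG rejection, low-trial subject
#' exclusion), derives lateralized window means, fits the mixture and TCC
#' models to the recall data, and runs the factorial comparison set:
#' Cowan's k by homogeneity x load, contralateral/ipsilateral delay means by
#' laterality x homogeneity x load, CDA by homogeneity x load, and model
#' parameters by trial type. The report records whether the qualitative
#' pattern of interest is reproduced: a bilateral homogeneity effect in the
#' raw delay-period signals that cancels in the contra - ipsi subtraction,
#' alongside a preserved CDA load effect.
#'
#' @param cfg a [gen_config()].
#' @param timing a [timing_spec()].
#' @param min_trials minimum surviving epochs per condition x load cell for
#'   a subject to enter the ERP analyses.
#' @param fit_models also fit mixture and TCC models to the recall data
#'   (slower; set `FALSE` for ERP-only runs).
#' @param restarts optimizer restarts for the mixture fits.
#' @return An object of class `cdawm_study`.
#' @export
run_study <- function(cfg = gen_config(), timing = timing_spec(),
                      min_trials = 75, fit_models = TRUE, restarts = 10) {
  windows <- default_windows(timing)

  ## Behaviour: delayed recognition and Cowan's k
  recog <- gen_recognition_trials(cfg, timing)
  ksum <- recognition_summary(recog, orientation_probes_only = TRUE)
  # subjects with an empty cell (possible at very small trial counts after
  # the orientation-probe filter) cannot enter the balanced ANOVA
  complete <- tapply(ksum$k, ksum$subject, function(x) !anyNA(x))
  ksum_cc <- ksum[complete[ksum$subject], , drop = FALSE]
  k_anova <- rm_anova(ksum_cc, dv = "k", within = c("condition", "load"))
  k_posthoc <- lapply(sort(unique(ksum_cc$load)), function(l) {
    a <- ksum_cc[ksum_cc$condition == "heterogeneous" & ksum_cc$load == l, ]
    b <- ksum_cc[ksum_cc$condition == "homogeneous" & ksum_cc$load == l, ]
    a <- a[order(a$subject), ]; b <- b[order(b$subject), ]
    c(load = l, paired_t(a$k, b$k)[c("t", "df", "p", "mean_diff")])
  })

  ## EEG: per-subject generation and reduction (keeps memory bounded)
  subjects <- sort(unique(recog$subject))
  wm_list <- list()
  counts <- list()
  for (i in seq_along(subjects)) {
    s <- subjects[i]
    tr_s <- recog[recog$subject == s, , drop = FALSE]
    ep <- gen_eeg_epochs(cfg, timing, tr_s, seed = cfg$seed + 1000L + i)
    ep <- baseline_correct(ep, windows$baseline)
    rej <- reject_amplitude(ep) | detect_heog_steps(ep)
    ep$meta$cell <- paste(ep$meta$condition, ep$meta$load, sep = "_")
    counts[[s]] <- exclude_low_trial_subjects(ep$meta, !rej, min_trials,
                                              type_col = "cell")
    if (length(counts[[s]]$excluded)) next
    ep <- subset_epochs(ep, !rej)
    lat <- lateralize(ep, by = c("subject", "condition", "load"))
    wm_list[[s]] <- window_means(lat, windows[c("sample", "delay")])
  }
  excluded <- subjects[!subjects %in% names(wm_list)]
  wm <- do.call(rbind, wm_list)
  rownames(wm) <- NULL

  erp <- list(window_means = wm, excluded_subjects = excluded)
  if (length(unique(wm$subject)) >= 3) {
    delay <- wm[wm$window == "delay", ]
    long <- rbind(
      data.frame(subject = delay$subject, condition = delay$condition,
                 load = delay$load, laterality = "contra", amp = delay$contra_mean),
      data.frame(subject = delay$subject, condition = delay$condition,
                 load = delay$load, laterality = "ipsi", amp = delay$ipsi_mean))
    erp$delay_anova3 <- rm_anova(long, dv = "amp",
                                 within = c("laterality", "condition", "load"))
    erp$cda_anova <- rm_anova(delay, dv = "diff_mean", within = c("condition", "load"))
    erp$contra_anova <- rm_anova(delay, dv = "contra_mean",
                                 within = c("condition", "load"))
    erp$ipsi_anova <- rm_anova(delay, dv = "ipsi_mean",
                               within = c("condition", "load"))
    agg <- function(col, cond) mean(delay[[col]][delay$condition == cond])
    erp$homogeneity_effect <- list(
      contra = agg("contra_mean", "homogeneous") - agg("contra_mean", "heterogeneous"),
      ipsi = agg("ipsi_mean", "homogeneous") - agg("ipsi_mean", "heterogeneous"),
      cda = agg("diff_mean", "homogeneous") - agg("diff_mean", "heterogeneous"))
  }

  ## Recall: mixture and TCC fits by trial type
  models <- NULL
  if (fit_models) {
    recall <- gen_recall_trials(cfg)
    lik <- gen_likert_trials(cfg, "orientation")
    sim <- estimate_similarity(lik)
    types <- sort(unique(recall$trial_type))
    mix <- list(); tcc <- list()
    for (tt in types) {
      tr_t <- recall[recall$trial_type == tt, ]
      ncomp <- if (tt == "3O") 3 else 2
      mix[[tt]] <- lapply(split(tr_t, tr_t$subject), fit_mixture,
                          n_components = ncomp, restarts = restarts,
                          seed = cfg$seed + 7L)
      fitter <- if (tt == "3O") fit_tcc_plus else fit_tcc
      tcc[[tt]] <- lapply(split(tr_t, tr_t$subject), fitter, sim = sim)
    }
    swap <- if ("3O" %in% types)
      swap_rate_test(vapply(mix[["3O"]], function(f) f$pN, numeric(1))) else NULL
    models <- list(similarity = sim, mixture = mix, tcc = tcc, swap_test = swap)
  }

  pattern <- NULL
  if (!is.null(erp$cda_anova)) {
    p_of <- function(tab, eff) tab$p[tab$effect == eff]
    pattern <- list(
      bilateral_homogeneity_effect =
        p_of(erp$contra_anova, "condition") < 0.05 &&
        p_of(erp$ipsi_anova, "condition") < 0.05,
      cda_homogeneity_effect_absent =
        p_of(erp$cda_anova, "condition") > 0.05 &&
        abs(erp$homogeneity_effect$cda) < 0.1,
      cda_load_effect = p_of(erp$cda_anova, "load") < 0.05)
    pattern$reproduced <- pattern$bilateral_homogeneity_effect &&
      pattern$cda_homogeneity_effect_absent && pattern$cda_load_effect
  }

  structure(list(config = cfg, timing = timing, windows = windows,
                 k_summary = ksum, k_anova = k_anova, k_posthoc = k_posthoc,
                 erp = erp, models = models, pattern = pattern,
                 subject_counts = counts),
            class = "cdawm_study")
}

#' @export
print.cdawm_study <- function(x, ...) {
  cat("<cdawm_study>\n")
  cat(sprintf("  %d subjects simulated, %d excluded from ERP analyses\n",
              x$config$n_subjects, length(x$erp$excluded_subjects)))
  cat("  Cowan's k ANOVA (condition x load):\n")
  print(x$k_anova, row.names = FALSE)
  if (!is.null(x$erp$cda_anova)) {
    cat("  CDA ANOVA (condition x load):\n")
    print(x$erp$cda_anova, row.names = FALSE)
    he <- x$erp$homogeneity_effect
    cat(sprintf("  homogeneity effect (homo - hetero, delay window): contra %.3f, ipsi %.3f, CDA %.3f uV\n",
                he$contra, he$ipsi, he$cda))
  }
  if (!is.null(x$models$swap_test))
    cat(sprintf("  swap test (pN > 0): headline %s, p = %.4g\n",
                x$models$swap_test$headline, x$models$swap_test$p_value))
  if (!is.null(x$pattern))
    cat(sprintf("  qualitative pattern reproduced: %s\n", x$pattern$reproduced))
  invisible(x)
}
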