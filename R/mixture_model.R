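# Maximum-likelihood mixture modelling of delayed-estimation responses:
# target recall (probability pT, von Mises precision kappa), nontarget
# ("swap") responses (pN), and uniform guessing (pU). All densities live on
# the doubled circle: errors in the 180-unit stimulus space are doubled onto
# 360 degrees, and the uniform component is expressed per degree of that
# doubled space (1/360), so log-likelihoods are comparable across models.

mixture_trial_errors <- function(trials) {
  stopifnot(all(c("response_deg", "target_deg") %in% names(trials)))
  err_t <- circ_diff180(trials$response_deg, trials$target_deg)
  nt_cols <- grep("^nontarget[0-9]+_deg$", names(trials), value = TRUE)
  err_nt <- NULL
  if (length(nt_cols)) {
    err_nt <- sapply(nt_cols, function(cl) circ_diff180(trials$response_deg, trials[[cl]]))
    if (is.null(dim(err_nt))) err_nt <- matrix(err_nt, nrow = nrow(trials))
    if (all(is.na(err_nt))) err_nt <- NULL
  }
  list(target = err_t, nontarget = err_nt)
}

# log density (per degree of the doubled circle) of a von Mises component at
# error `err180` degrees in the 180-space.
log_vm_component <- function(err180, kappa) {
  theta <- 2 * err180 * pi / 180
  log_dvm(theta, kappa) + log(pi / 180)
}

#' Mixture-model log-likelihood
#'
#' Per trial the density is
#' `pT * VM(2 * err_target; kappa) + (pN / m) * sum_j VM(2 * err_nontarget_j; kappa) + pU / 360`,
#' with all von Mises densities on the doubled circle expressed per degree
#' of the 360-degree space, and m the number of nontargets. `pN` mass is
#' split equally over nontargets.
#'
#' @param params numeric vector or list with `pT`, `pN`, `pU` (summing to 1)
#'   and `kappa` (>= 0).
#' @param trials data.frame of recall trials (`response_deg`, `target_deg`,
#'   optional `nontargetJ_deg` columns).
#' @return Total log-likelihood in nats.
#' @export
mixture_loglik <- function(params, trials) {
  p <- as.list(params)
  if (is.null(names(p)) || !all(c("pT", "pN", "pU", "kappa") %in% names(p)))
    names(p) <- c("pT", "pN", "pU", "kappa")
  if (abs(p$pT + p$pN + p$pU - 1) > 1e-8) stop("pT + pN + pU must sum to 1")
  if (p$kappa < 0) stop("kappa must be >= 0")
  err <- mixture_trial_errors(trials)
  if (is.null(err$nontarget) && p$pN > 0)
    stop("pN > 0 requested for trials without nontargets")
  dens <- p$pT * exp(log_vm_component(err$target, p$kappa)) + p$pU / 360
  if (!is.null(err$nontarget) && p$pN > 0) {
    m <- rowSums(!is.na(err$nontarget))
    nt_dens <- rowSums(exp(log_vm_component(err$nontarget, p$kappa)), na.rm = TRUE)
    has_nt <- m > 0
    if (any(!has_nt)) stop("pN > 0 requested but some trials have no nontargets")
    dens <- dens + p$pN * nt_dens / m
  }
  sum(log(dens))
}

softmax3 <- function(a, b) {
  e <- exp(c(a, b, 0) - max(a, b, 0))
  e / sum(e)
}

#' Fit the mixture model by maximum likelihood
#'
#' Maximizes [mixture_loglik()] with bounded multi-start quasi-Newton
#' optimization. Mixture weights are optimized in softmax space (so the
#' simplex constraint holds exactly) and kappa in log space. With
#' `n_components = 2` the nontarget component is fixed at zero; with
#' `n_components = 3` it is free (the trials must then carry nontargets).
#'
#' @param trials data.frame of recall trials (>= 20 rows).
#' @param n_components 2 (pT, pU, kappa) or 3 (adds pN).
#' @param restarts number of optimizer starts (the first is deterministic,
#'   the rest randomized).
#' @param seed RNG seed for the randomized starts; the fit is deterministic
#'   given it.
#' @param kappa_max upper bound for kappa; solutions at the bound are
#'   flagged as non-converged.
#' @return An object of class `mixture_fit`: `pT`, `pN`, `pU`, `kappa`,
#'   `loglik`, `n_trials`, `converged`, `n_restarts_used`.
#' @export
fit_mixture <- function(trials, n_components = 3, restarts = 20, seed = NULL,
                        kappa_max = 1e4) {
  stopifnot(n_components %in% c(2, 3))
  if (nrow(trials) < 20) stop("need at least 20 trials")
  err <- mixture_trial_errors(trials)
  if (n_components == 3 && is.null(err$nontarget))
    stop("3-component model requires trials with nontargets")

  # precompute errors once; objective works on them directly
  err_t <- err$target
  err_nt <- if (n_components == 3) err$nontarget else NULL
  m_nt <- if (!is.null(err_nt)) rowSums(!is.na(err_nt)) else NULL
  lk_min <- log(1e-4); lk_max <- log(kappa_max)

  negll <- function(par) {
    if (n_components == 3) {
      w <- softmax3(par[1], par[2]); lk <- par[3]
    } else {
      e <- exp(c(par[1], 0) - max(par[1], 0)); w0 <- e / sum(e)
      w <- c(w0[1], 0, w0[2]); lk <- par[2]
    }
    kappa <- exp(lk)
    dens <- w[1] * exp(log_vm_component(err_t, kappa)) + w[3] / 360
    if (n_components == 3 && w[2] > 0)
      dens <- dens + w[2] * rowSums(exp(log_vm_component(err_nt, kappa)), na.rm = TRUE) / m_nt
    -sum(log(pmax(dens, 1e-300)))
  }

  n_par <- if (n_components == 3) 3L else 2L
  lower <- c(rep(-15, n_par - 1L), lk_min)
  upper <- c(rep(15, n_par - 1L), lk_max)
  # deterministic first start: moderate target weight, kappa from a crude
  # precision guess
  sd_err <- stats::sd(err_t)
  k0 <- min(max(1 / max((sd_err * pi / 90)^2, 1e-3), 0.5), kappa_max / 10)
  starts <- list(if (n_components == 3) c(1.5, -1, log(k0)) else c(1.5, log(k0)))
  with_seed(seed, {
    if (restarts > 1) {
      for (i in seq_len(restarts - 1L)) {
        starts[[i + 1L]] <- c(stats::runif(n_par - 1L, -2, 3),
                              stats::runif(1, log(0.5), log(100)))
      }
    }
    best <- NULL
    n_ok <- 0L
    for (st in starts) {
      fit <- tryCatch(
        stats::optim(st, negll, method = "L-BFGS-B", lower = lower, upper = upper,
                     control = list(maxit = 500)),
        error = function(e) NULL)
      if (is.null(fit) || !is.finite(fit$value)) next
      n_ok <- n_ok + 1L
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    if (is.null(best)) stop("all ", restarts, " optimizer restarts failed")
    par <- best$par
    if (n_components == 3) {
      w <- softmax3(par[1], par[2])
    } else {
      e <- exp(c(par[1], 0) - max(par[1], 0)); w0 <- e / sum(e)
      w <- c(w0[1], 0, w0[2])
    }
    kappa <- exp(par[n_par])
    at_bound <- par[n_par] >= lk_max - 1e-6
    structure(list(pT = w[1], pN = w[2], pU = w[3], kappa = kappa,
                   loglik = -best$value, n_trials = nrow(trials),
                   converged = best$convergence == 0 && !at_bound,
                   kappa_at_bound = at_bound,
                   n_components = n_components, n_restarts_used = n_ok),
              class = "mixture_fit")
  })
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit> %d-component, n = %d trials\n", x$n_components, x$n_trials))
  cat(sprintf("  pT = %.3f  pN = %.3f  pU = %.3f  kappa = %.2f\n",
              x$pT, x$pN, x$pU, x$kappa))
  cat(sprintf("  logLik = %.2f  converged = %s (%d/%d restarts usable)\n",
              x$loglik, x$converged, x$n_restarts_used, x$n_restarts_used))
  if (x$kappa_at_bound) cat("  note: kappa at its upper bound\n")
  invisible(x)
}

#' @export
coef.mixture_fit <- function(object, ...) {
  c(pT = object$pT, pN = object$pN, pU = object$pU, kappa = object$kappa)
}

#' @export
logLik.mixture_fit <- function(object, ...) {
  structure(object$loglik, df = if (object$n_components == 3) 3 else 2,
            nobs = object$n_trials, class = "logLik")
}

#' Group-level test of the swap rate
#'
#' Tests whether per-subject nontarget-response probabilities (pN) exceed
#' zero, with both a one-sample t test and a Wilcoxon signed-rank test; a
#' Shapiro-Wilk normality check decides which is the headline result
#' (Wilcoxon when normality is rejected).
#'
#' @param pn numeric vector of per-subject pN estimates (>= 5 subjects).
#' @param alpha normality-test level used to pick the headline test.
#' @return List with both test results, the normality check, and the
#'   `headline` choice; degenerate all-zero input is flagged.
#' @export
swap_rate_test <- function(pn, alpha = 0.05) {
  stopifnot(is.numeric(pn))
  if (length(pn) < 5) stop("need at least 5 subjects")
  degenerate <- all(pn == 0)
  t_res <- if (stats::sd(pn) == 0) {
    # constant vector: the t statistic degenerates to signed infinity
    if (degenerate) NULL else
      list(statistic = c(t = sign(mean(pn)) * Inf), p.value = if (mean(pn) > 0) 0 else 1,
           degenerate_variance = TRUE)
  } else stats::t.test(pn, mu = 0, alternative = "greater")
  w_res <- if (degenerate) NULL else
    suppressWarnings(stats::wilcox.test(pn, mu = 0, alternative = "greater"))
  sh <- if (stats::sd(pn) == 0) NULL else stats::shapiro.test(pn)
  nonnormal <- !is.null(sh) && sh$p.value < alpha
  headline <- if (degenerate) "none (all pN are zero; Wilcoxon undefined)"
              else if (nonnormal) "wilcoxon" else "t"
  list(t = t_res, wilcoxon = w_res, shapiro = sh,
       normality_rejected = nonnormal, degenerate = degenerate,
       headline = headline,
       p_value = if (degenerate) NA_real_
                 else if (nonnormal) w_res$p.value else t_res$p.value)
}
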