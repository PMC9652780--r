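# Target confusability competition (TCC) modelling. Each of m response
# channels carries a familiarity signal d' * f(offset to target) plus
# independent unit-variance Gaussian noise; the response is the channel with
# the maximal signal. f is the psychophysical similarity function measured
# with Likert judgements and normalized to [0, 1]. The TCC-plus variant adds
# a swap component: with probability pSwap the race is run around a
# nontarget instead of the target.

#' Construct a psychophysical similarity function
#'
#' @param offsets numeric vector of sampled offsets (domain units,
#'   ascending, starting at 0).
#' @param f similarity values in `[0, 1]` at those offsets.
#' @param domain stimulus domain label.
#' @param interpolation descriptor (only `"linear"` is implemented).
#' @return An object of class `similarity_function`.
#' @export
similarity_function <- function(offsets, f, domain = "orientation",
                                interpolation = "linear") {
  stopifnot(length(offsets) == length(f), !is.unsorted(offsets),
            all(f >= 0 & f <= 1))
  if (f[1] != max(f)) stop("f(0) must be the maximum sampled value")
  structure(list(domain = domain, offsets = offsets, f = f,
                 interpolation = interpolation),
            class = "similarity_function")
}

#' @export
print.similarity_function <- function(x, ...) {
  cat(sprintf("<similarity_function> %s, %d offsets on [0, %g], f(0) = %.3f, f(max) = %.3f\n",
              x$domain, length(x$offsets), max(x$offsets), x$f[1], x$f[length(x$offsets)]))
  invisible(x)
}

#' Evaluate a similarity function at arbitrary offsets
#'
#' Linear interpolation between sampled offsets; beyond the sampled range
#' the value is linearly extrapolated from the last segment and clamped to
#' `[0, 1]`.
#'
#' @param sim a [similarity_function()].
#' @param offset numeric offsets in the function's domain units.
#' @return Similarity values in `[0, 1]`.
#' @export
similarity_eval <- function(sim, offset) {
  n <- length(sim$offsets)
  slope_hi <- if (n > 1) (sim$f[n] - sim$f[n - 1]) / (sim$offsets[n] - sim$offsets[n - 1]) else 0
  out <- stats::approx(sim$offsets, sim$f, xout = pmin(offset, max(sim$offsets)),
                       rule = 2)$y
  over <- offset > max(sim$offsets)
  if (any(over))
    out[over] <- sim$f[n] + slope_hi * (offset[over] - sim$offsets[n])
  pmin(pmax(out, 0), 1)
}

#' Estimate the psychophysical similarity function from Likert data
#'
#' Each rating S (1--7) is normalized as `f = (S - 1) / (7 - 1)` and
#' averaged per offset. Optional isotonic (monotone-decreasing)
#' regularization is available but off by default.
#'
#' @param likert data.frame with `domain`, `offset`, `rating` columns.
#' @param domain domain to estimate (default: the single domain present).
#' @param isotonic apply decreasing isotonic regression to the offset means.
#' @return A [similarity_function()].
#' @export
estimate_similarity <- function(likert, domain = NULL, isotonic = FALSE) {
  stopifnot(all(c("offset", "rating") %in% names(likert)))
  if (is.null(domain)) {
    domain <- unique(likert$domain)
    if (length(domain) != 1L) stop("multiple domains present; specify `domain`")
  } else likert <- likert[likert$domain == domain, , drop = FALSE]
  if (!all(likert$rating %in% 1:7)) stop("ratings must be integers 1..7")
  expected <- likert_offsets(domain)
  have <- sort(unique(likert$offset))
  gaps <- setdiff(expected, have)
  if (length(gaps))
    stop("no trials at sampled offsets: ", paste(gaps, collapse = ", "))
  fvals <- tapply((likert$rating - 1) / 6, likert$offset, mean)
  offs <- as.numeric(names(fvals))
  ord <- order(offs)
  offs <- offs[ord]; fvals <- as.numeric(fvals)[ord]
  if (isotonic) {
    iso <- stats::isoreg(offs, -fvals)
    fvals <- pmin(pmax(-iso$yf, 0), 1)
  }
  similarity_function(offs, fvals, domain = domain)
}

# Similarity of each response channel to a reference channel: channels are m
# equally spaced values on the 180-unit circle, so channel distances map to
# 0..90 degrees, which are rescaled onto the similarity function's sampled
# offset range.
channel_similarity <- function(sim, m) {
  ch <- 0:(m - 1)
  dist_deg <- pmin(ch, m - ch) * (180 / m)
  similarity_eval(sim, dist_deg / 90 * max(sim$offsets))
}

#' TCC response probability mass function
#'
#' Probability that each of the m channels wins the max-signal race when the
#' target sits at channel 1 (offset 0):
#' `P(x) = integral phi(z - d' f_x) prod_{y != x} Phi(z - d' f_y) dz`,
#' evaluated with fixed-order trapezoid quadrature over
#' `z in [-8, 8 + d']`. The trapezoid rule is spectrally accurate here
#' because the integrand decays smoothly to zero at both limits.
#'
#' @param dprime discriminability (>= 0).
#' @param sim a [similarity_function()].
#' @param m number of response channels (default 180, the response-wheel
#'   resolution).
#' @param n_quad number of quadrature nodes.
#' @return Probability vector of length m (sums to 1 within 1e-6; an error
#'   otherwise).
#' @export
tcc_response_pmf <- function(dprime, sim, m = 180, n_quad = 401) {
  stopifnot(dprime >= 0, m >= 2)
  fch <- channel_similarity(sim, m)
  z <- seq(-8, 8 + dprime, length.out = n_quad)
  h <- z[2] - z[1]
  M <- outer(z, dprime * fch, "-")          # n_quad x m
  log_phi <- stats::dnorm(M, log = TRUE)
  log_Phi <- stats::pnorm(M, log.p = TRUE)
  S <- rowSums(log_Phi)
  li <- log_phi + (S - log_Phi)
  w <- rep(h, n_quad); w[c(1, n_quad)] <- h / 2
  pmf <- colSums(exp(li) * w)
  raw_sum <- sum(pmf)
  if (abs(raw_sum - 1) > 1e-6)
    stop(sprintf("quadrature failure: pmf sums to %.8f", raw_sum))
  structure(pmf / raw_sum, quadrature_sum = raw_sum)
}

# Map responses to channel offsets relative to a reference value (degrees in
# the 180-space -> channel index 0..m-1).
response_channel <- function(response_deg, ref_deg, m = 180) {
  round(((response_deg - ref_deg) %% 180) / (180 / m)) %% m
}

#' Simulate responses from the TCC / TCC-plus generative model
#'
#' @param n number of trials.
#' @param dprime discriminability.
#' @param sim a [similarity_function()].
#' @param target_deg target values (recycled to length n).
#' @param nontargets_deg optional matrix (n x 2) of nontarget values.
#' @param swap_prob probability that the race is centred on a random
#'   nontarget (TCC-plus).
#' @param m channel count.
#' @return Numeric vector of responses in `[0, 180)`.
#' @export
simulate_tcc <- function(n, dprime, sim, target_deg = 0, nontargets_deg = NULL,
                         swap_prob = 0, m = 180) {
  pmf <- tcc_response_pmf(dprime, sim, m)
  target_deg <- rep_len(target_deg, n)
  offs <- sample.int(m, n, replace = TRUE, prob = pmf) - 1L
  center <- target_deg
  if (swap_prob > 0) {
    if (is.null(nontargets_deg)) stop("swap_prob > 0 requires nontargets")
    swap <- stats::runif(n) < swap_prob
    pick <- sample.int(ncol(nontargets_deg), n, replace = TRUE)
    nt <- nontargets_deg[cbind(seq_len(n), pick)]
    center[swap] <- nt[swap]
  }
  wrap180(center + offs * (180 / m))
}

tcc_loglik_values <- function(dprime, sim, chan_t, chan_nt = NULL, swap_prob = 0,
                              m = 180) {
  pmf <- tcc_response_pmf(dprime, sim, m)
  lt <- pmf[chan_t + 1L]
  if (is.null(chan_nt) || swap_prob == 0) return(sum(log(pmax(lt, 1e-300))))
  ln <- rowMeans(matrix(pmf[chan_nt + 1L], nrow = length(chan_t)))
  sum(log(pmax((1 - swap_prob) * lt + swap_prob * ln, 1e-300)))
}

#' Fit the TCC model by maximum likelihood
#'
#' One-dimensional bounded maximization of the summed log probability of
#' each trial's response channel; deterministic.
#'
#' @param trials data.frame of recall trials (>= 50 rows) with
#'   `response_deg` and `target_deg`.
#' @param sim a [similarity_function()].
#' @param dprime_max upper bound for d'.
#' @param m channel count.
#' @return An object of class `tcc_fit`: `dprime`, `swap_prob` (`NA`),
#'   `loglik`, `converged`, `n_trials`.
#' @export
fit_tcc <- function(trials, sim, dprime_max = 6, m = 180) {
  if (nrow(trials) < 50) stop("need at least 50 trials")
  chan <- response_channel(trials$response_deg, trials$target_deg, m)
  opt <- stats::optimize(function(d) -tcc_loglik_values(d, sim, chan, m = m),
                         interval = c(0, dprime_max), tol = 1e-6)
  if (!is.finite(opt$objective)) stop("non-finite log-likelihood")
  at_bound <- opt$minimum > dprime_max - 1e-3
  structure(list(dprime = opt$minimum, swap_prob = NA_real_,
                 loglik = -opt$objective, converged = !at_bound,
                 at_bound = at_bound, n_trials = nrow(trials),
                 m = m, model = "tcc"),
            class = "tcc_fit")
}

#' Fit the TCC-plus model (discriminability + swap rate)
#'
#' The response pmf is the swap mixture
#' `(1 - pSwap) * pmf(target) + pSwap * mean_j pmf(nontarget_j)`; `dprime`
#' and `pSwap` are estimated jointly by bounded maximum likelihood from a
#' small deterministic grid of starts.
#'
#' @param trials data.frame of recall trials, each with two nontargets
#'   (`nontarget1_deg`, `nontarget2_deg`).
#' @param sim a [similarity_function()].
#' @param dprime_max upper bound for d'.
#' @param m channel count.
#' @return An object of class `tcc_fit` with `swap_prob` estimated. When the
#'   nontargets coincide with the target the swap rate is unidentifiable and
#'   the fit is flagged non-converged.
#' @export
fit_tcc_plus <- function(trials, sim, dprime_max = 6, m = 180) {
  if (nrow(trials) < 50) stop("need at least 50 trials")
  stopifnot(all(c("nontarget1_deg", "nontarget2_deg") %in% names(trials)),
            !anyNA(trials$nontarget1_deg), !anyNA(trials$nontarget2_deg))
  chan_t <- response_channel(trials$response_deg, trials$target_deg, m)
  chan_nt <- cbind(response_channel(trials$response_deg, trials$nontarget1_deg, m),
                   response_channel(trials$response_deg, trials$nontarget2_deg, m))
  nt_chan_t <- cbind(response_channel(trials$nontarget1_deg, trials$target_deg, m),
                     response_channel(trials$nontarget2_deg, trials$target_deg, m))
  identifiable <- !all(nt_chan_t == 0L)

  negll <- function(par)
    -tcc_loglik_values(par[1], sim, chan_t, chan_nt, swap_prob = par[2], m = m)
  best <- NULL
  for (st in list(c(1, 0.1), c(2, 0.2), c(3, 0.05))) {
    fit <- tryCatch(
      stats::optim(st, negll, method = "L-BFGS-B",
                   lower = c(0, 0), upper = c(dprime_max, 1),
                   control = list(maxit = 300)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("non-finite log-likelihood: all starts failed")
  at_bound <- best$par[1] > dprime_max - 1e-3
  structure(list(dprime = best$par[1], swap_prob = best$par[2],
                 loglik = -best$value,
                 converged = best$convergence == 0 && !at_bound && identifiable,
                 at_bound = at_bound, identifiable = identifiable,
                 n_trials = nrow(trials), m = m, model = "tcc_plus"),
            class = "tcc_fit")
}

#' @export
print.tcc_fit <- function(x, ...) {
  cat(sprintf("<tcc_fit> %s, n = %d trials, m = %d channels\n", x$model, x$n_trials, x$m))
  cat(sprintf("  d' = %.3f", x$dprime))
  if (!is.na(x$swap_prob)) cat(sprintf("  pSwap = %.3f", x$swap_prob))
  cat(sprintf("  logLik = %.2f  converged = %s\n", x$loglik, x$converged))
  invisible(x)
}

#' @export
coef.tcc_fit <- function(object, ...) {
  if (is.na(object$swap_prob)) c(dprime = object$dprime)
  else c(dprime = object$dprime, swap_prob = object$swap_prob)
}

#' @export
logLik.tcc_fit <- function(object, ...) {
  structure(object$loglik, df = if (is.na(object$swap_prob)) 1 else 2,
            nobs = object$n_trials, class = "logLik")
}
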