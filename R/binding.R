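#' Fit a single Hill equation to a fluorescence polarisation titration
#'
#' Least-squares fit of `P(c) = baseline + amplitude * c^n / (KD^n + c^n)`.
#' Starting values come from the data (baseline = minimum signal, amplitude =
#' signal range, KD = concentration at half range, n = 1); the Hill
#' coefficient is bounded to `[0.5, 4]` or fixed at 1. A fit is accepted only
#' if R^2 >= 0.95 and the fitted KD lies within the titrated concentration
#' range scaled by [0.1, 10]; otherwise it is flagged unreliable.
#'
#' @param curve Data frame with columns `concentration_nM` (>= 0, strictly
#'   increasing, at least 6 points) and `polarisation`.
#' @param fix_n Fix the Hill coefficient at 1 instead of fitting it.
#' @param r2_accept Acceptance threshold on R^2 (default 0.95).
#' @return Object of class `hill_fit`: list with `KD`, `hill_n`, `baseline`,
#'   `amplitude`, `r_squared`, `accepted`, `reason`.
#' @examples
#' cv <- simulate_titration(kd = 66, seed = 1, noise_cv = 0)
#' fit_hill(cv)$KD
#' @export
fit_hill <- function(curve, fix_n = FALSE, r2_accept = 0.95) {
  conc <- curve$concentration_nM
  pol <- curve$polarisation
  if (length(conc) < 6 || any(conc < 0) || any(diff(conc) <= 0)) {
    abort("titration needs >= 6 points with strictly increasing, non-negative concentrations",
          class = "afmdna_invalid_input")
  }
  base0 <- min(pol)
  amp0 <- max(pol) - base0
  half <- base0 + amp0 / 2
  kd0 <- tryCatch(approx(pol, conc, xout = half, ties = mean)$y,
                  error = function(e) NA_real_)
  pos <- conc[conc > 0]
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- exp(mean(log(range(pos))))
  df <- data.frame(c = conc, p = pol)
  fit <- tryCatch({
    if (fix_n) {
      minpack.lm::nlsLM(p ~ b + a * c / (kd + c), data = df,
                        start = list(b = base0, a = amp0, kd = kd0),
                        lower = c(b = -Inf, a = 0, kd = 1e-9),
                        control = minpack.lm::nls.lm.control(maxiter = 300))
    } else {
      minpack.lm::nlsLM(p ~ b + a * c^n / (kd^n + c^n), data = df,
                        start = list(b = base0, a = amp0, kd = kd0, n = 1),
                        lower = c(b = -Inf, a = 0, kd = 1e-9, n = 0.5),
                        upper = c(b = Inf, a = Inf, kd = Inf, n = 4),
                        control = minpack.lm::nls.lm.control(maxiter = 300))
    }
  }, error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(KD = NA_real_, hill_n = NA_real_,
                          baseline = NA_real_, amplitude = NA_real_,
                          r_squared = NA_real_, accepted = FALSE,
                          reason = "did not converge"),
                     class = "hill_fit"))
  }
  cf <- coef(fit)
  rss <- sum(resid(fit)^2)
  tss <- sum((pol - mean(pol))^2)
  r2 <- 1 - rss / tss
  kd <- unname(cf[["kd"]])
  in_range <- kd >= 0.1 * min(pos) && kd <= 10 * max(pos)
  accepted <- r2 >= r2_accept && in_range
  reason <- if (accepted) "accepted" else if (!in_range)
    "KD outside titrated range x [0.1, 10]" else
      sprintf("R^2 = %.3f below %.2f", r2, r2_accept)
  structure(list(
    KD = kd,
    hill_n = if (fix_n) 1 else unname(cf[["n"]]),
    baseline = unname(cf[["b"]]),
    amplitude = unname(cf[["a"]]),
    r_squared = r2,
    accepted = accepted,
    reason = reason
  ), class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> KD = %.4g nM, n = %.3g, R^2 = %.4f [%s]\n",
              x$KD, x$hill_n, x$r_squared,
              if (x$accepted) "accepted" else x$reason))
  invisible(x)
}

#' Average binding affinity over replicate Hill fits
#'
#' Arithmetic mean and SD of the fitted KD over accepted replicate fits;
#' rejected fits are excluded and reported.
#'
#' @param fits List of `hill_fit` objects (one per replicate).
#' @return Object of class `affinity_summary`: list with `mean_KD`, `sd_KD`,
#'   `n_accepted`, `n_rejected`, `rejected_reasons`.
#' @examples
#' # mean of (60, 66, 72) nM is 66 +/- 6 nM
#' @export
summarise_affinity <- function(fits) {
  acc <- purrr::keep(fits, "accepted")
  rej <- purrr::discard(fits, "accepted")
  if (length(acc) == 0) {
    abort("no accepted fits: cannot estimate affinity",
          class = "afmdna_no_estimate")
  }
  kds <- purrr::map_dbl(acc, "KD")
  structure(list(
    mean_KD = mean(kds),
    sd_KD = if (length(kds) > 1) sd(kds) else NA_real_,
    n_accepted = length(acc),
    n_rejected = length(rej),
    rejected_reasons = purrr::map_chr(rej, "reason")
  ), class = "affinity_summary")
}

#' @export
print.affinity_summary <- function(x, ...) {
  cat(sprintf("<affinity_summary> KD = %.4g +/- %.3g nM (n = %d accepted",
              x$mean_KD, x$sd_KD, x$n_accepted))
  if (x$n_rejected > 0) cat(sprintf(", %d rejected", x$n_rejected))
  cat(")\n")
  invisible(x)
}

#' Simulate a fluorescence polarisation titration
#'
#' Hill-equation signal with optional multiplicative Gaussian noise; used for
#' calibration and recovery studies.
#'
#' @param concentrations_nM Titration series (default a 12-point half-log
#'   series from 1 to 2000 nM).
#' @param kd,hill_n,baseline,amplitude Hill parameters.
#' @param noise_cv Multiplicative noise coefficient of variation (default
#'   0.02).
#' @param replicate Replicate label.
#' @param seed Optional seed.
#' @return A tibble with `concentration_nM`, `polarisation`, `replicate`.
#' @export
simulate_titration <- function(concentrations_nM = 10^seq(0, log10(2000),
                                                          length.out = 12),
                               kd = 66, hill_n = 1, baseline = 100,
                               amplitude = 150, noise_cv = 0.02,
                               replicate = "r1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- baseline + amplitude * concentrations_nM^hill_n /
    (kd^hill_n + concentrations_nM^hill_n)
  if (noise_cv > 0) p <- p * (1 + rnorm(length(p), 0, noise_cv))
  tibble::tibble(concentration_nM = concentrations_nM, polarisation = p,
                 replicate = replicate)
}
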