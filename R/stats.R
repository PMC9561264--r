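#' Build a folded-position histogram normalised per DNA
#'
#' Bins folded binding positions on fixed edges `[0, bw, ..., 50]` (the last
#' bin right-inclusive) and divides counts by the number of DNA molecules
#' analysed, the per-DNA normalisation used for comparing depositions.
#'
#' @param measurements Measurement tibble (shared schema) or any data frame
#'   with a `position_pct_folded` column.
#' @param bin_width_pct Bin width in percent of DNA length (default 2).
#' @param n_dna Number of DNA molecules analysed; defaults to the table's
#'   `n_dna` attribute.
#' @return A tibble of class `position_histogram` with `bin_lo`, `bin_hi`,
#'   `mid`, `counts`, `counts_per_dna`, and attributes `n_dna`, `bin_width`.
#' @export
build_position_histogram <- function(measurements, bin_width_pct = 2,
                                     n_dna = attr(measurements, "n_dna")) {
  if (is.null(n_dna) || !is.numeric(n_dna) || n_dna <= 0) {
    abort("n_dna must be a positive count", class = "afmdna_invalid_input")
  }
  p <- measurements$position_pct_folded
  p <- p[!is.na(p)]
  if (any(p < 0 | p > 50)) {
    abort("folded positions must lie in [0, 50]", class = "afmdna_invalid_input")
  }
  edges <- seq(0, 50, by = bin_width_pct)
  if (tail(edges, 1) < 50) edges <- c(edges, 50)
  idx <- findInterval(p, edges, rightmost.closed = TRUE, left.open = FALSE)
  idx[p == 0] <- 1L  # findInterval puts 0 in bin 1 already; explicit for clarity
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  out <- tibble::tibble(
    bin_lo = edges[-length(edges)],
    bin_hi = edges[-1],
    mid = (edges[-length(edges)] + edges[-1]) / 2,
    counts = counts,
    counts_per_dna = counts / n_dna
  )
  attr(out, "n_dna") <- n_dna
  attr(out, "bin_width") <- bin_width_pct
  class(out) <- c("position_histogram", class(out))
  out
}

# reflected Gaussian density on the folded [0, 50] scale: events beyond the
# fold-point map back, so the component is mirrored at both boundaries
reflected_dnorm <- function(x, mean, sd, fold = 50) {
  dnorm(x, mean, sd) + dnorm(x, 2 * fold - mean, sd) + dnorm(x, -mean, sd)
}

#' Fit constant background + site Gaussian to a position histogram
#'
#' Least-squares fit of `counts = background + area * bw * G(mid; centre,
#' sd)` with the Gaussian reflected at the 0 and 50% folding boundaries and
#' its centre bounded within +/- 5% of the nominal site position. `A_sp` is
#' the fitted Gaussian area in event counts; `A_nsp` is the background level
#' times the number of bins (total background events over 0-50% DNA length).
#'
#' @param histogram A `position_histogram`.
#' @param site_pct Nominal specific-site position on the folded scale
#'   (e.g. 49.8).
#' @return Object of class `position_fit`: list with `components` (tibble:
#'   `center`, `sd`, `area`), `background_level`, `residual_rss`, `A_sp`,
#'   `A_nsp`, `converged`.
#' @export
fit_position_model <- function(histogram, site_pct = 49.8) {
  if (sum(histogram$counts) == 0) {
    abort("cannot fit an empty histogram", class = "afmdna_invalid_input")
  }
  bw <- attr(histogram, "bin_width")
  df <- tibble::tibble(x = histogram$mid, y = as.numeric(histogram$counts))
  near <- abs(df$x - site_pct) <= 6
  bg0 <- max(median(df$y[!near]), 0.01)
  area0 <- max(sum(df$y[near]) - bg0 * sum(near), 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bg + area * bw * reflected_dnorm(x, mu, sigma),
      data = df,
      start = list(bg = bg0, area = area0, mu = site_pct, sigma = 1.5),
      lower = c(bg = 0, area = 0, mu = site_pct - 5, sigma = 0.3),
      upper = c(bg = Inf, area = Inf, mu = min(site_pct + 5, 50 + 1e-9),
                sigma = 10),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(structure(list(components = tibble::tibble(center = NA_real_,
                                                      sd = NA_real_,
                                                      area = NA_real_),
                          background_level = NA_real_, residual_rss = NA_real_,
                          A_sp = NA_real_, A_nsp = NA_real_, converged = FALSE,
                          diagnostics = "nonlinear least squares failed"),
                     class = "position_fit"))
  }
  cf <- coef(fit)
  n_bins <- nrow(histogram)
  structure(list(
    components = tibble::tibble(center = cf[["mu"]], sd = cf[["sigma"]],
                                area = cf[["area"]]),
    background_level = cf[["bg"]],
    residual_rss = sum(resid(fit)^2),
    A_sp = cf[["area"]],
    A_nsp = cf[["bg"]] * n_bins,
    converged = TRUE
  ), class = "position_fit")
}

#' @export
print.position_fit <- function(x, ...) {
  cat("<position_fit>\n")
  if (x$converged) {
    cat(sprintf("  site Gaussian: centre %.2f%%, sd %.2f, area %.1f events\n",
                x$components$center, x$components$sd, x$A_sp))
    cat(sprintf("  background: %.3f events/bin (A_nsp = %.1f events), rss %.3g\n",
                x$background_level, x$A_nsp, x$residual_rss))
  } else {
    cat("  fit failed:", x$diagnostics, "\n")
  }
  invisible(x)
}

#' Binding specificity from specific and nonspecific occupancy
#'
#' `S = N * (A_sp / A_nsp) + 1`, where `A_sp` is the area under the
#' specific-site Gaussian, `A_nsp` the nonspecific background area over
#' 0-50% DNA length, and `N` the number of available binding sites (base
#' pairs; 505 for the standard substrate). `S = 1` means no specificity.
#'
#' @param A_sp Specific-site Gaussian area (event counts).
#' @param A_nsp Background area (event counts); must be positive.
#' @param N Number of available binding sites (default 505).
#' @return The dimensionless specificity.
#' @examples
#' specificity(10, 10, 505)  # 506
#' @export
specificity <- function(A_sp, A_nsp, N = 505) {
  if (N < 1) abort("N must be >= 1", class = "afmdna_invalid_input")
  if (!is.finite(A_nsp) || A_nsp <= 0) {
    abort("specificity undefined: no nonspecific events observed (A_nsp <= 0)",
          class = "afmdna_undefined_specificity")
  }
  N * (A_sp / A_nsp) + 1
}

#' Site occupancy per DNA in the specific-position bin
#'
#' Counts binding events in the folded-position bin (default 45-50% DNA
#' length) per DNA molecule, per replicate, and summarises across
#' replicates.
#'
#' @param measurements Measurement tibble with a `replicate` column.
#' @param n_dna Number of DNA molecules analysed: a single count (applied to
#'   each replicate), a named vector keyed by replicate label, or a data frame
#'   with columns `replicate` and `n_dna`.
#' @param bin Numeric length-2 folded-position bin (default `c(45, 50)`),
#'   right-inclusive.
#' @param count Count `"events"` in the bin per DNA (default) or
#'   `"molecules"` carrying at least one event in the bin.
#' @return Object of class `occupancy_result`: list with `per_replicate`
#'   (tibble: `replicate`, `n_events`, `n_dna`, `occupancy`), `mean`, `sd`
#'   (`NA` for a single replicate), `bin`.
#' @export
occupancy_at_site <- function(measurements, n_dna, bin = c(45, 50),
                              count = c("events", "molecules")) {
  count <- match.arg(count)
  reps <- unique(measurements$replicate)
  if (length(reps) == 0) reps <- "r1"
  lookup <- if (is.data.frame(n_dna)) {
    setNames(n_dna$n_dna, n_dna$replicate)
  } else if (!is.null(names(n_dna))) {
    n_dna
  } else {
    setNames(rep(n_dna[1], length(reps)), reps)
  }
  per <- purrr::map_dfr(reps, function(r) {
    sub <- measurements[measurements$replicate == r &
                          !is.na(measurements$position_pct_folded), ]
    hit <- sub$position_pct_folded >= bin[1] & sub$position_pct_folded <= bin[2]
    nd <- if (r %in% names(lookup)) lookup[[r]] else NA_real_
    if (is.na(nd) || nd <= 0) {
      abort(sprintf("n_dna missing or non-positive for replicate '%s'", r),
            class = "afmdna_invalid_input")
    }
    n_ev <- if (count == "events") sum(hit) else
      length(unique(sub$molecule_id[hit]))
    tibble::tibble(replicate = r, n_events = n_ev, n_dna = nd,
                   occupancy = n_ev / nd)
  })
  structure(list(
    per_replicate = per,
    mean = mean(per$occupancy),
    sd = if (nrow(per) > 1) sd(per$occupancy) else NA_real_,
    bin = bin
  ), class = "occupancy_result")
}

#' @export
print.occupancy_result <- function(x, ...) {
  cat(sprintf("<occupancy_result> bin [%g, %g]%%: %.4f", x$bin[1], x$bin[2],
              x$mean))
  if (!is.na(x$sd)) cat(sprintf(" +/- %.4f (SD, n = %d replicates)",
                                x$sd, nrow(x$per_replicate)))
  cat(" events/DNA\n")
  invisible(x)
}

#' Decompose a bend-angle distribution into Gaussian states
#'
#' Histograms the angle magnitudes (default 5 deg bins) and fits a
#' `k`-component Gaussian mixture by bounded nonlinear least squares on the
#' bin counts. Components are reflected at 0 deg (angles are magnitudes, so
#' the 0 deg state appears as a half-Gaussian) and centres are bounded to
#' +/- 15 deg of their initialisation.
#'
#' @param angles Bend angles in degrees, in `[0, 180)`.
#' @param k Number of states (1-3).
#' @param init_means Initial state means in degrees (default `c(0, 35, 70)`,
#'   truncated to `k`).
#' @param bin_width_deg Histogram bin width (default 5).
#' @param sd_init Initial within-state sd (default 8).
#' @return Object of class `bend_fit`: list with `components` (tibble:
#'   `center`, `sd`, `area`, ordered by centre), `residual_rss`,
#'   `histogram`, `converged`.
#' @export
decompose_bend_states <- function(angles, k = 3, init_means = c(0, 35, 70),
                                  bin_width_deg = 5, sd_init = 8) {
  angles <- angles[!is.na(angles)]
  if (length(angles) < 30) {
    abort("need at least 30 angles to decompose bend states",
          class = "afmdna_small_sample")
  }
  if (!k %in% 1:3) abort("k must be 1, 2 or 3", class = "afmdna_invalid_input")
  if (any(angles < 0 | angles >= 180)) {
    abort("angles must lie in [0, 180)", class = "afmdna_invalid_input")
  }
  init_means <- init_means[seq_len(k)]
  edges <- seq(0, 180, by = bin_width_deg)
  idx <- findInterval(angles, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  df <- tibble::tibble(x = mids, y = as.numeric(counts))
  bw <- bin_width_deg
  n <- length(angles)
  # a component initialised at 0 deg is a half-Gaussian with its centre fixed
  # at 0 (angles are magnitudes, and a free centre is not identifiable from a
  # half-normal sample); other centres float within +/- 15 deg
  fixed0 <- init_means == 0
  terms <- ifelse(
    fixed0,
    paste0("a", seq_len(k), " * bw * 2 * dnorm(x, 0, s", seq_len(k), ")"),
    paste0("a", seq_len(k), " * bw * (dnorm(x, m", seq_len(k), ", s",
           seq_len(k), ") + dnorm(x, -m", seq_len(k), ", s", seq_len(k), "))")
  )
  form <- stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
  free <- !fixed0
  start <- c(setNames(as.list(rep(n / k, k)), paste0("a", seq_len(k))),
             setNames(as.list(init_means[free]),
                      paste0("m", seq_len(k))[free]),
             setNames(as.list(rep(sd_init, k)), paste0("s", seq_len(k))))
  lower <- c(rep(0, k), pmax(init_means[free] - 15, 0), rep(2, k))
  upper <- c(rep(Inf, k), init_means[free] + 15, rep(25, k))
  do_fit <- function(st) tryCatch(
    minpack.lm::nlsLM(form, data = cbind(df, bw = bw), start = st,
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL
  )
  fit <- do_fit(start)
  cf <- NULL; rss <- NA_real_
  if (!is.null(fit)) {
    cf <- coef(fit)
    rss <- sum(resid(fit)^2)
  } else {
    # gradient can be singular at the start when a component sits over an
    # empty histogram region; fall back to direct bounded least squares
    par0 <- unlist(start)
    predict_counts <- function(p) {
      yy <- rep(0, length(mids))
      for (j in seq_len(k)) {
        aj <- p[[paste0("a", j)]]
        sj <- p[[paste0("s", j)]]
        mj <- if (fixed0[j]) 0 else p[[paste0("m", j)]]
        yy <- yy + aj * bw * (dnorm(mids, mj, sj) + dnorm(mids, -mj, sj))
      }
      yy
    }
    obj <- function(p) {
      names(p) <- names(par0)
      sum((df$y - predict_counts(as.list(p)))^2)
    }
    opt <- tryCatch(
      stats::optim(par0, obj, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 500)),
      error = function(e) NULL
    )
    if (!is.null(opt)) {
      cf <- opt$par
      rss <- opt$value
    }
  }
  hist_tbl <- tibble::tibble(mid = mids, counts = counts)
  if (is.null(cf)) {
    return(structure(list(components = tibble::tibble(center = NA_real_,
                                                      sd = NA_real_,
                                                      area = NA_real_),
                          residual_rss = NA_real_, histogram = hist_tbl,
                          converged = FALSE),
                     class = "bend_fit"))
  }
  centers <- ifelse(fixed0, 0,
                    unname(cf[paste0("m", seq_len(k))])[seq_len(k)])
  comp <- tibble::tibble(
    center = centers,
    sd = unname(cf[paste0("s", seq_len(k))]),
    area = unname(cf[paste0("a", seq_len(k))])
  )
  comp <- comp[order(comp$center), ]
  structure(list(components = comp, residual_rss = rss,
                 histogram = hist_tbl, converged = TRUE),
            class = "bend_fit")
}

#' @export
print.bend_fit <- function(x, ...) {
  cat("<bend_fit>\n")
  if (x$converged) {
    for (i in seq_len(nrow(x$components))) {
      cat(sprintf("  state %d: %.1f deg (sd %.1f), area %.1f\n", i,
                  x$components$center[i], x$components$sd[i],
                  x$components$area[i]))
    }
  } else cat("  fit failed\n")
  invisible(x)
}

#' Compare two triplicate sets by pooled-variance t-test
#'
#' Two-tailed two-sample Student t-test with equal (pooled) variance; with
#' three values per group this has 4 degrees of freedom. Significance stars
#' follow the thresholds * P < 0.05, ** P < 0.01, *** P < 0.005.
#'
#' @param group_a,group_b Numeric vectors of exactly 3 replicate values each.
#' @return Object of class `replicate_comparison`: list with `t_statistic`,
#'   `degrees_freedom` (4), `p_value`, `stars`, `mean_a`, `mean_b`.
#' @examples
#' compare_replicates(c(0.10, 0.10, 0.11), c(0.18, 0.17, 0.19))
#' @export
compare_replicates <- function(group_a, group_b) {
  if (length(group_a) != 3 || length(group_b) != 3) {
    abort("each group must contain exactly 3 replicate values",
          class = "afmdna_invalid_input")
  }
  pooled_var <- (var(group_a) + var(group_b)) / 2
  if (pooled_var == 0) {
    if (mean(group_a) == mean(group_b)) {
      t_stat <- 0; p <- 1; infinite <- FALSE
    } else {
      t_stat <- Inf * sign(mean(group_a) - mean(group_b)); p <- 0
      infinite <- TRUE
    }
  } else {
    ht <- t.test(group_a, group_b, var.equal = TRUE)
    t_stat <- unname(ht$statistic)
    p <- ht$p.value
    infinite <- FALSE
  }
  stars <- if (p < 0.005) "***" else if (p < 0.01) "**" else
    if (p < 0.05) "*" else "ns"
  structure(list(t_statistic = t_stat, degrees_freedom = 4L, p_value = p,
                 stars = stars, mean_a = mean(group_a), mean_b = mean(group_b),
                 infinite_t = infinite),
            class = "replicate_comparison")
}

#' @export
print.replicate_comparison <- function(x, ...) {
  cat(sprintf("<replicate_comparison> t = %.3f (df = %d), P = %.4g [%s]\n",
              x$t_statistic, x$degrees_freedom, x$p_value, x$stars))
  invisible(x)
}

#' @importFrom stats var
NULL
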