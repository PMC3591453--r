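# Richness estimation: frequency counts, bias-corrected Chao1, ACE,
# rarefaction curves with last-k diagnostics, and log-normal fitting of OTU
# abundance distributions.

#' Frequency counts of an abundance vector
#'
#' Histogram of cluster sizes: `F[i]` is the number of clusters with exactly
#' `i` members, so `sum(F) = S_obs` and `sum(i * F[i]) = N`. `F[1]` and
#' `F[2]` are the singleton and doubleton counts driving Chao1.
#'
#' @param av integer vector of cluster sizes (each >= 1), e.g. from
#'   [abundance_vector()].
#' @return An object of class `frequency_counts`: list with `F` (named
#'   integer vector over occupied abundance classes), `N`, `s_obs`.
#' @export
frequency_counts <- function(av) {
  av <- .check_av(av, allow_empty = TRUE)
  if (length(av) == 0L)
    return(structure(list(F = integer(0), N = 0L, s_obs = 0L),
                     class = "frequency_counts"))
  tab <- table(av)
  structure(list(F = setNames(as.integer(tab), names(tab)),
                 N = as.integer(sum(av)), s_obs = length(av)),
            class = "frequency_counts")
}

.check_av <- function(av, allow_empty = FALSE) {
  if (inherits(av, "cluster_map")) av <- abundance_vector(av)
  av <- as.integer(av)
  if (!allow_empty && length(av) == 0L)
    stop("abundance vector is empty")
  if (any(av < 1L)) stop("abundances must be >= 1")
  av
}

.f_count <- function(av, i) sum(av == i)

#' Bias-corrected Chao1 richness estimate
#'
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`: the bias-corrected form, finite
#' even without doubletons. Always `>= S_obs`, with equality iff at most one
#' singleton; with no singletons at all the estimate collapses onto the
#' observed richness, which is why duplicated (x2) communities are estimated
#' exactly.
#'
#' @param av abundance vector (or a `cluster_map`).
#' @return The Chao1 estimate.
#' @export
chao1_corrected <- function(av) {
  av <- .check_av(av)
  f1 <- .f_count(av, 1L)
  f2 <- .f_count(av, 2L)
  length(av) + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' ACE richness estimate
#'
#' Abundance-based Coverage Estimator with the classic rare/abundant split at
#' `rare_cutoff` (default 10). Writing `S_rare`, `N_rare`, `F1` for the rare
#' clusters, the sample coverage is `C = 1 - F1 / N_rare`, the rare-class
#' variation term is
#' `gamma2 = max((S_rare / C) * sum(i (i-1) F_i) / (N_rare (N_rare - 1)) - 1, 0)`,
#' and `ACE = S_abund + S_rare / C + (F1 / C) * gamma2`. Degenerate branches:
#' with no rare clusters the estimate is `S_obs`; with zero coverage (all
#' rare reads are singletons) it falls back to [chao1_corrected()].
#'
#' @inheritParams chao1_corrected
#' @param rare_cutoff rare/abundant split (cluster sizes `<= rare_cutoff`
#'   count as rare).
#' @return The ACE estimate.
#' @export
ace <- function(av, rare_cutoff = 10L) {
  av <- .check_av(av)
  rare <- av[av <= rare_cutoff]
  s_abund <- sum(av > rare_cutoff)
  if (length(rare) == 0L) return(length(av))
  n_rare <- sum(rare)
  f1 <- sum(rare == 1L)
  c_ace <- 1 - f1 / n_rare
  if (c_ace == 0) return(chao1_corrected(av))
  s_rare <- length(rare)
  ss <- sum(vapply(seq_len(rare_cutoff), function(i) i * (i - 1) * sum(rare == i),
                   numeric(1L)))
  gamma2 <- max((s_rare / c_ace) * ss / (n_rare * (n_rare - 1)) - 1, 0)
  s_abund + s_rare / c_ace + (f1 / c_ace) * gamma2
}

#' Richness estimates at one sampling depth
#'
#' @inheritParams ace
#' @param depth sampling depth the abundances were observed at; defaults to
#'   the total read count.
#' @return An object of class `richness_estimate`: list with `s_obs`,
#'   `chao1`, `ace`, `depth`.
#' @export
richness_estimate <- function(av, rare_cutoff = 10L, depth = NULL) {
  av <- .check_av(av)
  structure(list(s_obs = length(av),
                 chao1 = chao1_corrected(av),
                 ace = ace(av, rare_cutoff),
                 depth = if (is.null(depth)) sum(av) else as.integer(depth)),
            class = "richness_estimate")
}

#' @export
print.richness_estimate <- function(x, ...) {
  cat(sprintf("Richness at depth %d: S_obs = %d, Chao1 = %.2f, ACE = %.2f\n",
              x$depth, x$s_obs, x$chao1, x$ace))
  invisible(x)
}

#' Subsample a clustering to a given depth
#'
#' Draws `depth` reads without replacement from the full cluster assignment
#' and returns the sizes of the clusters still represented. Subsampling
#' reuses the one full clustering rather than re-clustering the subsample,
#' matching standard rarefaction practice.
#'
#' @param cm a `cluster_map` (or named integer assignment vector).
#' @param depth number of reads to draw, between 0 and the total read count.
#' @return Integer vector of non-empty cluster sizes (cluster-id order).
#' @export
rarefy_counts <- function(cm, depth) {
  assignments <- if (inherits(cm, "cluster_map")) cm$assignments else cm
  n <- length(assignments)
  if (depth < 0 || depth > n)
    stop("depth must be between 0 and ", n)
  if (depth == 0L) return(integer(0))
  sub <- assignments[sample.int(n, depth)]
  sizes <- tabulate(sub + 1L)
  sizes[sizes > 0L]
}

#' Rarefaction curve of observed and estimated richness
#'
#' For each depth on the grid `step, 2 step, ..., N` (with `N` itself
#' appended if not on the grid) the observed richness, bias-corrected Chao1
#' and ACE are averaged over `iters` independent subsamples. At the final
#' depth every subsample is the full data set, so the curve endpoint equals
#' the full-data estimates exactly.
#'
#' @param cm a `cluster_map`.
#' @param step depth grid spacing in reads (default 100).
#' @param iters subsamples averaged per depth (default 10).
#' @param rare_cutoff ACE rare/abundant split.
#' @param seed optional RNG seed.
#' @return An object of class `rarefaction_curve`: a data frame with columns
#'   `depth`, `mean_obs`, `mean_chao1`, `mean_ace` and attribute `iters`.
#' @export
rarefaction_curve <- function(cm, step = 100L, iters = 10L,
                              rare_cutoff = 10L, seed = NULL) {
  if (step < 1L) stop("step must be >= 1")
  if (iters < 1L) stop("iters must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  assignments <- if (inherits(cm, "cluster_map")) cm$assignments else cm
  n <- length(assignments)
  if (n == 0L) stop("empty cluster map")
  depths <- if (step <= n) as.integer(seq.int(step, n, by = step))
            else integer(0)
  if (length(depths) == 0L || depths[length(depths)] != n)
    depths <- c(depths, as.integer(n))
  res <- matrix(0, length(depths), 3L,
                dimnames = list(NULL, c("mean_obs", "mean_chao1", "mean_ace")))
  for (di in seq_along(depths)) {
    acc <- c(0, 0, 0)
    for (it in seq_len(iters)) {
      sizes <- rarefy_counts(assignments, depths[di])
      acc <- acc + c(length(sizes), chao1_corrected(sizes),
                     ace(sizes, rare_cutoff))
    }
    res[di, ] <- acc / iters
  }
  out <- data.frame(depth = depths, res)
  attr(out, "iters") <- as.integer(iters)
  attr(out, "rare_cutoff") <- as.integer(rare_cutoff)
  class(out) <- c("rarefaction_curve", "data.frame")
  out
}

.curve_series <- function(curve, which = c("chao1", "obs", "ace")) {
  which <- match.arg(which)
  curve[[paste0("mean_", which)]]
}

#' Average of the last k points of a rarefaction series
#'
#' The tail average summarizes where an estimator has settled at the end of
#' the curve (the usual last-10 diagnostic reported alongside rarefaction
#' tables).
#'
#' @param curve a `rarefaction_curve`.
#' @param k number of final points to average (default 10).
#' @param which series: `"chao1"` (default), `"obs"` or `"ace"`.
#' @return Arithmetic mean of the last `k` values.
#' @export
last_k_average <- function(curve, k = 10L, which = c("chao1", "obs", "ace")) {
  s <- .curve_series(curve, which)
  if (length(s) < k) stop("curve has fewer than k = ", k, " points")
  mean(tail(s, k))
}

#' Mean slope over the last k rarefaction steps
#'
#' Mean of the successive differences over the final `k` steps, in estimator
#' units per grid step (not per read; with the default grid one step is
#' `step` reads). Near-zero values indicate a plateau.
#'
#' @inheritParams last_k_average
#' @return Mean per-step difference over the last `k` steps.
#' @export
curve_slope <- function(curve, k = 10L, which = c("chao1", "obs", "ace")) {
  s <- .curve_series(curve, which)
  if (length(s) < k + 1L) stop("curve needs at least k + 1 points")
  mean(diff(tail(s, k + 1L)))
}

#' @export
print.rarefaction_curve <- function(x, ...) {
  cat(sprintf("Rarefaction curve: %d depths up to %d reads (%d iters/depth)\n",
              nrow(x), x$depth[nrow(x)], attr(x, "iters")))
  print.data.frame(tail(x, 5L), row.names = FALSE)
  invisible(x)
}

#' @export
#' @importFrom graphics plot
plot.rarefaction_curve <- function(x, ...) {
  ylim <- range(x$mean_obs, x$mean_chao1, x$mean_ace)
  plot(x$depth, x$mean_obs, type = "l", lwd = 2, ylim = ylim,
       xlab = "sampling depth (reads)", ylab = "OTUs", ...)
  lines(x$depth, x$mean_chao1, lty = 3, lwd = 2)
  lines(x$depth, x$mean_ace, lty = 2, lwd = 2)
  legend("bottomright", c("observed", "Chao1", "ACE"), lty = c(1, 3, 2),
         lwd = 2, bty = "n")
  invisible(x)
}

#' Fit a log-normal distribution to an OTU abundance vector
#'
#' Two estimators are available. `"censored"` (default) is the maximum
#' likelihood fit of a rounded log-normal: an observed size `k >= 2` is
#' treated as the interval `[log(k - 0.5), log(k + 0.5)]` on the log scale
#' and a size of 1 as `(-Inf, log 1.5]`, which models the integer rounding
#' and the floor at 1 that count data carry. This matters: on abundances
#' generated as `max(1, round(exp(z)))` the naive moments of `log(size)` are
#' biased well beyond their standard errors, while the censored fit recovers
#' the generating parameters. `"moments"` is that naive continuous
#' approximation (`mu_hat = mean(log sizes)`, ML sigma, closed-form
#' asymptotic standard errors), kept for comparison.
#'
#' @param av abundance vector (>= 10 clusters) or a `cluster_map`.
#' @param method `"censored"` (default) or `"moments"`.
#' @return An object of class `lognormal_fit`: list with `mu_hat`,
#'   `sigma_hat`, `sd_mu`, `sd_sigma`, `n`, `method`, `degenerate`.
#' @export
fit_lognormal <- function(av, method = c("censored", "moments")) {
  method <- match.arg(method)
  av <- .check_av(av)
  if (length(av) < 10L) stop("need at least 10 clusters to fit")
  n <- length(av)
  if (length(unique(av)) == 1L) {
    # all sizes identical: sigma is not identifiable, flag as degenerate
    return(structure(list(mu_hat = log(av[1L]), sigma_hat = 0,
                          sd_mu = 0, sd_sigma = 0, n = n, method = method,
                          degenerate = TRUE),
                     class = "lognormal_fit"))
  }
  lx <- log(av)
  mu0 <- mean(lx)
  s0 <- sqrt(mean((lx - mu0)^2))
  if (method == "moments") {
    fit <- list(mu_hat = mu0, sigma_hat = s0,
                sd_mu = s0 / sqrt(n), sd_sigma = s0 / sqrt(2 * n))
  } else {
    cens <- data.frame(left = ifelse(av == 1L, NA, log(av - 0.5)),
                       right = log(av + 0.5))
    f <- fitdistrplus::fitdistcens(cens, "norm",
                                   start = list(mean = mu0, sd = max(s0, 0.05)))
    fit <- list(mu_hat = unname(f$estimate["mean"]),
                sigma_hat = unname(f$estimate["sd"]),
                sd_mu = unname(f$sd["mean"]),
                sd_sigma = unname(f$sd["sd"]))
  }
  structure(c(fit, list(n = n, method = method, degenerate = FALSE)),
            class = "lognormal_fit")
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat(sprintf("Log-normal abundance fit (%s, %d clusters)%s\n",
              x$method, x$n, if (x$degenerate) " [degenerate]" else ""))
  cat(sprintf("  mu    = %.3f (sd %.3f)\n", x$mu_hat, x$sd_mu))
  cat(sprintf("  sigma = %.3f (sd %.3f)\n", x$sigma_hat, x$sd_sigma))
  invisible(x)
}

#' Expected rarefied richness (hypergeometric closed form)
#'
#' Exact expectation of the observed cluster count in a subsample of size
#' `depth` drawn without replacement:
#' `sum_j (1 - choose(N - N_j, depth) / choose(N, depth))`. Used as the
#' analytic reference for the Monte-Carlo rarefaction.
#'
#' @param av abundance vector of the full clustering (or a `cluster_map`).
#' @param depth subsample size.
#' @return Expected number of clusters represented in the subsample.
#' @export
expected_rarefied_richness <- function(av, depth) {
  av <- .check_av(av)
  n <- sum(av)
  if (depth < 0 || depth > n) stop("depth must be between 0 and ", n)
  # lchoose keeps this stable for large N
  sum(1 - exp(lchoose(n - av, depth) - lchoose(n, depth)))
}
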