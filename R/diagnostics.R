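#' Simulate response vectors from a fitted occurrence model
#'
#' Draws complete 0/1 response vectors from the fitted binomial mixed
#' model: each simulation redraws country intercepts from
#' Normal(0, sigma_u^2), adds them to the fixed-effect linear predictor,
#' and samples Bernoulli responses. Reproducible under \code{seed}.
#'
#' @param fit A converged \linkS4class{CoralGLMM}.
#' @param n_sim Number of simulations (>= 2).
#' @param seed Integer seed.
#' @param u Optional fixed country intercepts (one per country level):
#'   simulate conditionally on these instead of redrawing. Conditional
#'   simulation makes residuals independent across rows, which the pooled
#'   uniformity test assumes; the marginal (redrawing) form also probes
#'   the random-effect distribution but leaves residuals country-correlated.
#' @return Numeric matrix, response rows x \code{n_sim}.
#' @export
simulateResponses <- function(fit, n_sim = 1000L, seed = 1L, u = NULL) {
  if (!fit@converged) stop("cannot simulate from an unconverged fit")
  if (n_sim < 2L) stop("n_sim must be at least 2")
  d <- fit@data
  fml <- if (nlevels(d$species) > 1L) ~ bin * species else ~ bin
  X <- stats::model.matrix(fml, d)
  eta0 <- drop(X %*% fit@beta)
  ctry <- as.integer(d$country)
  nc <- nlevels(d$country)
  if (!is.null(u)) stopifnot(length(u) == nc)
  set.seed(seed)
  sims <- matrix(0, nrow(d), n_sim)
  for (k in seq_len(n_sim)) {
    uk <- if (is.null(u)) stats::rnorm(nc, 0, fit@sigma_u) else u
    p <- stats::plogis(eta0 + uk[ctry])
    sims[, k] <- stats::rbinom(nrow(d), 1L, p)
  }
  sims
}

#' Randomized-quantile scaled residuals
#'
#' Transforms each observed response to its empirical quantile within the
#' model-simulated distribution for that row, on a standardized [0,1]
#' scale: residual = (#\{sim < obs\} + U * #\{sim = obs\}) / n_sim with U
#' uniform on (0,1). Ties — universal for 0/1 responses — are broken by
#' the uniform jitter between adjacent ranks, using a dedicated RNG stream
#' from \code{seed}. Under a correctly specified model the residuals are
#' uniform on [0,1]; an observation above (below) every simulation scores
#' exactly 1 (0).
#'
#' @param observed Numeric response vector.
#' @param simulations Matrix with \code{length(observed)} rows.
#' @param seed Integer seed for the tie-breaking stream.
#' @param groups Optional factor of survey ids per row (used by the
#'   dispersion test); defaults to one group per row.
#' @return A \linkS4class{ResidualDiagnostics}.
#' @export
scaledResiduals <- function(observed, simulations, seed = 1L,
                            groups = NULL) {
  if (nrow(simulations) != length(observed)) {
    stop("simulations rows must match observed length")
  }
  n_sim <- ncol(simulations)
  k <- rowSums(simulations < observed)
  m <- rowSums(simulations == observed)
  set.seed(seed)
  u <- stats::runif(length(observed))
  res <- (k + u * m) / n_sim
  if (is.null(groups)) groups <- factor(seq_along(observed))
  methods::new("ResidualDiagnostics", scaled = res,
               observed = as.numeric(observed), simulations = simulations,
               expected = rowMeans(simulations), groups = factor(groups),
               n_sim = as.integer(n_sim), seed = as.integer(seed))
}

#' One-call residual diagnostics for a fitted model
#'
#' Simulates from the fit and computes scaled residuals pooled across all
#' response rows of the model, grouped by survey for the dispersion test.
#'
#' @param fit A converged \linkS4class{CoralGLMM}.
#' @param n_sim Number of simulations (default 1000).
#' @param seed Integer seed.
#' @param u Optional fixed country intercepts, see [simulateResponses()].
#' @return A \linkS4class{ResidualDiagnostics}.
#' @export
residualDiagnostics <- function(fit, n_sim = 1000L, seed = 1L, u = NULL) {
  sims <- simulateResponses(fit, n_sim = n_sim, seed = seed, u = u)
  scaledResiduals(fit@data$y, sims, seed = seed + 1L,
                  groups = factor(fit@data$survey))
}

#' Goodness-of-fit tests on scaled residuals
#'
#' Three pooled tests. Uniformity: exact Kolmogorov-Smirnov against
#' Uniform(0,1). Outliers: a binomial test of the count of residuals at
#' exactly 0 or 1 against the expectation 2/(n_sim + 1) per row.
#' Dispersion: because single 0/1 responses carry no free variance, the
#' statistic is the variance across surveys of the observed
#' (total - expected total) group presence count, compared with the same
#' statistic recomputed on each simulated response vector; the ratio of
#' observed to mean simulated variance is reported with a two-sided
#' simulated p-value (add-one convention).
#'
#' @param resid A \linkS4class{ResidualDiagnostics}.
#' @return List: \code{uniformity_p}, \code{dispersion_ratio},
#'   \code{dispersion_p}, \code{outlier_count}, \code{outlier_p},
#'   \code{n}.
#' @export
gofTests <- function(resid) {
  r <- resid@scaled
  n <- length(r)
  uni <- suppressWarnings(stats::ks.test(r, "punif"))$p.value

  out_count <- sum(r == 0 | r == 1)
  # one-sided: only an excess of extreme residuals indicates misfit
  out_p <- stats::binom.test(out_count, n, p = 2 / (resid@n_sim + 1),
                             alternative = "greater")$p.value

  g <- resid@groups
  s_obs <- stats::var(rowsum(resid@observed - resid@expected, g)[, 1])
  S <- rowsum(resid@simulations - resid@expected, g)
  s_sim <- colSums(sweep(S, 2, colMeans(S))^2) / (nrow(S) - 1)
  ratio <- s_obs / mean(s_sim)
  p_hi <- (1 + sum(s_sim >= s_obs)) / (resid@n_sim + 1)
  p_lo <- (1 + sum(s_sim <= s_obs)) / (resid@n_sim + 1)
  disp_p <- min(1, 2 * min(p_hi, p_lo))

  list(uniformity_p = uni, dispersion_ratio = ratio, dispersion_p = disp_p,
       outlier_count = out_count, outlier_p = out_p, n = n)
}

#' Plot-ready diagnostic tables
#'
#' \code{qqUniformTable} returns sorted residuals against uniform
#' theoretical quantiles; \code{residualVsPredictedTable} returns residuals
#' against model-expected values, for external plotting.
#'
#' @param resid A \linkS4class{ResidualDiagnostics}.
#' @return A data.frame.
#' @export
qqUniformTable <- function(resid) {
  n <- length(resid@scaled)
  data.frame(theoretical = (seq_len(n) - 0.5) / n,
             observed = sort(resid@scaled))
}

#' @rdname qqUniformTable
#' @export
residualVsPredictedTable <- function(resid) {
  data.frame(predicted = resid@expected, residual = resid@scaled)
}
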