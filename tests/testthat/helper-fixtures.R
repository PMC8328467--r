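# shared builders for unit and acceptance tests; all fixtures are built in
# code at test time

# minimal model frame for fitOccurrenceModel, bypassing ingest
make_design <- function(y, bin, species, country,
                        survey = sprintf("s%04d", seq_along(y))) {
  d <- data.frame(y = y, bin = bin, species = species, country = country,
                  survey = survey, stringsAsFactors = FALSE)
  attr(d, "cells") <- as.data.frame(table(bin = d$bin, species = d$species),
                                    stringsAsFactors = FALSE)
  d
}

# single-factor binomial mixed data with known truth
sim_bin_data <- function(beta, sigma_u, n_per_bin, n_countries, u = NULL,
                         bins = c("PLEISTOCENE", "B1500_1959",
                                  "B1985_1989", "B2005_2011")[
                                    seq_along(beta)]) {
  n <- n_per_bin * length(bins)
  bin <- factor(rep(bins, each = n_per_bin), levels = bins)
  country <- factor(rep_len(seq_len(n_countries), n))
  if (is.null(u)) u <- stats::rnorm(n_countries, 0, sigma_u)
  eta <- beta[as.integer(bin)] + u[as.integer(country)]
  d <- make_design(stats::rbinom(n, 1, stats::plogis(eta)), bin,
                   factor("X"), country)
  attr(d, "u") <- u
  d
}

# CoralGLMM at known (true) parameters, no fitting involved
true_model <- function(d, beta_by_bin, sigma_u) {
  bins <- levels(d$bin)
  beta <- stats::setNames(
    c(beta_by_bin[1], beta_by_bin[-1] - beta_by_bin[1]),
    c("(Intercept)", paste0("bin", bins[-1])))
  methods::new("CoralGLMM", fit = NULL, engine = "glmer", beta = beta,
               vcov = diag(length(beta)) * 0.01, sigma_u = sigma_u,
               loglik = 0, converged = TRUE, nAGQ = 1L, data = d,
               guild = "X", level = "guild", cells = attr(d, "cells"))
}

# brute-force marginal log-likelihood: fixed fine grid over the country
# random intercept (independent oracle for the AGQ fit)
brute_loglik <- function(fit) {
  d <- fit@data
  fml <- if (nlevels(d$species) > 1L) ~ bin * species else ~ bin
  X <- stats::model.matrix(fml, d)
  eta0 <- drop(X %*% fit@beta)
  half <- max(12 * fit@sigma_u, 8)
  gr <- seq(-half, half, length.out = 40001)
  h <- gr[2] - gr[1]
  sum(vapply(split(seq_len(nrow(d)), d$country), function(idx) {
    f <- vapply(gr, function(u) {
      exp(sum(stats::dbinom(d$y[idx], 1, stats::plogis(eta0[idx] + u),
                            log = TRUE)) +
            stats::dnorm(u, 0, fit@sigma_u, log = TRUE))
    }, numeric(1))
    log(sum(f) * h)
  }, numeric(1)))
}

# small handmade occurrence object
make_occurrence <- function(m, country, bin, zone = "CREST",
                            site = colnames(m)) {
  CoralOccurrence(m, country = country, site = site, bin = bin,
                  zone = zone)
}

# reference step-up BH implementation by direct enumeration
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    prev <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- prev
  }
  pmin(adj, 1)
}
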