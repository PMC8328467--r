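#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' CoralOccurrence: binned presence/absence surveys
#'
#' A \linkS4class{SummarizedExperiment} holding one assay
#' (\code{"occurrence"}): a species-group x survey matrix with cells 1
#' (present), 0 (scored absent) or NA (not scored). Column data carries per
#' survey: \code{survey_id}, \code{country}, \code{site}, \code{bin}
#' (ordered factor over the 11 time bins) and \code{zone}. Standard
#' \code{SummarizedExperiment} subsetting applies; curation counts live in
#' \code{metadata(x)$curation}.
#'
#' @slot .. inherited from SummarizedExperiment.
#' @aliases CoralOccurrence
#' @exportClass CoralOccurrence
setClass("CoralOccurrence", contains = "SummarizedExperiment")

setValidity("CoralOccurrence", function(object) {
  msg <- character(0)
  if (!"occurrence" %in% SummarizedExperiment::assayNames(object)) {
    msg <- c(msg, "assay 'occurrence' is required")
  } else {
    m <- SummarizedExperiment::assay(object, "occurrence")
    if (!all(m %in% c(0, 1) | is.na(m))) {
      msg <- c(msg, "occurrence cells must be 0, 1 or NA")
    }
  }
  if (!all(rownames(object) %in% speciesGroups())) {
    msg <- c(msg, "rownames must be canonical species-group codes")
  }
  cd <- SummarizedExperiment::colData(object)
  need <- c("survey_id", "country", "site", "bin", "zone")
  miss <- setdiff(need, colnames(cd))
  if (length(miss)) {
    msg <- c(msg, paste("colData lacks:", paste(miss, collapse = ", ")))
  } else {
    if (anyNA(cd$country) || any(!nzchar(as.character(cd$country)))) {
      msg <- c(msg, "country must be non-empty for every survey")
    }
    if (anyDuplicated(cd$survey_id)) {
      msg <- c(msg, "survey_id must be unique (one row per survey)")
    }
  }
  if (length(msg)) msg else TRUE
})

#' CoralGLMM: a fitted binomial occurrence model
#'
#' Wraps one binomial mixed-model fit of presence by time bin (x species
#' group) with a country random intercept, together with everything
#' downstream stages need: fixed-effect coefficients and covariance on the
#' logit scale, the country intercept SD, marginal log-likelihood,
#' convergence flag, the model frame and factor levels.
#'
#' @slot fit The underlying engine fit (merMod or glmmTMB).
#' @slot engine Character, \code{"glmer"} or \code{"glmmTMB"}.
#' @slot beta Named numeric, fixed effects (logit scale).
#' @slot vcov Matrix, covariance of \code{beta}.
#' @slot sigma_u Numeric, country random-intercept SD (logit scale).
#' @slot loglik Numeric, maximized marginal log-likelihood.
#' @slot converged Logical.
#' @slot nAGQ Integer, adaptive Gauss-Hermite nodes (1 = Laplace).
#' @slot data data.frame, the long model frame (y, bin, species, country,
#'   survey).
#' @slot guild Character, guild label (or species code for single-taxon
#'   fits).
#' @slot level Character, \code{"species"} (bin x species interaction) or
#'   \code{"guild"} (guild-presence response).
#' @slot cells data.frame of observed bin x species cell counts.
#' @exportClass CoralGLMM
setClass("CoralGLMM",
  representation(fit = "ANY", engine = "character", beta = "numeric",
                 vcov = "matrix", sigma_u = "numeric", loglik = "numeric",
                 converged = "logical", nAGQ = "integer",
                 data = "data.frame", guild = "character",
                 level = "character", cells = "data.frame"))

setValidity("CoralGLMM", function(object) {
  msg <- character(0)
  if (object@sigma_u < 0) msg <- c(msg, "sigma_u must be >= 0")
  if (nrow(object@vcov) != length(object@beta)) {
    msg <- c(msg, "vcov dimension must match beta")
  }
  if (object@converged && !is.finite(object@loglik)) {
    msg <- c(msg, "loglik must be finite for a converged fit")
  }
  if (length(msg)) msg else TRUE
})

#' ResidualDiagnostics: simulation-based scaled residuals
#'
#' Holds randomized-quantile (PIT) residuals of observed responses within
#' their simulated distributions under a fitted model, plus the simulation
#' matrix needed by the goodness-of-fit tests.
#'
#' @slot scaled Numeric in [0,1], one per response row.
#' @slot observed Numeric 0/1 response vector.
#' @slot simulations Matrix (rows x n_sim) of simulated responses.
#' @slot expected Numeric, per-row simulated mean.
#' @slot groups Factor grouping rows into surveys (dispersion test unit).
#' @slot n_sim Integer number of simulations.
#' @slot seed Integer seed used for simulation and tie-breaking.
#' @exportClass ResidualDiagnostics
setClass("ResidualDiagnostics",
  representation(scaled = "numeric", observed = "numeric",
                 simulations = "matrix", expected = "numeric",
                 groups = "factor", n_sim = "integer", seed = "integer"))

setValidity("ResidualDiagnostics", function(object) {
  msg <- character(0)
  if (any(object@scaled < 0 | object@scaled > 1)) {
    msg <- c(msg, "scaled residuals must lie in [0,1]")
  }
  if (length(object@scaled) != length(object@observed)) {
    msg <- c(msg, "residual length must equal response rows")
  }
  if (length(msg)) msg else TRUE
})

#' DissimilaritySeries: within-country community dissimilarity by time bin
#'
#' Per-bin country-equalized Jaccard dissimilarity: the per-country mean
#' over all within-country site pairs, the unweighted grand mean across
#' countries, a bootstrap interval from resampled country means, and
#' pairwise between-bin permutation tests (BH-adjusted).
#'
#' @slot zone Character.
#' @slot series data.frame: bin, grand_mean, ci_low, ci_high, n_countries,
#'   n_site_pairs.
#' @slot country_means Named list (by bin) of named numeric country means.
#' @slot comparisons data.frame: bin_a, bin_b, statistic, raw_p, adjusted_p.
#' @exportClass DissimilaritySeries
setClass("DissimilaritySeries",
  representation(zone = "character", series = "data.frame",
                 country_means = "list", comparisons = "data.frame"))

setValidity("DissimilaritySeries", function(object) {
  s <- object@series
  msg <- character(0)
  if (nrow(s)) {
    if (any(s$grand_mean < 0 | s$grand_mean > 1, na.rm = TRUE)) {
      msg <- c(msg, "dissimilarities must lie in [0,1]")
    }
    if (any(s$ci_low > s$grand_mean | s$ci_high < s$grand_mean,
            na.rm = TRUE)) {
      msg <- c(msg, "grand mean must lie inside its interval")
    }
  }
  if (length(msg)) msg else TRUE
})
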