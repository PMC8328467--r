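#' Jaccard dissimilarity between two presence vectors
#'
#' 1 minus the ratio of shared to total present species. Undefined (NA,
#' with the pair skipped downstream) when neither community has any
#' tracked species.
#'
#' @param a,b Equal-length 0/1 vectors.
#' @return Value in [0,1], or NA if both vectors are all-zero.
#' @export
#' @examples
#' jaccardDissimilarity(c(1, 1, 1, 0, 0), c(0, 0, 1, 1, 0))  # 0.75
jaccardDissimilarity <- function(a, b) {
  stopifnot(length(a) == length(b), all(a %in% 0:1), all(b %in% 0:1))
  uni <- sum(a == 1 | b == 1)
  if (uni == 0) return(NA_real_)
  1 - sum(a == 1 & b == 1) / uni
}

# all-pairs binary Jaccard distances for a sites x species matrix,
# via vegan; returns the dist object (NA where a pair's union is empty)
.jaccardPairs <- function(sites_by_species) {
  empty <- rowSums(sites_by_species) == 0
  d <- suppressWarnings(
    vegan::vegdist(sites_by_species, method = "jaccard", binary = TRUE))
  dm <- as.matrix(d)
  # only pairs where BOTH sites are empty are undefined (empty union);
  # an empty site against a non-empty one is maximally dissimilar
  dm[empty, empty] <- NA
  dm[empty, !empty] <- 1
  dm[!empty, empty] <- 1
  stats::as.dist(dm)
}

#' Mean within-country dissimilarity
#'
#' Unweighted mean of the Jaccard dissimilarity over all C(n,2) site pairs
#' of one country within one bin. Pairs where both sites are empty are
#' skipped (Jaccard is undefined on empty sets); countries need at least
#' two sites to contribute.
#'
#' @param sites_by_species 0/1 matrix, one row per site of the country.
#' @return List: \code{mean}, \code{n_pairs} (pairs actually scored).
#' @export
withinCountryMean <- function(sites_by_species) {
  if (nrow(sites_by_species) < 2L) {
    stop("need at least 2 sites for within-country pairs")
  }
  d <- as.vector(.jaccardPairs(sites_by_species))
  list(mean = mean(d, na.rm = TRUE), n_pairs = sum(!is.na(d)))
}

#' Country-equalized grand mean
#'
#' Each country contributes with weight 1 regardless of its number of
#' sites, so heavily surveyed countries do not dominate the bin mean.
#'
#' @param country_means Named numeric vector of per-country means.
#' @return The unweighted arithmetic mean.
#' @export
binGrandMean <- function(country_means) {
  if (!length(country_means)) stop("no country means supplied")
  mean(country_means)
}

#' Bootstrap interval for a bin's grand mean
#'
#' Resamples the country means with replacement (sample size = number of
#' countries) B times; the interval is formed by the 5th and 95th
#' empirical quantiles of the resampled grand means — as printed in the
#' source procedure this is a nominally 90% interval; \code{probs =
#' c(0.025, 0.975)} gives a conventional 95% one.
#'
#' @param country_means Named numeric vector.
#' @param B Number of resamples (default 1000).
#' @param seed Integer seed.
#' @param probs Lower/upper quantiles (default \code{c(0.05, 0.95)}).
#' @return Numeric \code{c(ci_low, ci_high)}.
#' @export
bootstrapCI <- function(country_means, B = 1000L, seed = 1L,
                        probs = c(0.05, 0.95)) {
  stopifnot(length(country_means) >= 1L, B >= 1L)
  n <- length(country_means)
  set.seed(seed)
  draws <- matrix(country_means[sample.int(n, n * B, replace = TRUE)],
                  nrow = B)
  stats::quantile(rowMeans(draws), probs = probs, names = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (delegates to
#' \code{stats::p.adjust}), with input validation.
#'
#' @param p Numeric vector of p-values in [0,1].
#' @return Adjusted p-values in input order.
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0,1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Pairwise between-bin permutation tests on country means
#'
#' For each pair of bins, a Welch t statistic on the two sets of country
#' means; the null distribution is built by B random reassignments of the
#' pooled country means to the two bins (the permutation unit is the
#' country-level mean, consistent with country-equalized inference).
#' p = (1 + #\{|t_perm| >= |t_obs|\}) / (B + 1); all raw p-values are
#' BH-adjusted as one family. Bins with fewer than 2 country means are
#' skipped.
#'
#' @param country_means_by_bin Named list (by bin code) of named numeric
#'   vectors of country means.
#' @param B Permutations per pair (default 1000).
#' @param seed Integer seed.
#' @return data.frame: bin_a, bin_b, statistic, raw_p, adjusted_p.
#' @export
pairwisePermutationTests <- function(country_means_by_bin, B = 1000L,
                                     seed = 1L) {
  stopifnot(B >= 1L)
  bins <- names(country_means_by_bin)
  usable <- bins[vapply(country_means_by_bin, length, 1L) >= 2L]
  if (length(usable) < 2L) {
    return(data.frame(bin_a = character(0), bin_b = character(0),
                      statistic = numeric(0), raw_p = numeric(0),
                      adjusted_p = numeric(0)))
  }
  set.seed(seed)
  welch_t <- function(x, y) {
    (mean(x) - mean(y)) /
      sqrt(stats::var(x) / length(x) + stats::var(y) / length(y))
  }
  pr <- utils::combn(usable, 2)
  rows <- lapply(seq_len(ncol(pr)), function(j) {
    x <- country_means_by_bin[[pr[1, j]]]
    y <- country_means_by_bin[[pr[2, j]]]
    t_obs <- welch_t(x, y)
    pool <- c(x, y); nx <- length(x)
    t_perm <- vapply(seq_len(B), function(b) {
      idx <- sample.int(length(pool), nx)
      welch_t(pool[idx], pool[-idx])
    }, numeric(1))
    raw <- (1 + sum(abs(t_perm) >= abs(t_obs))) / (B + 1)
    data.frame(bin_a = pr[1, j], bin_b = pr[2, j], statistic = t_obs,
               raw_p = raw, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- bhAdjust(out$raw_p)
  out
}

#' Within-country dissimilarity series across time bins
#'
#' The community-homogenization analysis: for each time bin and reef zone,
#' Jaccard dissimilarity over all within-country site pairs, per-country
#' means, the country-equalized grand mean, a bootstrap interval, and
#' pairwise between-bin permutation tests. Only surveys scoring all 14
#' species groups enter (dissimilarity needs complete presence vectors);
#' countries contribute to a bin only with >= 2 such surveys.
#'
#' @param x A \linkS4class{CoralOccurrence} (one zone; subset first if
#'   needed).
#' @param B_boot,B_perm Bootstrap / permutation iterations (default 1000).
#' @param seed Integer seed.
#' @param probs Bootstrap quantiles, see [bootstrapCI()].
#' @return A \linkS4class{DissimilaritySeries}.
#' @export
dissimilaritySeries <- function(x, B_boot = 1000L, B_perm = 1000L,
                                seed = 1L, probs = c(0.05, 0.95)) {
  zone <- unique(surveyData(x)$zone)
  if (length(zone) > 1L) stop("subset to a single zone first")
  full <- filterFullComplement(x, speciesGroups())
  cd <- surveyData(full)
  m <- t(occurrenceMatrix(full))  # sites x species
  bins <- binLevels()[binLevels() %in% as.character(cd$bin)]
  cmeans <- list()
  series <- list()
  for (i in seq_along(bins)) {
    b <- bins[i]
    sel <- as.character(cd$bin) == b
    cm <- c(); npairs <- 0L
    for (ctry in unique(cd$country[sel])) {
      rows <- sel & cd$country == ctry
      if (sum(rows) < 2L) next
      w <- withinCountryMean(m[rows, , drop = FALSE])
      if (is.nan(w$mean) || w$n_pairs == 0L) next
      cm[ctry] <- w$mean
      npairs <- npairs + w$n_pairs
    }
    cmeans[[b]] <- cm
    if (length(cm)) {
      ci <- bootstrapCI(cm, B = B_boot, seed = seed + i, probs = probs)
      series[[b]] <- data.frame(bin = b, grand_mean = binGrandMean(cm),
                                ci_low = ci[1], ci_high = ci[2],
                                n_countries = length(cm),
                                n_site_pairs = npairs,
                                stringsAsFactors = FALSE)
    }
  }
  comparisons <- pairwisePermutationTests(cmeans, B = B_perm,
                                          seed = seed + 1000L)
  methods::new("DissimilaritySeries", zone = zone,
               series = do.call(rbind, c(series,
                                         list(make.row.names = FALSE))),
               country_means = cmeans, comparisons = comparisons)
}

#' @describeIn DissimilaritySeries-accessors per-bin series table
#' @export
dissimilarityTable <- function(x) x@series

#' Accessors for DissimilaritySeries
#' @param x A \linkS4class{DissimilaritySeries}.
#' @name DissimilaritySeries-accessors
NULL

#' @describeIn DissimilaritySeries-accessors pairwise bin comparisons
#' @export
binComparisons <- function(x) x@comparisons

setMethod("show", "DissimilaritySeries", function(object) {
  cat("DissimilaritySeries zone:", object@zone, "\n")
  print(object@series, row.names = FALSE, digits = 3)
})
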