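# reefchrono

Reconstructing 131,000 years of Caribbean reef coral community change from
heterogeneous presence/absence survey records.

Paleoecological, historical, and modern reef surveys share only one
currency: whether a coral taxon was recorded present at a site. This
package turns such records into a harmonized, binned site x species
occurrence database and provides the statistical machinery to ask how the
occurrence of 14 common Caribbean coral species groups — and the
competitive, stress-tolerant, and weedy life-history guilds they form —
changed from the prehuman Pleistocene to 2011, and whether coral
communities homogenized within countries along the way. It is written for
quantitative ecologists and conservation paleobiologists working with
compiled occurrence databases.

## The models at the core

**Occurrence trends.** For member species *s* of a guild, presence at
survey *i* (country *c*, time bin *t*) is modelled by a binomial GLMM

> y_is ~ Bernoulli(p_is),  logit(p_is) = β_{t(i),s} + u_{c(i)},  u_c ~ N(0, σ_u²)

with a fully interacted bin x species fixed structure and a country random
intercept absorbing uneven geographic sampling; the marginal likelihood
integrates u by adaptive Gauss–Hermite quadrature (Laplace by default).
Fitted occurrence per bin is the inverse-logit of the cell predictor at
the random-effect mode, guild curves average member predictions on the
link scale, and all pairwise bin contrasts are tested with a single-step
max-|z| (Tukey-style) familywise adjustment. Model fit is checked with
simulation-based scaled residuals (uniformity, outlier, and dispersion
tests; 1,000 simulations).

**Homogenization.** Within each bin, Jaccard dissimilarity
1 − |A∩B|/|A∪B| over all within-country site pairs is averaged per
country, then across countries with equal weight; uncertainty comes from
bootstrap resampling of country means (1,000 draws, 5th/95th quantiles)
and between-bin differences from permutation tests on country means
(1,000 permutations, Welch t, Benjamini–Hochberg across bin pairs).

A synthetic survey generator (`defaultCaribbeanScenario()`) encodes the
qualitative three-phase history — competitive collapse by the 1960s,
stress-tolerant/weedy rise to late-1980s/early-1990s peaks, post-1960
homogenization, time-averaged fossil bins — as known ground truth, so the
entire pipeline is testable without access to compiled field data.

## Worked example

Generate the default scenario, harmonize it through the ingest path, fit
the weedy-guild model, and summarize trends:

```r
library(reefchrono)

sim <- generateDataset(defaultCaribbeanScenario(), seed = 1)
f <- tempfile(fileext = ".csv")
writeSurveyCSV(sim$surveys, f)
occ <- buildOccurrence(readSurveyCSV(f, "wide"))
occ
#> CoralOccurrence: 14 species groups x 2736 surveys
#>   zones: CREST
#>   bins:  PLEISTOCENE, HOLOCENE, B1500_1959, B1960_1969, B1970_1979, B1980_1984, B1985_1989, B1990_1994, B1995_2000, B2001_2004, B2005_2011
#>   countries: 24
#>   cells: 97.0% scored (non-missing)

filt <- filterFullComplement(occ, "WEEDY")
fit <- fitOccurrenceModel(buildGuildDesign(filt), engine = "glmmTMB",
                          guild = "WEEDY")
mm <- marginalMeans(fit, level = "guild")
ct <- tukeyContrasts(fit, level = "guild", seed = 1)
trendSummary(mm, ct)
#>   taxon start_proportion end_proportion overall_significant
#> 1 WEEDY        0.1795235      0.5487051                TRUE
#>   earliest_sig_change_vs_pleistocene   peak_bin earliest_sig_decline_from_peak
#> 1                         B1960_1969 B1995_2000                     B2001_2004
```

The summary reads: weedy corals occupied ~18% of sites in the Pleistocene
baseline and ~55% in 2005–2011; the first significant departure from the
baseline is in the 1960s bin; fitted occurrence peaks in the mid-1990s
bin (the generator's true peak is 1990–1994; at this seed the fitted
curve crests one bin later) and first declines significantly from that
peak in 2001–2004.

Homogenization on the same data:

```r
ds <- dissimilaritySeries(occ, seed = 1)
dissimilarityTable(ds)[c(1, 3, 11), ]
#>            bin grand_mean    ci_low   ci_high n_countries n_site_pairs
#> 1  PLEISTOCENE  0.4679951 0.4364335 0.5070581          24          304
#> 3   B1500_1959  0.5496501 0.5158323 0.5833057          24          329
#> 11  B2005_2011  0.4067007 0.3673524 0.4479380          24          641
```

Mean within-country dissimilarity falls from 0.55 in the 1500–1959
baseline to 0.41 in 2005–2011 (communities became more alike), while the
time-averaged fossil bins sit below the historical baseline — the
artifact fossil data are expected to show. The full pipeline
(`runPipeline()`) writes these tables plus contrasts, goodness-of-fit
reports, and a run report; `inst/scripts/reefchrono.R` wraps it for shell
use.

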