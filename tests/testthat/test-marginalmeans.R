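fit_small <- local({
  set.seed(23)
  d <- sim_bin_data(beta = c(0.5, -0.3, 0.9, 1.2), sigma_u = 0.8,
                    n_per_bin = 40, n_countries = 6)
  fitOccurrenceModel(d, engine = "glmer")
})

test_that("fitted proportions are inverse-logit images of the link scale", {
  mm <- marginalMeans(fit_small, level = "taxa")
  expect_equal(mm$proportion, plogis(mm$link_estimate))
  expect_equal(mm$ci_low,
               plogis(mm$link_estimate - qnorm(0.975) * mm$link_se))
  expect_true(all(mm$ci_low <= mm$proportion &
                    mm$proportion <= mm$ci_high))
  # link estimate 0 with se 1 gives 0.5 (0.123, 0.877)
  expect_equal(plogis(0), 0.5)
  expect_equal(round(plogis(c(-1, 1) * qnorm(0.975)), 3), c(0.123, 0.877))
})

test_that("marginal means match emmeans on the same fit", {
  skip_if_not_installed("emmeans")
  mm <- marginalMeans(fit_small, level = "taxa")
  em <- as.data.frame(emmeans::emmeans(fit_small@fit, ~bin))
  expect_equal(mm$link_estimate, em$emmean, tolerance = 1e-10)
  expect_equal(mm$link_se, em$SE, tolerance = 1e-8)
})

test_that("guild curves equal the enumeration over member species", {
  set.seed(29)
  ns <- 120
  m <- matrix(rbinom(3 * ns, 1, 0.5), 3, ns,
              dimnames = list(c("ACER", "APAL", "MILLEPORA"),
                              sprintf("s%03d", 1:ns)))
  occ <- make_occurrence(m, country = sample(c("JAM", "CUB", "BHS"), ns,
                                             replace = TRUE),
                         bin = rep(c("PLEISTOCENE", "B1985_1989",
                                     "B2005_2011"), each = ns / 3))
  fit <- fitOccurrenceModel(suppressWarnings(buildGuildDesign(occ)),
                            engine = "glmer", guild = "COMPETITIVE")
  mm <- marginalMeans(fit, level = "both")
  sp <- mm[mm$taxon %in% rownames(m), ]
  gd <- mm[mm$taxon == "COMPETITIVE", ]
  for (b in unique(gd$bin)) {
    expect_equal(gd$link_estimate[gd$bin == b],
                 mean(sp$link_estimate[sp$bin == b]), tolerance = 1e-12)
  }
})

test_that("a two-bin family needs no adjustment", {
  set.seed(31)
  d <- sim_bin_data(beta = c(0.2, 0.6), sigma_u = 0.5,
                    n_per_bin = 50, n_countries = 5)
  fit <- fitOccurrenceModel(d, engine = "glmer")
  ct <- tukeyContrasts(fit, level = "taxa")
  expect_equal(nrow(ct), 1L)
  expect_equal(ct$adjusted_p, ct$raw_p)
  expect_equal(ct$raw_p, 2 * pnorm(-abs(ct$z)))
})

test_that("familywise adjustment matches multivariate-normal quadrature", {
  # independent oracle: mvtnorm::pmvnorm over the contrast correlation
  ct <- tukeyContrasts(fit_small, level = "taxa", seed = 5)
  cg <- reefchrono:::.cellGrid(fit_small)
  pr <- utils::combn(4, 2)
  D <- cg$L[pr[2, ], ] - cg$L[pr[1, ], ]
  R <- stats::cov2cor(D %*% fit_small@vcov %*% t(D))
  oracle <- vapply(abs(ct$z), function(zz) {
    1 - mvtnorm::pmvnorm(lower = rep(-zz, 6), upper = rep(zz, 6),
                         corr = R,
                         algorithm = mvtnorm::GenzBretz(abseps = 1e-6))[1]
  }, numeric(1))
  expect_lt(max(abs(ct$adjusted_p - oracle)), 0.01)
  expect_true(all(ct$adjusted_p >= ct$raw_p - 1e-12))
})

test_that("adjusted p-values agree with emmeans mvt adjustment", {
  skip_if_not_installed("emmeans")
  ct <- tukeyContrasts(fit_small, level = "taxa", seed = 7)
  ec <- as.data.frame(emmeans::contrast(
    emmeans::emmeans(fit_small@fit, ~bin), "pairwise", adjust = "mvt"))
  expect_equal(ct$adjusted_p, ec$p.value, tolerance = 0.02)
})

test_that("trend summaries read peaks and changes off the fitted series", {
  bins <- c("PLEISTOCENE", "HOLOCENE", "B1960_1969", "B2005_2011")
  mk <- function(props) {
    data.frame(taxon = "X", bin = bins, link_estimate = qlogis(props),
               link_se = 0.1, proportion = props,
               ci_low = props - 0.05, ci_high = props + 0.05)
  }
  mk_ct <- function(p_by_pair) {
    pr <- utils::combn(bins, 2)
    data.frame(taxon = "X", bin_a = pr[1, ], bin_b = pr[2, ],
               estimate = 0, se = 1, z = 0, raw_p = p_by_pair,
               adjusted_p = p_by_pair)
  }
  # monotone increase, all changes significant: peak last, no decline
  tr <- trendSummary(mk(c(0.2, 0.4, 0.6, 0.8)), mk_ct(rep(0.001, 6)))
  expect_equal(tr$peak_bin, "B2005_2011")
  expect_true(is.na(tr$earliest_sig_decline_from_peak))
  expect_true(tr$overall_significant)
  expect_equal(tr$earliest_sig_change_vs_pleistocene, "HOLOCENE")
  # flat series with wide intervals: nothing significant anywhere
  tr2 <- trendSummary(mk(rep(0.5, 4)), mk_ct(rep(0.9, 6)))
  expect_false(tr2$overall_significant)
  expect_true(is.na(tr2$earliest_sig_change_vs_pleistocene))
  expect_true(is.na(tr2$earliest_sig_decline_from_peak))
  # collapse after an early peak: decline bin follows the peak
  props <- c(0.8, 0.85, 0.3, 0.2)
  pvals <- c(0.9, 0.01, 0.01, 0.001, 0.001, 0.2)  # PH,P60,P11,H60,H11,6011
  tr3 <- trendSummary(mk(props), mk_ct(pvals))
  expect_equal(tr3$peak_bin, "HOLOCENE")
  expect_equal(tr3$earliest_sig_decline_from_peak, "B1960_1969")
  expect_equal(tr3$earliest_sig_change_vs_pleistocene, "B1960_1969")
})
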