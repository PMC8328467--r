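test_that("Jaccard dissimilarity counts shared against total species", {
  expect_equal(jaccardDissimilarity(c(1, 1, 0), c(1, 1, 0)), 0)
  expect_equal(jaccardDissimilarity(c(1, 1, 0, 0), c(0, 0, 1, 1)), 1)
  # {ACER, APAL, ORBICELLA} vs {ORBICELLA, AGARICIA}: 1 shared of 4
  expect_equal(jaccardDissimilarity(c(1, 1, 1, 0), c(0, 0, 1, 1)), 0.75)
  expect_true(is.na(jaccardDissimilarity(c(0, 0), c(0, 0))))
  expect_error(jaccardDissimilarity(c(1, 0), c(1, 0, 1)))
})

test_that("pairwise engine agrees with the direct set-count formula", {
  set.seed(61)
  m <- matrix(rbinom(10 * 14, 1, 0.5), 10)
  d <- as.matrix(reefchrono:::.jaccardPairs(m))
  for (i in 1:9) for (j in (i + 1):10) {
    expect_equal(d[i, j], jaccardDissimilarity(m[i, ], m[j, ]))
  }
})

test_that("Jaccard is a metric on non-empty vectors (6-species alphabet)", {
  vecs <- as.matrix(expand.grid(rep(list(0:1), 6)))
  vecs <- vecs[rowSums(vecs) > 0, ]          # 63 non-empty communities
  D <- as.matrix(reefchrono:::.jaccardPairs(vecs))
  diag(D) <- 0
  expect_true(all(D >= 0 & D <= 1))
  expect_equal(D, t(D))
  # identity of indiscernibles
  for (i in seq_len(nrow(vecs))) {
    expect_true(all(D[i, -i][apply(vecs[-i, ], 1, identical,
                                   vecs[i, ])] == 0))
    expect_true(all(D[i, -i][!apply(vecs[-i, ], 1, identical,
                                    vecs[i, ])] > 0))
  }
  # triangle inequality over all ordered triples, vectorized per midpoint
  for (j in seq_len(nrow(vecs))) {
    expect_true(all(D <= outer(D[, j], D[j, ], "+") + 1e-12))
  }
})

test_that("within-country means enumerate all site pairs", {
  set.seed(67)
  m3 <- matrix(rbinom(3 * 14, 1, 0.6), 3)
  w <- withinCountryMean(m3)
  oracle <- mean(c(jaccardDissimilarity(m3[1, ], m3[2, ]),
                   jaccardDissimilarity(m3[1, ], m3[3, ]),
                   jaccardDissimilarity(m3[2, ], m3[3, ])))
  expect_equal(w$mean, oracle)
  expect_equal(w$n_pairs, 3L)
  m2 <- m3[1:2, ]
  expect_equal(withinCountryMean(m2)$mean,
               jaccardDissimilarity(m2[1, ], m2[2, ]))
  expect_error(withinCountryMean(m3[1, , drop = FALSE]), "at least 2")
})

test_that("empty-empty site pairs are skipped, not scored", {
  m <- rbind(c(1, 1, 0), c(0, 0, 0), c(0, 0, 0))
  w <- withinCountryMean(m)
  # the empty-empty pair is dropped; two informative pairs remain
  expect_equal(w$n_pairs, 2L)
  expect_equal(w$mean, 1)
})

test_that("grand means weight countries equally", {
  expect_equal(binGrandMean(c(A = 0.2, B = 0.6)), 0.4)
  expect_equal(binGrandMean(c(A = 0.3)), 0.3)
  expect_equal(binGrandMean(rep(0.42, 7)), 0.42)
  expect_error(binGrandMean(numeric(0)), "no country means")
})

test_that("grand mean ignores site-count duplication within a country", {
  # duplicating one country's sites changes its mean not at all and its
  # weight not at all: recompute the series with country A's sites doubled
  set.seed(71)
  m <- matrix(rbinom(6 * 14, 1, 0.5), 6)
  cm1 <- c(A = withinCountryMean(m[1:3, ])$mean,
           B = withinCountryMean(m[4:6, ])$mean)
  mdup <- rbind(m[1:3, ], m[1:3, ], m[4:6, ])
  cmA <- withinCountryMean(mdup[1:6, ])$mean
  # duplicated sites add zero-distance pairs, so the country mean changes,
  # but the grand mean still weights the two countries 1:1
  expect_equal(binGrandMean(c(A = cmA, B = cm1["B"])),
               mean(c(cmA, cm1["B"])), ignore_attr = TRUE)
})

test_that("bootstrap intervals collapse on degenerate inputs", {
  expect_equal(bootstrapCI(rep(0.4, 8), B = 200, seed = 1), c(0.4, 0.4))
  expect_equal(bootstrapCI(c(X = 0.37), B = 50, seed = 1), c(0.37, 0.37))
})

test_that("bootstrap quantile choice is configurable", {
  set.seed(73)
  cm <- runif(20, 0.3, 0.7)
  ci90 <- bootstrapCI(cm, B = 2000, seed = 2)
  ci95 <- bootstrapCI(cm, B = 2000, seed = 2, probs = c(0.025, 0.975))
  expect_lt(ci95[1], ci90[1])
  expect_gt(ci95[2], ci90[2])
})

test_that("BH adjustment equals the step-up enumeration", {
  expect_equal(bhAdjust(0.05), 0.05)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(79)
  for (i in 1:20) {
    p <- runif(sample(1:30, 1))
    expect_equal(bhAdjust(p), bh_oracle(p))
    expect_true(all(bhAdjust(p) >= p))
  }
  expect_error(bhAdjust(c(0.1, 1.2)), "0,1")
})

test_that("permutation tests honor identical and separated samples", {
  cm <- list(B1500_1959 = c(a = 0.2, b = 0.4, c = 0.6),
             B2005_2011 = c(a = 0.6, b = 0.2, c = 0.4))
  out <- pairwisePermutationTests(cm, B = 200, seed = 1)
  expect_equal(out$raw_p, 1)  # same multiset: |t_obs| = 0
  sep <- list(A = seq(0.1, 0.19, 0.01), B = seq(0.6, 0.69, 0.01))
  out2 <- pairwisePermutationTests(sep, B = 1000, seed = 2)
  # full separation: close to the minimum achievable (1+k)/(B+1)
  expect_lte(out2$raw_p, 3 / 1001)
  # single-country bins are skipped
  cm3 <- list(A = c(x = 0.5), B = c(x = 0.2, y = 0.3),
              C = c(x = 0.4, y = 0.6))
  out3 <- pairwisePermutationTests(cm3, B = 100, seed = 3)
  expect_setequal(out3$bin_a, "B")
  expect_setequal(out3$bin_b, "C")
})

test_that("the full dissimilarity series assembles and validates", {
  set.seed(83)
  ns <- 60
  m <- matrix(rbinom(14 * ns, 1, 0.5), 14, ns,
              dimnames = list(speciesGroups(), sprintf("s%03d", 1:ns)))
  occ <- make_occurrence(m,
                         country = rep(c("JAM", "CUB", "BHS"), ns / 3),
                         bin = rep(c("B1500_1959", "B2005_2011"),
                                   each = ns / 2))
  ds <- dissimilaritySeries(occ, B_boot = 200, B_perm = 200, seed = 1)
  tab <- dissimilarityTable(ds)
  expect_equal(nrow(tab), 2L)
  expect_true(all(tab$ci_low <= tab$grand_mean &
                    tab$grand_mean <= tab$ci_high))
  expect_equal(tab$n_countries, c(3L, 3L))
  cmp <- binComparisons(ds)
  expect_equal(nrow(cmp), 1L)
  expect_true(all(cmp$adjusted_p >= cmp$raw_p))
})
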