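rep_df <- function(present_by_rep, group = "AGARICIA") {
  do.call(rbind, lapply(seq_along(present_by_rep), function(i) {
    data.frame(country = "JAM", site = "siteA", zone = "CREST",
               year_or_age = 1987, group = group,
               present = present_by_rep[[i]], stringsAsFactors = FALSE)
  }))
}

test_that("replicates combine by logical OR with missing propagation", {
  expect_equal(aggregateReplicates(rep_df(list(1, 0, 0)))$present, 1)
  expect_equal(aggregateReplicates(rep_df(list(0, 0)))$present, 0)
  expect_equal(aggregateReplicates(rep_df(list(NA, NA)))$present,
               NA_real_)
  expect_equal(aggregateReplicates(rep_df(list(NA, 0)))$present, 0)
})

test_that("disjoint replicate scorings union with OR of presences", {
  # enumeration oracle: aggregate naively per species over all replicates
  set.seed(4)
  for (rep_i in 1:20) {
    n_rep <- sample(2:4, 1)
    sp <- sample(speciesGroups(), 5)
    long <- do.call(rbind, lapply(seq_len(n_rep), function(r) {
      scored <- sample(sp, sample(2:5, 1))
      data.frame(country = "CUB", site = "s1", zone = "CREST",
                 year_or_age = 1990, group = scored,
                 present = rbinom(length(scored), 1, 0.5),
                 stringsAsFactors = FALSE)
    }))
    agg <- aggregateReplicates(long)
    oracle <- vapply(sp, function(s) {
      v <- long$present[long$group == s]
      if (!length(v)) NA_real_ else as.numeric(any(v == 1))
    }, numeric(1))
    got <- stats::setNames(agg$present, agg$group)[sp]
    expect_identical(unname(got), unname(oracle))
  }
})

test_that("replicate aggregation is invariant to row order", {
  set.seed(9)
  long <- data.frame(country = "BHS", site = rep(c("a", "b"), each = 6),
                     zone = "CREST", year_or_age = 2001,
                     group = rep(c("ACER", "APAL", "MCAV"), 4),
                     present = rbinom(12, 1, 0.5),
                     stringsAsFactors = FALSE)
  a1 <- aggregateReplicates(long)
  a2 <- aggregateReplicates(long[sample(nrow(long)), ])
  key <- function(d) d[order(d$site, d$group), c("site", "group", "present")]
  expect_equal(key(a1), key(a2), ignore_attr = TRUE)
})

test_that("a site mapped to two countries is a metadata conflict", {
  bad <- rep_df(list(1, 0))
  bad$country <- c("JAM", "CUB")
  expect_error(aggregateReplicates(bad), "conflicting")
})

test_that("wide and long CSV dialects harmonize identically", {
  set.seed(21)
  wide <- data.frame(country = rep(c("JAM", "CUB"), each = 4),
                     site = paste0(rep(c("j", "c"), each = 4), rep(1:4, 2)),
                     year_or_age = rep(c(1987, 50000), 4),
                     era = rep(c("AD", "BP"), 4),
                     depth_m = runif(8, 1, 5), habitat = "forereef",
                     check.names = FALSE, stringsAsFactors = FALSE)
  wide[["Acropora palmata"]] <- rbinom(8, 1, 0.5)
  wide[["Agaricia spp."]] <- rbinom(8, 1, 0.5)
  wide[["Siderastrea"]] <- c(NA, rbinom(7, 1, 0.5))
  fw <- tempfile(fileext = ".csv"); fl <- tempfile(fileext = ".csv")
  utils::write.csv(wide, fw, row.names = FALSE, na = "")
  long <- do.call(rbind, lapply(
    c("Acropora palmata", "Agaricia spp.", "Siderastrea"), function(s) {
      out <- wide[1:6]
      out$taxon <- s
      out$present <- wide[[s]]
      out
    }))
  utils::write.csv(long, fl, row.names = FALSE, na = "")
  ow <- buildOccurrence(readSurveyCSV(fw, "wide"))
  ol <- buildOccurrence(readSurveyCSV(fl, "long"))
  key <- function(o) {
    cd <- surveyData(o)
    ord <- order(cd$country, cd$site)
    occurrenceMatrix(o)[c("APAL", "AGARICIA", "SIDERASTREA"), ord]
  }
  expect_identical(key(ow), key(ol))
  expect_equal(curationLog(ow)$n_surveys, 8L)
})

test_that("full-complement filtering keeps exactly the complete surveys", {
  m <- matrix(NA_real_, 14, 4,
              dimnames = list(speciesGroups(), paste0("s", 1:4)))
  st <- guildMembers("STRESS_TOLERANT")
  wd <- guildMembers("WEEDY")
  m[st, 1] <- 1                      # complete for stress-tolerant
  m[wd, 2] <- 0                      # complete for weedy
  m[setdiff(st, "MEANDRINA"), 3] <- 1  # misses MEANDRINA
  m[wd, 3] <- 1                      # but complete for weedy
  occ <- make_occurrence(m, country = rep("JAM", 4),
                         bin = rep("B1985_1989", 4))
  f_st <- filterFullComplement(occ, "STRESS_TOLERANT")
  f_wd <- filterFullComplement(occ, "WEEDY")
  expect_identical(colnames(f_st), "s1")
  expect_identical(sort(colnames(f_wd)), c("s2", "s3"))
  expect_false(anyNA(occurrenceMatrix(f_st)))
  expect_error(filterFullComplement(occ, character(0)), "no members")
  expect_warning(filterFullComplement(occ[, 4], "WEEDY"), "no surveys")
})

test_that("retained surveys never increase with guild size", {
  set.seed(31)
  m <- matrix(rbinom(14 * 40, 1, 0.6), 14, 40,
              dimnames = list(speciesGroups(), paste0("s", 1:40)))
  m[matrix(runif(560) < 0.15, 14, 40)] <- NA
  occ <- make_occurrence(m, country = rep("JAM", 40),
                         bin = rep("B1990_1994", 40))
  st <- guildMembers("STRESS_TOLERANT")
  kept <- vapply(seq_along(st), function(k) {
    suppressWarnings(ncol(filterFullComplement(occ, st[seq_len(k)])))
  }, integer(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("harmonized tables and curation log round-trip to disk", {
  set.seed(5)
  m <- matrix(rbinom(28, 1, 0.5), 14, 2,
              dimnames = list(speciesGroups(), c("s1", "s2")))
  occ <- make_occurrence(m, country = c("JAM", "CUB"),
                         bin = c("B1985_1989", "PLEISTOCENE"))
  dir <- tempfile()
  paths <- writeOccurrenceTables(occ, dir)
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(file.path(dir, "occurrence_crest_B1985_1989.csv"))
  expect_equal(back$ACER, unname(m["ACER", 1]))
})
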