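#' Read raw survey records from CSV
#'
#' Two dialects are supported. \code{layout = "long"}: one row per
#' record-taxon, with columns \code{taxon} and \code{present} plus the
#' survey metadata below. \code{layout = "wide"}: one row per record
#' (replicate), with one column per raw taxon name holding 0/1/empty.
#'
#' Metadata columns (all layouts): \code{country}, \code{site},
#' \code{year_or_age}, \code{era} ("AD" or "BP"); optional:
#' \code{depth_m}, \code{habitat}, \code{offshore_high_clarity},
#' \code{high_wave_exposure}, \code{acropora_context},
#' \code{replicate_id}.
#'
#' @param path CSV path.
#' @param layout \code{"long"} or \code{"wide"}.
#' @return A long-format data.frame of record-taxon rows with standardized
#'   columns (missing optional columns are filled with NA).
#' @export
readSurveyCSV <- function(path, layout = c("long", "wide")) {
  layout <- match.arg(layout)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("country", "site", "year_or_age", "era", "depth_m",
                 "habitat", "offshore_high_clarity", "high_wave_exposure",
                 "acropora_context", "replicate_id")
  if (layout == "wide") {
    sp_cols <- setdiff(names(df), meta_cols)
    if (!length(sp_cols)) stop("wide layout has no taxon columns")
    long <- do.call(rbind, lapply(sp_cols, function(s) {
      out <- df[intersect(meta_cols, names(df))]
      out$taxon <- s
      out$present <- suppressWarnings(as.numeric(df[[s]]))
      out
    }))
    df <- long
  }
  need <- c("country", "site", "year_or_age", "era", "taxon", "present")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  for (col in setdiff(meta_cols, names(df))) df[[col]] <- NA
  stopifnot(all(df$present %in% c(0, 1) | is.na(df$present)))
  df
}

#' Aggregate replicate records to the survey level
#'
#' A survey is a unique combination of reef site, depth zone and
#' year/period within a country; replicates (transects, quadrats) at the
#' same survey are combined with a logical OR: a species group is present
#' if present in any replicate, absent if scored absent in at least one
#' replicate and present in none, and missing if never scored. The result
#' is invariant to replicate order.
#'
#' @param df Long data.frame with columns \code{country}, \code{site},
#'   \code{zone}, \code{year_or_age}, \code{group} (canonical species
#'   code), \code{present} (0/1/NA), and optionally \code{bin}.
#' @return Aggregated long data.frame, one row per survey x species group.
#' @export
aggregateReplicates <- function(df) {
  stopifnot(all(c("country", "site", "zone", "year_or_age", "group",
                  "present") %in% names(df)))
  site_country <- unique(df[c("site", "country")])
  if (anyDuplicated(site_country$site)) {
    stop("conflicting metadata: a site maps to more than one country")
  }
  ckey <- paste(df$country, df$site, df$zone, df$year_or_age, df$group,
                sep = "\r")
  cf <- factor(ckey, levels = unique(ckey))
  scored <- !is.na(df$present)
  n_pres <- rowsum(ifelse(scored, df$present, 0), cf)[, 1]
  n_scored <- rowsum(scored + 0, cf)[, 1]
  first <- !duplicated(cf)
  keep <- c("country", "site", "zone", "year_or_age", "group",
            intersect("bin", names(df)))
  out <- df[first, keep, drop = FALSE]
  # rowsum rows follow factor levels = first-occurrence order, matching out
  out$present <- ifelse(n_scored == 0, NA_real_,
                        as.numeric(n_pres > 0))
  rownames(out) <- NULL
  out
}

#' Harmonize raw survey records into a CoralOccurrence object
#'
#' Applies the full curation chain to long-format record-taxon rows: taxon
#' canonicalization (untracked taxa dropped), time-bin assignment
#' (unassignable ages dropped), reef-zone assignment (excluded habitats and
#' depths dropped), replicate aggregation by logical OR, and pivoting to a
#' species x survey presence/absence matrix. Counts removed by each rule
#' are recorded in the curation log.
#'
#' @param df Long data.frame as returned by [readSurveyCSV()].
#' @param aliases Alias table, see [taxonAliases()].
#' @param bins_version Year-2000 placement, see [timeBins()].
#' @return A \linkS4class{CoralOccurrence} covering all zones present;
#'   subset by zone with \code{x[, surveyData(x)$zone == "CREST"]}.
#' @export
buildOccurrence <- function(df, aliases = taxonAliases(),
                            bins_version = "text") {
  log <- list(input_rows = nrow(df))

  df$group <- canonicalizeTaxon(df$taxon, aliases)
  log$dropped_not_tracked <- sum(df$group == "NOT_TRACKED")
  df <- df[df$group != "NOT_TRACKED", , drop = FALSE]

  bin <- assignTimeBin(df$year_or_age, df$era, version = bins_version,
                       on_invalid = "na")
  log$dropped_unassignable_time <- sum(is.na(bin))
  df$bin <- as.character(bin)
  df <- df[!is.na(bin), , drop = FALSE]

  zone <- assignReefZone(df$depth_m, df$habitat, df$offshore_high_clarity,
                         df$high_wave_exposure, df$acropora_context)
  reasons <- attr(zone, "reason")[zone == "EXCLUDED"]
  log$dropped_zone_excluded <- as.list(table(reasons))
  df$zone <- as.character(zone)
  df <- df[df$zone != "EXCLUDED", , drop = FALSE]
  if (!nrow(df)) stop("no records survive curation")

  agg <- aggregateReplicates(df)

  skey <- paste(agg$country, agg$site, agg$zone, agg$year_or_age, sep = "|")
  surveys <- unique(data.frame(key = skey, country = agg$country,
                               site = agg$site, zone = agg$zone,
                               bin = agg$bin, stringsAsFactors = FALSE))
  surveys$survey_id <- sprintf("S%05d", seq_len(nrow(surveys)))
  m <- matrix(NA_real_, nrow = length(speciesGroups()),
              ncol = nrow(surveys),
              dimnames = list(speciesGroups(), surveys$survey_id))
  idx <- match(skey, surveys$key)
  m[cbind(match(agg$group, speciesGroups()), idx)] <- agg$present
  log$n_surveys <- nrow(surveys)

  CoralOccurrence(m, country = surveys$country, site = surveys$site,
                  bin = surveys$bin, zone = surveys$zone, curation = log)
}

#' Write harmonized occurrence tables
#'
#' Writes one wide CSV per zone x bin combination present
#' (\code{survey_id, country, site}, then the 14 species columns with
#' 0/1/empty cells) plus a JSON curation log.
#'
#' @param x A \linkS4class{CoralOccurrence}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeOccurrenceTables <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cd <- surveyData(x)
  m <- t(occurrenceMatrix(x))
  paths <- character(0)
  for (z in unique(cd$zone)) {
    for (b in unique(as.character(cd$bin[cd$zone == z]))) {
      sel <- cd$zone == z & cd$bin == b
      tab <- cbind(cd[sel, c("survey_id", "country", "site")],
                   m[sel, , drop = FALSE])
      p <- file.path(dir, sprintf("occurrence_%s_%s.csv", tolower(z), b))
      utils::write.csv(tab, p, row.names = FALSE, na = "")
      paths <- c(paths, p)
    }
  }
  lp <- file.path(dir, "curation_log.json")
  jsonlite::write_json(curationLog(x), lp, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, lp))
}
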