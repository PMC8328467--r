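#' Construct a CoralOccurrence object
#'
#' @param occurrence Species x survey matrix of 0/1/NA; rownames must be
#'   canonical species-group codes, colnames survey ids.
#' @param country,site Character vectors, one per survey.
#' @param bin Factor or character of time-bin codes, one per survey.
#' @param zone Character or factor, one per survey (or a single value).
#' @param curation Optional list of curation counts stored in metadata.
#' @return A \linkS4class{CoralOccurrence}.
#' @export
#' @examples
#' m <- matrix(c(1, 0, NA, 1), 2, 2,
#'             dimnames = list(c("ACER", "APAL"), c("s1", "s2")))
#' CoralOccurrence(m, country = c("JAM", "CUB"), site = c("a", "b"),
#'                 bin = c("PLEISTOCENE", "B2005_2011"), zone = "CREST")
CoralOccurrence <- function(occurrence, country, site, bin, zone,
                            curation = list()) {
  stopifnot(is.matrix(occurrence), !is.null(rownames(occurrence)),
            !is.null(colnames(occurrence)))
  n <- ncol(occurrence)
  bin <- factor(as.character(bin), levels = binLevels(), ordered = TRUE)
  zone <- rep_len(as.character(zone), n)
  cd <- S4Vectors::DataFrame(
    survey_id = colnames(occurrence),
    country = as.character(country),
    site = as.character(site),
    bin = bin,
    zone = zone,
    row.names = colnames(occurrence))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(occurrence = occurrence), colData = cd)
  obj <- methods::new("CoralOccurrence", se)
  S4Vectors::metadata(obj)$curation <- curation
  obj
}

#' @describeIn CoralOccurrence-accessors the presence/absence matrix
#' @export
occurrenceMatrix <- function(x) SummarizedExperiment::assay(x, "occurrence")

#' Accessors for CoralOccurrence
#'
#' \code{occurrenceMatrix} returns the species x survey 0/1/NA matrix;
#' \code{surveyData} the per-survey metadata as a data.frame;
#' \code{curationLog} the list of curation counts recorded during ingest.
#'
#' @param x A \linkS4class{CoralOccurrence}.
#' @name CoralOccurrence-accessors
NULL

#' @describeIn CoralOccurrence-accessors per-survey metadata
#' @export
surveyData <- function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
}

#' @describeIn CoralOccurrence-accessors curation counts from ingest
#' @export
curationLog <- function(x) S4Vectors::metadata(x)$curation

setMethod("show", "CoralOccurrence", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("CoralOccurrence:", nrow(object), "species groups x",
      ncol(object), "surveys\n")
  if (ncol(object)) {
    cat("  zones:", paste(unique(cd$zone), collapse = ", "), "\n")
    cat("  bins: ", paste(levels(droplevels(cd$bin)), collapse = ", "), "\n")
    cat("  countries:", length(unique(cd$country)), "\n")
    m <- SummarizedExperiment::assay(object, "occurrence")
    cat(sprintf("  cells: %.1f%% scored (non-missing)\n",
                100 * mean(!is.na(m))))
  }
})

#' Keep surveys scoring the full complement of a guild
#'
#' Guild models require equal survey sets across member species, so only
#' surveys with a 0/1 value for \emph{every} member of the guild are
#' retained; the result is subset to the member rows and contains no
#' missing cells.
#'
#' @param x A \linkS4class{CoralOccurrence}.
#' @param guild Guild name, or a character vector of species codes.
#' @param millepora_included Passed to [guildMembers()] when \code{guild}
#'   is a guild name.
#' @return A \linkS4class{CoralOccurrence} restricted to complete surveys
#'   and member species.
#' @export
filterFullComplement <- function(x, guild, millepora_included = TRUE) {
  members <- if (length(guild) == 1L && guild %in% guildNames()) {
    guildMembers(guild, millepora_included)
  } else {
    guild
  }
  if (length(members) == 0L) stop("guild has no members")
  stopifnot(all(members %in% rownames(x)))
  m <- occurrenceMatrix(x)[members, , drop = FALSE]
  keep <- colSums(is.na(m)) == 0L
  if (!any(keep)) warning("no surveys score the full complement")
  x[members, keep]
}
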