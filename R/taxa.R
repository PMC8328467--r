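#' The 14 tracked coral species groups
#'
#' Occurrence trends are tracked for 14 coral taxonomic groups that are
#' consistently recorded across fossil, historical and modern surveys.
#' Several morphologically cryptic complexes are lumped (e.g. all branching
#' \emph{Porites}, the \emph{Orbicella annularis} complex), while distinct,
#' consistently recorded species (\emph{Porites astreoides},
#' \emph{Montastraea cavernosa}) keep their own group.
#'
#' @return Character vector of the 14 canonical group codes, in fixed order.
#' @export
#' @examples
#' speciesGroups()
speciesGroups <- function() {
  c("ACER", "APAL", "AGARICIA", "MCAV", "COLPOPHYLLIA", "PSEUDODIPLORIA",
    "MADRACIS", "MEANDRINA", "MILLEPORA", "ORBICELLA", "PORITES_BRANCHING",
    "PASTREOIDES", "SIDERASTREA", "STEPHANOCOENIA")
}

#' Human-readable labels for the species groups
#'
#' @return Named character vector mapping group codes to display names.
#' @export
speciesLabels <- function() {
  c(ACER = "Acropora cervicornis",
    APAL = "Acropora palmata",
    AGARICIA = "Agaricia spp.",
    MCAV = "Montastraea cavernosa",
    COLPOPHYLLIA = "Colpophyllia spp.",
    PSEUDODIPLORIA = "Pseudodiploria spp.",
    MADRACIS = "Madracis spp.",
    MEANDRINA = "Meandrina spp.",
    MILLEPORA = "Millepora spp.",
    ORBICELLA = "Orbicella spp.",
    PORITES_BRANCHING = "branching Porites spp.",
    PASTREOIDES = "Porites astreoides",
    SIDERASTREA = "Siderastrea spp.",
    STEPHANOCOENIA = "Stephanocoenia spp.")
}

.normalize_name <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[.,()]", " ", x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

#' Load the taxon alias table
#'
#' The alias table maps raw taxon names as they appear in survey sources to
#' canonical species-group codes. It is shipped as an editable CSV
#' (\code{alias,group}) so new synonymies can be added without a code change.
#'
#' @param path Path to an alias CSV; \code{NULL} uses the shipped table.
#' @return A data.frame with columns \code{alias} and \code{group}.
#' @export
taxonAliases <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "taxon_aliases.csv", package = "reefchrono")
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("alias", "group") %in% names(tab)))
  bad <- setdiff(unique(tab$group), speciesGroups())
  if (length(bad)) {
    stop("alias table maps to unknown groups: ", paste(bad, collapse = ", "))
  }
  tab
}

#' Map raw taxon names to canonical species groups
#'
#' Names are matched case-insensitively after stripping punctuation and
#' collapsing whitespace. Canonical group codes map to themselves. Names
#' outside the 14 tracked groups return \code{"NOT_TRACKED"}. Lumping rules
#' follow the database curation conventions: bare \emph{Porites} spp. and
#' \emph{P. porites} are treated as branching \emph{Porites};
#' \emph{Montastraea} spp. and the \emph{annularis} complex as
#' \emph{Orbicella}; \emph{Pseudodiploria} and \emph{Diploria
#' labyrinthiformis} as \emph{Pseudodiploria}.
#'
#' @param raw_name Character vector of raw names (non-empty).
#' @param aliases Alias table as returned by [taxonAliases()].
#' @return Character vector of group codes or \code{"NOT_TRACKED"}.
#' @export
#' @examples
#' canonicalizeTaxon(c("Porites porites", "Favia fragum"))
canonicalizeTaxon <- function(raw_name, aliases = taxonAliases()) {
  if (length(raw_name) == 0L) return(character(0))
  if (any(is.na(raw_name)) || any(!nzchar(trimws(raw_name)))) {
    stop("raw_name must be non-empty")
  }
  key <- .normalize_name(raw_name)
  # canonical codes round-trip to themselves
  canon <- speciesGroups()
  lut <- stats::setNames(aliases$group, .normalize_name(aliases$alias))
  lut[.normalize_name(canon)] <- canon
  out <- unname(lut[key])
  out[is.na(out)] <- "NOT_TRACKED"
  out
}
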