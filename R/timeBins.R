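#' The eleven time bins
#'
#' Survey records spanning ~131,000 years before present to 2011 AD are
#' pooled into eleven ordered bins: two fossil bins (Late Pleistocene,
#' Holocene), one long historical bin (1500--1959), and progressively finer
#' modern bins reflecting the post-1980 increase in reef survey effort.
#' Fossil ages are in years before present with "present" = 1950 AD
#' (radiocarbon convention). The printed bin series leaves a gap between
#' 12,000 and 9,100 ybp; records falling in it are unassignable.
#'
#' Two labelling variants of the two bins around the year 2000 exist in
#' published presentations ("1995--2000 / 2001--2004" vs "1995--1999 /
#' 2000--2004"); \code{version = "text"} (default) places year 2000 in the
#' earlier bin, \code{version = "table2"} in the later.
#'
#' @param version \code{"text"} or \code{"table2"} (year-2000 placement).
#' @return A data.frame with one row per bin: \code{bin} (code),
#'   \code{label}, \code{fossil} (logical), and inclusive year bounds
#'   \code{year_lo}, \code{year_hi} (calendar years AD; fossil bounds are
#'   converted from ybp).
#' @export
#' @examples
#' timeBins()
timeBins <- function(version = c("text", "table2")) {
  version <- match.arg(version)
  cut1 <- if (version == "text") 2000L else 1999L
  data.frame(
    bin = c("PLEISTOCENE", "HOLOCENE", "B1500_1959", "B1960_1969",
            "B1970_1979", "B1980_1984", "B1985_1989", "B1990_1994",
            "B1995_2000", "B2001_2004", "B2005_2011"),
    label = c("Pleistocene", "Holocene", "1500-1959", "1960-1969",
              "1970-1979", "1980-1984", "1985-1989", "1990-1994",
              if (version == "text") "1995-2000" else "1995-1999",
              if (version == "text") "2001-2004" else "2000-2004",
              "2005-2011"),
    fossil = c(TRUE, TRUE, rep(FALSE, 9)),
    year_lo = c(1950L - 131000L, 1950L - 9100L, 1500L, 1960L, 1970L,
                1980L, 1985L, 1990L, 1995L, cut1 + 1L, 2005L),
    year_hi = c(1950L - 12000L, 1499L, 1959L, 1969L, 1979L, 1984L,
                1989L, 1994L, cut1, 2004L, 2011L),
    stringsAsFactors = FALSE
  )
}

#' Ordered factor levels for the time bins
#' @param version Passed to [timeBins()].
#' @return Character vector of the 11 bin codes in temporal order.
#' @export
binLevels <- function(version = "text") timeBins(version)$bin

#' Assign records to time bins
#'
#' Calendar years (\code{era = "AD"}) and fossil ages in years before 1950
#' (\code{era = "BP"}) are both supported; \code{era} is recycled. Ages in
#' the 12,000--9,100 ybp gap between the Pleistocene and Holocene bins are
#' unassignable; values beyond 2011 AD or older than 131,000 ybp are out of
#' range. Year 1500 belongs to the 1500--1959 bin; earlier calendar years
#' fall in the Holocene.
#'
#' @param value Numeric vector of years AD or ages ybp.
#' @param era \code{"AD"} or \code{"BP"}, recycled along \code{value}.
#' @param version Year-2000 placement, see [timeBins()].
#' @param on_invalid \code{"error"} (default) or \code{"na"}: how to treat
#'   out-of-range values and gap ages. With \code{"na"} the return carries a
#'   \code{reason} attribute.
#' @return Factor with the 11 ordered bin levels.
#' @export
#' @examples
#' assignTimeBin(c(1987, 1960), "AD")
#' assignTimeBin(50000, "BP")
assignTimeBin <- function(value, era = "AD", version = "text",
                          on_invalid = c("error", "na")) {
  on_invalid <- match.arg(on_invalid)
  stopifnot(all(era %in% c("AD", "BP")))
  era <- rep_len(era, length(value))
  year <- ifelse(era == "BP", 1950 - value, value)
  bins <- timeBins(version)
  out <- rep(NA_character_, length(value))
  reason <- rep(NA_character_, length(value))

  too_new <- !is.na(year) & year > 2011
  too_old <- !is.na(year) & year < 1950 - 131000
  gap <- !is.na(year) & year > 1950 - 12000 & year < 1950 - 9100
  reason[too_new] <- "beyond final bin (year > 2011)"
  reason[too_old] <- "older than 131,000 ybp"
  reason[gap] <- "age in the 12,000-9,100 ybp gap between bins"
  reason[is.na(year)] <- "missing year/age"

  ok <- is.na(reason)
  for (i in seq_len(nrow(bins))) {
    hit <- ok & year >= bins$year_lo[i] & year <= bins$year_hi[i]
    out[hit] <- bins$bin[i]
  }
  if (on_invalid == "error" && any(!is.na(reason))) {
    stop("unassignable time values: ",
         paste(unique(stats::na.omit(reason)), collapse = "; "))
  }
  res <- factor(out, levels = bins$bin, ordered = TRUE)
  if (on_invalid == "na") attr(res, "reason") <- reason
  res
}
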