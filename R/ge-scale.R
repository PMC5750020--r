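#' Default global endangerment (GE) scale
#'
#' The conversion of the 10-level EGIDS language-vitality scale into a
#' global endangerment multiplier, built so that one unit of GE corresponds
#' to a doubling of the probability of extinction (the same logic as the
#' doubling interpretation of IUCN Red List categories in the species EDGE
#' framework).  Below "vigorous" consecutive levels halve exactly.
#'
#' @return a data frame with columns `status`, `ge` and `egids` (the EGIDS
#'   level usually associated with the status), ordered from most to least
#'   endangered.
#' @examples
#' ge_scale_default()
#' @export
ge_scale_default <- function() {
  data.frame(
    status = c("nearly extinct", "moribund", "shifting", "threatened",
               "vigorous", "developing", "educational",
               "wider communication", "provincial", "national"),
    ge = c(4, 3.5, 3, 2, 1, 1/2, 1/4, 1/8, 1/16, 1/32),
    egids = c("8b", "8a", "7", "6b", "6a", "5", "4", "3", "2", "1"),
    stringsAsFactors = FALSE
  )
}

# printed abbreviations used alongside the full names
.status_aliases <- c(
  "nearly ext."  = "nearly extinct",
  "nearly ext"   = "nearly extinct",
  "wider comm."  = "wider communication",
  "wider comm"   = "wider communication"
)

#' Convert an endangerment status to its GE value
#'
#' Accepts status names from the default scale (case-insensitive), the
#' common printed abbreviations ("nearly ext.", "wider comm.") and EGIDS
#' level codes (`"1"` through `"8b"`).  EGIDS levels 0, 9 and 10
#' (international, dormant, extinct) are rejected: only living languages
#' are scored, and dormant/extinct languages have no extinction probability
#' to weight.
#'
#' @param status character vector of status names or EGIDS codes.
#' @param scale a GE scale as returned by [ge_scale_default()].
#' @return numeric vector of GE values.
#' @examples
#' ge_from_status(c("nearly extinct", "vigorous", "national"))
#' ge_from_status(c("8b", "6a", "1"))
#' @export
ge_from_status <- function(status, scale = ge_scale_default()) {
  stopifnot(is.data.frame(scale), all(c("status", "ge") %in% names(scale)))
  s <- tolower(trimws(as.character(status)))
  aliased <- !is.na(match(s, names(.status_aliases)))
  s[aliased] <- .status_aliases[s[aliased]]
  out <- scale$ge[match(s, tolower(scale$status))]
  if ("egids" %in% names(scale)) {
    by_code <- scale$ge[match(s, tolower(scale$egids))]
    out[is.na(out)] <- by_code[is.na(out)]
  }
  if (any(s %in% c("0", "9", "10")))
    stop("EGIDS levels 0, 9 and 10 (international, dormant, extinct) are ",
         "not scored: only living languages carry a GE value")
  if (anyNA(out))
    stop("unknown endangerment status: ",
         paste(unique(status[is.na(out)]), collapse = ", "),
         "; valid names are: ", paste(scale$status, collapse = ", "),
         " (or EGIDS codes ", paste(scale$egids, collapse = ", "), ")")
  unname(out)
}

#' Read a status table
#'
#' Two columns: taxon identifier, endangerment status (name or EGIDS code).
#'
#' @param file path to a delimited UTF-8 file.
#' @param sep column separator.
#' @param header does the file carry a header row?
#' @return a named character vector, taxon -> status.
#' @export
read_statuses <- function(file, sep = ",", header = TRUE) {
  df <- utils::read.csv(file, sep = sep, header = header,
                        stringsAsFactors = FALSE, comment.char = "#",
                        fileEncoding = "UTF-8", colClasses = "character")
  if (ncol(df) < 2L) stop("status table needs two columns")
  if (anyDuplicated(df[[1L]]))
    stop("duplicate taxon id(s) in status table: ",
         paste(unique(df[[1L]][duplicated(df[[1L]])]), collapse = ", "))
  stats::setNames(df[[2L]], df[[1L]])
}
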