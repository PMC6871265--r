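#' Fossil occurrence tables
#'
#' An occurrence table is a data frame with one row per fossil occurrence of
#' some lineage at a dated locality/horizon. Required columns are
#' \code{taxon_id}, \code{lineage_id}, \code{locality_id}, \code{age_older_ma}
#' and \code{age_younger_ma}; optional columns are \code{horizon_id},
#' \code{region}, \code{axis_position} (a nonnegative coordinate in user units,
#' e.g. cumulative rock thickness), \code{apomorphy} (logical: does this
#' specimen document a diagnostic apomorphy of the lineage?) and
#' \code{voucher} (free text, e.g. museum numbers).
#'
#' @param taxon_id,lineage_id,locality_id Character labels.
#' @param age_older_ma,age_younger_ma Age interval bounds in Ma before present.
#' @param horizon_id Optional horizon labels; distinct horizons are the unit
#'   counted as \code{n} in the confidence-interval formulas.
#' @param region,voucher Optional character columns.
#' @param axis_position Optional nonnegative numeric (user units).
#' @param apomorphy Logical; defaults to \code{FALSE}.
#' @return A validated \code{data.frame} of class \code{fossil_occurrences}.
#' @seealso [read_occurrences()], [lineage_record()]
#' @export
occurrences <- function(taxon_id, lineage_id, locality_id,
                        age_older_ma, age_younger_ma,
                        horizon_id = NA_character_, region = NA_character_,
                        axis_position = NA_real_, apomorphy = FALSE,
                        voucher = NA_character_) {
  df <- data.frame(
    taxon_id = as.character(taxon_id),
    lineage_id = as.character(lineage_id),
    locality_id = as.character(locality_id),
    horizon_id = as.character(horizon_id),
    age_older_ma = as.numeric(age_older_ma),
    age_younger_ma = as.numeric(age_younger_ma),
    region = as.character(region),
    axis_position = as.numeric(axis_position),
    apomorphy = as.logical(apomorphy),
    voucher = as.character(voucher),
    stringsAsFactors = FALSE
  )
  validate_occurrences(df)
}

OCC_REQUIRED <- c("taxon_id", "lineage_id", "locality_id",
                  "age_older_ma", "age_younger_ma")
OCC_OPTIONAL <- c("horizon_id", "region", "axis_position", "apomorphy",
                  "voucher")

validate_occurrences <- function(df, source = "occurrence table") {
  missing_cols <- setdiff(OCC_REQUIRED, names(df))
  if (length(missing_cols))
    fb_stop(source, " is missing required column(s): ",
            paste(missing_cols, collapse = ", "))
  for (col in setdiff(OCC_OPTIONAL, names(df))) {
    df[[col]] <- switch(col,
      apomorphy = rep(FALSE, nrow(df)),
      axis_position = rep(NA_real_, nrow(df)),
      rep(NA_character_, nrow(df)))
  }
  df <- df[, c(OCC_REQUIRED[1:3], "horizon_id",
               "age_older_ma", "age_younger_ma",
               "region", "axis_position", "apomorphy", "voucher")]
  for (col in c("taxon_id", "lineage_id", "locality_id", "horizon_id",
                "region", "voucher"))
    df[[col]] <- as.character(df[[col]])
  for (col in c("age_older_ma", "age_younger_ma", "axis_position"))
    df[[col]] <- as.numeric(df[[col]])
  df$apomorphy <- as.logical(df$apomorphy)
  if (nrow(df)) {
    if (any(!nzchar(df$locality_id) | is.na(df$locality_id)))
      fb_stop(source, ": locality_id must be nonempty for every row")
    bad <- which(is.na(df$age_older_ma) | is.na(df$age_younger_ma) |
                 df$age_younger_ma < 0 |
                 df$age_older_ma < df$age_younger_ma)
    if (length(bad))
      fb_stop(source, ": invalid age interval (need older >= younger >= 0) ",
              "at row(s) ", paste(bad, collapse = ", "))
    if (any(!is.na(df$axis_position) & df$axis_position < 0))
      fb_stop(source, ": axis_position must be nonnegative")
    df$apomorphy[is.na(df$apomorphy)] <- FALSE
  }
  class(df) <- c("fossil_occurrences", "data.frame")
  df
}

#' Read a fossil occurrence table from CSV/TSV
#'
#' Reads a delimited occurrence table (UTF-8; comma by default, tab accepted —
#' the separator is sniffed from the header line unless given). Columns are
#' matched by name, not position. A parse report is logged to stderr.
#'
#' @param path Path to the file. A header row is required.
#' @param sep Field separator; \code{NULL} (default) sniffs "," vs tab.
#' @return A \code{fossil_occurrences} data frame (possibly zero rows).
#' @export
read_occurrences <- function(path, sep = NULL) {
  if (!file.exists(path)) fb_stop("file not found: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          fileEncoding = "UTF-8",
                          colClasses = NA, comment.char = "")
  out <- validate_occurrences(df, source = path)
  fb_log("read ", nrow(out), " occurrence row(s), ",
         length(unique(out$lineage_id)), " lineage(s) from ", path)
  out
}

#' Write a fossil occurrence table
#'
#' Writes the standard column set as CSV (or TSV). A write followed by
#' [read_occurrences()] round-trips all fields.
#'
#' @param occ A \code{fossil_occurrences} data frame.
#' @param path Output path.
#' @param sep "," (default) or "\t".
#' @export
write_occurrences <- function(occ, path, sep = ",") {
  occ <- validate_occurrences(as.data.frame(occ))
  utils::write.table(occ, path, sep = sep, row.names = FALSE,
                     quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Summarize a lineage's fossil record
#'
#' Collapses the occurrences of one lineage into the quantities the
#' confidence-interval machinery needs: the first appearance datum (FAD, the
#' oldest occurrence's age interval), the last appearance datum (LAD), the
#' number of distinct fossiliferous horizons \code{n}, and the observed
#' stratigraphic range \code{R} in Ma.
#'
#' Distinct horizons are counted by \code{horizon_id}; where \code{horizon_id}
#' is absent the rule falls back to distinct \code{locality_id}. Duplicated
#' horizon rows therefore count once. Ages enter the point formulas at the
#' midpoint of their dating interval; the endpoints are kept as an envelope
#' (\code{fad_envelope}, \code{range_envelope}) so that results can also be
#' reported at both dating extremes.
#'
#' For an extinct lineage \code{R = FAD - LAD}; for an extant one the range
#' runs to the present, \code{R = FAD - 0}.
#'
#' @param occ A \code{fossil_occurrences} data frame.
#' @param lineage Lineage to extract; may be omitted when the table holds a
#'   single lineage.
#' @param extant Is the lineage extant? (Determines the range convention and
#'   which confidence-interval formula applies downstream.)
#' @return An object of class \code{lineage_record}.
#' @examples
#' occ <- occurrences(
#'   taxon_id = c("Sahelanthropus", "Orrorin", "Ardipithecus", "Ardipithecus"),
#'   lineage_id = "hominin", locality_id = c("TM266", "Lukeino", "AsaKoma", "Aramis"),
#'   horizon_id = c("h1", "h2", "h3", "h4"),
#'   age_older_ma = c(7.5, 6.0, 5.8, 4.4),
#'   age_younger_ma = c(6.5, 5.7, 5.2, 4.4),
#'   apomorphy = TRUE)
#' lineage_record(occ, extant = TRUE)
#' @export
lineage_record <- function(occ, lineage = NULL, extant = TRUE) {
  occ <- validate_occurrences(as.data.frame(occ))
  if (is.null(lineage)) {
    ids <- unique(occ$lineage_id)
    if (length(ids) != 1L)
      fb_stop("table holds ", length(ids),
              " lineages; specify `lineage`")
    lineage <- ids
  }
  occ <- occ[occ$lineage_id == lineage, , drop = FALSE]
  if (!nrow(occ)) fb_stop("no occurrences for lineage '", lineage, "'")

  horizon_key <- occ$horizon_id
  if (all(is.na(horizon_key))) horizon_key <- occ$locality_id
  horizon_key[is.na(horizon_key)] <- occ$locality_id[is.na(horizon_key)]
  n <- length(unique(horizon_key))

  oldest <- which.max(occ$age_older_ma)
  youngest <- which.min(occ$age_younger_ma)
  fad <- age_interval(occ$age_older_ma[oldest], occ$age_younger_ma[oldest])
  lad <- age_interval(occ$age_older_ma[youngest], occ$age_younger_ma[youngest])

  fad_mid <- age_midpoint(fad)
  if (extant) {
    r_mid <- fad_mid
    r_env <- c(younger = fad$younger, older = fad$older)
  } else {
    r_mid <- fad_mid - age_midpoint(lad)
    r_env <- c(younger = fad$younger - lad$younger,
               older = fad$older - lad$older)
  }
  if (r_mid < 0) fb_stop("negative stratigraphic range for '", lineage, "'")

  structure(list(
    lineage_id = lineage,
    extant = isTRUE(extant),
    occurrences = occ,
    fad = fad, lad = lad,
    fad_ma = fad_mid,
    fad_envelope = c(younger = fad$younger, older = fad$older),
    n = n,
    range_ma = r_mid,
    range_envelope = r_env
  ), class = "lineage_record")
}

#' @export
print.lineage_record <- function(x, ...) {
  cat(sprintf("<lineage_record '%s': %s, n = %d horizons>\n",
              x$lineage_id, if (x$extant) "extant" else "extinct", x$n))
  cat(sprintf("  FAD %g-%g Ma (midpoint %g), range R = %g Ma\n",
              x$fad$younger, x$fad$older, x$fad_ma, x$range_ma))
  invisible(x)
}
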