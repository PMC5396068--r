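#' Canonical AAindex residue ordering
#'
#' AAindex1 `I` blocks list twenty values in a fixed residue order
#' (`A R N D C Q E G H I` on the first row, `L K M F P S T W Y V` on the
#' second).  All property tables in this package index residues by
#' one-letter code, so the ordering only matters while parsing or writing
#' the flat-file format.
#'
#' @return Character vector of the 20 standard one-letter residue codes in
#'   AAindex order.
#' @export
aaindex_residues <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' Accessions of the six thermostability-related property scales
#'
#' The pipeline contrasts groups on six physico-chemical scales: three
#' general properties (hydrophobicity, molecular weight, polarity) and
#' three specific ones (side chain, flexibility, buriability), identified
#' in AAindex by the accessions returned here.  The accession-to-name
#' mapping is never assumed from this ordering: names are read from each
#' entry's `D` title line at parse time (see [property_labels()]).
#'
#' @return Named character vector of six AAindex accessions; names are the
#'   short property labels used in reports.
#' @export
thermostability_properties <- function() {
  c(hydrophobicity   = "COWR900101",
    molecular_weight = "FASG760101",
    polarity         = "GRAR740102",
    side_chain       = "TAKK010101",
    flexibility      = "VINM940101",
    buriability      = "ZHOH040103")
}

#' Parse an AAindex1 flat file into a property table
#'
#' Reads records delimited by `//` from an AAindex1-format file.  Each
#' record contributes one property scale: the `H` line gives the
#' accession, the `D` line the human-readable title, and the `I` block two
#' rows of ten numeric values in the canonical residue order (see
#' [aaindex_residues()]).  Entries containing `NA` values are rejected
#' rather than imputed, since downstream window averages require complete
#' scales.
#'
#' @param path Path to an AAindex1-format file.
#' @param wanted Optional character vector of accessions to extract.  When
#'   supplied, exactly these entries are returned and a missing accession
#'   is an error; when `NULL` all entries in the file are returned.
#' @return An object of class `property_table`: a list with `entries` (a
#'   named list mapping accession to a named numeric vector of 20 residue
#'   values) and `names` (accession to title-line description).
#' @seealso [residue_value()], [write_aaindex()]
#' @export
parse_aaindex <- function(path, wanted = NULL) {
  if (!file.exists(path)) stop("AAindex file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  entries <- list()
  titles <- character()

  i <- 1L
  n <- length(lines)
  while (i <= n) {
    # find next record header
    while (i <= n && !startsWith(lines[[i]], "H ")) i <- i + 1L
    if (i > n) break
    acc <- trimws(sub("^H ", "", lines[[i]]))
    if (acc == "") stop("Empty accession on line ", i)
    if (acc %in% names(entries)) stop("Duplicate accession: ", acc)
    title <- ""
    j <- i + 1L
    vals <- NULL
    while (j <= n && !startsWith(lines[[j]], "//")) {
      if (startsWith(lines[[j]], "D ")) {
        title <- trimws(sub("^D ", "", lines[[j]]))
        # continuation lines of D are indented
        while (j + 1L <= n && grepl("^\\s+\\S", lines[[j + 1L]]) &&
               !grepl("^[A-Z*]", lines[[j + 1L]])) {
          j <- j + 1L
          title <- paste(title, trimws(lines[[j]]))
        }
      } else if (startsWith(lines[[j]], "I ")) {
        if (j + 2L > n) stop("Truncated I-block for ", acc, " at line ", j)
        row1 <- strsplit(trimws(lines[[j + 1L]]), "\\s+")[[1]]
        row2 <- strsplit(trimws(lines[[j + 2L]]), "\\s+")[[1]]
        if (length(row1) != 10L || length(row2) != 10L) {
          stop("Malformed I-block for ", acc, " at line ", j + 1L,
               ": expected two rows of ten values, got ",
               length(row1), " and ", length(row2))
        }
        raw <- c(row1, row2)
        if (any(raw == "NA")) {
          stop("Entry ", acc, " contains NA values (line ", j + 1L,
               "); incomplete scales are rejected")
        }
        vals <- suppressWarnings(as.numeric(raw))
        if (anyNA(vals)) {
          stop("Non-numeric value in I-block for ", acc,
               " at line ", j + 1L)
        }
        j <- j + 2L
      }
      j <- j + 1L
    }
    if (!is.null(vals)) {
      entries[[acc]] <- stats::setNames(vals, aaindex_residues())
      titles[[acc]] <- title
    }
    i <- j + 1L
  }

  if (!is.null(wanted)) {
    missing <- setdiff(wanted, names(entries))
    if (length(missing) > 0L) {
      stop("Accession(s) not found in ", path, ": ",
           paste(missing, collapse = ", "))
    }
    entries <- entries[wanted]
    titles <- titles[wanted]
  }
  structure(list(entries = entries, names = titles),
            class = "property_table")
}

#' @export
print.property_table <- function(x, ...) {
  cat("Property table with", length(x$entries), "AAindex entr",
      if (length(x$entries) == 1L) "y" else "ies", "\n", sep = "")
  for (acc in names(x$entries)) {
    cat("  ", acc, ": ", x$names[[acc]], "\n", sep = "")
  }
  invisible(x)
}

#' Serialize a property table back to AAindex1 format
#'
#' Inverse of [parse_aaindex()] for the fields this package uses (`H`,
#' `D`, `I`); parse/write/parse round-trips preserve every residue value.
#'
#' @param table A `property_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_aaindex <- function(table, path) {
  stopifnot(inherits(table, "property_table"))
  ord <- aaindex_residues()
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (acc in names(table$entries)) {
    v <- table$entries[[acc]][ord]
    writeLines(c(
      paste("H", acc),
      paste("D", table$names[[acc]]),
      "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
      paste0("  ", paste(formatC(v[1:10], format = "g", digits = 8),
                         collapse = "  ")),
      paste0("  ", paste(formatC(v[11:20], format = "g", digits = 8),
                         collapse = "  ")),
      "//"), con)
  }
  invisible(path)
}

#' Look up a published property value for one residue
#'
#' @param table A `property_table`.
#' @param accession AAindex accession present in `table`.
#' @param residue One uppercase standard one-letter code.  Gap characters
#'   are not valid here; non-standard codes (`B`, `Z`, `X`, `U`, `O`) are
#'   handled per `nonstandard`.
#' @param nonstandard Policy for non-standard residue codes: `"error"`
#'   (default) or `"na"` to return `NA_real_`, matching how window
#'   averages treat them (excluded like gaps).
#' @return The published scale value (numeric scalar).
#' @export
residue_value <- function(table, accession, residue,
                          nonstandard = c("error", "na")) {
  stopifnot(inherits(table, "property_table"))
  nonstandard <- match.arg(nonstandard)
  if (!accession %in% names(table$entries)) {
    stop("Accession not in table: ", accession)
  }
  if (!is.character(residue) || length(residue) != 1L || nchar(residue) != 1L) {
    stop("residue must be a single one-letter code")
  }
  if (!residue %in% aaindex_residues()) {
    if (nonstandard == "na") return(NA_real_)
    stop("Non-standard residue code: ", residue)
  }
  unname(table$entries[[accession]][[residue]])
}

#' Property scales as a 20 x K matrix
#'
#' @param table A `property_table`.
#' @param standardize If `TRUE`, z-standardize each scale across the 20
#'   residues (sample standard deviation), making properties comparable on
#'   one axis for per-position difference profiles.
#' @return Numeric matrix, rows the 20 residues (AAindex order), columns
#'   the accessions.
#' @export
property_matrix <- function(table, standardize = FALSE) {
  stopifnot(inherits(table, "property_table"))
  m <- vapply(table$entries, function(v) v[aaindex_residues()],
              numeric(20L))
  rownames(m) <- aaindex_residues()
  if (standardize) m <- scale(m)[, , drop = FALSE]
  m
}

#' Short property labels for a table
#'
#' Maps each entry to a short label (hydrophobicity, molecular weight,
#' polarity, side chain, flexibility, buriability) by keyword-matching its
#' `D` title line; entries whose title matches none of the six keywords
#' keep their accession as label.  Labels are carried as metadata so no
#' fixed accession-to-property ordering is ever assumed.
#'
#' @param table A `property_table`.
#' @return Named character vector, accession -> label.
#' @export
property_labels <- function(table) {
  stopifnot(inherits(table, "property_table"))
  keys <- c(hydrophobicity   = "hydrophob",
            molecular_weight = "molecular weight|molecular mass",
            polarity         = "polarity|polar ",
            side_chain       = "side chain|side-chain",
            flexibility     = "flexib",
            buriability     = "buriab|buried")
  out <- stats::setNames(names(table$entries), names(table$entries))
  for (acc in names(table$entries)) {
    title <- tolower(table$names[[acc]])
    hit <- which(vapply(keys, function(k) grepl(k, title), logical(1)))
    if (length(hit) >= 1L) out[[acc]] <- names(keys)[hit[[1L]]]
  }
  out
}
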