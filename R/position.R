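# Per-position analysis within candidate fragments: single-column
# property-difference profiles and residue-composition contrasts.

#' Per-position property difference profiles
#'
#' Single-column analogue of the fragment difference: for each requested
#' column and property, the mean property value of the thermophilic
#' residues at that column minus the mesophilic mean, computed on
#' z-standardized scales (across the 20 residues) so that the six
#' properties share one unit-free axis.  Gaps and non-standard codes are
#' excluded; the reference sequence is never counted.
#'
#' @param set Merged `alignment_set`.
#' @param table A `property_table`.
#' @param columns Alignment columns to profile.
#' @param standardized If `FALSE`, use the raw published scales instead.
#' @return Data frame: `column`, `ref_residue`, then one difference
#'   column per property label.
#' @export
position_differences <- function(set, table, columns,
                                 standardized = TRUE) {
  stopifnot(inherits(set, "alignment_set"), inherits(table, "property_table"))
  if (any(columns < 1L | columns > set$s)) stop("Column out of range")
  pm <- property_matrix(table, standardize = standardized)
  labels <- property_labels(table)
  tro <- group_rows(set, "thermophilic")
  mes <- group_rows(set, "mesophilic")
  if (length(tro) == 0L || length(mes) == 0L) stop("Both groups are required")
  diffs <- matrix(NA_real_, length(columns), ncol(pm),
                  dimnames = list(NULL, unname(labels[colnames(pm)])))
  for (j in seq_along(columns)) {
    ch_t <- set$mat[tro, columns[j]]
    ch_m <- set$mat[mes, columns[j]]
    for (k in seq_len(ncol(pm))) {
      vt <- pm[, k][ch_t]
      vm <- pm[, k][ch_m]
      mt <- if (all(is.na(vt))) NA_real_ else mean(vt, na.rm = TRUE)
      mm <- if (all(is.na(vm))) NA_real_ else mean(vm, na.rm = TRUE)
      diffs[j, k] <- mt - mm
    }
  }
  data.frame(column = as.integer(columns),
             ref_residue = set$col_map[columns],
             diffs, row.names = NULL, check.names = FALSE)
}

#' Residue composition of one group at one column
#'
#' Percentage of the group's non-gap sequences carrying each residue at
#' the column.  Gaps are excluded from both numerator and denominator, so
#' compositions reflect the residues actually present rather than
#' unrelated indel behaviour.
#'
#' @param set Merged `alignment_set`.
#' @param column Alignment column (1-based).
#' @param group `"mesophilic"` or `"thermophilic"`.
#' @return Named numeric vector of percentages summing to 100 (named by
#'   residue, decreasing); an empty vector with attribute `all_gap =
#'   TRUE` when every group sequence is gapped at the column.
#' @export
residue_content <- function(set, column, group) {
  stopifnot(inherits(set, "alignment_set"), length(column) == 1L)
  if (column < 1L || column > set$s) stop("Column out of range: ", column)
  rows <- group_rows(set, match.arg(group, c("mesophilic", "thermophilic")))
  if (length(rows) == 0L) stop("No sequences in group ", group)
  ch <- set$mat[rows, column]
  ch <- ch[ch != GAP]
  if (length(ch) == 0L) {
    out <- numeric(0)
    attr(out, "all_gap") <- TRUE
    return(out)
  }
  tab <- sort(table(ch), decreasing = TRUE)
  out <- as.numeric(tab) / length(ch) * 100
  names(out) <- names(tab)
  attr(out, "all_gap") <- FALSE
  out
}

#' Tabulate position profiles for report output
#'
#' Combines [position_differences()] with the top residue (and
#' percentage) of each group at every requested column.
#'
#' @inheritParams position_differences
#' @return Data frame: the difference profile plus `top_thermo`,
#'   `pct_thermo`, `top_meso`, `pct_meso`.
#' @export
position_profile_table <- function(set, table, columns,
                                   standardized = TRUE) {
  pd <- position_differences(set, table, columns, standardized)
  top <- function(column, group) {
    rc <- residue_content(set, column, group)
    if (length(rc) == 0L) c(res = NA_character_, pct = NA_character_) else
      c(res = names(rc)[1L], pct = format(round(rc[[1L]], 1), nsmall = 1))
  }
  tt <- t(vapply(columns, top, character(2), group = "thermophilic"))
  tm <- t(vapply(columns, top, character(2), group = "mesophilic"))
  pd$top_thermo <- tt[, 1L]
  pd$pct_thermo <- as.numeric(tt[, 2L])
  pd$top_meso <- tm[, 1L]
  pd$pct_meso <- as.numeric(tm[, 2L])
  pd
}
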