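# Sliding-window property profiling.
#
# Fragment i covers alignment columns i..i+w-1 (default w = 7), so an
# alignment of s columns yields s-6 fragments.  A sequence's window index
# for a property is the arithmetic mean of the property value over the
# non-gap residues in the window; gaps and non-standard residue codes are
# excluded from the mean (denominator = number of scored residues), never
# scored as zero, so indels do not masquerade as property shifts.  A
# window with no scorable residue has an undefined (NA) index.

#' Window property index of one sequence fragment
#'
#' @param seq A character vector of aligned single characters, or a
#'   single aligned string.
#' @param table A `property_table`.
#' @param accession Accession of the property scale to average.
#' @param i Fragment start column (1-based); the window covers columns
#'   `i..i+w-1`.
#' @param w Window width in columns (default 7).
#' @return Mean property value over the scorable residues in the window;
#'   `NA` if none are scorable.
#' @export
window_index <- function(seq, table, accession, i, w = 7L) {
  if (length(seq) == 1L && nchar(seq) > 1L) seq <- strsplit(seq, "")[[1]]
  s <- length(seq)
  if (i < 1L || i + w - 1L > s) stop("Fragment start out of range: ", i)
  if (!accession %in% names(table$entries)) {
    stop("Accession not in table: ", accession)
  }
  vals <- table$entries[[accession]][seq[i:(i + w - 1L)]]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) return(NA_real_)
  mean(vals)
}

#' Per-sequence window profiles for all properties
#'
#' Computes, for every sequence, fragment and property, the window
#' property index in one vectorized pass (running sums over non-gap
#' residues).  This is the shared substrate for group mean profiles,
#' per-fragment regression features, and label-permutation nulls (the
#' profiles do not depend on group labels, so a permutation only has to
#' re-average them).
#'
#' @param set An `alignment_set`.
#' @param table A `property_table`.
#' @param w Window width in columns (default 7).
#' @return Object of class `window_profiles`: list with `w`, `m` (number
#'   of fragments, `s - w + 1`), `acc`, `labels`, `ids`, `group`, and
#'   `val`, a list per accession of sequences x fragments matrices of
#'   window indices (NA where undefined).
#' @export
window_profiles <- function(set, table, w = 7L) {
  stopifnot(inherits(set, "alignment_set"), inherits(table, "property_table"))
  s <- set$s
  if (s < w) stop("Alignment has fewer columns (", s, ") than the window (", w, ")")
  m <- s - w + 1L
  n <- nrow(set$mat)
  pm <- property_matrix(table)
  val <- vector("list", ncol(pm))
  names(val) <- colnames(pm)
  for (acc in colnames(pm)) {
    lut <- pm[, acc]
    X <- matrix(lut[set$mat], nrow = n, ncol = s,
                dimnames = list(set$ids, NULL))
    A <- X
    A[is.na(A)] <- 0
    K <- !is.na(X)
    csA <- cbind(0, t(apply(A, 1L, cumsum)))
    csK <- cbind(0L, t(apply(K, 1L, cumsum)))
    sums <- csA[, (w + 1L):(s + 1L), drop = FALSE] - csA[, 1L:m, drop = FALSE]
    cnts <- csK[, (w + 1L):(s + 1L), drop = FALSE] - csK[, 1L:m, drop = FALSE]
    Wm <- sums / cnts
    Wm[cnts == 0L] <- NA_real_
    val[[acc]] <- Wm
  }
  structure(list(w = as.integer(w), m = m, acc = colnames(pm),
                 labels = property_labels(table), ids = set$ids,
                 group = set$group, val = val),
            class = "window_profiles")
}

#' Gap (missing-number) counts per alignment column
#'
#' Counts, for every column, the sequences carrying a gap there, over
#' both thermal groups; the reference/template sequence is excluded (it
#' is a coordinate anchor, not a data point).  A column with missing
#' number zero cannot host an insertion or deletion, so only point
#' substitutions can alter its properties.
#'
#' @param set An `alignment_set`.
#' @return Integer vector of length `set$s`.
#' @export
missing_numbers <- function(set) {
  stopifnot(inherits(set, "alignment_set"))
  rows <- which(set$group != "reference")
  colSums(set$mat[rows, , drop = FALSE] == GAP)
}

#' Group mean window profiles
#'
#' Averages the per-sequence window indices within each thermal group,
#' fragment by fragment and property by property, over the sequences
#' whose window index is defined.  The reference sequence belongs to
#' neither group and is never averaged.
#'
#' @param set An `alignment_set` containing both groups.
#' @param table A `property_table`.
#' @param w Window width (default 7).
#' @param profiles Optional precomputed [window_profiles()] for `set`.
#' @return List with `Pt_bar` and `Pm_bar`, fragments x properties
#'   matrices of thermophilic and mesophilic group means.
#' @export
group_mean_profiles <- function(set, table, w = 7L, profiles = NULL) {
  if (is.null(profiles)) profiles <- window_profiles(set, table, w)
  tro <- which(profiles$group == "thermophilic")
  mes <- which(profiles$group == "mesophilic")
  if (length(tro) == 0L) stop("No thermophilic sequences in alignment")
  if (length(mes) == 0L) stop("No mesophilic sequences in alignment")
  gmean <- function(rows) {
    out <- vapply(profiles$acc, function(acc) {
      Wm <- profiles$val[[acc]][rows, , drop = FALSE]
      colMeans(Wm, na.rm = TRUE)
    }, numeric(profiles$m))
    matrix(out, nrow = profiles$m, dimnames = list(NULL, profiles$acc))
  }
  Pt_bar <- gmean(tro)
  Pm_bar <- gmean(mes)
  Pt_bar[is.nan(Pt_bar)] <- NA_real_
  Pm_bar[is.nan(Pm_bar)] <- NA_real_
  list(Pt_bar = Pt_bar, Pm_bar = Pm_bar)
}

#' Thermophile-minus-mesophile difference matrix
#'
#' The per-fragment, per-property difference `D = Pt_bar - Pm_bar` is the
#' thermostability contribution attributed to the fragment; `V` stacks
#' the D rows of the retained (gap-free) fragments, one column per
#' property, and is the matrix later decomposed by PCA.
#'
#' @param Pt_bar,Pm_bar Group mean matrices from [group_mean_profiles()].
#' @param retained Logical vector per fragment (gap-free rule); when
#'   `NULL`, all fragments with complete difference rows are retained.
#' @return List with `D` (all fragments) and `V` (retained rows only,
#'   with `rownames` giving fragment start columns).
#' @export
difference_matrix <- function(Pt_bar, Pm_bar, retained = NULL) {
  stopifnot(identical(dim(Pt_bar), dim(Pm_bar)))
  D <- Pt_bar - Pm_bar
  rownames(D) <- seq_len(nrow(D))
  keep <- stats::complete.cases(D)
  if (!is.null(retained)) keep <- keep & retained
  list(D = D, V = D[keep, , drop = FALSE], retained = keep)
}

#' Build the full fragment matrix for one merged alignment
#'
#' Convenience constructor running [window_profiles()],
#' [group_mean_profiles()], [missing_numbers()] and
#' [difference_matrix()], and applying the gap filter: fragment i is
#' retained iff every column in its window has missing number zero.
#'
#' @param set Merged `alignment_set` with both groups (reference
#'   optional).
#' @param table A `property_table`.
#' @param w Window width (default 7).
#' @return Object of class `fragment_matrix`: list with `w`, `m`,
#'   `start` (fragment start columns), `ref_from`/`ref_to` (reference
#'   residue span of each fragment, 0 where the window holds no
#'   reference residue), `Pt_bar`, `Pm_bar`, `D`, `missing`, `retained`,
#'   `V` (retained difference rows), `acc`, `labels`, `profiles`, and
#'   `group`/`col_map`/`s` copied from the alignment.
#' @export
fragment_matrix <- function(set, table, w = 7L) {
  profiles <- window_profiles(set, table, w)
  gm <- group_mean_profiles(set, table, w, profiles = profiles)
  miss <- missing_numbers(set)
  m <- profiles$m
  gapfree <- miss == 0L
  csg <- cumsum(c(0L, !gapfree))
  retained <- (csg[(w + 1L):(set$s + 1L)] - csg[1L:m]) == 0L
  dm <- difference_matrix(gm$Pt_bar, gm$Pm_bar, retained)
  ref_from <- ref_to <- integer(m)
  for (i in seq_len(m)) {
    rr <- set$col_map[i:(i + w - 1L)]
    rr <- rr[rr > 0L]
    ref_from[i] <- if (length(rr)) min(rr) else 0L
    ref_to[i] <- if (length(rr)) max(rr) else 0L
  }
  structure(list(w = as.integer(w), m = m, start = seq_len(m),
                 ref_from = ref_from, ref_to = ref_to,
                 Pt_bar = gm$Pt_bar, Pm_bar = gm$Pm_bar,
                 D = dm$D, missing = miss, retained = dm$retained,
                 V = dm$V, acc = profiles$acc, labels = profiles$labels,
                 profiles = profiles, group = set$group,
                 col_map = set$col_map, s = set$s),
            class = "fragment_matrix")
}

#' @export
print.fragment_matrix <- function(x, ...) {
  cat("Fragment matrix: ", x$m, " fragments (window ", x$w, ", alignment ",
      x$s, " columns), ", sum(x$retained), " retained after the gap filter\n",
      sep = "")
  invisible(x)
}

#' Export fragment-level results as data frames
#'
#' @param x A `fragment_matrix`.
#' @param ... Unused.
#' @return Data frame with one row per fragment: start column, reference
#'   residue span, retained flag and the six property differences.
#' @export
as.data.frame.fragment_matrix <- function(x, ...) {
  D <- x$D
  colnames(D) <- paste0("d_", x$labels[x$acc])
  data.frame(fragment = x$start, start_col = x$start,
             end_col = x$start + x$w - 1L,
             ref_from = x$ref_from, ref_to = x$ref_to,
             retained = x$retained, D, row.names = NULL)
}
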