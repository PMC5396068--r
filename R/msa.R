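# Alignment containers and reference-anchored merging.
#
# An alignment_set holds one or both thermal groups of an aligned protein
# family plus an optional reference (template) sequence shared by both
# group alignments.  The reference anchors the merge of the two group
# alignments and translates alignment columns into reference residue
# numbers, the coordinate system in which domain boundaries are stated.

GAP <- "-"
NONSTANDARD <- c("B", "Z", "X", "U", "O", "J")

#' Construct an alignment set
#'
#' Low-level constructor; most users will call [read_alignment()] or
#' [merge_on_reference()].  Validates the alphabet, equal sequence
#' lengths, and the thermal-class/OGT consistency rule: mesophilic
#' sequences must have 20 <= OGT < 40 degrees C and thermophilic
#' sequences OGT >= 50 (sequences from the 40-50 band are excluded by
#' construction of the dataset).
#'
#' @param mat Character matrix (sequences x columns) of single characters
#'   over the 20 standard residues, non-standard codes (B, Z, X, U, O, J)
#'   and the gap `-`; row names are sequence ids.
#' @param group Character vector per sequence: `"mesophilic"`,
#'   `"thermophilic"` or `"reference"`.
#' @param ogt Numeric vector of optimal growth temperatures (degrees C);
#'   `NA` allowed only for the reference.
#' @param ref_id Id of the reference sequence, or `NULL`.
#' @return An object of class `alignment_set` with elements `ids`,
#'   `group`, `ogt`, `mat`, `s` (number of columns), `ref_id`, and
#'   `col_map` (alignment column to reference residue number, 0 where the
#'   reference has a gap; all zero when `ref_id` is `NULL`).
#' @export
alignment_set <- function(mat, group, ogt, ref_id = NULL) {
  stopifnot(is.matrix(mat), is.character(mat))
  n <- nrow(mat)
  if (n == 0L || ncol(mat) == 0L) stop("Empty alignment")
  if (is.null(rownames(mat))) stop("Sequence matrix must have row names (ids)")
  if (anyDuplicated(rownames(mat))) stop("Duplicate sequence ids")
  if (length(group) != n || length(ogt) != n) {
    stop("group and ogt must have one entry per sequence")
  }
  bad_group <- setdiff(unique(group), c("mesophilic", "thermophilic", "reference"))
  if (length(bad_group) > 0L) {
    stop("Unknown group label(s): ", paste(bad_group, collapse = ", "))
  }
  alphabet <- c(aaindex_residues(), NONSTANDARD, GAP)
  bad <- !(mat %in% alphabet)
  if (any(bad)) {
    ids <- unique(rownames(mat)[row(mat)[bad]])
    stop("Invalid characters in sequence(s): ", paste(ids, collapse = ", "))
  }
  is_ref <- group == "reference"
  if (any(is.na(ogt) & !is_ref)) {
    stop("Missing OGT for non-reference sequence(s): ",
         paste(rownames(mat)[is.na(ogt) & !is_ref], collapse = ", "))
  }
  bad_meso <- group == "mesophilic" & (ogt < 20 | ogt >= 40)
  bad_thermo <- group == "thermophilic" & ogt < 50
  if (any(bad_meso, na.rm = TRUE)) {
    stop("OGT outside the mesophilic range [20, 40): ",
         paste(rownames(mat)[which(bad_meso)], collapse = ", "))
  }
  if (any(bad_thermo, na.rm = TRUE)) {
    stop("OGT below the thermophilic minimum of 50: ",
         paste(rownames(mat)[which(bad_thermo)], collapse = ", "))
  }
  if (!is.null(ref_id) && !ref_id %in% rownames(mat)) {
    stop("Reference id not present in alignment: ", ref_id)
  }
  obj <- structure(
    list(ids = rownames(mat), group = as.character(group),
         ogt = as.numeric(ogt), mat = mat, s = ncol(mat),
         ref_id = ref_id, col_map = integer(ncol(mat))),
    class = "alignment_set")
  if (!is.null(ref_id)) {
    refrow <- mat[ref_id, ]
    obj$col_map <- as.integer(ifelse(refrow != GAP, cumsum(refrow != GAP), 0L))
  }
  obj
}

#' @export
print.alignment_set <- function(x, ...) {
  cat("Alignment set: ", length(x$ids), " sequences x ", x$s, " columns\n",
      sep = "")
  tab <- table(x$group)
  cat("  groups: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n",
      sep = "")
  if (!is.null(x$ref_id)) {
    cat("  reference: ", x$ref_id, " (",
        max(x$col_map), " residues)\n", sep = "")
  }
  invisible(x)
}

#' Read an aligned FASTA file with a metadata table
#'
#' The metadata file is tab-separated with header columns
#' `id organism ogt group`; every FASTA id must appear, and OGT may be
#' missing only for the reference record.  Input gaps written as `.` are
#' normalized to `-`; sequences are uppercased.
#'
#' @param fasta Path to aligned FASTA.
#' @param metadata Path to the TSV metadata file.
#' @param group Optional expected group for the non-reference sequences
#'   (`"mesophilic"` or `"thermophilic"`); an error is raised if the
#'   metadata disagrees.  With the default `NULL`, mixed groups (e.g. a
#'   merged alignment) are accepted.
#' @param ref_id Optional reference sequence id; enables the column map.
#' @return An [alignment_set()].
#' @export
read_alignment <- function(fasta, metadata, group = NULL, ref_id = NULL) {
  seqs <- Biostrings::readBStringSet(fasta)
  if (length(seqs) == 0L) stop("No sequences in ", fasta)
  widths <- Biostrings::width(seqs)
  if (length(unique(widths)) != 1L) {
    off <- names(seqs)[widths != stats::median(widths)]
    stop("Ragged alignment in ", fasta, "; offending id(s): ",
         paste(off, collapse = ", "))
  }
  ids <- sub("\\s.*$", "", names(seqs))
  chars <- toupper(as.character(seqs))
  chars <- gsub(".", "-", chars, fixed = TRUE)
  mat <- matrix(unlist(strsplit(chars, ""), use.names = FALSE),
                nrow = length(seqs), byrow = TRUE,
                dimnames = list(ids, NULL))

  meta <- utils::read.delim(metadata, stringsAsFactors = FALSE)
  need <- c("id", "organism", "ogt", "group")
  if (!all(need %in% names(meta))) {
    stop("Metadata must have columns: ", paste(need, collapse = ", "))
  }
  missing_meta <- setdiff(ids, meta$id)
  if (length(missing_meta) > 0L) {
    stop("FASTA id(s) absent from metadata: ",
         paste(missing_meta, collapse = ", "))
  }
  meta <- meta[match(ids, meta$id), ]
  if (!is.null(group)) {
    wrong <- meta$group != group & meta$group != "reference"
    if (any(wrong)) {
      stop("Sequence(s) not labelled '", group, "' in metadata: ",
           paste(ids[wrong], collapse = ", "))
    }
  }
  alignment_set(mat, group = meta$group, ogt = as.numeric(meta$ogt),
                ref_id = ref_id)
}

#' Write an alignment set to aligned FASTA
#'
#' @param set An `alignment_set`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(set, path) {
  stopifnot(inherits(set, "alignment_set"))
  seqs <- Biostrings::BStringSet(apply(set$mat, 1L, paste, collapse = ""))
  names(seqs) <- set$ids
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

degap <- function(chars) paste(chars[chars != GAP], collapse = "")

group_rows <- function(set, group) which(set$group == group)

# Anchor each alignment column to a reference residue: columns where the
# reference carries a residue get that residue's number; insertion columns
# (reference gap) get the number of the preceding residue (0 before the
# first residue).
anchor_columns <- function(set) {
  refrow <- set$mat[set$ref_id, ]
  isres <- refrow != GAP
  list(isres = isres, anchor = cumsum(isres))
}

#' Merge two group alignments on a shared reference sequence
#'
#' Both alignments must contain the reference (template) sequence with an
#' identical ungapped residue string.  The merged alignment is the
#' reference-anchored column union: columns where the reference carries a
#' residue are shared; insertion columns (reference gaps) are carried
#' over per group, placed after their anchoring reference residue with
#' mesophilic insertions before thermophilic ones.  No residue is created
#' or destroyed: degapping any sequence before and after the merge yields
#' the same string.  The result is symmetric in its two arguments (group
#' labels, not argument order, decide insertion placement).
#'
#' @param a,b `alignment_set`s for the two thermal groups (either order);
#'   each must be homogeneous in its non-reference group label and the
#'   two groups must differ.
#' @param ref_id Reference sequence id present in both.
#' @return Merged `alignment_set` containing one reference record plus
#'   all non-reference records of both inputs, with `col_map` populated.
#' @export
merge_on_reference <- function(a, b, ref_id) {
  stopifnot(inherits(a, "alignment_set"), inherits(b, "alignment_set"))
  for (set in list(a, b)) {
    if (!ref_id %in% set$ids) stop("Reference '", ref_id, "' missing from input")
  }
  ga <- setdiff(unique(a$group), "reference")
  gb <- setdiff(unique(b$group), "reference")
  if (length(ga) != 1L || length(gb) != 1L || ga == gb) {
    stop("Each input must hold one thermal group and the groups must differ")
  }
  meso <- if (ga == "mesophilic") a else b
  thermo <- if (ga == "mesophilic") b else a
  meso$ref_id <- thermo$ref_id <- ref_id

  ref_m <- degap(meso$mat[ref_id, ])
  ref_t <- degap(thermo$mat[ref_id, ])
  if (ref_m != ref_t) {
    stop("Ungapped reference differs between the two alignments; merge undefined")
  }
  L <- nchar(ref_m)

  am <- anchor_columns(meso)
  at <- anchor_columns(thermo)
  # insertion counts per anchor residue 0..L
  ins_m <- tabulate(am$anchor[!am$isres] + 1L, nbins = L + 1L)
  ins_t <- tabulate(at$anchor[!at$isres] + 1L, nbins = L + 1L)
  blocksize <- c(0L, rep(1L, L)) + ins_m + ins_t
  blockstart <- cumsum(c(0L, blocksize[-(L + 1L)]))  # start offset of block r
  s_new <- sum(blocksize)
  pos_res <- blockstart[2:(L + 1L)] + 1L  # residue column leads its block

  col_positions <- function(anch, ins_before) {
    # merged position of every original column of one input alignment
    pos <- integer(length(anch$anchor))
    isres <- anch$isres
    pos[isres] <- pos_res[anch$anchor[isres]]
    inscols <- which(!isres)
    if (length(inscols) > 0L) {
      r <- anch$anchor[inscols]
      # offset within this anchor's insertion run, in original column order
      off <- stats::ave(seq_along(inscols), r, FUN = seq_along)
      base <- blockstart[r + 1L] + ifelse(r > 0L, 1L, 0L) + ins_before[r + 1L]
      pos[inscols] <- base + off
    }
    pos
  }
  pos_m <- col_positions(am, integer(L + 1L))
  pos_t <- col_positions(at, ins_m)

  keep_m <- setdiff(meso$ids, ref_id)
  keep_t <- setdiff(thermo$ids, ref_id)
  ids_new <- c(ref_id, keep_m, keep_t)
  mat_new <- matrix(GAP, nrow = length(ids_new), ncol = s_new,
                    dimnames = list(ids_new, NULL))
  mat_new[ref_id, pos_res] <- strsplit(ref_m, "")[[1]]
  mat_new[keep_m, pos_m] <- meso$mat[keep_m, , drop = FALSE]
  mat_new[keep_t, pos_t] <- thermo$mat[keep_t, , drop = FALSE]

  grp <- c("reference",
           meso$group[match(keep_m, meso$ids)],
           thermo$group[match(keep_t, thermo$ids)])
  ogt <- c(NA_real_,
           meso$ogt[match(keep_m, meso$ids)],
           thermo$ogt[match(keep_t, thermo$ids)])
  alignment_set(mat_new, group = grp, ogt = ogt, ref_id = ref_id)
}

#' Define the three-domain partition in reference coordinates
#'
#' Defaults follow the reference enzyme's domain model: a small
#' N-terminal sub-domain (residues 1-111), the PLP-binding domain
#' (112-370) and the C-terminal domain (371 to the end of the chain).
#'
#' @param n1_end Last reference residue of the N-terminal sub-domain.
#' @param n2_end Last reference residue of the PLP-binding domain.
#' @param c_end Nominal last residue of the C-terminal domain (metadata
#'   only; residues beyond `n2_end` are always labelled `C`).
#' @return An object of class `domain_partition`.
#' @export
domain_partition <- function(n1_end = 111L, n2_end = 370L, c_end = 562L) {
  if (!(n1_end >= 1L && n2_end > n1_end && c_end > n2_end)) {
    stop("Domain boundaries must satisfy 1 <= n1_end < n2_end < c_end")
  }
  structure(list(n1_end = as.integer(n1_end), n2_end = as.integer(n2_end),
                 c_end = as.integer(c_end)),
            class = "domain_partition")
}

#' Label every alignment column with its domain
#'
#' Columns mapped to a reference residue take that residue's domain;
#' insertion columns (where the reference has a gap) inherit the domain
#' of the nearest preceding reference residue, and insertions before the
#' first residue are assigned to `N1`.
#'
#' @param set Merged `alignment_set` with a reference column map.
#' @param partition A [domain_partition()].
#' @return Character vector of length `set$s` over `{"N1","N2","C"}`.
#' @export
map_to_domains <- function(set, partition = domain_partition()) {
  stopifnot(inherits(set, "alignment_set"), inherits(partition, "domain_partition"))
  if (is.null(set$ref_id)) stop("Domain mapping requires a reference column map")
  # anchor residue of each column (preceding-residue rule for insertions)
  anchor <- cummax(set$col_map)
  anchor[anchor == 0L] <- 1L  # leading insertions -> domain of residue 1 (N1)
  ifelse(anchor <= partition$n1_end, "N1",
         ifelse(anchor <= partition$n2_end, "N2", "C"))
}

#' Write the column map of a merged alignment
#'
#' Emits a TSV with columns `column`, `ref_residue` (0 at insertion
#' columns) and `domain`, linking alignment and reference coordinates.
#'
#' @param set Merged `alignment_set`.
#' @param path Output TSV path.
#' @param partition A [domain_partition()].
#' @return The data frame written, invisibly.
#' @export
write_column_map <- function(set, path, partition = domain_partition()) {
  df <- data.frame(column = seq_len(set$s),
                   ref_residue = set$col_map,
                   domain = map_to_domains(set, partition))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
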