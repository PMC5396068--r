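# Insertion/deletion analysis: per-column gap rates per thermal group,
# the MRT contrast, and three-domain summaries.
#
# MRT ("missing rate of thermostability") is defined here as the signed
# difference of per-column gap rates, thermophilic minus mesophilic.  It
# lies in [-1, 1], is zero when indel behaviour is group-independent, and
# its +/-0.5 thresholds match the scale of the statistic; positive values
# mark thermophile-specific deletions (or mesophile-specific insertions)
# and negative values the converse.

#' Per-column gap rates per thermal group
#'
#' @param set Merged `alignment_set` with both groups; the reference is
#'   excluded.
#' @return Data frame with `column`, `mr_thermo`, `mr_meso` (gapped
#'   fraction of each group, in `[0, 1]`).
#' @export
missing_rates <- function(set) {
  stopifnot(inherits(set, "alignment_set"))
  tro <- group_rows(set, "thermophilic")
  mes <- group_rows(set, "mesophilic")
  if (length(tro) == 0L || length(mes) == 0L) stop("Both groups are required")
  data.frame(column = seq_len(set$s),
             mr_thermo = colMeans(set$mat[tro, , drop = FALSE] == GAP),
             mr_meso = colMeans(set$mat[mes, , drop = FALSE] == GAP))
}

#' Per-column MRT profile with domain labels
#'
#' @param set Merged `alignment_set` with a reference column map.
#' @param partition A [domain_partition()].
#' @param mrt_threshold Absolute MRT above which a column is flagged
#'   `high` (default 0.5, strict inequality).
#' @return Object of class `indel_profile`: data frame with `column`,
#'   `ref_residue`, `mr_thermo`, `mr_meso`, `mrt`, `missing` (gap count
#'   over both groups), `domain`, `high`.
#' @export
mrt_profile <- function(set, partition = domain_partition(),
                        mrt_threshold = 0.5) {
  rates <- missing_rates(set)
  mrt <- rates$mr_thermo - rates$mr_meso
  out <- data.frame(column = rates$column,
                    ref_residue = set$col_map,
                    mr_thermo = rates$mr_thermo,
                    mr_meso = rates$mr_meso,
                    mrt = mrt,
                    missing = missing_numbers(set),
                    domain = map_to_domains(set, partition),
                    high = abs(mrt) > mrt_threshold)
  structure(out, class = c("indel_profile", "data.frame"),
            mrt_threshold = mrt_threshold)
}

#' Three-domain summary of high-|MRT| columns
#'
#' Summarises, per domain (N1 = N-terminal sub-domain, N2 = PLP-binding
#' domain, C = C-terminal domain), how many columns carry any gap, how
#' many exceed the MRT threshold in absolute value, and each domain's
#' share of all high columns; also reports the share of high columns in
#' the two chain ends (N1 and C together).
#'
#' @param profile An `indel_profile` from [mrt_profile()].
#' @return List with `by_domain` (data frame: `domain`,
#'   `n_indel_columns`, `n_high`, `fraction_of_high`), `n_high_total`,
#'   `ends_fraction` (share of high columns in N1 or C), and `empty`
#'   (`TRUE` when no column is high, in which case all fractions are 0).
#' @export
domain_summary <- function(profile) {
  stopifnot(inherits(profile, "indel_profile"))
  doms <- c("N1", "N2", "C")
  n_high_total <- sum(profile$high)
  by_domain <- data.frame(
    domain = doms,
    n_indel_columns = vapply(doms, function(d)
      sum(profile$domain == d & profile$missing > 0L), integer(1)),
    n_high = vapply(doms, function(d)
      sum(profile$domain == d & profile$high), integer(1)),
    row.names = NULL)
  by_domain$fraction_of_high <- if (n_high_total == 0L) rep(0, 3L) else
    by_domain$n_high / n_high_total
  ends <- if (n_high_total == 0L) 0 else
    sum(by_domain$fraction_of_high[by_domain$domain %in% c("N1", "C")])
  list(by_domain = by_domain, n_high_total = n_high_total,
       ends_fraction = ends, empty = n_high_total == 0L)
}
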