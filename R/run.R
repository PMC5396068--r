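# Pipeline orchestration: merge -> profile -> PCA score -> candidates ->
# MLR -> positions -> indel/MRT -> domain summary, with TSV/JSON outputs
# and a Markdown report.

#' Assemble a pipeline run configuration
#'
#' @param meso,thermo Group inputs: paths to aligned FASTA files, or
#'   `alignment_set`s built in memory.
#' @param metadata Path to the TSV metadata file (only needed when the
#'   group inputs are paths).
#' @param aaindex Path to an AAindex1 property file, or a
#'   `property_table`.
#' @param ref_id Reference (template) sequence id present in both groups.
#' @param accessions Accessions to extract from the property file
#'   (default [thermostability_properties()]).
#' @param window Sliding-window width in columns (default 7).
#' @param sd_threshold Component retention threshold on the PC standard
#'   deviation (default 1).
#' @param cumvar Cumulative variance share for FL choice (default 0.80).
#' @param score_threshold Candidate score threshold (default 1.2).
#' @param alpha Candidate significance level (default 0.01).
#' @param mrt_threshold Absolute MRT flagging threshold (default 0.5).
#' @param n_perm Label permutations for the null (default 999).
#' @param seed Integer seed for the permutation stream (default 17).
#' @param partition A [domain_partition()].
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @return Object of class `run_config`.
#' @export
run_config <- function(meso, thermo, metadata = NULL, aaindex,
                       ref_id, accessions = thermostability_properties(),
                       window = 7L, sd_threshold = 1, cumvar = 0.80,
                       score_threshold = 1.2, alpha = 0.01,
                       mrt_threshold = 0.5, n_perm = 999L, seed = 17L,
                       partition = domain_partition(), out_dir = NULL) {
  stopifnot(window >= 1, sd_threshold > 0, cumvar > 0, cumvar <= 1,
            score_threshold > 0, alpha > 0, alpha < 1, mrt_threshold > 0,
            n_perm >= 1)
  structure(list(meso = meso, thermo = thermo, metadata = metadata,
                 aaindex = aaindex, ref_id = ref_id,
                 accessions = accessions, window = as.integer(window),
                 sd_threshold = sd_threshold, cumvar = cumvar,
                 score_threshold = score_threshold, alpha = alpha,
                 mrt_threshold = mrt_threshold, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), partition = partition,
                 out_dir = out_dir),
            class = "run_config")
}

load_group <- function(input, metadata, group, ref_id, stage) {
  if (inherits(input, "alignment_set")) return(input)
  tryCatch(read_alignment(input, metadata, group = group, ref_id = ref_id),
           error = function(e) stop("[", stage, "] ", conditionMessage(e),
                                    call. = FALSE))
}

sig6 <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- signif(df[[j]], 6)
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(sig6(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the full thermostability-determinant pipeline
#'
#' Executes every stage on one pair of group alignments and (optionally)
#' writes all module outputs: `fragments.tsv`, `missing.tsv`,
#' `scores.tsv`, `pca.json`, `mlr.tsv`, `positions.tsv`, `mrt.tsv`,
#' `domains.tsv`, `column_map.tsv` and a human-readable `report.md`.
#' All thresholds and the seed are logged in `pca.json` and the report;
#' reruns with the same inputs and seed produce byte-identical files.
#'
#' @param config A [run_config()].
#' @return Object of class `thermodet_run`: list with `merged`
#'   (alignment), `table`, `fm` (fragment matrix), `track_all`
#'   (unfiltered score track), `candidates`, `mlr`, `positions`,
#'   `indel`, `domains`, and `config`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  table <- if (inherits(config$aaindex, "property_table")) config$aaindex
  else tryCatch(parse_aaindex(config$aaindex, wanted = config$accessions),
                error = function(e) stop("[aaindex] ", conditionMessage(e),
                                         call. = FALSE))
  meso <- load_group(config$meso, config$metadata, "mesophilic",
                     config$ref_id, "read meso")
  thermo <- load_group(config$thermo, config$metadata, "thermophilic",
                       config$ref_id, "read thermo")
  merged <- tryCatch(merge_on_reference(meso, thermo, config$ref_id),
                     error = function(e) stop("[merge] ", conditionMessage(e),
                                              call. = FALSE))
  fm <- fragment_matrix(merged, table, config$window)
  track_all <- score_fragments(fm, config$sd_threshold, config$cumvar,
                               use = "all")
  cand <- candidate_fragments(fm, config$sd_threshold, config$cumvar,
                              threshold = config$score_threshold,
                              alpha = config$alpha, n_perm = config$n_perm,
                              seed = config$seed)
  hits <- cand$fragment[cand$candidate]
  mlr <- if (length(hits) > 0L) validate_candidates(fm, hits) else
    data.frame(fragment = integer(0), R = numeric(0),
               p_overall = numeric(0), significant = character(0))
  pos_cols <- if (length(hits) > 0L)
    sort(unique(unlist(lapply(hits, function(h) h:(h + config$window - 1L)))))
  else integer(0)
  positions <- if (length(pos_cols) > 0L)
    position_profile_table(merged, table, pos_cols) else NULL
  indel <- mrt_profile(merged, config$partition, config$mrt_threshold)
  domains <- domain_summary(indel)

  run <- structure(list(merged = merged, table = table, fm = fm,
                        track_all = track_all, candidates = cand,
                        mlr = mlr, positions = positions, indel = indel,
                        domains = domains, config = config),
                   class = "thermodet_run")
  if (!is.null(config$out_dir)) write_outputs(run, config$out_dir)
  run
}

write_outputs <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config <- run$config
  fm <- run$fm
  cand <- run$candidates

  write_tsv(as.data.frame(fm), file.path(out_dir, "fragments.tsv"))
  write_tsv(data.frame(column = seq_len(fm$s),
                       ref_residue = fm$col_map,
                       missing = fm$missing),
            file.path(out_dir, "missing.tsv"))
  write_tsv(as.data.frame(unclass(cand), stringsAsFactors = FALSE),
            file.path(out_dir, "scores.tsv"))
  write_tsv(run$mlr, file.path(out_dir, "mlr.tsv"))
  if (!is.null(run$positions)) {
    write_tsv(run$positions, file.path(out_dir, "positions.tsv"))
  }
  write_tsv(as.data.frame(unclass(run$indel), stringsAsFactors = FALSE),
            file.path(out_dir, "mrt.tsv"))
  write_tsv(run$domains$by_domain, file.path(out_dir, "domains.tsv"))
  write_column_map(run$merged, file.path(out_dir, "column_map.tsv"),
                   config$partition)

  fls <- attr(cand, "fls")
  pca_meta <- list(
    sdev = if (!is.null(fls)) fls$sdev else NULL,
    variance_proportion = if (!is.null(fls)) fls$prop else NULL,
    retained_components = if (!is.null(fls)) fls$retained else NULL,
    rotation_matrix = if (!is.null(fls)) unclass(fls$rotmat) else NULL,
    rotated_loadings = if (!is.null(fls)) unclass(fls$loadings_rot) else NULL,
    rotated_variance_share = if (!is.null(fls)) fls$var_share else NULL,
    chosen_fls = if (!is.null(fls)) fls$chosen else NULL,
    fl_weights = if (!is.null(fls)) fls$weights else NULL,
    thresholds = attr(cand, "thresholds"),
    seed = config$seed)
  jsonlite::write_json(pca_meta, file.path(out_dir, "pca.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  writeLines(report_lines(run), file.path(out_dir, "report.md"))
  invisible(out_dir)
}

report_lines <- function(run) {
  config <- run$config
  cand <- run$candidates
  hits <- cand[cand$candidate, , drop = FALSE]
  fls <- attr(cand, "fls")
  lines <- c(
    "# Thermostability determinant report",
    "",
    sprintf("Alignment: %d sequences (%d mesophilic, %d thermophilic), %d columns.",
            length(run$merged$ids),
            sum(run$merged$group == "mesophilic"),
            sum(run$merged$group == "thermophilic"),
            run$merged$s),
    sprintf("Fragments: %d (window %d); %d retained after the gap filter.",
            run$fm$m, config$window, sum(run$fm$retained)),
    sprintf("Thresholds: PC sd > %g, cumulative variance >= %g%%, score > %g, alpha = %g, |MRT| > %g; %d permutations, seed %d.",
            config$sd_threshold, 100 * config$cumvar,
            config$score_threshold, config$alpha, config$mrt_threshold,
            config$n_perm, config$seed),
    "")
  if (!is.null(fls)) {
    lines <- c(lines,
      sprintf("Principal components: variance proportions %s; retained %s; chosen FLs (rotated) %s.",
              paste(sprintf("%.1f%%", 100 * fls$prop), collapse = ", "),
              paste(fls$retained, collapse = ", "),
              paste(fls$chosen, collapse = ", ")),
      "")
  }
  lines <- c(lines, "## Candidate fragments", "")
  if (nrow(hits) == 0L) {
    lines <- c(lines, "No fragment passed the score and significance rule.", "")
  } else {
    mlr <- run$mlr
    lines <- c(lines,
      "| fragment (cols) | ref span | score | p | R | overall p | significant factors |",
      "|---|---|---|---|---|---|---|")
    for (i in seq_len(nrow(hits))) {
      mr <- mlr[mlr$fragment == hits$fragment[i], , drop = FALSE]
      lines <- c(lines, sprintf(
        "| %d-%d | %d-%d | %.3f | %.4g | %.3f | %.3g | %s |",
        hits$start_col[i], hits$end_col[i], hits$ref_from[i], hits$ref_to[i],
        hits$score[i], hits$p[i],
        if (nrow(mr)) mr$R else NA, if (nrow(mr)) mr$p_overall else NA,
        if (nrow(mr)) mr$significant else ""))
    }
    lines <- c(lines, "")
  }
  ds <- run$domains
  lines <- c(lines, "## Insertion/deletion (MRT) summary", "",
    sprintf("Columns with any gap: %d; columns with |MRT| > %g: %d.",
            sum(run$indel$missing > 0L), config$mrt_threshold,
            ds$n_high_total),
    "")
  if (ds$empty) {
    lines <- c(lines, "No column exceeds the MRT threshold.", "")
  } else {
    bd <- ds$by_domain
    lines <- c(lines,
      "| domain | indel columns | high-MRT columns | share of high |",
      "|---|---|---|---|",
      sprintf("| %s | %d | %d | %.1f%% |", bd$domain, bd$n_indel_columns,
              bd$n_high, 100 * bd$fraction_of_high),
      "",
      sprintf("Share of high-MRT columns in the chain ends (N1 + C): %.1f%%.",
              100 * ds$ends_fraction),
      "")
  }
  lines
}

#' @export
print.thermodet_run <- function(x, ...) {
  cat(report_lines(x), sep = "\n")
  invisible(x)
}
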