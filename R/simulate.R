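# Synthetic two-group alignment generator with planted determinants.
#
# Columns follow a shared consensus-plus-noise model: each column has a
# consensus residue drawn from the background composition, and every
# sequence copies the consensus with probability rho (default 0.8,
# emulating the ~80% within-family identity of the real data) or draws
# from the background otherwise.  Planted determinant columns make
# thermophilic sequences draw from a designated residue set with
# probability e, while the column consensus is drawn outside that set so
# the contrast is genuine.  Gap hotspots delete a whole column span from
# a sequence of the designated group with probability g (one Bernoulli
# per sequence per hotspot, mimicking a segmental indel).  A gap-free
# consensus reference sequence is included in both groups' alignments
# under a fixed id, so the synthetic sets merge exactly like real data.

#' Configuration for the synthetic alignment generator
#'
#' Defaults mirror the study design of the family analysis the pipeline
#' implements: 305 mesophilic and 73 thermophilic sequences over a
#' 562-column alignment, three planted determinant columns carrying
#' thermophile-enriched residues from the Leu/Val/Lys/Asp/Glu/Phe set
#' (two in the PLP-binding domain, one C-terminal), and one
#' thermophile-biased gap hotspot in the C-terminal domain.  Each default
#' determinant pairs its enriched residues with a property-contrasting
#' consensus (Lys vs Gly: charge and side-chain gain; Val/Phe vs Ser:
#' hydrophobicity and buriability gain; Asp/Glu vs Val: charge gain with
#' hydrophobicity loss), the directional shifts that characterise
#' thermophile-enriched positions.
#'
#' @param n_meso,n_thermo Sequence counts per group.
#' @param s Alignment length in columns (the synthetic reference is
#'   gap-free, so reference residue numbers equal columns).
#' @param background Residue frequency vector over the 20 standard
#'   residues (AAindex order); default uniform.
#' @param planted_columns List of lists `(column, residues, e)`: at each
#'   planted column, thermophilic sequences draw uniformly from
#'   `residues` with probability `e`.  An optional `consensus` element
#'   fixes the column's consensus residue (the mesophilic identity);
#'   otherwise it is drawn from the background outside `residues`.  Note
#'   that the recoverable signal is the physico-chemical contrast between
#'   the enriched residues and the consensus, not the residue identity:
#'   a planted Lys against a property-similar consensus (e.g. Glu) is a
#'   weak determinant by construction.
#' @param gap_hotspots List of lists `(columns, group, g)`: each sequence
#'   of `group` has its residues over `columns` replaced by gaps with
#'   probability `g`.
#' @param meso_ogt,thermo_ogt OGT ranges (degrees C) to draw uniformly
#'   from; defaults `[20, 40)` and `[50, 85]` per the thermal-class
#'   definition.
#' @param rho Conservation: probability a cell copies the column
#'   consensus (default 0.8).
#' @param ref_id Id of the gap-free consensus reference included in both
#'   sets.
#' @param partition Domain boundaries in reference coordinates; by
#'   default scaled from the 111/370/562 boundaries to length `s`.
#' @param seed Integer seed driving all randomness of one simulation.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_meso = 305L, n_thermo = 73L, s = 562L,
                             background = rep(1 / 20, 20L),
                             planted_columns = list(
                               list(column = round(s * 116 / 562),
                                    residues = "K", consensus = "G",
                                    e = 0.9),
                               list(column = round(s * 244 / 562),
                                    residues = c("V", "F"), consensus = "S",
                                    e = 0.9),
                               list(column = round(s * 462 / 562),
                                    residues = c("D", "E"), consensus = "V",
                                    e = 0.9)),
                             gap_hotspots = list(
                               list(columns = (s - 4L):s,
                                    group = "thermophilic", g = 0.8)),
                             meso_ogt = c(20, 40), thermo_ogt = c(50, 85),
                             rho = 0.8, ref_id = "REF_TEMPLATE",
                             partition = NULL, seed = 1L) {
  if (length(background) != 20L || any(background < 0)) {
    stop("background must be 20 non-negative frequencies")
  }
  if (abs(sum(background) - 1) > 1e-8) stop("background must sum to 1")
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]")
  if (s < 7L) stop("s must be at least the window width")
  for (p in planted_columns) {
    if (p$column < 1L || p$column > s) stop("Planted column out of range")
    if (p$e < 0 || p$e > 1) stop("Enrichment probability e must be in [0, 1]")
    if (!all(p$residues %in% aaindex_residues())) {
      stop("Planted residues must be standard one-letter codes")
    }
    if (!is.null(p$consensus)) {
      if (!(length(p$consensus) == 1L && p$consensus %in% aaindex_residues())) {
        stop("Planted consensus must be a single standard residue code")
      }
      if (p$consensus %in% p$residues) {
        stop("Planted consensus residue must lie outside the enriched set")
      }
    }
  }
  for (h in gap_hotspots) {
    if (any(h$columns < 1L | h$columns > s)) stop("Hotspot columns out of range")
    if (h$g < 0 || h$g > 1) stop("Gap probability g must be in [0, 1]")
    if (!h$group %in% c("mesophilic", "thermophilic")) {
      stop("Hotspot group must be mesophilic or thermophilic")
    }
    if (h$group == "thermophilic") {
      clash <- vapply(planted_columns, function(p)
        p$column %in% h$columns, logical(1))
      if (any(clash)) {
        stop("Planted determinant column inside a thermophilic gap hotspot: ",
             "the two signals would be confounded")
      }
    }
  }
  if (is.null(partition)) {
    partition <- domain_partition(max(1L, round(s * 111 / 562)),
                                  max(2L, round(s * 370 / 562)), s)
  }
  structure(list(n_meso = as.integer(n_meso), n_thermo = as.integer(n_thermo),
                 s = as.integer(s), background = background,
                 planted_columns = planted_columns,
                 gap_hotspots = gap_hotspots,
                 meso_ogt = meso_ogt, thermo_ogt = thermo_ogt, rho = rho,
                 ref_id = ref_id, partition = partition,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Simulate a mesophilic/thermophilic alignment pair with known truth
#'
#' @param config A [synthetic_config()].
#' @return Object of class `synthetic_alignments`: list with `meso` and
#'   `thermo` (`alignment_set`s, each containing the shared gap-free
#'   reference) and `truth` (planted columns, hotspots, consensus
#'   string, seed).
#' @export
simulate_alignments <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  res <- aaindex_residues()
  s <- config$s

  consensus <- sample(res, s, replace = TRUE, prob = config$background)
  for (p in config$planted_columns) {
    if (!is.null(p$consensus)) {
      consensus[p$column] <- p$consensus
    } else {
      # draw the consensus outside the enriched set so some contrast is
      # planted rather than accidental
      pool <- setdiff(res, p$residues)
      bg <- config$background[match(pool, res)]
      consensus[p$column] <- sample(pool, 1L, prob = bg / sum(bg))
    }
  }

  draw_group <- function(n, prefix, planted) {
    noise <- matrix(sample(res, n * s, replace = TRUE,
                           prob = config$background), n, s)
    keep <- matrix(stats::runif(n * s) < config$rho, n, s)
    mat <- noise
    consmat <- matrix(consensus, n, s, byrow = TRUE)
    mat[keep] <- consmat[keep]
    if (planted) {
      for (p in config$planted_columns) {
        sel <- stats::runif(n) < p$e
        if (any(sel)) {
          mat[sel, p$column] <- sample(p$residues, sum(sel), replace = TRUE)
        }
      }
    }
    rownames(mat) <- sprintf("%s_%03d", prefix, seq_len(n))
    mat
  }

  mat_m <- draw_group(config$n_meso, "MESO", planted = FALSE)
  mat_t <- draw_group(config$n_thermo, "THERMO", planted = TRUE)

  for (h in config$gap_hotspots) {
    mat <- if (h$group == "mesophilic") mat_m else mat_t
    hit <- stats::runif(nrow(mat)) < h$g
    if (any(hit)) mat[hit, h$columns] <- GAP
    if (h$group == "mesophilic") mat_m <- mat else mat_t <- mat
  }

  ogt_m <- pmin(round(stats::runif(config$n_meso, config$meso_ogt[1],
                                   config$meso_ogt[2]), 1), 39.9)
  ogt_t <- pmax(round(stats::runif(config$n_thermo, config$thermo_ogt[1],
                                   config$thermo_ogt[2]), 1), 50)

  with_ref <- function(mat, group, ogt) {
    full <- rbind(matrix(consensus, 1L, s,
                         dimnames = list(config$ref_id, NULL)), mat)
    alignment_set(full,
                  group = c("reference", rep(group, nrow(mat))),
                  ogt = c(NA_real_, ogt), ref_id = config$ref_id)
  }

  truth <- list(
    planted_columns = lapply(config$planted_columns, function(p)
      list(column = p$column, residues = p$residues, e = p$e)),
    gap_hotspots = lapply(config$gap_hotspots, function(h)
      list(columns = h$columns, group = h$group, g = h$g)),
    consensus = paste(consensus, collapse = ""),
    seed = config$seed)

  structure(list(meso = with_ref(mat_m, "mesophilic", ogt_m),
                 thermo = with_ref(mat_t, "thermophilic", ogt_t),
                 truth = truth, config = config),
            class = "synthetic_alignments")
}

#' Write a simulated dataset as pipeline input files
#'
#' Emits `meso.fasta`, `thermo.fasta` (aligned FASTA, reference included
#' in both), `metadata.tsv` (`id organism ogt group`; the reference has
#' no OGT) and `truth.json`.  Output is byte-stable for a fixed seed.
#'
#' @param sim A `synthetic_alignments` object.
#' @param outdir Output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_fixture <- function(sim, outdir) {
  stopifnot(inherits(sim, "synthetic_alignments"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(meso = file.path(outdir, "meso.fasta"),
             thermo = file.path(outdir, "thermo.fasta"),
             metadata = file.path(outdir, "metadata.tsv"),
             truth = file.path(outdir, "truth.json"))
  write_alignment(sim$meso, paths[["meso"]])
  write_alignment(sim$thermo, paths[["thermo"]])
  meta_rows <- function(set) {
    keep <- set$group != "reference"
    data.frame(id = set$ids[keep],
               organism = paste0("synthetic_", tolower(set$ids[keep])),
               ogt = set$ogt[keep], group = set$group[keep])
  }
  meta <- rbind(
    data.frame(id = sim$config$ref_id, organism = "synthetic_reference",
               ogt = NA_real_, group = "reference"),
    meta_rows(sim$meso), meta_rows(sim$thermo))
  utils::write.table(meta, paths[["metadata"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(sim$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
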