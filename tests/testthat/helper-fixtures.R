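# Shared fixture builders: small property tables and alignments built in
# code, plus a default synthetic AAindex path.

aa_fixture_path <- function() {
  system.file("extdata", "aaindex_six_synthetic.txt", package = "thermodet")
}

# property_table from a named list of length-20 numeric vectors (AAindex
# residue order)
make_table <- function(entries, names = NULL) {
  entries <- lapply(entries, function(v) stats::setNames(v, aaindex_residues()))
  if (is.null(names)) {
    names <- stats::setNames(paste("Synthetic scale", names(entries)),
                             names(entries))
  }
  structure(list(entries = entries, names = names), class = "property_table")
}

const_table <- function(val = 1, acc = "TEST000001") {
  make_table(stats::setNames(list(rep(val, 20)), acc))
}

ramp_table <- function(acc = "RAMP000001") {
  make_table(stats::setNames(list(as.numeric(1:20)), acc))
}

# six-scale random table for oracle fixtures
random_table <- function(k = 6) {
  accs <- sprintf("RND%07d", seq_len(k))
  make_table(stats::setNames(lapply(seq_len(k), function(i)
    round(stats::runif(20, -5, 5), 3)), accs))
}

# alignment_set from named aligned strings
make_set <- function(seqs, group, ogt, ref_id = NULL) {
  mat <- do.call(rbind, strsplit(unname(seqs), ""))
  rownames(mat) <- names(seqs)
  alignment_set(mat, group = group, ogt = ogt, ref_id = ref_id)
}

# random two-group alignment (no reference) for brute-force oracles
random_set <- function(n_meso, n_thermo, s, gap_prob = 0.05) {
  n <- n_meso + n_thermo
  res <- aaindex_residues()
  mat <- matrix(sample(res, n * s, replace = TRUE), n, s)
  gaps <- matrix(stats::runif(n * s) < gap_prob, n, s)
  mat[gaps] <- "-"
  rownames(mat) <- c(sprintf("M%03d", seq_len(n_meso)),
                     sprintf("T%03d", seq_len(n_thermo)))
  alignment_set(mat,
                group = c(rep("mesophilic", n_meso),
                          rep("thermophilic", n_thermo)),
                ogt = c(round(stats::runif(n_meso, 20, 39), 1),
                        round(stats::runif(n_thermo, 50, 85), 1)))
}

write_fixture_files <- function(sim, dir = tempfile("fix")) {
  write_fixture(sim, dir)
}
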