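write_test_inputs <- function(seqs, meta, dir = tempfile("msa")) {
  dir.create(dir)
  fa <- file.path(dir, "aln.fasta")
  writeLines(unlist(lapply(names(seqs), function(id)
    c(paste0(">", id), seqs[[id]]))), fa)
  tsv <- file.path(dir, "meta.tsv")
  utils::write.table(meta, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  list(fasta = fa, metadata = tsv)
}

test_that("read_alignment validates lengths, metadata and the OGT class rule", {
  seqs <- c(M1 = "ACDEFGHIKL", M2 = "ACDEFGH-KL", REF = "ACDEFGHIKL")
  meta <- data.frame(id = c("M1", "M2", "REF"),
                     organism = c("o1", "o2", "ref"),
                     ogt = c(25, 37, NA),
                     group = c("mesophilic", "mesophilic", "reference"))
  p <- write_test_inputs(seqs, meta)
  set <- read_alignment(p$fasta, p$metadata, group = "mesophilic",
                        ref_id = "REF")
  expect_s3_class(set, "alignment_set")
  expect_identical(set$s, 10L)
  expect_identical(set$col_map, 1:10)

  # thermophilic label with OGT 45 violates the dataset rule
  meta$ogt <- c(25, 45, NA)
  meta$group <- c("mesophilic", "thermophilic", "reference")
  p2 <- write_test_inputs(seqs, meta)
  expect_error(read_alignment(p2$fasta, p2$metadata), "thermophilic minimum")

  # ragged alignment names the offender
  seqs_bad <- c(M1 = "ACDEFGHIKL", M2 = "ACDEFGHIKLM", REF = "ACDEFGHIKL")
  p3 <- write_test_inputs(seqs_bad, meta)
  expect_error(read_alignment(p3$fasta, p3$metadata), "M2")

  # dots are accepted and normalized to gaps
  seqs_dot <- c(M1 = "ACDEFGHIKL", M2 = "ACDEFGH.KL", REF = "ACDEFGHIKL")
  meta$ogt <- c(25, 37, NA); meta$group <- c("mesophilic", "mesophilic", "reference")
  p4 <- write_test_inputs(seqs_dot, meta)
  set4 <- read_alignment(p4$fasta, p4$metadata)
  expect_identical(unname(set4$mat["M2", 8L]), "-")
})

test_that("merge anchors columns on the reference: hand-built insertion case", {
  meso <- make_set(c(REF = "A-CD", M1 = "AWCD"),
                   group = c("reference", "mesophilic"),
                   ogt = c(NA, 30), ref_id = "REF")
  thermo <- make_set(c(REF = "ACD", T1 = "AC-"),
                     group = c("reference", "thermophilic"),
                     ogt = c(NA, 60), ref_id = "REF")
  mg <- merge_on_reference(meso, thermo, "REF")
  expect_identical(mg$s, 4L)
  expect_identical(mg$col_map, c(1L, 0L, 2L, 3L))
  expect_identical(paste(mg$mat["T1", ], collapse = ""), "A-C-")
  expect_identical(paste(mg$mat["M1", ], collapse = ""), "AWCD")
  expect_identical(paste(mg$mat["REF", ], collapse = ""), "A-CD")
})

test_that("merge is symmetric, preserves residues, and errors on reference mismatch", {
  set.seed(42)
  res <- aaindex_residues()
  ref <- paste(sample(res, 12, replace = TRUE), collapse = "")
  gapify <- function(seq, at) {
    ch <- strsplit(seq, "")[[1]]
    out <- character(nchar(seq) + length(at))
    out[at] <- "-"
    out[-at] <- ch
    paste(out, collapse = "")
  }
  meso <- make_set(c(REF = gapify(ref, c(3, 9)),
                     M1 = paste(sample(res, 14, replace = TRUE), collapse = "")),
                   group = c("reference", "mesophilic"), ogt = c(NA, 25),
                   ref_id = "REF")
  thermo <- make_set(c(REF = gapify(ref, 5),
                       T1 = paste(sample(res, 13, replace = TRUE), collapse = "")),
                     group = c("reference", "thermophilic"), ogt = c(NA, 70),
                     ref_id = "REF")
  ab <- merge_on_reference(meso, thermo, "REF")
  ba <- merge_on_reference(thermo, meso, "REF")
  expect_identical(ab$col_map, ba$col_map)
  for (id in ab$ids) {
    expect_identical(ab$mat[id, ], ba$mat[id, ])
  }
  # degapping any sequence is unchanged by the merge
  for (set in list(meso, thermo)) {
    for (id in setdiff(set$ids, "REF")) {
      expect_identical(paste(ab$mat[id, ][ab$mat[id, ] != "-"], collapse = ""),
                       gsub("-", "", paste(set$mat[id, ], collapse = "")))
    }
  }
  expect_identical(paste(ab$mat["REF", ][ab$mat["REF", ] != "-"], collapse = ""),
                   ref)

  # identity merge: both groups already column-identical on an ungapped reference
  m2 <- make_set(c(REF = ref, M1 = gapify(substr(ref, 1, 11), 4)),
                 group = c("reference", "mesophilic"), ogt = c(NA, 25),
                 ref_id = "REF")
  t2 <- make_set(c(REF = ref, T1 = gapify(substr(ref, 1, 11), 7)),
                 group = c("reference", "thermophilic"), ogt = c(NA, 55),
                 ref_id = "REF")
  mg2 <- merge_on_reference(m2, t2, "REF")
  expect_identical(mg2$s, nchar(ref))
  expect_identical(mg2$mat["M1", ], m2$mat["M1", ])
  expect_identical(mg2$mat["T1", ], t2$mat["T1", ])

  # differing ungapped references make the merge undefined
  t3 <- make_set(c(REF = paste0(substr(ref, 1, 11), "W"), T1 = ref),
                 group = c("reference", "thermophilic"), ogt = c(NA, 55),
                 ref_id = "REF")
  expect_error(merge_on_reference(m2, t3, "REF"), "merge undefined")
})

test_that("domain labels follow reference coordinates and the preceding-residue rule", {
  # reference of 380 residues with one insertion column after residue 370
  # and one before residue 1
  res <- rep("A", 380)
  refchars <- c("-", res[1:370], "-", res[371:380])
  other <- rep("C", length(refchars))
  mat <- rbind(REF = refchars, M1 = other)
  set <- alignment_set(mat, group = c("reference", "mesophilic"),
                       ogt = c(NA, 30), ref_id = "REF")
  dom <- map_to_domains(set, domain_partition(111, 370, 562))
  expect_identical(dom[1L], "N1")          # insertion before residue 1
  expect_identical(dom[1L + 111L], "N1")   # residue 111
  expect_identical(dom[1L + 112L], "N2")   # residue 112
  expect_identical(dom[1L + 370L], "N2")   # residue 370
  expect_identical(dom[1L + 371L], "N2")   # insertion after residue 370
  expect_identical(dom[1L + 372L], "C")    # residue 371
  expect_error(domain_partition(111, 111, 562), "boundaries")
})
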