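test_that("config validation rejects confounded or malformed designs", {
  expect_error(synthetic_config(background = rep(1, 20)), "sum to 1")
  expect_error(synthetic_config(rho = 1.2), "rho")
  expect_error(synthetic_config(s = 100, planted_columns = list(
    list(column = 150, residues = "K", e = 0.9))), "out of range")
  expect_error(synthetic_config(s = 100, planted_columns = list(
    list(column = 50, residues = "K", e = 1.5)),
    gap_hotspots = list()), "in \\[0, 1\\]")
  # planted determinant inside a thermophilic gap hotspot is confounded
  expect_error(synthetic_config(
    s = 100,
    planted_columns = list(list(column = 90, residues = "K", e = 0.9)),
    gap_hotspots = list(list(columns = 88:92, group = "thermophilic",
                             g = 0.8))),
    "confounded")
  # the same span in the other group is allowed
  cfg <- synthetic_config(
    s = 100,
    planted_columns = list(list(column = 90, residues = "K", e = 0.9)),
    gap_hotspots = list(list(columns = 88:92, group = "mesophilic",
                             g = 0.5)))
  expect_s3_class(cfg, "synthetic_config")
})

test_that("simulation is reproducible and fixtures are byte-stable", {
  cfg <- synthetic_config(n_meso = 12, n_thermo = 6, s = 40, seed = 99)
  sim1 <- simulate_alignments(cfg)
  sim2 <- simulate_alignments(cfg)
  expect_identical(sim1$meso$mat, sim2$meso$mat)
  expect_identical(sim1$thermo$ogt, sim2$thermo$ogt)

  d1 <- tempfile("fx1"); d2 <- tempfile("fx2")
  p1 <- write_fixture(sim1, d1)
  p2 <- write_fixture(sim2, d2)
  for (f in names(p1)) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]),
                     label = paste("file", f))
  }
  truth <- jsonlite::read_json(p1[["truth"]])
  expect_identical(
    vapply(truth$planted_columns, function(p) p$column, integer(1)),
    vapply(cfg$planted_columns, function(p) as.integer(p$column), integer(1)))

  # round trip through the reader reproduces the in-memory sets
  meso_rt <- read_alignment(p1[["meso"]], p1[["metadata"]],
                            group = "mesophilic", ref_id = cfg$ref_id)
  thermo_rt <- read_alignment(p1[["thermo"]], p1[["metadata"]],
                              group = "thermophilic", ref_id = cfg$ref_id)
  expect_identical(meso_rt$mat, sim1$meso$mat)
  expect_identical(thermo_rt$mat, sim1$thermo$mat)
  expect_equal(thermo_rt$ogt, sim1$thermo$ogt)
})

test_that("simulated signals land where planted: composition and gaps", {
  cfg <- synthetic_config(
    n_meso = 60, n_thermo = 20, s = 60, seed = 5, rho = 0.8,
    planted_columns = list(list(column = 30, residues = "K", e = 1.0)),
    gap_hotspots = list(list(columns = 50:54, group = "thermophilic",
                             g = 0.8)))
  sim <- simulate_alignments(cfg)
  mg <- merge_on_reference(sim$meso, sim$thermo, cfg$ref_id)
  # e = 1: every thermophilic sequence carries the planted residue
  rc <- residue_content(mg, 30L, "thermophilic")
  expect_equal(rc[["K"]], 100)
  # consensus was drawn outside the enriched set, so meso K stays rare
  rcm <- residue_content(mg, 30L, "mesophilic")
  expect_lt(ifelse("K" %in% names(rcm), rcm[["K"]], 0), 50)
  # hotspot gap rate near g for thermo, zero for meso
  r <- missing_rates(mg)
  expect_true(all(r$mr_meso[50:54] == 0))
  expect_true(all(r$mr_thermo[50:54] > 0.5))
  # the reference is gap-free and identical in both sets
  expect_false(any(sim$meso$mat[cfg$ref_id, ] == "-"))
  expect_identical(sim$meso$mat[cfg$ref_id, ], sim$thermo$mat[cfg$ref_id, ])

  # no planted signal: per-column group compositions agree within
  # binomial sampling error (3.5 sigma per cell)
  cfg0 <- synthetic_config(n_meso = 60, n_thermo = 20, s = 60, seed = 6,
                           planted_columns = list(), gap_hotspots = list())
  sim0 <- simulate_alignments(cfg0)
  mg0 <- merge_on_reference(sim0$meso, sim0$thermo, cfg0$ref_id)
  for (cc in seq(5, 60, by = 5)) {
    pm <- residue_content(mg0, cc, "mesophilic") / 100
    pt <- residue_content(mg0, cc, "thermophilic") / 100
    for (res in union(names(pm), names(pt))) {
      fm <- ifelse(res %in% names(pm), pm[[res]], 0)
      ft <- ifelse(res %in% names(pt), pt[[res]], 0)
      pbar <- (fm * 60 + ft * 20) / 80
      se <- sqrt(pbar * (1 - pbar) * (1 / 60 + 1 / 20))
      expect_lt(abs(fm - ft), 3.5 * se + 1e-9)
    }
  }
})

test_that("recovery power is monotone in the enrichment probability", {
  ranks <- vapply(c(0.3, 0.6, 0.9), function(e) {
    cfg <- synthetic_config(
      n_meso = 60, n_thermo = 20, s = 60, seed = 11,
      planted_columns = list(list(column = 30, residues = "K", e = e)),
      gap_hotspots = list())
    sim <- simulate_alignments(cfg)
    mg <- merge_on_reference(sim$meso, sim$thermo, cfg$ref_id)
    fm <- fragment_matrix(mg, parse_aaindex(aa_fixture_path()))
    sr <- score_fragments(fm)
    covers <- sr$rows <= 30L & (sr$rows + fm$w - 1L) >= 30L
    min(rank(-sr$scores)[covers])   # best rank of a planted-covering fragment
  }, numeric(1))
  expect_true(all(diff(ranks) <= 0))
})
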