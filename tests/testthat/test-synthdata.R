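tb <- residue_tables()

test_that("family generation is byte-identical under a fixed seed", {
  f1 <- synth_family(family_spec(seed = 11))
  f2 <- synth_family(family_spec(seed = 11))
  expect_identical(lapply(f1$records, `[[`, "residues"),
                   lapply(f2$records, `[[`, "residues"))
  expect_identical(f1$truth, f2$truth)
  f3 <- synth_family(family_spec(seed = 12))
  expect_false(identical(lapply(f1$records, `[[`, "residues"),
                         lapply(f3$records, `[[`, "residues")))
})

test_that("planted variant pairs are moment-matched across archetypes", {
  v <- element_variants()
  expect_length(v$organellar, length(v$other))
  for (k in seq_along(v$other)) {
    for (delta in c(100, 1080 / 11))
      expect_lt(abs(hydrophobic_moment(v$other[k], tb, delta) -
                    hydrophobic_moment(v$organellar[k], tb, delta)), 1e-3)
    # composition trade-off: basics and hydrophobicity differ sharply
    expect_gt(basic_fraction(v$organellar[k]) - basic_fraction(v$other[k]),
              0.15)
    expect_gt(mean_hydrophobicity(v$other[k], tb) -
              mean_hydrophobicity(v$organellar[k], tb), 0.15)
    # every variant detects as one full-span element with 5 wheel slots
    for (tp in c(v$other[k], v$organellar[k])) {
      el <- detect_elements(strrep(tp, 2), tb)
      expect_equal(nrow(el), 1L)
      expect_equal(c(el$start, el$end, el$n_hydro_slots), c(1L, 22L, 5L))
    }
  }
})

test_that("planted truth intervals contain the planted element strings", {
  fam <- synth_family(family_spec(seed = 5))
  for (id in names(fam$records)) {
    seqr <- fam$records[[id]]$residues
    tr <- fam$truth[[id]]
    expect_equal(nchar(seqr), tr$length)
    for (k in seq_len(nrow(tr$elements)))
      expect_equal(substr(seqr, tr$elements$start[k], tr$elements$end[k]),
                   tr$elements$residues[k])
  }
})

test_that("detector recovers planted elements with reciprocal overlap", {
  fam <- synth_family(family_spec(seed = 21))
  n_planted <- 0L; n_found <- 0L
  for (id in names(fam$records)) {
    el <- detect_elements(fam$records[[id]], tb)
    tr <- fam$truth[[id]]$elements
    for (k in seq_len(nrow(tr))) {
      n_planted <- n_planted + 1L
      if (!nrow(el)) next
      ov <- pmax(0, pmin(el$end, tr$end[k]) - pmax(el$start, tr$start[k]) + 1L)
      rec <- ov / (tr$end[k] - tr$start[k] + 1L)
      prec <- ov / el$n_res
      if (any(rec >= 0.5 & prec >= 0.5)) n_found <- n_found + 1L
    }
  }
  expect_gte(n_found / n_planted, 0.8)
})

test_that("background-only decoys rarely trigger detections", {
  dec <- synth_decoys(40, c(120, 180), "disordered", seed = 9)
  none <- vapply(dec, function(r) nrow(detect_elements(r, tb)) == 0L, TRUE)
  expect_gte(mean(none), 0.95)
})

test_that("family files round-trip through FASTA/TSV/JSON", {
  fam <- synth_family(family_spec(seed = 3))
  dir <- withr::local_tempdir()
  paths <- write_family(fam, dir)
  recs <- read_fasta(file.path(dir, "family.fasta"))
  expect_equal(length(recs), length(fam$records))
  labs <- read_labels(file.path(dir, "labels.tsv"))
  expect_equal(unname(labs[recs[[1]]$id]), fam$records[[1]]$label)
  truth <- jsonlite::fromJSON(file.path(dir, "truth.json"))
  expect_equal(sort(names(truth)), sort(names(fam$truth)))
})

test_that("synthetic shift datasets encode the planted profile exactly", {
  prof <- c(rep(0, 10), rep(0.6, 5), rep(0, 10))
  ds <- synth_shift_dataset(prof, noise = 0, seed = 1)
  model <- shift_model()
  expect_equal(ds$target$ca, ds$rc_table$ca + prof * model$offsets[["ca"]])
  expect_equal(ds$target$n, ds$rc_table$n + prof * model$offsets[["n"]])
  # zero profile, zero noise: targets equal the reference
  ds0 <- synth_shift_dataset(rep(0, 12), noise = 0)
  expect_equal(ds0$target, ds0$rc_table)
  # reproducibility with noise
  dsa <- synth_shift_dataset(prof, noise = 1, seed = 7)
  dsb <- synth_shift_dataset(prof, noise = 1, seed = 7)
  expect_identical(dsa$target, dsb$target)
})

test_that("trace generators are seeded bijections with recorded truth", {
  for (kind in c("isotherm", "decay", "thermogram", "anisotropy")) {
    a <- synth_traces(kind, seed = 4)
    b <- synth_traces(kind, seed = 4)
    expect_identical(a, b, info = kind)
    expect_false(is.null(a$truth))
  }
  expect_error(synth_traces("spectrum"))
})
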