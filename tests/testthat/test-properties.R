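tb <- residue_tables()

test_that("mean hydrophobicity is a plain scale average", {
  expect_equal(mean_hydrophobicity("GGGG", tb), 0)
  for (aa in c("L", "K", "W", "S"))
    expect_equal(mean_hydrophobicity(strrep(aa, 9), tb),
                 unname(tb$hydrophobicity[aa]))
  expect_equal(mean_hydrophobicity("LI", tb), 1.75)  # (1.70 + 1.80)/2
  expect_error(mean_hydrophobicity("", tb))
})

test_that("hydrophobic moment matches the direct vector-sum oracle", {
  # closure: unit vectors cancel after full turns
  expect_lt(hydrophobic_moment(strrep("L", 18), tb, 100), 1e-10)
  expect_lt(hydrophobic_moment(strrep("K", 11), tb, 1080 / 11), 1e-10)
  # two-residue hand computation: L at 0 deg, K at 100 deg
  expect_equal(hydrophobic_moment("LK", tb, 100), 1.0553, tolerance = 1e-4)
  set.seed(42)
  for (i in 1:25) {
    s <- random_sequence(sample(2:30, 1))
    d <- sample(c(100, 1080 / 11, 97.5), 1)
    expect_equal(hydrophobic_moment(s, tb, d),
                 unname(oracle_moment(s, tb$hydrophobicity, d)))
  }
})

test_that("moment scales linearly with the hydrophobicity table", {
  set.seed(1)
  for (i in 1:10) {
    s <- random_sequence(15)
    tb2 <- residue_tables(hydrophobicity = tb$hydrophobicity * 2.5)
    expect_equal(hydrophobic_moment(s, tb2, 100),
                 2.5 * hydrophobic_moment(s, tb, 100), tolerance = 1e-12)
  }
  # adding a constant leaves closure-length homopolymers at zero
  tb3 <- residue_tables(hydrophobicity = tb$hydrophobicity + 1)
  expect_lt(hydrophobic_moment(strrep("G", 18), tb3, 100), 1e-10)
})

test_that("net charge and discriminant factor follow their formulas", {
  expect_equal(net_charge("KKDE", tb), 0)
  expect_equal(net_charge("RKH", tb), 2)   # histidine neutral by default
  expect_equal(net_charge("DDDD", tb), -4)
  expect_equal(discriminant_factor(0, 0), 0)
  expect_equal(discriminant_factor(1, 0), 0.944)
  expect_equal(discriminant_factor(0.5, -2), -0.188)
})

test_that("windowed charge tracks are bounded and consistent", {
  ct <- windowed_charge("KKKKKKKKKK", 10)
  expect_equal(ct$ncpr, 1); expect_equal(ct$fcr, 1)
  ct <- windowed_charge("AAAAAAAAAA", 10)
  expect_equal(ct$ncpr, 0); expect_equal(ct$fcr, 0)
  ct <- windowed_charge("KKKKKDDDDD", 10)
  expect_equal(ct$ncpr, 0); expect_equal(ct$fcr, 1)
  expect_error(windowed_charge("KKK", 10), "shorter")
  set.seed(5)
  for (i in 1:20) {
    ct <- windowed_charge(random_sequence(40), 10)
    expect_true(all(abs(ct$ncpr) <= ct$fcr + 1e-12))
    expect_true(all(ct$fcr >= 0 & ct$fcr <= 1))
  }
})

test_that("foldindex proxy reproduces hand-computed values", {
  # poly-K: normalized KD hydropathy (-3.9+4.5)/9, |NCPR| = 1
  fi <- foldindex_track(strrep("K", 60), tb, 51)
  expect_equal(fi$foldindex[30], 2.785 * (0.6 / 9) - 1 - 1.151,
               tolerance = 1e-12)
  expect_equal(fi$disorder[30], pmin(1, 0.5 - fi$foldindex[30] / 2))
  # FI = 0 maps to pseudo-disorder 0.5
  expect_equal(pmin(pmax(0.5 - 0 / 2, 0), 1), 0.5)
  # disordered composition scores disordered, globular scores ordered
  dis <- synth_decoys(3, 120, "disordered", seed = 2)
  ord <- synth_decoys(3, 120, "ordered", seed = 3)
  for (r in dis) expect_gt(mean(foldindex_track(r, tb)$disorder), 0.5)
  for (r in ord) expect_lt(mean(foldindex_track(r, tb)$disorder), 0.5)
})

test_that("annotation fills the full property set consistently", {
  rec <- helix311:::new_sequence_record("x", strrep("ATERTKEFLSD", 4),
                                        disorder_track = rep(0.7, 44))
  el <- detect_elements(rec)
  expect_gt(nrow(el), 0)
  ann <- annotate_elements(el, rec, tb, disorder_source = "track")
  expect_equal(ann$D, 0.944 * ann$muH + 0.33 * ann$z)
  expect_equal(ann$mean_disorder, rep(0.7, nrow(ann)))
  # all-G element cascades to zeros
  recg <- helix311:::new_sequence_record("g", strrep("G", 10))
  eg <- data.frame(sequence_id = "g", start = 1L, end = 10L)
  ag <- annotate_elements(eg, recg, tb, disorder_source = "none")
  expect_equal(unlist(ag[, c("H", "muH", "z", "D")]), c(H = 0, muH = 0, z = 0, D = 0))
  expect_error(annotate_elements(data.frame(sequence_id = "g", start = 5L, end = 12L),
                                 recg, tb, disorder_source = "none"), "bounds")
})
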