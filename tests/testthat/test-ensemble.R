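test_that("backbone geometry is ideal and helical dihedrals give a helix", {
  phi <- rep(-60, 12); psi <- rep(-45, 12)
  xyz <- build_backbone(phi, psi)
  ca <- xyz[seq(2, nrow(xyz), by = 3), ]
  d <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(d > 3.7 & d < 3.9))  # trans-peptide CA-CA spacing
  # helical rise: ~1.5 A per residue along the axis over one turn
  rise <- sqrt(sum((ca[12, ] - ca[1, ])^2)) / 11
  expect_true(rise > 1.2 && rise < 1.9)
})

test_that("backbone torsions round-trip through an independent dihedral oracle", {
  skip_if_not_installed("bio3d")
  set.seed(2)
  phi <- runif(8, -180, 180)
  psi <- runif(8, -180, 180)
  xyz <- build_backbone(phi, psi)
  tor <- function(p1, p2, p3, p4) {  # bio3d convention, degrees
    bio3d::torsion.xyz(c(t(rbind(p1, p2, p3, p4))), atm.inc = 4)
  }
  for (i in 2:7) {
    r0 <- 3 * (i - 1)
    got_phi <- tor(xyz[r0, ], xyz[r0 + 1, ], xyz[r0 + 2, ], xyz[r0 + 3, ])
    got_psi <- tor(xyz[r0 + 1, ], xyz[r0 + 2, ], xyz[r0 + 3, ], xyz[r0 + 4, ])
    dphi <- (got_phi - phi[i] + 180) %% 360 - 180
    dpsi <- (got_psi - psi[i] + 180) %% 360 - 180
    expect_lt(abs(dphi), 1e-6)
    expect_lt(abs(dpsi), 1e-6)
  }
})

test_that("radius of gyration obeys closed forms and rigid-motion invariance", {
  two <- rbind(c(0, 0, 0), c(6, 0, 0))
  expect_equal(radius_of_gyration(two), 3)
  expect_equal(radius_of_gyration(rbind(c(1, 2, 3), c(1, 2, 3))), 0)
  set.seed(3)
  m <- matrix(rnorm(60), ncol = 3)
  th <- 0.7
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  m2 <- m %*% Rz + matrix(c(5, -2, 9), nrow(m), 3, byrow = TRUE)
  expect_equal(radius_of_gyration(m2), radius_of_gyration(m), tolerance = 1e-9)
})

test_that("coil sampling is seed-reproducible and clash-free", {
  p1 <- sample_coil_ensemble(40, 5, seed = 9)
  p2 <- sample_coil_ensemble(40, 5, seed = 9)
  expect_identical(p1$phi, p2$phi)
  expect_identical(p1$rg, p2$rg)
  for (k in 1:5) {
    ca <- p1$conformers[[k]][seq(2, 120, by = 3), ]
    d <- sqrt(rowSums(diff(ca)^2))
    expect_true(all(d > 3.7 & d < 3.9))
    expect_false(helix311:::.has_clash(ca, 4.0, 3L))
  }
})

test_that("degenerate all-helical mixture flags every residue helical", {
  b <- coil_basins(weights = c(beta = 0, ppii = 0, alphaR = 1, alphaL = 0))
  pool <- sample_coil_ensemble(25, 30, seed = 4, basins = b,
                               build_coords = FALSE)
  # alphaR basin sits inside the helical bounds; tails may just exit
  expect_gt(mean(pool$flags), 0.95)
})

test_that("pool propensity approximates the helical basin weight", {
  pool <- sample_coil_ensemble(30, 800, seed = 5, build_coords = FALSE)
  w <- coil_basins()$weights[["alphaR"]]
  p <- mean(ensemble_propensity(pool))
  expect_lt(abs(p - w), 0.04)  # basin tails + binomial error
  freq <- basin_frequencies(pool)
  expect_equal(rowSums(freq), rep(1, 30))
})

test_that("secondary-shift deltas follow the printed formula", {
  st <- data.frame(residue = 1:3, aa = c("A", "G", "L"),
                   ca_obs = c(55.3, 45.1, 57.9), ca_rc = c(52.5, 45.1, 55.1),
                   cb_obs = c(18.6, NA, 42.0), cb_rc = c(19.1, NA, 42.4))
  dd <- delta_delta_cacb(st)
  expect_equal(dd$ddcacb[1], (55.3 - 52.5) - (18.6 - 19.1))
  expect_true(dd$ca_only[2])   # glycine: CA term only
  expect_equal(dd$ddcacb[2], 0)
  # obs = rc everywhere -> 0
  st0 <- data.frame(residue = 1:2, aa = c("A", "K"),
                    ca_obs = c(52.5, 56.2), ca_rc = c(52.5, 56.2),
                    cb_obs = c(19.1, 32.9), cb_rc = c(19.1, 32.9))
  expect_equal(delta_delta_cacb(st0)$ddcacb, c(0, 0))
  st_bad <- st; st_bad$ca_rc[1] <- NA
  expect_error(delta_delta_cacb(st_bad), "residue\\(s\\) 1")
})

test_that("shift prediction is linear in propensity", {
  rc <- random_coil_table("AKLE")
  model <- shift_model()
  expect_equal(predict_shifts(rep(0, 4), rc, model)$ca, rc$ca)
  full <- predict_shifts(rep(1, 4), rc, model)
  expect_equal(full$ca, rc$ca + model$offsets[["ca"]])
  half <- predict_shifts(rep(0.5, 4), rc, model)
  expect_equal(half$ca, rc$ca + 0.5 * model$offsets[["ca"]])
})

test_that("GA selection beats random restarts on a recoverable target", {
  set.seed(11)
  L <- 30
  pool <- sample_coil_ensemble(L, 400, seed = 12, build_coords = FALSE)
  rc <- random_coil_table(strrep("A", L))
  truth_idx <- sample.int(400, 20)
  target <- predict_shifts(ensemble_propensity(pool, truth_idx), rc)
  sel <- ga_select(pool, target, rc, M = 20, seed = 13)
  # random-restart oracle: best of 1000 random 20-subsets
  cf <- helix311:::.chi2_coeffs(target, rc, shift_model())
  rand_best <- min(vapply(1:1000, function(k) {
    idx <- sample.int(400, 20)
    helix311:::.chi2_of_propensity(colMeans(pool$flags[idx, , drop = FALSE]), cf)
  }, 1))
  expect_lte(sel$fitness, rand_best)
  expect_true(all(diff(sel$fitness_history) <= 1e-12))
  expect_length(sel$selected_indices, 20)
})

test_that("a flat forward model makes all selections equivalent", {
  pool <- sample_coil_ensemble(20, 100, seed = 21, build_coords = FALSE)
  rc <- random_coil_table(strrep("A", 20))
  m0 <- shift_model(offsets = c(ca = 0, cb = 0, co = 0, n = 0, hn = 0))
  sel <- ga_select(pool, rc, rc, M = 10, model = m0, seed = 22,
                   params = ga_params(max_generations = 30))
  expect_equal(sel$fitness, 0)
  expect_equal(diff(range(sel$fitness_history)), 0)
})

test_that("iterative selection recovers a planted propensity profile", {
  L <- 50
  prof <- rep(0.05, L); prof[20:33] <- 0.6
  scheme <- list(n_pool = 1200L, M = 40L, n_bias = 1000L, n_base = 200L,
                 iterations = 3L)
  ds <- synth_shift_dataset(prof, noise = 0, seed = 31)
  sel <- iterate_selection(strrep("A", L), ds$target, ds$rc_table,
                           scheme = scheme, seed = 32,
                           params = ga_params(max_generations = 200))
  rmse <- sqrt(mean((sel$recovered_profile - prof)^2))
  expect_lt(rmse, 0.1)
  expect_length(sel$profile_changes, 3L)
  # zero iterations reduce to the plain GA result
  scheme0 <- scheme; scheme0$iterations <- 0L
  sel0 <- iterate_selection(strrep("A", L), ds$target, ds$rc_table,
                            scheme = scheme0, seed = 33,
                            params = ga_params(max_generations = 120))
  expect_length(sel0$profile_changes, 0L)
  expect_length(sel0$selected_indices, 40L)
})

test_that("the Rg restraint pulls the selected ensemble toward the target", {
  L <- 40
  rc <- random_coil_table(strrep("A", L))
  prof0 <- rep(0.2, L)
  target <- predict_shifts(prof0, rc)
  base <- select_with_rg(L, target, rc, rg_target = c(18, 2), n_pool = 600L,
                         M = 30L, rg_weight = 0, seed = 41,
                         params = ga_params(max_generations = 120))
  expanded <- select_with_rg(L, target, rc,
                             rg_target = c(base$pool_mean_rg * 1.2, 0.5),
                             n_pool = 600L, M = 30L, rg_weight = 50,
                             seed = 41, params = ga_params(max_generations = 120))
  expect_gt(expanded$ensemble_mean_rg, base$ensemble_mean_rg)
  # strong restraint lands within ~1 sigma of the target
  expect_lt(abs(expanded$ensemble_mean_rg - base$pool_mean_rg * 1.2), 1.0)
  expect_error(select_with_rg(L, target, rc, rg_target = c(18, 0)), "sd > 0")
})
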