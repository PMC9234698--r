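test_that("summation distance follows the r^-6 closed form", {
  expect_equal(summation_distance(3), 3)
  expect_equal(summation_distance(c(3, 3)), 3 / 2^(1 / 6))
  expect_equal(summation_distance(c(3, 100)), 3, tolerance = 1e-4)
  expect_error(summation_distance(numeric(0)), "empty")
  expect_error(summation_distance(c(2, 0)), "> 0")
  # never larger than the shortest member distance
  set.seed(42)
  for (i in 1:20) {
    d <- stats::runif(sample(1:6, 1), 1.5, 9)
    expect_lte(summation_distance(d), min(d))
  }
})

test_that("proton grouping merges methyls, ring pairs and prochiral pairs", {
  fx <- helix_fixture()
  g <- fx$groups
  ala1 <- g[g$residue_index == 5, ]
  expect_setequal(ala1$group_name, c("H", "HA", "QB"))
  expect_setequal(ala1$members[[which(ala1$group_name == "QB")]],
                  c("HB1", "HB2", "HB3"))

  # handcrafted residues exercising the non-trivial chemistry
  mk <- function(ri, rn, atoms) {
    data.frame(residue_index = ri, residue_name = rn, atom_name = atoms,
               element = ifelse(startsWith(atoms, "H"), "H",
                                substr(atoms, 1, 1)),
               x = seq_along(atoms), y = 0, z = 0, chain_id = "A")
  }
  leu <- mk(1, "LEU", c("N", "CA", "CB", "CG", "CD1", "CD2", "H", "HA",
                        "HB2", "HB3", "HG",
                        "HD11", "HD12", "HD13", "HD21", "HD22", "HD23"))
  gly <- mk(2, "GLY", c("N", "CA", "H", "HA2", "HA3"))
  tyr <- mk(3, "TYR", c("N", "CA", "CB", "CD1", "CD2", "CE1", "CE2",
                        "H", "HA", "HB2", "HB3", "HD1", "HD2", "HE1", "HE2"))
  conf <- conformer(rbind(leu, gly, tyr))

  g0 <- group_equivalent_protons(conf)
  # Leu isopropyl methyls merge to one 6-member group without stereo info
  qqd <- g0[g0$residue_index == 1 & g0$group_name == "QQD", ]
  expect_equal(nrow(qqd), 1L)
  expect_length(qqd$members[[1]], 6L)
  # Gly alpha methylene merges
  expect_true("QA" %in% g0$group_name[g0$residue_index == 2])
  # Tyr ring delta/epsilon pairs merge
  expect_setequal(intersect(g0$group_name[g0$residue_index == 3],
                            c("QD", "QE")), c("QD", "QE"))

  # stereo assignments split the corresponding groups
  g1 <- group_equivalent_protons(conf, stereo_assignments = c("2:HA", "1:QD"))
  expect_setequal(g1$group_name[g1$residue_index == 2], c("H", "HA2", "HA3"))
  expect_setequal(intersect(g1$group_name[g1$residue_index == 1],
                            c("QD1", "QD2")), c("QD1", "QD2"))

  # unknown residue types degrade to singletons with a warning
  odd <- mk(4, "XYZ", c("N", "CA", "H", "HB1", "HB2", "HB3"))
  expect_warning(g2 <- group_equivalent_protons(conformer(odd)), "unknown")
  expect_equal(sort(g2$group_name), sort(c("H", "HB1", "HB2", "HB3")))
})

test_that("model network equals the all-pairs brute-force network", {
  # ~200 protons: 25-residue helix
  fx <- helix_fixture(seed = 9, n_residues = 25)
  net <- build_model_network(fx$conformer, fx$groups, 5)
  oracle <- brute_force_network(fx$conformer, fx$groups, 5)
  expect_equal(net$key_a, oracle$key_a)
  expect_equal(net$key_b, oracle$key_b)
  expect_equal(net$distance, oracle$distance, tolerance = 1e-12)
  expect_true(all(net$distance <= 5))
  expect_true(all(net$key_a != net$key_b))
})

test_that("three singleton protons at 2.5 and 6 Angstrom give one edge", {
  conf <- conformer(data.frame(
    residue_index = 1:3, residue_name = "GLY", atom_name = "H",
    element = "H", x = c(0, 2.5, 8.5), y = 0, z = 0, chain_id = "A"))
  g <- suppressWarnings(group_equivalent_protons(conf))
  g$residue_name <- "GLY"
  net <- build_model_network(conf, g)   # default cutoff 5
  expect_equal(nrow(net), 1L)
  expect_equal(net$distance, 2.5)
  expect_error(
    build_model_network(conf, within(g, members[[1]] <- "HZ9")),
    "missing atom")
})

test_that("ambiguous NOE network matching honors tolerances and diagonals", {
  g <- data.frame(residue_index = 1:3, residue_name = "ALA",
                  group_name = "H", heavy_name = "N")
  g$members <- I(list("H", "H", "H"))
  g$key <- paste0(1:3, ":H")
  g$shift <- c(8.0, 7.0, 7.04)        # B and B' degenerate at 0.05 ppm tol
  g$heavy_shift <- c(120, 115, 110)
  asg <- assignment_table(g, tolerance_h = 0.05, tolerance_heavy = 0.5)

  peaks <- data.frame(w1 = c(8.0, 8.0, 3.0, 8.0),
                      w2 = c(7.0, 7.04, 3.0, 8.01))
  anoe <- build_anoe_network(peaks, asg)
  # peak 1 and 2: both match the degenerate pair {B, B'}
  expect_length(anoe$candidates, 2L)
  expect_setequal(anoe$candidates[[1]], c("1:H|2:H", "1:H|3:H"))
  # peak 3 is 4 ppm from anything assigned
  expect_equal(anoe$unassignable, 3L)
  # peak 4 is a diagonal peak
  expect_equal(anoe$n_diagonal, 1L)

  # heavy-dimension filtering prunes candidates
  peaks3d <- data.frame(w1 = 7.02, w2 = 8.0, heavy1 = 115)
  anoe3d <- build_anoe_network(peaks3d, asg)
  expect_equal(anoe3d$candidates[[1]], "1:H|2:H")
  expect_error(build_anoe_network(peaks, assignment_table(
    within(g, shift <- NA_real_))), "shifts")
})

test_that("recall/precision/F follow the TP/FP/FN conventions", {
  # G = {AB}; peaks at (A,B) and (A,C); uniform weighting
  g <- data.frame(residue_index = 1:3, residue_name = "ALA",
                  group_name = "H", heavy_name = "N")
  g$members <- I(list("H", "H", "H"))
  g$key <- paste0(1:3, ":H")
  g$shift <- c(8, 7, 6)
  g$heavy_shift <- NA_real_
  asg <- assignment_table(g)
  net <- data.frame(key_a = "1:H", key_b = "2:H", distance = 3)
  peaks <- data.frame(w1 = c(8, 8), w2 = c(7, 6))
  anoe <- build_anoe_network(peaks, asg)
  s <- score_rpf(net, anoe, weighting = "uniform")
  expect_equal(s$recall, 0.5)
  expect_equal(s$precision, 1)
  expect_equal(s$f_measure, 2 / 3)
  expect_equal(s$tp, 1)
  expect_equal(s$fn, 1)

  # an ambiguous peak is TP if any candidate is a model edge
  g2 <- g; g2$shift <- c(8, 7, 7.04)
  anoe2 <- build_anoe_network(data.frame(w1 = 8, w2 = 7.02),
                              assignment_table(g2))
  s2 <- score_rpf(net, anoe2, weighting = "uniform")
  expect_equal(s2$recall, 1)

  # empty peak list is an error; empty network warns precision = 1
  expect_error(score_rpf(net, build_anoe_network(
    data.frame(w1 = 1, w2 = 2), asg)), "recall undefined")
  empty_net <- net[0, ]
  expect_warning(s3 <- score_rpf(empty_net, anoe, weighting = "uniform"),
                 "precision")
  expect_equal(s3$precision, 1)
})

test_that("noise peaks never raise recall; deleted peaks never raise precision", {
  fx <- helix_fixture(seed = 13)
  base <- simulate_noesy(fx$conformer, fx$groups, fx$config)
  net <- build_model_network(fx$conformer, base$assignments$groups, 5)
  s0 <- score_rpf(net, build_anoe_network(base$peaks, base$assignments))
  set.seed(99)
  for (i in 1:5) {
    extra <- data.frame(w1 = stats::runif(30, 0, 9),
                        w2 = stats::runif(30, 0, 9), intensity = 1)
    s_noise <- score_rpf(net, build_anoe_network(
      rbind(base$peaks, extra), base$assignments))
    expect_lte(s_noise$recall, s0$recall + 1e-12)
    keep <- sample(nrow(base$peaks), round(0.7 * nrow(base$peaks)))
    s_del <- score_rpf(net, build_anoe_network(
      base$peaks[keep, ], base$assignments))
    expect_lte(s_del$precision, s0$precision + 1e-12)
  }
})

test_that("F-measure bounds and DP normalization behave as anchors", {
  # completeness 1 when every short covalent pair is represented
  fx <- helix_fixture(seed = 2)
  sim <- simulate_noesy(fx$conformer, fx$groups, fx$config)
  fm <- estimate_f_max(sim$peaks, sim$assignments)
  expect_equal(fm$completeness, 1)
  expect_equal(fm$f_max, 1)
  # half the expected pairs present -> f_max = 2/3
  anoe <- build_anoe_network(sim$peaks, sim$assignments)
  g <- sim$assignments$groups
  # drop all peaks touching the amide shift of even residues: removes a
  # known fraction of expected pairs
  expect_error(estimate_f_max(sim$peaks[0, ], sim$assignments), "empty")

  expect_equal(dp_score(0.9, 0.5, 0.9), 1)
  expect_equal(dp_score(0.5, 0.5, 0.9), 0)
  expect_lt(dp_score(0.3, 0.5, 0.9), 0)       # worse than random coil
  expect_equal(dp_score(1, 0.5, 0.75), 1)     # capped above
  expect_error(dp_score(0.5, 0.8, 0.7), "f_free")
  # monotone in F for fixed normalization
  fs <- seq(0, 1, 0.1)
  dps <- vapply(fs, dp_score, numeric(1), f_free = 0.4, f_max = 0.9)
  expect_true(all(diff(dps) >= 0))
})

test_that("f_max formula reproduces the half-completeness value", {
  # two expected pairs, peak list covering exactly one
  atoms <- data.frame(
    residue_index = 1, residue_name = "ALA",
    atom_name = c("N", "CA", "CB", "H", "HA", "HB1", "HB2", "HB3"),
    element = c("N", "C", "C", "H", "H", "H", "H", "H"),
    x = c(0, 1.4, 2.0, -0.5, 1.6, 2.5, 2.8, 2.2),
    y = c(0, 0.4, 1.8, -0.8, -0.6, 1.9, 2.4, 2.9), z = 0, chain_id = "A")
  conf <- conformer(atoms)
  g <- group_equivalent_protons(conf)
  g$shift <- c(4.1, 8.2, 1.2)[match(g$group_name, c("HA", "H", "QB"))]
  asg <- assignment_table(g)
  # expected 2-4 bond pairs: H-HA, HA-QB, H-QB (ranks 0,1,2)
  peaks <- data.frame(w1 = 8.2, w2 = 4.1)   # only H-HA present
  fm <- estimate_f_max(peaks, asg)
  expect_equal(fm$n_expected, 3L)
  expect_equal(fm$completeness, 1 / 3)
  peaks2 <- rbind(peaks, data.frame(w1 = 4.1, w2 = 1.2),
                  data.frame(w1 = 8.2, w2 = 1.2))
  fm2 <- estimate_f_max(peaks2, asg)
  expect_equal(fm2$f_max, 1)
  # the stated harmonic-mean form at c = 1/2
  expect_equal(2 * 0.5 / (1 + 0.5), 2 / 3)
  fm_half <- estimate_f_max(rbind(peaks, data.frame(w1 = 4.1, w2 = 1.2))[1:1, ],
                            asg)
  expect_equal(fm_half$f_max, 2 * fm_half$completeness / (1 + fm_half$completeness))
})

test_that("random-coil baseline is seeded, reproducible and below a folded model's F", {
  fx <- helix_fixture(seed = 21)
  sim <- simulate_noesy(fx$conformer, fx$groups, fx$config)
  anoe <- build_anoe_network(sim$peaks, sim$assignments)
  f1 <- estimate_f_free(sim$assignments, anoe, 20, n_samples = 20, seed = 7)
  f2 <- estimate_f_free(sim$assignments, anoe, 20, n_samples = 20, seed = 7)
  expect_identical(f1$f_values, f2$f_values)
  net <- build_model_network(fx$conformer, sim$assignments$groups, 5)
  f_model <- score_rpf(net, anoe)$f_measure
  expect_lt(f1$f_free, f_model)
})

test_that("ensemble DP collapses to the single-conformer DP for identical members", {
  cfg <- sim_config(seed = 8, ensemble_size = 3, coordinate_noise = 0,
                    noesy = list(shift_jitter = 0, noise_peak_fraction = 0,
                                 missing_peak_fraction = 0))
  ens <- make_toy_structure(cfg)
  g <- group_equivalent_protons(ens$conformers[[1]])
  sim <- simulate_noesy(ens$conformers[[1]], g, cfg)
  res <- ensemble_dp(ens, sim$peaks, sim$assignments, n_free_samples = 20,
                     seed = 3)
  expect_equal(res$dp_ensemble, res$dp_avg, tolerance = 1e-12)
  expect_equal(length(res$dp_per_conformer), 3L)
  expect_equal(res$dp_per_conformer[1], res$dp_per_conformer[2])
  single <- ensemble_dp(ens$conformers[[1]], sim$peaks, sim$assignments,
                        n_free_samples = 20, seed = 3)
  expect_equal(single$dp_ensemble, res$dp_avg, tolerance = 1e-12)
})

test_that("noise and missing-peak fractions degrade recall and precision as constructed", {
  fx <- helix_fixture(seed = 31)
  cfg_noise <- sim_config(seed = 31, noesy = list(
    shift_jitter = 0, noise_peak_fraction = 0.2, missing_peak_fraction = 0))
  sim_n <- simulate_noesy(fx$conformer, fx$groups, cfg_noise)
  net <- build_model_network(fx$conformer, sim_n$assignments$groups, 5)
  s_n <- score_rpf(net, build_anoe_network(sim_n$peaks, sim_n$assignments))
  expect_lt(s_n$recall, 1)
  expect_equal(s_n$precision, 1)

  cfg_miss <- sim_config(seed = 31, noesy = list(
    shift_jitter = 0, noise_peak_fraction = 0, missing_peak_fraction = 0.2))
  sim_m <- simulate_noesy(fx$conformer, fx$groups, cfg_miss)
  net_m <- build_model_network(fx$conformer, sim_m$assignments$groups, 5)
  s_m <- score_rpf(net_m, build_anoe_network(sim_m$peaks, sim_m$assignments))
  expect_lt(s_m$precision, 1)
  expect_equal(s_m$recall, 1)
})

test_that("d_noe_max calibration picks the smallest F-maximizing cutoff", {
  fx <- helix_fixture(seed = 17)
  sim <- simulate_noesy(fx$conformer, fx$groups, fx$config)  # generated at 5 A
  pick <- calibrate_d_noe_max(fx$conformer, sim$peaks, sim$assignments)
  expect_true(pick %in% c(4.5, 5, 5.5, 6))
  expect_equal(pick, 5)
})
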