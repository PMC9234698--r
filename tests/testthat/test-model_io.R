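test_that("residue-range expressions parse to index unions", {
  expect_equal(parse_residue_ranges("4-91"), 4:91)
  expect_length(parse_residue_ranges("13-38,47-134,138-143"), 120L)
  expect_equal(parse_residue_ranges("7"), 7L)
  expect_equal(parse_residue_ranges("3-5, 4-6"), 3:6)
  expect_error(parse_residue_ranges("91-4"), "reversed")
  expect_error(parse_residue_ranges("4-x"), "parse")
  expect_error(parse_residue_ranges(""), "non-empty")
})

test_that("PDB ensembles round-trip through write/read within field precision", {
  ens <- make_toy_structure(sim_config(seed = 4, ensemble_size = 3,
                                       coordinate_noise = 0.7))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_ensemble(ens, path)
  back <- read_pdb_ensemble(path)
  expect_length(back, 3L)
  for (k in 1:3) {
    a0 <- ens$conformers[[k]]$atoms
    a1 <- back$conformers[[k]]$atoms
    expect_equal(a1$atom_name, a0$atom_name)
    expect_equal(a1$residue_index, a0$residue_index)
    expect_lt(max(abs(as.matrix(a1[, c("x", "y", "z")]) -
                      as.matrix(a0[, c("x", "y", "z")]))), 1e-3)
  }
})

test_that("files without MODEL records yield a single-conformer ensemble", {
  conf <- make_toy_structure(sim_config(seed = 1, ensemble_size = 1,
                                        coordinate_noise = 0))$conformers[[1]]
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_ensemble(conf, path)
  expect_false(any(grepl("^MODEL", readLines(path))))
  expect_length(read_pdb_ensemble(path), 1L)
})

test_that("topology mismatches between models are rejected with the atom named", {
  conf <- make_toy_structure(sim_config(seed = 2, ensemble_size = 1,
                                        coordinate_noise = 0))$conformers[[1]]
  conf2 <- conformer(conf$atoms[-5, ])
  expect_error(structure_ensemble(list(conf, conf2)), "topology mismatch")
})

test_that("amide protons are placed with ideal bisector geometry", {
  conf <- make_toy_structure(sim_config(seed = 3, ensemble_size = 1,
                                        coordinate_noise = 0))$conformers[[1]]
  bare <- conformer(conf$atoms[conf$atoms$atom_name != "H", ])
  prot <- place_amide_protons(bare)
  a <- prot$atoms
  expect_false("H" %in% a$atom_name[a$residue_index == 1])  # chain-initial
  for (ri in c(2, 10, 20)) {
    get <- function(nm, rr = ri) {
      as.numeric(a[a$residue_index == rr & a$atom_name == nm,
                   c("x", "y", "z")])
    }
    pH <- get("H"); pN <- get("N"); pCA <- get("CA"); pC <- get("C", ri - 1)
    expect_equal(sqrt(sum((pH - pN)^2)), 1.02, tolerance = 1e-9)
    ang <- function(p) {
      u <- (p - pN) / sqrt(sum((p - pN)^2))
      v <- (pH - pN) / sqrt(sum((pH - pN)^2))
      acos(sum(u * v))
    }
    expect_equal(ang(pCA), ang(pC), tolerance = 1e-6)
    # planarity: H lies in the C(i-1)-N-CA plane
    n <- c((pCA - pN)[2] * (pC - pN)[3] - (pCA - pN)[3] * (pC - pN)[2],
           (pCA - pN)[3] * (pC - pN)[1] - (pCA - pN)[1] * (pC - pN)[3],
           (pCA - pN)[1] * (pC - pN)[2] - (pCA - pN)[2] * (pC - pN)[1])
    expect_lt(abs(sum((pH - pN) * n / sqrt(sum(n^2)))), 1e-6)
  }
})

test_that("amide proton placement is idempotent without overwrite", {
  conf <- make_toy_structure(sim_config(seed = 5, ensemble_size = 1,
                                        coordinate_noise = 0))$conformers[[1]]
  again <- place_amide_protons(conf, overwrite = FALSE)
  expect_equal(again$atoms[order(again$atoms$residue_index,
                                 again$atoms$atom_name), ],
               conf$atoms[order(conf$atoms$residue_index,
                                conf$atoms$atom_name), ],
               ignore_attr = TRUE)
})

test_that("medoid conformer minimizes mean RMSD and is rigid-motion invariant", {
  sel <- 1:20
  ens <- make_toy_structure(sim_config(seed = 6, ensemble_size = 5,
                                       coordinate_noise = 1))
  # brute-force oracle over all pairs
  n <- length(ens)
  rms <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    X <- ca_coords(ens$conformers[[i]], sel)
    Y <- ca_coords(ens$conformers[[j]], sel)
    rms[i, j] <- rms[j, i] <- quaternion_rmsd(X, Y)
  }
  expect_equal(medoid_conformer(ens, sel), which.min(rowMeans(rms)))
  # identical conformers: tie-break to lowest index
  ens0 <- make_toy_structure(sim_config(seed = 6, ensemble_size = 4,
                                        coordinate_noise = 0))
  expect_equal(medoid_conformer(ens0, sel), 1L)
  expect_equal(medoid_conformer(structure_ensemble(ens$conformers[1]), sel), 1L)
  # rotating/translating every conformer leaves the medoid unchanged
  ens_rt <- structure_ensemble(lapply(ens$conformers, rigid_transform))
  expect_equal(medoid_conformer(ens_rt, sel), medoid_conformer(ens, sel))
})

test_that("a conformer midway between two others is the medoid", {
  base <- make_toy_structure(sim_config(seed = 7, ensemble_size = 1,
                                        coordinate_noise = 0))$conformers[[1]]
  shift <- function(conf, dz) {
    a <- conf$atoms
    # non-rigid stretch along z so the three differ by genuine deformation
    a$z <- a$z + dz * (a$z - mean(a$z))
    conformer(a)
  }
  ens <- structure_ensemble(list(shift(base, -0.1), shift(base, 0),
                                 shift(base, 0.1)))
  expect_equal(medoid_conformer(ens, 1:20), 2L)
})

test_that("bundled well-defined ranges parse and match stated sizes", {
  tb <- well_defined_ranges()
  expect_true("RpR324" %in% tb$target)
  rng <- tb$well_defined_range[tb$target == "SgR209C"]
  expect_length(parse_residue_ranges(rng), 120L)
  expect_length(parse_residue_ranges(tb$well_defined_range[tb$target == "RpR324"]),
                88L)
})
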