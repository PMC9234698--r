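#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generators with defaults
#' emulating a small, rigid, well-behaved NMR target: a 20-residue
#' poly-alanine helix modeled as a 20-conformer ensemble with modest
#' coordinate spread, a NOESY peak list with realistic shift jitter and
#' noise/missing-peak rates, and a 15N-1H RDC set from a moderately rhombic
#' tensor with ~1 Hz measurement noise.
#'
#' @param seed integer seed fixing every stochastic draw.
#' @param n_residues chain length (>= 5).
#' @param geometry `"helix"` (phi = -57, psi = -47), `"extended"`, or
#'   `"random"` (torsions drawn uniformly).
#' @param ensemble_size number of conformers.
#' @param coordinate_noise per-conformer Gaussian coordinate perturbation,
#'   Angstrom.
#' @param noesy list: `shift_jitter` (ppm), `noise_peak_fraction`,
#'   `missing_peak_fraction`, `d_noe_max` (Angstrom).
#' @param rdc list: `da` (Hz), `rhombicity` (in [0, 2/3]), `orientation`
#'   (z-y-z Euler angles, radians), `noise_sigma` (Hz).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_residues = 20, geometry = "helix",
                       ensemble_size = 20, coordinate_noise = 0.5,
                       noesy = list(), rdc = list()) {
  noesy_def <- list(shift_jitter = 0.01, noise_peak_fraction = 0.1,
                    missing_peak_fraction = 0.1, d_noe_max = 5)
  rdc_def <- list(da = 10, rhombicity = 0.3, orientation = c(0, 0, 0),
                  noise_sigma = 1)
  noesy <- utils::modifyList(noesy_def, noesy)
  rdc <- utils::modifyList(rdc_def, rdc)
  stopifnot(n_residues >= 5,
            noesy$noise_peak_fraction >= 0, noesy$noise_peak_fraction <= 1,
            noesy$missing_peak_fraction >= 0, noesy$missing_peak_fraction <= 1,
            rdc$rhombicity >= 0, rdc$rhombicity <= 2 / 3)
  structure(list(seed = as.integer(seed), n_residues = n_residues,
                 geometry = geometry, ensemble_size = ensemble_size,
                 coordinate_noise = coordinate_noise,
                 noesy = noesy, rdc = rdc),
            class = "sim_config")
}

# ideal backbone internal coordinates (Engh-Huber-like)
BB <- list(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
           a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
           a_ca_c_o = 120.8)

# build one poly-alanine conformer from per-residue (phi, psi) torsions
build_backbone <- function(phi, psi) {
  n <- length(phi)
  N <- CA <- C <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(BB$b_n_ca, 0, 0)
  ang <- BB$a_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + BB$b_ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n)[-1L]) {
    N[i, ]  <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                          BB$b_c_n, BB$a_ca_c_n, psi[i - 1])
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                          BB$b_n_ca, BB$a_c_n_ca, 180)   # trans peptide
    C[i, ]  <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                          BB$b_ca_c, BB$a_n_ca_c, phi[i])
  }
  rows <- list()
  push <- function(ri, name, el, p) {
    rows[[length(rows) + 1L]] <<- data.frame(
      residue_index = ri, residue_name = "ALA", atom_name = name,
      element = el, x = p[1], y = p[2], z = p[3], chain_id = "A",
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    push(i, "N", "N", N[i, ])
    push(i, "CA", "C", CA[i, ])
    push(i, "C", "C", C[i, ])
    if (i < n) {
      O <- place_atom(N[i + 1, ], CA[i, ], C[i, ], BB$b_c_o, BB$a_ca_c_o, 180)
      push(i, "O", "O", O)
    }
    # L-configuration beta carbon and its methyl protons; HA opposite CB
    CB <- place_atom(N[i, ], C[i, ], CA[i, ], 1.521, 110.4, 122.6)
    HA <- place_atom(N[i, ], C[i, ], CA[i, ], 1.090, 108.0, -118.0)
    push(i, "CB", "C", CB)
    push(i, "HA", "H", HA)
    for (k in 1:3) {
      HB <- place_atom(N[i, ], CA[i, ], CB, 1.090, 109.5, 60 + 120 * (k - 1))
      push(i, paste0("HB", k), "H", HB)
    }
  }
  place_amide_protons(conformer(do.call(rbind, rows)))
}

#' Generate a toy structure ensemble
#'
#' Builds a poly-alanine chain with ideal covalent geometry in the
#' requested secondary structure (amide H, HA and beta-methyl protons
#' included), then replicates it into an ensemble with independent Gaussian
#' coordinate noise per conformer. Deterministic under the config seed.
#'
#' @param config a [sim_config].
#' @return a [structure_ensemble].
#' @export
make_toy_structure <- function(config = sim_config()) {
  n <- config$n_residues
  set.seed(config$seed)
  tors <- switch(config$geometry,
                 helix = list(phi = rep(-57, n), psi = rep(-47, n)),
                 extended = list(phi = rep(-139, n), psi = rep(135, n)),
                 random = list(phi = stats::runif(n, -180, 180),
                               psi = stats::runif(n, -180, 180)),
                 stop("geometry must be 'helix', 'extended' or 'random'"))
  base <- build_backbone(tors$phi, tors$psi)
  confs <- lapply(seq_len(config$ensemble_size), function(k) {
    a <- base$atoms
    if (config$coordinate_noise > 0) {
      m <- as.matrix(a[, c("x", "y", "z")]) +
        matrix(stats::rnorm(3 * nrow(a), sd = config$coordinate_noise),
               ncol = 3)
      a$x <- m[, 1]; a$y <- m[, 2]; a$z <- m[, 3]
    }
    conformer(a)
  })
  structure_ensemble(confs, label = sprintf("toy-%s-%d", config$geometry, n))
}

#' Simulate a NOESY peak list and matching assignment table
#'
#' Assigns every proton group a synthetic chemical shift (unique, spaced
#' more than twice the match tolerance apart, in randomized order so shift
#' is uncorrelated with sequence), generates one cross peak per group pair
#' with summation distance within `d_noe_max` in the generating structure,
#' then degrades the list: a fraction of true peaks is deleted, spurious
#' peaks are added at positions drawn uniformly over the occupied shift
#' range (so some land near real resonances, injecting ambiguity), and
#' Gaussian jitter is applied to every retained peak position. Seeded and
#' reproducible.
#'
#' @param x a [conformer], or a [structure_ensemble] to generate peaks from
#'   pooled (ensemble-averaged) distances.
#' @param groups a `proton_groups` table for `x`.
#' @param config a [sim_config]; the `noesy` entries are used.
#' @param tolerance_h,tolerance_heavy tolerances recorded in the returned
#'   assignment table.
#' @return list with `peaks` (data frame `w1`, `w2`, `intensity`) and
#'   `assignments` (an [assignment_table]).
#' @export
simulate_noesy <- function(x, groups, config = sim_config(),
                           tolerance_h = 0.05, tolerance_heavy = 0.5) {
  cfg <- config$noesy
  set.seed(config$seed + 1L)
  ng <- nrow(groups)
  spacing <- max(2.5 * tolerance_h, 9 / max(ng, 1))
  shifts <- 0.5 + spacing * (seq_len(ng) - 1L)
  groups$shift <- sample(shifts, ng)
  groups$heavy_shift <- 10 + 2.5 * tolerance_heavy * sample(seq_len(ng), ng)
  net <- build_model_network(x, groups, cfg$d_noe_max)
  if (nrow(net) == 0L) stop("no proton pairs within the NOE cutoff")
  i <- match(net$key_a, groups$key)
  j <- match(net$key_b, groups$key)
  peaks <- data.frame(w1 = groups$shift[i], w2 = groups$shift[j],
                      intensity = net$distance^-6)
  if (cfg$missing_peak_fraction > 0) {
    drop <- stats::runif(nrow(peaks)) < cfg$missing_peak_fraction
    peaks <- peaks[!drop, , drop = FALSE]
    if (nrow(peaks) == 0L) stop("all peaks deleted; lower missing_peak_fraction")
  }
  if (cfg$noise_peak_fraction > 0) {
    n_noise <- round(cfg$noise_peak_fraction * nrow(peaks))
    if (n_noise > 0) {
      rng <- range(groups$shift)
      peaks <- rbind(peaks,
                     data.frame(w1 = stats::runif(n_noise, rng[1], rng[2]),
                                w2 = stats::runif(n_noise, rng[1], rng[2]),
                                intensity = stats::runif(n_noise)))
    }
  }
  if (cfg$shift_jitter > 0) {
    peaks$w1 <- peaks$w1 + stats::rnorm(nrow(peaks), sd = cfg$shift_jitter)
    peaks$w2 <- peaks$w2 + stats::rnorm(nrow(peaks), sd = cfg$shift_jitter)
  }
  rownames(peaks) <- NULL
  list(peaks = peaks,
       assignments = assignment_table(groups, tolerance_h, tolerance_heavy))
}

#' Simulate a 15N-1H RDC set from a known alignment tensor
#'
#' Back-calculates one-bond N-H couplings from the configured tensor
#' (axial component, rhombicity, principal-axis orientation) contracted
#' with each amide N-H unit vector of the conformer, then adds Gaussian
#' measurement noise. Amide protons are placed if absent.
#'
#' @param conf a [conformer].
#' @param config a [sim_config]; the `rdc` entries are used.
#' @return an [rdc_set] (medium label `"synthetic"`).
#' @export
simulate_rdc <- function(conf, config = sim_config()) {
  cfg <- config$rdc
  if (cfg$da == 0) stop("da must be nonzero")
  S <- saupe_from_parameters(cfg$da, cfg$rhombicity, cfg$orientation)
  if (!any(conf$atoms$atom_name == "H")) conf <- place_amide_protons(conf)
  a <- conf$atoms
  res <- intersect(unique(a$residue_index[a$atom_name == "N"]),
                   unique(a$residue_index[a$atom_name == "H"]))
  if (length(res) == 0L) stop("no residues with both amide N and H")
  N <- atom_coords(conf, res, "N")
  H <- atom_coords(conf, res, "H")
  V <- H - N
  V <- V / sqrt(rowSums(V^2))
  d <- rowSums((V %*% S) * V)
  set.seed(config$seed + 2L)
  if (cfg$noise_sigma > 0) {
    d <- d + stats::rnorm(length(d), sd = cfg$noise_sigma)
  }
  rdc_set(data.frame(residue_index = res, atom_a = "N", atom_b = "H",
                     d_exp = d, uncertainty = cfg$noise_sigma),
          medium_label = "synthetic")
}

#' Sample freely-rotating-chain null conformers
#'
#' Coarse random-coil model used for the F-measure lower bound: C-alpha
#' virtual-bond chains with fixed 3.8 Angstrom bonds and a fixed virtual
#' bond angle, torsions drawn uniformly. Each residue carries a generic
#' proton set placed at fixed offsets in the local chain frame: an amide-H
#' proxy, an HA proxy, and a 3-proton beta-methyl. The mean-square
#' end-to-end distance of such chains grows linearly with chain length.
#'
#' @param n_residues chain length (>= 3).
#' @param n_samples number of independent chains.
#' @param seed RNG seed.
#' @param virtual_angle fixed C-alpha virtual bond angle, degrees.
#' @return list of [conformer] objects.
#' @export
sample_freely_rotating_chain <- function(n_residues, n_samples, seed = 1,
                                         virtual_angle = 120) {
  if (n_residues < 3L) stop("n_residues must be >= 3")
  set.seed(seed)
  atom_names <- c("CA", "H", "HA", "HB1", "HB2", "HB3")
  template <- data.frame(
    residue_index = rep(seq_len(n_residues), each = length(atom_names)),
    residue_name = "ALA",
    atom_name = rep(atom_names, n_residues),
    element = rep(c("C", "H", "H", "H", "H", "H"), n_residues),
    x = 0, y = 0, z = 0, chain_id = "A", stringsAsFactors = FALSE)
  lapply(seq_len(n_samples), function(s) {
    ca <- matrix(NA_real_, n_residues, 3)
    ca[1, ] <- c(0, 0, 0)
    ca[2, ] <- c(3.8, 0, 0)
    ang0 <- virtual_angle * pi / 180
    ca[3, ] <- ca[2, ] + 3.8 * c(-cos(ang0), sin(ang0), 0)
    for (i in seq_len(n_residues)[-(1:3)]) {
      ca[i, ] <- place_atom(ca[i - 3, ], ca[i - 2, ], ca[i - 1, ],
                            3.8, virtual_angle, stats::runif(1, -180, 180))
    }
    xyz <- matrix(NA_real_, n_residues * length(atom_names), 3)
    for (i in seq_len(n_residues)) {
      prev <- ca[max(i - 1L, 1L), ]
      nxt <- ca[min(i + 1L, n_residues), ]
      e1 <- unitv(if (i < n_residues) nxt - ca[i, ] else ca[i, ] - prev)
      ref <- if (i > 1L) prev - ca[i, ] else c(0, 0, 1)
      e2 <- ref - sum(ref * e1) * e1
      e2 <- if (vnorm(e2) < 1e-6) unitv(cross3(e1, c(1, 0, 0))) else unitv(e2)
      e3 <- cross3(e1, e2)
      cb <- ca[i, ] - 1.8 * e2 + 0.9 * e3
      base <- (i - 1L) * length(atom_names)
      xyz[base + 1L, ] <- ca[i, ]
      xyz[base + 2L, ] <- ca[i, ] + 2.1 * e2
      xyz[base + 3L, ] <- ca[i, ] + 1.1 * e3
      for (k in 1:3) {
        xyz[base + 3L + k, ] <- cb +
          0.9 * (cos(2 * pi * k / 3) * e1 + sin(2 * pi * k / 3) * e3)
      }
    }
    a <- template
    a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
    conformer(a)
  })
}
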