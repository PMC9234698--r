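# Shared fixtures and independent oracles, all generated in code.

# noiseless single-conformer helix plus its proton groups
helix_fixture <- function(seed = 1, n_residues = 20) {
  cfg <- sim_config(seed = seed, n_residues = n_residues,
                    coordinate_noise = 0, ensemble_size = 1,
                    noesy = list(shift_jitter = 0, noise_peak_fraction = 0,
                                 missing_peak_fraction = 0))
  ens <- make_toy_structure(cfg)
  list(config = cfg, ensemble = ens, conformer = ens$conformers[[1L]],
       groups = group_equivalent_protons(ens$conformers[[1L]]))
}

# conformer with one N-H vector per residue, vectors supplied by the caller
nh_conformer <- function(V) {
  n <- nrow(V)
  origins <- matrix(stats::runif(3 * n, -20, 20), ncol = 3)
  rows <- rbind(
    data.frame(residue_index = seq_len(n), residue_name = "ALA",
               atom_name = "N", element = "N",
               x = origins[, 1], y = origins[, 2], z = origins[, 3],
               chain_id = "A"),
    data.frame(residue_index = seq_len(n), residue_name = "ALA",
               atom_name = "H", element = "H",
               x = origins[, 1] + V[, 1], y = origins[, 2] + V[, 2],
               z = origins[, 3] + V[, 3], chain_id = "A"))
  conformer(rows[order(rows$residue_index), ])
}

random_unit_vectors <- function(n, seed) {
  set.seed(seed)
  V <- matrix(stats::rnorm(3 * n), ncol = 3)
  V / sqrt(rowSums(V^2))
}

# brute-force model network: direct double loop over group pairs using
# summation_distance on raw member-atom distances
brute_force_network <- function(conf, groups, d_noe_max = 5) {
  coords <- function(i) {
    a <- conf$atoms
    mem <- groups$members[[i]]
    as.matrix(a[match(paste(groups$residue_index[i], mem),
                      paste(a$residue_index, a$atom_name)),
                c("x", "y", "z")])
  }
  out <- list()
  for (i in seq_len(nrow(groups) - 1L)) {
    ci <- coords(i)
    for (j in seq.int(i + 1L, nrow(groups))) {
      cj <- coords(j)
      d <- c(outer(seq_len(nrow(ci)), seq_len(nrow(cj)), Vectorize(
        function(a, b) sqrt(sum((ci[a, ] - cj[b, ])^2)))))
      ds <- summation_distance(d)
      if (ds <= d_noe_max) {
        k <- sort(c(groups$key[i], groups$key[j]))
        out[[length(out) + 1L]] <- data.frame(key_a = k[1], key_b = k[2],
                                              distance = ds)
      }
    }
  }
  net <- do.call(rbind, out)
  net[order(net$key_a, net$key_b), ]
}

# independent superposition oracle: Horn's quaternion method
quaternion_rmsd <- function(X, Y) {
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  S <- crossprod(Xc, Yc)
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lam <- max(eigen(K, symmetric = TRUE)$values)
  msd <- (sum(Xc^2) + sum(Yc^2) - 2 * lam) / nrow(X)
  sqrt(max(msd, 0))
}

# CA coordinate matrix over a residue selection (or all residues)
ca_coords <- function(conf, residues = NULL) {
  a <- conf$atoms
  if (is.null(residues)) residues <- unique(a$residue_index)
  idx <- match(paste(residues, "CA"), paste(a$residue_index, a$atom_name))
  as.matrix(a[idx, c("x", "y", "z")])
}

# apply a deterministic rigid transform to a conformer
rigid_transform <- function(conf, angle = 0.7, axis = c(1, 2, 3),
                            shift = c(5, -3, 12)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  m <- as.matrix(conf$atoms[, c("x", "y", "z")]) %*% t(R)
  a <- conf$atoms
  a$x <- m[, 1] + shift[1]; a$y <- m[, 2] + shift[2]; a$z <- m[, 3] + shift[3]
  conformer(a, reliability = conf$reliability)
}
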