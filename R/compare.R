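#' Kabsch least-squares superposition
#'
#' Computes the optimal proper rotation and translation superposing the
#' C-alpha atoms of `mobile` onto `reference` over a residue selection,
#' by SVD of the cross-covariance matrix with the determinant-corrected
#' (Kabsch) sign convention so the rotation is never a reflection.
#'
#' @param mobile,reference [conformer] objects sharing residue numbering.
#' @param selection integer vector of residue indices (see
#'   [parse_residue_ranges]); at least 3 residues with CA atoms in both
#'   structures are required.
#' @param atom_name atom used for fitting, default `"CA"`.
#' @return list of class `superposition` with elements `rotation` (3x3),
#'   `translation` (length 3), `rmsd` (Angstrom, over the fitted atoms),
#'   `n_atoms`, and `deviations` (per-residue distances after fitting,
#'   named by residue index).
#' @export
kabsch_superpose <- function(mobile, reference, selection,
                             atom_name = "CA") {
  selection <- intersect_selection(mobile, reference, selection, atom_name)
  if (length(selection) < 3L) {
    stop("superposition needs >= 3 shared ", atom_name, " atoms in selection")
  }
  X <- atom_coords(mobile, selection, atom_name)     # mobile
  Y <- atom_coords(reference, selection, atom_name)  # reference
  xc <- colMeans(X); yc <- colMeans(Y)
  Xc <- sweep(X, 2, xc); Yc <- sweep(Y, 2, yc)
  H <- crossprod(Xc, Yc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)   # rotation applied as x' = R x
  Xfit <- Xc %*% t(R)
  dev <- sqrt(rowSums((Xfit - Yc)^2))
  structure(list(rotation = R,
                 translation = as.numeric(yc - R %*% xc),
                 rmsd = sqrt(mean(dev^2)),
                 n_atoms = length(selection),
                 deviations = stats::setNames(dev, selection)),
            class = "superposition")
}

# residues present (with the named atom) in both structures
intersect_selection <- function(a, b, selection, atom_name = "CA") {
  has <- function(cf) {
    at <- cf$atoms
    unique(at$residue_index[at$atom_name == atom_name])
  }
  sel <- intersect(selection, intersect(has(a), has(b)))
  sort(sel)
}

#' Convert per-residue deviations to a GDT_TS result
#'
#' The global distance test total score is the mean of the percentages of
#' residues whose C-alpha deviates by less than 1, 2, 4, and 8 Angstroms
#' after a single superposition: GDT_TS = (P1 + P2 + P4 + P8) / 4, reported
#' on a 0-100 scale. Thresholds are strict (a deviation exactly at a
#' threshold does not count below it).
#'
#' @param deviations non-negative per-residue C-alpha deviations (Angstrom).
#' @return list of class `gdt_result` with `p1`, `p2`, `p4`, `p8`, `gdt_ts`
#'   (all percent) and `n_residues`.
#' @export
deviations_to_gdt <- function(deviations) {
  deviations <- as.numeric(deviations)
  if (length(deviations) == 0L) stop("empty deviation list")
  if (any(deviations < 0)) stop("negative deviation supplied")
  p <- vapply(c(1, 2, 4, 8),
              function(thr) 100 * mean(deviations < thr), numeric(1))
  structure(list(p1 = p[1], p2 = p[2], p4 = p[3], p8 = p[4],
                 gdt_ts = mean(p), n_residues = length(deviations)),
            class = "gdt_result")
}

#' @export
print.gdt_result <- function(x, ...) {
  cat(sprintf("GDT_TS = %.1f  (P1 %.1f, P2 %.1f, P4 %.1f, P8 %.1f; n = %d)\n",
              x$gdt_ts, x$p1, x$p2, x$p4, x$p8, x$n_residues))
  invisible(x)
}

#' GDT_TS between two structures
#'
#' Superposes `model_a` onto `model_b` with a single least-squares fit over
#' the selection C-alpha atoms, then scores the per-residue deviations with
#' [deviations_to_gdt]. Symmetric in its arguments. Residues missing a CA
#' in either structure are dropped from the selection and the count used is
#' reported.
#'
#' @inheritParams kabsch_superpose
#' @param model_a,model_b [conformer] objects.
#' @return a `gdt_result` (see [deviations_to_gdt]) with an extra `rmsd`
#'   element (the superposition C-alpha RMSD).
#' @export
gdt_ts <- function(model_a, model_b, selection) {
  sup <- kabsch_superpose(model_a, model_b, selection)
  out <- deviations_to_gdt(sup$deviations)
  out$rmsd <- sup$rmsd
  out
}

#' Medoid conformer of an ensemble
#'
#' The representative conformer of an NMR-style ensemble: the member with
#' minimal mean C-alpha RMSD (after pairwise least-squares superposition on
#' the selection) to all other members. Ties break to the lowest index.
#'
#' @param ensemble a [structure_ensemble].
#' @param selection residue selection used for superposition.
#' @return integer conformer index (1-based).
#' @export
medoid_conformer <- function(ensemble, selection) {
  n <- length(ensemble)
  if (n == 1L) return(1L)
  rms <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      rms[i, j] <- rms[j, i] <- kabsch_superpose(
        ensemble$conformers[[i]], ensemble$conformers[[j]], selection)$rmsd
    }
  }
  which.min(rowSums(rms) / (n - 1L))
}

#' Ensemble spread about the medoid
#'
#' Mean C-alpha RMSD of every conformer to the medoid conformer, after
#' pairwise superposition on the selection. Zero for single-conformer
#' ensembles. This is the diagonal statistic of the pairwise similarity
#' matrix.
#'
#' @inheritParams medoid_conformer
#' @return numeric scalar (Angstrom).
#' @export
ensemble_spread <- function(ensemble, selection) {
  n <- length(ensemble)
  if (n == 1L) return(0)
  m <- medoid_conformer(ensemble, selection)
  others <- setdiff(seq_len(n), m)
  mean(vapply(others, function(i) {
    kabsch_superpose(ensemble$conformers[[i]], ensemble$conformers[[m]],
                     selection)$rmsd
  }, numeric(1)))
}

#' Pairwise structure similarity matrix
#'
#' Builds the standard publication-style comparison matrix for a set of
#' structure ensembles (e.g. NMR, X-ray, predicted): each ensemble is
#' represented by its medoid conformer; the upper triangle holds GDT_TS
#' scores (percent), the lower triangle C-alpha RMSDs (Angstrom), and the
#' diagonal the within-ensemble spread (mean C-alpha RMSD of conformers to
#' the medoid; 0 for single-conformer entries).
#'
#' @param structures list of [structure_ensemble] objects.
#' @param selection residue selection shared by all structures.
#' @param labels column/row labels; default the ensemble labels.
#' @return matrix of class `similarity_matrix`.
#' @export
similarity_matrix <- function(structures, selection, labels = NULL) {
  if (is.null(labels)) {
    labels <- vapply(structures, function(e) e$label, character(1))
  }
  n <- length(structures)
  reps <- lapply(structures, function(e) {
    e$conformers[[medoid_conformer(e, selection)]]
  })
  m <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    m[i, i] <- ensemble_spread(structures[[i]], selection)
    if (i < n) for (j in seq.int(i + 1L, n)) {
      g <- gdt_ts(reps[[i]], reps[[j]], selection)
      m[i, j] <- g$gdt_ts
      m[j, i] <- g$rmsd
    }
  }
  class(m) <- c("similarity_matrix", class(m))
  m
}

#' Write a similarity matrix as TSV
#'
#' @param x a `similarity_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(x, path) {
  utils::write.table(format(unclass(x), digits = 4), path, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}

#' Per-residue convergence spread (plumbing helper)
#'
#' Mean C-alpha deviation of each residue from the medoid conformer across
#' the ensemble, after superposition on `selection`. May be used with a
#' cutoff to suggest well-defined residue ranges, but it does not reproduce
#' the dedicated range-finding algorithms used in the literature:
#' authoritative ranges should be supplied by the user.
#'
#' @inheritParams medoid_conformer
#' @return named numeric vector of per-residue mean deviations (Angstrom).
#' @export
residue_convergence <- function(ensemble, selection) {
  n <- length(ensemble)
  m <- medoid_conformer(ensemble, selection)
  if (n == 1L) {
    return(stats::setNames(rep(0, length(selection)), selection))
  }
  devs <- sapply(setdiff(seq_len(n), m), function(i) {
    kabsch_superpose(ensemble$conformers[[i]], ensemble$conformers[[m]],
                     selection)$deviations
  })
  rowMeans(devs)
}
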