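# Small 3D geometry helpers shared by proton placement, structure builders
# and the superposition code.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Place atom D given positions A, B, C and internal coordinates of D
# relative to them: |C-D| = bond, angle B-C-D (degrees), torsion
# A-B-C-D (degrees). Standard internal-to-cartesian (NeRF) construction.
place_atom <- function(a, b, c_, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- unitv(c_ - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c_ + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Place backbone amide protons with ideal geometry
#'
#' For every non-proline residue that has a preceding residue, an amide H
#' is placed in the C(i-1)-N-CA plane at 1.02 A from N, along the direction
#' opposed to the bisector of the N-CA and N-C(i-1) bonds (so the H-N-CA
#' and H-N-C(i-1) angles are equal). Only backbone amide protons are
#' placed: they carry the N-H bond vectors needed for 15N-1H RDC analysis
#' of models deposited without hydrogens.
#'
#' @param conf a [conformer].
#' @param overwrite replace an existing amide H? Default keeps it.
#' @return the conformer with H atoms added.
#' @export
place_amide_protons <- function(conf, overwrite = FALSE) {
  a <- conf$atoms
  res <- unique(a$residue_index)
  new_rows <- list()
  drop_idx <- integer(0)
  for (ri in res) {
    rows <- a$residue_index == ri
    if (a$residue_name[rows][1L] == "PRO") next
    prev <- ri - 1L
    if (!(prev %in% res)) next     # chain-initial residue: no amide H
    has_h <- which(rows & a$atom_name == "H")
    if (length(has_h) > 0L && !overwrite) next
    nN  <- which(rows & a$atom_name == "N")
    nCA <- which(rows & a$atom_name == "CA")
    nC  <- which(a$residue_index == prev & a$atom_name == "C")
    if (length(nN) != 1L || length(nCA) != 1L || length(nC) != 1L) {
      warning(sprintf("residue %d: missing backbone atoms, amide H skipped", ri))
      next
    }
    pN  <- as.numeric(a[nN,  c("x", "y", "z")])
    pCA <- as.numeric(a[nCA, c("x", "y", "z")])
    pC  <- as.numeric(a[nC,  c("x", "y", "z")])
    hdir <- -unitv(unitv(pCA - pN) + unitv(pC - pN))
    pH <- pN + 1.02 * hdir
    if (length(has_h) > 0L) drop_idx <- c(drop_idx, has_h)
    row <- a[nN, , drop = FALSE]
    row$atom_name <- "H"
    row$element <- "H"
    row$x <- pH[1]; row$y <- pH[2]; row$z <- pH[3]
    new_rows[[length(new_rows) + 1L]] <- row
  }
  if (length(drop_idx) > 0L) a <- a[-drop_idx, , drop = FALSE]
  if (length(new_rows) > 0L) {
    a <- rbind(a, do.call(rbind, new_rows))
    a <- a[order(match(a$residue_index, res)), , drop = FALSE]
    rownames(a) <- NULL
  }
  conformer(a, reliability = conf$reliability)
}
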