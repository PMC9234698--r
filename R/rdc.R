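#' Construct an RDC set
#'
#' A set of one-bond 15N-1H residual dipolar couplings measured in one
#' alignment medium (PEG, PAG, phage, ...). Couplings are in Hz.
#'
#' @param records data frame with columns `residue_index`, `atom_a` (the
#'   nitrogen, typically `"N"`), `atom_b` (the amide proton, `"H"`),
#'   `d_exp` (Hz), and optionally `uncertainty` (Hz).
#' @param medium_label free-text alignment-medium label.
#' @return object of class `rdc_set`.
#' @export
rdc_set <- function(records, medium_label = "") {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("residue_index", "atom_a", "atom_b", "d_exp")
  if (!all(need %in% names(records))) {
    stop("records needs columns: ", paste(need, collapse = ", "))
  }
  if (!all(is.finite(records$d_exp))) stop("non-finite d_exp")
  if (is.null(records$uncertainty)) records$uncertainty <- NA_real_
  key <- paste(records$residue_index, records$atom_a, records$atom_b)
  if (anyDuplicated(key)) {
    stop("duplicate RDC record: ", key[duplicated(key)][1L])
  }
  structure(list(records = records, medium_label = medium_label),
            class = "rdc_set")
}

#' Read a plain-text RDC table
#'
#' Whitespace- or tab-separated columns: residue_index, atom_a, atom_b,
#' d_exp (Hz), and optionally an uncertainty (Hz). Lines starting with `#`
#' are comments. One file per alignment medium.
#'
#' @param path input file.
#' @param medium_label alignment-medium label; defaults to the file name.
#' @return an [rdc_set].
#' @export
read_rdc_table <- function(path, medium_label = basename(path)) {
  tb <- utils::read.table(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(tb) < 4L) stop("RDC table needs >= 4 columns")
  names(tb)[1:4] <- c("residue_index", "atom_a", "atom_b", "d_exp")
  if (ncol(tb) >= 5L) names(tb)[5L] <- "uncertainty"
  rdc_set(tb[, seq_len(min(ncol(tb), 5L))], medium_label = medium_label)
}

#' Write an RDC set to a plain-text table
#'
#' @param rdcs an [rdc_set].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rdc_table <- function(rdcs, path) {
  r <- rdcs$records
  header <- sprintf("# RDC table, medium: %s", rdcs$medium_label)
  body <- sprintf("%d\t%s\t%s\t%.6f%s", r$residue_index, r$atom_a, r$atom_b,
                  r$d_exp,
                  ifelse(is.na(r$uncertainty), "",
                         sprintf("\t%.6f", r$uncertainty)))
  writeLines(c(header, body), path)
  invisible(path)
}

# eigen-decompose a traceless symmetric Saupe matrix into the
# (da, rhombicity) parameterization with |lzz| >= |lyy| >= |lxx|
tensor_from_saupe <- function(S) {
  ev <- eigen(S, symmetric = TRUE)
  ord <- order(abs(ev$values))        # |lxx| <= |lyy| <= |lzz|
  lxx <- ev$values[ord[1]]
  lyy <- ev$values[ord[2]]
  lzz <- ev$values[ord[3]]
  structure(list(saupe = S,
                 eigenvalues = c(xx = lxx, yy = lyy, zz = lzz),
                 da = lzz / 2,
                 rhombicity = (2 / 3) * (lxx - lyy) / lzz),
            class = "alignment_tensor")
}

# build a Saupe matrix (Hz, coupling-scaled) from da, rhombicity and a
# z-y-z Euler rotation (radians) of the principal axis system
saupe_from_parameters <- function(da, rhombicity, euler = c(0, 0, 0)) {
  if (rhombicity < 0 || rhombicity > 2 / 3) {
    stop("rhombicity must lie in [0, 2/3]")
  }
  lzz <- 2 * da
  lxx <- lzz * (3 * rhombicity / 2 - 1) / 2
  lyy <- -lzz * (3 * rhombicity / 2 + 1) / 2
  R <- euler_zyz(euler)
  R %*% diag(c(lxx, lyy, lzz)) %*% t(R)
}

euler_zyz <- function(ang) {
  rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3)
  ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3)
  rz(ang[1]) %*% ry(ang[2]) %*% rz(ang[3])
}

# 5-column direction-cosine design matrix for unit bond vectors (rows);
# D = Sxx (x^2 - z^2) + Syy (y^2 - z^2) + 2 Sxy xy + 2 Sxz xz + 2 Syz yz
rdc_design <- function(V) {
  cbind(V[, 1]^2 - V[, 3]^2,
        V[, 2]^2 - V[, 3]^2,
        2 * V[, 1] * V[, 2],
        2 * V[, 1] * V[, 3],
        2 * V[, 2] * V[, 3])
}

saupe_from_elements <- function(s) {
  matrix(c(s[1], s[3], s[4],
           s[3], s[2], s[5],
           s[4], s[5], -s[1] - s[2]), 3, 3)
}

#' RDC quality factors Q1 and Q2
#'
#' Q1 normalizes the rms misfit by the rms of the observed couplings;
#' Q2 normalizes by the tensor-implied isotropic rms coupling,
#' `sqrt(Da^2 (4 + 3 Rh^2) / 5)`, which is preferable when the bond vectors
#' sample orientations non-uniformly. Both are rms ratios, i.e. the square
#' root of the ratio of sums of squares:
#' `Q1 = sqrt( sum (D_exp - D_calc)^2 / sum D_exp^2 )` and
#' `Q2 = sqrt( sum (D_exp - D_calc)^2 / (N Da^2 (4 + 3 Rh^2) / 5) )`.
#'
#' @param d_exp,d_calc observed and back-calculated couplings (Hz), equal
#'   length.
#' @param tensor an `alignment_tensor` (needed for Q2); may be NULL to get
#'   Q1 only.
#' @return list with `q1` and `q2` (NA if no tensor given).
#' @export
q_factors <- function(d_exp, d_calc, tensor = NULL) {
  if (length(d_exp) != length(d_calc) || length(d_exp) == 0L) {
    stop("d_exp and d_calc must be non-empty and of equal length")
  }
  ss_res <- sum((d_exp - d_calc)^2)
  ss_exp <- sum(d_exp^2)
  if (ss_exp == 0) stop("all observed couplings are zero")
  q1 <- sqrt(ss_res / ss_exp)
  q2 <- NA_real_
  if (!is.null(tensor)) {
    if (tensor$da == 0) stop("tensor has zero axial component")
    denom <- length(d_exp) * tensor$da^2 * (4 + 3 * tensor$rhombicity^2) / 5
    q2 <- sqrt(ss_res / denom)
  }
  list(q1 = q1, q2 = q2)
}

#' Fit the alignment (Saupe) tensor to RDC data by SVD
#'
#' Builds the standard 5-column direction-cosine design matrix from the
#' unit N-H bond vectors of the model and solves the linear system for the
#' five independent elements of the traceless symmetric alignment tensor by
#' singular value decomposition (minimum-norm least squares). The tensor is
#' fitted directly in coupling units (Hz), so the axial component Da and
#' the rhombicity follow from its eigenvalues without any physical-constant
#' table. Amide protons are placed with ideal geometry if absent from the
#' model. The fit is unweighted; reported uncertainties are carried through
#' but not used.
#'
#' @param conf a [conformer].
#' @param rdcs an [rdc_set].
#' @param selection residue selection; records outside it are excluded
#'   (counted in `n_excluded`).
#' @return list of class `rdc_fit` with `tensor` (`alignment_tensor`:
#'   `saupe`, `eigenvalues`, `da`, `rhombicity`), `d_calc`, `records` (the
#'   fitted records), `n_used`, `n_excluded`, `q1`, `q2`, `residual_rms`.
#' @export
fit_alignment_tensor <- function(conf, rdcs, selection = NULL) {
  rec <- rdcs$records
  if (is.null(selection)) selection <- unique(conf$atoms$residue_index)
  keep <- rec$residue_index %in% selection
  rec <- rec[keep, , drop = FALSE]
  if (!any(conf$atoms$atom_name == "H")) {
    conf <- place_amide_protons(conf)
  }
  a <- conf$atoms
  akey <- paste(a$residue_index, a$atom_name)
  ia <- match(paste(rec$residue_index, rec$atom_a), akey)
  ib <- match(paste(rec$residue_index, rec$atom_b), akey)
  ok <- !is.na(ia) & !is.na(ib)
  n_excluded <- sum(!keep) + sum(!ok)
  rec <- rec[ok, , drop = FALSE]
  ia <- ia[ok]; ib <- ib[ok]
  if (nrow(rec) < 5L) {
    stop("fewer than 5 usable RDC records (need >= 5 for a tensor fit)")
  }
  V <- as.matrix(a[ib, c("x", "y", "z")]) - as.matrix(a[ia, c("x", "y", "z")])
  V <- V / sqrt(rowSums(V^2))
  A <- rdc_design(V)
  sv <- svd(A)
  if (sv$d[5] <= 0 || sv$d[1] / sv$d[5] > 1e8) {
    stop("degenerate bond-vector geometry: design matrix is rank-deficient")
  }
  s <- sv$v %*% (crossprod(sv$u, rec$d_exp) / sv$d)
  tensor <- tensor_from_saupe(saupe_from_elements(as.numeric(s)))
  d_calc <- as.numeric(A %*% s)
  q <- q_factors(rec$d_exp, d_calc, tensor)
  structure(list(tensor = tensor, d_calc = d_calc, records = rec,
                 n_used = nrow(rec), n_excluded = n_excluded,
                 q1 = q$q1, q2 = q$q2,
                 residual_rms = sqrt(mean((rec$d_exp - d_calc)^2))),
            class = "rdc_fit")
}

#' @export
print.rdc_fit <- function(x, ...) {
  cat(sprintf("<rdc_fit> N = %d  Da = %.3f Hz  Rh = %.3f  Q1 = %.3f  Q2 = %.3f\n",
              x$n_used, x$tensor$da, x$tensor$rhombicity, x$q1, x$q2))
  invisible(x)
}

#' Per-conformer RDC Q factors across an ensemble
#'
#' Fits an independent alignment tensor to each conformer of an ensemble
#' (the ensemble members are alternative models of the same molecule, not a
#' simultaneous average) and summarizes Q1 and Q2 as mean +/- standard
#' deviation, the form in which ensemble Q factors are conventionally
#' tabulated. The medoid conformer's fit is reported separately.
#'
#' @param ensemble a [structure_ensemble].
#' @param rdcs an [rdc_set].
#' @param selection residue selection ("trimmed" well-defined range).
#' @return list of class `ensemble_q` with `fits` (per-conformer `rdc_fit`,
#'   NULL where a conformer was skipped), `q1_mean`, `q1_sd`, `q2_mean`,
#'   `q2_sd`, `medoid_index`, `medoid_fit`, `medium_label`.
#' @export
ensemble_q <- function(ensemble, rdcs, selection = NULL) {
  fits <- lapply(seq_along(ensemble$conformers), function(i) {
    tryCatch(fit_alignment_tensor(ensemble$conformers[[i]], rdcs, selection),
             error = function(e) {
               warning(sprintf("conformer %d skipped: %s", i,
                               conditionMessage(e)))
               NULL
             })
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("tensor fit failed for every conformer")
  q1 <- vapply(fits[ok], `[[`, numeric(1), "q1")
  q2 <- vapply(fits[ok], `[[`, numeric(1), "q2")
  sd0 <- function(v) if (length(v) > 1L) stats::sd(v) else 0
  sel <- if (is.null(selection)) {
    unique(ensemble$conformers[[1L]]$atoms$residue_index)
  } else selection
  med <- medoid_conformer(ensemble, sel)
  structure(list(fits = fits,
                 q1_mean = mean(q1), q1_sd = sd0(q1),
                 q2_mean = mean(q2), q2_sd = sd0(q2),
                 medoid_index = med,
                 medoid_fit = fits[[med]],
                 medium_label = rdcs$medium_label),
            class = "ensemble_q")
}

#' @export
print.ensemble_q <- function(x, ...) {
  f <- function(m, s) if (is.na(s)) sprintf("%.3f", m) else
    sprintf("%.3f +/- %.3f", m, s)
  cat(sprintf("<ensemble_q> medium %s: Q1 = %s, Q2 = %s (medoid: conformer %d)\n",
              x$medium_label, f(x$q1_mean, x$q1_sd), f(x$q2_mean, x$q2_sd),
              x$medoid_index))
  invisible(x)
}
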