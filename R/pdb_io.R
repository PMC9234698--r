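#' Read a (multi-model) PDB file as a structure ensemble
#'
#' Each `MODEL`/`ENDMDL` block becomes one conformer; files without MODEL
#' records (crystal structures) yield an ensemble of size 1. Hydrogens
#' present in the file are retained. Alternate locations other than 'A' or
#' blank are dropped, and a single chain is kept (the first chain in the
#' file unless `chain` is given) — the proteins this toolkit targets are
#' monomeric in the scored asymmetric unit.
#'
#' @param path PDB-format text file.
#' @param chain chain identifier to keep; default first chain encountered.
#' @param reliability_from_bfactor if TRUE, read a per-residue reliability
#'   score (e.g. pLDDT, as written by structure-prediction pipelines) from
#'   the B-factor column of each residue's CA atom.
#' @param label ensemble label; defaults to the file name.
#' @return a [structure_ensemble].
#' @export
read_pdb_ensemble <- function(path, chain = NULL,
                              reliability_from_bfactor = FALSE,
                              label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0L) {
    chunks <- list(lines)
  } else {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) < length(starts)) ends <- c(ends, length(lines))
    chunks <- Map(function(s, e) lines[s:e], starts, ends)
  }
  confs <- lapply(chunks, function(chunk) {
    tf <- tempfile(fileext = ".pdb")
    on.exit(unlink(tf))
    writeLines(chunk, tf)
    pdb <- tryCatch(bio3d::read.pdb(tf, verbose = FALSE),
                    error = function(e) stop("unparseable PDB file: ",
                                             conditionMessage(e)))
    a <- pdb$atom
    a <- a[a$type == "ATOM", , drop = FALSE]
    if (nrow(a) == 0L) stop("no ATOM records in ", path)
    a <- a[is.na(a$alt) | a$alt %in% c("", "A"), , drop = FALSE]
    keep_chain <- if (is.null(chain)) a$chain[1L] else chain
    a <- a[is.na(a$chain) | a$chain == keep_chain | is.na(keep_chain), ,
           drop = FALSE]
    if (nrow(a) == 0L) stop("no atoms in chain '", keep_chain, "'")
    rel <- NULL
    if (reliability_from_bfactor) {
      ca <- a[a$elety == "CA", , drop = FALSE]
      rel <- stats::setNames(ca$b, as.character(ca$resno))
      miss <- setdiff(unique(a$resno), ca$resno)
      for (m in miss) rel[as.character(m)] <- NA_real_
    }
    elem <- a$elesy
    elem[is.na(elem) | elem == ""] <- substr(gsub("[0-9]", "", a$elety), 1, 1)[
      is.na(elem) | elem == ""]
    conformer(data.frame(residue_index = a$resno,
                         residue_name = a$resid,
                         atom_name = a$elety,
                         element = elem,
                         x = a$x, y = a$y, z = a$z,
                         chain_id = ifelse(is.na(a$chain), "A", a$chain),
                         stringsAsFactors = FALSE),
              reliability = rel)
  })
  structure_ensemble(confs, label = label)
}

#' Write a structure ensemble to a PDB file
#'
#' Ensembles of size > 1 are written with MODEL/ENDMDL records; a size-1
#' ensemble is written as a plain single-model file.
#'
#' @param ensemble a [structure_ensemble] or single [conformer].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb_ensemble <- function(ensemble, path) {
  if (inherits(ensemble, "conformer")) {
    ensemble <- structure_ensemble(list(ensemble))
  }
  a <- ensemble$conformers[[1L]]$atoms
  xyz <- do.call(rbind, lapply(ensemble$conformers, function(cf) {
    as.numeric(t(as.matrix(cf$atoms[, c("x", "y", "z")])))
  }))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = a$residue_index, resid = a$residue_name,
                   eleno = seq_len(nrow(a)), elety = a$atom_name,
                   chain = a$chain_id, elesy = a$element)
  invisible(path)
}
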