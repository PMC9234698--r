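#' Construct a conformer
#'
#' A conformer is a single set of atomic coordinates for one polypeptide
#' chain. Atoms are stored as a data frame with one row per atom; coordinates
#' are in Angstroms. An optional per-residue reliability score (e.g. the
#' pLDDT estimate carried in the B-factor column of predicted models) may be
#' attached; when present it must cover every residue and lie in [0, 100].
#'
#' @param atoms data frame with columns `residue_index` (integer, 1-based as
#'   numbered in the source file), `residue_name` (3-letter code),
#'   `atom_name`, `element`, `x`, `y`, `z`, `chain_id`.
#' @param reliability optional named numeric vector, names = residue indices,
#'   values in [0, 100].
#' @return object of class `conformer`.
#' @export
conformer <- function(atoms, reliability = NULL) {
  required <- c("residue_index", "residue_name", "atom_name", "element",
                "x", "y", "z", "chain_id")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("atoms is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  atoms$residue_index <- as.integer(atoms$residue_index)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite coordinates in atom table")
  }
  key <- paste(atoms$chain_id, atoms$residue_index, atoms$atom_name)
  if (anyDuplicated(key)) {
    stop("duplicate atom name within a residue: ", key[duplicated(key)][1L])
  }
  if (!is.null(reliability)) {
    reliability <- unlist(reliability)
    res <- unique(atoms$residue_index)
    if (!all(as.character(res) %in% names(reliability))) {
      stop("reliability must cover every residue")
    }
    if (any(reliability < 0 | reliability > 100)) {
      stop("reliability scores must lie in [0, 100]")
    }
  }
  structure(list(atoms = atoms, reliability = reliability),
            class = "conformer")
}

#' @export
print.conformer <- function(x, ...) {
  res <- unique(x$atoms$residue_index)
  cat(sprintf("<conformer> %d atoms, %d residues (%d-%d)\n",
              nrow(x$atoms), length(res), min(res), max(res)))
  invisible(x)
}

#' Construct a structure ensemble
#'
#' An ordered set of conformers sharing one topology (identical residue
#' numbering, residue names, and atom names). NMR structures are deposited
#' as such ensembles (typically 20 conformers); crystal structures and most
#' predicted models are ensembles of size 1 or 5.
#'
#' @param conformers list of [conformer] objects.
#' @param label free-text label for reports.
#' @return object of class `structure_ensemble`.
#' @export
structure_ensemble <- function(conformers, label = "") {
  if (length(conformers) < 1L) stop("ensemble must contain >= 1 conformer")
  ref <- topology_key(conformers[[1L]])
  for (k in seq_along(conformers)[-1L]) {
    cur <- topology_key(conformers[[k]])
    if (length(cur) != length(ref) || any(cur != ref)) {
      bad <- if (length(cur) != length(ref)) {
        i <- min(length(cur), length(ref)) + 1L
        c(cur, ref)[i]
      } else cur[which(cur != ref)[1L]]
      stop(sprintf("topology mismatch between model 1 and model %d at atom %s",
                   k, bad))
    }
  }
  structure(list(conformers = conformers, label = label),
            class = "structure_ensemble")
}

topology_key <- function(conf) {
  paste(conf$atoms$chain_id, conf$atoms$residue_index, conf$atoms$atom_name)
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat(sprintf("<structure_ensemble> '%s': %d conformer(s), %d atoms each\n",
              x$label, length(x$conformers),
              nrow(x$conformers[[1L]]$atoms)))
  invisible(x)
}

#' @export
length.structure_ensemble <- function(x) length(x$conformers)

#' Parse a residue-range expression
#'
#' Residue selections are written as comma-separated inclusive ranges,
#' e.g. `"13-38,47-134,138-143"`, or single indices. The result is the
#' sorted union of all ranges.
#'
#' @param text range expression.
#' @return integer vector of residue indices (a residue selection).
#' @export
#' @examples
#' parse_residue_ranges("4-91")            # 88 indices
#' parse_residue_ranges("13-38,47-134,138-143")
parse_residue_ranges <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text))) {
    stop("range expression must be a non-empty string")
  }
  tokens <- trimws(strsplit(text, ",", fixed = TRUE)[[1L]])
  out <- integer(0)
  for (tok in tokens) {
    if (grepl("^[0-9]+$", tok)) {
      out <- c(out, as.integer(tok))
    } else if (grepl("^[0-9]+\\s*-\\s*[0-9]+$", tok)) {
      ab <- as.integer(strsplit(tok, "-", fixed = TRUE)[[1L]])
      if (ab[1L] > ab[2L]) {
        stop(sprintf("reversed range '%s': start exceeds end", tok))
      }
      out <- c(out, seq.int(ab[1L], ab[2L]))
    } else {
      stop(sprintf("cannot parse range token '%s'", tok))
    }
  }
  sort(unique(out))
}

#' Shipped consensus well-defined residue ranges
#'
#' Returns the bundled table of consensus well-defined / reliably-predicted
#' residue ranges for the NMR/X-ray pair targets this toolkit was designed
#' around, as range expressions consumable by [parse_residue_ranges].
#' Authoritative ranges for new proteins must be supplied by the user (see
#' [residue_convergence] for a rough convergence helper).
#'
#' @return data frame with columns `target`, `total_residues`,
#'   `well_defined_range`, `rdc_media`.
#' @export
well_defined_ranges <- function() {
  path <- system.file("extdata", "well_defined_ranges.tsv",
                      package = "nmrmodelcheck")
  tb <- utils::read.table(path, header = FALSE, sep = "\t",
                          comment.char = "#", fill = TRUE,
                          stringsAsFactors = FALSE)
  names(tb) <- c("target", "total_residues", "well_defined_range",
                 "rdc_media")[seq_len(ncol(tb))]
  tb
}

# coordinates of one named atom per residue of a selection, in residue order;
# errors (or returns NULL when must_exist = FALSE) on missing atoms
atom_coords <- function(conf, residues, atom_name = "CA", must_exist = TRUE) {
  a <- conf$atoms
  idx <- match(paste(residues, atom_name), paste(a$residue_index, a$atom_name))
  if (anyNA(idx)) {
    if (must_exist) {
      stop(sprintf("residue %d has no %s atom",
                   residues[which(is.na(idx))[1L]], atom_name))
    }
    return(NULL)
  }
  as.matrix(a[idx, c("x", "y", "z")])
}
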