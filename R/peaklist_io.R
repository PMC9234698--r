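# Readers and writers for the plain-text NMR data formats the scoring
# modules consume: Sparky .list and XEASY .peaks NOESY peak lists, NMR-STAR
# chemical-shift loops, simple TSV shift tables, and RDC tables (rdc.R).

#' Read a Sparky peak list
#'
#' Sparky `.list` export: a header line (`Assignment w1 w2 ...`) followed by
#' one line per peak with an assignment label and the shift coordinates.
#' Two shift columns are read as the two proton dimensions; a third is
#' treated as a heavy-atom dimension attached to the first proton. A
#' trailing intensity column (`Height`/`Data`) is kept when present.
#'
#' @param path input file.
#' @return peak data frame with columns `w1`, `w2`, optionally `heavy1`,
#'   `intensity`.
#' @export
read_sparky_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) > 0L && grepl("Assignment", lines[1L], ignore.case = TRUE)) {
    lines <- lines[-1L]
  }
  if (length(lines) == 0L) stop("empty peak list: ", path)
  rows <- lapply(lines, function(l) {
    toks <- strsplit(l, "\\s+")[[1L]]
    vals <- suppressWarnings(as.numeric(toks))
    vals[!is.na(vals)]
  })
  nval <- lengths(rows)
  if (any(nval < 2L)) stop("unparseable peak line in ", path)
  to_df <- function(r) {
    if (length(r) == 2L) c(r, NA, NA)
    else if (length(r) == 3L) c(r[1:2], NA, r[3])     # w1 w2 intensity
    else c(r[1:3], r[4])                               # w1 w2 heavy1 intensity
  }
  m <- do.call(rbind, lapply(rows, to_df))
  out <- data.frame(w1 = m[, 1], w2 = m[, 2], heavy1 = m[, 3],
                    intensity = m[, 4])
  if (all(is.na(out$heavy1))) out$heavy1 <- NULL
  out
}

#' Write a Sparky peak list
#'
#' @param peaks peak data frame (`w1`, `w2`, optional `heavy1`, `intensity`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sparky_list <- function(peaks, path) {
  has_heavy <- "heavy1" %in% names(peaks) && !all(is.na(peaks$heavy1))
  has_int <- "intensity" %in% names(peaks) && !all(is.na(peaks$intensity))
  header <- paste(c("Assignment", "w1", "w2",
                    if (has_heavy) "w3", if (has_int) "Height"),
                  collapse = "\t")
  body <- sprintf("?-?\t%.4f\t%.4f%s%s", peaks$w1, peaks$w2,
                  if (has_heavy) sprintf("\t%.4f", peaks$heavy1) else "",
                  if (has_int) sprintf("\t%.4e", peaks$intensity) else "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an XEASY peak list
#'
#' XEASY `.peaks`: `#`-comment header, then one line per peak: peak number,
#' shift coordinates (2 for 2D, 3 for 3D), followed by color code, spectrum
#' type and the peak volume. For 3D lists the heavy dimension is taken as
#' the third shift column.
#'
#' @param path input file.
#' @param n_dims 2 or 3; default guessed from the first peak line.
#' @return peak data frame (`w1`, `w2`, optional `heavy1`, `intensity`).
#' @export
read_xeasy_peaks <- function(path, n_dims = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty peak list: ", path)
  rows <- lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1L]])
  if (is.null(n_dims)) {
    # dimensions = numeric fields between the peak id and the color code
    # (XEASY writes id, shifts..., color(int), type(letter), volume, ...)
    first <- rows[[1L]]
    letter <- which(grepl("^[A-Za-z]", first))[1L]
    n_dims <- if (is.na(letter)) length(first) - 1L else letter - 3L
    if (is.na(n_dims) || n_dims < 2L) n_dims <- 2L
  }
  m <- do.call(rbind, lapply(rows, function(r) {
    shifts <- as.numeric(r[2:(1 + n_dims)])
    vol_idx <- which(grepl("^[A-Za-z]$", r))[1L] + 1L
    vol <- if (!is.na(vol_idx) && vol_idx <= length(r)) {
      suppressWarnings(as.numeric(r[vol_idx]))
    } else NA_real_
    c(shifts, vol)
  }))
  out <- data.frame(w1 = m[, 1], w2 = m[, 2], intensity = m[, n_dims + 1L])
  if (n_dims == 3L) out$heavy1 <- m[, 3]
  out
}

#' Write an XEASY peak list
#'
#' @inheritParams write_sparky_list
#' @return `path`, invisibly.
#' @export
write_xeasy_peaks <- function(peaks, path) {
  has_heavy <- "heavy1" %in% names(peaks) && !all(is.na(peaks$heavy1))
  n_dims <- if (has_heavy) 3L else 2L
  header <- c(sprintf("# Number of dimensions %d", n_dims))
  vol <- if ("intensity" %in% names(peaks)) peaks$intensity else
    rep(1, nrow(peaks))
  vol[is.na(vol)] <- 1
  body <- if (has_heavy) {
    sprintf("%4d %8.3f %8.3f %8.3f 1 U %12.4e 0.0e+00 e 0 0 0",
            seq_len(nrow(peaks)), peaks$w1, peaks$w2, peaks$heavy1, vol)
  } else {
    sprintf("%4d %8.3f %8.3f 1 U %12.4e 0.0e+00 e 0 0 0",
            seq_len(nrow(peaks)), peaks$w1, peaks$w2, vol)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read chemical shifts from an NMR-STAR 3.1 file
#'
#' Extracts the `Atom_chem_shift` loop (residue index, residue name, atom
#' name, shift value). Only the columns needed for NOESY matching are kept.
#'
#' @param path NMR-STAR text file.
#' @return data frame with `residue_index`, `residue_name`, `atom_name`,
#'   `shift`.
#' @export
read_nmrstar_shifts <- function(path) {
  lines <- readLines(path, warn = FALSE)
  loop_starts <- grep("^\\s*loop_\\s*$", lines)
  for (ls in loop_starts) {
    i <- ls + 1L
    tags <- character(0)
    while (i <= length(lines) && grepl("^\\s*_", lines[i])) {
      tags <- c(tags, trimws(lines[i]))
      i <- i + 1L
    }
    if (!any(grepl("_Atom_chem_shift", tags))) next
    col <- function(name) {
      hit <- grep(paste0("\\.", name, "$"), tags)
      if (length(hit) != 1L) NA_integer_ else hit
    }
    ci <- col("Comp_index_ID"); cn <- col("Comp_ID")
    ca <- col("Atom_ID"); cv <- col("Val")
    if (anyNA(c(ci, cn, ca, cv))) {
      stop("Atom_chem_shift loop lacks required tags in ", path)
    }
    out <- list()
    while (i <= length(lines)) {
      l <- trimws(lines[i])
      if (l == "stop_" || l == "" || startsWith(l, "#")) {
        if (l == "stop_") break
        i <- i + 1L
        next
      }
      toks <- strsplit(l, "\\s+")[[1L]]
      if (length(toks) >= max(ci, cn, ca, cv)) {
        out[[length(out) + 1L]] <- data.frame(
          residue_index = as.integer(toks[ci]),
          residue_name = toks[cn],
          atom_name = toks[ca],
          shift = as.numeric(toks[cv]),
          stringsAsFactors = FALSE)
      }
      i <- i + 1L
    }
    if (length(out) > 0L) return(do.call(rbind, out))
  }
  stop("no Atom_chem_shift loop found in ", path)
}

#' Read a plain TSV chemical-shift table
#'
#' Columns (tab or whitespace separated, `#` comments): residue_index,
#' residue_name, atom_name, shift (ppm).
#'
#' @param path input file.
#' @return data frame with `residue_index`, `residue_name`, `atom_name`,
#'   `shift`.
#' @export
read_shift_table <- function(path) {
  tb <- utils::read.table(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(tb) < 4L) stop("shift table needs 4 columns")
  names(tb)[1:4] <- c("residue_index", "residue_name", "atom_name", "shift")
  tb[, 1:4]
}

#' Write a plain TSV chemical-shift table
#'
#' One row per assigned proton group (pseudoatom names for merged groups),
#' readable back by [read_shift_table].
#'
#' @param assignments an [assignment_table].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_shift_table <- function(assignments, path) {
  g <- assignments$groups
  g <- g[!is.na(g$shift), , drop = FALSE]
  writeLines(c("# residue_index residue_name atom_name shift",
               sprintf("%d\t%s\t%s\t%.4f", g$residue_index, g$residue_name,
                       g$group_name, g$shift)), path)
  invisible(path)
}
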