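# Proton-group construction for NOE network analysis.
#
# NOESY cross peaks cannot distinguish protons whose resonances are
# degenerate by chemistry: the three hydrogens of a methyl group, the
# two-fold-symmetric ring protons of Tyr/Phe, prochiral methylene pairs
# without stereospecific assignments, and the isopropyl methyl pairs of
# Leu/Val without stereospecific assignments. Such protons are merged into
# a single "proton group" (pseudoatom) and inter-group distances are
# r^-6 summation distances over the member atoms.

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

# attached-heavy-atom guess for a proton name within one residue's atom set
heavy_for_proton <- function(hname, residue_atoms) {
  if (hname %in% c("H", "HN")) return("N")
  if (grepl("^HA", hname)) return("CA")
  suffix <- sub("^H", "", hname)
  for (stem in c(suffix, sub("[0-9]$", "", suffix))) {
    for (el in c("C", "N", "O")) {
      cand <- paste0(el, stem)
      if (cand %in% residue_atoms) return(cand)
    }
  }
  NA_character_
}

group_key <- function(residue_index, group_name) {
  paste0(residue_index, ":", group_name)
}

#' Group chemically equivalent / unresolvable protons
#'
#' Builds the proton-group universe over which NOE networks are defined:
#' methyls become single 3-member groups; degenerate Tyr/Phe ring protons
#' (delta and epsilon pairs) are merged; prochiral methylene pairs and
#' Leu/Val isopropyl methyl pairs are merged unless a stereospecific
#' assignment is supplied for them. All other protons stay singletons.
#'
#' @param conf a [conformer] (only the topology — residue and atom names —
#'   is used).
#' @param stereo_assignments character vector marking prochiral pairs with
#'   known stereospecific assignments, as `"<residue_index>:<stem>"`, e.g.
#'   `"12:HB"` for the beta-methylene of residue 12 or `"8:QD"` for the
#'   Leu-8 isopropyl methyls.
#' @return data frame of class `proton_groups` with columns `residue_index`,
#'   `residue_name`, `group_name`, `heavy_name`, `members` (list column of
#'   member atom names), `key`, plus `shift` and `heavy_shift` columns
#'   initialized to NA (filled by an assignment table).
#' @export
group_equivalent_protons <- function(conf, stereo_assignments = character(0)) {
  a <- conf$atoms
  out <- list()
  for (ri in unique(a$residue_index)) {
    rows <- a[a$residue_index == ri, , drop = FALSE]
    rname <- rows$residue_name[1L]
    hn <- rows$atom_name[rows$element == "H" | grepl("^H", rows$atom_name)]
    if (length(hn) == 0L) next
    res_atoms <- rows$atom_name
    if (!(rname %in% STANDARD_AA)) {
      warning(sprintf("residue %d (%s): unknown type, protons kept as singletons",
                      ri, rname))
      for (h in hn) {
        out[[length(out) + 1L]] <- list(ri, rname, h,
                                        heavy_for_proton(h, res_atoms), list(h))
      }
      next
    }
    used <- character(0)
    add <- function(gname, members, heavy) {
      out[[length(out) + 1L]] <<- list(ri, rname, gname, heavy, list(members))
      used <<- c(used, members)
    }
    stems <- sub("[0-9]$", "", hn)
    # methyls: three protons sharing a stem (HB1-3, HG11-13, HD21-23, ...)
    methyl_groups <- character(0)
    for (st in unique(stems)) {
      mem <- hn[stems == st]
      if (length(mem) == 3L && st != "H") {
        heavy <- heavy_for_proton(mem[1L], res_atoms)
        is_methyl <- !is.na(heavy) && startsWith(heavy, "C")
        if (is_methyl) {
          gname <- paste0("Q", sub("^H", "", st))
          add(gname, mem, heavy)
          methyl_groups <- c(methyl_groups, gname)
        }
      }
    }
    # Leu/Val isopropyl methyl pairs: merge the two methyls when no
    # stereospecific assignment is available
    iso <- list(LEU = c("QD1", "QD2"), VAL = c("QG1", "QG2"))[[rname]]
    if (!is.null(iso) && all(iso %in% methyl_groups)) {
      stereo_key <- paste0(ri, ":", sub("[0-9]$", "", iso[1L]))
      if (!(stereo_key %in% stereo_assignments)) {
        keep <- vapply(out, function(g) !(g[[1L]] == ri &&
                                            g[[3L]] %in% iso), logical(1))
        mem6 <- unlist(lapply(out[!keep], function(g) g[[5L]][[1L]]))
        out <- out[keep]
        add(paste0("Q", sub("[0-9]$", "", iso[1L])), mem6,
            sub("[0-9]$", "", heavy_for_proton(mem6[1L], res_atoms)))
      }
    }
    # degenerate aromatic ring pairs of Tyr/Phe (two-fold ring flip)
    if (rname %in% c("PHE", "TYR")) {
      for (st in c("HD", "HE")) {
        mem <- setdiff(hn[stems == st], used)
        if (length(mem) == 2L) add(paste0("Q", sub("^H", "", st)), mem,
                                   sub("^H", "C", st))
      }
    }
    # prochiral methylene (and amide NH2) pairs: merged unless stereo known;
    # protons sharing a name stem but attached to different heavy atoms
    # (e.g. Trp HE1/HE3, His HD1/HD2) are not equivalent and stay apart
    for (st in unique(stems)) {
      mem <- setdiff(hn[stems == st], used)
      if (length(mem) == 2L) {
        heavies <- vapply(mem, heavy_for_proton, character(1),
                          residue_atoms = res_atoms)
        same_heavy <- !anyNA(heavies) && heavies[1L] == heavies[2L]
        if (same_heavy && !(paste0(ri, ":", st) %in% stereo_assignments)) {
          add(paste0("Q", sub("^H", "", st)), mem, heavies[1L])
        } else {
          for (h in mem) add(h, h, heavy_for_proton(h, res_atoms))
        }
      }
    }
    # everything left is a singleton
    for (h in setdiff(hn, used)) add(h, h, heavy_for_proton(h, res_atoms))
  }
  df <- data.frame(residue_index = vapply(out, function(g) as.integer(g[[1L]]),
                                          integer(1)),
                   residue_name = vapply(out, `[[`, character(1), 2L),
                   group_name = vapply(out, `[[`, character(1), 3L),
                   heavy_name = vapply(out, `[[`, character(1), 4L),
                   stringsAsFactors = FALSE)
  df$members <- I(lapply(out, function(g) g[[5L]][[1L]]))
  df <- df[order(df$residue_index, df$group_name), , drop = FALSE]
  df$key <- group_key(df$residue_index, df$group_name)
  df$shift <- NA_real_
  df$heavy_shift <- NA_real_
  rownames(df) <- NULL
  class(df) <- c("proton_groups", class(df))
  df
}

#' Assemble an assignment table
#'
#' Pairs a proton-group universe (with chemical shifts filled in) with the
#' shift-match tolerances used to interpret NOESY peak positions.
#'
#' @param groups a `proton_groups` data frame with `shift` (ppm) filled for
#'   assigned groups (`heavy_shift` optional, used for 3D matching).
#' @param tolerance_h proton match tolerance, ppm (default 0.05).
#' @param tolerance_heavy heavy-atom (13C/15N) match tolerance, ppm
#'   (default 0.5).
#' @return object of class `assignment_table`.
#' @export
assignment_table <- function(groups, tolerance_h = 0.05,
                             tolerance_heavy = 0.5) {
  if (tolerance_h <= 0 || tolerance_heavy <= 0) stop("tolerances must be > 0")
  if (all(is.na(groups$shift))) stop("no chemical shifts in group table")
  structure(list(groups = groups, tolerance_h = tolerance_h,
                 tolerance_heavy = tolerance_heavy),
            class = "assignment_table")
}

#' Fill group shifts from a per-atom chemical shift table
#'
#' Group shifts are the mean over member-atom shifts found in the table
#' (degenerate members share one resonance in practice); the heavy-partner
#' shift is taken from the attached heavy atom when assigned.
#'
#' @param groups a `proton_groups` data frame.
#' @param shifts data frame with columns `residue_index`, `atom_name`,
#'   `shift` (as returned by [read_shift_table] / [read_nmrstar_shifts]).
#' @inheritParams assignment_table
#' @return an [assignment_table].
#' @export
assignment_from_shifts <- function(groups, shifts, tolerance_h = 0.05,
                                   tolerance_heavy = 0.5) {
  skey <- paste(shifts$residue_index, shifts$atom_name)
  for (i in seq_len(nrow(groups))) {
    # match member atom names, or the group pseudoatom name itself
    mem <- c(groups$members[[i]], groups$group_name[i])
    hit <- match(paste(groups$residue_index[i], mem), skey)
    if (any(!is.na(hit))) {
      groups$shift[i] <- mean(shifts$shift[hit[!is.na(hit)]])
    }
    hh <- match(paste(groups$residue_index[i], groups$heavy_name[i]), skey)
    if (!is.na(hh)) groups$heavy_shift[i] <- shifts$shift[hh]
  }
  assignment_table(groups, tolerance_h, tolerance_heavy)
}
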