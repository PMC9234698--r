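#' Run a full validation report
#'
#' Orchestrates every score this package computes into one per-model-set
#' report: RPF-DP scores when a peak list and shift table are supplied, RDC
#' Q factors per alignment medium when RDC tables are supplied, and
#' GDT_TS / C-alpha RMSD comparisons against reference structures when
#' given. Missing inputs leave their columns empty; they are never filled
#' with placeholder values. The configuration defaults (tolerances, NOE
#' cutoff, seed) are echoed into the report header for provenance.
#'
#' @param config named list, or path to a YAML file, with entries:
#'   \describe{
#'     \item{models}{path to the model coordinate file (PDB), required.}
#'     \item{selection}{residue-range expression, required (e.g. "4-91").}
#'     \item{peaks}{optional NOESY peak list (`.list` Sparky or `.peaks`
#'       XEASY, by extension).}
#'     \item{shifts}{optional shift table (NMR-STAR if the file contains an
#'       `Atom_chem_shift` loop, else plain TSV). Required with `peaks`.}
#'     \item{rdc}{optional character vector of RDC table paths (one per
#'       alignment medium).}
#'     \item{references}{optional character vector of reference PDB paths
#'       for GDT/RMSD columns.}
#'     \item{d_noe_max, tolerance_h, tolerance_heavy, seed, weighting,
#'       n_free_samples}{optional overrides of the defaults 5, 0.05, 0.5,
#'       1, "distance", 50.}
#'     \item{label, chain, out_prefix}{optional labelling/output controls;
#'       with `out_prefix`, TSV and JSON reports are written.}
#'   }
#' @return list of class `validation_report` with `header` (settings used),
#'   `row` (the score row as a one-row data frame) and the underlying
#'   result objects (`dp`, `rdc_fits`, `comparisons`).
#' @export
run_report <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$models)) stop("configuration error: 'models' is required")
  has_noesy <- !is.null(config$peaks) && !is.null(config$shifts)
  has_rdc <- !is.null(config$rdc)
  if (!has_noesy && !has_rdc && is.null(config$references)) {
    stop("configuration error: no data source (peaks+shifts, rdc, or references)")
  }
  defaults <- list(d_noe_max = 5, tolerance_h = 0.05, tolerance_heavy = 0.5,
                   seed = 1L, weighting = "distance", n_free_samples = 100)
  cfg <- utils::modifyList(defaults, config)
  ens <- read_pdb_ensemble(cfg$models, chain = cfg$chain,
                           label = if (is.null(cfg$label)) basename(cfg$models)
                                   else cfg$label)
  sel <- parse_residue_ranges(cfg$selection)
  row <- data.frame(label = ens$label, n_conformers = length(ens),
                    residues_used = length(sel))
  out <- list(dp = NULL, rdc_fits = list(), comparisons = list())

  if (has_noesy) {
    peaks <- if (grepl("\\.peaks$", cfg$peaks)) read_xeasy_peaks(cfg$peaks)
             else read_sparky_list(cfg$peaks)
    star <- any(grepl("_Atom_chem_shift",
                      readLines(cfg$shifts, n = 200L, warn = FALSE)))
    shifts <- if (star) read_nmrstar_shifts(cfg$shifts)
              else read_shift_table(cfg$shifts)
    groups <- group_equivalent_protons(ens$conformers[[1L]])
    asg <- assignment_from_shifts(groups, shifts, cfg$tolerance_h,
                                  cfg$tolerance_heavy)
    out$dp <- ensemble_dp(ens, peaks, asg, d_noe_max = cfg$d_noe_max,
                          weighting = cfg$weighting,
                          n_free_samples = cfg$n_free_samples, seed = cfg$seed)
    row$dp_ensemble <- out$dp$dp_ensemble
    row$dp_avg <- out$dp$dp_avg
    row$r_avg <- out$dp$r_avg
    row$p_avg <- out$dp$p_avg
    row$f_avg <- out$dp$f_avg
  } else {
    row$dp_ensemble <- row$dp_avg <- row$r_avg <- row$p_avg <- row$f_avg <-
      NA_real_
  }

  if (has_rdc) {
    for (rp in cfg$rdc) {
      rs <- read_rdc_table(rp)
      eq <- ensemble_q(ens, rs, sel)
      out$rdc_fits[[rs$medium_label]] <- eq
      row[[paste0("q1_", rs$medium_label)]] <-
        sprintf("%.3f +/- %.3f", eq$q1_mean, eq$q1_sd)
      row[[paste0("q2_", rs$medium_label)]] <-
        sprintf("%.3f +/- %.3f", eq$q2_mean, eq$q2_sd)
    }
  }

  if (!is.null(cfg$references)) {
    med <- ens$conformers[[medoid_conformer(ens, sel)]]
    for (rp in cfg$references) {
      ref <- read_pdb_ensemble(rp)
      refc <- ref$conformers[[medoid_conformer(ref, sel)]]
      g <- tryCatch(gdt_ts(med, refc, sel), error = function(e) {
        warning("comparison with ", rp, " failed: ", conditionMessage(e))
        NULL
      })
      if (is.null(g)) next
      out$comparisons[[basename(rp)]] <- g
      row[[paste0("gdt_vs_", basename(rp))]] <- g$gdt_ts
      row[[paste0("rmsd_vs_", basename(rp))]] <- g$rmsd
    }
  }

  header <- cfg[c("models", "selection", "d_noe_max", "tolerance_h",
                  "tolerance_heavy", "seed", "weighting", "n_free_samples")]
  header$package_version <- as.character(utils::packageVersion("nmrmodelcheck"))
  rep <- structure(list(header = header, row = row, dp = out$dp,
                        rdc_fits = out$rdc_fits,
                        comparisons = out$comparisons),
                   class = "validation_report")
  if (!is.null(cfg$out_prefix)) write_report(rep, cfg$out_prefix)
  rep
}

#' Write a validation report as TSV and JSON
#'
#' The two files carry identical cell values: the TSV mirrors the tabular
#' layout, the JSON adds the settings header.
#'
#' @param report a `validation_report`.
#' @param prefix output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @return the two paths, invisibly.
#' @export
write_report <- function(report, prefix) {
  tsv <- paste0(prefix, ".tsv")
  json <- paste0(prefix, ".json")
  utils::write.table(report$row, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(header = report$header,
                            scores = as.list(report$row)),
                       json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(tsv, json))
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation report:", x$row$label, "\n")
  for (nm in names(x$row)) cat(sprintf("  %-24s %s\n", nm,
                                       format(x$row[[nm]])))
  invisible(x)
}
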