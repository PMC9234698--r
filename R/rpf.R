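#' r^-6 summation distance
#'
#' Effective distance of a set of degenerate proton-proton distances:
#' `(sum d_i^-6)^(-1/6)`. Always no larger than the shortest individual
#' distance; used so that unresolved proton groups contribute the way their
#' NOE intensities add.
#'
#' @param distances positive distances, Angstrom.
#' @return effective distance, Angstrom.
#' @export
#' @examples
#' summation_distance(3)            # 3
#' summation_distance(c(3, 3))      # 3 / 2^(1/6)
summation_distance <- function(distances) {
  if (length(distances) == 0L) stop("empty distance list")
  if (any(distances <= 0)) stop("distances must be > 0")
  sum(distances^-6)^(-1 / 6)
}

# group-pair sums of r^-6 for one coordinate matrix; returns a G x G matrix
# (G = number of groups) of sum_{a in A, b in B} d_ab^-6
group_r6_sums <- function(coords, atom_group) {
  d <- as.matrix(stats::dist(coords))
  r6 <- d^-6
  diag(r6) <- 0
  gi <- factor(atom_group)
  s <- rowsum(r6, gi)
  t(rowsum(t(s), gi))
}

#' Build a model interproton distance network
#'
#' The network G of a structure model: proton groups are nodes, and two
#' groups are joined by an edge when their r^-6 summation distance is at
#' most `d_noe_max` (default 5 Angstrom, the conventional maximum distance
#' at which an NOE is observable). Given an ensemble, the edge distances
#' are ensemble-averaged effective distances: atom-pair r^-6 values are
#' averaged across conformers before the group summation, the averaging
#' appropriate to NOE intensities.
#'
#' @param x a [conformer] or a [structure_ensemble] (ensemble-averaged
#'   network).
#' @param groups a `proton_groups` table (see [group_equivalent_protons]);
#'   every member atom must exist in the structure.
#' @param d_noe_max distance cutoff, Angstrom.
#' @return data frame of class `model_network` with columns `key_a`,
#'   `key_b` (canonically ordered group keys) and `distance`; attributes
#'   `d_noe_max` and `group_keys`.
#' @export
build_model_network <- function(x, groups, d_noe_max = 5) {
  confs <- if (inherits(x, "structure_ensemble")) x$conformers else list(x)
  # map every member atom to its group, once
  member_res <- rep(groups$residue_index, lengths(groups$members))
  member_atom <- unlist(groups$members)
  member_grp <- rep(groups$key, lengths(groups$members))
  acc <- NULL
  for (conf in confs) {
    akey <- paste(conf$atoms$residue_index, conf$atoms$atom_name)
    idx <- match(paste(member_res, member_atom), akey)
    if (anyNA(idx)) {
      bad <- which(is.na(idx))[1L]
      stop(sprintf("group %s refers to missing atom %s in residue %d",
                   member_grp[bad], member_atom[bad], member_res[bad]))
    }
    coords <- as.matrix(conf$atoms[idx, c("x", "y", "z")])
    s <- group_r6_sums(coords, member_grp)
    acc <- if (is.null(acc)) s else acc + s
  }
  acc <- acc / length(confs)
  keys <- rownames(acc)
  ord <- order(keys)          # deterministic edge order
  acc <- acc[ord, ord]
  keys <- keys[ord]
  ut <- which(upper.tri(acc) & acc > d_noe_max^-6, arr.ind = TRUE)
  net <- data.frame(key_a = keys[ut[, 1]], key_b = keys[ut[, 2]],
                    distance = acc[ut]^(-1 / 6),
                    stringsAsFactors = FALSE)
  net <- net[order(net$key_a, net$key_b), , drop = FALSE]
  rownames(net) <- NULL
  attr(net, "d_noe_max") <- d_noe_max
  attr(net, "group_keys") <- keys
  class(net) <- c("model_network", class(net))
  net
}

edge_key <- function(key_a, key_b) {
  paste(pmin(key_a, key_b), pmax(key_a, key_b), sep = "|")
}

#' Build the ambiguous NOE network from a peak list
#'
#' Interprets each NOESY cross peak as the set of all proton-group pairs
#' whose shifts match both proton dimensions within the proton tolerance
#' (and, for 3D peaks carrying a heavy-atom dimension, whose attached heavy
#' shift matches within the heavy tolerance). Diagonal peaks — both proton
#' shifts within tolerance of each other with a single group matching both
#' dimensions — are discarded. Peaks matching no assigned pair are listed
#' as unassignable and excluded from scoring (but reported, so data
#' problems stay visible).
#'
#' @param peaks data frame with proton-shift columns `w1`, `w2` (ppm) and
#'   optionally `heavy1` (heavy shift attached to the `w1` proton) and
#'   `intensity`.
#' @param assignments an [assignment_table].
#' @return list of class `anoe_network`: `candidates` (per retained peak, a
#'   character vector of candidate edge keys), `peak_index` (row of `peaks`
#'   each candidate set came from), `unassignable` (row indices),
#'   `n_diagonal`, and the inputs.
#' @export
build_anoe_network <- function(peaks, assignments) {
  g <- assignments$groups
  g <- g[!is.na(g$shift), , drop = FALSE]
  if (nrow(g) == 0L) stop("assignment table has no assigned groups")
  tol <- assignments$tolerance_h
  tolh <- assignments$tolerance_heavy
  has_heavy <- "heavy1" %in% names(peaks)
  candidates <- list()
  peak_index <- integer(0)
  unassignable <- integer(0)
  n_diagonal <- 0L
  for (p in seq_len(nrow(peaks))) {
    m1 <- abs(g$shift - peaks$w1[p]) <= tol
    if (has_heavy && !is.na(peaks$heavy1[p])) {
      m1 <- m1 & !is.na(g$heavy_shift) &
        abs(g$heavy_shift - peaks$heavy1[p]) <= tolh
    }
    m2 <- abs(g$shift - peaks$w2[p]) <= tol
    if (abs(peaks$w1[p] - peaks$w2[p]) <= tol && any(m1 & m2)) {
      n_diagonal <- n_diagonal + 1L
      next
    }
    ia <- which(m1); ib <- which(m2)
    if (length(ia) == 0L || length(ib) == 0L) {
      unassignable <- c(unassignable, p)
      next
    }
    pairs <- expand.grid(a = ia, b = ib)
    pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
    if (nrow(pairs) == 0L) {
      unassignable <- c(unassignable, p)
      next
    }
    candidates[[length(candidates) + 1L]] <-
      unique(edge_key(g$key[pairs$a], g$key[pairs$b]))
    peak_index <- c(peak_index, p)
  }
  structure(list(candidates = candidates, peak_index = peak_index,
                 unassignable = unassignable, n_diagonal = n_diagonal,
                 peaks = peaks, assignments = assignments),
            class = "anoe_network")
}

#' Recall, precision and F-measure of a model against NOESY data
#'
#' A peak is a true positive when at least one of its candidate proton-pair
#' assignments is an edge of the model network G, and a false negative only
#' when none is. Recall is the matched fraction of (assignable) peaks.
#' Precision is the fraction of G's edges supported by at least one peak,
#' with each edge weighted by its interproton distance (w = d^-6 scaled so
#' the shortest edge has weight 1) so that weak NOEs near the cutoff carry
#' little weight; `weighting = "uniform"` disables the weighting. The
#' F-measure is the harmonic mean of recall and precision.
#'
#' @param model_net a `model_network` (see [build_model_network]).
#' @param anoe an `anoe_network` (see [build_anoe_network]).
#' @param weighting `"distance"` (default) or `"uniform"`.
#' @return list of class `rpf_scores`: `tp`, `fp`, `fn` (peak counts for
#'   recall, edge weights for precision), `recall`, `precision`,
#'   `f_measure`, `n_peaks_scored`, `n_unassignable`.
#' @export
score_rpf <- function(model_net, anoe, weighting = c("distance", "uniform")) {
  weighting <- match.arg(weighting)
  if (length(anoe$candidates) == 0L) {
    stop("no assignable peaks: recall undefined")
  }
  edges <- edge_key(model_net$key_a, model_net$key_b)
  matched <- vapply(anoe$candidates,
                    function(cand) any(cand %in% edges), logical(1))
  tp <- sum(matched)
  fn <- sum(!matched)
  recall <- tp / (tp + fn)
  if (length(edges) == 0L) {
    warning("model network has no edges: precision defined as 1")
    precision <- 1
    fp <- 0
  } else {
    supported_keys <- unique(unlist(anoe$candidates))
    supported <- edges %in% supported_keys
    w <- if (weighting == "distance") {
      (min(model_net$distance) / model_net$distance)^6
    } else rep(1, length(edges))
    precision <- sum(w[supported]) / sum(w)
    fp <- sum(w[!supported])
  }
  f <- if (recall + precision > 0) {
    2 * recall * precision / (recall + precision)
  } else 0
  structure(list(tp = tp, fp = fp, fn = fn, recall = recall,
                 precision = precision, f_measure = f,
                 n_peaks_scored = length(anoe$candidates),
                 n_unassignable = length(anoe$unassignable)),
            class = "rpf_scores")
}

#' @export
print.rpf_scores <- function(x, ...) {
  cat(sprintf("R = %.3f  P = %.3f  F = %.3f  (%d peaks scored, %d unassignable)\n",
              x$recall, x$precision, x$f_measure, x$n_peaks_scored,
              x$n_unassignable))
  invisible(x)
}

# side-chain rank of a heavy atom name: N (backbone) = 0, CA = 1, CB = 2,
# G = 3, D = 4, ... Used to enumerate 2-4 bond proton pairs.
heavy_rank <- function(heavy) {
  ifelse(heavy == "N", 0L,
         ifelse(is.na(heavy), NA_integer_,
                match(substr(heavy, 2, 2), c("A", "B", "G", "D", "E", "Z", "H"))))
}

#' Upper F-measure bound from NOESY data completeness
#'
#' Protons separated by 2-4 covalent bonds (geminal and vicinal pairs, plus
#' e.g. the amide-H to beta-H pair) are always closer than 5 Angstrom, so
#' the fraction of such pairs actually represented in the peak list bounds
#' the recall any model can reach. Completeness c is that fraction,
#' enumerated from heavy-atom-attachment adjacency within each residue, and
#' the bound is `f_max = 2c / (1 + c)`, the F-measure at recall c and
#' precision 1.
#'
#' @inheritParams build_anoe_network
#' @param groups the proton-group universe (defaults to the assignment
#'   table's groups).
#' @return list with `f_max`, `completeness`, `n_expected`, `n_present`.
#' @export
estimate_f_max <- function(peaks, assignments, groups = assignments$groups) {
  if (nrow(peaks) == 0L) stop("empty peak list")
  g <- groups[!is.na(groups$shift), , drop = FALSE]
  rank <- heavy_rank(g$heavy_name)
  expected <- character(0)
  for (ri in unique(g$residue_index)) {
    idx <- which(g$residue_index == ri & !is.na(rank))
    if (length(idx) < 2L) next
    for (i in seq_along(idx)[-length(idx)]) {
      for (j in seq.int(i + 1L, length(idx))) {
        if (abs(rank[idx[i]] - rank[idx[j]]) <= 2L) {
          expected <- c(expected, edge_key(g$key[idx[i]], g$key[idx[j]]))
        }
      }
    }
  }
  expected <- unique(expected)
  if (length(expected) == 0L) stop("no 2-4 bond proton pairs to assess")
  anoe <- build_anoe_network(peaks, assignments)
  present_keys <- unique(unlist(anoe$candidates))
  n_present <- sum(expected %in% present_keys)
  c_ <- n_present / length(expected)
  list(f_max = 2 * c_ / (1 + c_), completeness = c_,
       n_expected = length(expected), n_present = n_present)
}

#' Lower F-measure bound from a random-coil null model
#'
#' Estimates `F(G_free)`: the F-measure that a structureless chain would
#' score against the same NOESY data. Freely-rotating virtual-bond chains
#' are sampled (see [sample_freely_rotating_chain]), each chain's distance
#' network is scored against the ambiguous NOE network through the same
#' scoring path as any model, and the mean F-measure is returned.
#'
#' @param assignments an [assignment_table]; its group universe defines the
#'   chain's proton mapping.
#' @param anoe an `anoe_network` built from the peaks being scored.
#' @param n_residues chain length (use the scored protein's length).
#' @param n_samples number of sampled chains (default 100).
#' @param seed RNG seed.
#' @param d_noe_max distance cutoff, Angstrom.
#' @inheritParams score_rpf
#' @return list with `f_free`, `f_values` (per-chain), `n_samples`, `seed`.
#' @export
estimate_f_free <- function(assignments, anoe, n_residues, n_samples = 100,
                            seed = 1, d_noe_max = 5,
                            weighting = c("distance", "uniform")) {
  weighting <- match.arg(weighting)
  chains <- sample_freely_rotating_chain(n_residues, n_samples, seed)
  groups <- assignments$groups
  f_values <- vapply(chains, function(chain) {
    chain <- complete_chain_atoms(chain, groups)
    net <- build_model_network(chain, groups, d_noe_max)
    score_rpf(net, anoe, weighting)$f_measure
  }, numeric(1))
  list(f_free = mean(f_values), f_values = f_values,
       n_samples = n_samples, seed = seed)
}

# coil chains carry a generic proton set (H, HA, HB1-3); any further member
# atoms required by the group universe are represented by the residue's
# side-chain centroid so arbitrary assignment tables can be scored
complete_chain_atoms <- function(chain, groups) {
  a <- chain$atoms
  akey <- paste(a$residue_index, a$atom_name)
  need_res <- rep(groups$residue_index, lengths(groups$members))
  need_atom <- unlist(groups$members)
  miss <- !(paste(need_res, need_atom) %in% akey)
  if (!any(miss)) return(chain)
  add <- unique(data.frame(residue_index = need_res[miss],
                           atom_name = need_atom[miss],
                           stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(add)), function(i) {
    rr <- a[a$residue_index == add$residue_index[i], , drop = FALSE]
    if (nrow(rr) == 0L) return(NULL)
    sc <- rr[rr$atom_name %in% c("HB1", "HB2", "HB3"), c("x", "y", "z")]
    pos <- if (nrow(sc) > 0L) colMeans(sc) else
      as.numeric(rr[rr$atom_name == "CA", c("x", "y", "z")][1L, ])
    row <- rr[1L, , drop = FALSE]
    row$atom_name <- add$atom_name[i]
    row$element <- "H"
    row$x <- pos[1]; row$y <- pos[2]; row$z <- pos[3]
    row
  })
  a <- rbind(a, do.call(rbind, rows))
  a <- a[order(a$residue_index), , drop = FALSE]
  rownames(a) <- NULL
  conformer(a)
}

#' Discriminating power from an F-measure and its bounds
#'
#' Rescales an F-measure between the random-coil lower bound (`DP = 0`) and
#' the data-completeness upper bound (`DP = 1`):
#' `DP = (F - F_free) / (F_max - F_free)`, capped at 1 above but not below
#' — a model fitting the data worse than a random coil scores negative.
#'
#' @param f F-measure of the model.
#' @param f_free random-coil baseline F (see [estimate_f_free]).
#' @param f_max completeness bound (see [estimate_f_max]).
#' @return DP score (numeric, at most 1, possibly negative).
#' @export
dp_score <- function(f, f_free, f_max) {
  if (f_free >= f_max) {
    stop("f_free must be smaller than f_max (normalization undefined)")
  }
  min((f - f_free) / (f_max - f_free), 1)
}

#' RPF-DP scores for a structure ensemble
#'
#' Runs the full RPF-DP analysis: builds the ambiguous NOE network from the
#' peak list and assignments, estimates the normalization bounds, scores
#' each conformer (DP per conformer, averaged as `dp_avg` along with
#' `r_avg`, `p_avg`, `f_avg`), and scores the ensemble-averaged distance
#' network (`dp_ensemble`, the `<DP>` score). `<DP>` typically exceeds
#' `dp_avg`, increasingly so for diverse ensembles whose pooled short
#' contacts explain peaks no single conformer explains.
#'
#' @param ensemble a [structure_ensemble] (or single [conformer]).
#' @param peaks NOESY peak data frame (see [build_anoe_network]).
#' @param assignments an [assignment_table].
#' @param d_noe_max distance cutoff, Angstrom (default 5).
#' @param weighting precision weighting mode, see [score_rpf].
#' @param n_free_samples,seed random-coil baseline sampling controls.
#' @return list of class `dp_result`: `dp_per_conformer`, `dp_avg`,
#'   `dp_ensemble`, `scores_per_conformer`, `r_avg`, `p_avg`, `f_avg`,
#'   `f_free`, `f_max`, `anoe`.
#' @export
ensemble_dp <- function(ensemble, peaks, assignments, d_noe_max = 5,
                        weighting = c("distance", "uniform"),
                        n_free_samples = 100, seed = 1) {
  weighting <- match.arg(weighting)
  if (inherits(ensemble, "conformer")) {
    ensemble <- structure_ensemble(list(ensemble))
  }
  groups <- assignments$groups
  anoe <- build_anoe_network(peaks, assignments)
  fmax <- estimate_f_max(peaks, assignments, groups)
  n_res <- length(unique(ensemble$conformers[[1L]]$atoms$residue_index))
  ffree <- estimate_f_free(assignments, anoe, n_res, n_free_samples, seed,
                           d_noe_max, weighting)
  scores <- lapply(ensemble$conformers, function(conf) {
    net <- build_model_network(conf, groups, d_noe_max)
    score_rpf(net, anoe, weighting)
  })
  dp_per <- vapply(scores, function(s) {
    dp_score(s$f_measure, ffree$f_free, fmax$f_max)
  }, numeric(1))
  ens_net <- build_model_network(ensemble, groups, d_noe_max)
  ens_scores <- score_rpf(ens_net, anoe, weighting)
  structure(list(
    dp_per_conformer = dp_per,
    dp_avg = mean(dp_per),
    dp_ensemble = dp_score(ens_scores$f_measure, ffree$f_free, fmax$f_max),
    scores_per_conformer = scores,
    scores_ensemble = ens_scores,
    r_avg = mean(vapply(scores, `[[`, numeric(1), "recall")),
    p_avg = mean(vapply(scores, `[[`, numeric(1), "precision")),
    f_avg = mean(vapply(scores, `[[`, numeric(1), "f_measure")),
    f_free = ffree$f_free, f_max = fmax$f_max,
    anoe = anoe), class = "dp_result")
}

#' @export
print.dp_result <- function(x, ...) {
  cat(sprintf("<DP> = %.3f  DP_avg = %.3f  R_avg = %.3f  P_avg = %.3f  F_avg = %.3f\n",
              x$dp_ensemble, x$dp_avg, x$r_avg, x$p_avg, x$f_avg))
  cat(sprintf("  normalization: F_free = %.3f, F_max = %.3f\n",
              x$f_free, x$f_max))
  invisible(x)
}

#' Calibrate the NOE distance cutoff from the data
#'
#' Heuristic calibration of `d_noe_max`: the smallest cutoff among the
#' candidates that maximizes the F-measure of the query model set against
#' the peak list. A convenience only; the conventional default is 5
#' Angstrom.
#'
#' @inheritParams ensemble_dp
#' @param candidates cutoffs to try, Angstrom.
#' @return the selected cutoff (Angstrom).
#' @export
calibrate_d_noe_max <- function(ensemble, peaks, assignments,
                                candidates = c(4.5, 5, 5.5, 6),
                                weighting = c("distance", "uniform")) {
  weighting <- match.arg(weighting)
  if (inherits(ensemble, "conformer")) {
    ensemble <- structure_ensemble(list(ensemble))
  }
  anoe <- build_anoe_network(peaks, assignments)
  f <- vapply(candidates, function(dm) {
    mean(vapply(ensemble$conformers, function(conf) {
      net <- build_model_network(conf, assignments$groups, dm)
      score_rpf(net, anoe, weighting)$f_measure
    }, numeric(1)))
  }, numeric(1))
  candidates[which.max(f)]   # which.max takes the first (smallest) maximizer
}
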