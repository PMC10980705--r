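# Ensemble-level fractions and the xHAT nucleation-propensity score.

#' Summarise an ensemble into hairpin/coil/beta fractions and the xHAT score
#'
#' Runs the per-frame pipeline (H-bond detection, hairpin registry
#' classification, secondary-structure assignment) over every frame and
#' aggregates with frame weights:
#' \itemize{
#'   \item \code{f_even}, \code{f_odd}: weighted fraction of frames whose
#'     registry is even / odd;
#'   \item \code{f_coil}: weighted sum of hexapeptide coil counts divided by
#'     the normalisation constant 6 x (weighted frames) -- the probability
#'     that a hexapeptide residue is random coil, with hairpin frames
#'     excluded (orthogonality);
#'   \item \code{f_beta_hex}: weighted fraction of frames in which every
#'     residue of \code{beta_hex_residues} is extended sheet "E";
#'   \item \code{S_xHAT}: \code{f_odd * f_even^2}.
#' }
#' Duplicating every frame (or permuting frame order) leaves all fractions
#' unchanged.
#'
#' @param ensemble an \code{\link{ensemble}}.
#' @param regions a \code{\link{make_region_map}} object.
#' @param mutant_id identifier copied into the output row.
#' @param beta_hex_residues residues (author numbering) that must all be "E"
#'   for the beta-content flag; defaults to the full hexapeptide.
#' @param keep_frames also return the per-frame table as attribute
#'   \code{"frames"}.
#' @param ... passed to \code{\link{classify_hairpin}}.
#' @return one-row data.frame with columns \code{mutant_id},
#'   \code{n_frames}, \code{f_even}, \code{f_odd}, \code{f_coil},
#'   \code{f_beta_hex}, \code{S_xHAT}.
#' @export
summarize_ensemble <- function(ensemble, regions, mutant_id = "ensemble",
                               beta_hex_residues = regions$hexapeptide,
                               keep_frames = FALSE, ...) {
  stopifnot(inherits(ensemble, "ensemble"))
  n <- length(ensemble$conformers)
  if (n == 0) stop("empty ensemble")
  w <- vapply(ensemble$conformers, function(cf) cf$weight, numeric(1))
  if (sum(w) <= 0) stop("sum of frame weights must be positive")

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cf <- ensemble$conformers[[i]]
    hb <- detect_backbone_hbonds(cf)
    asg <- classify_hairpin(cf, regions, hbonds = hb, ...)
    ss <- assign_secondary_structure(cf)
    fl <- frame_flags(cf, regions, asg, ss)
    beta_int <- beta_hex_residues - cf$offset
    rows[[i]] <- data.frame(
      frame_id = cf$frame_id, weight = w[i], registry = asg$registry,
      n_bonds = nrow(asg$support_bonds),
      coil_count = fl$coil_count_hex, coil_count_raw = fl$coil_count_raw,
      all_E = all(ss[beta_int] == "E"), stringsAsFactors = FALSE)
  }
  frames <- do.call(rbind, rows)

  wsum <- sum(w)
  f_even <- sum(w[frames$registry == "even"]) / wsum
  f_odd <- sum(w[frames$registry == "odd"]) / wsum
  f_coil <- sum(w * frames$coil_count) / (6 * wsum)
  f_beta <- sum(w[frames$all_E]) / wsum
  out <- data.frame(mutant_id = mutant_id, n_frames = n,
                    f_even = f_even, f_odd = f_odd, f_coil = f_coil,
                    f_beta_hex = f_beta,
                    S_xHAT = xhat_score(f_even, f_odd),
                    stringsAsFactors = FALSE)
  if (keep_frames) attr(out, "frames") <- frames
  out
}

#' xHAT nucleation-propensity score
#'
#' The cross-beta hairpin amyloid trimer score S = f_odd * f_even^2: the
#' transition-state trimer requires two even-registry hairpins plus one
#' registry-shifted (odd) hairpin, so the score is the product of the
#' ensemble probabilities of drawing that combination.  Maximal value 4/27
#' at (f_even, f_odd) = (2/3, 1/3) on the simplex f_even + f_odd = 1.
#'
#' @param f_even,f_odd hairpin registry fractions, non-negative with
#'   \code{f_even + f_odd <= 1}.
#' @return \code{f_odd * f_even^2}.
#' @export
xhat_score <- function(f_even, f_odd) {
  if (any(f_even < 0) || any(f_odd < 0) || any(f_even + f_odd > 1 + 1e-9))
    stop("(f_even, f_odd) must lie in the probability simplex")
  f_odd * f_even^2
}

#' Rank mutants by a structural metric
#'
#' Ranks descending (largest metric = rank 1) with ties assigned the
#' average rank.
#'
#' @param summaries data.frame of \code{\link{summarize_ensemble}} rows.
#' @param key one of \code{"S_xHAT"}, \code{"f_coil"}, \code{"hairpin"}
#'   (= f_even + f_odd, the total hairpin content), \code{"f_beta_hex"}.
#' @return data.frame (mutant_id, value, rank) sorted by rank.
#' @export
rank_mutants <- function(summaries,
                         key = c("S_xHAT", "f_coil", "hairpin", "f_beta_hex")) {
  key <- match.arg(key)
  if (nrow(summaries) < 2) stop("need at least 2 summaries to rank")
  if (anyDuplicated(summaries$mutant_id))
    stop("duplicate mutant ids in summaries")
  value <- switch(key,
                  S_xHAT = summaries$S_xHAT,
                  f_coil = summaries$f_coil,
                  hairpin = summaries$f_even + summaries$f_odd,
                  f_beta_hex = summaries$f_beta_hex)
  rk <- rank(-value, ties.method = "average")
  out <- data.frame(mutant_id = summaries$mutant_id, value = value, rank = rk,
                    stringsAsFactors = FALSE)
  out[order(out$rank), , drop = FALSE]
}
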