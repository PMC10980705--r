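# k18 repeat-domain statistics: local hairpins around each PGGG motif,
# inter-hexapeptide beta pairing, segment beta totals, SASA differentials.

#' Repeat-domain specification for tau k18
#'
#' Defines, in author numbering, the four aggregation-prone hexapeptides at
#' the start of each repeat (1: 275-280 VQIINK/PHF6*, 2: 306-311
#' VQIVYK/PHF6, 3: 337-342 VEVKSE/Module-B, 4: 369-374 KKIETH), their
#' N-terminal flanking sites (1': 264-268, 2': 295-299, 3': 325-329,
#' 4': 357-361) and the four PGGG turn motifs.  Ranges extending past the
#' available sequence (hexapeptide 4 runs past the k18 terminus at 372) are
#' clipped with a warning.
#'
#' @param sequence one-letter sequence (default \code{\link{tau_k18_sequence}}).
#' @param numbering_offset author id = internal index + offset (243 for k18).
#' @param hexapeptides,flanks,pggg_motifs lists of 4 author-numbered integer
#'   ranges overriding the defaults.
#' @return object of class \code{"repeat_spec"}.
#' @export
make_repeat_spec <- function(sequence = tau_k18_sequence(),
                             numbering_offset = 243L,
                             hexapeptides = list(275:280, 306:311,
                                                 337:342, 369:374),
                             flanks = list(264:268, 295:299,
                                           325:329, 357:361),
                             pggg_motifs = list(270:273, 301:304,
                                                332:335, 364:367)) {
  stopifnot(length(hexapeptides) == 4, length(flanks) == 4,
            length(pggg_motifs) == 4)
  lo <- numbering_offset + 1L
  hi <- numbering_offset + nchar(sequence)
  clip <- function(ranges, what) {
    lapply(seq_along(ranges), function(k) {
      r <- as.integer(ranges[[k]])
      kept <- r[r >= lo & r <= hi]
      if (length(kept) < length(r))
        warning(sprintf("%s %d clipped to %d-%d (sequence covers %d-%d)",
                        what, k, min(kept), max(kept), lo, hi), call. = FALSE)
      if (length(kept) == 0) stop(what, " ", k, " entirely outside sequence")
      sort(kept)
    })
  }
  hexapeptides <- clip(hexapeptides, "hexapeptide")
  flanks <- clip(flanks, "flank")
  pggg_motifs <- clip(pggg_motifs, "PGGG motif")
  all_hex <- unlist(hexapeptides)
  if (anyDuplicated(all_hex)) stop("hexapeptide ranges overlap")
  for (k in 1:4) {
    if (max(pggg_motifs[[k]]) >= min(hexapeptides[[k]]))
      stop("hexapeptide ", k, " must lie downstream of its PGGG motif")
  }
  structure(list(sequence = sequence,
                 numbering_offset = as.integer(numbering_offset),
                 hexapeptides = hexapeptides, flanks = flanks,
                 pggg_motifs = pggg_motifs),
            class = "repeat_spec")
}

#' @export
print.repeat_spec <- function(x, ...) {
  cat("<repeat_spec>", nchar(x$sequence), "residues, offset",
      sprintf("%+d", x$numbering_offset), "\n")
  for (k in 1:4)
    cat(sprintf("  hex %d: %d-%d  flank %d': %d-%d  PGGG: %d-%d\n", k,
                min(x$hexapeptides[[k]]), max(x$hexapeptides[[k]]), k,
                min(x$flanks[[k]]), max(x$flanks[[k]]),
                min(x$pggg_motifs[[k]]), max(x$pggg_motifs[[k]])))
  invisible(x)
}

# RegionMap for the local hairpin around PGGG motif k: the hexapeptide k is
# the C-terminal strand; the N-arm is the flank extended upstream to (but
# not including) the previous hexapeptide.  Parity sets follow the tau
# 295-311 layout relative to the first hexapeptide residue h1: even
# {h1, h1+2, h1+4}, odd {h1-1, h1+1, h1+3}.
.local_region_map <- function(spec, k) {
  hex <- spec$hexapeptides[[k]]
  h1 <- min(hex)
  lo <- spec$numbering_offset + 1L
  arm_start <- if (k == 1) lo else max(spec$hexapeptides[[k - 1]]) + 1L
  hi_seq <- spec$numbering_offset + nchar(spec$sequence)
  keep_in <- function(v) v[v >= lo & v <= hi_seq]
  make_region_map(spec$sequence,
                  spec = list(hexapeptide = hex,
                              scored_hex = keep_in(h1:(h1 + 4)),
                              even_set = keep_in(c(h1, h1 + 2, h1 + 4)),
                              odd_set = keep_in(c(h1 - 1, h1 + 1, h1 + 3)),
                              n_arm = arm_start:(h1 - 2L),
                              excluded_termini = integer(0),
                              turn = (h1 - 5L):(h1 - 2L)),
                  numbering_offset = spec$numbering_offset)
}

#' Local hairpin probability around one PGGG motif
#'
#' Fraction of frames in which hexapeptide k forms a hairpin with its
#' upstream flanking segment, using the \code{\link{classify_hairpin}}
#' criteria with a region map built from (hexapeptide k, flank extended to
#' the inter-motif segment).  Registry parity is not restricted: any
#' registry counts as a local hairpin.
#'
#' @param ensemble an \code{\link{ensemble}} of repeat-domain frames.
#' @param spec a \code{\link{make_repeat_spec}} object.
#' @param k motif index 1-4 (H1..H4).
#' @param ... passed to \code{\link{classify_hairpin}}.
#' @return weighted probability in [0, 1].
#' @export
local_hairpin_probability <- function(ensemble, spec, k, ...) {
  if (!(k %in% 1:4)) stop("k must be 1, 2, 3 or 4")
  regions <- .local_region_map(spec, k)
  w <- vapply(ensemble$conformers, function(cf) cf$weight, numeric(1))
  hit <- vapply(ensemble$conformers, function(cf) {
    classify_hairpin(cf, regions, ...)$registry != "none"
  }, logical(1))
  sum(w[hit]) / sum(w)
}

#' Inter-hexapeptide beta-pairing probability matrix
#'
#' \code{pairwise[i, j]} is the weighted fraction of frames with at least
#' \code{min_bonds} backbone H-bonds between residues of hexapeptide i and
#' hexapeptide j (any direction, any registry).  The matrix is symmetric
#' with an unused diagonal.  Local hairpin probabilities H1-H4 are included
#' alongside.
#'
#' @param ensemble an \code{\link{ensemble}}.
#' @param spec a \code{\link{make_repeat_spec}} object.
#' @param min_bonds bonds required to call a pairing event (default 2).
#' @param cutoff H-bond distance cutoff (A).
#' @param include_local also compute H1-H4 local hairpin probabilities
#'   (default TRUE).
#' @return object of class \code{"pairing_matrix"}: list with \code{local}
#'   (named numeric H1..H4, or NULL), \code{pairwise} (symmetric 4x4),
#'   \code{n_frames}.
#' @export
interhexapeptide_pairing <- function(ensemble, spec, min_bonds = 2,
                                     cutoff = 3.5, include_local = TRUE) {
  w <- vapply(ensemble$conformers, function(cf) cf$weight, numeric(1))
  wsum <- sum(w)
  acc <- matrix(0, 4, 4)
  for (fidx in seq_along(ensemble$conformers)) {
    cf <- ensemble$conformers[[fidx]]
    hb <- detect_backbone_hbonds(cf, cutoff = cutoff)
    for (i in 1:3) for (j in (i + 1):4) {
      hi <- spec$hexapeptides[[i]]; hj <- spec$hexapeptides[[j]]
      nb <- sum((hb$donor_residue %in% hi & hb$acceptor_residue %in% hj) |
                (hb$donor_residue %in% hj & hb$acceptor_residue %in% hi))
      if (nb >= min_bonds) acc[i, j] <- acc[i, j] + w[fidx]
    }
  }
  pairwise <- (acc + t(acc)) / wsum
  diag(pairwise) <- NA_real_
  dimnames(pairwise) <- list(paste0("hex", 1:4), paste0("hex", 1:4))
  local <- NULL
  if (include_local) {
    local <- vapply(1:4, function(k)
      local_hairpin_probability(ensemble, spec, k, cutoff = cutoff),
      numeric(1))
    names(local) <- paste0("H", 1:4)
  }
  structure(list(local = local, pairwise = pairwise,
                 n_frames = length(ensemble$conformers)),
            class = "pairing_matrix")
}

#' @export
print.pairing_matrix <- function(x, ...) {
  cat("<pairing_matrix>", x$n_frames, "frames\n")
  if (!is.null(x$local)) {
    cat("  local hairpins: ",
        paste(sprintf("%s=%.3f", names(x$local), x$local), collapse = "  "),
        "\n")
  }
  print(round(x$pairwise, 3))
  invisible(x)
}

#' Total beta formation for one hexapeptide segment
#'
#' Sum of the local hairpin probability of segment k and selected
#' inter-hexapeptide pairing probabilities involving it (e.g. the
#' hexapeptide-2 total combines H2 with the 2-3 pairing).  Because the
#' underlying events may overlap, a total above 1 is permitted but
#' triggers a warning.
#'
#' @param local_k local hairpin probability in [0, 1].
#' @param pairwise_row numeric vector of pairing probabilities in [0, 1]
#'   selected by the caller.
#' @return \code{local_k + sum(pairwise_row)}.
#' @export
total_beta_for_segment <- function(local_k, pairwise_row) {
  vals <- c(local_k, pairwise_row)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1))
    stop("probabilities must lie in [0, 1]")
  total <- local_k + sum(pairwise_row)
  if (total > 1)
    warning("total beta formation exceeds 1; component events may overlap")
  total
}

#' Per-residue SASA differential between two ensembles
#'
#' Ensemble-mean solvent-accessible surface area of \code{ensemble_a} minus
#' that of \code{ensemble_b}, per residue (frame weights respected).  Sign
#' convention: positive values mean \code{a} is more solvent-exposed at
#' that residue.
#'
#' @param ensemble_a,ensemble_b ensembles over equal-length sequences
#'   (e.g. wild type and a point mutant).
#' @param ... passed to \code{\link{compute_sasa}}.
#' @return data.frame with \code{resno} (author numbering of \code{a}),
#'   \code{sasa_a}, \code{sasa_b}, \code{delta_sasa}.
#' @export
sasa_differential <- function(ensemble_a, ensemble_b, ...) {
  if (nchar(ensemble_a$sequence) != nchar(ensemble_b$sequence))
    stop("ensembles must have equal sequence lengths")
  mean_sasa <- function(ens) {
    w <- vapply(ens$conformers, function(cf) cf$weight, numeric(1))
    acc <- NULL
    for (i in seq_along(ens$conformers)) {
      s <- compute_sasa(ens$conformers[[i]], ...)
      acc <- if (is.null(acc)) w[i] * s$sasa else acc + w[i] * s$sasa
    }
    acc / sum(w)
  }
  sa <- mean_sasa(ensemble_a)
  sb <- mean_sasa(ensemble_b)
  data.frame(resno = seq_len(nchar(ensemble_a$sequence)) +
               ensemble_a$numbering_offset,
             sasa_a = sa, sasa_b = sb, delta_sasa = sa - sb)
}
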