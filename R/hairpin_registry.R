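# Per-frame hairpin classification (even/odd registry) and frame flags.

#' Classify a frame as even-registry hairpin, odd-registry hairpin, or none
#'
#' A frame is a hairpin when (1) the scored hexapeptide residues all lie
#' within the hairpin span, and (2) hexapeptide residues internally bound to
#' N-arm residues form proper backbone hydrogen bonds (heavy-atom N-O
#' distance criterion, either donor orientation).  The span is delimited by
#' the outermost hexapeptide residues carrying cross-arm bonds, extended by
#' \code{span_slack} residues on each side: antiparallel ladders alternate
#' hydrogen-bonded and non-bonded rungs, so the sheet extends one residue
#' past the outermost bonded rung.  At least two cross-arm-bonded
#' hexapeptide residues are required.  The registry is \code{"even"}
#' (\code{"odd"}) when the bonded hexapeptide residues are a pure subset of
#' the even (odd) parity set with at least \code{min_parity_bonds} members;
#' mixed parity gives \code{"none"} unless \code{allow_mixed}.  Cross-arm
#' partners must decrease strictly as the hexapeptide index increases
#' (antiparallel geometry); violations give \code{"none"} with a reason.
#'
#' @param frame a \code{\link{conformer}}.
#' @param regions a \code{\link{make_region_map}} object.
#' @param hbonds optional precomputed \code{\link{detect_backbone_hbonds}}
#'   table; computed at \code{cutoff} when NULL.
#' @param cutoff H-bond heavy-atom distance cutoff (A).
#' @param min_parity_bonds minimum number of one-parity bonded residues
#'   (default 2).
#' @param allow_mixed accept mixed-parity bonding, assigning the majority
#'   parity (default FALSE, the strictest rule).
#' @param span_slack residues by which the hairpin span extends past the
#'   outermost bonded rung on each side (default 1).
#' @return object of class \code{"hairpin_assignment"}: list with
#'   \code{registry} ("even"/"odd"/"none"), \code{pairing} (named integer
#'   vector, hexapeptide residue -> N-arm partner), \code{support_bonds}
#'   (the cross-arm H-bond table), \code{span_ok}, and \code{reason}.
#' @export
classify_hairpin <- function(frame, regions, hbonds = NULL, cutoff = 3.5,
                             min_parity_bonds = 2, allow_mixed = FALSE,
                             span_slack = 1) {
  if (is.null(hbonds)) hbonds <- detect_backbone_hbonds(frame, cutoff = cutoff)
  hex_side <- sort(unique(c(regions$scored_hex, regions$even_set,
                            regions$odd_set)))
  arm <- regions$n_arm

  none <- function(reason, span_ok = FALSE, pairing = integer(0),
                   bonds = hbonds[0, ]) {
    structure(list(registry = "none", pairing = pairing,
                   support_bonds = bonds, span_ok = span_ok, reason = reason),
              class = "hairpin_assignment")
  }

  fwd <- hbonds$donor_residue %in% hex_side & hbonds$acceptor_residue %in% arm
  rev <- hbonds$donor_residue %in% arm & hbonds$acceptor_residue %in% hex_side
  cross <- hbonds[fwd | rev, , drop = FALSE]
  if (nrow(cross) == 0) return(none("no cross-arm bonds"))
  hex_res <- as.integer(ifelse(cross$donor_residue %in% hex_side,
                               cross$donor_residue, cross$acceptor_residue))
  arm_res <- as.integer(ifelse(cross$donor_residue %in% hex_side,
                               cross$acceptor_residue, cross$donor_residue))

  bonded <- sort(unique(hex_res))
  if (length(bonded) < 2)
    return(none("fewer than 2 cross-arm bonded hexapeptide residues",
                bonds = cross))

  # one partner per bonded hexapeptide residue: the shortest-distance bond
  pairing <- vapply(bonded, function(r) {
    sel <- hex_res == r
    arm_res[sel][which.min(cross$distance[sel])]
  }, integer(1))
  names(pairing) <- bonded

  n_even <- sum(bonded %in% regions$even_set)
  n_odd <- sum(bonded %in% regions$odd_set)
  n_other <- length(bonded) - n_even - n_odd
  registry <- if (n_even >= min_parity_bonds && n_odd == 0 && n_other == 0) {
    "even"
  } else if (n_odd >= min_parity_bonds && n_even == 0 && n_other == 0) {
    "odd"
  } else if (allow_mixed && max(n_even, n_odd) >= min_parity_bonds) {
    if (n_even >= n_odd) "even" else "odd"
  } else if (n_even > 0 && n_odd > 0) {
    return(none("mixed registry", pairing = pairing, bonds = cross))
  } else {
    return(none("too few bonded residues of one parity",
                pairing = pairing, bonds = cross))
  }

  span <- c(min(bonded) - span_slack, max(bonded) + span_slack)
  span_ok <- all(regions$scored_hex >= span[1] & regions$scored_hex <= span[2])
  if (!span_ok)
    return(none("scored hexapeptide not fully within hairpin span",
                pairing = pairing, bonds = cross))

  if (any(diff(pairing) >= 0))
    return(none("not antiparallel (partners do not strictly decrease)",
                span_ok = TRUE, pairing = pairing, bonds = cross))

  structure(list(registry = registry, pairing = pairing,
                 support_bonds = cross, span_ok = TRUE, reason = ""),
            class = "hairpin_assignment")
}

#' @export
print.hairpin_assignment <- function(x, ...) {
  cat(sprintf("<hairpin_assignment> registry = %s", x$registry))
  if (x$registry == "none") cat(sprintf(" (%s)", x$reason))
  if (length(x$pairing) > 0)
    cat("\n  pairing: ",
        paste(sprintf("%s->%d", names(x$pairing), x$pairing), collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Per-frame hairpin/coil flags
#'
#' Combines a hairpin assignment with a secondary-structure string into the
#' per-frame counters aggregated by \code{\link{summarize_ensemble}}.  The
#' hairpin and random-coil metrics are mutually orthogonal: when the frame
#' is classified as a hairpin (either registry), its hexapeptide coil count
#' is zeroed so that no fold is counted in both categories.  The pre-zeroing
#' count is retained as \code{coil_count_raw} for diagnostics.
#'
#' @param frame a \code{\link{conformer}}.
#' @param regions a \code{\link{make_region_map}} object.
#' @param assignment a \code{\link{classify_hairpin}} result.
#' @param ss per-residue secondary-structure codes
#'   (\code{\link{assign_secondary_structure}} vector, or a single string).
#' @return list with \code{is_even}, \code{is_odd}, \code{coil_count_hex}
#'   (0-6), \code{coil_count_raw}, and \code{all_E_hex}.
#' @export
frame_flags <- function(frame, regions, assignment, ss) {
  if (length(ss) == 1 && nchar(ss) > 1) ss <- strsplit(ss, "")[[1]]
  L <- .n_res(frame)
  if (length(ss) != L)
    stop("secondary-structure length does not match residue count")
  hex_internal <- regions$hexapeptide - frame$offset
  if (any(hex_internal < 1 | hex_internal > L))
    stop("hexapeptide residues outside frame")
  hex_ss <- ss[hex_internal]
  raw <- sum(hex_ss == "C")
  is_even <- assignment$registry == "even"
  is_odd <- assignment$registry == "odd"
  list(is_even = is_even, is_odd = is_odd,
       coil_count_hex = if (is_even || is_odd) 0L else raw,
       coil_count_raw = raw,
       all_E_hex = all(hex_ss == "E"))
}
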