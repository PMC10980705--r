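# Shared fixtures built in code (no stored data).

tau_regions <- function() make_region_map(tau295_sequence())

k18_spec <- function() suppressWarnings(make_repeat_spec())

# brute-force all-pairs N-O scan: the independent oracle for the H-bond
# detector (no shared code path with detect_backbone_hbonds)
brute_force_hbonds <- function(frame, cutoff = 3.5, min_sep = 2) {
  at <- frame$atoms
  res <- sort(unique(at$resno))
  out <- NULL
  for (i in res) for (j in res) {
    if (abs(i - j) < min_sep) next
    ni <- which(at$resno == i & at$elety == "N")
    oj <- which(at$resno == j & at$elety == "O")
    if (length(ni) == 0 || length(oj) == 0) next
    d <- sqrt(sum((frame$xyz[ni, ] - frame$xyz[oj, ])^2))
    if (d <= cutoff + 1e-9)
      out <- rbind(out, data.frame(donor_residue = i + frame$offset,
                                   acceptor_residue = j + frame$offset,
                                   distance = d))
  }
  if (is.null(out)) {
    return(data.frame(donor_residue = integer(0),
                      acceptor_residue = integer(0), distance = numeric(0)))
  }
  out[order(out$donor_residue, out$acceptor_residue), , drop = FALSE]
}

# textbook Spearman with tie correction, computed from scratch (oracle)
spearman_textbook <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  # Pearson on average ranks equals tie-corrected Spearman
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# a minimal three-residue conformer with the N(1)-O(3) distance set exactly
# (all other N-O pairs far apart)
pair_distance_frame <- function(no_dist) {
  atoms <- data.frame(resno = rep(1:3, each = 4),
                      resid = "ALA",
                      elety = rep(c("N", "CA", "C", "O"), 3))
  xyz <- rbind(
    c(0, 0, 0), c(1.46, 0, 0), c(2.2, 0, 1.2), c(2.2, 0, 2.4),
    c(0, 20, 0), c(1.46, 20, 0), c(2.2, 20, 1.2), c(2.2, 20, 2.4),
    c(0, 40, 0), c(1.46, 40, 0), c(2.9, 40, 1.2), c(no_dist, 0, 0))
  conformer(xyz, atoms)
}

# rigid motion helper
apply_rigid <- function(xyz, angle = 0.7, axis = c(1, 2, 2),
                        shift = c(5, -3, 2)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  sweep(xyz %*% t(R), 2, shift, "+")
}
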