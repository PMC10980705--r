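# Per-frame geometric primitives: backbone hydrogen bonds, DSSP-style
# secondary structure, Shrake-Rupley SASA, Kabsch superposition RMSD.

#' Detect backbone hydrogen bonds by heavy-atom distance
#'
#' Reports one bond per (donor amide N, acceptor carbonyl O) pair whose
#' N-O distance is at or below \code{cutoff} (3.5 A by default, inclusive),
#' excluding self and adjacent residues (|i - j| >= 2).  No angular term is
#' applied by default; an optional donor-H/acceptor angle filter is
#' available for sensitivity analysis.
#'
#' @param frame a \code{\link{conformer}}.
#' @param cutoff heavy-atom N-O distance cutoff in Angstrom (inclusive).
#' @param min_sep minimum residue separation |i - j| (default 2).
#' @param angle_min optional minimum N-H...O angle in degrees; when set,
#'   amide hydrogens are taken from the frame or reconstructed and bonds
#'   with a smaller angle are dropped (donors without H, e.g. proline and
#'   the N-terminus, are kept).
#' @return data.frame with columns \code{donor_residue},
#'   \code{acceptor_residue} (author numbering) and \code{distance},
#'   sorted by (donor, acceptor).
#' @export
detect_backbone_hbonds <- function(frame, cutoff = 3.5, min_sep = 2,
                                   angle_min = NULL) {
  N <- .atom_xyz(frame, "N")
  O <- .atom_xyz(frame, "O")
  L <- nrow(N)
  d2 <- outer(rowSums(N^2), rowSums(O^2), "+") - 2 * N %*% t(O)
  d2[d2 < 0] <- 0
  sep <- abs(outer(seq_len(L), seq_len(L), "-"))
  hit <- which(d2 <= cutoff^2 + 1e-9 & sep >= min_sep, arr.ind = TRUE)
  if (nrow(hit) == 0) {
    return(data.frame(donor_residue = integer(0), acceptor_residue = integer(0),
                      distance = numeric(0)))
  }
  don <- hit[, 1]; acc <- hit[, 2]
  dist <- sqrt(d2[hit])
  if (!is.null(angle_min)) {
    H <- .amide_h_xyz(frame)
    keep <- rep(TRUE, length(don))
    for (k in seq_along(don)) {
      h <- H[don[k], ]
      if (anyNA(h)) next
      v1 <- N[don[k], ] - h
      v2 <- O[acc[k], ] - h
      ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) / (.vnorm(v1) * .vnorm(v2)))))
      keep[k] <- (ang * 180 / pi) >= angle_min
    }
    don <- don[keep]; acc <- acc[keep]; dist <- dist[keep]
  }
  ord <- order(don, acc)
  data.frame(donor_residue = don[ord] + frame$offset,
             acceptor_residue = acc[ord] + frame$offset,
             distance = dist[ord])
}

# Amide hydrogen coordinates for all residues: taken from the frame where
# present, reconstructed (1.0 A from N on the bisector-opposed direction of
# C(i-1)-N-CA) where absent; NA for residue 1 and prolines without H.
.amide_h_xyz <- function(frame) {
  N <- .atom_xyz(frame, "N")
  CA <- .atom_xyz(frame, "CA")
  C <- .atom_xyz(frame, "C")
  H <- .atom_xyz(frame, "H", required = FALSE)
  L <- nrow(N)
  first <- match(seq_len(L), frame$atoms$resno)
  is_pro <- frame$atoms$resid[first] == "PRO"
  for (i in seq_len(L)) {
    if (!anyNA(H[i, ])) next
    if (i == 1 || is_pro[i]) next
    H[i, ] <- .place_amide_h(N[i, ], CA[i, ], C[i - 1, ])
  }
  H[1, ] <- NA_real_
  H[is_pro, ] <- NA_real_
  H
}

#' Assign per-residue secondary structure
#'
#' DSSP-style (Kabsch-Sander) assignment over the alphabet
#' \{H, G, I, E, B, T, C\}: backbone H-bonds are scored with the
#' Kabsch-Sander electrostatic energy (bond when E < -0.5 kcal/mol), from
#' which n-turns (3,4,5), helices (G, H, I), and parallel/antiparallel
#' bridges and ladders (B, E) are derived.  Residues matching no pattern are
#' coil \code{"C"}.  Amide hydrogens are reconstructed when absent; proline
#' and the N-terminal residue do not donate.
#'
#' @param frame a \code{\link{conformer}}.
#' @param energy_cutoff H-bond energy threshold in kcal/mol (default -0.5).
#' @return character vector of one-letter codes, one per residue (named by
#'   author residue id).
#' @export
assign_secondary_structure <- function(frame, energy_cutoff = -0.5) {
  L <- .n_res(frame)
  codes <- rep("C", L)
  names(codes) <- seq_len(L) + frame$offset
  if (L < 3) return(codes)
  N <- .atom_xyz(frame, "N")
  O <- .atom_xyz(frame, "O")
  C <- .atom_xyz(frame, "C")
  H <- .amide_h_xyz(frame)

  # Kabsch-Sander energy for donor i -> acceptor j (kcal/mol)
  q <- 27.888
  hb <- matrix(FALSE, L, L)
  for (i in seq_len(L)) {
    if (anyNA(H[i, ])) next
    rON <- sqrt(rowSums((O - matrix(N[i, ], L, 3, byrow = TRUE))^2))
    rCH <- sqrt(rowSums((C - matrix(H[i, ], L, 3, byrow = TRUE))^2))
    rOH <- sqrt(rowSums((O - matrix(H[i, ], L, 3, byrow = TRUE))^2))
    rCN <- sqrt(rowSums((C - matrix(N[i, ], L, 3, byrow = TRUE))^2))
    e <- q * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
    e[abs(seq_len(L) - i) < 2] <- 0
    e[!is.finite(e)] <- -9.9
    e[e < -9.9] <- -9.9
    hb[i, ] <- e < energy_cutoff
  }

  hbond <- function(don, acc) {
    ok <- don >= 1 & don <= L & acc >= 1 & acc <= L
    out <- rep(FALSE, length(don))
    out[ok] <- hb[cbind(don[ok], acc[ok])]
    out
  }

  # n-turns: turn_n[i] is TRUE when N-H(i+n) bonds C=O(i)
  turn <- function(n) {
    i <- seq_len(L)
    hbond(i + n, i)
  }
  t3 <- turn(3); t4 <- turn(4); t5 <- turn(5)

  # turn T on interior residues of any n-turn
  is_T <- rep(FALSE, L)
  for (n in 3:5) {
    tn <- list(t3, t4, t5)[[n - 2]]
    for (i in which(tn)) {
      sel <- (i + 1):(i + n - 1)
      is_T[sel[sel <= L]] <- TRUE
    }
  }

  # helices: two consecutive n-turns
  run_helix <- function(tn, n) {
    out <- rep(FALSE, L)
    for (i in which(tn)) {
      if (i > 1 && tn[i - 1]) out[i:min(i + n - 1, L)] <- TRUE
    }
    out
  }
  is_G <- run_helix(t3, 3)
  is_H <- run_helix(t4, 4)
  is_I <- run_helix(t5, 5)

  # bridges (i < j - 2)
  para <- matrix(FALSE, L, L)
  anti <- matrix(FALSE, L, L)
  for (i in seq_len(L)) {
    js <- seq_len(L)
    js <- js[js >= i + 3]
    if (length(js) == 0) next
    p <- (hbond(rep(i - 1, length(js)), js) & hbond(js, rep(i + 1, length(js)))) |
         (hbond(js - 1, rep(i, length(js))) & hbond(rep(i, length(js)), js + 1))
    a <- (hbond(rep(i, length(js)), js) & hbond(js, rep(i, length(js)))) |
         (hbond(rep(i - 1, length(js)), js + 1) & hbond(js - 1, rep(i + 1, length(js))))
    para[i, js] <- p
    anti[i, js] <- a
  }
  para <- para | t(para)
  anti <- anti | t(anti)

  bridge_at <- function(m, i, j) {
    if (i < 1 || i > L || j < 1 || j > L) return(FALSE)
    m[i, j]
  }
  is_E <- rep(FALSE, L)
  is_B <- rep(FALSE, L)
  idx <- which(para | anti, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    in_ladder <-
      (para[i, j] && (bridge_at(para, i + 1, j + 1) || bridge_at(para, i - 1, j - 1))) ||
      (anti[i, j] && (bridge_at(anti, i + 1, j - 1) || bridge_at(anti, i - 1, j + 1)))
    if (in_ladder) is_E[i] <- TRUE else is_B[i] <- TRUE
  }

  # priority (low to high): T < I < G < B < E < H
  codes[is_T] <- "T"
  codes[is_I] <- "I"
  codes[is_G] <- "G"
  codes[is_B & !is_E] <- "B"
  codes[is_E] <- "E"
  codes[is_H] <- "H"
  codes
}

# -- Solvent-accessible surface area ----------------------------------------

# fixed, versioned heavy-atom radii (A); H ignored by default
.SASA_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20)

# deterministic golden-spiral unit sphere point set (no RNG)
.golden_spiral <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Per-atom solvent-accessible surface area of an arbitrary atom set
#'
#' Shrake-Rupley quadrature over a deterministic golden-spiral point set.
#' The workhorse behind \code{\link{compute_sasa}}, exposed for direct use
#' on atom collections that are not conformers.
#'
#' @param xyz n x 3 coordinate matrix (Angstrom).
#' @param elements character vector of element symbols (C, N, O, S, H).
#' @param probe_radius probe sphere radius (A).
#' @param n_points quadrature points per atom.
#' @return numeric vector of per-atom accessible areas (A^2).
#' @export
atom_sasa <- function(xyz, elements, probe_radius = 1.4, n_points = 960) {
  xyz <- as.matrix(xyz)
  unknown <- setdiff(unique(elements), names(.SASA_RADII))
  if (length(unknown) > 0)
    stop("unknown element(s) for SASA radii: ", paste(unknown, collapse = ", "))
  rad <- unname(.SASA_RADII[elements]) + probe_radius
  n_atoms <- nrow(xyz)
  pts <- .golden_spiral(n_points)
  area <- numeric(n_atoms)
  d2 <- as.matrix(stats::dist(xyz))^2
  # exactly coincident spheres count once: later duplicates get zero area
  # (the boundary test is ill-conditioned there otherwise)
  dup <- rep(FALSE, n_atoms)
  if (n_atoms > 1) {
    for (i in 2:n_atoms) {
      j <- which(d2[i, 1:(i - 1)] < 1e-12 & rad[1:(i - 1)] >= rad[i])
      if (length(j) > 0) dup[i] <- TRUE
    }
  }
  for (i in seq_len(n_atoms)) {
    if (dup[i]) next
    neigh <- which(d2[i, ] < (rad[i] + rad)^2 & seq_len(n_atoms) != i & !dup)
    P <- pts * rad[i]
    P <- sweep(P, 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in neigh) {
      if (!any(acc)) break
      dj2 <- (P[, 1] - xyz[j, 1])^2 + (P[, 2] - xyz[j, 2])^2 +
             (P[, 3] - xyz[j, 3])^2
      acc <- acc & (dj2 >= rad[j]^2 - 1e-9)
    }
    area[i] <- 4 * pi * rad[i]^2 * sum(acc) / n_points
  }
  area
}

#' Per-residue solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA with a deterministic golden-spiral quadrature point set
#' (bit-reproducible, no RNG).  Heavy-atom radii: C 1.7, N 1.55, O 1.52,
#' S 1.8 A; hydrogens are ignored by default.
#'
#' @param frame a \code{\link{conformer}}.
#' @param probe_radius probe sphere radius in Angstrom (default 1.4).
#' @param n_points quadrature points per atom (default 960).
#' @param include_h include hydrogens as spheres (default FALSE).
#' @return data.frame with columns \code{resno} (author numbering) and
#'   \code{sasa} (A^2); probe radius stored as attribute
#'   \code{"probe_radius"}.
#' @export
compute_sasa <- function(frame, probe_radius = 1.4, n_points = 960,
                         include_h = FALSE) {
  elem <- substr(sub("^[0-9]*", "", frame$atoms$elety), 1, 1)
  keep <- rep(TRUE, length(elem))
  if (!include_h) keep <- elem != "H"
  area <- atom_sasa(frame$xyz[keep, , drop = FALSE], elem[keep],
                    probe_radius = probe_radius, n_points = n_points)
  resno <- frame$atoms$resno[keep]
  per_res <- tapply(area, resno, sum)
  out <- data.frame(resno = as.integer(names(per_res)) + frame$offset,
                    sasa = as.numeric(per_res))
  out <- out[order(out$resno), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "probe_radius") <- probe_radius
  out
}

#' Minimal RMSD under rigid-body superposition (Kabsch)
#'
#' Optimal rotation via SVD of the cross-covariance matrix with reflection
#' correction, after centering both coordinate sets.
#'
#' @param coords_a,coords_b N x 3 coordinate matrices, equal N >= 3.
#' @return non-negative RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(coords_a, coords_b) {
  A <- as.matrix(coords_a); B <- as.matrix(coords_b)
  if (!all(dim(A) == dim(B))) stop("coordinate sets must have equal dimensions")
  if (nrow(A) < 3) stop("need at least 3 points")
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  s <- svd(t(A) %*% B)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((A %*% t(R) - B)^2)))
}
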