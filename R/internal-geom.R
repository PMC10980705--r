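# Internal geometric primitives shared by the builders and analyses.
# All lengths in Angstrom, all angles in degrees unless noted.

.deg2rad <- function(x) x * pi / 180

.vnorm <- function(v) sqrt(sum(v * v))

.vunit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("cannot normalise zero-length vector")
  v / n
}

.vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Place atom D given positions A, B, C, the bond length |CD|, the bond angle
# B-C-D and the dihedral A-B-C-D (natural extension reference frame).
.place_atom <- function(a, b, c, length, angle, dihedral) {
  th <- .deg2rad(angle)
  chi <- .deg2rad(dihedral)
  bc <- .vunit(c - b)
  n <- .vunit(.vcross(b - a, bc))
  m <- .vcross(n, bc)
  d2 <- length * c(-cos(th), sin(th) * cos(chi), sin(th) * sin(chi))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Ideal backbone internal coordinates
.BB <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231, n_h = 1.00,
  ca_cb = 1.532,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8
)

# Ideal C-beta direction from backbone N, CA, C.
.place_cb <- function(n, ca, c) {
  u1 <- .vunit(n - ca)
  u2 <- .vunit(c - ca)
  v <- -.vunit(u1 + u2)
  w <- .vunit(.vcross(u2, u1))
  ca + .BB$ca_cb * .vunit(0.817 * v + 0.577 * w)
}

# Amide hydrogen on the bisector-opposed direction of C(i-1)-N-CA,
# 1.0 A from N.  Returns NA for the first residue (no preceding carbonyl).
.place_amide_h <- function(n, ca, c_prev) {
  n + .BB$n_h * .vunit(.vunit(n - ca) + .vunit(n - c_prev))
}

# Build a backbone chain from per-residue (phi, psi) dihedrals with ideal
# bond lengths/angles; omega fixed trans.  Returns a list of per-residue
# matrices of named atom rows (N, CA, C, O, and H/CB where applicable).
.chain_from_dihedrals <- function(sequence, phi, psi, omega = 180) {
  L <- nchar(sequence)
  aa <- strsplit(sequence, "")[[1]]
  stopifnot(length(phi) == L, length(psi) == L)
  N <- CA <- C <- O <- matrix(NA_real_, L, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(.BB$n_ca, 0, 0)
  th <- .deg2rad(180 - .BB$ang_n_ca_c)
  C[1, ] <- CA[1, ] + .BB$ca_c * c(cos(th), sin(th), 0)
  for (i in seq_len(L - 1)) {
    N[i + 1, ] <- .place_atom(N[i, ], CA[i, ], C[i, ], .BB$c_n,
                              .BB$ang_ca_c_n, psi[i])
    CA[i + 1, ] <- .place_atom(CA[i, ], C[i, ], N[i + 1, ], .BB$n_ca,
                               .BB$ang_c_n_ca, omega)
    C[i + 1, ] <- .place_atom(C[i, ], N[i + 1, ], CA[i + 1, ], .BB$ca_c,
                              .BB$ang_n_ca_c, phi[i + 1])
    O[i, ] <- C[i, ] + .BB$c_o *
      .vunit(.vunit(C[i, ] - CA[i, ]) + .vunit(C[i, ] - N[i + 1, ]))
  }
  O[L, ] <- .place_atom(N[L, ], CA[L, ], C[L, ], .BB$c_o, .BB$ang_ca_c_o,
                        psi[L] - 180)
  .assemble_residues(aa, N, CA, C, O)
}

# Common assembly: add H (not PRO, not residue 1) and CB (not GLY) and
# produce the per-residue atom list used by .conformer_from_atoms().
.assemble_residues <- function(aa, N, CA, C, O) {
  L <- length(aa)
  res <- vector("list", L)
  for (i in seq_len(L)) {
    atoms <- rbind(N = N[i, ], CA = CA[i, ], C = C[i, ], O = O[i, ])
    if (i > 1 && aa[i] != "P") {
      atoms <- rbind(atoms, H = .place_amide_h(N[i, ], CA[i, ], C[i - 1, ]))
    }
    if (aa[i] != "G") {
      atoms <- rbind(atoms, CB = .place_cb(N[i, ], CA[i, ], C[i, ]))
    }
    res[[i]] <- atoms
  }
  res
}

# -- Idealised antiparallel strand template ---------------------------------
#
# Residues are laid out along the x axis with CA spacing 3.8 A.  The face
# argument (+1/-1) controls which side of the strand the amide H and the
# carbonyl O point to; dir (+1/-1) is the chain direction along x.  Two
# strands separated by 4.90 A in y give an N...O distance of exactly 2.90 A
# at rungs whose faces point at each other, with the next-nearest
# non-designated N/O pairs > 4.7 A apart.
.STRAND <- list(spacing = 3.8, sep = 4.90,
                nx = 1.41, ny = 0.37, cx = 1.45, cy = 0.40,
                oy = 1.23, hy = 1.00)

.strand_residue <- function(ca, dir, face) {
  s <- .STRAND
  N <- ca + c(-dir * s$nx, face * s$ny, 0)
  H <- N + c(0, face * s$hy, 0)
  C <- ca + c(dir * s$cx, face * s$cy, 0)
  O <- C + c(0, face * s$oy, 0)
  rbind(N = N, CA = ca, C = C, O = O, H = H)
}

# -- Circular-arc turn ------------------------------------------------------
#
# Interpolates n_seg equal chords of length `chord` between p0 and p1 along
# the major arc of a circle in the plane spanned by unit(p1 - p0) and the
# out-of-plane direction zhat, bulging towards zhat.  Returns the n_seg - 1
# interior points plus the circle centre and radius (for radial placement of
# turn carbonyls).
.arc_turn <- function(p0, p1, n_seg, chord = 3.8, zhat = c(0, 0, 1)) {
  u <- .vunit(p1 - p0)
  z <- .vunit(zhat - sum(zhat * u) * u)
  Cd <- .vnorm(p1 - p0)
  if (Cd >= n_seg * chord) stop("turn endpoints too far apart for arc")
  g <- function(phi) Cd * sin(phi / (2 * n_seg)) - chord * sin(phi / 2)
  phi <- stats::uniroot(g, c(pi + 1e-9, 2 * pi - 1e-6), tol = 1e-12)$root
  R <- chord / (2 * sin(phi / (2 * n_seg)))
  h <- sqrt(max(R^2 - (Cd / 2)^2, 0))
  centre <- (p0 + p1) / 2 + h * z
  # angular coordinates of p0/p1 in the (u, z) basis around the centre
  rel0 <- p0 - centre
  th0 <- atan2(sum(rel0 * z), sum(rel0 * u))
  step <- phi / n_seg
  pts <- matrix(NA_real_, n_seg - 1, 3)
  for (k in seq_len(n_seg - 1)) {
    th <- th0 - k * step
    pts[k, ] <- centre + R * (cos(th) * u + sin(th) * z)
  }
  list(points = pts, centre = centre, radius = R, u = u, z = z)
}

# Backbone atoms for turn residues whose CA positions are already fixed.
# Each peptide unit (between consecutive CAs) carries its C/N pair offset
# perpendicular to the CA-CA axis by beta, the side alternating per peptide,
# which keeps C-N near bond length (3.8 - a1 - a2 = 1.32 A along the axis
# with a shared perpendicular offset); O and H point radially away from the
# arc centre, keeping them clear of both strands.  `perp` is the shared
# out-of-plane unit vector; `side_in`/`side_out` are +-1 per peptide unit.
.turn_backbone <- function(ca_prev, ca, ca_next, centre, perp,
                           side_in, side_out, up = NULL) {
  a1 <- 1.279; a2 <- 1.198; beta <- 0.83
  u_in <- .vunit(ca - ca_prev)
  u_out <- .vunit(ca_next - ca)
  N <- ca - a2 * u_in + beta * side_in * perp
  C <- ca + a1 * u_out + beta * side_out * perp
  rad <- .vunit(ca - centre)
  # O/H point radially out of the arc with an out-of-plane bias (`up`, the
  # arc bulge direction) so no near-cutoff stray contacts with either
  # strand remain
  dir <- if (is.null(up)) rad else .vunit(rad + 1.4 * up)
  O <- C + .BB$c_o * dir
  H <- N + .BB$n_h * dir
  rbind(N = N, CA = ca, C = C, O = O, H = H)
}

# Run a function with a private RNG state (leaves the caller's RNG alone).
.with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}
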