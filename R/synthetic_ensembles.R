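# Ground-truth synthetic inputs: ideal hairpin/extended/coil conformers,
# k18-scale chains with designated local and long-range pairings, and noisy
# ThT plates.  These are geometric fixtures with labelled truth, not
# thermodynamic samples.

# Feasible turn-centre candidates for a parity: every partner 2*tc - rung
# must fall inside the N-arm and leave at least one turn residue.
.feasible_turn_centres <- function(regions, parity) {
  rungs <- if (parity == "even") regions$even_set else regions$odd_set
  b_start <- min(c(regions$scored_hex, regions$even_set, regions$odd_set))
  Filter(function(tc) {
    partners <- 2L * tc - rungs
    a_end <- max(partners)
    all(partners %in% regions$n_arm) &&
      min(partners) > regions$numbering_offset + 1L &&  # room for the arm
      (b_start - a_end) >= 2L                           # >= 1 turn residue
  }, regions$turn)
}

#' Build an ideal beta-hairpin conformer with a designated registry
#'
#' Constructs two antiparallel strands joined by a circular-arc turn, with
#' ideal strand geometry (consecutive CA-CA 3.8 A; inter-strand N-O 2.90 A
#' at the hydrogen-bonded rungs) arranged so that the cross-arm hydrogen
#' bonds land exactly on the requested parity set, pairing each rung r with
#' arm residue 2*turn_center - r.  The construction is validated by running
#' \code{\link{detect_backbone_hbonds}} and \code{\link{classify_hairpin}}
#' on the result; a geometrically infeasible request errors.
#'
#' @param sequence one-letter sequence.
#' @param regions a \code{\link{make_region_map}} object.
#' @param parity \code{"even"} or \code{"odd"}.
#' @param turn_center residue id (author numbering) inside the turn region
#'   about which rungs pair; default: first feasible turn residue.
#' @return a \code{\link{conformer}} that classifies as the requested
#'   registry.
#' @export
build_ideal_hairpin <- function(sequence, regions, parity = c("even", "odd"),
                                turn_center = NULL) {
  parity <- match.arg(parity)
  off <- regions$numbering_offset
  lo <- off + 1L
  hi <- off + nchar(sequence)
  rungs <- sort(if (parity == "even") regions$even_set else regions$odd_set)
  if (length(rungs) < 2) stop("parity set must contain at least 2 residues")
  feas <- .feasible_turn_centres(regions, parity)
  if (is.null(turn_center)) {
    if (length(feas) == 0)
      stop("no feasible turn centre: arms too short for >= 2 parity bonds")
    turn_center <- feas[[1]]
  }
  turn_center <- as.integer(turn_center)
  if (!(turn_center %in% regions$turn))
    stop("turn_center must lie inside the turn region")
  if (!(turn_center %in% feas))
    stop("geometrically infeasible: partners of ", parity,
         " rungs about ", turn_center, " fall outside the N-arm")
  partners <- 2L * turn_center - rungs
  a_end <- max(partners)
  b_start <- min(c(regions$scored_hex, regions$even_set, regions$odd_set))
  sp <- .STRAND
  aa <- strsplit(sequence, "")[[1]]
  L <- nchar(sequence)

  ax <- function(r) sp$spacing * (r - lo)           # arm x of author residue
  res_atoms <- vector("list", L)

  for (r in lo:a_end) {
    face <- if (r %in% partners) 1 else -1
    res_atoms[[r - off]] <- .strand_residue(c(ax(r), 0, 0), dir = 1,
                                            face = face)
  }
  for (r in b_start:hi) {
    face <- if (r %in% rungs) -1 else 1
    ca <- c(ax(2L * turn_center - r) + 0.04, sp$sep, 0)
    res_atoms[[r - off]] <- .strand_residue(ca, dir = -1, face = face)
  }
  # turn residues on the arc between the two strand anchors
  turn_res <- (a_end + 1L):(b_start - 1L)
  n_seg <- length(turn_res) + 1L
  p0 <- res_atoms[[a_end - off]]["CA", ]
  p1 <- res_atoms[[b_start - off]]["CA", ]
  # the arc bulges out of the strand plane, tilted sideways away from both
  # strands so the junction carbonyls keep a wide margin from strand amides
  u01 <- .vunit(p1 - p0)
  zhat <- .vunit(c(0, 0, 1) + 0.8 * c(u01[2], -u01[1], 0))
  arc <- .arc_turn(p0, p1, n_seg, chord = sp$spacing, zhat = zhat)
  perp <- .vunit(.vcross(arc$u, arc$z))
  ca_path <- rbind(p0, arc$points, p1)
  for (k in seq_along(turn_res)) {
    r <- turn_res[k]
    res_atoms[[r - off]] <- .turn_backbone(
      ca_path[k, ], ca_path[k + 1, ], ca_path[k + 2, ], arc$centre, perp,
      side_in = (-1)^(k - 1), side_out = (-1)^k, up = arc$z)
  }
  cf <- .conformer_from_residue_atoms(res_atoms, aa, offset = off)

  # closed-loop validation: the designated rungs and nothing else
  asg <- classify_hairpin(cf, regions)
  ok <- asg$registry == parity &&
    identical(sort(as.integer(names(asg$pairing))), rungs) &&
    identical(unname(asg$pairing[as.character(rungs)]), partners)
  if (!ok)
    stop("geometrically infeasible hairpin spec (constructed frame ",
         "classifies as '", asg$registry, "')")
  cf
}

# Assemble per-residue atom matrices (rows N, CA, C, O, optionally H) into a
# conformer: amide H dropped for prolines and the N-terminus, CB added for
# non-glycines.
.conformer_from_residue_atoms <- function(res_atoms, aa, offset = 0L,
                                          frame_id = 1L, weight = 1) {
  rows <- list(); xyz <- list()
  for (i in seq_along(res_atoms)) {
    m <- res_atoms[[i]]
    keep <- rownames(m)
    if (aa[i] == "P" || i == 1) keep <- setdiff(keep, "H")
    m <- m[keep, , drop = FALSE]
    if (aa[i] != "G") {
      m <- rbind(m, CB = .place_cb(m["N", ], m["CA", ], m["C", ]))
    }
    rows[[i]] <- data.frame(resno = i, resid = bio3d::aa123(aa[i]),
                            elety = rownames(m), stringsAsFactors = FALSE)
    xyz[[i]] <- m
  }
  conformer(do.call(rbind, xyz), do.call(rbind, rows),
            frame_id = frame_id, weight = weight, offset = offset)
}

#' Build a fully extended conformer
#'
#' Ideal-geometry chain with beta-region dihedrals (phi = -139, psi = 135);
#' the construction is checked to contain no intra-chain N-O pair within
#' the 3.5 A hydrogen-bond cutoff.
#'
#' @param sequence one-letter sequence.
#' @param numbering_offset author id = internal index + offset.
#' @return a \code{\link{conformer}}.
#' @export
build_extended <- function(sequence, numbering_offset = 0L) {
  L <- nchar(sequence)
  aa <- strsplit(sequence, "")[[1]]
  res <- .chain_from_dihedrals(sequence, phi = rep(-139, L), psi = rep(135, L))
  cf <- .conformer_from_assembled(res, aa, numbering_offset)
  if (nrow(detect_backbone_hbonds(cf)) > 0)
    stop("extended chain unexpectedly contains hydrogen bonds")
  cf
}

# .assemble_residues output (already has H/CB logic applied) -> conformer
.conformer_from_assembled <- function(res, aa, offset = 0L, frame_id = 1L,
                                      weight = 1) {
  rows <- list(); xyz <- list()
  for (i in seq_along(res)) {
    m <- res[[i]]
    rows[[i]] <- data.frame(resno = i, resid = bio3d::aa123(aa[i]),
                            elety = rownames(m), stringsAsFactors = FALSE)
    xyz[[i]] <- m
  }
  conformer(do.call(rbind, xyz), do.call(rbind, rows),
            frame_id = frame_id, weight = weight, offset = offset)
}

#' Build a self-avoiding random-coil conformer
#'
#' Per-residue dihedrals are drawn uniformly from broad extended/polyproline
#' and left-handed basins (excluding the tight beta-sheet and alpha-helical
#' cores), with clash rejection at 2.5 A between heavy atoms of
#' non-adjacent residues.  Deterministic under a fixed seed.  When
#' \code{regions} is supplied the draw additionally retries until the frame
#' classifies as registry \code{"none"}.
#'
#' @param sequence one-letter sequence.
#' @param seed integer seed (deterministic output).
#' @param numbering_offset author id = internal index + offset.
#' @param regions optional \code{\link{make_region_map}} for the
#'   registry-none guarantee.
#' @param max_tries retry budget for self-avoidance (default 200).
#' @return a \code{\link{conformer}}.
#' @export
build_coil <- function(sequence, seed, numbering_offset = 0L, regions = NULL,
                       max_tries = 200) {
  L <- nchar(sequence)
  aa <- strsplit(sequence, "")[[1]]
  .with_seed(seed, function() {
    for (try in seq_len(max_tries)) {
      ext <- stats::runif(L) < 0.85
      phi <- ifelse(ext, stats::runif(L, -160, -55), stats::runif(L, 50, 90))
      psi <- ifelse(ext, stats::runif(L, 60, 175), stats::runif(L, -40, 40))
      res <- .chain_from_dihedrals(sequence, phi, psi)
      cf <- .conformer_from_assembled(res, aa, numbering_offset)
      heavy <- cf$atoms$elety != "H"
      d <- as.matrix(stats::dist(cf$xyz[heavy, , drop = FALSE]))
      sep <- abs(outer(cf$atoms$resno[heavy], cf$atoms$resno[heavy], "-"))
      if (min(d[sep >= 2]) < 2.5) next
      if (!is.null(regions) &&
          classify_hairpin(cf, regions)$registry != "none") next
      return(cf)
    }
    stop("self-avoiding coil not found within ", max_tries, " tries")
  })
}

#' Sample a labelled synthetic ensemble
#'
#' Draws frames per the composition (even/odd hairpin, extended, coil),
#' applies i.i.d. Gaussian coordinate noise, and returns the ensemble with
#' its ground-truth labels.  Deterministic under the recipe seed.
#'
#' @param recipe list with fields \code{sequence}, \code{composition}
#'   (named fractions over even/odd/extended/coil summing to 1),
#'   \code{n_frames}, \code{noise_sigma} (A, default 0), \code{seed},
#'   \code{numbering_offset} (default 294) and optionally \code{regions}
#'   (default tau295).
#' @return list with \code{ensemble} (an \code{\link{ensemble}}) and
#'   \code{truth} (data.frame frame_id, label, turn_center).
#' @export
sample_ensemble <- function(recipe) {
  comp <- recipe$composition[c("even", "odd", "extended", "coil")]
  comp[is.na(comp)] <- 0
  names(comp) <- c("even", "odd", "extended", "coil")
  if (abs(sum(comp) - 1) > 1e-9) stop("composition must sum to 1")
  n <- recipe$n_frames
  if (is.null(n) || n < 1) stop("n_frames must be >= 1")
  off <- if (is.null(recipe$numbering_offset)) 294L else recipe$numbering_offset
  regions <- if (is.null(recipe$regions)) {
    make_region_map(recipe$sequence, numbering_offset = off)
  } else recipe$regions
  sigma <- if (is.null(recipe$noise_sigma)) 0 else recipe$noise_sigma

  .with_seed(recipe$seed, function() {
    labels <- sample(names(comp), n, replace = TRUE, prob = comp)
    ext_cf <- if (any(labels == "extended"))
      build_extended(recipe$sequence, off) else NULL
    feas_even <- .feasible_turn_centres(regions, "even")
    feas_odd <- .feasible_turn_centres(regions, "odd")
    coil_seeds <- sample.int(2^30, n)
    conformers <- vector("list", n)
    tcs <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      cf <- switch(labels[i],
        even = {
          tcs[i] <- feas_even[[sample.int(length(feas_even), 1)]]
          build_ideal_hairpin(recipe$sequence, regions, "even", tcs[i])
        },
        odd = {
          tcs[i] <- feas_odd[[sample.int(length(feas_odd), 1)]]
          build_ideal_hairpin(recipe$sequence, regions, "odd", tcs[i])
        },
        extended = ext_cf,
        coil = build_coil(recipe$sequence, coil_seeds[i], off,
                          regions = regions))
      cf$frame_id <- i
      if (sigma > 0) {
        cf$xyz <- cf$xyz + matrix(stats::rnorm(length(cf$xyz), 0, sigma),
                                  ncol = 3)
      }
      conformers[[i]] <- cf
    }
    list(ensemble = ensemble(conformers, sequence = recipe$sequence,
                             numbering_offset = off),
         truth = data.frame(frame_id = seq_len(n), label = labels,
                            turn_center = tcs, stringsAsFactors = FALSE))
  })
}

#' Build a k18-scale conformer realising designated beta events
#'
#' Lays the chain out as an extended strand and repositions segments to
#' realise exactly the requested events under
#' \code{\link{detect_backbone_hbonds}} and the repeat-domain statistics:
#' \code{"Hk"} (k = 1..4) folds hexapeptide k back onto its upstream
#' flanking segment as a local hairpin; \code{c(i, j)} pairs hexapeptide j
#' antiparallel onto hexapeptide i with hydrogen-bonded rungs.  Requested
#' events must use non-overlapping segments.  The result is a geometric
#' fixture: chain continuity is not maintained across repositioned
#' segments.
#'
#' @param spec a \code{\link{make_repeat_spec}} object.
#' @param events list of event descriptors: strings \code{"H1"}..\code{"H4"}
#'   and/or integer pairs \code{c(i, j)} with i < j.  Empty list gives the
#'   fully extended chain.
#' @param frame_id frame identifier.
#' @return a \code{\link{conformer}}.
#' @export
build_k18_frame <- function(spec, events = list(), frame_id = 1L) {
  off <- spec$numbering_offset
  lo <- off + 1L
  hi <- off + nchar(spec$sequence)
  aa <- strsplit(spec$sequence, "")[[1]]
  sp <- .STRAND
  L <- nchar(spec$sequence)

  # default layout: straight strand along +x, everything facing -y
  ca_x <- sp$spacing * (seq_len(L) - 1)
  ca_y <- rep(0, L)
  dirs <- rep(1, L)
  faces <- rep(-1, L)

  used <- list()
  for (ev in events) {
    if (is.character(ev) && grepl("^H[1-4]$", ev)) {
      k <- as.integer(substr(ev, 2, 2))
      hex <- spec$hexapeptides[[k]]
      h1 <- min(hex)
      tc <- h1 - 3L
      rungs <- intersect(c(h1, h1 + 2L, h1 + 4L), hex)
      partners <- 2L * tc - rungs
      arm_lo <- if (k == 1) lo else max(spec$hexapeptides[[k - 1]]) + 1L
      if (any(partners < arm_lo) || any(partners > h1 - 2L))
        stop("local hairpin ", ev, " infeasible: partners leave the arm")
      seg <- c(min(partners):max(spec$hexapeptides[[k]]))
      used <- c(used, list(seg))
      for (r in hex) {
        i <- r - off
        ca_x[i] <- sp$spacing * (2L * tc - r - off - 1L) + 0.04
        ca_y[i] <- sp$sep
        dirs[i] <- -1
        faces[i] <- if (r %in% rungs) -1 else 1
      }
      faces[partners - off] <- 1
    } else if (is.numeric(ev) && length(ev) == 2) {
      i <- as.integer(min(ev)); j <- as.integer(max(ev))
      if (!(i %in% 1:4) || !(j %in% 1:4) || i == j)
        stop("pairing event must name two distinct hexapeptides 1-4")
      hi_ <- spec$hexapeptides[[i]]; hj <- spec$hexapeptides[[j]]
      j2 <- max(hj); i1 <- min(hi_)
      rungs_j <- intersect(c(j2, j2 - 2L, j2 - 4L), hj)
      partners <- i1 + (j2 - rungs_j)
      if (any(!(partners %in% hi_)))
        stop("pairing event (", i, ",", j, ") infeasible: rungs outrun ",
             "hexapeptide ", i)
      used <- c(used, list(hi_), list(hj))
      for (r in hj) {
        ii <- r - off
        ca_x[ii] <- sp$spacing * (i1 + j2 - r - off - 1L) + 0.04
        ca_y[ii] <- sp$sep
        dirs[ii] <- -1
        faces[ii] <- if (r %in% rungs_j) -1 else 1
      }
      faces[partners - off] <- 1
    } else {
      stop("events must be 'H1'..'H4' strings or integer pairs c(i, j)")
    }
  }
  if (length(used) > 1) {
    all_used <- unlist(used)
    if (anyDuplicated(all_used))
      stop("requested events use overlapping segments")
  }

  res_atoms <- lapply(seq_len(L), function(i)
    .strand_residue(c(ca_x[i], ca_y[i], 0), dir = dirs[i], face = faces[i]))
  .conformer_from_residue_atoms(res_atoms, aa, offset = off,
                                frame_id = frame_id)
}

#' Simulate a ThT plate with known kinetics
#'
#' Generates quadruplicate wells per mutant from the 4-parameter logistic
#' plus Gaussian noise (standard deviation = \code{noise_sigma_frac} times
#' the curve amplitude) on top of a blank fluorescence level, and blank
#' wells with the same noise.  Mutants with missing \code{T_half} give flat
#' wells (the "no aggregation" case).  Seeded and reproducible.
#'
#' @param recipe list with fields: \code{mutants} (data.frame with columns
#'   \code{id}, \code{T_half} (hours, NA for non-aggregators),
#'   \code{baseline}, \code{plateau}, \code{slope}), \code{times} (hours
#'   grid, default \code{seq(0, 144, 0.5)}), \code{noise_sigma_frac}
#'   (default 0.02), \code{seed}, \code{n_replicates} (default 4),
#'   \code{n_blanks} (default 4), \code{blank_level} (default 100).
#' @return list with \code{plate} (data.frame: \code{time_h}, one column
#'   per well, blank wells prefixed \code{"blank"}) and \code{truth}
#'   (the mutants table).
#' @export
simulate_tht_plate <- function(recipe) {
  mt <- recipe$mutants
  stopifnot(is.data.frame(mt),
            all(c("id", "T_half", "baseline", "plateau", "slope") %in% names(mt)))
  times <- if (is.null(recipe$times)) seq(0, 144, by = 0.5) else recipe$times
  frac <- if (is.null(recipe$noise_sigma_frac)) 0.02 else recipe$noise_sigma_frac
  n_rep <- if (is.null(recipe$n_replicates)) 4L else recipe$n_replicates
  n_bl <- if (is.null(recipe$n_blanks)) 4L else recipe$n_blanks
  blank <- if (is.null(recipe$blank_level)) 100 else recipe$blank_level
  ok_T <- is.na(mt$T_half) |
    (mt$T_half >= min(times) & mt$T_half <= max(times))
  if (!all(ok_T)) stop("T_half must lie within the time grid where present")

  .with_seed(recipe$seed, function() {
    cols <- list(time_h = times)
    for (m in seq_len(nrow(mt))) {
      amp <- mt$plateau[m] - mt$baseline[m]
      mean_curve <- if (is.na(mt$T_half[m])) {
        rep(mt$baseline[m], length(times))
      } else {
        mt$baseline[m] + amp /
          (1 + exp(-mt$slope[m] * (times - mt$T_half[m])))
      }
      for (rep_i in seq_len(n_rep)) {
        nm <- paste0(mt$id[m], "_", rep_i)
        cols[[nm]] <- blank + mean_curve +
          stats::rnorm(length(times), 0, frac * abs(amp))
      }
    }
    amp_ref <- mean(abs(mt$plateau - mt$baseline))
    for (b in seq_len(n_bl)) {
      cols[[paste0("blank_", b)]] <- blank +
        stats::rnorm(length(times), 0, frac * amp_ref)
    }
    list(plate = as.data.frame(cols, check.names = FALSE), truth = mt)
  })
}

#' Extract one mutant's wells from a simulated plate as a ThT curve
#'
#' @param plate the \code{plate} data.frame from
#'   \code{\link{simulate_tht_plate}} (or a CSV read into the same layout).
#' @param id mutant id whose replicate wells (\code{"<id>_<k>"}) to pull.
#' @param blank_prefix prefix of the blank-well columns.
#' @return a \code{\link{tht_curve}} with blanks attached.
#' @export
plate_curves <- function(plate, id, blank_prefix = "blank") {
  wells <- grep(paste0("^", id, "_[0-9]+$"), names(plate), value = TRUE)
  if (length(wells) == 0) stop("no wells found for id ", id)
  blanks <- grep(paste0("^", blank_prefix, "_[0-9]+$"), names(plate),
                 value = TRUE)
  tht_curve(plate$time_h, as.matrix(plate[, wells, drop = FALSE]),
            if (length(blanks) > 0)
              as.matrix(plate[, blanks, drop = FALSE]) else NULL)
}
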