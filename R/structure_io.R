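# Ensemble containers, PDB input/output, region conventions.
#
# Residue numbering convention: internal indices are 1-based and contiguous;
# author numbering (e.g. tau 295-311) is internal index + numbering_offset.
# All user-facing residue sets (RegionMap, RepeatSpec, H-bond tables) are in
# author numbering.

.BACKBONE <- c("N", "CA", "C", "O")

#' Construct a single-frame conformer
#'
#' A conformer holds the coordinates and minimal topology of one frame of a
#' conformational ensemble: per-atom positions plus (residue index, residue
#' name, atom name).  Every residue must contribute the backbone atoms
#' N, CA, C and O; amide hydrogens are optional (they are reconstructed
#' geometrically when a calculation needs them).
#'
#' @param xyz numeric matrix (n_atoms x 3) of coordinates in Angstrom.
#' @param atoms data.frame with columns \code{resno} (internal 1-based
#'   residue index), \code{resid} (3-letter residue name) and \code{elety}
#'   (atom name).
#' @param frame_id integer frame identifier.
#' @param weight non-negative frame weight (default 1).
#' @param offset numbering offset: author residue id = internal index +
#'   \code{offset}.
#' @return an object of class \code{"conformer"}.
#' @export
conformer <- function(xyz, atoms, frame_id = 1L, weight = 1, offset = 0L) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3) stop("xyz must have 3 columns")
  if (nrow(xyz) != nrow(atoms)) stop("xyz and atoms row counts differ")
  if (!all(is.finite(xyz)))
    stop("non-finite coordinates in frame ", frame_id)
  if (weight < 0) stop("frame weight must be non-negative")
  need <- c("resno", "resid", "elety")
  if (!all(need %in% names(atoms))) stop("atoms needs columns resno, resid, elety")
  resno <- as.integer(atoms$resno)
  ur <- sort(unique(resno))
  if (!identical(ur, seq_along(ur)))
    stop("residue indices must be contiguous and 1-based in frame ", frame_id)
  for (r in ur) {
    have <- atoms$elety[resno == r]
    miss <- setdiff(.BACKBONE, have)
    if (length(miss) > 0)
      stop(sprintf("frame %s residue %d (%s): missing backbone atom(s) %s",
                   frame_id, r + offset, atoms$resid[match(r, resno)],
                   paste(miss, collapse = ", ")))
  }
  structure(list(frame_id = as.integer(frame_id),
                 atoms = data.frame(resno = resno,
                                    resid = as.character(atoms$resid),
                                    elety = as.character(atoms$elety),
                                    stringsAsFactors = FALSE),
                 xyz = unname(xyz),
                 weight = as.numeric(weight),
                 offset = as.integer(offset)),
            class = "conformer")
}

# number of residues in a conformer
.n_res <- function(frame) max(frame$atoms$resno)

# index of one named backbone atom per residue (NA where absent)
.atom_index <- function(frame, elety) {
  idx <- rep(NA_integer_, .n_res(frame))
  sel <- which(frame$atoms$elety == elety)
  idx[frame$atoms$resno[sel]] <- sel
  idx
}

# L x 3 coordinate matrix of one named atom per residue
.atom_xyz <- function(frame, elety, required = TRUE) {
  idx <- .atom_index(frame, elety)
  if (required && anyNA(idx))
    stop(sprintf("residue %s lacks backbone atom %s",
                 paste(which(is.na(idx)) + frame$offset, collapse = ","), elety))
  out <- matrix(NA_real_, length(idx), 3)
  ok <- !is.na(idx)
  out[ok, ] <- frame$xyz[idx[ok], , drop = FALSE]
  out
}

.conformer_sequence <- function(frame) {
  first <- match(seq_len(.n_res(frame)), frame$atoms$resno)
  paste(bio3d::aa321(frame$atoms$resid[first]), collapse = "")
}

#' @export
print.conformer <- function(x, ...) {
  cat(sprintf("<conformer> frame %d: %d residues, %d atoms, weight %.3g\n",
              x$frame_id, .n_res(x), nrow(x$atoms), x$weight))
  invisible(x)
}

#' Construct an ensemble of conformers
#'
#' An ensemble is an ordered, weighted collection of conformers sharing one
#' topology, together with the one-letter sequence and the author numbering
#' offset.
#'
#' @param conformers list of \code{\link{conformer}} objects.
#' @param sequence one-letter sequence; derived from the first conformer when
#'   \code{NULL}.
#' @param numbering_offset author residue id = internal index + offset.
#' @return an object of class \code{"ensemble"}.
#' @export
ensemble <- function(conformers, sequence = NULL, numbering_offset = 0L) {
  if (length(conformers) == 0) stop("ensemble must contain at least one frame")
  ref <- conformers[[1]]$atoms
  for (cf in conformers) {
    if (!identical(cf$atoms$elety, ref$elety) ||
        !identical(cf$atoms$resno, ref$resno))
      stop("all conformers must share one topology")
  }
  w <- vapply(conformers, function(cf) cf$weight, numeric(1))
  if (sum(w) <= 0) stop("sum of frame weights must be positive")
  if (is.null(sequence)) sequence <- .conformer_sequence(conformers[[1]])
  conformers <- lapply(conformers, function(cf) {
    cf$offset <- as.integer(numbering_offset); cf
  })
  structure(list(conformers = conformers,
                 sequence = sequence,
                 numbering_offset = as.integer(numbering_offset)),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("<ensemble> %d frames of %d-residue peptide (%s...), offset %+d\n",
              length(x$conformers), nchar(x$sequence),
              substr(x$sequence, 1, 8), x$numbering_offset))
  invisible(x)
}

#' @export
length.ensemble <- function(x) length(x$conformers)

#' Read a conformational ensemble
#'
#' Reads a multi-model PDB file (every MODEL record is one frame; files
#' without MODEL records are single-frame) into an \code{\link{ensemble}}.
#' Frame weights default to 1.  Author numbering in the file is preserved
#' through \code{numbering_offset}; internally residues are renumbered
#' 1-based contiguous.
#'
#' @param path path to a PDB file.
#' @param format \code{"pdb"} (multi-model PDB, via \pkg{bio3d}).  Other
#'   ensemble formats can be plugged in through \code{reader}.
#' @param numbering_offset author-numbering offset; inferred from the first
#'   residue id in the file when \code{NULL}.
#' @param reader optional function \code{(path) -> ensemble} implementing an
#'   additional format behind the same interface.
#' @return an \code{\link{ensemble}}.
#' @export
load_ensemble <- function(path, format = c("pdb", "custom"),
                          numbering_offset = NULL, reader = NULL) {
  format <- match.arg(format)
  if (format == "custom") {
    if (is.null(reader)) stop("format = 'custom' requires a reader function")
    return(reader(path))
  }
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in ", path)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_frames <- nrow(xyz)
  if (n_frames == 0) stop("zero frames in ", path)
  keep <- which(pdb$atom$type == "ATOM")
  resno_file <- at$resno
  ur <- unique(resno_file)
  if (is.null(numbering_offset)) numbering_offset <- min(ur) - 1L
  internal <- match(resno_file, ur)
  if (!identical(sort(unique(internal)), seq_along(ur)))
    stop("residue numbering not resolvable in ", path)
  atoms <- data.frame(resno = internal, resid = at$resid, elety = at$elety,
                      stringsAsFactors = FALSE)
  cols <- as.vector(t(cbind((keep - 1) * 3 + 1, (keep - 1) * 3 + 2,
                            (keep - 1) * 3 + 3)))
  conformers <- lapply(seq_len(n_frames), function(i) {
    m <- matrix(xyz[i, cols], ncol = 3, byrow = TRUE)
    conformer(m, atoms, frame_id = i, weight = 1, offset = numbering_offset)
  })
  ensemble(conformers, numbering_offset = numbering_offset)
}

#' Write an ensemble as a multi-model PDB file
#'
#' Each conformer becomes one MODEL; coordinates are written at standard PDB
#' precision (0.001 A).  The file round-trips through
#' \code{\link{load_ensemble}}.
#'
#' @param x an \code{\link{ensemble}} or single \code{\link{conformer}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_ensemble <- function(x, path) {
  if (inherits(x, "conformer")) x <- ensemble(list(x), numbering_offset = x$offset)
  stopifnot(inherits(x, "ensemble"))
  con <- file(path, "w")
  on.exit(close(con))
  off <- x$numbering_offset
  for (cf in x$conformers) {
    writeLines(sprintf("MODEL     %4d", cf$frame_id), con)
    elem <- sub("^[0-9]*", "", cf$atoms$elety)
    elem <- substr(elem, 1, 1)
    lines <- sprintf(
      "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(cf$atoms)),
      ifelse(nchar(cf$atoms$elety) < 4, paste0(" ", cf$atoms$elety),
             cf$atoms$elety),
      cf$atoms$resid, cf$atoms$resno + off,
      cf$xyz[, 1], cf$xyz[, 2], cf$xyz[, 3], 1, 0, elem)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# -- Region conventions -----------------------------------------------------

#' Residue-region map for hairpin classification
#'
#' Defines, in author numbering, the residue sets that parameterise the
#' hairpin classifiers: the aggregation-prone hexapeptide, the subset of it
#' scored by the span criterion, the even/odd parity sets, the N-terminal
#' arm, the excluded termini, and the turn region.  The default
#' \code{"tau295_default"} reproduces the tau 295-311 conventions: the PHF6
#' hexapeptide VQIVYK at 306-311, scored residues 306-310, even set
#' \{306, 308, 310\}, odd set \{305, 307, 309\}, N-arm 296-304, excluded
#' termini \{295, 311\} and turn 301-304.
#'
#' @param sequence one-letter sequence the regions refer to.
#' @param spec \code{"tau295_default"} or a named list overriding any of the
#'   fields \code{hexapeptide}, \code{scored_hex}, \code{even_set},
#'   \code{odd_set}, \code{n_arm}, \code{excluded_termini}, \code{turn}
#'   (author-numbered integer vectors).
#' @param numbering_offset author id = internal index + offset (294 for the
#'   tau 295-311 peptide).
#' @return an object of class \code{"region_map"}.
#' @export
make_region_map <- function(sequence, spec = "tau295_default",
                            numbering_offset = 294L) {
  defaults <- list(hexapeptide = 306:311, scored_hex = 306:310,
                   even_set = c(306L, 308L, 310L), odd_set = c(305L, 307L, 309L),
                   n_arm = 296:304, excluded_termini = c(295L, 311L),
                   turn = 301:304)
  if (identical(spec, "tau295_default")) {
    rm_ <- defaults
  } else if (is.list(spec)) {
    unknown <- setdiff(names(spec), names(defaults))
    if (length(unknown) > 0)
      stop("unknown region field(s): ", paste(unknown, collapse = ", "))
    rm_ <- utils::modifyList(defaults, spec)
  } else stop("spec must be 'tau295_default' or a named list")
  rm_ <- lapply(rm_, function(v) sort(as.integer(v)))
  if (length(intersect(rm_$even_set, rm_$odd_set)) > 0)
    stop("even_set and odd_set overlap")
  if (length(intersect(rm_$excluded_termini,
                       union(rm_$even_set, rm_$odd_set))) > 0)
    stop("excluded termini cannot carry parity assignments")
  lo <- numbering_offset + 1L
  hi <- numbering_offset + nchar(sequence)
  all_ids <- unlist(rm_, use.names = FALSE)
  if (any(all_ids < lo | all_ids > hi))
    stop(sprintf("region residue ids outside sequence range %d-%d", lo, hi))
  structure(c(rm_, list(sequence = sequence,
                        numbering_offset = as.integer(numbering_offset))),
            class = "region_map")
}

#' @export
print.region_map <- function(x, ...) {
  cat("<region_map>\n")
  cat("  hexapeptide:", paste(range(x$hexapeptide), collapse = "-"),
      " scored:", paste(range(x$scored_hex), collapse = "-"), "\n")
  cat("  even:", paste(x$even_set, collapse = ","),
      " odd:", paste(x$odd_set, collapse = ","), "\n")
  cat("  n_arm:", paste(range(x$n_arm), collapse = "-"),
      " turn:", paste(range(x$turn), collapse = "-"),
      " excluded:", paste(x$excluded_termini, collapse = ","), "\n")
  invisible(x)
}

# -- Mutant library table ---------------------------------------------------

#' Load a mutant-library table
#'
#' Reads a CSV with one row per mutant: \code{mutant_id}, \code{sequence},
#' \code{numbering_offset}, and optionally \code{experimental_T_half}
#' (hours; empty/missing allowed for structural-only runs).
#'
#' @param path CSV file path.
#' @return data.frame of class \code{"mutant_table"}.
#' @export
load_mutant_table <- function(path) {
  tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("mutant_id", "sequence", "numbering_offset")
  miss <- setdiff(need, names(tb))
  if (length(miss) > 0)
    stop("mutant table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(tb$mutant_id))
    stop("duplicate mutant_id: ",
         paste(unique(tb$mutant_id[duplicated(tb$mutant_id)]), collapse = ", "))
  if (length(unique(nchar(tb$sequence))) > 1)
    stop("sequences in a library must share one length")
  if (!"experimental_T_half" %in% names(tb)) {
    tb$experimental_T_half <- NA_real_
  } else {
    tb$experimental_T_half <- suppressWarnings(as.numeric(tb$experimental_T_half))
    bad <- !is.na(tb$experimental_T_half) & tb$experimental_T_half <= 0
    if (any(bad)) stop("experimental_T_half must be positive where present")
  }
  class(tb) <- c("mutant_table", "data.frame")
  tb
}

# -- Built-in sequences -----------------------------------------------------

#' Reference tau sequences
#'
#' \code{tau295_sequence()} returns the 17-residue tau 295-311 peptide
#' (DNIKHVPGGGSVQIVYK, author numbering offset +294).
#' \code{tau_k18_sequence()} returns the four-repeat k18 fragment
#' (residues 244-372, offset +243).
#'
#' @return one-letter character string.
#' @export
tau295_sequence <- function() "DNIKHVPGGGSVQIVYK"

#' @rdname tau295_sequence
#' @export
tau_k18_sequence <- function() {
  paste0("QTAPVPMPDLKNVKSKIGSTENLKHQPGGGK",
         "VQIINKKLDLSNVQSKCGSKDNIKHVPGGGS",
         "VQIVYKPVDLSKVTSKCGSLGNIHHKPGGGQ",
         "VEVKSEKLDFKDRVQSKIGSLDNITHVPGGGN",
         "KKIE")
}
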