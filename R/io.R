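#' Construct a conformational ensemble
#'
#' An `ensemble` holds a fixed set of atoms and their coordinates over one or
#' more frames (models), following the trajectory convention of a frames x 3N
#' coordinate matrix with each atom's x, y, z in consecutive columns.
#'
#' @param atoms data.frame with one row per atom: columns `chain`, `resno`
#'   (author numbering), `resid` (3-letter residue name), `elety` (atom name),
#'   and optionally `b` (B-factor, set to 0 when absent).
#' @param xyz numeric matrix, `n_frames` x `3 * nrow(atoms)`; or a numeric
#'   vector for a single frame.
#' @param dt_ps frame spacing in picoseconds (metadata only).
#' @return object of class `ensemble`.
#' @export
ensemble <- function(atoms, xyz, dt_ps = 100) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  stopifnot(is.data.frame(atoms),
            all(c("chain", "resno", "resid", "elety") %in% names(atoms)))
  if (ncol(xyz) != 3 * nrow(atoms)) {
    stop("xyz has ", ncol(xyz), " columns but atoms table implies ",
         3 * nrow(atoms))
  }
  if (!all(is.finite(xyz))) stop("non-finite coordinates in ensemble")
  if (is.null(atoms$b)) atoms$b <- 0
  structure(list(atoms = atoms, xyz = xyz, dt_ps = dt_ps),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat("ensemble:", nrow(x$xyz), "frame(s),", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$resno)), "residues; frame spacing",
      x$dt_ps, "ps\n")
  invisible(x)
}

#' Number of frames in an ensemble
#' @param x an `ensemble`.
#' @return integer frame count.
#' @export
n_frames <- function(x) nrow(x$xyz)

#' Select atom indices from an ensemble
#'
#' @param x an `ensemble`.
#' @param elety optional atom-name filter (e.g. `"CA"`).
#' @param resno optional residue-number filter.
#' @param chain optional chain filter.
#' @return integer vector of atom row indices.
#' @export
select_atoms <- function(x, elety = NULL, resno = NULL, chain = NULL) {
  keep <- rep(TRUE, nrow(x$atoms))
  if (!is.null(elety)) keep <- keep & x$atoms$elety %in% elety
  if (!is.null(resno)) keep <- keep & x$atoms$resno %in% resno
  if (!is.null(chain)) keep <- keep & x$atoms$chain %in% chain
  which(keep)
}

#' Extract one frame's coordinates as an n x 3 matrix
#' @param x an `ensemble`.
#' @param frame frame index.
#' @param inds optional atom indices.
#' @return numeric matrix with one row per atom.
#' @export
frame_coords <- function(x, frame = 1, inds = NULL) {
  v <- x$xyz[frame, ]
  m <- matrix(v, ncol = 3, byrow = TRUE)
  if (!is.null(inds)) m <- m[inds, , drop = FALSE]
  m
}

xyz_cols <- function(inds) as.vector(rbind(3 * inds - 2, 3 * inds - 1, 3 * inds))

#' Read a multi-model PDB file as an ensemble
#'
#' Parses a multi-model (MODEL/ENDMDL) PDB file; each model becomes one frame.
#' All models must contain the same atoms in the same order. Only the first
#' alternate location of an atom is kept; insertion codes are rejected.
#'
#' @param path path to a PDB file.
#' @param chain optional single chain id to keep.
#' @param resno_range optional length-2 inclusive residue-number range.
#' @param dt_ps frame spacing metadata in picoseconds.
#' @return an [ensemble()].
#' @export
read_ensemble <- function(path, chain = NULL, resno_range = NULL, dt_ps = 100) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  lines <- readLines(path)
  atom_lines <- grepl("^ATOM  |^HETATM", lines)
  if (!any(atom_lines)) stop("'", path, "' contains no ATOM records")
  # pre-scan MODEL blocks for consistent atom counts before delegating parsing
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 1) {
    model_id <- cumsum(grepl("^MODEL", lines))
    counts <- table(model_id[atom_lines])
    if (length(unique(counts)) > 1) {
      bad <- names(counts)[counts != counts[1]][1]
      stop("inconsistent atom count across models: model ", bad,
           " has ", counts[bad], " atoms, model 1 has ", counts[1])
    }
  }
  icodes <- substr(lines[atom_lines], 27, 27)
  if (any(icodes != " ")) stop("insertion codes are not supported")

  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  sel <- rep(TRUE, nrow(at))
  if (!is.null(chain)) sel <- sel & at$chain %in% chain
  if (!is.null(resno_range)) {
    sel <- sel & at$resno >= resno_range[1] & at$resno <= resno_range[2]
  }
  # first altloc only
  sel <- sel & (is.na(at$alt) | at$alt %in% c("", "A"))
  if (!any(sel)) stop("selection matches no atoms in '", path, "'")
  inds <- which(sel)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  atoms <- data.frame(chain = at$chain[inds], resno = at$resno[inds],
                      resid = at$resid[inds], elety = at$elety[inds],
                      b = at$b[inds], stringsAsFactors = FALSE)
  atoms$chain[is.na(atoms$chain)] <- "A"
  ensemble(atoms, xyz[, xyz_cols(inds), drop = FALSE], dt_ps = dt_ps)
}

#' Write an ensemble as a multi-model PDB file
#'
#' Emits standard fixed-width ATOM records wrapped in MODEL/ENDMDL blocks,
#' one model per frame; coordinates are written at PDB precision (0.001 A).
#'
#' @param x an `ensemble`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(x, path) {
  at <- x$atoms
  name4 <- ifelse(nchar(at$elety) < 4, sprintf(" %-3s", at$elety),
                  sprintf("%-4s", at$elety))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nrow(x$xyz))) {
    m <- frame_coords(x, f)
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(sprintf(
      "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      seq_len(nrow(at)), name4, at$resid, at$chain, at$resno,
      m[, 1], m[, 2], m[, 3], 1.00, at$b), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
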