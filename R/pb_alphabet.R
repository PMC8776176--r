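# Protein Blocks: a 16-letter structural alphabet of local backbone
# prototypes. Each letter (a..p) is defined by 8 reference dihedrals over a
# 5-residue window -- psi(i-2), phi(i-1), psi(i-1), phi(i), psi(i),
# phi(i+1), psi(i+1), phi(i+2) -- and a residue is assigned the letter whose
# reference window is nearest in angular RMSD. Letter Z marks positions that
# cannot be assigned (incomplete window).

PB_LETTERS <- letters[1:16]

.pbflex_env <- new.env(parent = emptyenv())

#' The Protein Block reference alphabet
#'
#' Loads the canonical 16-prototype dihedral table shipped with the package
#' (`inst/extdata/pb_reference_angles.tsv`, provenance in its header).
#'
#' @return list with `letters` (a..p), `ref` (16 x 8 matrix of reference
#'   dihedrals in degrees, rows named by letter, columns
#'   `psi_m2 ... phi_p2`), and `category` (named secondary-structure
#'   annotation per letter: m ~ helix core, d ~ central strand, etc.).
#' @export
pb_alphabet <- function() {
  if (!is.null(.pbflex_env$alphabet)) return(.pbflex_env$alphabet)
  path <- system.file("extdata", "pb_reference_angles.tsv", package = "pbflex",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(identical(tab$pb, PB_LETTERS))
  ref <- as.matrix(tab[, 2:9])
  rownames(ref) <- tab$pb
  stopifnot(all(ref > -180 & ref <= 180))
  ab <- list(letters = tab$pb, ref = ref,
             category = stats::setNames(tab$category, tab$pb))
  .pbflex_env$alphabet <- ab
  ab
}

#' Angular RMSD between a dihedral window and every PB prototype
#'
#' Dissimilarity used for assignment: sqrt of the mean squared minimal
#' angular difference over the 8 window dihedrals (360-degree wraparound).
#'
#' @param windows numeric 8-vector, or an n x 8 matrix of windows.
#' @param alphabet a [pb_alphabet()].
#' @return n x 16 matrix of angular RMSDs in degrees.
#' @export
pb_distances <- function(windows, alphabet = pb_alphabet()) {
  if (is.null(dim(windows))) windows <- matrix(windows, nrow = 1)
  stopifnot(ncol(windows) == 8)
  d <- matrix(NA_real_, nrow(windows), 16,
              dimnames = list(NULL, alphabet$letters))
  for (l in seq_len(16)) {
    diff <- angular_diff(windows, matrix(alphabet$ref[l, ], nrow(windows), 8,
                                         byrow = TRUE))
    d[, l] <- sqrt(rowMeans(diff^2))
  }
  d
}

#' Assign a PB letter to a single dihedral window
#'
#' Returns the letter of the nearest prototype in angular RMSD; exact ties
#' are broken alphabetically (a first). A window containing any undefined
#' angle is unassignable and returns `"Z"`.
#'
#' @param window numeric 8-vector: psi(i-2), phi(i-1), psi(i-1), phi(i),
#'   psi(i), phi(i+1), psi(i+1), phi(i+2), degrees.
#' @param alphabet a [pb_alphabet()].
#' @return single character in `a..p`, or `"Z"`.
#' @export
assign_pb_window <- function(window, alphabet = pb_alphabet()) {
  stopifnot(length(window) == 8)
  if (any(is.na(window))) return("Z")
  d <- pb_distances(window, alphabet)
  alphabet$letters[which.min(d)]   # which.min takes the first = alphabetical
}

#' Assign PB letters to every residue of every frame
#'
#' Slides the 5-residue window along the chain for each frame and assigns the
#' central residue. The first two and last two positions, and any position
#' whose window includes an undefined dihedral, are `"Z"`.
#'
#' @param dihedrals a `dihedral_series` (see [compute_dihedrals()]).
#' @param alphabet a [pb_alphabet()].
#' @return a `pb_ensemble`: character matrix frames x positions over
#'   `{a..p, Z}` with residue numbers as column names.
#' @export
assign_ensemble <- function(dihedrals, alphabet = pb_alphabet()) {
  phi <- dihedrals$phi
  psi <- dihedrals$psi
  n <- ncol(phi)
  if (n < 5) stop("chain has ", n, " residues; PB assignment needs >= 5")
  nf <- nrow(phi)
  out <- matrix("Z", nf, n, dimnames = list(NULL, dihedrals$resno))
  for (i in 3:(n - 2)) {
    w <- cbind(psi[, i - 2], phi[, i - 1], psi[, i - 1], phi[, i], psi[, i],
               phi[, i + 1], psi[, i + 1], phi[, i + 2])
    ok <- rowSums(is.na(w)) == 0
    if (any(ok)) {
      d <- pb_distances(w[ok, , drop = FALSE], alphabet)
      out[ok, i] <- alphabet$letters[apply(d, 1, which.min)]
    }
  }
  pb_ensemble(out, as.integer(dihedrals$resno))
}

#' Construct a PB ensemble
#'
#' @param letters character matrix frames x positions over `{a..p, Z}`.
#' @param resno residue numbers labelling positions.
#' @return object of class `pb_ensemble` (a character matrix with residue
#'   numbers as column names).
#' @export
pb_ensemble <- function(letters, resno = seq_len(ncol(letters))) {
  stopifnot(is.matrix(letters), is.character(letters),
            ncol(letters) == length(resno))
  bad <- setdiff(unique(as.vector(letters)), c(PB_LETTERS, "Z"))
  if (length(bad) > 0) {
    stop("invalid PB letters: ", paste(bad, collapse = ", "))
  }
  colnames(letters) <- resno
  structure(letters, class = c("pb_ensemble", "matrix"))
}

#' @export
print.pb_ensemble <- function(x, ...) {
  cat("pb_ensemble:", nrow(x), "frame(s) x", ncol(x), "positions (residues",
      colnames(x)[1], "to", colnames(x)[ncol(x)], ")\n")
  invisible(x)
}

#' Residue numbers of a PB ensemble
#' @param x a `pb_ensemble`.
#' @return integer vector.
#' @export
pb_resno <- function(x) as.integer(colnames(x))

#' Write a PB ensemble as PB-fasta
#'
#' One record per frame; the sequence is the frame's letter string over
#' `{a..p, Z}` (the de-facto dialect of PB assignment tools). The residue
#' range is recorded on each header.
#'
#' @param x a `pb_ensemble`.
#' @param path output file path.
#' @param label system label used in headers.
#' @return `path`, invisibly.
#' @export
write_pb_fasta <- function(x, path, label = "system") {
  resno <- pb_resno(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nrow(x))) {
    writeLines(sprintf(">%s | frame %d | residues %d-%d",
                       label, f, resno[1], resno[length(resno)]), con)
    writeLines(paste(x[f, ], collapse = ""), con)
  }
  invisible(path)
}

#' Read a PB-fasta file
#'
#' @param path PB-fasta file written by [write_pb_fasta()] or a compatible
#'   tool (one record per frame, equal-length sequences over `{a..p, Z}`).
#' @return a `pb_ensemble`; residue numbers are recovered from the header
#'   `residues N-M` tag when present, else `1..n`.
#' @export
read_pb_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("'", path, "' is not a PB-fasta file")
  rec <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], rec[!hdr]),
                 function(ss) paste(ss, collapse = ""), character(1))
  lens <- unique(nchar(seqs))
  if (length(lens) != 1) stop("frames differ in sequence length")
  m <- do.call(rbind, strsplit(seqs, ""))
  first_hdr <- lines[hdr][1]
  resno <- seq_len(lens)
  rr <- regmatches(first_hdr,
                   regexec("residues ([0-9]+)-([0-9]+)", first_hdr))[[1]]
  if (length(rr) == 3) {
    resno <- as.integer(rr[2]):as.integer(rr[3])
  }
  pb_ensemble(unname(m), resno)
}
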