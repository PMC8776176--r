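#' Torsion angle of four points
#'
#' Signed dihedral about the b-c axis in the IUPAC convention: 0 for a cis
#' (eclipsed) arrangement, 180 for trans, positive for clockwise rotation
#' viewed from b towards c. Vectorised over rows.
#'
#' @param a,b,c,d numeric n x 3 matrices (or length-3 vectors) of coordinates.
#' @return torsion angles in degrees, range (-180, 180].
#' @export
torsion_angle <- function(a, b, c, d) {
  as_m <- function(p) if (is.null(dim(p))) matrix(p, ncol = 3) else p
  a <- as_m(a); b <- as_m(b); c <- as_m(c); d <- as_m(d)
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  cross <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                                u[, 3] * v[, 1] - u[, 1] * v[, 3],
                                u[, 1] * v[, 2] - u[, 2] * v[, 1])
  n1 <- cross(b1, b2)
  n2 <- cross(b2, b3)
  m1 <- cross(b2 / sqrt(rowSums(b2^2)), n1)
  ang <- atan2(rowSums(m1 * n2), rowSums(n1 * n2)) * 180 / pi
  wrap_angle(ang)
}

#' Backbone phi/psi dihedrals of every frame
#'
#' For each frame, phi_i is the C(i-1)-N(i)-CA(i)-C(i) torsion and psi_i the
#' N(i)-CA(i)-C(i)-N(i+1) torsion. The first residue's phi and the last
#' residue's psi do not exist and are returned as `NA`.
#'
#' @param x an [ensemble()]; every residue must carry N, CA and C atoms.
#' @return a `dihedral_series`: list with `phi` and `psi` (each an
#'   `n_frames` x `n_residues` matrix in degrees, `NA` where undefined) and
#'   `resno` (residue numbers, also the matrix column names).
#' @export
compute_dihedrals <- function(x) {
  resno <- unique(x$atoms$resno)
  n <- length(resno)
  idx <- function(ele) {
    i <- vapply(resno, function(r) {
      j <- which(x$atoms$resno == r & x$atoms$elety == ele)
      if (length(j) == 0) {
        stop("residue ", r, " is missing backbone atom ", ele)
      }
      j[1]
    }, integer(1))
    i
  }
  iN <- idx("N"); iCA <- idx("CA"); iC <- idx("C")
  nf <- nrow(x$xyz)
  phi <- matrix(NA_real_, nf, n, dimnames = list(NULL, resno))
  psi <- matrix(NA_real_, nf, n, dimnames = list(NULL, resno))
  for (f in seq_len(nf)) {
    m <- frame_coords(x, f)
    if (n >= 2) {
      phi[f, 2:n] <- torsion_angle(m[iC[1:(n - 1)], , drop = FALSE],
                                   m[iN[2:n], , drop = FALSE],
                                   m[iCA[2:n], , drop = FALSE],
                                   m[iC[2:n], , drop = FALSE])
      psi[f, 1:(n - 1)] <- torsion_angle(m[iN[1:(n - 1)], , drop = FALSE],
                                         m[iCA[1:(n - 1)], , drop = FALSE],
                                         m[iC[1:(n - 1)], , drop = FALSE],
                                         m[iN[2:n], , drop = FALSE])
    }
  }
  dihedral_series(phi, psi, resno)
}

#' Construct a dihedral series
#'
#' @param phi,psi frames x residues matrices of angles in degrees, `NA` where
#'   undefined (phi of the first residue, psi of the last).
#' @param resno residue numbers labelling the columns.
#' @return object of class `dihedral_series`.
#' @export
dihedral_series <- function(phi, psi, resno) {
  stopifnot(all(dim(phi) == dim(psi)), ncol(phi) == length(resno))
  if (any(!is.na(phi)) || any(!is.na(psi))) {
    rng <- range(c(phi, psi), na.rm = TRUE)
    if (rng[1] <= -180 || rng[2] > 180) {
      stop("dihedral angles must lie in (-180, 180]")
    }
  }
  colnames(phi) <- colnames(psi) <- resno
  structure(list(phi = phi, psi = psi, resno = resno),
            class = "dihedral_series")
}

#' Minimum (Kabsch) RMSD between two coordinate sets
#'
#' Root-mean-square deviation after least-squares rigid-body superposition
#' (optimal rotation and translation).
#'
#' @param a,b numeric n x 3 coordinate matrices, equal n >= 3.
#' @return RMSD in the coordinate units (Angstrom for PDB input).
#' @export
kabsch_rmsd <- function(a, b) {
  stopifnot(is.matrix(a), is.matrix(b), ncol(a) == 3, ncol(b) == 3)
  if (nrow(a) != nrow(b)) {
    stop("coordinate sets differ in size: ", nrow(a), " vs ", nrow(b))
  }
  if (nrow(a) < 3) stop("need at least 3 points for superposition")
  va <- as.vector(t(a))
  fitted <- bio3d::fit.xyz(fixed = va, mobile = as.vector(t(b)),
                           fixed.inds = seq_along(va),
                           mobile.inds = seq_along(va))
  # full-precision RMSD from the fitted coordinates (bio3d::rmsd rounds)
  sqrt(mean(rowSums((a - matrix(fitted, ncol = 3, byrow = TRUE))^2)))
}

#' Per-residue RMSF over an ensemble
#'
#' Root-mean-square fluctuation of each Calpha over frames. Each frame is
#' first superposed (one Kabsch pass) onto the reference -- the ensemble
#' average structure by default, or the first frame -- and the mean structure
#' is recomputed once after alignment before fluctuations are measured:
#' RMSF_i = sqrt(mean over frames of |x_i - <x_i>|^2).
#'
#' @param x an [ensemble()].
#' @param elety atom selection; Calpha by default.
#' @param fit superpose frames before measuring? Default `TRUE`.
#' @param reference `"mean"` (default) or `"first"` frame as fitting target.
#' @param unit `"A"` (Angstrom, default) or `"nm"`.
#' @param burnin number of leading frames discarded before the calculation.
#' @return data.frame with `resno` and `rmsf`.
#' @export
rmsf_profile <- function(x, elety = "CA", fit = TRUE,
                         reference = c("mean", "first"), unit = c("A", "nm"),
                         burnin = 0) {
  reference <- match.arg(reference)
  unit <- match.arg(unit)
  inds <- select_atoms(x, elety = elety)
  if (length(inds) == 0) stop("no atoms match selection '", elety, "'")
  xyz <- x$xyz[, xyz_cols(inds), drop = FALSE]
  if (burnin > 0) {
    if (burnin >= nrow(xyz)) stop("burn-in discards every frame")
    xyz <- xyz[-seq_len(burnin), , drop = FALSE]
  }
  resno <- x$atoms$resno[inds]
  if (nrow(xyz) < 2) {
    warning("single-frame ensemble: RMSF is identically zero")
    return(data.frame(resno = resno, rmsf = rep(0, length(inds))))
  }
  if (fit && length(inds) >= 3) {
    ref <- if (reference == "mean") colMeans(xyz) else xyz[1, ]
    xyz <- bio3d::fit.xyz(fixed = ref, mobile = xyz,
                          fixed.inds = seq_along(ref),
                          mobile.inds = seq_along(ref))
  }
  mu <- colMeans(xyz)
  dev2 <- sweep(xyz, 2, mu)^2
  per_atom <- sqrt(colMeans(dev2[, seq(1, ncol(xyz), 3), drop = FALSE] +
                            dev2[, seq(2, ncol(xyz), 3), drop = FALSE] +
                            dev2[, seq(3, ncol(xyz), 3), drop = FALSE]))
  if (unit == "nm") per_atom <- per_atom / 10
  data.frame(resno = resno, rmsf = as.numeric(per_atom))
}

#' Convert RMSF to an equivalent crystallographic B-factor
#'
#' Uses the isotropic relation B = (8 pi^2 / 3) RMSF^2, which ties the
#' thermal factor to the mean square displacement of the atom. Intended for
#' side-by-side comparison of simulated fluctuations with the B-factor
#' column of an experimental structure.
#'
#' @param rmsf non-negative fluctuation in Angstrom (vectorised).
#' @return B-factor in Angstrom^2.
#' @examples
#' bfactor_from_rmsf(1)  # 8 pi^2 / 3 ~ 26.32
#' @export
bfactor_from_rmsf <- function(rmsf) {
  stopifnot(all(rmsf >= 0))
  (8 * pi^2 / 3) * rmsf^2
}

#' Fraction of frames in which two atom groups are in contact
#'
#' A frame counts as a contact when the minimum distance between any site
#' atom and any partner atom is at or below the cutoff. Useful for, e.g.,
#' the persistence of a Ca2+ ion's coordination by nearby side-chain oxygens
#' over a trajectory. The per-residue breakdown reports, for each partner
#' residue, the fraction of frames in which that residue alone satisfies
#' the cutoff.
#'
#' @param x an [ensemble()].
#' @param site integer atom indices of the site (e.g. the ion).
#' @param partner integer atom indices of candidate coordinating atoms.
#' @param cutoff contact distance in Angstrom (default 3.0).
#' @return list with `fraction` (overall persistence) and `by_residue`
#'   (data.frame `resno`, `fraction`).
#' @export
contact_persistence <- function(x, site, partner, cutoff = 3.0) {
  if (length(site) == 0 || length(partner) == 0) {
    stop("site and partner selections must be non-empty")
  }
  nf <- nrow(x$xyz)
  pres <- x$atoms$resno[partner]
  hit_any <- logical(nf)
  hit_res <- matrix(FALSE, nf, length(unique(pres)),
                    dimnames = list(NULL, unique(pres)))
  for (f in seq_len(nf)) {
    s <- frame_coords(x, f, site)
    p <- frame_coords(x, f, partner)
    d2 <- outer(rowSums(s^2), rowSums(p^2), "+") - 2 * s %*% t(p)
    dmin_per_atom <- sqrt(pmax(apply(d2, 2, min), 0))
    hit_any[f] <- any(dmin_per_atom <= cutoff)
    in_contact <- tapply(dmin_per_atom <= cutoff, pres, any)
    hit_res[f, names(in_contact)] <- in_contact
  }
  list(fraction = mean(hit_any),
       by_residue = data.frame(resno = as.integer(colnames(hit_res)),
                               fraction = colMeans(hit_res)))
}
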