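# Synthetic conformational ensembles with known per-position PB statistics.
# Stands in for MD trajectories in tests: the generator controls the exact
# categorical distribution of local conformations at every position, so the
# downstream estimates (frequencies, Neq, dPB, long-range flags) can be
# checked against analytic ground truth.

# ideal backbone internal coordinates (Engh & Huber-type standard values)
.BOND_N_CA <- 1.458
.BOND_CA_C <- 1.525
.BOND_C_N <- 1.329
.ANGLE_N_CA_C <- 111.2
.ANGLE_CA_C_N <- 116.2
.ANGLE_C_N_CA <- 121.7
.OMEGA_TRANS <- 180

#' Specification for a synthetic ensemble
#'
#' Describes the ground truth a synthetic system is drawn from: the residue
#' range, a target PB distribution per position, the sampling design
#' (frames per replicate, number of independent replicates, emulating an
#' 11-replicate MD campaign with frames saved every 100 ps), angular noise,
#' and the generation mode.
#'
#' @param resno integer vector of consecutive residue numbers.
#' @param targets per-position target distribution over the 16 PBs: a single
#'   named vector (recycled to every position, see [pb_target()]), a list of
#'   one per position, or an `n x 16` matrix.
#' @param n_frames frames per replicate (default 100).
#' @param n_replicates independent replicates (default 11).
#' @param sigma wrapped-Gaussian dihedral noise, degrees (default 10); only
#'   used by the geometry/coordinate modes.
#' @param mode `"string"` (PB letters directly), `"geometry"` (dihedrals),
#'   or `"coordinate"` (dihedrals realised as a backbone chain).
#' @param seed RNG seed (default 1).
#' @param dt_ps frame spacing metadata (default 100).
#' @return object of class `generator_spec`.
#' @export
generator_spec <- function(resno, targets, n_frames = 100, n_replicates = 11,
                           sigma = 10, mode = c("string", "geometry",
                                                "coordinate"),
                           seed = 1, dt_ps = 100) {
  mode <- match.arg(mode)
  n <- length(resno)
  stopifnot(n >= 1, n_frames >= 1, n_replicates >= 1)
  if (sigma < 0) stop("dihedral noise sigma must be >= 0")
  if (is.list(targets)) {
    stopifnot(length(targets) == n)
    tm <- do.call(rbind, lapply(targets, pb_target))
  } else if (is.matrix(targets)) {
    stopifnot(nrow(targets) == n, ncol(targets) == 16)
    tm <- targets
  } else {
    tm <- matrix(pb_target(targets), n, 16, byrow = TRUE)
  }
  colnames(tm) <- PB_LETTERS
  rownames(tm) <- resno
  if (any(tm < 0) || any(abs(rowSums(tm) - 1) > 1e-9)) {
    stop("each position's target distribution must be normalised")
  }
  structure(list(resno = as.integer(resno), targets = tm,
                 n_frames = n_frames, n_replicates = n_replicates,
                 sigma = sigma, mode = mode, seed = seed, dt_ps = dt_ps),
            class = "generator_spec")
}

draw_labels <- function(spec) {
  n <- length(spec$resno)
  per_rep <- lapply(seq_len(spec$n_replicates), function(r) {
    set.seed(spec$seed + r - 1L)
    m <- matrix("", spec$n_frames, n)
    for (i in seq_len(n)) {
      m[, i] <- sample(PB_LETTERS, spec$n_frames, replace = TRUE,
                       prob = spec$targets[i, ])
    }
    m
  })
  labels <- do.call(rbind, per_rep)
  attr(labels, "replicate") <- rep(seq_len(spec$n_replicates),
                                   each = spec$n_frames)
  labels
}

#' Generate a PB ensemble by direct letter sampling (string mode)
#'
#' Each frame's letter at each position is drawn i.i.d. from that position's
#' target distribution; replicates use consecutive seeds derived from the
#' spec seed. This mode realises arbitrary per-position mixtures exactly
#' and is the reference surface for parameter-recovery tests.
#'
#' @param spec a [generator_spec()].
#' @return a `pb_ensemble` with a `replicate` attribute (per-frame ids).
#' @export
generate_string_mode <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  labels <- draw_labels(spec)
  out <- pb_ensemble(unclass(labels)[, , drop = FALSE], spec$resno)
  attr(out, "replicate") <- attr(labels, "replicate")
  out
}

#' Generate dihedrals (and optionally coordinates) from PB targets
#'
#' For each frame, a PB label is drawn per position from its target
#' distribution and the residue's (phi, psi) are set to that PB's central
#' reference dihedrals plus wrapped Gaussian noise of `sigma` degrees.
#' In `"coordinate"` mode the dihedrals are additionally realised as a
#' backbone chain (N, CA, C per residue) with ideal bond geometry and trans
#' peptide bonds, returned as a multi-model-ready [ensemble()].
#'
#' Because adjacent PB windows share dihedrals, arbitrary per-position
#' mixtures are not simultaneously realisable in geometry mode; exact
#' assignment recovery is guaranteed only for locally consistent label
#' paths (homogeneous segments) at zero noise.
#'
#' @param spec a [generator_spec()] with mode `"geometry"` or
#'   `"coordinate"`.
#' @return list with `dihedrals` (a `dihedral_series`), `labels` (the drawn
#'   letter matrix, a `pb_ensemble`), `replicate` ids, and `ensemble` (in
#'   coordinate mode, else `NULL`).
#' @export
generate_geometry_mode <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  if (spec$mode == "string") stop("spec mode is 'string'; use ",
                                  "generate_string_mode()")
  ab <- pb_alphabet()
  labels <- draw_labels(spec)
  replicate <- attr(labels, "replicate")
  nf <- nrow(labels)
  n <- length(spec$resno)
  # central-residue reference angles per letter: phi = phi_0, psi = psi_0
  phi_ref <- stats::setNames(ab$ref[, "phi_0"], ab$letters)
  psi_ref <- stats::setNames(ab$ref[, "psi_0"], ab$letters)
  phi <- matrix(phi_ref[labels], nf, n)
  psi <- matrix(psi_ref[labels], nf, n)
  if (spec$sigma > 0) {
    # noise frames follow the label draws in the same per-replicate streams
    set.seed(spec$seed + spec$n_replicates)
    phi <- phi + matrix(stats::rnorm(nf * n, 0, spec$sigma), nf, n)
    psi <- psi + matrix(stats::rnorm(nf * n, 0, spec$sigma), nf, n)
  }
  phi <- wrap_angle(phi)
  psi <- wrap_angle(psi)
  # chain termini: phi of the first and psi of the last residue do not exist
  phi[, 1] <- NA
  psi[, n] <- NA
  dih <- dihedral_series(phi, psi, spec$resno)
  ens <- NULL
  if (spec$mode == "coordinate") {
    xyz <- t(vapply(seq_len(nf), function(f) {
      as.vector(t(build_backbone(phi[f, ], psi[f, ])))
    }, numeric(9 * n)))
    atoms <- data.frame(
      chain = "A",
      resno = rep(spec$resno, each = 3),
      resid = "ALA",
      elety = rep(c("N", "CA", "C"), n),
      b = 0, stringsAsFactors = FALSE)
    ens <- ensemble(atoms, xyz, dt_ps = spec$dt_ps)
  }
  list(dihedrals = dih, labels = pb_ensemble(unclass(labels), spec$resno),
       replicate = replicate, ensemble = ens)
}

#' Build backbone coordinates from phi/psi dihedrals
#'
#' Sequential natural-extension (NeRF) chain construction: places N, CA, C
#' for each residue from ideal bond lengths and angles, the supplied
#' phi/psi torsions, and trans peptide bonds (omega = 180). `phi[1]` and
#' `psi[n]` are ignored (they do not exist for a chain).
#'
#' @param phi,psi numeric vectors of length n, degrees.
#' @return numeric (3n) x 3 coordinate matrix, atom order N, CA, C per
#'   residue.
#' @export
build_backbone <- function(phi, psi) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 2)
  coords <- matrix(NA_real_, 3 * n, 3)
  # first residue: N at origin, CA along +x, C in the xy-plane
  coords[1, ] <- c(0, 0, 0)
  coords[2, ] <- c(.BOND_N_CA, 0, 0)
  th <- (180 - .ANGLE_N_CA_C) * pi / 180
  coords[3, ] <- coords[2, ] + .BOND_CA_C * c(cos(th), sin(th), 0)
  for (i in seq_len(n - 1)) {
    iN <- 3 * i - 2; iCA <- 3 * i - 1; iC <- 3 * i
    # N(i+1) from N(i), CA(i), C(i) via psi(i)
    coords[iC + 1, ] <- nerf_place(coords[iN, ], coords[iCA, ], coords[iC, ],
                                   .BOND_C_N, .ANGLE_CA_C_N, psi[i])
    # CA(i+1) from CA(i), C(i), N(i+1) via omega
    coords[iC + 2, ] <- nerf_place(coords[iCA, ], coords[iC, ],
                                   coords[iC + 1, ], .BOND_N_CA,
                                   .ANGLE_C_N_CA, .OMEGA_TRANS)
    # C(i+1) from C(i), N(i+1), CA(i+1) via phi(i+1)
    coords[iC + 3, ] <- nerf_place(coords[iC, ], coords[iC + 1, ],
                                   coords[iC + 2, ], .BOND_CA_C,
                                   .ANGLE_N_CA_C, phi[i + 1])
  }
  coords
}

# place atom D given A-B-C, bond |CD|, angle B-C-D and torsion A-B-C-D
nerf_place <- function(p1, p2, p3, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  d_local <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  bc <- p3 - p2
  bc <- bc / sqrt(sum(bc^2))
  ab <- p2 - p1
  nrm <- c(ab[2] * bc[3] - ab[3] * bc[2],
           ab[3] * bc[1] - ab[1] * bc[3],
           ab[1] * bc[2] - ab[2] * bc[1])
  nrm <- nrm / sqrt(sum(nrm^2))
  m <- cbind(bc, c(nrm[2] * bc[3] - nrm[3] * bc[2],
                   nrm[3] * bc[1] - nrm[1] * bc[3],
                   nrm[1] * bc[2] - nrm[2] * bc[1]), nrm)
  as.numeric(p3 + m %*% d_local)
}

#' Derive a wild-type / variant spec pair with a long-range effect
#'
#' Returns two specs identical except that the *distant* position's target
#' distribution is replaced; the mutation site itself is untouched. This is
#' the canonical fixture for long-range flag tests: the variant's local
#' conformation at the site is conserved while a remote position diverges.
#'
#' @param base a [generator_spec()] (the wild type).
#' @param site mutation-site residue number (validated, not modified).
#' @param distant residue number whose distribution is swapped.
#' @param effect replacement distribution: named sparse vector (see
#'   [pb_target()]) or full 16-vector.
#' @param variant_seed seed for the variant spec (default `base$seed + 1000`
#'   so the two systems are independent draws).
#' @return list with elements `wt` and `variant` (both `generator_spec`s).
#' @export
inject_variant_effect <- function(base, site, distant, effect,
                                  variant_seed = base$seed + 1000L) {
  stopifnot(inherits(base, "generator_spec"))
  if (!site %in% base$resno) stop("site ", site, " outside residue range")
  if (!distant %in% base$resno) {
    stop("distant position ", distant, " outside residue range")
  }
  eff <- if (!is.null(names(effect))) pb_target(effect) else effect
  stopifnot(length(eff) == 16, abs(sum(eff) - 1) < 1e-9)
  variant <- base
  variant$targets[match(distant, base$resno), ] <- eff
  variant$seed <- variant_seed
  wt <- base
  list(wt = wt, variant = variant)
}

#' Analytic Neq of a generator spec's target distributions
#'
#' The ground-truth Neq implied by each position's target distribution,
#' for parameter-recovery checks.
#'
#' @param spec a [generator_spec()].
#' @return data.frame `resno`, `neq`.
#' @export
target_neq <- function(spec) {
  data.frame(resno = spec$resno, neq = neq(spec$targets))
}
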