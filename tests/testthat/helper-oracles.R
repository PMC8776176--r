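# Independent oracles and fixture builders used across the suite.

# Neq oracle, coded independently of neq(): entropy in bits, converted to
# nats inside the exponential.
oracle_neq <- function(f) {
  p <- f[f > 0]
  h_bits <- -sum(p * log2(p))
  exp(log(2) * h_bits)
}

# Brute-force minimum RMSD over rigid motions. For any fixed rotation the
# optimal translation matches the centroids, so both sets are centred and
# the search runs over Euler angles only, from a coarse grid of starts.
oracle_min_rmsd <- function(a, b) {
  a <- sweep(a, 2, colMeans(a))
  b <- sweep(b, 2, colMeans(b))
  rot <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    matrix(c(cy * cz, cy * sz, -sy,
             sx * sy * cz - cx * sz, sx * sy * sz + cx * cz, sx * cy,
             cx * sy * cz + sx * sz, cx * sy * sz - sx * cz, cx * cy),
           3, 3, byrow = TRUE)
  }
  obj <- function(par) {
    sqrt(mean(rowSums((a - b %*% t(rot(par)))^2)))
  }
  best <- NULL
  grid <- seq(-pi, pi, length.out = 7)
  for (gx in grid) for (gy in grid) for (gz in grid) {
    fit <- stats::optim(c(gx, gy, gz), obj,
                        control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  # polish the best basin until the Nelder-Mead simplex stops improving
  for (i in 1:5) {
    best <- stats::optim(best$par, obj,
                         control = list(maxit = 5000, reltol = 1e-15))
  }
  best$value
}

# random normalised PB frequency row (sparse with probability 1/2)
random_pb_row <- function() {
  k <- sample(c(3, 16), 1)
  idx <- sample(16, k)
  v <- numeric(16)
  v[idx] <- stats::rexp(k)
  v / sum(v)
}

# minimal n-residue, n_frames ensemble built from prescribed dihedrals
make_backbone_ensemble <- function(phi, psi, n_frames = 1, resno = NULL,
                                   jitter = 0) {
  n <- length(phi)
  if (is.null(resno)) resno <- seq_len(n)
  atoms <- data.frame(chain = "A", resno = rep(resno, each = 3),
                      resid = "ALA", elety = rep(c("N", "CA", "C"), n),
                      stringsAsFactors = FALSE)
  xyz <- t(vapply(seq_len(n_frames), function(f) {
    co <- build_backbone(phi, psi)
    if (jitter > 0) co <- co + stats::rnorm(length(co), 0, jitter)
    as.vector(t(co))
  }, numeric(9 * n)))
  ensemble(atoms, xyz)
}

# rigid-body transform of every frame of an ensemble
transform_ensemble <- function(x, ang = c(0.3, -1.1, 2.0), shift = c(5, -3, 8)) {
  r1 <- matrix(c(1, 0, 0, 0, cos(ang[1]), -sin(ang[1]),
                 0, sin(ang[1]), cos(ang[1])), 3, 3, byrow = TRUE)
  r2 <- matrix(c(cos(ang[2]), 0, sin(ang[2]), 0, 1, 0,
                 -sin(ang[2]), 0, cos(ang[2])), 3, 3, byrow = TRUE)
  r3 <- matrix(c(cos(ang[3]), -sin(ang[3]), 0,
                 sin(ang[3]), cos(ang[3]), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  rr <- r1 %*% r2 %*% r3
  out <- x
  for (f in seq_len(nrow(x$xyz))) {
    m <- frame_coords(x, f) %*% t(rr)
    m <- sweep(m, 2, -shift)
    out$xyz[f, ] <- as.vector(t(m))
  }
  out
}
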