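#' Per-position PB frequency profile
#'
#' For each position, the frequency of each PB letter over the frames in
#' which the position was assignable. `Z` frames are excluded from the
#' denominator, never counted as a 17th category.
#'
#' @param x a `pb_ensemble`.
#' @param min_frames positions with fewer counted frames than this are
#'   flagged low-confidence (default 10).
#' @return a `pb_profile`: list with `freq` (positions x 16 matrix, rows
#'   named by residue number; rows of empty positions are `NA`), `n`
#'   (counted frames per position), `empty` and `low_confidence` flags,
#'   and `resno`.
#' @export
pb_frequencies <- function(x, min_frames = 10) {
  resno <- pb_resno(x)
  counts <- vapply(seq_len(ncol(x)), function(i) {
    tab <- table(factor(x[, i], levels = PB_LETTERS))
    as.numeric(tab)
  }, numeric(16))
  counts <- t(counts)  # positions x 16
  colnames(counts) <- PB_LETTERS
  n <- rowSums(counts)
  freq <- counts / ifelse(n > 0, n, NA)
  rownames(freq) <- resno
  structure(list(freq = freq, n = as.integer(n), empty = n == 0,
                 low_confidence = n < min_frames, resno = resno),
            class = "pb_profile")
}

#' @export
print.pb_profile <- function(x, ...) {
  cat("pb_profile:", length(x$resno), "positions (residues", x$resno[1], "to",
      x$resno[length(x$resno)], ");", sum(x$empty), "empty,",
      sum(x$low_confidence & !x$empty), "low-confidence\n")
  invisible(x)
}

#' Equivalent number of Protein Blocks (Neq)
#'
#' Neq = exp(-sum_x f_x ln f_x), the exponential of the Shannon entropy
#' (natural log) of a position's PB frequency vector, with the convention
#' 0 ln 0 = 0. Neq is 1 when a single PB is observed and 16 for a uniform
#' distribution over all 16 PBs.
#'
#' @param f numeric frequency vector summing to 1 (any length; 16 for a PB
#'   profile row), or a matrix of such rows.
#' @param tol tolerance on the row-sum normalisation check.
#' @return Neq value(s) in `[1, 16]` for 16-letter rows.
#' @examples
#' neq(rep(1 / 16, 16))  # 16
#' neq(c(1, rep(0, 15))) # 1
#' @export
neq <- function(f, tol = 1e-6) {
  if (is.matrix(f)) return(apply(f, 1, neq, tol = tol))
  if (any(is.na(f))) return(NA_real_)
  if (any(f < 0)) stop("negative frequency in profile row")
  if (abs(sum(f) - 1) > tol) {
    stop("profile row sums to ", format(sum(f)), ", not 1")
  }
  p <- f[f > 0]
  exp(-sum(p * log(p)))
}

#' Flexibility class from Neq
#'
#' Thresholds: Neq > 8 disordered; 6 < Neq <= 8 highly flexible;
#' 3 <= Neq <= 6 flexible (the "inherent flexibility around 4" band);
#' Neq < 3 rigid.
#'
#' @param x Neq value(s), each in `[1, 16]` (`NA` allowed, passed through).
#' @return factor with levels rigid, flexible, highly_flexible, disordered.
#' @export
classify_flexibility <- function(x) {
  ok <- is.na(x) | (x >= 1 - 1e-9 & x <= 16 + 1e-9)
  if (!all(ok)) stop("Neq out of [1, 16]: ", paste(x[!ok], collapse = ", "))
  cls <- ifelse(x > 8, "disordered",
         ifelse(x > 6, "highly_flexible",
         ifelse(x >= 3, "flexible", "rigid")))
  factor(cls, levels = c("rigid", "flexible", "highly_flexible", "disordered"))
}

#' Per-position flexibility profile
#'
#' Joins Neq (from a PB profile) with its flexibility class and, optionally,
#' RMSF and B-factor tracks keyed by residue number.
#'
#' @param profile a `pb_profile`.
#' @param rmsf optional data.frame `resno`, `rmsf` (see [rmsf_profile()]).
#' @param bfactor optional data.frame `resno`, `b`.
#' @return a `flex_profile` data.frame: `resno`, `neq`, `class`, plus
#'   `rmsf`/`b` columns when supplied (`NA` at empty positions).
#' @export
flex_profile <- function(profile, rmsf = NULL, bfactor = NULL) {
  out <- data.frame(resno = profile$resno, neq = neq(profile$freq))
  out$class <- classify_flexibility(out$neq)
  if (!is.null(rmsf)) out$rmsf <- rmsf$rmsf[match(out$resno, rmsf$resno)]
  if (!is.null(bfactor)) out$b <- bfactor$b[match(out$resno, bfactor$resno)]
  class(out) <- c("flex_profile", "data.frame")
  out
}

#' Per-position absolute Neq difference between two systems
#'
#' @param a,b `flex_profile`s with overlapping residue numbering.
#' @return data.frame `resno`, `dneq` = |Neq_a - Neq_b| on the intersection
#'   of positions assignable in both.
#' @export
delta_neq <- function(a, b) {
  shared <- intersect(a$resno, b$resno)
  if (length(shared) == 0) stop("profiles share no residue positions")
  na <- a$neq[match(shared, a$resno)]
  nb <- b$neq[match(shared, b$resno)]
  keep <- !is.na(na) & !is.na(nb)
  data.frame(resno = shared[keep], dneq = abs(na - nb)[keep])
}

#' PB profile divergence (dPB) between two frequency vectors
#'
#' The L1 distance between two PB frequency vectors at one position:
#' dPB = sum_x |f_x^A - f_x^B| over the 16 letters. 0 means identical
#' profiles, 2 disjoint support (a total change of local conformation).
#'
#' @param a,b normalised 16-vectors of PB frequencies.
#' @param tol tolerance on the normalisation check.
#' @return list with `dpb` (scalar in `[0, 2]`) and `per_letter` (named
#'   16-vector of absolute frequency differences).
#' @examples
#' a <- c(b = 0.6, d = 0.2, h = 0.2)
#' delta_pb(pb_target(a), pb_target(c(h = 1)))$dpb  # 1.6
#' @export
delta_pb <- function(a, b, tol = 1e-6) {
  stopifnot(length(a) == 16, length(b) == 16)
  if (abs(sum(a) - 1) > tol || abs(sum(b) - 1) > tol) {
    stop("dPB requires normalised frequency vectors")
  }
  d <- abs(a - b)
  names(d) <- PB_LETTERS
  list(dpb = sum(d), per_letter = d)
}

#' Per-position dPB track between two PB profiles
#'
#' @param a,b `pb_profile`s with overlapping residue numbering; dPB is
#'   computed only at positions assignable (non-empty) in both.
#' @return data.frame `resno`, `dpb`.
#' @export
delta_pb_profile <- function(a, b) {
  shared <- intersect(a$resno, b$resno)
  if (length(shared) == 0) stop("profiles share no residue positions")
  ia <- match(shared, a$resno)
  ib <- match(shared, b$resno)
  keep <- !a$empty[ia] & !b$empty[ib]
  shared <- shared[keep]; ia <- ia[keep]; ib <- ib[keep]
  dpb <- rowSums(abs(a$freq[ia, , drop = FALSE] - b$freq[ib, , drop = FALSE]))
  data.frame(resno = shared, dpb = as.numeric(dpb))
}

#' Dense 16-vector from sparse named PB frequencies
#'
#' @param x named numeric vector, names in `a..p` (e.g.
#'   `c(b = 0.6, d = 0.2, h = 0.2)`).
#' @return numeric 16-vector over the full alphabet, names `a..p`.
#' @export
pb_target <- function(x) {
  stopifnot(!is.null(names(x)), all(names(x) %in% PB_LETTERS))
  out <- stats::setNames(numeric(16), PB_LETTERS)
  out[names(x)] <- x
  out
}

#' PB occurrence map for a residue region
#'
#' The position x letter frequency sub-matrix over a region, ordered for
#' heatmap rendering (letters a..p on one axis, residue positions on the
#' other).
#'
#' @param profile a `pb_profile`.
#' @param region inclusive residue-number range `c(start, end)`.
#' @return numeric matrix, positions x 16, rows named by residue number.
#' @export
occurrence_map <- function(profile, region) {
  stopifnot(length(region) == 2, region[1] <= region[2])
  keep <- profile$resno >= region[1] & profile$resno <= region[2]
  if (!any(keep)) {
    stop("region ", region[1], "-", region[2], " lies outside the profile")
  }
  profile$freq[keep, , drop = FALSE]
}

#' Letter-height table for a PB conservation logo
#'
#' Heights equal the relative PB frequencies at each position (not
#' information content), letters stacked by descending frequency, so one
#' tall letter means a single dominant conformation and many small letters
#' mean high local diversity. Empty positions are omitted with a note.
#'
#' @param profile a `pb_profile`.
#' @param region inclusive residue-number range `c(start, end)`.
#' @return data.frame `resno`, `letter`, `height`, `rank` (1 = tallest),
#'   zero-frequency letters dropped; heights per position sum to 1.
#' @export
logo_table <- function(profile, region = range(profile$resno)) {
  m <- occurrence_map(profile, region)
  resno <- as.integer(rownames(m))
  empty <- rowSums(is.na(m)) > 0
  if (any(empty)) {
    message("omitting ", sum(empty), " empty position(s): ",
            paste(resno[empty], collapse = ", "))
  }
  rows <- lapply(which(!empty), function(i) {
    f <- m[i, ]
    ord <- order(f, decreasing = TRUE)
    ord <- ord[f[ord] > 0]
    data.frame(resno = resno[i], letter = PB_LETTERS[ord],
               height = as.numeric(f[ord]), rank = seq_along(ord))
  })
  do.call(rbind, rows)
}

#' Per-replicate PB profiles and their Neq cross-correlations
#'
#' Splits the frames of a PB ensemble by replicate, computes a profile and
#' Neq track per replicate, and reports the Pearson correlation of Neq
#' between every replicate pair -- the standard check that independent runs
#' sampled similar local dynamics before pooling them.
#'
#' @param x a `pb_ensemble`.
#' @param replicate integer vector, one replicate id per frame (e.g. the
#'   `replicate` attribute set by [generate_string_mode()]).
#' @param min_frames forwarded to [pb_frequencies()].
#' @return list with `profiles` (one `pb_profile` per replicate) and
#'   `neq_correlations` (data.frame `rep_a`, `rep_b`, `r`).
#' @export
replicate_profiles <- function(x, replicate, min_frames = 10) {
  stopifnot(length(replicate) == nrow(x))
  ids <- sort(unique(replicate))
  profs <- lapply(ids, function(r) {
    pb_frequencies(pb_ensemble(x[replicate == r, , drop = FALSE],
                               pb_resno(x)), min_frames = min_frames)
  })
  names(profs) <- ids
  pairs <- if (length(ids) > 1) utils::combn(seq_along(ids), 2) else
    matrix(integer(0), 2, 0)
  cors <- apply(pairs, 2, function(p) {
    fa <- flex_profile(profs[[p[1]]])
    fb <- flex_profile(profs[[p[2]]])
    profile_correlation(data.frame(resno = fa$resno, value = fa$neq),
                        data.frame(resno = fb$resno, value = fb$neq))
  })
  list(profiles = profs,
       neq_correlations = data.frame(
         rep_a = ids[pairs[1, ]], rep_b = ids[pairs[2, ]],
         r = as.numeric(cors)))
}

#' Write a per-position track as TSV
#'
#' Fixed 6-decimal formatting so identical inputs yield byte-identical
#' files.
#'
#' @param track data.frame whose first column is `resno`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_track_tsv <- function(track, path) {
  out <- track
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && names(out)[j] != "resno") {
      out[[j]] <- sprintf("%.6f", out[[j]])
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an occurrence map as CSV
#'
#' @param map matrix from [occurrence_map()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_occurrence_csv <- function(map, path) {
  out <- data.frame(resno = rownames(map),
                    apply(map, 2, function(v) sprintf("%.6f", v)),
                    check.names = FALSE)
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
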