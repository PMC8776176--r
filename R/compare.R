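#' Pearson correlation between two per-residue tracks
#'
#' Computed on the intersection of residue positions defined in both tracks.
#' A constant track makes the correlation undefined; this is reported as
#' `NA` with a warning rather than an arbitrary number.
#'
#' @param a,b data.frames with columns `resno` and `value`.
#' @return Pearson r, or `NA` when undefined.
#' @export
profile_correlation <- function(a, b) {
  shared <- intersect(a$resno, b$resno)
  va <- a$value[match(shared, a$resno)]
  vb <- b$value[match(shared, b$resno)]
  keep <- !is.na(va) & !is.na(vb)
  if (sum(keep) < 3) stop("fewer than 3 shared positions")
  va <- va[keep]; vb <- vb[keep]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    warning("constant track: correlation undefined")
    return(NA_real_)
  }
  stats::cor(va, vb)
}

#' Bundle one system's PB and flexibility profiles
#'
#' A `system_run` carries everything the comparison stage needs for one
#' simulated system: its pooled PB profile, its per-position flexibility
#' profile, the optional replicate partition, and provenance.
#'
#' @param label system name (e.g. `"WT"`, `"H798P"`).
#' @param pb a `pb_ensemble`.
#' @param rmsf optional data.frame `resno`, `rmsf` (see [rmsf_profile()]).
#' @param bfactor optional data.frame `resno`, `b`.
#' @param replicate optional per-frame replicate ids (enables
#'   [replicate_profiles()] output downstream).
#' @param min_frames forwarded to [pb_frequencies()].
#' @param provenance free-form list recorded in reports.
#' @return object of class `system_run`.
#' @export
system_run <- function(label, pb, rmsf = NULL, bfactor = NULL,
                       replicate = NULL, min_frames = 10,
                       provenance = list()) {
  profile <- pb_frequencies(pb, min_frames = min_frames)
  flex <- flex_profile(profile, rmsf = rmsf, bfactor = bfactor)
  structure(list(label = label, profile = profile, flex = flex,
                 replicate = replicate, pb = pb, provenance = provenance),
            class = "system_run")
}

#' @export
print.system_run <- function(x, ...) {
  cat("system_run '", x$label, "': ", nrow(x$pb), " frame(s), ",
      length(x$profile$resno), " positions\n", sep = "")
  invisible(x)
}

#' Flag divergent positions and summarise them
#'
#' Positions whose dPB exceeds the threshold, the fraction of assignable
#' residues they represent, their region annotation, and the positions of
#' maximal dPB and dNeq.
#'
#' @param record data.frame with `resno`, `dpb` and optionally `dneq`
#'   (the comparison record of [compare_systems()]).
#' @param threshold dPB flag threshold (default 1.0).
#' @param registry region registry for annotation, or `NULL` to skip.
#' @return list with `flagged` (data.frame `resno`, `dpb`, `region`),
#'   `fraction`, `max_dpb` and `max_dneq` (one-row data.frames).
#' @export
divergence_summary <- function(record, threshold = 1.0,
                               registry = integrin_registry()) {
  stopifnot(nrow(record) > 0)
  flag <- record$resno[record$dpb > threshold]
  flagged <- data.frame(resno = flag,
                        dpb = record$dpb[match(flag, record$resno)])
  flagged$region <- if (is.null(registry) || nrow(flagged) == 0) {
    character(nrow(flagged))
  } else {
    annotate_positions(flagged$resno, registry)
  }
  i_dpb <- which.max(record$dpb)
  max_dneq <- if (!is.null(record$dneq)) {
    i <- which.max(record$dneq)
    data.frame(resno = record$resno[i], dneq = record$dneq[i])
  } else NULL
  list(flagged = flagged,
       fraction = nrow(flagged) / nrow(record),
       threshold = threshold,
       max_dpb = data.frame(resno = record$resno[i_dpb],
                            dpb = record$dpb[i_dpb]),
       max_dneq = max_dneq)
}

#' Classify flagged positions as local or distant to a mutation site
#'
#' Each flagged position is `local` when within `window` residues of the
#' mutation site, else `distant`. The headline long-range call is `TRUE`
#' when at least one distant position is flagged while the site's own dPB
#' stays below the local-stability bound -- the signature of a mutation
#' whose local conformation is conserved but whose effect surfaces
#' elsewhere (conformational compensation).
#'
#' @param summary output of [divergence_summary()].
#' @param record the comparison record (`resno`, `dpb`).
#' @param site mutation-site residue number.
#' @param window local neighbourhood half-width in residues (default 5).
#' @param local_bound site dPB below which the site counts as locally
#'   stable (default 0.2).
#' @return list with `positions` (flagged table plus `locality`),
#'   `site_dpb`, `site_stable`, and `long_range` (logical).
#' @export
long_range_flag <- function(summary, record, site, window = 5,
                            local_bound = 0.2) {
  if (!site %in% record$resno) {
    stop("mutation site ", site, " is outside the compared positions")
  }
  pos <- summary$flagged
  pos$locality <- ifelse(abs(pos$resno - site) <= window, "local", "distant")
  site_dpb <- record$dpb[record$resno == site]
  site_stable <- site_dpb < local_bound
  list(positions = pos, site = site, site_dpb = site_dpb,
       site_stable = site_stable,
       long_range = site_stable && any(pos$locality == "distant"))
}

#' Compare two systems position by position
#'
#' The central wild-type-versus-variant comparison: per-position dNeq and
#' dPB on the positions assignable in both systems, Pearson correlations of
#' the Neq (and RMSF, when available) tracks, divergence flagging, and the
#' long-range effect call when a mutation site is given. All measures are
#' symmetric in the two systems.
#'
#' @param a,b `system_run`s with overlapping residue numbering.
#' @param site optional mutation-site residue number.
#' @param threshold dPB flag threshold (default 1.0).
#' @param window local neighbourhood half-width for the long-range call.
#' @param local_bound site-stability dPB bound for the long-range call.
#' @param registry region registry used to annotate flagged positions.
#' @return a `pb_comparison`: list with `labels`, `record` (data.frame
#'   `resno`, `neq_a`, `neq_b`, `dneq`, `dpb`), `correlations` (`neq`,
#'   and `rmsf` when available), `summary` (see [divergence_summary()]),
#'   and `long_range` (see [long_range_flag()]; `NULL` without a site).
#' @export
compare_systems <- function(a, b, site = NULL, threshold = 1.0, window = 5,
                            local_bound = 0.2,
                            registry = integrin_registry()) {
  stopifnot(inherits(a, "system_run"), inherits(b, "system_run"))
  dpb <- delta_pb_profile(a$profile, b$profile)
  dneq <- delta_neq(a$flex, b$flex)
  record <- merge(dpb, dneq, by = "resno")
  record$neq_a <- a$flex$neq[match(record$resno, a$flex$resno)]
  record$neq_b <- b$flex$neq[match(record$resno, b$flex$resno)]
  record <- record[order(record$resno),
                   c("resno", "neq_a", "neq_b", "dneq", "dpb")]
  rownames(record) <- NULL

  correlations <- list(
    neq = profile_correlation(
      data.frame(resno = a$flex$resno, value = a$flex$neq),
      data.frame(resno = b$flex$resno, value = b$flex$neq)))
  if (!is.null(a$flex$rmsf) && !is.null(b$flex$rmsf)) {
    correlations$rmsf <- profile_correlation(
      data.frame(resno = a$flex$resno, value = a$flex$rmsf),
      data.frame(resno = b$flex$resno, value = b$flex$rmsf))
  }

  summary <- divergence_summary(record, threshold = threshold,
                                registry = registry)
  long_range <- if (!is.null(site)) {
    long_range_flag(summary, record, site, window = window,
                    local_bound = local_bound)
  } else NULL

  structure(list(labels = c(a$label, b$label), record = record,
                 correlations = correlations, summary = summary,
                 long_range = long_range,
                 config = list(threshold = threshold, window = window,
                               local_bound = local_bound)),
            class = "pb_comparison")
}

#' @export
print.pb_comparison <- function(x, ...) {
  cat("pb_comparison:", x$labels[1], "vs", x$labels[2], "over",
      nrow(x$record), "positions\n")
  cat("  Neq correlation:", formatC(x$correlations$neq, digits = 3,
                                    format = "f"), "\n")
  if (!is.null(x$correlations$rmsf)) {
    cat("  RMSF correlation:", formatC(x$correlations$rmsf, digits = 3,
                                       format = "f"), "\n")
  }
  cat("  positions with dPB >", x$summary$threshold, ":",
      nrow(x$summary$flagged),
      sprintf("(%.1f%% of assignable)", 100 * x$summary$fraction), "\n")
  cat("  max dPB", sprintf("%.2f", x$summary$max_dpb$dpb), "at residue",
      x$summary$max_dpb$resno, "\n")
  if (!is.null(x$long_range)) {
    cat("  site", x$long_range$site,
        sprintf("dPB %.2f (%s);", x$long_range$site_dpb,
                if (x$long_range$site_stable) "stable" else "perturbed"),
        "long-range effect:", x$long_range$long_range, "\n")
  }
  invisible(x)
}

#' Write a comparison report to disk
#'
#' Emits `comparison_record.tsv` (per-position tracks), `flagged.tsv`, and
#' `report.json` (correlations, summary, long-range call, configuration)
#' into a directory.
#'
#' @param x a `pb_comparison`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_comparison <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_track_tsv(x$record, file.path(dir, "comparison_record.tsv"))
  flagged <- x$summary$flagged
  flagged$dpb <- sprintf("%.6f", flagged$dpb)
  utils::write.table(flagged, file.path(dir, "flagged.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  report <- list(labels = x$labels, correlations = x$correlations,
                 fraction_flagged = x$summary$fraction,
                 threshold = x$summary$threshold,
                 max_dpb = x$summary$max_dpb,
                 max_dneq = x$summary$max_dneq,
                 long_range = x$long_range, config = x$config)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(dir)
}
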