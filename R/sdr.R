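# SDR discovery from pooled female/male coverage. Windows are classified by
# the F/(F+M) ratio around the 0.5 cutoff with a +-delta noise margin, runs
# of non-balanced windows form divergent runs, and runs separated by gaps up
# to max_gap merge into one SDR span (the SDR is a mosaic of W-specific
# segments and W homologs of Z sequence, so internally balanced gaps are
# expected). Independent SNP evidence layers are then overlaid.

#' Average two pooled coverage tracks onto common windows
#'
#' @param female,male coverage tracks (`chrom`, `start`, `end`, `depth`), on
#'   the same reference
#' @param window window size in bp (default 10 kb)
#' @param min_total minimum summed depth for ratio computation; windows below
#'   it are classed `low_coverage` (default 10 reads)
#' @return data.frame of coverage windows with `f_depth`, `m_depth`,
#'   `ratio_f`, `ratio_m` and `class` (all `NA`/`low_coverage` until
#'   [classify_windows()] is applied to the ratio classes)
#' @export
coverage_windows <- function(female, male, window = 10000, min_total = 10) {
  validate_gi(female); validate_gi(male)
  chr_f <- unique(female$chrom); chr_m <- unique(male$chrom)
  if (!setequal(chr_f, chr_m))
    stop("female and male tracks cover different chromosomes")
  chrom_lengths <- vapply(chr_f, function(ch)
    max(female$end[female$chrom == ch], male$end[male$chrom == ch]),
    numeric(1))
  windows <- make_windows(chrom_lengths, window = window, step = window)
  wgr <- gi_to_gr(windows)
  mean_depth <- function(track) {
    tgr <- gi_to_gr(track)
    hits <- suppressWarnings(GenomicRanges::findOverlaps(wgr, tgr))
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    ov <- pmin(windows$end[qi], track$end[si]) -
      pmax(windows$start[qi], track$start[si]) + 1
    depth_bp <- rowsum(ov * track$depth[si], qi)
    out <- rep(0, nrow(windows))
    out[as.integer(rownames(depth_bp))] <- depth_bp[, 1]
    out / (windows$end - windows$start + 1)
  }
  fd <- mean_depth(female); md <- mean_depth(male)
  tot <- fd + md
  rf <- ifelse(tot >= min_total, fd / tot, NA_real_)
  cls <- ifelse(tot < min_total, "low_coverage", NA_character_)
  data.frame(chrom = windows$chrom, start = windows$start, end = windows$end,
             f_depth = fd, m_depth = md, ratio_f = rf, ratio_m = 1 - rf,
             class = cls, stringsAsFactors = FALSE)
}

#' Classify coverage windows against the 0.5 ratio cutoff
#'
#' `W_specific` when `ratio_f > 0.5 + delta` (male read reduction/absence),
#' `male_elevated` when `ratio_f < 0.5 - delta`, otherwise `balanced`.
#' `delta = 0` reproduces the literal 0.5 cutoff; the default 0.05 margin
#' absorbs Poisson depth noise.
#'
#' @param cw output of [coverage_windows()]
#' @param delta ratio margin in `[0, 0.5)`
#' @return `cw` with the `class` column filled in
#' @export
classify_windows <- function(cw, delta = 0.05) {
  if (delta < 0 || delta >= 0.5) stop("delta must be in [0, 0.5)")
  cls <- cw$class
  idx <- is.na(cls)
  cls[idx & cw$ratio_f > 0.5 + delta] <- "W_specific"
  cls[idx & cw$ratio_f < 0.5 - delta] <- "male_elevated"
  cls[is.na(cls)] <- "balanced"
  cw$class <- cls
  cw
}

#' @noRd
runs_of <- function(flag, chrom) {
  # maximal runs of TRUE within one chromosome; returns start/end indices
  r <- rle(paste0(chrom, ":", flag))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- grepl(":TRUE$", r$values)
  cbind(start = starts[keep], end = ends[keep])
}

#' Call the SDR from classified coverage windows
#'
#' Divergent runs are maximal runs of non-balanced (and non-low-coverage)
#' windows of at least `min_run` windows. Runs on one chromosome whose
#' inter-run gaps are at most `max_gap` bp chain together; the SDR span is
#' the envelope of the chain with the most divergent bp, on the chromosome
#' ranked best by total divergent bp. W-specific sub-intervals are the runs
#' of `W_specific` windows inside the span.
#'
#' The span edges are then refined: they are trimmed inward to the outermost
#' window whose ratio deviates strongly from 0.5 (`|ratio_f - 0.5| >=
#' edge_delta`), so that isolated noise windows attached to a run edge do not
#' inflate the reported boundaries (the boundary of a real SDR is marked by
#' W-specific or strongly male-elevated coverage, not by marginal ratios).
#'
#' @param cw classified coverage windows ([classify_windows()])
#' @param min_run minimum windows per divergent run (default 20)
#' @param max_gap maximum gap (bp) bridged when chaining runs (default 1 Mb)
#' @param edge_delta minimum `|ratio_f - 0.5|` for a window to anchor a span
#'   boundary (default 0.25; 0 disables refinement)
#' @param min_seed_run minimum windows for a run fragment to take part in
#'   chaining (default 3); fragments below `min_run` never seed a call on
#'   their own but do bridge gaps inside a fragmented divergent segment
#' @return an `sdr_call` list: `chrom`, `interval`, `runs`, `w_specific`,
#'   `chrom_ranking`, `support` (NA until [integrate_evidence()]), or an
#'   empty call when no divergent run exists
#' @export
call_sdr <- function(cw, min_run = 20, max_gap = 1e6, edge_delta = 0.25,
                     min_seed_run = 3) {
  cw <- cw[order(cw$chrom, cw$start), , drop = FALSE]
  divergent <- cw$class %in% c("W_specific", "male_elevated")
  idx <- runs_of(divergent, cw$chrom)
  empty <- structure(list(chrom = NA_character_, interval = NULL,
                          runs = NULL, w_specific = NULL,
                          chrom_ranking = NULL, support = 0L,
                          evidence = NULL),
                     class = "sdr_call")
  if (!nrow(idx)) return(empty)
  all_runs <- data.frame(chrom = cw$chrom[idx[, "start"]],
                         start = cw$start[idx[, "start"]],
                         end = cw$end[idx[, "end"]],
                         n_windows = idx[, "end"] - idx[, "start"] + 1)
  runs <- all_runs[all_runs$n_windows >= min_run, , drop = FALSE]
  rownames(runs) <- NULL
  if (!nrow(runs)) return(empty)
  ranking <- stats::aggregate(list(divergent_bp = runs$end - runs$start + 1),
                              by = list(chrom = runs$chrom), FUN = sum)
  ranking <- ranking[order(-ranking$divergent_bp), , drop = FALSE]
  best <- ranking$chrom[1]
  # chain over all divergent runs (fragments included, so that a major run
  # split by noise does not widen the apparent gap); a chain must contain at
  # least one major (>= min_run) run, and the best chain carries the most
  # major-run bp
  br <- all_runs[all_runs$chrom == best &
                   all_runs$n_windows >= min_seed_run, , drop = FALSE]
  br <- br[order(br$start), , drop = FALSE]
  gap <- c(0, br$start[-1] - br$end[-nrow(br)] - 1)
  chain <- cumsum(gap > max_gap)
  major_bp <- tapply(ifelse(br$n_windows >= min_run,
                            br$end - br$start + 1, 0), chain, sum)
  if (all(major_bp == 0)) return(empty)
  keep <- chain == as.integer(names(major_bp)[which.max(major_bp)])
  span <- gi(best, min(br$start[keep]), max(br$end[keep]))
  if (edge_delta > 0) {
    inwin <- which(cw$chrom == best & cw$start >= span$start &
                     cw$end <= span$end)
    strong <- inwin[!is.na(cw$ratio_f[inwin]) &
                      abs(cw$ratio_f[inwin] - 0.5) >= edge_delta]
    if (length(strong))
      span <- gi(best, cw$start[min(strong)], cw$end[max(strong)])
  }
  wrun <- runs_of(cw$class == "W_specific" & cw$chrom == best, cw$chrom)
  w_spec <- NULL
  if (nrow(wrun)) {
    w_spec <- data.frame(chrom = best,
                         start = cw$start[wrun[, "start"]],
                         end = cw$end[wrun[, "end"]],
                         n_windows = wrun[, "end"] - wrun[, "start"] + 1)
    w_spec <- w_spec[w_spec$end >= span$start & w_spec$start <= span$end &
                       w_spec$n_windows >= min_run, , drop = FALSE]
    if (nrow(w_spec)) {
      w_spec$start <- pmax(w_spec$start, span$start)
      w_spec$end <- pmin(w_spec$end, span$end)
    }
    rownames(w_spec) <- NULL
  }
  structure(list(chrom = best, interval = span, runs = runs,
                 w_specific = w_spec, chrom_ranking = ranking,
                 support = NA_integer_, evidence = NULL),
            class = "sdr_call")
}

#' @export
print.sdr_call <- function(x, ...) {
  if (is.null(x$interval)) {
    cat("sdr_call: empty (no divergent runs)\n")
    return(invisible(x))
  }
  cat(sprintf("sdr_call: %s:%d-%d (%.2f Mb), %d divergent run(s), support=%s\n",
              x$chrom, x$interval$start, x$interval$end,
              (x$interval$end - x$interval$start) / 1e6,
              sum(x$runs$chrom == x$chrom),
              ifelse(is.na(x$support), "?", x$support)))
  invisible(x)
}

#' Overlay SNP-based evidence layers on an SDR call
#'
#' Three layers: association scores at or above `assoc_cut`, Fst windows at
#' or above the empirical top `fst_top` quantile (computed genome-wide), and
#' female-specific SNP blocks as given. The call is annotated with per-layer
#' overlap and `support` counts how many layers overlap the SDR span (0-3).
#'
#' @param sdr an `sdr_call` from [call_sdr()]
#' @param assoc [sex_association()] result
#' @param fst windowed Fst ([fst_weir_cockerham()])
#' @param fem_blocks `blocks` element of [female_specific_snps()]
#' @param assoc_cut `-log10(P)` threshold (default 10)
#' @param fst_top upper-tail quantile for the Fst layer (default 0.01)
#' @return the `sdr_call` with `support` and an `evidence` list filled in
#' @export
integrate_evidence <- function(sdr, assoc, fst, fem_blocks,
                               assoc_cut = 10, fst_top = 0.01) {
  stopifnot(inherits(sdr, "sdr_call"))
  chroms <- unique(c(assoc$chrom, fst$chrom, fem_blocks$chrom))
  if (!is.null(sdr$chrom) && !is.na(sdr$chrom) &&
      length(chroms) && !sdr$chrom %in% chroms &&
      !any(startsWith(chroms, substr(sdr$chrom, 1, 3))))
    stop("evidence uses a different chromosome naming than the coverage call")
  assoc_hits <- assoc[assoc$neg_log10_p >= assoc_cut, , drop = FALSE]
  fst_ok <- fst[!is.na(fst$value), , drop = FALSE]
  fst_cut <- if (nrow(fst_ok)) stats::quantile(fst_ok$value, 1 - fst_top,
                                               names = FALSE) else Inf
  fst_hits <- fst_ok[fst_ok$value >= fst_cut, , drop = FALSE]
  evidence <- list(assoc_sites = assoc_hits, fst_windows = fst_hits,
                   fem_blocks = fem_blocks, fst_cutoff = fst_cut,
                   assoc_cut = assoc_cut)
  if (is.null(sdr$interval)) { sdr$support <- 0L; sdr$evidence <- evidence
    return(sdr) }
  span <- sdr$interval
  overlap_frac <- function(feat_chrom, feat_start, feat_end) {
    if (!length(feat_chrom)) return(0)
    on <- feat_chrom == span$chrom & feat_end >= span$start &
      feat_start <= span$end
    if (!any(on)) return(0)
    cov <- gi_reduce(gi(feat_chrom[on],
                        pmax(feat_start[on], span$start),
                        pmin(feat_end[on], span$end)))
    sum(cov$end - cov$start + 1) / (span$end - span$start + 1)
  }
  fr <- c(assoc = overlap_frac(assoc_hits$chrom, assoc_hits$pos, assoc_hits$pos),
          fst = overlap_frac(fst_hits$chrom, fst_hits$start, fst_hits$end),
          fem = overlap_frac(fem_blocks$chrom, fem_blocks$start,
                             fem_blocks$end))
  evidence$overlap_fraction <- fr
  sdr$evidence <- evidence
  sdr$support <- sum(fr > 0)
  sdr
}

#' Rank chromosomes by recombination suppression
#'
#' Computes the Spearman correlation between physical (bp) and genetic (cM)
#' marker positions per chromosome, plus the longest physical span over which
#' cM does not increase (the recombination plateau). Chromosomes are ranked
#' ascending by correlation: a sex chromosome carrying a large
#' non-recombining region sorts first.
#'
#' @param markers marker table ([read_map()]); chromosomes with fewer than
#'   `min_markers` markers are skipped with a warning
#' @param min_markers minimum markers per chromosome (default 10)
#' @return data.frame `chrom`, `rho`, `plateau_bp`, `n_markers`, ranked
#'   ascending by `rho`
#' @export
detect_recomb_suppressed_chromosome <- function(markers, min_markers = 10) {
  rows <- list(); k <- 0L
  for (ch in unique(markers$chrom)) {
    sub <- markers[markers$chrom == ch, , drop = FALSE]
    if (nrow(sub) < min_markers) {
      warning("chromosome ", ch, " skipped (<", min_markers, " markers)")
      next
    }
    sub <- sub[order(sub$pos_bp), , drop = FALSE]
    rho <- suppressWarnings(stats::cor(sub$pos_bp, sub$pos_cm,
                                       method = "spearman"))
    # longest physical span with no cM increase
    plateau <- 0
    i <- 1
    while (i < nrow(sub)) {
      j <- i
      while (j < nrow(sub) && sub$pos_cm[j + 1] <= sub$pos_cm[i]) j <- j + 1
      plateau <- max(plateau, sub$pos_bp[j] - sub$pos_bp[i])
      i <- i + 1
    }
    k <- k + 1L
    rows[[k]] <- data.frame(chrom = ch, rho = rho, plateau_bp = plateau,
                            n_markers = nrow(sub))
  }
  if (!k) return(data.frame(chrom = character(), rho = numeric(),
                            plateau_bp = numeric(), n_markers = integer()))
  out <- do.call(rbind, rows)
  out <- out[order(out$rho, -out$plateau_bp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Marker alignment rate
#'
#' @param aligned number of aligned markers, or a logical vector of
#'   per-marker alignment flags
#' @param total total markers (ignored when `aligned` is logical)
#' @return percentage rounded half-up to 1 decimal
#' @export
marker_alignment_rate <- function(aligned, total = NULL) {
  if (is.logical(aligned)) { total <- length(aligned); aligned <- sum(aligned) }
  stopifnot(!is.null(total))
  if (total <= 0) stop("total marker count must be positive")
  round_half_up(100 * aligned / total, 1)
}
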