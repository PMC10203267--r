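# Domestication sweep scan: top-5% wild/cultivar diversity-ratio windows and
# top-5% omega grid points, each extended by 4-kb flanks, intersected and
# merged. Optional absolute effect-size floors (pi-ratio, omega) control
# false positives on null data; floors of 0 reproduce the literal
# quantile-only rule.

#' Wild/cultivar diversity-ratio windows
#'
#' Ratio `pi_W / pi_C` per window. Windows where the cultivar diversity is
#' zero but the wild diversity is positive become `Inf` (they are the most
#' extreme outliers and rank above all finite values); windows with zero
#' diversity in both groups are dropped.
#'
#' @param wild,cultivar window-statistic frames from [nucleotide_diversity()]
#'   computed on identical windows
#' @return window-statistic data.frame (`stat = "pi_ratio"`)
#' @export
pi_ratio_windows <- function(wild, cultivar) {
  same <- nrow(wild) == nrow(cultivar) &&
    all(wild$chrom == cultivar$chrom) && all(wild$start == cultivar$start) &&
    all(wild$end == cultivar$end)
  if (!same) stop("wild and cultivar statistics use different windows")
  ratio <- ifelse(cultivar$value > 0, wild$value / cultivar$value,
                  ifelse(wild$value > 0, Inf, NA_real_))
  out <- window_stat_frame(wild[, c("chrom", "start", "end")], "pi_ratio",
                           ratio, pmin(wild$n_sites, cultivar$n_sites))
  out[!is.na(out$value), , drop = FALSE]
}

# prefix-summed r2 sums for the omega split maximisation
#' @noRd
omega_from_r2 <- function(r2, nL, nR, eps) {
  # r2: (nL+nR) x (nL+nR) matrix ordered [left nearest-first, right
  # nearest-first]; maximises omega over split sizes l, r >= 2
  best <- -Inf; best_lr <- c(NA, NA)
  li <- seq_len(nL); ri <- nL + seq_len(nR)
  sumL <- numeric(nL)
  acc <- 0
  for (l in seq_len(nL)) {
    if (l > 1) acc <- acc + sum(r2[li[l], li[seq_len(l - 1)]])
    sumL[l] <- acc
  }
  sumR <- numeric(nR)
  acc <- 0
  for (r in seq_len(nR)) {
    if (r > 1) acc <- acc + sum(r2[ri[r], ri[seq_len(r - 1)]])
    sumR[r] <- acc
  }
  # 2-D prefix sums of the between-block rectangle
  B <- apply(apply(r2[li, ri, drop = FALSE], 2, cumsum), 1, cumsum)
  B <- t(B)  # B[l, r] = sum of r2 between first l left and first r right
  for (l in 2:nL) {
    for (r in 2:nR) {
      within <- (sumL[l] + sumR[r]) / (choose(l, 2) + choose(r, 2))
      between <- B[l, r] / (l * r)
      om <- within / (between + eps)
      if (om > best) { best <- om; best_lr <- c(l, r) }
    }
  }
  c(omega = best, l = best_lr[1], r = best_lr[2])
}

#' LD-based omega statistic on a grid
#'
#' At each grid point, considers the nearest `max_snps_side` polymorphic
#' sites on each side and maximises, over left/right set sizes `l, r >= 2`,
#' the ratio of mean within-side r-squared to mean between-side r-squared
#' (with `eps` added to the denominator). Elevated omega marks the
#' LD-breakdown signature of a completed sweep. Grid points with fewer than
#' 2 polymorphic sites on either side are `NA`.
#'
#' @param gm a [geno_matrix()]
#' @param subgroup subgroup label(s) scanned
#' @param chrom_lengths named lengths of the chromosomes to scan
#' @param grid_size grid spacing in bp (default 20 kb)
#' @param max_snps_side maximum SNPs per side (default 25)
#' @param eps denominator stabiliser (default 1e-6)
#' @return data.frame `chrom`, `pos`, `omega`, `n_left`, `n_right`
#' @export
omega_statistic <- function(gm, subgroup = NULL, chrom_lengths,
                            grid_size = 20000, max_snps_side = 25,
                            eps = 1e-6) {
  if (!is.null(subgroup)) gm <- gm_samples(gm, subgroup = subgroup)
  if (nrow(gm$geno) < 4) stop("need at least 4 samples in the scanned group")
  g <- gm$geno
  v <- matrixStats_colVars(g)
  res <- list(); k <- 0L
  for (ch in names(chrom_lengths)) {
    poly <- which(gm$sites$chrom == ch & !is.na(v) & v > 0)
    poly <- poly[order(gm$sites$pos[poly])]
    pos <- gm$sites$pos[poly]
    grid <- seq(grid_size, chrom_lengths[[ch]], by = grid_size)
    for (gp in grid) {
      k <- k + 1L
      left <- poly[pos <= gp]; right <- poly[pos > gp]
      nl <- min(length(left), max_snps_side)
      nr <- min(length(right), max_snps_side)
      if (nl < 2 || nr < 2) {
        res[[k]] <- data.frame(chrom = ch, pos = gp, omega = NA_real_,
                               n_left = NA_integer_, n_right = NA_integer_)
        next
      }
      lsel <- rev(utils::tail(left, nl))   # nearest first
      rsel <- utils::head(right, nr)
      cols <- c(lsel, rsel)
      r2 <- suppressWarnings(stats::cor(g[, cols, drop = FALSE],
                                        use = "pairwise.complete.obs"))^2
      r2[is.na(r2)] <- 0
      om <- omega_from_r2(r2, nl, nr, eps)
      res[[k]] <- data.frame(chrom = ch, pos = gp, omega = om[["omega"]],
                             n_left = as.integer(om[["l"]]),
                             n_right = as.integer(om[["r"]]))
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' @noRd
matrixStats_colVars <- function(g) {
  n <- colSums(!is.na(g))
  mu <- colMeans(g, na.rm = TRUE)
  ss <- colSums(g^2, na.rm = TRUE)
  ifelse(n > 1, (ss - n * mu^2) / (n - 1), NA_real_)
}

#' Select outlier regions by upper-tail quantile
#'
#' Values at or above the empirical `1 - q` quantile (ties inclusive) are
#' selected, each carrier interval is expanded by `flank` bp on both sides,
#' and overlapping expansions are merged. An optional absolute floor
#' (`value_floor`) must also be exceeded; infinite values always rank at the
#' top.
#'
#' @param stats window-statistic frame (intervals) or omega frame (`pos`
#'   grid points)
#' @param q upper-tail mass (default 0.05)
#' @param flank flank size in bp (default 4 kb)
#' @param value_floor minimum value for a carrier (default `-Inf`, i.e. the
#'   pure quantile rule)
#' @return merged interval table of outlier regions
#' @export
top_percentile_regions <- function(stats, q = 0.05, flank = 4000,
                                   value_floor = -Inf) {
  val_col <- if ("value" %in% names(stats)) "value" else "omega"
  vals <- stats[[val_col]]
  ok <- !is.na(vals)
  if (sum(ok) < 20)
    warning("fewer than 20 values: quantile threshold is unstable")
  finite <- vals[ok & is.finite(vals)]
  n_inf <- sum(ok & is.infinite(vals))
  if (length(finite) && length(unique(finite)) == 1 && n_inf == 0) {
    warning("all values identical: no outliers")
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric()))
  }
  cut <- stats::quantile(vals[ok], 1 - q, names = FALSE, type = 7)
  sel <- ok & vals >= cut & vals >= value_floor
  if (!any(sel))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric()))
  if ("start" %in% names(stats)) {
    iv <- gi(stats$chrom[sel], stats$start[sel], stats$end[sel])
  } else {
    iv <- gi(stats$chrom[sel], stats$pos[sel], stats$pos[sel])
  }
  iv$start <- pmax(1, iv$start - flank)
  iv$end <- iv$end + flank
  gi_reduce(iv)
}

#' Intersect two outlier region sets and merge the overlaps
#'
#' Computes all pairwise intersections between `a` and `b`, merges
#' intersections that overlap each other, and retains provenance: for each
#' merged region, the indices of the supporting members of `a` and `b`.
#' Every reported region therefore has non-empty support from both inputs.
#'
#' @param a,b interval tables (e.g. from [top_percentile_regions()])
#' @return interval table with `n_a_support`, `n_b_support` columns and
#'   attributes `a_support`/`b_support` (lists of member indices)
#' @export
intersect_merge <- function(a, b) {
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      n_a_support = integer(), n_b_support = integer())
  if (nrow(a) == 0 || nrow(b) == 0) {
    attr(empty, "a_support") <- list(); attr(empty, "b_support") <- list()
    return(empty)
  }
  gra <- gi_to_gr(a); grb <- gi_to_gr(b)
  inter <- suppressWarnings(GenomicRanges::reduce(
    GenomicRanges::intersect(gra, grb, ignore.strand = TRUE)))
  if (!length(inter)) {
    attr(empty, "a_support") <- list(); attr(empty, "b_support") <- list()
    return(empty)
  }
  out <- gr_to_gi(inter)
  ha <- suppressWarnings(GenomicRanges::findOverlaps(inter, gra))
  hb <- suppressWarnings(GenomicRanges::findOverlaps(inter, grb))
  a_support <- split(S4Vectors::subjectHits(ha), S4Vectors::queryHits(ha))
  b_support <- split(S4Vectors::subjectHits(hb), S4Vectors::queryHits(hb))
  out$n_a_support <- vapply(seq_len(nrow(out)), function(i)
    length(a_support[[as.character(i)]] %||% integer()), integer(1))
  out$n_b_support <- vapply(seq_len(nrow(out)), function(i)
    length(b_support[[as.character(i)]] %||% integer()), integer(1))
  stopifnot(all(out$n_a_support >= 1), all(out$n_b_support >= 1))
  attr(out, "a_support") <- a_support
  attr(out, "b_support") <- b_support
  out
}

#' Attach overlapping genes to sweep regions
#'
#' Any overlap of at least 1 bp assigns a gene to a region.
#'
#' @param regions interval table of sweep regions
#' @param genes interval table with a `gene_id` column ([read_gff_genes()])
#' @return `regions` with a `genes` list-column and `n_genes`; attribute
#'   `all_genes` holds the unique gene ids across regions
#' @export
annotate_sweep_genes <- function(regions, genes) {
  if (nrow(regions) == 0) {
    regions$genes <- list(); regions$n_genes <- integer()
    attr(regions, "all_genes") <- character()
    return(regions)
  }
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gi_to_gr(regions),
                                                       gi_to_gr(genes)))
  gl <- split(genes$gene_id[S4Vectors::subjectHits(hits)],
              S4Vectors::queryHits(hits))
  regions$genes <- lapply(seq_len(nrow(regions)), function(i)
    unname(gl[[as.character(i)]] %||% character()))
  regions$n_genes <- vapply(regions$genes, length, integer(1))
  attr(regions, "all_genes") <- unique(unlist(regions$genes))
  regions
}

#' Run the full sweep scan for one cultivar subgroup
#'
#' pi in 50-kb/10-kb sliding windows for the wild and cultivar groups, the
#' wild/cultivar ratio, omega on a 20-kb grid in the cultivar group, top-5%
#' outliers of each statistic extended by 4-kb flanks, intersected and
#' merged, and (optionally) annotated with overlapping genes.
#'
#' @param gm a filtered [geno_matrix()]
#' @param wild wild subgroup label
#' @param cultivar cultivar subgroup label
#' @param chrom_lengths named chromosome lengths (bp)
#' @param window,step pi window and step (bp)
#' @param grid_size omega grid (bp)
#' @param top_q upper-tail mass (default 0.05)
#' @param flank flank size (default 4 kb)
#' @param ratio_floor absolute pi-ratio floor for outlier windows (default 2;
#'   0 disables)
#' @param omega_floor absolute omega floor for outlier grid points (default
#'   5; 0 disables)
#' @param max_snps_side omega SNPs per side (default 25)
#' @param genes optional gene interval table
#' @return list with `regions` (sweep regions with support counts and genes),
#'   `pi_ratio`, `omega`, `ratio_regions`, `omega_regions`
#' @export
scan_sweeps <- function(gm, wild, cultivar, chrom_lengths,
                        window = 50000, step = 10000, grid_size = 20000,
                        top_q = 0.05, flank = 4000,
                        ratio_floor = 2, omega_floor = 5,
                        max_snps_side = 25, genes = NULL) {
  windows <- make_windows(chrom_lengths, window, step)
  pw <- nucleotide_diversity(gm, windows, subgroup = wild)
  pc <- nucleotide_diversity(gm, windows, subgroup = cultivar)
  ratio <- pi_ratio_windows(pw, pc)
  om <- omega_statistic(gm, subgroup = cultivar, chrom_lengths = chrom_lengths,
                        grid_size = grid_size, max_snps_side = max_snps_side)
  rr <- top_percentile_regions(ratio, q = top_q, flank = flank,
                               value_floor = ratio_floor)
  orx <- top_percentile_regions(om, q = top_q, flank = flank,
                                value_floor = omega_floor)
  regions <- intersect_merge(rr, orx)
  if (!is.null(genes)) regions <- annotate_sweep_genes(regions, genes)
  list(regions = regions, pi_ratio = ratio, omega = om,
       ratio_regions = rr, omega_regions = orx)
}
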