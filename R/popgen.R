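# Windowed population-genetic statistics. All estimators work from unphased
# alt-allele dosages with pairwise (per-site) exclusion of missing genotypes.
# Window values for pi use the window length in bp as denominator (the
# VCFtools --window-pi convention), and Fst windows aggregate variance
# components by ratio-of-sums.

#' Tile chromosomes with sliding windows
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp)
#' @param window window size in bp (default 50 kb)
#' @param step step between window starts in bp (default 10 kb)
#' @return interval table of windows; the last window of each chromosome is
#'   truncated at the chromosome end
#' @export
make_windows <- function(chrom_lengths, window = 50000, step = 10000) {
  stopifnot(!is.null(names(chrom_lengths)), all(chrom_lengths >= 1))
  if (window < step)
    warning("window smaller than step: windows will not tile the chromosome")
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(1, max(1, len), by = step)
    starts <- starts[starts <= len]
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + window - 1, len))
  })
  do.call(rbind, out)
}

# map sites onto (possibly overlapping) windows; returns a two-column matrix
# of (window index, site index) pairs
#' @noRd
window_site_hits <- function(windows, sites) {
  wgr <- gi_to_gr(windows)
  sgr <- GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(sites$pos, sites$pos))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(wgr, sgr))
  cbind(win = S4Vectors::queryHits(hits), site = S4Vectors::subjectHits(hits))
}

#' @noRd
window_stat_frame <- function(windows, stat, value, n_sites) {
  data.frame(chrom = windows$chrom, start = windows$start, end = windows$end,
             stat = stat, value = value, n_sites = n_sites,
             stringsAsFactors = FALSE)
}

#' Filter a variant panel by the standard hard thresholds
#'
#' Removes sites with `DP < dp_min` or `DP > dp_max`, quality `< q_min`,
#' missing-genotype rate `> max_missing`, or minor allele frequency
#' `< maf_min` (a site with MAF exactly `maf_min` is retained: the rule is a
#' strict "less than"). The defaults (2, 40, 20, 0.20, 0.05) are the usual
#' resequencing hard filters for ~10x panels.
#'
#' @param gm a [geno_matrix()]
#' @param dp_min,dp_max site depth bounds (inclusive)
#' @param q_min minimum site quality
#' @param max_missing maximum tolerated missing-genotype fraction
#' @param maf_min minimum minor allele frequency (strict lower bound on
#'   removal)
#' @return filtered `geno_matrix`
#' @export
filter_variants <- function(gm, dp_min = 2, dp_max = 40, q_min = 20,
                            max_missing = 0.20, maf_min = 0.05) {
  stopifnot(inherits(gm, "geno_matrix"), dp_min <= dp_max,
            max_missing >= 0, max_missing <= 1, maf_min >= 0, maf_min <= 0.5)
  if (ncol(gm$geno) == 0) stop("empty genotype matrix")
  st <- gm$sites
  miss <- colMeans(is.na(gm$geno))
  ac <- site_allele_counts(gm)
  maf <- pmin(ac$p, 1 - ac$p)
  keep_dp <- is.na(st$dp) | (st$dp >= dp_min & st$dp <= dp_max)
  keep_q <- is.na(st$qual) | st$qual >= q_min
  keep_miss <- miss <= max_missing
  keep_maf <- !is.na(maf) & maf >= maf_min
  gm_subset(gm, sites = which(keep_dp & keep_q & keep_miss & keep_maf))
}

# per-site unbiased heterozygosity 2*p*q*n/(n-1) (the per-site contribution
# to mean pairwise differences)
#' @noRd
site_pi <- function(gm) {
  ac <- site_allele_counts(gm)
  h <- ifelse(ac$n >= 2, 2 * ac$p * (1 - ac$p) * ac$n / (ac$n - 1), 0)
  h[is.na(h)] <- 0
  h
}

#' Windowed nucleotide diversity (pi)
#'
#' Per window, pi is the sum over sites of the unbiased per-site mean pairwise
#' difference `2*p*q*n/(n-1)` divided by the window length in bp (monomorphic
#' and uncalled positions contribute zero).
#'
#' @param gm a [geno_matrix()]
#' @param windows interval table from [make_windows()]
#' @param subgroup optional subgroup label(s); statistics are computed on the
#'   matching samples only
#' @return window-statistic data.frame (`stat = "pi"`)
#' @export
nucleotide_diversity <- function(gm, windows, subgroup = NULL) {
  if (!is.null(subgroup)) gm <- gm_samples(gm, subgroup = subgroup)
  if (2 * nrow(gm$geno) < 2) stop("need at least 2 sequences for pi")
  h <- site_pi(gm)
  hits <- window_site_hits(windows, gm$sites)
  val <- rep(0, nrow(windows)); nsit <- rep(0L, nrow(windows))
  if (nrow(hits)) {
    sums <- rowsum(h[hits[, "site"]], hits[, "win"])
    poly <- rowsum(as.numeric(h[hits[, "site"]] > 0), hits[, "win"])
    idx <- as.integer(rownames(sums))
    val[idx] <- sums[, 1]
    nsit[idx] <- as.integer(poly[, 1])
  }
  wlen <- windows$end - windows$start + 1
  window_stat_frame(windows, "pi", val / wlen, nsit)
}

# Tajima (1989) constants for sample size n (number of sequences)
#' @noRd
tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Windowed Tajima's D
#'
#' Standard normalized difference between mean pairwise diversity and
#' Watterson's theta. Windows with no segregating sites are `NA` (the
#' statistic is undefined there, not zero). The sample size used for the
#' constants is the median number of observed alleles across the window's
#' sites.
#'
#' @inheritParams nucleotide_diversity
#' @return window-statistic data.frame (`stat = "tajimas_d"`)
#' @export
tajimas_d <- function(gm, windows, subgroup = NULL) {
  if (!is.null(subgroup)) gm <- gm_samples(gm, subgroup = subgroup)
  ac <- site_allele_counts(gm)
  h <- site_pi(gm)
  seg <- !is.na(ac$p) & ac$p > 0 & ac$p < 1 & ac$n >= 4
  hits <- window_site_hits(windows, gm$sites)
  val <- rep(NA_real_, nrow(windows)); nsit <- rep(0L, nrow(windows))
  if (nrow(hits)) {
    keep <- seg[hits[, "site"]]
    hits <- hits[keep, , drop = FALSE]
  }
  if (nrow(hits)) {
    for (w in unique(hits[, "win"])) {
      s_idx <- hits[hits[, "win"] == w, "site"]
      S <- length(s_idx)
      nsit[w] <- S
      n <- stats::median(ac$n[s_idx])
      if (n < 4 || S < 1) next
      k <- sum(h[s_idx])
      cst <- tajima_constants(n)
      denom <- sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
      if (denom == 0) next
      val[w] <- (k - S / cst$a1) / denom
    }
  }
  window_stat_frame(windows, "tajimas_d", val, nsit)
}

# Weir & Cockerham (1984) per-site variance components for two populations of
# diploids; returns the a (among-population), b (among-individual) and c
# (within-individual) components per site.
#' @noRd
wc_components <- function(gm_a, gm_b) {
  aa <- site_allele_counts(gm_a); ab <- site_allele_counts(gm_b)
  n1 <- aa$n / 2; n2 <- ab$n / 2            # individuals with data
  p1 <- aa$p; p2 <- ab$p
  h1 <- ifelse(n1 > 0, aa$het / n1, NA); h2 <- ifelse(n2 > 0, ab$het / n2, NA)
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- ifelse(nbar > 0, (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1), NA)
  pbar <- ifelse(nbar > 0, (n1 * p1 + n2 * p2) / (r * nbar), NA)
  s2 <- ifelse(nbar > 0, (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) /
                 ((r - 1) * nbar), NA)
  hbar <- ifelse(nbar > 0, (n1 * h1 + n2 * h2) / (r * nbar), NA)
  ok <- !is.na(pbar) & n1 >= 2 & n2 >= 2 & nbar > 1 & nc > 0
  a <- b <- cc <- rep(NA_real_, length(p1))
  a[ok] <- (nbar[ok] / nc[ok]) *
    (s2[ok] - (1 / (nbar[ok] - 1)) *
       (pbar[ok] * (1 - pbar[ok]) - ((r - 1) / r) * s2[ok] - hbar[ok] / 4))
  b[ok] <- (nbar[ok] / (nbar[ok] - 1)) *
    (pbar[ok] * (1 - pbar[ok]) - ((r - 1) / r) * s2[ok] -
       ((2 * nbar[ok] - 1) / (4 * nbar[ok])) * hbar[ok])
  cc[ok] <- hbar[ok] / 2
  list(a = a, b = b, c = cc, ok = ok)
}

#' Windowed Weir-Cockerham Fst between two groups
#'
#' Two-level (population / individual / allele) variance-components estimator
#' for two groups of diploids, aggregated per window by ratio of sums
#' `sum(a) / sum(a + b + c)` over the window's sites.
#'
#' @param gm a [geno_matrix()]
#' @param group_a,group_b group labels
#' @param windows interval table
#' @param by which sample label carries the groups: `"subgroup"` or `"sex"`
#' @return window-statistic data.frame (`stat = "fst_wc"`); windows with no
#'   usable site are `NA`
#' @export
fst_weir_cockerham <- function(gm, group_a, group_b, windows,
                               by = c("subgroup", "sex")) {
  by <- match.arg(by)
  lab <- gm$samples[[by]]
  ga <- gm_subset(gm, samples = which(lab %in% group_a))
  gb <- gm_subset(gm, samples = which(lab %in% group_b))
  if (nrow(ga$geno) < 2 || nrow(gb$geno) < 2)
    stop("need at least 2 diploid samples per group")
  comp <- wc_components(ga, gb)
  hits <- window_site_hits(windows, gm$sites)
  val <- rep(NA_real_, nrow(windows)); nsit <- rep(0L, nrow(windows))
  if (nrow(hits)) {
    keep <- comp$ok[hits[, "site"]]
    hits <- hits[keep, , drop = FALSE]
  }
  if (nrow(hits)) {
    num <- rowsum(comp$a[hits[, "site"]], hits[, "win"])
    den <- rowsum(comp$a[hits[, "site"]] + comp$b[hits[, "site"]] +
                    comp$c[hits[, "site"]], hits[, "win"])
    cnt <- rowsum(rep(1L, nrow(hits)), hits[, "win"])
    idx <- as.integer(rownames(num))
    val[idx] <- ifelse(den[, 1] != 0, num[, 1] / den[, 1], NA_real_)
    nsit[idx] <- as.integer(cnt[, 1])
  }
  window_stat_frame(windows, "fst_wc", val, nsit)
}

#' Folded site-frequency spectrum
#'
#' Counts polymorphic sites by minor-allele count; a site with alt count `k`
#' of `n` observed alleles contributes to class `min(k, n - k)`. Sites with
#' any missing genotype are skipped (reported via `message`), since folding
#' requires a constant sample size.
#'
#' @param gm a [geno_matrix()]
#' @param subgroup optional subgroup label(s)
#' @return data.frame with columns `k` (1..floor(n/2)) and `count`, plus
#'   attribute `n_alleles`
#' @export
folded_sfs <- function(gm, subgroup = NULL) {
  if (!is.null(subgroup)) gm <- gm_samples(gm, subgroup = subgroup)
  g <- gm$geno
  full <- colSums(is.na(g)) == 0
  if (any(!full))
    message(sum(!full), " site(s) with missing genotypes skipped in folded SFS")
  g <- g[, full, drop = FALSE]
  n <- 2L * nrow(g)
  kmax <- n %/% 2L
  alt <- colSums(g)
  minor <- pmin(alt, n - alt)
  counts <- tabulate(minor[minor >= 1], nbins = kmax)
  out <- data.frame(k = seq_len(kmax), count = counts)
  attr(out, "n_alleles") <- n
  out
}

#' Pairwise genotype r-squared within a distance limit
#'
#' Squared Pearson correlation of dosage vectors for all site pairs on the
#' same chromosome closer than `max_dist`. Zero-variance sites are skipped.
#'
#' @param gm a [geno_matrix()]
#' @param max_dist maximum pair distance (bp)
#' @param subgroup optional subgroup label(s)
#' @return data.frame `chrom`, `pos1`, `pos2`, `dist`, `r2`
#' @export
ld_r2 <- function(gm, max_dist, subgroup = NULL) {
  if (!is.null(subgroup)) gm <- gm_samples(gm, subgroup = subgroup)
  if (nrow(gm$geno) < 4) stop("need at least 4 samples for LD")
  g <- gm$geno
  v <- apply(g, 2, stats::var, na.rm = TRUE)
  chrom_res <- list()
  for (ch in unique(gm$sites$chrom)) {
    idx <- which(gm$sites$chrom == ch & !is.na(v) & v > 0)
    if (length(idx) < 2) next
    idx <- idx[order(gm$sites$pos[idx])]
    pos <- gm$sites$pos[idx]
    rows <- list(); k <- 0L
    for (i in seq_along(idx)[-length(idx)]) {
      j <- i + 1L
      while (j <= length(idx) && pos[j] - pos[i] <= max_dist) {
        r <- suppressWarnings(stats::cor(g[, idx[i]], g[, idx[j]],
                                         use = "pairwise.complete.obs"))
        if (!is.na(r)) {
          k <- k + 1L
          rows[[k]] <- c(pos[i], pos[j], r^2)
        }
        j <- j + 1L
      }
    }
    if (k > 0) {
      mat <- do.call(rbind, rows)
      chrom_res[[ch]] <- data.frame(chrom = ch, pos1 = mat[, 1],
                                    pos2 = mat[, 2],
                                    dist = mat[, 2] - mat[, 1],
                                    r2 = mat[, 3])
    }
  }
  if (!length(chrom_res))
    return(data.frame(chrom = character(), pos1 = numeric(), pos2 = numeric(),
                      dist = numeric(), r2 = numeric()))
  res <- do.call(rbind, chrom_res)
  rownames(res) <- NULL
  res
}

#' Distance at which LD has decayed to half its maximum
#'
#' Bins r-squared by pair distance, takes the largest bin mean as the
#' reference level, and returns the interpolated distance at which the binned
#' mean first falls to half that level. The statistic is a ratio, so it is
#' invariant to uniform scaling of the r-squared values.
#'
#' @param r2_records data.frame from [ld_r2()] (needs `dist`, `r2`)
#' @param bin_width distance bin width in bp
#' @return half-decay distance in bp, or `NA` (with a warning) if the binned
#'   curve never falls to half its maximum
#' @export
ld_half_decay <- function(r2_records, bin_width = 1000) {
  stopifnot(all(c("dist", "r2") %in% names(r2_records)))
  if (nrow(r2_records) == 0) { warning("no r2 records"); return(NA_real_) }
  bin <- floor(r2_records$dist / bin_width)
  m <- tapply(r2_records$r2, bin, mean)
  d <- (as.numeric(names(m)) + 0.5) * bin_width
  o <- order(d); d <- d[o]; m <- as.numeric(m[o])
  if (length(m) < 2) { warning("need at least 2 distance bins"); return(NA_real_) }
  peak <- max(m)
  target <- peak / 2
  below <- which(m <= target)
  below <- below[below > which.max(m)]
  if (!length(below)) {
    warning("LD curve never decays to half its maximum")
    return(NA_real_)
  }
  i <- below[1]
  if (i == 1) return(d[1])
  # linear interpolation between the bracketing bin centres
  d[i - 1] + (d[i] - d[i - 1]) * (m[i - 1] - target) / (m[i - 1] - m[i])
}

#' Per-site allelic association with sex
#'
#' For each site builds the 2x2 sex-by-allele count table from observed
#' dosages and computes the 1-df chi-square `n(ad-bc)^2 / (row and column
#' products)` together with `-log10` of its p-value. Monomorphic sites (or
#' empty margins) score zero.
#'
#' @param gm a [geno_matrix()] with both sexes present
#' @return data.frame `chrom`, `pos`, `chisq`, `neg_log10_p`
#' @export
sex_association <- function(gm) {
  sex <- gm$samples$sex
  if (!any(sex == "F") || !any(sex == "M"))
    stop("both sexes must be present")
  gf <- gm$geno[sex == "F", , drop = FALSE]
  gmale <- gm$geno[sex == "M", , drop = FALSE]
  altF <- colSums(gf, na.rm = TRUE); nF <- 2 * colSums(!is.na(gf))
  altM <- colSums(gmale, na.rm = TRUE); nM <- 2 * colSums(!is.na(gmale))
  a <- altF; b <- nF - altF; cc <- altM; d <- nM - altM
  n <- nF + nM
  denom <- (a + b) * (cc + d) * (a + cc) * (b + d)
  chisq <- ifelse(denom > 0, n * (a * d - b * cc)^2 / denom, 0)
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  data.frame(chrom = gm$sites$chrom, pos = gm$sites$pos,
             chisq = chisq, neg_log10_p = -log10(pmax(p, .Machine$double.xmin)),
             stringsAsFactors = FALSE)
}

#' Female-specific SNPs and their blocks
#'
#' A site is female-specific when one of its alleles is carried by at least
#' `min_female_carrier_frac` of the females and by at most `max_male_carriers`
#' males. Flagged sites are grouped into blocks: runs of at least `min_snps`
#' sites with inter-SNP gaps no larger than `max_gap`.
#'
#' @param gm a [geno_matrix()] with both sexes present
#' @param min_female_carrier_frac minimum fraction of females carrying the
#'   allele (default 0.9)
#' @param max_male_carriers maximum number of male carriers (default 0)
#' @param min_snps minimum sites per block (default 10)
#' @param max_gap maximum gap between consecutive block sites in bp
#'   (default 100 kb)
#' @return list with `sites` (flagged site table) and `blocks` (interval
#'   table with `n_snps`)
#' @export
female_specific_snps <- function(gm, min_female_carrier_frac = 0.9,
                                 max_male_carriers = 0,
                                 min_snps = 10, max_gap = 1e5) {
  sex <- gm$samples$sex
  if (!any(sex == "F") || !any(sex == "M"))
    stop("both sexes must be present")
  gf <- gm$geno[sex == "F", , drop = FALSE]
  gmale <- gm$geno[sex == "M", , drop = FALSE]
  carrier_frac <- function(g, allele) {
    car <- if (allele == "alt") g > 0 else g < 2
    colSums(car, na.rm = TRUE) / pmax(colSums(!is.na(g)), 1)
  }
  carrier_n <- function(g, allele) {
    car <- if (allele == "alt") g > 0 else g < 2
    colSums(car, na.rm = TRUE)
  }
  flag <- (carrier_frac(gf, "alt") >= min_female_carrier_frac &
             carrier_n(gmale, "alt") <= max_male_carriers) |
    (carrier_frac(gf, "ref") >= min_female_carrier_frac &
       carrier_n(gmale, "ref") <= max_male_carriers)
  sites <- gm$sites[flag, c("chrom", "pos"), drop = FALSE]
  rownames(sites) <- NULL
  blocks <- list(); bi <- 0L
  for (ch in unique(sites$chrom)) {
    pos <- sort(sites$pos[sites$chrom == ch])
    if (!length(pos)) next
    brk <- c(0, which(diff(pos) > max_gap), length(pos))
    for (i in seq_len(length(brk) - 1)) {
      run <- pos[(brk[i] + 1):brk[i + 1]]
      if (length(run) >= min_snps) {
        bi <- bi + 1L
        blocks[[bi]] <- data.frame(chrom = ch, start = run[1],
                                   end = run[length(run)],
                                   n_snps = length(run))
      }
    }
  }
  blocks <- if (bi) do.call(rbind, blocks) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               n_snps = integer())
  list(sites = sites, blocks = blocks)
}
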