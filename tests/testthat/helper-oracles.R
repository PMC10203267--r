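# Independent oracles and toy builders. Each oracle recomputes a statistic
# from first principles (explicit loops, direct enumeration), deliberately
# avoiding the package's vectorised/table-driven code paths.

toy_gm <- function(dos, pos = NULL, chrom = "Chr1", sex = NULL,
                   subgroup = NULL, dp = NULL, qual = NULL) {
  dos <- as.matrix(dos)
  n_samp <- nrow(dos); n_site <- ncol(dos)
  if (is.null(pos)) pos <- seq_len(n_site) * 100
  sites <- data.frame(chrom = rep(chrom, length.out = n_site), pos = pos,
                      ref = "A", alt = "T",
                      dp = if (is.null(dp)) rep(NA_real_, n_site) else dp,
                      qual = if (is.null(qual)) rep(NA_real_, n_site) else qual)
  samples <- data.frame(id = sprintf("s%02d", seq_len(n_samp)),
                        sex = if (is.null(sex)) "unknown" else sex,
                        subgroup = if (is.null(subgroup)) "other" else subgroup)
  geno_matrix(dos, sites, samples)
}

# mean pairwise difference per site by explicit loop over allele copies
oracle_pi_sum <- function(dos) {
  dos <- as.matrix(dos)
  total <- 0
  for (j in seq_len(ncol(dos))) {
    alleles <- integer()
    for (i in seq_len(nrow(dos))) {
      d <- dos[i, j]
      if (is.na(d)) next
      alleles <- c(alleles, c(rep(1L, d), rep(0L, 2 - d)))
    }
    n <- length(alleles)
    if (n < 2) next
    diffs <- 0; pairs <- 0
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      pairs <- pairs + 1
      if (alleles[a] != alleles[b]) diffs <- diffs + 1
    }
    total <- total + diffs / pairs * 1
  }
  total
}

# Tajima's D from S, mean pairwise differences k and sample size n,
# constants written out independently
oracle_tajima <- function(n, S, k) {
  if (S == 0) return(NA_real_)
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- (2 * (n * n + n + 3)) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / (a1 * a1)
  e1 <- c1 / a1
  e2 <- c2 / (a1 * a1 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Weir & Cockerham (1984) single-site estimator, written directly from the
# published equations (two populations, diploid)
oracle_fst_site <- function(dosA, dosB) {
  dosA <- dosA[!is.na(dosA)]; dosB <- dosB[!is.na(dosB)]
  n1 <- length(dosA); n2 <- length(dosB); r <- 2
  p1 <- sum(dosA) / (2 * n1); p2 <- sum(dosB) / (2 * n2)
  h1 <- mean(dosA == 1); h2 <- mean(dosB == 1)
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  ssq <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (ssq - (pbar * (1 - pbar) - (r - 1) / r * ssq -
                               hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * ssq -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc, fst = a / (a + b + cc))
}

# the same Weir-Cockerham equations from idealised population parameters
# (sample sizes, allele frequencies, observed het), for examples that are
# not realisable with integer genotype counts
oracle_fst_params <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  ssq <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (ssq - (pbar * (1 - pbar) - (r - 1) / r * ssq -
                               hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * ssq -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc, fst = a / (a + b + cc))
}

# Nei-Gojobori by direct per-codon recursion (no lookup tables)
oracle_ng86 <- function(s1, s2) {
  gc_map <- Biostrings::GENETIC_CODE
  aa_of <- function(codon) unname(gc_map[[codon]])
  bases <- c("A", "C", "G", "T")
  s1 <- toupper(s1); s2 <- toupper(s2)
  cods1 <- substring(s1, seq(1, nchar(s1), 3), seq(3, nchar(s1), 3))
  cods2 <- substring(s2, seq(1, nchar(s2), 3), seq(3, nchar(s2), 3))
  syn_sites_codon <- function(codon) {
    cs <- strsplit(codon, "")[[1]]
    s <- 0
    for (p in 1:3) {
      syn <- 0; tot <- 0
      for (b in setdiff(bases, cs[p])) {
        alt <- cs; alt[p] <- b
        alt <- paste(alt, collapse = "")
        if (aa_of(alt) == "*") next
        tot <- tot + 1
        if (aa_of(alt) == aa_of(codon)) syn <- syn + 1
      }
      if (tot > 0) s <- s + syn / tot
    }
    s
  }
  # recursively enumerate all substitution orderings
  enum_paths <- function(cur, target) {
    diffs <- which(strsplit(cur, "")[[1]] != strsplit(target, "")[[1]])
    if (!length(diffs)) return(list(list(sd = 0, nd = 0, ok = TRUE)))
    out <- list()
    for (p in diffs) {
      nxt <- strsplit(cur, "")[[1]]
      nxt[p] <- strsplit(target, "")[[1]][p]
      nxt <- paste(nxt, collapse = "")
      step_syn <- aa_of(cur) == aa_of(nxt)
      hits_stop <- aa_of(nxt) == "*" && nxt != target
      for (tail in enum_paths(nxt, target)) {
        out[[length(out) + 1]] <- list(
          sd = tail$sd + as.integer(step_syn),
          nd = tail$nd + as.integer(!step_syn),
          ok = tail$ok && !hits_stop && aa_of(nxt) != "*")
      }
    }
    out
  }
  S <- 0; Sd <- 0; Nd <- 0
  for (k in seq_along(cods1)) {
    S <- S + (syn_sites_codon(cods1[k]) + syn_sites_codon(cods2[k])) / 2
    if (cods1[k] == cods2[k]) next
    paths <- enum_paths(cods1[k], cods2[k])
    valid <- Filter(function(p) p$ok, paths)
    use <- if (length(valid)) valid else paths
    Sd <- Sd + mean(vapply(use, `[[`, numeric(1), "sd"))
    Nd <- Nd + mean(vapply(use, `[[`, numeric(1), "nd"))
  }
  N <- 3 * length(cods1) - S
  pS <- Sd / S; pN <- Nd / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
       Ks = jc(pS), Ka = jc(pN))
}

# random CDS without stop codons
random_cds <- function(n_codons) {
  gc_map <- Biostrings::GENETIC_CODE
  sense <- names(gc_map)[gc_map != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# omega by explicit loops over all splits and pairs
oracle_omega_point <- function(g, pos, grid_pos, max_side = 25, eps = 1e-6) {
  keep <- apply(g, 2, function(x) stats::var(x) > 0)
  g <- g[, keep, drop = FALSE]; pos <- pos[keep]
  left <- which(pos <= grid_pos); right <- which(pos > grid_pos)
  left <- left[order(grid_pos - pos[left])][seq_len(min(length(left), max_side))]
  right <- right[order(pos[right] - grid_pos)][seq_len(min(length(right), max_side))]
  if (length(left) < 2 || length(right) < 2) return(NA_real_)
  r2 <- function(i, j) {
    r <- stats::cor(g[, i], g[, j])
    if (is.na(r)) 0 else r^2
  }
  best <- -Inf
  for (l in 2:length(left)) for (r in 2:length(right)) {
    L <- left[1:l]; R <- right[1:r]
    sw <- 0; nw <- 0
    for (a in seq_along(L)) for (b in seq_along(L))
      if (a < b) { sw <- sw + r2(L[a], L[b]); nw <- nw + 1 }
    for (a in seq_along(R)) for (b in seq_along(R))
      if (a < b) { sw <- sw + r2(R[a], R[b]); nw <- nw + 1 }
    sb <- 0
    for (a in seq_along(L)) for (b in seq_along(R)) sb <- sb + r2(L[a], R[b])
    om <- (sw / nw) / (sb / (l * r) + eps)
    if (om > best) best <- om
  }
  best
}

# collinear blocks by breakpoint splitting (independent of the greedy
# state-machine in the package)
oracle_monotone_runs <- function(z_ranks, min_anchors = 2, max_gap = 2) {
  n <- length(z_ranks)
  if (n == 1) return(list())
  d <- diff(z_ranks)
  brk <- logical(n - 1)
  for (i in seq_len(n - 1)) {
    if (abs(d[i]) > max_gap) { brk[i] <- TRUE; next }
    if (i > 1 && !brk[i - 1] && sign(d[i]) != sign(d[i - 1])) brk[i] <- TRUE
  }
  bounds <- c(0, which(brk), n)
  out <- list()
  for (k in seq_len(length(bounds) - 1)) {
    idx <- (bounds[k] + 1):bounds[k + 1]
    if (length(idx) < min_anchors) next
    dir <- if (z_ranks[idx[length(idx)]] > z_ranks[idx[1]])
      "collinear" else "inverted"
    out[[length(out) + 1]] <- list(idx = idx, orientation = dir)
  }
  out
}

# quick anchor table from a vector of Z ranks
anchors_from_ranks <- function(z_ranks) {
  n <- length(z_ranks)
  data.frame(w_gene = sprintf("w%02d", seq_len(n)), w_chrom = "W",
             w_start = seq_len(n) * 1000, w_end = seq_len(n) * 1000 + 500,
             z_gene = sprintf("z%02d", seq_len(n)), z_chrom = "Z",
             z_start = z_ranks * 1000, z_end = z_ranks * 1000 + 500,
             stringsAsFactors = FALSE)
}
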