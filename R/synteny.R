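# W-Z microsynteny and divergence dating. Collinearity is computed by
# monotone-run chaining on anchor ranks (sufficient for a pre-paired gene set,
# where full DP block scoring would reduce to the same runs), inversions are
# the descending runs, and each inverted block is dated from its member gene
# pairs via Nei-Gojobori (1986) synonymous divergence and a molecular clock.

#' Chain anchor pairs into collinear and inverted blocks
#'
#' Anchors are ordered along the W chromosome and assigned Z ranks by Z
#' position. Maximal runs of anchors whose Z ranks move monotonically
#' (ascending = collinear, descending = inverted) with jumps of at most
#' `max_rank_gap` form blocks; runs shorter than `min_block_anchors` are
#' discarded. Duplicate gene ids keep their first (best) anchor with a
#' warning.
#'
#' @param anchors anchor-pair data.frame (see [read_anchors()])
#' @param min_block_anchors minimum anchors per reported block (default 3)
#' @param max_rank_gap maximum allowed jump in Z rank between consecutive
#'   anchors in a run (default 2; 1 means strictly consecutive ranks)
#' @return data.frame of blocks with W/Z spans, orientation and anchor count;
#'   attribute `assignment` maps anchor rows to block ids (NA = unassigned)
#' @export
build_collinear_blocks <- function(anchors, min_block_anchors = 3,
                                   max_rank_gap = 2) {
  stopifnot(nrow(anchors) >= 1)
  dup <- duplicated(anchors$w_gene) | duplicated(anchors$z_gene)
  if (any(dup)) {
    warning(sum(dup), " duplicate anchor(s) dropped (first occurrence kept)")
    anchors <- anchors[!dup, , drop = FALSE]
  }
  ord <- order(anchors$w_chrom, anchors$w_start)
  anchors <- anchors[ord, , drop = FALSE]
  z_rank <- rank(anchors$z_start, ties.method = "first")
  n <- nrow(anchors)
  run_id <- integer(n); run_id[1] <- 1L
  dir <- 0L
  for (i in seq_len(n)[-1]) {
    d <- z_rank[i] - z_rank[i - 1]
    same_chrom <- anchors$w_chrom[i] == anchors$w_chrom[i - 1]
    ok <- same_chrom && abs(d) <= max_rank_gap &&
      (dir == 0L || sign(d) == dir)
    if (ok) {
      run_id[i] <- run_id[i - 1]
      dir <- sign(d)
    } else {
      run_id[i] <- run_id[i - 1] + 1L
      dir <- 0L
    }
  }
  blocks <- list(); assignment <- rep(NA_integer_, n); bid <- 0L
  for (r in unique(run_id)) {
    idx <- which(run_id == r)
    if (length(idx) < max(2, min_block_anchors)) next
    d <- diff(z_rank[idx])
    orientation <- if (all(d > 0)) "collinear" else "inverted"
    bid <- bid + 1L
    assignment[idx] <- bid
    blocks[[bid]] <- data.frame(
      block = bid, orientation = orientation,
      w_chrom = anchors$w_chrom[idx[1]],
      w_start = min(anchors$w_start[idx]), w_end = max(anchors$w_end[idx]),
      z_chrom = anchors$z_chrom[idx[1]],
      z_start = min(anchors$z_start[idx]), z_end = max(anchors$z_end[idx]),
      n_anchors = length(idx), stringsAsFactors = FALSE)
  }
  out <- if (bid) do.call(rbind, blocks) else
    data.frame(block = integer(), orientation = character(),
               w_chrom = character(), w_start = numeric(), w_end = numeric(),
               z_chrom = character(), z_start = numeric(), z_end = numeric(),
               n_anchors = integer())
  attr(out, "assignment") <- assignment
  attr(out, "anchors") <- anchors
  out
}

#' Report inversions from collinear blocks
#'
#' @param blocks output of [build_collinear_blocks()]
#' @return list with `inversions` (the inverted blocks, W and Z spans and
#'   anchor counts), `total_anchors` and `envelope` (smallest W interval
#'   covering all inversions, or NULL)
#' @export
detect_inversions <- function(blocks) {
  inv <- blocks[blocks$orientation == "inverted", , drop = FALSE]
  envelope <- NULL
  if (nrow(inv))
    envelope <- gi(inv$w_chrom[1], min(inv$w_start), max(inv$w_end))
  list(inversions = inv, total_anchors = sum(inv$n_anchors),
       envelope = envelope)
}

#' Call W-specific and Z-specific genes by reciprocal-hit criteria
#'
#' A gene is non-specific when it has at least one hit in the reciprocal
#' table with identity `>= id_min` AND matching length `>= len_min`. The
#' specific call additionally requires the gene to be unpaired in the
#' collinearity result (both conditions must hold): W-specific genes fail the
#' hit criteria against Z and belong to no anchor pair, and symmetrically for
#' Z-specific genes.
#'
#' @param w_genes,z_genes character vectors of gene ids
#' @param hits_wz hits of W genes against the Z chromosome ([read_hits()])
#' @param hits_zw hits of Z genes against the Z/W chromosome
#' @param id_min identity threshold in percent (default 99)
#' @param len_min matching base pairs threshold (default 1000)
#' @param anchors optional anchor table; genes appearing in it are paired and
#'   therefore never specific
#' @return list with character vectors `w_specific` and `z_specific`
#' @export
call_specific_genes <- function(w_genes, z_genes, hits_wz, hits_zw,
                                id_min = 99, len_min = 1000, anchors = NULL) {
  qualifying <- function(hits) {
    good <- hits$identity >= id_min & hits$matching_bp >= len_min
    unique(hits$query[good])
  }
  check_known <- function(hits, genes, label) {
    unknown <- setdiff(unique(hits$query), genes)
    if (length(unknown))
      warning(length(unknown), " ", label,
              " hit query gene(s) not in the gene list; ignored")
  }
  check_known(hits_wz, w_genes, "W")
  check_known(hits_zw, z_genes, "Z")
  paired_w <- paired_z <- character()
  if (!is.null(anchors)) {
    paired_w <- unique(anchors$w_gene)
    paired_z <- unique(anchors$z_gene)
  }
  list(w_specific = setdiff(w_genes, union(qualifying(hits_wz), paired_w)),
       z_specific = setdiff(z_genes, union(qualifying(hits_zw), paired_z)))
}

# ---- Nei-Gojobori (1986) machinery --------------------------------------

# cached codon tables: per-codon fractional synonymous site counts and
# per-ordered-codon-pair path-averaged synonymous/nonsynonymous differences
.ng_cache <- new.env(parent = emptyenv())

#' @noRd
ng_codons <- function() {
  bases <- c("T", "C", "A", "G")
  as.vector(outer(outer(bases, bases, paste0), bases,
                  function(ab, c) paste0(ab, c)))
}

#' @noRd
ng_tables <- function(stop_paths = "exclude") {
  key <- paste0("tab_", stop_paths)
  if (!is.null(.ng_cache[[key]])) return(.ng_cache[[key]])
  gc_map <- Biostrings::GENETIC_CODE
  codons <- ng_codons()
  aa <- unname(gc_map[codons])
  is_stop <- aa == "*"
  bases <- c("T", "C", "A", "G")

  # fractional synonymous sites per codon: at each position, the fraction of
  # possible single-base changes (excluding changes to stop codons, with the
  # denominator renormalised) that preserve the amino acid
  syn_sites <- rep(NA_real_, 64)
  for (ci in seq_along(codons)) {
    if (is_stop[ci]) next
    s <- 0
    cod <- strsplit(codons[ci], "")[[1]]
    for (p in 1:3) {
      neigh_syn <- 0L; neigh_tot <- 0L
      for (b in setdiff(bases, cod[p])) {
        nc <- cod; nc[p] <- b
        naa <- unname(gc_map[paste(nc, collapse = "")])
        if (naa == "*") next
        neigh_tot <- neigh_tot + 1L
        if (naa == aa[ci]) neigh_syn <- neigh_syn + 1L
      }
      if (neigh_tot > 0) s <- s + neigh_syn / neigh_tot * 1
    }
    syn_sites[ci] <- s
  }

  # path-averaged synonymous/nonsynonymous differences per ordered codon pair
  sd_tab <- matrix(NA_real_, 64, 64)
  nd_tab <- matrix(NA_real_, 64, 64)
  split_codons <- strsplit(codons, "")
  step_counts <- function(from, to) {
    # single-base step from codon 'from' to 'to'
    if (gc_map[from] == gc_map[to]) c(1, 0) else c(0, 1)
  }
  for (i in seq_along(codons)) {
    if (is_stop[i]) next
    for (j in seq_along(codons)) {
      if (is_stop[j]) next
      if (i == j) { sd_tab[i, j] <- 0; nd_tab[i, j] <- 0; next }
      c1 <- split_codons[[i]]; c2 <- split_codons[[j]]
      diffpos <- which(c1 != c2)
      paths <- perms(diffpos)
      acc <- matrix(0, 0, 2); acc_all <- matrix(0, 0, 2)
      for (pi in seq_len(nrow(paths))) {
        cur <- c1; sd <- 0; nd <- 0; valid <- TRUE
        for (p in paths[pi, ]) {
          nxt <- cur; nxt[p] <- c2[p]
          fromc <- paste(cur, collapse = ""); toc <- paste(nxt, collapse = "")
          if (gc_map[[toc]] == "*") valid <- FALSE  # path through a stop
          st <- step_counts(fromc, toc)
          sd <- sd + st[1]; nd <- nd + st[2]
          cur <- nxt
        }
        acc_all <- rbind(acc_all, c(sd, nd))
        if (valid) acc <- rbind(acc, c(sd, nd))
      }
      use <- if (stop_paths == "exclude" && nrow(acc) > 0) acc else acc_all
      sd_tab[i, j] <- mean(use[, 1])
      nd_tab[i, j] <- mean(use[, 2])
    }
  }
  tab <- list(codons = codons, syn_sites = syn_sites,
              sd = sd_tab, nd = nd_tab, is_stop = is_stop)
  .ng_cache[[key]] <- tab
  tab
}

#' @noRd
perms <- function(x) {
  if (length(x) <= 1) return(matrix(x, nrow = 1))
  out <- NULL
  for (i in seq_along(x))
    out <- rbind(out, cbind(x[i], perms(x[-i])))
  out
}

#' @noRd
codon_index <- function(seq, codons) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n %% 3 != 0) stop("CDS length is not a multiple of 3")
  cods <- substring(seq, seq(1, n, 3), seq(3, n, 3))
  idx <- match(cods, codons)
  if (anyNA(idx)) stop("non-ACGT codon at codon ", which(is.na(idx))[1])
  idx
}

#' Nei-Gojobori divergence between an aligned CDS pair
#'
#' Counting method of Nei & Gojobori (1986): fractional synonymous site
#' counts per codon (averaged over the two sequences), observed synonymous
#' and nonsynonymous differences with multi-hit codons resolved by averaging
#' over all orderings of single changes, and Jukes-Cantor correction
#' `d = -(3/4) log(1 - (4/3) p)` applied to both proportions. Pathways
#' passing through stop codons are excluded and the path weights renormalised
#' (`stop_paths = "exclude"`, the DnaSP-like behaviour); with
#' `stop_paths = "count"` such pathways are retained. Silent-site divergence
#' `Ksil` equals `Ks` for CDS-only input (no noncoding sites are supplied);
#' this is flagged in the output.
#'
#' @param cds1,cds2 aligned coding sequences (equal length, multiple of 3, no
#'   internal stop codons)
#' @param stop_paths `"exclude"` (default) or `"count"`
#' @return one-row data.frame with `S`, `N`, `Sd`, `Nd`, `pS`, `pN`, `Ks`,
#'   `Ka`, `Ksil`, `ksil_is_ks` and `saturated` (`TRUE` when a proportion
#'   reached 0.75 so the correction is undefined and the estimate is `NA`)
#' @export
nei_gojobori <- function(cds1, cds2, stop_paths = c("exclude", "count")) {
  stop_paths <- match.arg(stop_paths)
  tab <- ng_tables(stop_paths)
  i1 <- codon_index(cds1, tab$codons)
  i2 <- codon_index(cds2, tab$codons)
  if (length(i1) != length(i2)) stop("aligned CDS lengths differ")
  if (any(tab$is_stop[i1]) || any(tab$is_stop[i2]))
    stop("internal stop codon in input CDS")
  S <- (sum(tab$syn_sites[i1]) + sum(tab$syn_sites[i2])) / 2
  N <- 3 * length(i1) - S
  Sd <- sum(tab$sd[cbind(i1, i2)])
  Nd <- sum(tab$nd[cbind(i1, i2)])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) {
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  Ks <- jc(pS); Ka <- jc(pN)
  data.frame(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
             Ks = Ks, Ka = Ka, Ksil = Ks, ksil_is_ks = TRUE,
             saturated = is.na(Ks) || is.na(Ka))
}

#' Nei-Gojobori estimates for a table of CDS pairs
#'
#' @param pairs data.frame with columns `w_gene`, `z_gene` (and optionally
#'   `block`)
#' @param cds named character vector of sequences covering every gene id
#' @param stop_paths see [nei_gojobori()]
#' @return `pairs` with the divergence columns appended
#' @export
kaks_table <- function(pairs, cds, stop_paths = "exclude") {
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    s1 <- cds[[pairs$w_gene[i]]]; s2 <- cds[[pairs$z_gene[i]]]
    if (is.null(s1) || is.null(s2))
      stop("missing CDS for pair ", pairs$w_gene[i], " / ", pairs$z_gene[i])
    nei_gojobori(s1, s2, stop_paths)
  })
  cbind(pairs, do.call(rbind, res))
}

#' Date a divergence estimate with a molecular clock
#'
#' `T = Ksil / (2 * mu)` years: the silent divergence accumulates along both
#' lineages, so the per-lineage time is half the divergence over the clock
#' rate.
#'
#' @param ksil silent-site divergence (substitutions per site); `NA` gives
#'   `NA` time
#' @param mu clock rate in substitutions per site per year (default 7.5e-10,
#'   the rate estimated for *Pistacia*)
#' @return divergence time in years
#' @export
date_divergence <- function(ksil, mu = 7.5e-10) {
  stopifnot(mu > 0)
  ksil / (2 * mu)
}

#' Assign evolutionary strata from inverted blocks and pair dates
#'
#' One stratum per inverted block, summarised by the median divergence time
#' of its member pairs and numbered by descending age (the oldest inversion
#' is stratum 1). Blocks with fewer than 3 dated pairs are flagged
#' low-confidence.
#'
#' @param inversions `inversions` element of [detect_inversions()]
#' @param pair_times data.frame with columns `block` and `t_years`
#' @return data.frame of strata: `stratum`, `block`, W/Z spans,
#'   `median_t_years`, `median_t_mya`, `n_pairs`, `low_confidence`
#' @export
assign_strata <- function(inversions, pair_times) {
  if (nrow(inversions) == 0)
    return(data.frame(stratum = integer(), block = integer(),
                      w_chrom = character(), w_start = numeric(),
                      w_end = numeric(), median_t_years = numeric(),
                      median_t_mya = numeric(), n_pairs = integer(),
                      low_confidence = logical()))
  rows <- lapply(seq_len(nrow(inversions)), function(i) {
    b <- inversions$block[i]
    tt <- pair_times$t_years[pair_times$block == b & !is.na(pair_times$t_years)]
    data.frame(block = b,
               w_chrom = inversions$w_chrom[i],
               w_start = inversions$w_start[i], w_end = inversions$w_end[i],
               median_t_years = if (length(tt)) stats::median(tt) else NA_real_,
               n_pairs = length(tt),
               low_confidence = length(tt) < 3)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$median_t_years), , drop = FALSE]
  out$stratum <- seq_len(nrow(out))
  out$median_t_mya <- out$median_t_years / 1e6
  rownames(out) <- NULL
  out[, c("stratum", "block", "w_chrom", "w_start", "w_end",
          "median_t_years", "median_t_mya", "n_pairs", "low_confidence")]
}
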