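# Seeded synthetic-data generators. Every generator is a pure function of
# (config, seed): it emulates the statistical structure the detectors assume
# (pooled Poisson coverage with W-specific dropout, fully penetrant sex-linked
# SNPs, neutral folded-spectrum genotype panels with planted sweeps,
# clock-divergent W-Z CDS pairs, recombination-suppressed genetic maps) and
# ships a machine-readable truth set, so every downstream stage is testable
# without external data.

#' Simulation configuration
#'
#' Defaults mirror the study conditions of a ZW nut-tree genome at desk
#' scale: one 55-Mb ZW chromosome plus two 20-Mb autosomes; an SDR at
#' Chr14:39979216-52678755 (12.70 Mb) containing three inversions aged 8.18,
#' 3.80 and 3.47 Mya with 170/173/44 anchor pairs; pooled depth 30x per sex;
#' a 22-female/22-male resequencing panel; and wild/cultivar panels with
#' theta = 0.008 and planted sweeps (diversity reduction factor 5) on a
#' dedicated 2-Mb population chromosome.
#'
#' @param seed integer seed; all generators derive their streams from it
#' @param ... overrides for any default element (see the function body for
#'   the full list)
#' @return a `sim_config` list
#' @export
sim_config <- function(seed = 1, ...) {
  defaults <- list(
    seed = as.integer(seed),
    chromosomes = c(Chr14 = 55e6, Chr01 = 20e6, Chr02 = 20e6),
    zw_chrom = "Chr14",
    sdr = c(start = 39979216, end = 52678755),
    # three W inversions: W span, age (years), anchor pairs
    inversions = data.frame(
      w_start = c(49032998, 42858892, 40647874),
      w_end = c(52416681, 48612698, 42816399),
      age_years = c(8.18e6, 3.80e6, 3.47e6),
      n_pairs = c(170L, 173L, 44L)),
    # Z counterpart region the inversions map into
    z_counterpart = c(start = 50002496, end = 52514087),
    # collinear (pseudoautosomal-like) anchor blocks flanking the inversions
    collinear_blocks = data.frame(
      w_start = c(39979216, 52417733), w_end = c(40460393, 52678755),
      age_years = c(3e5, 3e5), n_pairs = c(10L, 10L)),
    # divergent-coverage mosaic inside the SDR (first segment starts at the
    # SDR start and the last ends at the SDR end, so the coverage caller can
    # recover the truth boundaries)
    w_specific = data.frame(
      start = c(39979216, 43700000, 45800000, 49600000, 50430000, 52100000),
      end = c(41300000, 45000000, 47000000, 50400000, 51350000, 52678755)),
    male_elevated = data.frame(
      start = c(42000000, 47800000), end = c(43000000, 48900000)),
    # pooled coverage
    lambda_f = 30, lambda_m = 30, cov_window = 10000,
    # sex panel
    n_females = 22L, n_males = 22L,
    bg_snp_per_bp = 2e-4, sdr_snp_per_bp = 5e-4,
    # population panel (simulated on its own down-scaled chromosome)
    pop_chromosomes = c(Chr01 = 4e6),
    subgroup_sizes = c(wild = 20L, Cultivar_I = 20L, Cultivar_II = 20L,
                       Cultivar_III = 40L),
    theta = 0.008,
    sweeps = data.frame(chrom = "Chr01",
                        center = c(8e5, 2e6, 3.2e6),
                        half_width = 30000, core_half_width = 10000,
                        factor = 5),
    sweep_subgroups = c("Cultivar_I", "Cultivar_II", "Cultivar_III"),
    latent_q = 0.25, flip_prob = 0.05, latent_tile = 5000,
    pi_window = 50000,
    gene_spacing = 25000, gene_width = 10000,
    # W-Z gene pairs
    mu = 7.5e-10, codons_per_gene = 1000L, length_jitter = 0.5,
    nonsyn_factor = 0.05,
    # genetic map
    marker_spacing = 2e5, cm_per_mb = 2, map_noise_sd = 0.1
  )
  cfg <- merge_params(defaults, list(...))
  class(cfg) <- "sim_config"
  cfg
}

#' Read a simulation configuration from YAML
#'
#' Table-valued fields (inversions, collinear_blocks, w_specific,
#' male_elevated, sweeps) are written in YAML as parallel lists and coerced
#' to data frames; chromosome maps and subgroup sizes become named vectors.
#' Any field not present keeps its [sim_config()] default.
#'
#' @param path path to a YAML file
#' @param seed seed override (the YAML `seed` wins if present)
#' @return a `sim_config`
#' @export
read_sim_config <- function(path, seed = 1) {
  raw <- yaml::read_yaml(path)
  df_fields <- c("inversions", "collinear_blocks", "w_specific",
                 "male_elevated", "sweeps")
  vec_fields <- c("chromosomes", "sdr", "z_counterpart", "pop_chromosomes",
                  "subgroup_sizes")
  for (f in intersect(df_fields, names(raw)))
    raw[[f]] <- as.data.frame(raw[[f]], stringsAsFactors = FALSE)
  for (f in intersect(vec_fields, names(raw)))
    raw[[f]] <- unlist(raw[[f]])
  if (!is.null(raw$seed)) seed <- raw$seed
  raw$seed <- NULL
  do.call(sim_config, c(list(seed = as.integer(seed)), raw))
}

#' @noRd
check_intervals_inside <- function(x, lo, hi, what) {
  if (nrow(x) == 0) return(invisible())
  if (any(x[[1]] < lo) || any(x[[2]] > hi))
    stop(what, " interval outside the chromosome/SDR bounds")
  o <- order(x[[1]])
  s <- x[[1]][o]; e <- x[[2]][o]
  if (length(s) > 1 && any(s[-1] <= e[-length(s)]))
    stop("overlapping ", what, " truth intervals")
  invisible()
}

#' Lay out the synthetic ZW reference and its truth set
#'
#' Designates the ZW chromosome, places the SDR with its W-specific and
#' male-elevated coverage segments, the inversion blocks with their ages, and
#' the planted sweeps of the population chromosome, and returns the
#' machine-readable truth set alongside.
#'
#' @param config a [sim_config()]
#' @return a `zw_layout` list: `config`, `chromosomes`, `zw_chrom`, `sdr`,
#'   `segments`, `inversions`, `collinear_blocks`, `sweeps`, `truth`
#' @export
simulate_zw_reference <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cl <- config$chromosomes
  if (!config$zw_chrom %in% names(cl)) stop("zw_chrom not in chromosomes")
  sdr <- gi(config$zw_chrom, config$sdr[["start"]], config$sdr[["end"]])
  if (sdr$end > cl[[config$zw_chrom]]) stop("SDR outside ZW chromosome")
  if (nrow(config$inversions) &&
      any(config$inversions$w_start < sdr$start |
            config$inversions$w_end > sdr$end))
    stop("inversion truth intervals must lie inside the SDR")
  seg <- rbind(
    if (nrow(config$w_specific))
      data.frame(type = "W_specific", config$w_specific),
    if (nrow(config$male_elevated))
      data.frame(type = "male_elevated", config$male_elevated))
  if (is.null(seg))
    seg <- data.frame(type = character(), start = numeric(), end = numeric())
  seg <- seg[order(seg$start), , drop = FALSE]
  check_intervals_inside(seg[, c("start", "end")], sdr$start, sdr$end,
                         "coverage segment")
  check_intervals_inside(
    config$inversions[order(config$inversions$w_start),
                      c("w_start", "w_end")],
    sdr$start, sdr$end, "inversion")
  if (nrow(config$sweeps)) {
    sw <- config$sweeps
    if (any(sw$factor < 1)) stop("sweep reduction factor must be >= 1")
    sw$start <- sw$center - sw$half_width
    sw$end <- sw$center + sw$half_width
    for (ch in unique(sw$chrom)) {
      if (!ch %in% names(config$pop_chromosomes))
        stop("sweep chromosome absent from pop_chromosomes")
      check_intervals_inside(sw[sw$chrom == ch, c("start", "end")],
                             1, config$pop_chromosomes[[ch]], "sweep")
    }
  } else sw <- config$sweeps
  seg$chrom <- rep(config$zw_chrom, nrow(seg))
  truth <- list(
    seed = config$seed,
    zw_chrom = config$zw_chrom,
    sdr = list(chrom = sdr$chrom, start = sdr$start, end = sdr$end),
    w_specific = config$w_specific,
    male_elevated = config$male_elevated,
    inversions = config$inversions,
    sweeps = if (nrow(sw)) sw[, c("chrom", "start", "end", "center",
                                  "factor")] else sw)
  structure(list(config = config, chromosomes = cl,
                 zw_chrom = config$zw_chrom, sdr = sdr, segments = seg,
                 inversions = config$inversions,
                 collinear_blocks = config$collinear_blocks,
                 sweeps = sw, truth = truth),
            class = "zw_layout")
}

#' Write / read a truth set as JSON
#' @param layout a `zw_layout`
#' @param path output path
#' @return `path` invisibly
#' @export
write_truth <- function(layout, path) {
  jsonlite::write_json(layout$truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

#' Simulate pooled female and male coverage tracks
#'
#' Per-window depths are Poisson: the male pool has mean 0 on W-specific
#' truth segments and twice its base mean on male-elevated (Z-analogue)
#' segments; the female pool has its base mean everywhere. Window membership
#' is decided by the window midpoint.
#'
#' @param layout a `zw_layout`
#' @param config its [sim_config()] (defaults to `layout$config`)
#' @return list with `female` and `male` coverage tracks
#' @export
simulate_pooled_coverage <- function(layout, config = layout$config) {
  stopifnot(inherits(layout, "zw_layout"))
  w <- config$cov_window
  if (any(w > layout$chromosomes)) stop("window size exceeds a chromosome")
  windows <- make_windows(layout$chromosomes, window = w, step = w)
  mid <- (windows$start + windows$end) / 2
  seg <- layout$segments
  lam_m <- rep(config$lambda_m, nrow(windows))
  on_zw <- windows$chrom == layout$zw_chrom
  for (i in seq_len(nrow(seg))) {
    inside <- on_zw & mid >= seg$start[i] & mid <= seg$end[i]
    lam_m[inside] <- if (seg$type[i] == "W_specific") 0 else
      2 * config$lambda_m
  }
  with_seed(config$seed + 1L, {
    fd <- stats::rpois(nrow(windows), config$lambda_f)
    md <- stats::rpois(nrow(windows), lam_m)
  })
  list(female = data.frame(chrom = windows$chrom, start = windows$start,
                           end = windows$end, depth = as.numeric(fd)),
       male = data.frame(chrom = windows$chrom, start = windows$start,
                         end = windows$end, depth = as.numeric(md)))
}

# draw a derived-allele count from the neutral spectrum (weight 1/i) and
# scatter exactly that many alt alleles over the 2N allele slots
#' @noRd
plant_site_dosages <- function(n_alleles, count) {
  slots <- sample.int(n_alleles, count)
  ind <- (slots + 1L) %/% 2L
  tabulate(ind, nbins = n_alleles %/% 2L)
}

#' @noRd
draw_spectrum_counts <- function(n_sites, n_alleles) {
  i <- seq_len(n_alleles - 1)
  sample(i, n_sites, replace = TRUE, prob = 1 / i)
}

#' @noRd
random_bases <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

#' Simulate the sexed resequencing panel
#'
#' Background sites segregate independently of sex with allele counts drawn
#' from the neutral folded spectrum (planted exactly, so the realised SFS
#' matches the model). Inside the SDR, sex-linked sites are heterozygous in
#' every female and absent from every male, emulating fully penetrant Z/W
#' divergent sites.
#'
#' @param layout a `zw_layout`
#' @param config its [sim_config()]
#' @return a [geno_matrix()]; attribute `sexlinked` marks the planted sites
#' @export
simulate_sex_panel <- function(layout, config = layout$config) {
  nf <- config$n_females; nm <- config$n_males
  if (nf < 1 || nm < 1) stop("need at least one sample of each sex")
  n_samp <- nf + nm
  n_all <- 2L * n_samp
  with_seed(config$seed + 2L, {
    sites <- list(); dos <- list(); linked <- list(); k <- 0L
    for (ch in names(layout$chromosomes)) {
      len <- layout$chromosomes[[ch]]
      n_bg <- stats::rpois(1, config$bg_snp_per_bp * len)
      pos <- sort(sample.int(len, n_bg))
      cnt <- draw_spectrum_counts(n_bg, n_all)
      for (j in seq_len(n_bg)) {
        k <- k + 1L
        dos[[k]] <- plant_site_dosages(n_all, cnt[j])
        sites[[k]] <- c(ch, pos[j])
        linked[[k]] <- FALSE
      }
      if (ch == layout$zw_chrom) {
        sdr <- layout$sdr
        span <- sdr$end - sdr$start + 1
        n_sl <- stats::rpois(1, config$sdr_snp_per_bp * span)
        slpos <- sort(sample.int(span, n_sl)) + sdr$start - 1
        for (p in slpos) {
          k <- k + 1L
          dos[[k]] <- c(rep(1L, nf), rep(0L, nm))
          sites[[k]] <- c(ch, p)
          linked[[k]] <- TRUE
        }
      }
    }
    geno <- do.call(cbind, dos)
    chrom <- vapply(sites, `[`, character(1), 1)
    pos <- as.numeric(vapply(sites, `[`, character(1), 2))
    o <- order(match(chrom, names(layout$chromosomes)), pos)
    geno <- geno[, o, drop = FALSE]
    site_df <- data.frame(chrom = chrom[o], pos = pos[o],
                          ref = random_bases(k), alt = random_bases(k),
                          dp = pmax(2, stats::rpois(k, 20)),
                          qual = round(stats::runif(k, 30, 90), 1))
    is_linked <- unlist(linked)[o]
  })
  samples <- data.frame(
    id = c(sprintf("F%02d", seq_len(nf)), sprintf("M%02d", seq_len(nm))),
    sex = c(rep("F", nf), rep("M", nm)), subgroup = "other")
  gm <- geno_matrix(geno, site_df, samples)
  attr(gm, "sexlinked") <- is_linked
  gm
}

# expected per-site heterozygosity of the neutral folded spectrum with 1/i
# weights: sum_i (1/i) 2i(n-i)/(n(n-1)) / a_n = 1/a_n
#' @noRd
spectrum_het <- function(n_alleles) 1 / sum(1 / seq_len(n_alleles - 1))

#' Simulate the wild + cultivar population panel
#'
#' Site allele counts are drawn from the neutral folded spectrum and planted
#' exactly across the pooled panel (subgroup frequencies are then
#' hypergeometric, so subgroups are undifferentiated). Inside each planted
#' sweep, the affected cultivar subgroups lose diversity: the core around
#' the sweep centre is monomorphic, and flanking sites are either silenced
#' or carry one of two side-specific latent haplotypes (left and right of
#' the centre) with a small per-individual flip rate, producing the high
#' within-flank / low cross-flank LD signature of a completed sweep. The
#' retained-site fraction is calibrated so that a `pi_window` window centred
#' on the sweep has `pi_C = pi_W / factor` in expectation.
#'
#' @param layout a `zw_layout`
#' @param config its [sim_config()]
#' @return a [geno_matrix()] over the population chromosomes
#' @export
simulate_population_panel <- function(layout, config = layout$config) {
  sizes <- config$subgroup_sizes
  if (any(sizes < 4)) stop("subgroup sizes must be >= 4")
  if (nrow(layout$sweeps) && any(layout$sweeps$factor < 1))
    stop("sweep reduction factor must be >= 1")
  n_samp <- sum(sizes)
  n_all <- 2L * n_samp
  subgroup <- rep(names(sizes), sizes)
  ids <- sprintf("P%03d", seq_len(n_samp))
  a_n <- sum(1 / seq_len(n_all - 1))
  h_neu <- spectrum_het(n_all)
  h_lat <- 2 * config$latent_q * (1 - config$latent_q)
  with_seed(config$seed + 3L, {
    chrom_list <- list(); pos_list <- list(); geno_list <- list()
    for (ch in names(config$pop_chromosomes)) {
      len <- config$pop_chromosomes[[ch]]
      n_sites <- stats::rpois(1, config$theta * a_n * len)
      pos <- sort(sample.int(len, n_sites))
      cnt <- draw_spectrum_counts(n_sites, n_all)
      g <- matrix(0L, n_samp, n_sites)
      for (j in seq_len(n_sites)) g[, j] <- plant_site_dosages(n_all, cnt[j])
      # plant sweeps
      sw <- layout$sweeps
      sw <- sw[sw$chrom == ch, , drop = FALSE]
      for (si in seq_len(nrow(sw))) {
        f <- sw$factor[si]
        if (f <= 1) next
        ctr <- sw$center[si]; hw <- sw$half_width[si]
        chw <- sw$core_half_width[si]
        wnd <- config$pi_window
        keep_p <- min(1, (wnd / (wnd - 2 * chw)) * h_neu / (f * h_lat))
        in_sweep <- which(pos >= ctr - hw & pos <= ctr + hw)
        tile_w <- config$latent_tile
        for (grp in config$sweep_subgroups) {
          rows <- which(subgroup == grp)
          m <- length(rows)
          # one latent haplotype-dosage vector per flank tile; tiles never
          # span the sweep centre, so cross-centre LD stays at background
          tiles <- new.env(parent = emptyenv())
          tile_latent <- function(p_j) {
            side <- if (p_j < ctr) "L" else "R"
            key <- paste0(side, floor(abs(p_j - ctr) / tile_w))
            if (is.null(tiles[[key]]))
              tiles[[key]] <- stats::rbinom(m, 2, config$latent_q)
            tiles[[key]]
          }
          for (j in in_sweep) {
            p_j <- pos[j]
            if (abs(p_j - ctr) <= chw) { g[rows, j] <- 0L; next }
            if (stats::runif(1) > keep_p) { g[rows, j] <- 0L; next }
            lat <- tile_latent(p_j)
            flip <- stats::runif(m) < config$flip_prob
            val <- lat
            if (any(flip))
              val[flip] <- stats::rbinom(sum(flip), 2, config$latent_q)
            g[rows, j] <- val
          }
        }
      }
      chrom_list[[ch]] <- rep(ch, n_sites)
      pos_list[[ch]] <- pos
      geno_list[[ch]] <- g
    }
    geno <- do.call(cbind, geno_list)
    k <- ncol(geno)
    site_df <- data.frame(chrom = unlist(chrom_list), pos = unlist(pos_list),
                          ref = random_bases(k), alt = random_bases(k),
                          dp = pmax(2, stats::rpois(k, 20)),
                          qual = round(stats::runif(k, 30, 90), 1))
  })
  samples <- data.frame(id = ids, sex = "unknown", subgroup = subgroup)
  geno_matrix(geno, site_df, samples)
}

#' Gene annotation for the population chromosomes
#'
#' Regularly spaced gene models used for sweep-gene overlap; the truth set of
#' sweep genes is the subset overlapping planted sweeps.
#'
#' @param layout a `zw_layout`
#' @param config its [sim_config()]
#' @return interval table with `gene_id`
#' @export
simulate_gene_annotation <- function(layout, config = layout$config) {
  rows <- lapply(names(config$pop_chromosomes), function(ch) {
    len <- config$pop_chromosomes[[ch]]
    starts <- seq(1, len - config$gene_width, by = config$gene_spacing)
    data.frame(chrom = ch, start = starts,
               end = starts + config$gene_width - 1)
  })
  out <- do.call(rbind, rows)
  out$gene_id <- sprintf("gene%04d", seq_len(nrow(out)))
  out
}

# ---- W-Z gene pair simulation -------------------------------------------

#' @noRd
ng_change_tables <- function() {
  if (!is.null(.ng_cache$changes)) return(.ng_cache$changes)
  tab <- ng_tables("exclude")
  codons <- tab$codons
  gc_map <- Biostrings::GENETIC_CODE
  aa <- unname(gc_map[codons])
  bases <- c("T", "C", "A", "G")
  syn <- vector("list", 64); nonsyn <- vector("list", 64)
  for (ci in seq_along(codons)) {
    if (tab$is_stop[ci]) next
    cod <- strsplit(codons[ci], "")[[1]]
    s <- integer(); ns <- integer()
    for (p in 1:3) for (b in setdiff(bases, cod[p])) {
      nc <- cod; nc[p] <- b
      ni <- match(paste(nc, collapse = ""), codons)
      if (aa[ni] == "*") next
      if (aa[ni] == aa[ci]) s <- c(s, ni) else ns <- c(ns, ni)
    }
    syn[[ci]] <- s; nonsyn[[ci]] <- ns
  }
  .ng_cache$changes <- list(syn = syn, nonsyn = nonsyn,
                            sense = which(!tab$is_stop),
                            syn_sites = tab$syn_sites, codons = codons)
  .ng_cache$changes
}

# apply m single-base changes of the given kind ("syn"/"nonsyn") to a codon
# index vector split at random between the two lineages
#' @noRd
plant_changes <- function(w, z, m, kind, ch) {
  opts <- ch[[kind]]
  if (m <= 0) return(list(w = w, z = z))
  for (rep_i in seq_len(m)) {
    to_w <- stats::runif(1) < 0.5
    target <- if (to_w) w else z
    wts <- lengths(opts)[target]
    if (all(wts == 0)) break
    cpos <- sample.int(length(target), 1, prob = wts)
    cands <- opts[[target[cpos]]]
    nc <- if (length(cands) == 1) cands else sample(cands, 1)
    if (to_w) w[cpos] <- nc else z[cpos] <- nc
  }
  list(w = w, z = z)
}

#' Simulate W-Z anchor gene pairs with clock-divergent CDS
#'
#' For each inversion (and collinear) block, CDS pairs are evolved so the
#' true Jukes-Cantor synonymous-site distance equals `2 * mu * T` for the
#' block's age `T`: the clock-expected number of synonymous single-base
#' changes (rounded) is planted at random synonymous positions, split at
#' random between the W and Z lineages, with the nonsynonymous change count
#' reduced to `nonsyn_factor` of the synonymous expectation (purifying
#' selection). Gene lengths vary uniformly by `+-length_jitter` around
#' `codons_per_gene`. Anchor order within inversion blocks is reversed on W
#' relative to Z.
#'
#' @param layout a `zw_layout`
#' @param config its [sim_config()]
#' @param cds generate CDS sequences (set `FALSE` for coordinate-only
#'   anchors)
#' @return list with `anchors` (anchor table with `block`, `block_type`,
#'   `age_years`), `cds` (named vector) and `truth` (per-pair planted
#'   divergence)
#' @export
simulate_wz_gene_pairs <- function(layout, config = layout$config,
                                   cds = TRUE) {
  blocks <- rbind(
    if (nrow(layout$inversions))
      data.frame(layout$inversions[, c("w_start", "w_end", "age_years",
                                       "n_pairs")],
                 type = "inverted"),
    if (nrow(layout$collinear_blocks))
      data.frame(layout$collinear_blocks[, c("w_start", "w_end", "age_years",
                                             "n_pairs")],
                 type = "collinear"))
  blocks <- blocks[order(blocks$w_start), , drop = FALSE]
  d_target <- 2 * config$mu * blocks$age_years
  if (any(d_target >= 0.74))
    stop("2*mu*T >= 0.74: Jukes-Cantor correction undefined at this age")
  ch <- ng_change_tables()
  zc <- config$z_counterpart
  z_cursor <- zc[["start"]]
  total_pairs <- sum(blocks$n_pairs)
  z_pitch <- max(1000, floor((zc[["end"]] - zc[["start"]]) / total_pairs))
  anchors <- list(); cds_out <- list(); truth <- list(); k <- 0L
  with_seed(config$seed + 4L, {
    for (bi in seq_len(nrow(blocks))) {
      np <- blocks$n_pairs[bi]
      wlo <- blocks$w_start[bi]; whi <- blocks$w_end[bi]
      w_pitch <- floor((whi - wlo) / np)
      p_raw <- 0.75 * (1 - exp(-4 / 3 * d_target[bi]))
      for (g in seq_len(np)) {
        k <- k + 1L
        L <- config$codons_per_gene
        if (config$length_jitter > 0)
          L <- round(L * stats::runif(1, 1 - config$length_jitter,
                                      1 + config$length_jitter))
        L <- max(30L, as.integer(L))
        z_start <- z_cursor; z_end <- z_cursor + min(z_pitch, 3 * L) - 1
        z_cursor <- z_cursor + z_pitch
        # W order reversed within inverted blocks
        slot <- if (blocks$type[bi] == "inverted") np - g + 1 else g
        w_start <- wlo + (slot - 1) * w_pitch
        w_end <- w_start + min(w_pitch, 3 * L) - 1
        wg <- sprintf("W_b%d_g%03d", bi, g)
        zg <- sprintf("Z_b%d_g%03d", bi, g)
        d_real <- NA_real_
        if (cds) {
          anc <- sample(ch$sense, L, replace = TRUE)
          S_anc <- sum(ch$syn_sites[anc])
          N_anc <- 3 * L - S_anc
          m_syn <- round(p_raw * S_anc)
          m_non <- round(config$nonsyn_factor * p_raw * N_anc)
          ev <- plant_changes(anc, anc, m_syn, "syn", ch)
          ev <- plant_changes(ev$w, ev$z, m_non, "nonsyn", ch)
          cds_out[[wg]] <- paste(ch$codons[ev$w], collapse = "")
          cds_out[[zg]] <- paste(ch$codons[ev$z], collapse = "")
          d_real <- d_target[bi]
        }
        anchors[[k]] <- data.frame(
          w_gene = wg, w_chrom = layout$zw_chrom,
          w_start = w_start, w_end = w_end,
          z_gene = zg, z_chrom = layout$zw_chrom,
          z_start = z_start, z_end = z_end,
          block = bi, block_type = blocks$type[bi],
          age_years = blocks$age_years[bi], stringsAsFactors = FALSE)
        truth[[k]] <- data.frame(w_gene = wg, z_gene = zg,
                                 true_ks = d_real,
                                 age_years = blocks$age_years[bi])
      }
    }
  })
  anchors <- do.call(rbind, anchors)
  anchors <- anchors[order(anchors$w_start), , drop = FALSE]
  rownames(anchors) <- NULL
  list(anchors = anchors, cds = unlist(cds_out),
       truth = do.call(rbind, truth))
}

#' Simulate genetic-map markers
#'
#' Autosomal genetic positions grow approximately linearly with physical
#' position (`cm_per_mb` with multiplicative noise on each inter-marker
#' increment); across the SDR of the ZW chromosome the genetic position is
#' exactly constant (complete recombination suppression).
#'
#' @param layout a `zw_layout`
#' @param config its [sim_config()]
#' @return marker data.frame `map_id`, `chrom`, `pos_bp`, `pos_cm`
#' @export
simulate_genetic_map <- function(layout, config = layout$config) {
  with_seed(config$seed + 5L, {
    rows <- lapply(names(layout$chromosomes), function(chn) {
      len <- layout$chromosomes[[chn]]
      pos <- seq(config$marker_spacing, len, by = config$marker_spacing)
      base_inc <- diff(c(0, pos)) / 1e6 * config$cm_per_mb
      noise <- pmax(0, 1 + stats::rnorm(length(pos), 0, config$map_noise_sd))
      inc <- base_inc * noise
      if (chn == layout$zw_chrom) {
        in_sdr <- pos >= layout$sdr$start & pos <= layout$sdr$end
        inc[in_sdr] <- 0
      }
      data.frame(map_id = "sim_map", chrom = chn, pos_bp = pos,
                 pos_cm = cumsum(inc))
    })
    out <- do.call(rbind, rows)
  })
  rownames(out) <- NULL
  out
}
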