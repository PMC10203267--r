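# End-to-end orchestration of the three analyses with one parameter list,
# seeded determinism and a run report whose numbers are all re-derivable from
# the returned tables.

#' Default pipeline parameters
#'
#' Window and cutoff defaults follow the published protocol where stated
#' (50-kb/10-kb diversity windows, 20-kb Fst windows for the sex scan, 20-kb
#' omega grid, top 5% outliers with 4-kb flanks, top-1% Fst,
#' mu = 7.5e-10/site/year) and the package's documented defaults elsewhere
#' (coverage window 10 kb, ratio margin 0.05, min divergent run 20 windows,
#' 1-Mb run-merging gap, association cutoff 6 for the allelic chi-square
#' test, pi-ratio/omega effect floors 2 and 5).
#'
#' @return named list of parameters
#' @export
pipeline_defaults <- function() {
  list(cov_window = 10000, min_total = 10, delta = 0.12,
       min_run = 20, max_gap = 1e6, edge_delta = 0.25,
       assoc_cut = 6, fst_top = 0.01, fst_window = 20000,
       fem_frac = 0.9, fem_max_male = 0, fem_min_snps = 10,
       fem_max_gap = 1e5,
       dp_min = 2, dp_max = 40, q_min = 20, max_missing = 0.20,
       maf_min = 0.05,
       pi_window = 50000, pi_step = 10000, grid_size = 20000,
       top_q = 0.05, flank = 4000, ratio_floor = 2, omega_floor = 5,
       max_snps_side = 25,
       mu = 7.5e-10, min_block_anchors = 3, max_rank_gap = 2)
}

#' @noRd
resolve_params <- function(params) merge_params(pipeline_defaults(), params)

#' Run the SDR discovery pipeline
#'
#' Coverage windows -> ratio classification -> SDR call -> SNP evidence
#' (allelic sex association, windowed sex Fst, female-specific SNP blocks)
#' -> evidence integration. Deterministic given its inputs.
#'
#' @param female_cov,male_cov pooled coverage tracks (data.frame or bedGraph
#'   path)
#' @param panel sexed variant panel ([geno_matrix()] or VCF path)
#' @param labels sample-label table (needed when `panel` is a path)
#' @param markers optional genetic-map markers (data.frame or TSV path)
#' @param params overrides of [pipeline_defaults()]
#' @return list with `sdr` (the annotated `sdr_call`), `assoc`, `fst`,
#'   `fem`, `recomb` and `report`
#' @export
run_sdr_pipeline <- function(female_cov, male_cov, panel, labels = NULL,
                             markers = NULL, params = list()) {
  p <- resolve_params(params)
  if (is.character(female_cov)) female_cov <- read_bedgraph(female_cov)
  if (is.character(male_cov)) male_cov <- read_bedgraph(male_cov)
  if (is.character(panel)) panel <- read_vcf(panel, labels)
  if (is.character(markers)) markers <- read_map(markers)
  if (nrow(female_cov) == 0 || nrow(male_cov) == 0)
    stop("empty coverage track")
  cw <- coverage_windows(female_cov, male_cov, window = p$cov_window,
                         min_total = p$min_total)
  cw <- classify_windows(cw, delta = p$delta)
  sdr <- call_sdr(cw, min_run = p$min_run, max_gap = p$max_gap,
                  edge_delta = p$edge_delta)
  chrom_lengths <- tapply(cw$end, cw$chrom, max)
  windows20 <- make_windows(chrom_lengths[unique(cw$chrom)],
                            window = p$fst_window, step = p$fst_window)
  assoc <- sex_association(panel)
  fst <- fst_weir_cockerham(panel, "F", "M", windows20, by = "sex")
  fem <- female_specific_snps(panel, min_female_carrier_frac = p$fem_frac,
                              max_male_carriers = p$fem_max_male,
                              min_snps = p$fem_min_snps,
                              max_gap = p$fem_max_gap)
  sdr <- integrate_evidence(sdr, assoc, fst, fem$blocks,
                            assoc_cut = p$assoc_cut, fst_top = p$fst_top)
  recomb <- if (!is.null(markers))
    detect_recomb_suppressed_chromosome(markers) else NULL
  report <- list(
    params = p,
    n_windows = nrow(cw),
    class_counts = as.list(table(cw$class)),
    n_sites = ncol(panel$geno),
    sdr_chrom = sdr$chrom,
    sdr_interval = if (!is.null(sdr$interval))
      as.list(sdr$interval[1, c("chrom", "start", "end")]) else NULL,
    sdr_span_mb = if (!is.null(sdr$interval))
      round_half_up((sdr$interval$end - sdr$interval$start) / 1e6, 2) else NA,
    support = sdr$support,
    fst_cutoff = sdr$evidence$fst_cutoff,
    assoc_cut = p$assoc_cut,
    recomb_top = if (!is.null(recomb) && nrow(recomb)) recomb$chrom[1] else NA)
  list(sdr = sdr, cw = cw, assoc = assoc, fst = fst, fem = fem,
       recomb = recomb, report = report)
}

#' Run the strata dating pipeline
#'
#' Anchor chaining -> inversion detection -> per-pair Nei-Gojobori Ka/Ks ->
#' molecular-clock dating -> stratum assignment, plus a Ks-vs-Z-position
#' table for plotting.
#'
#' @param anchors anchor table (data.frame or TSV path)
#' @param cds named CDS vector (or FASTA path) covering every anchored gene
#' @param params overrides of [pipeline_defaults()]
#' @return list with `blocks`, `inversions`, `kaks`, `strata`, `ks_track`
#'   and `report`
#' @export
run_strata_pipeline <- function(anchors, cds, params = list()) {
  p <- resolve_params(params)
  if (is.character(anchors)) anchors <- read_anchors(anchors)
  if (is.character(cds) && length(cds) == 1 && is.null(names(cds)))
    cds <- read_fasta(cds)
  if (nrow(anchors) == 0) stop("no anchor pairs supplied")
  blocks <- build_collinear_blocks(anchors,
                                   min_block_anchors = p$min_block_anchors,
                                   max_rank_gap = p$max_rank_gap)
  inv <- detect_inversions(blocks)
  assignment <- attr(blocks, "assignment")
  used <- attr(blocks, "anchors")
  kaks <- kaks_table(used, cds)
  kaks$block <- assignment
  kaks$t_years <- date_divergence(kaks$Ksil, mu = p$mu)
  strata <- assign_strata(inv$inversions, kaks[!is.na(kaks$block), ])
  ks_track <- kaks[order(kaks$z_start),
                   c("z_gene", "z_start", "Ks", "Ka", "block")]
  report <- list(params = p, n_anchors = nrow(used),
                 n_blocks = nrow(blocks),
                 n_inversions = nrow(inv$inversions),
                 inversion_anchors = inv$total_anchors,
                 strata_ages_mya = strata$median_t_mya)
  list(blocks = blocks, inversions = inv, kaks = kaks, strata = strata,
       ks_track = ks_track, report = report)
}

#' Run the sweep-scan pipeline for one or more cultivar subgroups
#'
#' Variant filtering -> per-group windowed pi -> wild/cultivar ratio ->
#' omega -> top-percentile outliers with flanks and effect floors ->
#' intersect-and-merge -> gene overlap, with a cross-tabulation of sweep
#' genes shared between subgroups.
#'
#' @param panel population panel ([geno_matrix()] or VCF path)
#' @param labels sample labels (needed when `panel` is a path)
#' @param wild wild subgroup label
#' @param cultivars character vector of cultivar subgroup labels
#' @param chrom_lengths named chromosome lengths; defaults to the span of
#'   the panel's sites
#' @param genes optional gene interval table (or GFF3 path)
#' @param filter apply [filter_variants()] first (default TRUE)
#' @param params overrides of [pipeline_defaults()]
#' @return list with per-subgroup `scans`, `shared_genes` cross-tab and
#'   `report`
#' @export
run_sweep_pipeline <- function(panel, labels = NULL, wild = "wild",
                               cultivars = c("Cultivar_I", "Cultivar_II",
                                             "Cultivar_III"),
                               chrom_lengths = NULL, genes = NULL,
                               filter = TRUE, params = list()) {
  p <- resolve_params(params)
  if (is.character(panel)) panel <- read_vcf(panel, labels)
  if (is.character(genes)) genes <- read_gff_genes(genes)
  have <- unique(panel$samples$subgroup)
  missing <- setdiff(c(wild, cultivars), have)
  if (length(missing))
    stop("subgroup(s) absent from labels: ", paste(missing, collapse = ", "))
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(panel$sites$pos, panel$sites$chrom, max)
    chrom_lengths <- chrom_lengths[unique(panel$sites$chrom)]
  }
  if (filter)
    panel <- filter_variants(panel, dp_min = p$dp_min, dp_max = p$dp_max,
                             q_min = p$q_min, max_missing = p$max_missing,
                             maf_min = p$maf_min)
  scans <- lapply(cultivars, function(cv)
    scan_sweeps(panel, wild = wild, cultivar = cv,
                chrom_lengths = chrom_lengths,
                window = p$pi_window, step = p$pi_step,
                grid_size = p$grid_size, top_q = p$top_q, flank = p$flank,
                ratio_floor = p$ratio_floor, omega_floor = p$omega_floor,
                max_snps_side = p$max_snps_side, genes = genes))
  names(scans) <- cultivars
  gene_sets <- lapply(scans, function(s)
    attr(s$regions, "all_genes") %||% character())
  combos <- list()
  if (length(cultivars) > 1) {
    for (i in seq_along(cultivars)) for (j in seq_along(cultivars)) {
      if (i < j)
        combos[[paste(cultivars[i], cultivars[j], sep = "&")]] <-
          length(intersect(gene_sets[[i]], gene_sets[[j]]))
    }
    if (length(cultivars) >= 3)
      combos[["all"]] <- length(Reduce(intersect, gene_sets))
  }
  report <- list(params = p,
                 n_sites = ncol(panel$geno),
                 n_regions = vapply(scans, function(s) nrow(s$regions),
                                    integer(1)),
                 mean_region_kb = vapply(scans, function(s)
                   if (nrow(s$regions))
                     mean(s$regions$end - s$regions$start + 1) / 1000
                   else NA_real_, numeric(1)),
                 n_genes = vapply(gene_sets, length, integer(1)),
                 shared_genes = combos)
  list(scans = scans, gene_sets = gene_sets, shared_genes = combos,
       report = report)
}
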