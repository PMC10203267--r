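# The generators: determinism, truth-set structure, and the statistical
# properties each downstream detector relies on.

small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed,
             chromosomes = c(Chr14 = 6e6, Chr01 = 2e6),
             sdr = c(start = 2e6, end = 4e6),
             inversions = data.frame(w_start = c(3e6, 2.4e6),
                                     w_end = c(3.8e6, 2.9e6),
                                     age_years = c(8e6, 3e6),
                                     n_pairs = c(12L, 10L)),
             z_counterpart = c(start = 4.5e6, end = 5.5e6),
             collinear_blocks = data.frame(w_start = 2e6, w_end = 2.3e6,
                                           age_years = 3e5, n_pairs = 6L),
             w_specific = data.frame(start = c(2e6, 3.2e6),
                                     end = c(2.6e6, 4e6)),
             male_elevated = data.frame(start = 2.8e6, end = 3.1e6),
             pop_chromosomes = c(Chr01 = 6e5),
             sweeps = data.frame(chrom = "Chr01", center = 3e5,
                                 half_width = 30000,
                                 core_half_width = 10000, factor = 5),
             subgroup_sizes = c(wild = 8L, Cultivar_I = 4L,
                                Cultivar_II = 4L, Cultivar_III = 10L),
             codons_per_gene = 300L,
             ...)
}

test_that("layout validation and truth sets are deterministic", {
  cfg <- small_cfg(seed = 5)
  lay1 <- simulate_zw_reference(cfg)
  lay2 <- simulate_zw_reference(small_cfg(seed = 5))
  t1 <- withr::local_tempfile(fileext = ".json")
  t2 <- withr::local_tempfile(fileext = ".json")
  write_truth(lay1, t1); write_truth(lay2, t2)
  expect_identical(readLines(t1), readLines(t2))  # byte-identical truth
  expect_equal(nrow(lay1$truth$inversions), 2)    # as many as configured

  # default config carries the 12.70-Mb SDR on a 55-Mb chromosome
  layd <- simulate_zw_reference(sim_config())
  expect_equal(interval_report(layd$sdr)$length_mb, 12.70)
  expect_equal(layd$zw_chrom, "Chr14")

  # overlapping truth intervals are rejected
  expect_error(simulate_zw_reference(small_cfg(
    w_specific = data.frame(start = c(2e6, 2.5e6), end = c(2.6e6, 3e6)))),
    "overlapping")
})

test_that("pooled coverage drops male depth on W-specific truth segments", {
  cfg <- small_cfg(seed = 3)
  lay <- simulate_zw_reference(cfg)
  cov1 <- simulate_pooled_coverage(lay)
  cov2 <- simulate_pooled_coverage(simulate_zw_reference(small_cfg(seed = 3)))
  expect_identical(cov1, cov2)                    # seeded determinism

  m <- cov1$male
  mid <- (m$start + m$end) / 2
  w_seg <- lay$segments[lay$segments$type == "W_specific", ]
  in_w <- m$chrom == "Chr14" &
    Reduce(`|`, lapply(seq_len(nrow(w_seg)), function(i)
      mid >= w_seg$start[i] & mid <= w_seg$end[i]))
  expect_lt(mean(m$depth[in_w]), 0.5)             # Poisson(0) dropout

  # autosomal female depth obeys the CLT bound around lambda_F
  f <- cov1$female
  auto <- f$depth[f$chrom == "Chr01"]
  expect_lt(abs(mean(auto) - cfg$lambda_f),
            3 * sqrt(cfg$lambda_f / length(auto)))

  # male-elevated truth segments double the male mean
  in_me <- m$chrom == "Chr14" & mid >= 2.8e6 & mid <= 3.1e6
  expect_gt(mean(m$depth[in_me]), 1.7 * cfg$lambda_m)

  expect_error(simulate_pooled_coverage(lay, modifyList(cfg, list(
    cov_window = 1e7))), "exceeds")
})

test_that("sex panel plants fully penetrant W-linked sites inside the SDR", {
  cfg <- small_cfg(seed = 11)
  lay <- simulate_zw_reference(cfg)
  gm <- simulate_sex_panel(lay)
  gm2 <- simulate_sex_panel(simulate_zw_reference(small_cfg(seed = 11)))
  expect_identical(gm$geno, gm2$geno)             # seeded determinism

  linked <- attr(gm, "sexlinked")
  is_f <- gm$samples$sex == "F"
  lg <- gm$geno[, linked, drop = FALSE]
  expect_true(all(lg[is_f, ] == 1L))              # every female het
  expect_true(all(lg[!is_f, ] == 0L))             # absent from every male
  expect_true(all(gm$sites$pos[linked] >= lay$sdr$start &
                    gm$sites$pos[linked] <= lay$sdr$end))

  # autosomal sites segregate independently of sex: chi-square p-values
  # are null-distributed (~5% below 0.05)
  bg <- which(!linked & gm$sites$chrom == "Chr01")
  a <- sex_association(gm_subset(gm, sites = bg))
  frac <- mean(10^(-a$neg_log10_p) < 0.05)
  expect_lt(abs(frac - 0.05), 0.03)

  expect_error(simulate_sex_panel(lay, modifyList(cfg, list(n_males = 0L))),
               "each sex")
})

test_that("population panel calibrates the planted diversity reduction", {
  # reduction factor 5, theta = 0.01: realized pi_C ~ pi_W / 5 within 25%
  cfg <- sim_config(seed = 21, theta = 0.01,
                    pop_chromosomes = c(Chr01 = 1e6),
                    sweeps = data.frame(chrom = "Chr01", center = 5e5,
                                        half_width = 30000,
                                        core_half_width = 10000, factor = 5),
                    subgroup_sizes = c(wild = 20L, Cultivar_I = 4L,
                                       Cultivar_II = 4L, Cultivar_III = 40L))
  lay <- simulate_zw_reference(cfg)
  gm <- simulate_population_panel(lay)
  w <- make_windows(cfg$pop_chromosomes, 50000, 10000)
  rr <- pi_ratio_windows(
    nucleotide_diversity(gm, w, subgroup = "wild"),
    nucleotide_diversity(gm, w, subgroup = "Cultivar_III"))
  inside <- rr$start >= 5e5 - 30000 & rr$end <= 5e5 + 30000
  expect_lt(abs(mean(rr$value[inside]) - 5) / 5, 0.25)

  # factor 1 everywhere: genome-wide ratio stays near 1
  cfg1 <- small_cfg(seed = 22,
                    sweeps = data.frame(chrom = "Chr01", center = 3e5,
                                        half_width = 30000,
                                        core_half_width = 10000, factor = 1))
  gm1 <- simulate_population_panel(simulate_zw_reference(cfg1))
  w1 <- make_windows(cfg1$pop_chromosomes, 50000, 10000)
  rr1 <- pi_ratio_windows(
    nucleotide_diversity(gm1, w1, subgroup = "wild"),
    nucleotide_diversity(gm1, w1, subgroup = "Cultivar_III"))
  expect_gt(median(rr1$value), 0.8)
  expect_lt(median(rr1$value), 1.25)

  # determinism and the factor < 1 guard
  gma <- simulate_population_panel(simulate_zw_reference(small_cfg(seed = 2)))
  gmb <- simulate_population_panel(simulate_zw_reference(small_cfg(seed = 2)))
  expect_identical(gma$geno, gmb$geno)
  expect_error(simulate_zw_reference(small_cfg(
    sweeps = data.frame(chrom = "Chr01", center = 3e5, half_width = 3e4,
                        core_half_width = 1e4, factor = 0.5))), "factor")
})

test_that("W-Z gene pairs carry the planted clock divergence", {
  cfg <- small_cfg(seed = 31)
  lay <- simulate_zw_reference(cfg)

  # age 0 -> identical CDS
  cfg0 <- small_cfg(seed = 31,
                    inversions = data.frame(w_start = 3e6, w_end = 3.8e6,
                                            age_years = 0, n_pairs = 5L),
                    collinear_blocks = data.frame(w_start = numeric(),
                                                  w_end = numeric(),
                                                  age_years = numeric(),
                                                  n_pairs = integer()))
  pr0 <- simulate_wz_gene_pairs(simulate_zw_reference(cfg0), cfg0)
  kk0 <- kaks_table(pr0$anchors, pr0$cds)
  expect_true(all(kk0$Ks == 0))

  # T = 10 Mya at mu = 7.5e-10: mean realized Ks ~ 0.015 within 5%
  cfg10 <- sim_config(seed = 32,
                      inversions = data.frame(w_start = 41e6, w_end = 52e6,
                                              age_years = 1e7,
                                              n_pairs = 200L),
                      collinear_blocks = data.frame(w_start = numeric(),
                                                    w_end = numeric(),
                                                    age_years = numeric(),
                                                    n_pairs = integer()))
  pr10 <- simulate_wz_gene_pairs(simulate_zw_reference(cfg10), cfg10)
  kk10 <- kaks_table(pr10$anchors, pr10$cds)
  expect_lt(abs(mean(kk10$Ks) - 0.015) / 0.015, 0.05)
  # purifying selection keeps Ka well below Ks
  expect_lt(mean(kk10$Ka), 0.2 * mean(kk10$Ks))

  # saturation guard
  cfg_sat <- small_cfg(inversions = data.frame(
    w_start = 3e6, w_end = 3.8e6, age_years = 6e8, n_pairs = 3L))
  expect_error(simulate_wz_gene_pairs(simulate_zw_reference(cfg_sat),
                                      cfg_sat), "0.74")
})

test_that("genetic maps are linear on autosomes and flat across the SDR", {
  cfg <- small_cfg(seed = 41)
  lay <- simulate_zw_reference(cfg)
  mk <- simulate_genetic_map(lay)
  mk2 <- simulate_genetic_map(simulate_zw_reference(small_cfg(seed = 41)))
  expect_identical(mk, mk2)

  auto <- mk[mk$chrom == "Chr01", ]
  expect_gt(stats::cor(auto$pos_bp, auto$pos_cm, method = "spearman"), 0.99)

  zw <- mk[mk$chrom == "Chr14", ]
  in_sdr <- zw$pos_bp >= lay$sdr$start & zw$pos_bp <= lay$sdr$end
  expect_equal(diff(range(zw$pos_cm[in_sdr])), 0)  # exact plateau
})
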