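# Windowed population statistics against hand-computed values and
# independently coded oracles.

test_that("variant filtering applies the four hard rules exactly", {
  # 10 sites; four distinct single-rule failures
  dos <- matrix(1L, nrow = 10, ncol = 10)
  dos[, 1] <- c(2L, rep(0L, 9))          # MAF 0.1 fine
  dos[6:10, ] <- 0L
  dp <- rep(20, 10); dp[1] <- 1          # DP too low
  dp[2] <- 41                            # DP too high
  qual <- rep(50, 10); qual[3] <- 10     # quality fail
  dos[1:3, 4] <- NA                      # 30% missing
  dos[, 5] <- c(1L, rep(0L, 9))          # MAF 0.05 exactly -> retained
  gm <- toy_gm(dos, dp = dp, qual = qual)
  kept <- filter_variants(gm)
  expect_equal(ncol(kept$geno), 6L)
  expect_true(500 %in% kept$sites$pos)   # the MAF==0.05 site (pos 5*100)

  # idempotence and identity on clean input
  again <- filter_variants(kept)
  expect_equal(again$sites$pos, kept$sites$pos)
  clean <- toy_gm(dos[, 5:10], dp = rep(20, 6), qual = rep(50, 6))
  expect_equal(ncol(filter_variants(clean)$geno), 6L)
  expect_error(filter_variants(gm_subset(gm, sites = integer(0))), "empty")
})

test_that("windowed pi matches hand values and the allele-pair oracle", {
  # single site, allele counts 2/2 among n = 4 alleles
  gm <- toy_gm(matrix(c(2L, 0L), 2, 1), pos = 50)
  w <- data.frame(chrom = "Chr1", start = 1, end = 100)
  expect_equal(nucleotide_diversity(gm, w)$value * 100, 2 / 3,
               tolerance = 1e-12)

  # monomorphic window
  gm0 <- toy_gm(matrix(0L, 4, 3))
  expect_equal(nucleotide_diversity(gm0, w)$value, 0)

  # two haplotypes differing at 3 of 1000 sites: one diploid individual het
  # at exactly those sites -> pi = 3/1000
  gm2 <- toy_gm(matrix(1L, 1, 3), pos = c(10, 20, 30))
  w2 <- data.frame(chrom = "Chr1", start = 1, end = 1000)
  expect_equal(nucleotide_diversity(gm2, w2)$value, 0.003, tolerance = 1e-12)

  # brute-force oracle equivalence on random toys
  set.seed(11)
  for (i in 1:10) {
    dos <- matrix(sample(c(0:2, NA), 8 * 12, TRUE, prob = c(4, 2, 2, 1)),
                  8, 12)
    gm3 <- toy_gm(dos, pos = sample.int(5000, 12))
    w3 <- data.frame(chrom = "Chr1", start = 1, end = 5000)
    expect_equal(nucleotide_diversity(gm3, w3)$value * 5000,
                 oracle_pi_sum(dos), tolerance = 1e-12)
  }
})

test_that("Tajima's D matches hand constants and the formula oracle", {
  # n = 4 alleles, S = 1, allele counts 2/2 -> D = 1.63
  gm <- toy_gm(matrix(c(2L, 0L), 2, 1), pos = 50)
  w <- data.frame(chrom = "Chr1", start = 1, end = 100)
  d <- tajimas_d(gm, w)$value
  expect_equal(round(d, 2), 1.63)
  cst <- zwscan:::tajima_constants(4)
  expect_equal(round(cst$a1, 4), 1.8333)
  expect_equal(round(cst$e1, 6), 0.005510)

  # no segregating sites -> NA, not 0
  expect_true(is.na(tajimas_d(toy_gm(matrix(0L, 4, 2)), w)$value))

  # all singletons at large S -> negative D
  dos <- matrix(0L, 10, 40)
  for (j in 1:40) dos[1 + (j %% 10), j] <- 1L
  gmS <- toy_gm(dos, pos = seq_len(40))
  expect_lt(tajimas_d(gmS, w)$value, 0)

  # oracle equivalence on 50 random toys
  set.seed(99)
  for (i in 1:50) {
    ns <- sample(3:10, 1); S <- sample(1:25, 1)
    dos <- matrix(sample(0:2, ns * S, TRUE), ns, S)
    gmr <- toy_gm(dos, pos = seq_len(S) * 3)
    wr <- data.frame(chrom = "Chr1", start = 1, end = 1000)
    got <- tajimas_d(gmr, wr)$value
    p <- colSums(dos) / (2 * ns)
    seg <- p > 0 & p < 1
    k <- sum((2 * p * (1 - p) * 2 * ns / (2 * ns - 1))[seg])
    want <- oracle_tajima(2 * ns, sum(seg), k)
    if (sum(seg) == 0) expect_true(is.na(got)) else
      expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("Weir-Cockerham Fst matches hand values and the equation oracle", {
  w <- data.frame(chrom = "Chr1", start = 1, end = 100)
  # fixed difference -> Fst = 1
  gm <- toy_gm(matrix(c(rep(2L, 5), rep(0L, 5)), 10, 1), pos = 50,
               subgroup = rep(c("A", "B"), each = 5))
  expect_equal(fst_weir_cockerham(gm, "A", "B", w)$value, 1)

  # identical frequencies and heterozygosity -> Fst <= 0
  dos <- matrix(rep(c(1L, 1L, 0L, 2L, 0L), 2), 10, 1)
  gm2 <- toy_gm(dos, pos = 50, subgroup = rep(c("A", "B"), each = 5))
  expect_lte(fst_weir_cockerham(gm2, "A", "B", w)$value, 0)

  # n1 = n2 = 10, p = 0.8 / 0.2, HWE het 0.32 -> a=0.17111 b=0.00889 c=0.16,
  # Fst = 0.5033 (idealised parameters, checked against the equation oracle)
  orc <- oracle_fst_params(10, 10, 0.8, 0.2, 0.32, 0.32)
  expect_equal(round(orc$a, 5), 0.17111)
  expect_equal(round(orc$b, 5), 0.00889)
  expect_equal(round(orc$c, 5), 0.16)
  expect_equal(round(orc$fst, 4), 0.5033)
  # a realisable configuration with het 0.4: implementation == oracle
  dosA <- c(rep(2L, 6), rep(1L, 4), rep(0L, 0))
  dosB <- c(rep(2L, 0), rep(1L, 4), rep(0L, 6))
  gm3 <- toy_gm(matrix(c(dosA, dosB), 20, 1), pos = 50,
                subgroup = rep(c("A", "B"), each = 10))
  got <- fst_weir_cockerham(gm3, "A", "B", w)$value
  expect_equal(got, oracle_fst_site(dosA, dosB)$fst, tolerance = 1e-12)

  # window aggregation is ratio-of-sums over per-site components
  set.seed(4)
  dos <- matrix(sample(0:2, 20 * 6, TRUE), 20, 6)
  gm4 <- toy_gm(dos, pos = 1:6 * 10, subgroup = rep(c("A", "B"), each = 10))
  got4 <- fst_weir_cockerham(gm4, "A", "B", w)$value
  comp <- lapply(1:6, function(j) oracle_fst_site(dos[1:10, j], dos[11:20, j]))
  want4 <- sum(vapply(comp, `[[`, numeric(1), "a")) /
    sum(vapply(comp, function(x) x$a + x$b + x$c, numeric(1)))
  expect_equal(got4, want4, tolerance = 1e-12)
})

test_that("folded SFS folds counts and matches the neutral spectrum", {
  # 8 alleles: alt count 3 -> class 3; alt count 6 -> class 2
  dos <- matrix(0L, 4, 2)
  dos[, 1] <- c(2L, 1L, 0L, 0L)   # alt count 3
  dos[, 2] <- c(2L, 2L, 2L, 0L)   # alt count 6 -> folded 2
  sfs <- folded_sfs(toy_gm(dos))
  expect_equal(sfs$count, c(0L, 1L, 1L, 0L))

  # monomorphic-only input -> all-zero vector
  expect_true(all(folded_sfs(toy_gm(matrix(0L, 4, 3)))$count == 0))

  # neutral simulation: GOF against 1/k + 1/(n-k)
  cfg <- sim_config(seed = 31, pop_chromosomes = c(Chr01 = 4e5),
                    sweeps = data.frame(chrom = character(),
                                        center = numeric(),
                                        half_width = numeric(),
                                        core_half_width = numeric(),
                                        factor = numeric()),
                    subgroup_sizes = c(wild = 10L, Cultivar_I = 4L,
                                       Cultivar_II = 4L, Cultivar_III = 4L))
  lay <- simulate_zw_reference(cfg)
  pan <- simulate_population_panel(lay)
  sfs <- folded_sfs(pan)
  n <- attr(sfs, "n_alleles")
  k <- sfs$k
  expected_w <- 1 / k + ifelse(k < n / 2, 1 / (n - k), 0)
  # collapse the sparse tail so chi-square expected counts stay reasonable
  grp <- pmin(sfs$k, 8)
  obs <- tapply(sfs$count, grp, sum)
  expw <- tapply(expected_w, grp, sum)
  gof <- suppressWarnings(stats::chisq.test(obs, p = expw / sum(expw)))
  expect_gt(gof$p.value, 0.01)
})

test_that("genotype r2 and the LD half-decay distance behave as defined", {
  set.seed(5)
  base <- sample(0:2, 20, TRUE)
  dos <- cbind(base, base, 2L - base, sample(0:2, 20, TRUE))
  gm <- toy_gm(dos, pos = c(100, 200, 300, 400))
  r2 <- ld_r2(gm, max_dist = 500)
  dup <- r2[r2$pos1 == 100 & r2$pos2 == 200, ]
  expect_equal(dup$r2, 1)                       # duplicated site
  rep_pair <- r2[r2$pos1 == 100 & r2$pos2 == 300, ]
  expect_equal(rep_pair$r2, 1)                  # perfect repulsion |r| = 1

  # independent sites: mean r2 ~ 1/n
  set.seed(6)
  n <- 50
  dosI <- matrix(rbinom(n * 60, 2, 0.5), n, 60)
  gmI <- toy_gm(dosI, pos = seq_len(60))
  r2I <- ld_r2(gmI, max_dist = 100)
  expect_lt(abs(mean(r2I$r2) - 1 / n), 3 / n)

  # synthetic exponential decay: half distance = 10kb * ln 2 = 6.93 kb
  d <- rep(seq(50, 40000, by = 100), each = 2)
  rec <- data.frame(dist = d, r2 = exp(-d / 10000))
  expect_equal(ld_half_decay(rec, bin_width = 100), 10000 * log(2),
               tolerance = 0.02)
  # invariant to uniform scaling
  rec2 <- rec; rec2$r2 <- rec2$r2 * 0.37
  expect_equal(ld_half_decay(rec2, bin_width = 100),
               ld_half_decay(rec, bin_width = 100))
  # constant r2 never decays
  recc <- data.frame(dist = d, r2 = 0.4)
  expect_warning(out <- ld_half_decay(recc, bin_width = 100))
  expect_true(is.na(out))
})

test_that("allelic sex association matches the 2x2 chi-square", {
  # allele on one chromosome of every female, absent in males: chi2 = 29.33
  dos <- matrix(c(rep(1L, 22), rep(0L, 22)), 44, 1)
  gm <- toy_gm(dos, pos = 50, sex = rep(c("F", "M"), each = 22))
  got <- sex_association(gm)
  expect_equal(round(got$chisq, 2), 29.33)

  # swapping sex labels leaves the statistic unchanged
  gm_sw <- toy_gm(dos, pos = 50, sex = rep(c("M", "F"), each = 22))
  expect_equal(sex_association(gm_sw)$chisq, got$chisq)

  # monomorphic -> 0; balanced independent allele ~ 0
  gm0 <- toy_gm(matrix(1L, 44, 1), pos = 50,
                sex = rep(c("F", "M"), each = 22))
  expect_equal(sex_association(gm0)$chisq, 0)
})

test_that("sex association keeps its type-I error at alpha = 1e-3", {
  # null: dosages independent of sex at common frequencies
  set.seed(77)
  n_sites <- 20000
  p <- runif(n_sites, 0.1, 0.9)
  dos <- vapply(p, function(pp) rbinom(44, 2, pp), integer(44))
  gm <- toy_gm(dos, pos = seq_len(n_sites),
               sex = rep(c("F", "M"), each = 22))
  a <- sex_association(gm)
  rate <- mean(a$neg_log10_p >= 3)
  se <- sqrt(1e-3 / n_sites)
  expect_lt(abs(rate - 1e-3), 3 * se + 1e-6)
})

test_that("female-specific SNPs and blocks follow the carrier rules", {
  # planted W-linked sites: all F het, all M ref
  dos <- matrix(c(rep(1L, 22), rep(0L, 22)), 44, 12)
  gm <- toy_gm(dos, pos = seq(1e6, by = 50000, length.out = 12),
               sex = rep(c("F", "M"), each = 22))
  fem <- female_specific_snps(gm)
  expect_equal(nrow(fem$sites), 12)
  # 12 flagged sites spaced 50 kb -> one block spanning them
  expect_equal(nrow(fem$blocks), 1)
  expect_equal(fem$blocks$start, 1e6)
  expect_equal(fem$blocks$n_snps, 12)

  # neutral autosomal sites: flagged fraction < 1e-3
  set.seed(13)
  n_sites <- 5000
  p <- runif(n_sites, 0.05, 0.95)
  dosN <- vapply(p, function(pp) rbinom(44, 2, pp), integer(44))
  gmN <- toy_gm(dosN, pos = seq_len(n_sites) * 10,
                sex = rep(c("F", "M"), each = 22))
  femN <- female_specific_snps(gmN)
  expect_lt(nrow(femN$sites) / n_sites, 1e-3)
})
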