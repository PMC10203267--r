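# Collinearity chaining, reciprocal-hit gene specificity, Nei-Gojobori
# divergence and clock dating.

test_that("monotone-run chaining finds collinear and inverted blocks", {
  b1 <- build_collinear_blocks(anchors_from_ranks(1:5), min_block_anchors = 2)
  expect_equal(nrow(b1), 1)
  expect_equal(b1$orientation, "collinear")
  expect_equal(b1$n_anchors, 5L)

  b2 <- build_collinear_blocks(anchors_from_ranks(5:1), min_block_anchors = 2)
  expect_equal(b2$orientation, "inverted")
  expect_equal(b2$n_anchors, 5L)

  # [1,2,5,4,3] -> collinear {1,2}, inverted {5,4,3}
  b3 <- build_collinear_blocks(anchors_from_ranks(c(1, 2, 5, 4, 3)),
                               min_block_anchors = 2)
  expect_equal(nrow(b3), 2)
  expect_equal(b3$orientation, c("collinear", "inverted"))
  expect_equal(b3$n_anchors, c(2L, 3L))
})

test_that("chaining equals the breakpoint-splitting oracle on permutations", {
  set.seed(21)
  cases <- c(lapply(1:200, function(i) sample.int(6)),
             lapply(1:150, function(i) sample.int(8)))
  for (ranks in cases) {
    got <- build_collinear_blocks(anchors_from_ranks(ranks),
                                  min_block_anchors = 2, max_rank_gap = 2)
    want <- oracle_monotone_runs(ranks, min_anchors = 2, max_gap = 2)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      expect_equal(got$n_anchors,
                   vapply(want, function(x) length(x$idx), integer(1)))
      expect_equal(got$orientation,
                   vapply(want, `[[`, character(1), "orientation"))
    }
  }
})

test_that("inversion report totals anchors and envelopes inverted blocks", {
  lay <- simulate_zw_reference(sim_config(seed = 2))
  pr <- simulate_wz_gene_pairs(lay, cds = FALSE)
  blocks <- build_collinear_blocks(pr$anchors)
  inv <- detect_inversions(blocks)
  expect_equal(nrow(inv$inversions), 3)
  expect_equal(sort(inv$inversions$n_anchors), c(44L, 170L, 173L))
  expect_equal(inv$total_anchors, 387L)

  # collinear-only input -> empty
  coll <- build_collinear_blocks(anchors_from_ranks(1:6),
                                 min_block_anchors = 2)
  expect_equal(nrow(detect_inversions(coll)$inversions), 0)

  # single inverted pair below min_block_anchors = 3 -> not called
  mix <- build_collinear_blocks(anchors_from_ranks(c(1, 2, 3, 5, 4)),
                                min_block_anchors = 3)
  expect_equal(nrow(detect_inversions(mix)$inversions), 0)
})

test_that("specific-gene calls apply the 99% / 1000-bp reciprocal criteria", {
  hits <- function(...) {
    h <- data.frame(...)
    names(h) <- c("query", "subject", "identity", "matching_bp")
    n <- nrow(h)
    h$qstart <- rep(1, n); h$qend <- rep(1, n)
    h$sstart <- rep(1, n); h$send <- rep(1, n)
    h
  }
  w_genes <- c("w1", "w2", "w3")
  z_genes <- c("z1")
  hw <- hits(query = c("w1", "w2"), subject = "z",
             identity = c(99.5, 99.5), matching_bp = c(1200, 800))
  hz <- hits(query = character(), subject = character(),
             identity = numeric(), matching_bp = numeric())
  out <- call_specific_genes(w_genes, z_genes, hw, hz)
  expect_false("w1" %in% out$w_specific)  # passes both criteria
  expect_true("w2" %in% out$w_specific)   # length fails
  expect_true("w3" %in% out$w_specific)   # no hit at all
  expect_true("z1" %in% out$z_specific)

  # paired genes are never specific, regardless of hits
  anch <- anchors_from_ranks(1:2)
  anch$w_gene <- c("w2", "w3"); anch$z_gene <- c("zx", "zy")
  out2 <- call_specific_genes(w_genes, z_genes, hw, hz, anchors = anch)
  expect_equal(out2$w_specific, character(0))
})

test_that("Nei-Gojobori matches the hand-worked example and is symmetric", {
  s1 <- strrep("GAT", 10)
  s2 <- paste0("GAC", strrep("GAT", 9))
  ng <- nei_gojobori(s1, s2)
  expect_equal(ng$S, 10 / 3, tolerance = 1e-9)
  expect_equal(ng$Sd, 1)
  expect_equal(ng$pS, 0.30, tolerance = 1e-9)
  expect_equal(ng$Ks, -0.75 * log(0.6), tolerance = 1e-9)
  expect_equal(round(ng$Ks, 4), 0.3831)
  expect_equal(ng$Ka, 0)

  # identical sequences
  ng0 <- nei_gojobori(s1, s1)
  expect_equal(ng0$Ks, 0); expect_equal(ng0$Ka, 0)

  # symmetry and site-count closure on random pairs
  set.seed(8)
  for (i in 1:5) {
    a <- random_cds(40); b <- random_cds(40)
    f <- nei_gojobori(a, b); r <- nei_gojobori(b, a)
    expect_equal(f$Ks, r$Ks, tolerance = 1e-12)
    expect_equal(f$Ka, r$Ka, tolerance = 1e-12)
    expect_equal(f$S + f$N, 3 * 40, tolerance = 1e-9)
  }

  # malformed input
  expect_error(nei_gojobori("ACGTA", "ACGTA"), "multiple of 3")
  expect_error(nei_gojobori("TAAACG", "TAAACG"), "stop")
})

test_that("Nei-Gojobori equals the pathway-enumeration oracle", {
  set.seed(303)
  for (i in 1:100) {
    anc <- random_cds(30)
    # derive a partner with scattered single/multi-hit codons
    cods <- substring(anc, seq(1, nchar(anc), 3), seq(3, nchar(anc), 3))
    nmut <- sample(1:8, 1)
    gc_map <- Biostrings::GENETIC_CODE
    sense <- names(gc_map)[gc_map != "*"]
    idx <- sample(seq_along(cods), nmut)
    cods[idx] <- sample(sense, nmut, replace = TRUE)
    der <- paste(cods, collapse = "")
    got <- nei_gojobori(anc, der)
    want <- oracle_ng86(anc, der)
    expect_equal(got$S, want$S, tolerance = 1e-9)
    expect_equal(got$Sd, want$Sd, tolerance = 1e-9)
    expect_equal(got$Nd, want$Nd, tolerance = 1e-9)
    if (is.na(want$Ks)) expect_true(is.na(got$Ks)) else
      expect_equal(got$Ks, want$Ks, tolerance = 1e-9)
  }
})

test_that("clock dating is the closed form T = Ksil / (2 mu)", {
  expect_equal(date_divergence(0), 0)
  expect_equal(date_divergence(0.015, mu = 7.5e-10) / 1e6, 10.0)
  expect_true(is.na(date_divergence(NA_real_)))
  # linear in Ksil, inverse in mu
  set.seed(9)
  ks <- runif(20, 0, 0.5); mus <- runif(20, 1e-10, 1e-8)
  expect_equal(date_divergence(2 * ks, mus), 2 * date_divergence(ks, mus))
  expect_equal(date_divergence(ks, 2 * mus), date_divergence(ks, mus) / 2)
})

test_that("strata are numbered by descending age with median summaries", {
  inv <- data.frame(block = c(1L, 2L), orientation = "inverted",
                    w_chrom = "Chr14", w_start = c(100, 5000),
                    w_end = c(4000, 9000), z_chrom = "Chr14",
                    z_start = c(1, 2), z_end = c(3, 4),
                    n_anchors = c(3L, 3L))
  times <- data.frame(block = c(1, 1, 1, 2, 2, 2),
                      t_years = c(3.2e6, 3.47e6, 3.9e6, 8e6, 8.2e6, 8.4e6))
  st <- assign_strata(inv, times)
  expect_equal(st$stratum, 1:2)
  expect_equal(st$block, c(2L, 1L))             # oldest first
  expect_equal(st$median_t_mya, c(8.2, 3.47))   # medians of member times
  expect_false(any(st$low_confidence))

  # single block; fewer than 3 timed pairs flagged
  st1 <- assign_strata(inv[1, ], times[1:2, ])
  expect_equal(nrow(st1), 1)
  expect_true(st1$low_confidence)
})

test_that("planted inversions are recovered exactly at anchor level", {
  lay <- simulate_zw_reference(sim_config(seed = 14))
  pr <- simulate_wz_gene_pairs(lay, cds = FALSE)
  blocks <- build_collinear_blocks(pr$anchors)
  inv <- detect_inversions(blocks)$inversions
  inv <- inv[order(inv$w_start), ]
  truth <- lay$inversions[order(lay$inversions$w_start), ]
  expect_equal(nrow(inv), nrow(truth))
  expect_equal(inv$n_anchors, truth$n_pairs)
  # every anchor of a planted inversion is inside the recovered W span
  for (i in seq_len(nrow(truth))) {
    members <- pr$anchors[pr$anchors$age_years == truth$age_years[i] &
                            pr$anchors$block_type == "inverted", ]
    expect_true(all(members$w_start >= inv$w_start[i] - 1 &
                      members$w_end <= inv$w_end[i] + 1))
  }
  # z-ranks strictly decreasing along W within each planted inversion
  for (b in unique(members$block)) {
    m <- pr$anchors[pr$anchors$block == b, ]
    m <- m[order(m$w_start), ]
    expect_true(all(diff(m$z_start) < 0))
  }
})
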