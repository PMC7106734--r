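test_that("fixed differences give F_ST exactly 1, identical groups at most 0", {
  for (sizes in list(c(2, 2), c(4, 13), c(3, 9))) {
    g1 <- matrix(1L, sizes[1], 2)
    g2 <- matrix(0L, sizes[2], 2)
    expect_equal(wc_fst_site(g1, g2)$fst, 1)
    expect_equal(wc_fst_site(g2, g1)$fst, 1)   # group exchange symmetry
  }
  # identical genotype counts in both groups: no differentiation, fst <= 0
  g <- rbind(matrix(1L, 2, 2), matrix(0L, 3, 2), matrix(c(0L, 1L), 2, 2))
  r <- wc_fst_site(g, g)
  expect_lte(r$fst, 0)
  # monomorphic pooled sample: undefined
  expect_true(is.na(wc_fst_site(matrix(0L, 4, 2), matrix(0L, 4, 2))$fst))
})

test_that("estimator matches the independent variance-component oracle", {
  # the genotype configuration of the exonic missense site:
  # cases 1/1 x4; controls 0/0 x9, 0/1 x4
  g1 <- matrix(1L, 4, 2)
  g2 <- rbind(matrix(0L, 9, 2), matrix(c(0L, 1L), 4, 2, byrow = TRUE))
  got <- wc_fst_site(g1, g2)
  want <- wc_oracle(list(g1, g2))
  expect_equal(got$a, want$a, tolerance = 1e-12)
  expect_equal(got$b, want$b, tolerance = 1e-12)
  expect_equal(got$c, want$c, tolerance = 1e-12)
  expect_equal(got$fst, want$fst, tolerance = 1e-12)

  set.seed(11)
  for (i in 1:100) {
    cfg <- random_config()
    got <- wc_fst_site(cfg$g1, cfg$g2)
    want <- wc_oracle(list(cfg$g1, cfg$g2))
    expect_equal(got$fst, want$fst, tolerance = 1e-12)
    # exchanging the groups leaves the estimate unchanged
    expect_equal(wc_fst_site(cfg$g2, cfg$g1)$fst, got$fst, tolerance = 1e-12)
  }
})

test_that("vectorised scan agrees with the per-site estimator and handles missing data", {
  set.seed(7)
  d <- tiny_dataset(
    case_gts = replicate(6, paste(sample(0:1, 4, TRUE), sample(0:1, 4, TRUE),
                                  sep = "|"), simplify = FALSE),
    control_gts = replicate(6, paste(sample(0:1, 7, TRUE), sample(0:1, 7, TRUE),
                                     sep = "|"), simplify = FALSE))
  d$genotypes$a1[2, 3] <- NA; d$genotypes$a2[2, 3] <- NA
  sc <- fst_scan(d$variants, d$genotypes, d$pedigree)
  for (i in seq_len(nrow(sc))) {
    k <- which(d$variants$pos == sc$pos[i])
    g1 <- cbind(d$genotypes$a1[k, 1:4], d$genotypes$a2[k, 1:4])
    g2 <- cbind(d$genotypes$a1[k, 5:11], d$genotypes$a2[k, 5:11])
    expect_equal(sc$fst[i], wc_oracle(list(g1, g2))$fst, tolerance = 1e-12)
  }
})

test_that("window statistic is the ratio of summed components", {
  # single site with fst 1 alone in its windows
  s <- data.frame(chrom = "c1", pos = 5000L, a = 0.5, b = 0, c = 0, d = 0.5,
                  fst = 1)
  w <- fst_windows(s, 10000, 2000)
  expect_true(all(w$WEIGHTED_FST[w$N_VARIANTS == 1] == 1))
  # two sites (a=1, d=2) and (a=0, d=2): weighted = 1/4, mean = 1/4
  s2 <- data.frame(chrom = "c1", pos = c(1000L, 2000L),
                   a = c(1, 0), b = 0, c = 0, d = c(2, 2), fst = c(0.5, 0))
  w2 <- fst_windows(s2, 10000, 2000)
  expect_equal(w2$WEIGHTED_FST[1], 0.25)
  expect_equal(w2$MEAN_FST[1], 0.25)
  # windows with no usable site are emitted with NA
  expect_true(any(is.na(fst_windows(s, 10000, 2000,
                                    chrom_lengths = c(c1 = 50000))$WEIGHTED_FST)))
  expect_error(fst_windows(s, 1000, 2000), "span")
})

test_that("windowed values equal a brute-force per-window recomputation", {
  set.seed(3)
  n <- 300
  s <- data.frame(chrom = "c1", pos = sort(sample.int(100000, n)),
                  a = rnorm(n, 0.2, 0.3), b = 0, c = 0)
  s$c <- abs(rnorm(n, 0.3, 0.1))
  s$d <- s$a + s$b + s$c
  s$fst <- s$a / s$d
  w <- fst_windows(s, 10000, 2000, chrom_lengths = c(c1 = 100000))
  for (i in sample(nrow(w), 25)) {
    inw <- s$pos >= w$BIN_START[i] & s$pos <= w$BIN_END[i]
    expect_equal(w$N_VARIANTS[i], sum(inw))
    if (any(inw)) {
      expect_equal(w$WEIGHTED_FST[i], sum(s$a[inw]) / sum(s$d[inw]),
                   tolerance = 1e-12)
      expect_equal(w$MEAN_FST[i], mean(s$fst[inw]), tolerance = 1e-12)
    }
  }
})

test_that("window selection uses strict > on F_ST and >= on count, then merges", {
  w <- data.frame(CHROM = "c1",
                  BIN_START = c(1L, 2001L, 40001L, 60001L),
                  BIN_END = c(10000L, 12000L, 50000L, 70000L),
                  N_VARIANTS = c(10L, 50L, 9L, 12L),
                  WEIGHTED_FST = c(0.61, 0.60, 0.90, 0.70),
                  MEAN_FST = 0.5)
  keep <- filter_fst_windows(w, 0.6, 10)
  expect_equal(keep$BIN_START, c(1L, 60001L))   # 0.60 dropped, 9 variants dropped
  reg <- attr(keep, "regions")
  expect_equal(nrow(reg), 2)
  # overlapping passing windows merge into one region
  w2 <- w; w2$WEIGHTED_FST <- 0.7; w2$N_VARIANTS <- 20L
  reg2 <- attr(filter_fst_windows(w2, 0.6, 10), "regions")
  expect_equal(reg2$start, c(1L, 40001L, 60001L))
  expect_equal(reg2$end, c(12000L, 50000L, 70000L))
})

test_that("label permutation on null-like data rarely produces high-F_ST windows", {
  set.seed(5)
  cfg <- sim_config(chrom_length_bp = 500000L, n_background_snps = 2000L,
                    n_background_indels = 0L, n_causal_tag_snps = 0L,
                    causal_position_bp = 250000L,
                    causal_haplotype_length_bp = 1000L, seed = 99L)
  ds <- simulate_ppd_cohort(cfg)
  fracs <- vapply(1:8, function(i) {
    ped <- ds$pedigree
    sampled <- ped$id[ped$sampled]
    ped$phenotype[ped$id %in% sampled] <- 1L
    ped$phenotype[ped$id %in% sample(sampled, 4)] <- 2L
    sc <- fst_scan(ds$variants, ds$genotypes, ped)
    w <- fst_windows(sc, 10000, 2000)
    mean(w$WEIGHTED_FST > 0.6, na.rm = TRUE)
  }, 0)
  expect_lt(mean(fracs), 0.05)
})
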