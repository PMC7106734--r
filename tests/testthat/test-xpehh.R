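test_that("EHH equals the pair-enumeration oracle and respects its invariants", {
  # identical haplotypes: EHH 1 everywhere
  h <- matrix(1L, 4, 5)
  pos <- c(0, 100, 250, 400, 600)
  cv <- ehh(h, 1, pos, "right", cutoff = 0)
  expect_true(all(cv$ehh == 1))

  # all pairwise distinct at the first flank marker: EHH 0 there
  h2 <- rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
  h2 <- cbind(0L, h2)  # core column
  cv2 <- ehh(h2, 1, c(0, 50, 80), "right")
  expect_equal(cv2$ehh, c(1, 1 / 3, 0))  # 4 haps: classes 2/2 then all split

  # 6 haplotypes splitting 4/2 at the first marker: (C(4,2)+C(2,2))/C(6,2)
  h3 <- cbind(rep(0L, 6), c(0L, 0L, 0L, 0L, 1L, 1L))
  expect_equal(ehh(h3, 1, c(0, 10), "right")$ehh[2], 7 / 15)

  # random panels of <= 10 haplotypes against brute-force pair enumeration,
  # both directions; EHH is monotone non-increasing and within [0, 1]
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(3:10, 1); S <- sample(5:12, 1)
    h <- matrix(rbinom(n * S, 1, runif(1, 0.2, 0.8)), n, S)
    pos <- sort(sample.int(5000, S))
    core <- sample(2:(S - 1), 1)
    for (dirn in c("right", "left")) {
      cv <- ehh(h, core, pos, dirn, cutoff = 0)
      expect_equal(cv$ehh[1], 1)
      expect_true(all(diff(cv$ehh) <= 1e-12))
      expect_true(all(cv$ehh >= 0 & cv$ehh <= 1))
      js <- if (dirn == "right") seq(core + 1, along.with = cv$ehh[-1])
            else seq(core - 1, by = -1, along.with = cv$ehh[-1])
      for (k in seq_along(js))
        expect_equal(cv$ehh[k + 1], ehh_pairs_oracle(h, core, js[k]))
    }
  }
  expect_error(ehh(h[1, , drop = FALSE], 1, pos), "2 haplotypes")
})

test_that("iHH is the trapezoid area of the curve against physical distance", {
  # EHH == 1 over a 1000 bp flank: rectangle of area 1000
  rect <- data.frame(pos = c(0, 1000), dist = c(0, 1000), ehh = c(1, 1))
  expect_equal(ihh(rect), 1000)
  # EHH 1 then 0.5 at 100 bp: trapezoid of area 75
  trap <- data.frame(pos = c(0, 100), dist = c(0, 100), ehh = c(1, 0.5))
  expect_equal(ihh(trap), 75)
  # zero-length flank contributes 0
  expect_equal(ihh(trap[1, ]), 0)
  # random curves against a dense linear-interpolation integral
  set.seed(31)
  for (rep in 1:10) {
    S <- sample(6:15, 1)
    h <- matrix(rbinom(8 * S, 1, 0.5), 8, S)
    cv <- ehh(h, 1, sort(sample.int(3000, S)), "right", cutoff = 0)
    expect_equal(ihh(cv), ihh_grid_oracle(cv), tolerance = 1e-9)
  }
})

test_that("the scan's C++ kernel agrees with the R curve implementation", {
  set.seed(41)
  n1 <- 6L; n2 <- 8L; S <- 40L
  pos <- sort(sample.int(20000, S))
  hc <- matrix(rbinom(n1 * S, 1, 0.5), n1, S)
  hu <- matrix(rbinom(n2 * S, 1, 0.5), n2, S)
  m <- ppdscan:::cpp_xpehh_ihh(hc, hu, as.numeric(pos), 0.05, Inf)
  for (s in sample(S, 10)) {
    expect_equal(m[s, 1],
                 ihh(ehh(hc, s, pos, "right")) + ihh(ehh(hc, s, pos, "left")),
                 tolerance = 1e-9)
    expect_equal(m[s, 2],
                 ihh(ehh(hu, s, pos, "right")) + ihh(ehh(hu, s, pos, "left")),
                 tolerance = 1e-9)
  }
  # the maximal-extension bound truncates both implementations identically
  m2 <- ppdscan:::cpp_xpehh_ihh(hc, hu, as.numeric(pos), 0.05, 5000)
  s <- which.max(pos > 6000)
  expect_equal(m2[s, 1],
               ihh(ehh(hc, s, pos, "right", max_extend_bp = 5000)) +
               ihh(ehh(hc, s, pos, "left", max_extend_bp = 5000)),
               tolerance = 1e-9)
})

test_that("XP-EHH is zero for identical panels, antisymmetric under group swap, and standardised", {
  set.seed(51)
  S <- 120L
  pos <- sort(sample.int(60000, S))
  hap <- matrix(rbinom(10 * S, 1, runif(S, 0.2, 0.8)[col(matrix(0, 10, S))]),
                10, S)
  d <- tiny_dataset(
    case_gts = lapply(seq_len(S), function(i)
      paste(hap[1:5, i], hap[6:10, i], sep = "|")),
    control_gts = lapply(seq_len(S), function(i)
      paste(hap[1:5, i], hap[6:10, i], sep = "|")),
    pos = pos)
  sc <- xpehh_scan(d$variants, d$genotypes, d$pedigree)
  expect_true(all(sc$RAW == 0))   # identical panels: exact zero

  # antisymmetry: swap phenotype labels, raw scores negate exactly
  set.seed(52)
  d2 <- tiny_dataset(
    case_gts = lapply(seq_len(S), function(i)
      paste(rbinom(4, 1, 0.5), rbinom(4, 1, 0.5), sep = "|")),
    control_gts = lapply(seq_len(S), function(i)
      paste(rbinom(6, 1, 0.5), rbinom(6, 1, 0.5), sep = "|")),
    pos = pos)
  sc2 <- xpehh_scan(d2$variants, d2$genotypes, d2$pedigree)
  ped_sw <- d2$pedigree
  ped_sw$phenotype <- ifelse(ped_sw$phenotype == 2L, 1L, 2L)
  sc_sw <- xpehh_scan(d2$variants, d2$genotypes, ped_sw)
  expect_equal(sc_sw$RAW, -sc2$RAW)

  # normalised scores: mean 0, SD 1 over the non-edge scored set
  ok <- sc2$FLAGS == ""
  expect_gt(sum(ok), 10)
  expect_equal(mean(sc2$NORMALIZED[ok]), 0, tolerance = 1e-9)
  expect_equal(stats::sd(sc2$NORMALIZED[ok]), 1, tolerance = 1e-9)
})

test_that("a planted sweep is localised and called as a region", {
  set.seed(61)
  S <- 800L
  pos <- sort(sample.int(1000000L, S))
  block <- c(475000L, 525000L)
  in_block <- pos >= block[1] & pos <= block[2]
  freq <- runif(S, 0.2, 0.8)
  ctrl <- sapply(seq_len(S), function(i) rbinom(26, 1, freq[i]))  # 26 x S
  case <- sapply(seq_len(S), function(i) rbinom(8, 1, freq[i]))
  shared <- rbinom(sum(in_block), 1, freq[in_block])
  case[, in_block] <- matrix(shared, 8, sum(in_block), byrow = TRUE)
  d <- tiny_dataset(
    case_gts = lapply(seq_len(S), function(i)
      paste(case[1:4, i], case[5:8, i], sep = "|")),
    control_gts = lapply(seq_len(S), function(i)
      paste(ctrl[1:13, i], ctrl[14:26, i], sep = "|")),
    pos = pos)
  sc <- xpehh_scan(d$variants, d$genotypes, d$pedigree)
  peak <- sc$POS[which.max(sc$NORMALIZED)]
  expect_gte(peak, block[1] - 10000)
  expect_lte(peak, block[2] + 10000)
  reg <- call_xpehh_regions(sc, threshold = 2)
  expect_gt(nrow(reg), 0)
  expect_true(any(reg$start <= block[2] & reg$end >= block[1]))
  # all scores below threshold: no regions
  reg0 <- call_xpehh_regions(sc, threshold = max(sc$NORMALIZED, na.rm = TRUE) + 1)
  expect_equal(nrow(reg0), 0)
})
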