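small_cfg <- function(...) {
  args <- utils::modifyList(
    list(chrom_length_bp = 200000L, causal_position_bp = 100000L,
         causal_haplotype_length_bp = 20000L, n_background_snps = 800L,
         n_background_indels = 200L, n_causal_tag_snps = 20L, seed = 5L),
    list(...))
  do.call(sim_config, args)
}

test_that("configuration invariants are enforced with the field named", {
  expect_error(sim_config(causal_position_bp = 0), "causal_position_bp")
  expect_error(sim_config(causal_position_bp = 6e6), "causal_position_bp")
  expect_error(sim_config(penetrance = 1.2), "penetrance")
  expect_error(sim_config(n_background_snps = -1), "n_background_snps")
  expect_error(sim_config(founder_allele_freq_beta = c(-1, 1)),
               "founder_allele_freq_beta")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
})

test_that("empty background leaves only the implanted sites", {
  cfg <- small_cfg(n_background_snps = 0L, n_background_indels = 0L,
                   n_causal_tag_snps = 0L)
  panel <- simulate_founder_haplotypes(cfg)
  expect_equal(nrow(panel$variants), 1L)
  expect_equal(panel$variants$pos, cfg$causal_position_bp)
  cfg2 <- small_cfg(n_background_snps = 0L, n_background_indels = 0L)
  panel2 <- simulate_founder_haplotypes(cfg2)
  expect_equal(nrow(panel2$variants), 21L)   # causal + 20 tag markers
  # every carrier haplotype is an identical copy of the implanted block
  carriers <- paste0(panel2$founders$id[panel2$founders$carrier], "_1")
  blk <- panel2$haps[carriers, , drop = FALSE]
  expect_true(all(apply(blk, 2, function(x) length(unique(x)) == 1)))
  expect_true(all(blk[, which(panel2$variants$pos == cfg2$causal_position_bp)] == 1))
})

test_that("founder site frequencies follow the ascertained Beta-binomial law", {
  cfg <- sim_config(chrom_length_bp = 2000000L, causal_position_bp = 1000000L,
                    causal_haplotype_length_bp = 1000L,
                    n_background_snps = 1000L, n_background_indels = 0L,
                    n_causal_tag_snps = 0L,
                    founder_allele_freq_beta = c(0.5, 0.5), seed = 13L)
  panel <- simulate_founder_haplotypes(cfg)
  bg <- panel$variants$kind == "bg_snp" &
    (panel$variants$pos < panel$block["start"] |
     panel$variants$pos > panel$block["end"])
  counts <- colSums(panel$haps)[bg]
  nh <- nrow(panel$haps)
  # analytic Beta-binomial pmf truncated to polymorphic counts
  k <- 1:(nh - 1)
  pk <- choose(nh, k) * beta(k + 0.5, nh - k + 0.5) / beta(0.5, 0.5)
  pk <- pk / sum(pk)
  mu <- sum(k * pk)
  v <- sum(k^2 * pk) - mu^2
  se <- sqrt(v / length(counts))
  expect_lt(abs(mean(counts) - mu), 3 * se)
  expect_true(all(counts >= 1 & counts <= nh - 1))
})

test_that("gene dropping is Mendelian: offspring alleles come from their parents", {
  cfg <- small_cfg()
  panel <- simulate_founder_haplotypes(cfg)
  cohort <- gene_drop(panel)
  ped <- cohort$pedigree
  for (i in which(ped$sire != "0")) {
    kid <- ped$id[i]
    for (h in 1:2) {
      par <- if (h == 1) ped$sire[i] else ped$dam[i]
      gam <- cohort$haps[paste0(kid, "_", h), ]
      p1 <- cohort$haps[paste0(par, "_1"), ]
      p2 <- cohort$haps[paste0(par, "_2"), ]
      expect_true(all(gam == p1 | gam == p2))
    }
  }
})

test_that("zero recombination transmits whole parental haplotypes; forced homozygotes are affected", {
  cfg <- small_cfg(recombination_rate_per_bp = 0)
  panel <- simulate_founder_haplotypes(cfg)
  cohort <- gene_drop(panel)
  ped <- cohort$pedigree
  for (i in which(ped$sire != "0")) {
    for (h in 1:2) {
      par <- if (h == 1) ped$sire[i] else ped$dam[i]
      gam <- cohort$haps[paste0(ped$id[i], "_", h), ]
      expect_true(identical(gam, unname(cohort$haps[paste0(par, "_1"), ])) ||
                  identical(gam, unname(cohort$haps[paste0(par, "_2"), ])))
    }
  }
  # penetrance 1 and recessive forcing: affected set == homozygote set
  ci <- cohort$causal_index
  hom <- cohort$haps[paste0(ped$id, "_1"), ci] == 1 &
         cohort$haps[paste0(ped$id, "_2"), ci] == 1
  expect_equal(ped$phenotype == 2L, unname(hom))
  expect_equal(sum(ped$phenotype == 2L & ped$sampled), 4L)
  expect_equal(sum(ped$phenotype == 1L & ped$sampled), 13L)

  # a parent homozygous at every site determines the offspring haplotype
  panel0 <- panel
  panel0$haps["F0-3_2", ] <- panel0$haps["F0-3_1", ]
  cohort0 <- gene_drop(panel0)
  kidhap <- cohort0$haps["F1-b5_2", ]   # dam F0-3 homozygous everywhere
  expect_identical(unname(kidhap), unname(panel0$haps["F0-3_1", ]))
})

test_that("crossover counts follow the configured Poisson rate", {
  set.seed(17)
  pos <- sort(sample.int(10000000L, 50L))
  h1 <- rep(0L, 50); h2 <- rep(1L, 50)
  k <- vapply(1:10000, function(i)
    attr(ppdscan:::sim_gamete(h1, h2, pos, 1e7, 1e-8), "crossovers"), 0L)
  expect_lt(abs(mean(k) - 0.1), 3 * sqrt(0.1 / 10000))
})

test_that("datasets are deterministic per seed and honour QC-noise settings", {
  cfg <- small_cfg(qc_annotation_noise = list(
    snp = c(QUAL = 0, QD = 0, MQ = 0, FS = 0, MQRankSum = 0,
            ReadPosRankSum = 0, MQ0DP = 0),
    indel = c(QD = 0, FS = 0, ReadPosRankSum = 0)))
  ds <- simulate_ppd_cohort(cfg)
  snp <- ds$variants[ds$variants$vclass == "SNP", ]
  ind <- ds$variants[ds$variants$vclass == "INDEL", ]
  class(snp) <- class(ind) <- c("variant_table", "data.frame")
  expect_true(all(apply_hard_filters(snp, "SNP")$filter_flags == ""))
  expect_true(all(apply_hard_filters(ind, "INDEL")$filter_flags == ""))

  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  p1 <- emit_dataset(ds, dir1)
  ds2 <- simulate_ppd_cohort(cfg)
  p2 <- emit_dataset(ds2, dir2)
  for (f in names(p1))
    expect_identical(unname(tools::md5sum(p1[[f]])),
                     unname(tools::md5sum(p2[[f]])), label = f)

  # a non-zero clause fraction produces failures of exactly that clause
  cfg3 <- small_cfg(qc_annotation_noise = list(
    snp = c(QUAL = 0, QD = 0.2, MQ = 0, FS = 0, MQRankSum = 0,
            ReadPosRankSum = 0, MQ0DP = 0),
    indel = c(QD = 0, FS = 0, ReadPosRankSum = 0)), seed = 6L)
  ds3 <- simulate_ppd_cohort(cfg3)
  snp3 <- ds3$variants[ds3$variants$vclass == "SNP", ]
  class(snp3) <- c("variant_table", "data.frame")
  fl <- apply_hard_filters(snp3, "SNP")$filter_flags
  expect_gt(sum(fl == "QD"), 0)
  expect_true(all(fl %in% c("", "QD")))
  # the causal site always passes
  expect_equal(fl[snp3$pos == cfg3$causal_position_bp], "")
})

test_that("emitted files round-trip into the same dataset", {
  cfg <- small_cfg()
  ds <- simulate_ppd_cohort(cfg)
  dir <- withr::local_tempdir()
  p <- emit_dataset(ds, dir)
  rt <- read_vcf(p["vcf"])
  expect_equal(rt$variants$pos, ds$variants$pos)
  expect_equal(rt$variants$ref, ds$variants$ref)
  expect_equal(rt$variants$alt, ds$variants$alt)
  expect_equal(rt$genotypes$a1, ds$genotypes$a1, ignore_attr = TRUE)
  expect_equal(rt$genotypes$a2, ds$genotypes$a2, ignore_attr = TRUE)
  expect_true(all(rt$genotypes$phased))
  ped <- read_pedigree(p["ped"])
  expect_equal(sort(case_ids(ped)), sort(c("F1-a1", "F1-a2", "F1-a3", "F0-4")))
  expect_length(control_ids(ped), 13L)
  m <- read_gene_model(p["gtf"])
  expect_equal(sort(m$genes$gene_id), c("SIMG1", "SIMG2", "SIMG3"))
  fa <- Biostrings::readDNAStringSet(p["fasta"])
  expect_equal(as.character(fa[[1]]), ds$ref_seq)
})

test_that("pedigree errors are detected", {
  cfg <- small_cfg()
  panel <- simulate_founder_haplotypes(cfg)
  ped <- build_sim_pedigree(cfg)
  bad <- ped
  bad$sire[bad$id == "F1-a1"] <- "NOBODY"
  expect_error(gene_drop(panel, bad), "cycle or missing parent")
})
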