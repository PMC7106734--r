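test_that("each hard-filter clause is evaluated independently, with printed boundaries", {
  mk <- function(...) {
    base <- data.frame(chrom = "c1", pos = 100L, ref = "A", alt = "G",
                       qual = 100, QD = 10, MQ = 50, FS = 10,
                       MQRankSum = 0, ReadPosRankSum = 0, MQ0 = 0, DP = 40)
    ov <- list(...)
    base[names(ov)] <- ov
    variant_table(base)
  }
  flags <- function(v, mode = "SNP") apply_hard_filters(v, mode)$filter_flags

  # single-clause failures, SNP expression
  expect_identical(flags(mk(QD = 1.5)), "QD")
  expect_identical(flags(mk(qual = 40)), "QUAL")        # QUAL <= 40 inclusive
  expect_identical(flags(mk(MQ = 40)), "MQ")            # MQ <= 40 inclusive
  expect_identical(flags(mk(FS = 60)), "FS")            # FS >= 60 inclusive
  expect_identical(flags(mk(MQRankSum = -12.5)), "MQRankSum")
  expect_identical(flags(mk(ReadPosRankSum = -8)), "")  # strict < -8
  expect_identical(flags(mk(ReadPosRankSum = -8.001)), "ReadPosRankSum")
  expect_identical(flags(mk(MQ0 = 4, DP = 39)), "MQ0DP")  # 4/39 > 0.1
  expect_identical(flags(mk(MQ0 = 4, DP = 41)), "")       # ratio below 0.1
  expect_identical(flags(mk(MQ0 = 3, DP = 10)), "")       # MQ0 below 4

  # flag set is the union of failing clauses
  expect_identical(flags(mk(QD = 1, MQ = 30)), "QD;MQ")

  # INDEL expression: different thresholds and strict operators
  mi <- function(...) {
    v <- mk(...)
    v$ref <- "AT"; v$vclass <- "INDEL"
    v
  }
  expect_identical(flags(mi(FS = 200), "INDEL"), "")       # strict > 200
  expect_identical(flags(mi(FS = 200.01), "INDEL"), "FS")
  expect_identical(flags(mi(QD = 2), "INDEL"), "")         # strict < 2
  expect_identical(flags(mi(QD = 1.99), "INDEL"), "QD")
  expect_identical(flags(mi(ReadPosRankSum = -20), "INDEL"), "")
  expect_identical(flags(mi(ReadPosRankSum = -20.5), "INDEL"), "ReadPosRankSum")
  # MQ clause is not part of the INDEL expression
  expect_identical(flags(mi(MQ = 10), "INDEL"), "")

  # missing annotation: clause skipped, not failed
  expect_identical(flags(mk(QD = NA)), "")
})

test_that("SNP cluster rule flags exactly 3-in-10-bp clusters", {
  mk <- function(pos, ref = "A") variant_table(
    data.frame(chrom = "c1", pos = pos, ref = ref, alt = "G"))
  f <- function(pos) snp_cluster_filter(mk(pos))$filter_flags

  expect_identical(f(c(100L, 105L, 109L)), rep("SnpCluster", 3))  # span 10
  expect_identical(f(c(100L, 105L, 111L)), rep("", 3))            # span 12
  expect_identical(f(c(100L, 109L)), rep("", 2))                  # below min
  # four SNPs where only the last three form a cluster
  expect_identical(f(c(50L, 100L, 104L, 108L)),
                   c("", "SnpCluster", "SnpCluster", "SnpCluster"))
  # INDELs neither count nor get flagged
  v <- variant_table(data.frame(chrom = "c1", pos = c(100L, 105L, 109L),
                                ref = c("A", "AT", "A"), alt = "G"))
  expect_identical(snp_cluster_filter(v)$filter_flags, rep("", 3))
  # invariance to input order is enforced via the sortedness contract
  expect_error(snp_cluster_filter(
    structure(mk(c(100L, 105L, 109L))[c(3, 1, 2), ],
              class = c("variant_table", "data.frame"))), "sorted")
})

test_that("VCF round-trip preserves records, phase, missingness and INFO", {
  d <- tiny_dataset(
    case_gts = list(c("1|1", "1|1"), c("0|1", "1|0"), c("0|0", ".|.")),
    control_gts = list(c("0|0", "0|0", "0|1"), c("0/0", "1/1", "0|0"),
                       c("1|2", "0|0", "0|2")),
    pos = c(150L, 400L, 900L))
  d$variants$alt[3] <- "G,T"   # multi-allelic site
  d$variants$qual <- c(55.5, 200, 1000)
  d$variants$QD <- c(12, 3.25, NA)
  d$variants$DP <- c(400, 500, 600)
  dir <- withr::local_tempdir()
  p <- file.path(dir, "t.vcf")
  write_vcf(d$variants, d$genotypes, p, contig_lengths = c(chr1 = 1000L))
  rt <- read_vcf(p)
  expect_equal(rt$variants$pos, d$variants$pos)
  expect_equal(rt$variants$ref, d$variants$ref)
  expect_equal(rt$variants$alt, d$variants$alt)
  expect_equal(rt$variants$qual, d$variants$qual, tolerance = 1e-6)
  expect_equal(rt$variants$QD, d$variants$QD, tolerance = 1e-6)
  expect_equal(rt$genotypes$a1, d$genotypes$a1, ignore_attr = TRUE)
  expect_equal(rt$genotypes$a2, d$genotypes$a2, ignore_attr = TRUE)
  # phase preserved, including the unphased control genotypes at site 2
  expect_false(rt$genotypes$phased[2, 3])
  expect_true(rt$genotypes$phased[1, 1])
  # missing genotype round-trips as NA and is excluded from counts
  expect_true(is.na(rt$genotypes$a1[3, 2]))
  dd <- daf(rt$variants, rt$genotypes, d$pedigree)
  expect_equal(dd$daf[1], 5 / 10)
  # site 3: one missing case dropped; multi-allelic projection keeps the
  # most frequent alternate (2) and masks the genotype carrying allele 1
  expect_equal(dd$daf[3], 1 / 6)
})

test_that("pedigree reader defines disjoint case/control groups and drops phenotype 0", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "t.ped")
  ids <- sprintf("S%02d", 1:18)
  phe <- c(rep(2, 4), rep(1, 13), 0)
  writeLines(paste("FAM", ids, "0", "0", "1", phe, sep = "\t"), p)
  ped <- read_pedigree(p)
  expect_s3_class(ped, "pedigree")
  expect_length(case_ids(ped), 4)
  expect_length(control_ids(ped), 13)
  expect_length(intersect(case_ids(ped), control_ids(ped)), 0)
  expect_false("S18" %in% c(case_ids(ped), control_ids(ped)))
  # duplicate ids rejected
  writeLines(paste("FAM", c("A", "A"), "0", "0", "1", "1", sep = "\t"), p)
  expect_error(read_pedigree(p), "duplicate")
})

test_that("gene model enforces CDS frame and containment; GTF round-trips", {
  feats <- data.frame(
    gene_id = "g1", transcript_id = "g1.t1",
    type = c("exon", "CDS", "exon", "CDS"),
    chrom = "c1", strand = "+",
    start = c(101L, 161L, 301L, 301L), end = c(220L, 220L, 420L, 360L))
  m <- gene_model(feats)
  expect_equal(nrow(m$genes), 1)
  expect_equal(sum(m$cds$end - m$cds$start + 1), 120)
  # UTR = exon minus CDS
  expect_equal(m$utr$start, c(101L, 361L))
  expect_equal(m$utr$end, c(160L, 420L))

  bad <- feats
  bad$end[2] <- 221L   # CDS length 121+60 not divisible by 3, and outside exon
  expect_error(gene_model(bad), "divisible by 3|contained")

  dir <- withr::local_tempdir()
  p <- file.path(dir, "t.gtf")
  write_gene_model(m, p)
  m2 <- read_gene_model(p)
  expect_equal(m2$genes$start, m$genes$start)
  expect_equal(m2$cds[c("start", "end")], m$cds[c("start", "end")])
})
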