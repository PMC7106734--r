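#' Expand a genotype-count table into a dataset
#'
#' Published association tables often report, per SNP, the genotype counts
#' of the case and control groups (e.g. cases `1/1:4`, controls
#' `0/0:9,0/1:4`, with 0 = reference and 1 = altered allele). This helper
#' expands such a table into a [variant_table], a [geno_matrix] and a
#' [pedigree] so that the association, DAF and concordance machinery can be
#' run directly on printed results. The package ships the genotyping table
#' of the top ten PPD-associated SNPs from the two pig families as
#' `system.file("extdata", "ppd_top_snps.tsv", package = "ppdscan")`.
#'
#' @param path A tab-separated file with columns `snp_id, chrom, pos,
#'   region, ref, alt, gt_cases, gt_controls`; genotype counts written as
#'   `"GT:count"` joined by commas.
#' @return A list with `variants`, `genotypes`, `pedigree` (cases first,
#'   phenotype 2; controls phenotype 1).
#' @export
read_genotype_counts <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  expand <- function(spec) {
    parts <- strsplit(strsplit(spec, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
    do.call(rbind, lapply(parts, function(p) {
      al <- as.integer(strsplit(p[1], "/", fixed = TRUE)[[1]])
      matrix(rep(al, as.integer(p[2])), ncol = 2, byrow = TRUE)
    }))
  }
  case_gt <- lapply(tab$gt_cases, expand)
  ctrl_gt <- lapply(tab$gt_controls, expand)
  n_case <- unique(vapply(case_gt, nrow, 0L))
  n_ctrl <- unique(vapply(ctrl_gt, nrow, 0L))
  if (length(n_case) != 1L || length(n_ctrl) != 1L)
    stop("genotype counts imply unequal sample sizes across rows")
  a1 <- cbind(t(vapply(case_gt, function(m) m[, 1], integer(n_case))),
              t(vapply(ctrl_gt, function(m) m[, 1], integer(n_ctrl))))
  a2 <- cbind(t(vapply(case_gt, function(m) m[, 2], integer(n_case))),
              t(vapply(ctrl_gt, function(m) m[, 2], integer(n_ctrl))))
  samples <- c(paste0("case", seq_len(n_case)),
               paste0("control", seq_len(n_ctrl)))
  variants <- variant_table(data.frame(
    chrom = tab$chrom, pos = tab$pos, id = tab$snp_id,
    ref = tab$ref, alt = tab$alt))
  ord <- order(tab$chrom, tab$pos)
  ped <- pedigree(data.frame(
    fam = "FAM", id = samples, sire = "0", dam = "0", sex = 0L,
    phenotype = rep(c(2L, 1L), c(n_case, n_ctrl))))
  list(variants = variants,
       genotypes = geno_matrix(a1[ord, , drop = FALSE],
                               a2[ord, , drop = FALSE],
                               phased = FALSE, samples = samples),
       pedigree = ped)
}
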