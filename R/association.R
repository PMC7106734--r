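#' Allelic case-control chi-square test
#'
#' Pearson chi-square (1 df, no continuity correction) on the 2x2 table of
#' allele counts (not genotypes), the basic allelic association test.
#' Counts come from non-missing genotypes only. A pooled-monomorphic table
#' gives `chisq = 0`, `p = 1` and is flagged; a warning flag is attached
#' when any expected cell count is below 5 (asymptotic caveat for sparse
#' tables; no minimum-count gate is applied).
#'
#' @param case_ref,case_alt,control_ref,control_alt Allele counts.
#' @return List with `table` (2x2 matrix), `chisq`, `df = 1`, `p`, `flags`.
#' @export
allelic_chisq <- function(case_ref, case_alt, control_ref, control_alt) {
  tab <- matrix(c(case_ref, case_alt, control_ref, control_alt), 2,
                byrow = TRUE,
                dimnames = list(c("case", "control"), c("ref", "alt")))
  if (any(tab < 0)) stop("allele counts must be non-negative")
  n <- sum(tab)
  flags <- character()
  rs <- rowSums(tab); cs <- colSums(tab)
  if (n == 0 || any(cs == 0) || any(rs == 0)) {
    chisq <- 0; p <- 1
    flags <- c(flags, "monomorphic")
  } else {
    expd <- outer(rs, cs) / n
    chisq <- sum((tab - expd)^2 / expd)
    p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
    if (any(expd < 5)) flags <- c(flags, "sparse_table")
  }
  list(table = tab, chisq = chisq, df = 1L, p = p, flags = flags)
}

#' Genome-wide allelic association scan
#'
#' Runs [allelic_chisq()] at every site on the bi-allelic projection,
#' dropping missing genotypes per site. Output columns mirror a standard
#' case-control association table: per-site counted allele (`A1` = the
#' alternate), its frequency in affected (`F_A`) and unaffected (`F_U`)
#' samples, `CHISQ` and the asymptotic `P`.
#'
#' @param variants A [variant_table].
#' @param genotypes Matching [geno_matrix].
#' @param ped A [pedigree].
#' @return Data.frame `CHR, SNP, BP, A1, F_A, F_U, A2, CHISQ, P, FLAGS`.
#' @export
assoc_scan <- function(variants, genotypes, ped) {
  stopifnot(nrow(variants) == nrow(genotypes$a1))
  cnt <- group_allele_counts(genotypes, ped)
  n <- cnt$case_ref + cnt$case_alt + cnt$control_ref + cnt$control_alt
  r1 <- cnt$case_ref + cnt$case_alt
  r2 <- cnt$control_ref + cnt$control_alt
  c1 <- cnt$case_ref + cnt$control_ref
  c2 <- cnt$case_alt + cnt$control_alt
  mono <- n == 0 | c1 == 0 | c2 == 0 | r1 == 0 | r2 == 0
  chisq <- ifelse(mono, 0,
                  n * (cnt$case_ref * cnt$control_alt -
                       cnt$case_alt * cnt$control_ref)^2 /
                    (r1 * r2 * c1 * c2))
  p <- ifelse(mono, 1, stats::pchisq(chisq, 1, lower.tail = FALSE))
  sparse <- !mono & outer_min(r1, r2, c1, c2, n) < 5
  alt1 <- vapply(strsplit(variants$alt, ",", fixed = TRUE), `[`, "", 1L)
  data.frame(
    CHR = variants$chrom,
    SNP = ifelse(is.na(variants$id),
                 paste0(variants$chrom, ":", variants$pos), variants$id),
    BP = variants$pos, A1 = alt1,
    F_A = ifelse(r1 > 0, cnt$case_alt / r1, NA_real_),
    F_U = ifelse(r2 > 0, cnt$control_alt / r2, NA_real_),
    A2 = variants$ref, CHISQ = chisq, P = p,
    FLAGS = ifelse(mono, "monomorphic", ifelse(sparse, "sparse_table", "")))
}

# smallest expected cell of each site's 2x2 table
outer_min <- function(r1, r2, c1, c2, n) {
  pmin(r1 * c1, r1 * c2, r2 * c1, r2 * c2) / ifelse(n > 0, n, NA)
}

# per-site case/control ref and alt allele counts on the bi-allelic projection
group_allele_counts <- function(genotypes, ped) {
  gr <- split_groups(project_biallelic(genotypes), ped)
  count <- function(g) {
    ok <- !is.na(g$a1) & !is.na(g$a2)
    alt <- g$a1 + g$a2
    alt[!ok] <- 0L
    list(alt = rowSums(alt), tot = 2L * rowSums(ok))
  }
  ca <- count(gr$case); co <- count(gr$control)
  list(case_ref = ca$tot - ca$alt, case_alt = ca$alt,
       control_ref = co$tot - co$alt, control_alt = co$alt)
}

#' Derived allele frequency per group
#'
#' Computes the derived allele frequency (DAF) overall, in cases and in
#' controls. Under the default `"reference"` ancestral policy the reference
#' allele is ancestral and the (projected) alternate allele is derived,
#' matching a 0 = reference / 1 = derived genotype coding. A custom vector
#' of ancestral alleles can be supplied instead; the ancestral allele must
#' then be either the reference or an observed alternate at each site.
#'
#' @param variants A [variant_table].
#' @param genotypes Matching [geno_matrix].
#' @param ped A [pedigree].
#' @param ancestral `"reference"`, or a character vector of ancestral
#'   alleles (length = sites).
#' @return Data.frame `chrom, pos, daf, daf_case, daf_control, derived`.
#' @export
daf <- function(variants, genotypes, ped, ancestral = "reference") {
  cnt <- group_allele_counts(genotypes, ped)
  alt1 <- vapply(strsplit(variants$alt, ",", fixed = TRUE), `[`, "", 1L)
  if (identical(ancestral, "reference")) {
    flip <- rep(FALSE, nrow(variants))
  } else {
    if (length(ancestral) != nrow(variants))
      stop("ancestral allele vector must match the number of sites")
    if (!all(ancestral == variants$ref | ancestral == alt1))
      stop("ancestral allele not among the observed alleles at some site")
    flip <- ancestral == alt1    # alternate is ancestral => reference derived
  }
  der_case <- ifelse(flip, cnt$case_ref, cnt$case_alt)
  der_ctrl <- ifelse(flip, cnt$control_ref, cnt$control_alt)
  tot_case <- cnt$case_ref + cnt$case_alt
  tot_ctrl <- cnt$control_ref + cnt$control_alt
  data.frame(
    chrom = variants$chrom, pos = variants$pos,
    daf = (der_case + der_ctrl) / (tot_case + tot_ctrl),
    daf_case = ifelse(tot_case > 0, der_case / tot_case, NA_real_),
    daf_control = ifelse(tot_ctrl > 0, der_ctrl / tot_ctrl, NA_real_),
    derived = ifelse(flip, variants$ref, alt1))
}

#' Genotype-phenotype concordance under a monogenic model
#'
#' Tests, per site, whether genotypes segregate with the phenotype.
#' Recessive model: every affected sample is homozygous for the derived
#' allele AND no unaffected sample is homozygous derived. Dominant model:
#' every affected carries at least one derived allele AND no unaffected is
#' homozygous derived (with `strict_dominant = TRUE`, no unaffected carries
#' any derived allele). Missing genotypes are ignored; a site with no
#' segregating derived allele is never concordant.
#'
#' @param variants A [variant_table].
#' @param genotypes Matching [geno_matrix].
#' @param ped A [pedigree].
#' @param model `"recessive"` or `"dominant"`.
#' @param strict_dominant Disallow unaffected carriers under the dominant
#'   model.
#' @return Data.frame `chrom, pos, model, concordant, reason`.
#' @export
concordance <- function(variants, genotypes, ped,
                        model = c("recessive", "dominant"),
                        strict_dominant = FALSE) {
  model <- match.arg(model)
  gr <- split_groups(project_biallelic(genotypes), ped)
  stat <- function(g) {
    ok <- !is.na(g$a1) & !is.na(g$a2)
    hom <- g$a1 == 1L & g$a2 == 1L & ok
    car <- (g$a1 == 1L | g$a2 == 1L) & ok
    list(n = rowSums(ok), hom = rowSums(hom), car = rowSums(car))
  }
  ca <- stat(gr$case); co <- stat(gr$control)
  present <- (ca$car + co$car) > 0
  fixed <- present & ca$hom == ca$n & co$hom == co$n
  seg <- present & !fixed
  if (model == "recessive") {
    conc <- ca$hom == ca$n & ca$n > 0 & co$hom == 0 & seg
    reason <- ifelse(!seg, "no segregating derived allele",
              ifelse(ca$hom < ca$n, "affected not all homozygous derived",
              ifelse(co$hom > 0, "unaffected homozygous derived", "")))
  } else {
    ctrl_bad <- if (strict_dominant) co$car > 0 else co$hom > 0
    conc <- ca$car == ca$n & ca$n > 0 & !ctrl_bad & seg
    reason <- ifelse(!seg, "no segregating derived allele",
              ifelse(ca$car < ca$n, "affected without derived allele",
              ifelse(ctrl_bad, "unaffected carries derived allele", "")))
  }
  reason[conc] <- ""
  data.frame(chrom = variants$chrom, pos = variants$pos, model = model,
             concordant = conc, reason = reason)
}
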