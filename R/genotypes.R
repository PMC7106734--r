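#' Phased diploid genotype matrix
#'
#' Container for per-site, per-sample allele pairs with an optional phase
#' flag, the in-memory representation of a phased multi-sample VCF. Allele
#' codes are integers: 0 = reference, k = k-th alternate allele, `NA` =
#' missing. Sites are rows, samples are columns.
#'
#' @param a1,a2 Integer matrices (sites x samples) holding the first and
#'   second allele of each genotype. For phased genotypes `a1` is the
#'   paternal-side haplotype as written in the VCF (`a1|a2`).
#' @param phased Logical matrix of the same shape, or a single logical
#'   recycled to all genotypes.
#' @param samples Character vector of sample identifiers; defaults to the
#'   column names of `a1`.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(a1, a2, phased = TRUE, samples = colnames(a1)) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  stopifnot(identical(dim(a1), dim(a2)))
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(a1)))
  if (length(samples) != ncol(a1))
    stop("length(samples) must equal the number of genotype columns")
  if (length(phased) == 1L)
    phased <- matrix(phased, nrow(a1), ncol(a1))
  stopifnot(identical(dim(phased), dim(a1)))
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  colnames(a1) <- colnames(a2) <- colnames(phased) <- samples
  structure(list(samples = samples, a1 = a1, a2 = a2, phased = phased),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d sites x %d samples (%.1f%% phased, %.2f%% missing)\n",
              nrow(x$a1), length(x$samples),
              100 * mean(x$phased), 100 * mean(is.na(x$a1) | is.na(x$a2))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$a1)

n_sites <- function(g) nrow(g$a1)

#' Subset a genotype matrix
#'
#' @param g A [geno_matrix].
#' @param sites Row (site) index.
#' @param samples Sample names or column index.
#' @return A `geno_matrix` restricted to the requested sites/samples.
#' @export
subset_geno <- function(g, sites = NULL, samples = NULL) {
  if (is.null(sites)) sites <- seq_len(nrow(g$a1))
  if (is.null(samples)) samples <- g$samples
  if (is.character(samples)) {
    miss <- setdiff(samples, g$samples)
    if (length(miss)) stop("unknown sample(s): ", paste(miss, collapse = ", "))
  }
  geno_matrix(g$a1[sites, samples, drop = FALSE],
              g$a2[sites, samples, drop = FALSE],
              g$phased[sites, samples, drop = FALSE])
}

#' Haplotype view of a phased genotype matrix
#'
#' Returns the haplotype matrix (haplotypes x sites) underlying a phased
#' genotype matrix. Defined only where every queried genotype is phased and
#' non-missing; anything else is an error, because an unphased genotype has
#' no meaningful haplotype decomposition.
#'
#' @param g A [geno_matrix].
#' @param sites Optional site (row) index.
#' @param samples Optional sample subset.
#' @return Integer matrix with `2 * n_samples` rows (sample haplotypes in
#'   order `<sample>_1`, `<sample>_2`) and one column per site.
#' @export
hap_matrix <- function(g, sites = NULL, samples = NULL) {
  g <- subset_geno(g, sites, samples)
  if (anyNA(g$a1) || anyNA(g$a2))
    stop("haplotype view undefined: missing genotypes in the queried block")
  if (!all(g$phased))
    stop("haplotype view undefined: unphased genotypes in the queried block")
  h <- rbind(t(g$a1), t(g$a2))
  ord <- as.vector(rbind(seq_along(g$samples),
                         seq_along(g$samples) + length(g$samples)))
  h <- h[ord, , drop = FALSE]
  rownames(h) <- paste(rep(g$samples, each = 2), 1:2, sep = "_")
  h
}

#' Pedigree and phenotype table
#'
#' Validates a 6-column pedigree (family, individual, sire, dam, sex,
#' phenotype) and returns it with class `pedigree`. Phenotype coding follows
#' the PED convention: 1 = unaffected, 2 = affected, 0/-9 = missing. The
#' affected samples form the case group and the unaffected samples the
#' control group; the two are disjoint by construction.
#'
#' @param df A data.frame with columns `fam`, `id`, `sire`, `dam`, `sex`,
#'   `phenotype` (aliases `family`/`individual` accepted).
#' @return A `pedigree` data.frame.
#' @export
pedigree <- function(df) {
  names(df)[names(df) == "family"] <- "fam"
  names(df)[names(df) == "individual"] <- "id"
  need <- c("fam", "id", "sire", "dam", "sex", "phenotype")
  if (!all(need %in% names(df)))
    stop("pedigree requires columns: ", paste(need, collapse = ", "))
  df <- df[need]
  df$id <- as.character(df$id)
  df$sire <- as.character(df$sire); df$dam <- as.character(df$dam)
  df$phenotype <- as.integer(df$phenotype)
  df$phenotype[df$phenotype %in% c(-9L)] <- 0L
  if (anyDuplicated(df$id))
    stop("duplicate sample id in pedigree: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  class(df) <- c("pedigree", "data.frame")
  df
}

#' @rdname pedigree
#' @param ped A `pedigree`.
#' @export
case_ids <- function(ped) ped$id[ped$phenotype == 2L]

#' @rdname pedigree
#' @export
control_ids <- function(ped) ped$id[ped$phenotype == 1L]

# split a geno_matrix into case/control sub-matrices restricted to samples
# present in both the genotypes and the pedigree
split_groups <- function(g, ped) {
  cases <- intersect(case_ids(ped), g$samples)
  controls <- intersect(control_ids(ped), g$samples)
  if (!length(cases) || !length(controls))
    stop("need at least one genotyped case and one genotyped control")
  list(case = subset_geno(g, samples = cases),
       control = subset_geno(g, samples = controls))
}
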