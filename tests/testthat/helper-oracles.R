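# Independent oracles used across the suite. These deliberately re-derive
# each statistic from its definition, on a different code path from the
# package implementation.

# Weir & Cockerham (1984) variance components, general-r formulation,
# from a list of (individuals x 2) allele-code matrices, one per population
wc_oracle <- function(geno_list) {
  clean <- lapply(geno_list, function(m) m[!is.na(m[, 1]) & !is.na(m[, 2]), ,
                                           drop = FALSE])
  r <- length(clean)
  n <- vapply(clean, nrow, 0L)
  p <- vapply(clean, function(m) mean(c(m[, 1], m[, 2])), 0)
  h <- vapply(clean, function(m) mean(m[, 1] != m[, 2]), 0)
  nbar <- mean(n)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / sum(n)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) *
       (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc,
       fst = if (a + b + cc == 0) NA_real_ else a / (a + b + cc))
}

# closed-form allelic chi-square n(ad - bc)^2 / (row and column products)
chisq_closed_form <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# EHH by brute-force pair enumeration: fraction of haplotype pairs
# identical at every column from just outside the core to marker j
ehh_pairs_oracle <- function(hap, core, j) {
  n <- nrow(hap)
  cols <- if (j > core) (core + 1):j else if (j < core) j:(core - 1)
    else integer()
  same <- 0L
  for (x in 1:(n - 1)) for (y in (x + 1):n) {
    if (length(cols) == 0 || all(hap[x, cols] == hap[y, cols]))
      same <- same + 1L
  }
  same / choose(n, 2)
}

# trapezoid on a dense grid by linear interpolation of the EHH curve
ihh_grid_oracle <- function(curve, step = 0.01) {
  if (nrow(curve) < 2) return(0)
  xs <- seq(min(curve$dist), max(curve$dist), by = step)
  ys <- stats::approx(curve$dist, curve$ehh, xout = xs)$y
  sum((utils::head(ys, -1) + utils::tail(ys, -1)) / 2 * diff(xs))
}

# random two-group diploid genotype configuration for FST checks
random_config <- function(min_n = 2, max_n = 15) {
  repeat {
    n1 <- sample(min_n:max_n, 1); n2 <- sample(min_n:max_n, 1)
    p1 <- runif(1); p2 <- runif(1)
    g1 <- matrix(rbinom(2 * n1, 1, p1), ncol = 2)
    g2 <- matrix(rbinom(2 * n2, 1, p2), ncol = 2)
    if (sum(g1) + sum(g2) > 0 && sum(g1) + sum(g2) < 2 * (n1 + n2))
      return(list(g1 = g1, g2 = g2))
  }
}

# small genotype fixture: build variant_table + geno_matrix + pedigree from
# case/control genotype string vectors like c("1|1", "0|1")
tiny_dataset <- function(case_gts, control_gts, pos = NULL,
                         ref = "A", alt = "G", chrom = "chr1") {
  ns <- length(case_gts[[1]]) + length(control_gts[[1]])
  S <- length(case_gts)
  if (is.null(pos)) pos <- seq_len(S) * 100L
  allg <- lapply(seq_len(S), function(i) c(case_gts[[i]], control_gts[[i]]))
  a1 <- t(vapply(allg, function(r) suppressWarnings(
    as.integer(sub("[|/].*$", "", r))), integer(ns)))
  a2 <- t(vapply(allg, function(r) suppressWarnings(
    as.integer(sub("^.*[|/]", "", r))), integer(ns)))
  phased <- t(vapply(allg, function(r) grepl("|", r, fixed = TRUE),
                     logical(ns)))
  nc <- length(case_gts[[1]])
  samples <- c(paste0("case", seq_len(nc)), paste0("ctrl", seq_len(ns - nc)))
  v <- variant_table(data.frame(chrom = chrom, pos = pos,
                                ref = rep_len(ref, S), alt = rep_len(alt, S)))
  ped <- pedigree(data.frame(fam = "F", id = samples, sire = "0", dam = "0",
                             sex = 0, phenotype = rep(c(2L, 1L),
                                                      c(nc, ns - nc))))
  list(variants = v,
       genotypes = geno_matrix(a1, a2, phased, samples),
       pedigree = ped)
}

# published top-SNP genotyping table shipped with the package
top_snps_path <- function() {
  system.file("extdata", "ppd_top_snps.tsv", package = "ppdscan")
}
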