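#' Weir-Cockerham variance components for one site
#'
#' Two-population diploid estimator of population differentiation built from
#' the among-population (`a`), among-individual-within-population (`b`) and
#' within-individual (`c`) variance components, using observed heterozygote
#' proportions. Missing genotypes are excluded from that site's counts.
#' `fst = a / (a + b + c)`, undefined (NA) when the pooled sample is
#' monomorphic (`a + b + c == 0`). Negative estimates are reported as
#' computed, not clamped.
#'
#' @param case_gt,control_gt Two-column integer matrices (individuals x 2) of
#'   allele codes 0/1, `NA` for missing; or a [geno_matrix] row split done by
#'   the caller.
#' @return A list with `a`, `b`, `c`, `fst`, `n_case`, `n_control`.
#' @export
wc_fst_site <- function(case_gt, control_gt) {
  comp <- wc_components(
    gcount(case_gt[, 1], case_gt[, 2]),
    gcount(control_gt[, 1], control_gt[, 2]))
  d <- comp$a + comp$b + comp$c
  list(a = comp$a, b = comp$b, c = comp$c,
       fst = ifelse(is.finite(d) & d != 0, comp$a / d, NA_real_),
       n_case = comp$n1, n_control = comp$n2)
}

# per-group summary: n individuals, alt-allele freq, het proportion
gcount <- function(a1, a2) {
  ok <- !is.na(a1) & !is.na(a2)
  n <- sum(ok)
  list(n = n,
       p = if (n) sum(a1[ok] + a2[ok]) / (2 * n) else NA_real_,
       h = if (n) mean(a1[ok] != a2[ok]) else NA_real_)
}

# vectorised Weir-Cockerham (1984) components for two populations (r = 2)
wc_components <- function(g1, g2) {
  n1 <- g1$n; n2 <- g2$n; p1 <- g1$p; p2 <- g2$p; h1 <- g1$h; h2 <- g2$h
  N <- n1 + n2
  nbar <- N / 2
  nc <- N - (n1^2 + n2^2) / N            # (r-1) = 1
  pbar <- (n1 * p1 + n2 * p2) / N
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  hbar <- (n1 * h1 + n2 * h2) / N
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - s2 / 2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  bad <- !is.finite(a) | n1 < 1 | n2 < 1 | nbar <= 1
  a[bad] <- NA_real_; b[bad] <- NA_real_; cc[bad] <- NA_real_
  list(a = a, b = b, c = cc, n1 = n1, n2 = n2)
}

#' Per-site F_ST scan between cases and controls
#'
#' Applies the Weir-Cockerham estimator at every site on the bi-allelic
#' projection (sites with more than two observed alleles are reduced to
#' reference vs. most frequent alternate; INDELs are treated as bi-allelic
#' presence/absence of the alternate). Sites where either group is entirely
#' missing are skipped with a reason recorded in the `skipped` attribute.
#'
#' @param variants A [variant_table].
#' @param genotypes Matching [geno_matrix].
#' @param ped A [pedigree] defining case (affected) and control (unaffected)
#'   groups.
#' @return Data.frame `chrom, pos, a, b, c, d, fst` (`d = a+b+c`), one row
#'   per usable site, with skipped sites in `attr(, "skipped")`.
#' @export
fst_scan <- function(variants, genotypes, ped) {
  stopifnot(nrow(variants) == nrow(genotypes$a1))
  gr <- split_groups(project_biallelic(genotypes), ped)
  g1 <- list(n = rowSums(!is.na(gr$case$a1) & !is.na(gr$case$a2)))
  g2 <- list(n = rowSums(!is.na(gr$control$a1) & !is.na(gr$control$a2)))
  sum_ok <- function(m1, m2) {
    x <- m1 + m2; x[is.na(x)] <- 0L; rowSums(x)
  }
  g1$p <- ifelse(g1$n > 0, sum_ok(gr$case$a1, gr$case$a2) / (2 * g1$n), NA)
  g2$p <- ifelse(g2$n > 0, sum_ok(gr$control$a1, gr$control$a2) / (2 * g2$n), NA)
  het <- function(g) {
    x <- (g$a1 != g$a2); x[is.na(x)] <- FALSE; rowSums(x)
  }
  g1$h <- ifelse(g1$n > 0, het(gr$case) / g1$n, NA)
  g2$h <- ifelse(g2$n > 0, het(gr$control) / g2$n, NA)
  comp <- wc_components(g1, g2)
  d <- comp$a + comp$b + comp$c
  out <- data.frame(chrom = variants$chrom, pos = variants$pos,
                    a = comp$a, b = comp$b, c = comp$c, d = d,
                    fst = ifelse(is.finite(d) & d != 0, comp$a / d, NA_real_))
  usable <- g1$n >= 1 & g2$n >= 1
  skipped <- data.frame(chrom = variants$chrom[!usable],
                        pos = variants$pos[!usable],
                        reason = rep("group entirely missing", sum(!usable)))
  out <- out[usable, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Windowed weighted F_ST
#'
#' Aggregates per-site variance components into sliding windows (default
#' 10 kb span, 2 kb step, anchored at position 1 of each chromosome).
#' The weighted statistic is the ratio of sums,
#' `sum(a) / sum(a + b + c)`, over all sites in the window with defined
#' components; `mean_fst` is the unweighted mean of per-site ratios.
#' Windows with no usable site are emitted with `NA` statistics.
#'
#' @param site_fsts Output of [fst_scan()] (coordinate-sorted).
#' @param span_bp,step_bp Window span and slide step in bp; span must be a
#'   multiple of (or at least no smaller than) the step.
#' @param chrom_lengths Optional named vector giving the full extent of each
#'   chromosome; defaults to the last site position.
#' @return Data.frame `CHROM, BIN_START, BIN_END, N_VARIANTS, WEIGHTED_FST,
#'   MEAN_FST`.
#' @export
fst_windows <- function(site_fsts, span_bp = 10000L, step_bp = 2000L,
                        chrom_lengths = NULL) {
  if (span_bp < step_bp) stop("window span must be >= step")
  res <- list()
  for (chr in unique(site_fsts$chrom)) {
    s <- site_fsts[site_fsts$chrom == chr, , drop = FALSE]
    len <- if (!is.null(chrom_lengths) && chr %in% names(chrom_lengths))
      chrom_lengths[[chr]] else max(s$pos)
    grid <- window_grid(len, span_bp, step_bp)
    nw <- nrow(grid)
    ok <- is.finite(s$d) & s$d != 0
    s <- s[ok, , drop = FALSE]
    A <- numeric(nw); D <- numeric(nw); Fs <- numeric(nw); n <- integer(nw)
    rng <- window_index_range(s$pos, span_bp, step_bp)
    for (i in seq_len(nrow(s))) {
      ks <- seq.int(rng$lo[i], min(rng$hi[i], nw - 1L)) + 1L
      A[ks] <- A[ks] + s$a[i]
      D[ks] <- D[ks] + s$d[i]
      Fs[ks] <- Fs[ks] + s$a[i] / s$d[i]
      n[ks] <- n[ks] + 1L
    }
    res[[chr]] <- data.frame(
      CHROM = chr, BIN_START = grid$start, BIN_END = grid$end,
      N_VARIANTS = n,
      WEIGHTED_FST = ifelse(n > 0 & D != 0, A / D, NA_real_),
      MEAN_FST = ifelse(n > 0, Fs / n, NA_real_))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Select highly differentiated windows
#'
#' Keeps windows with weighted F_ST strictly above `min_weighted_fst` and at
#' least `min_variants` usable variants (`>` on the statistic, `>=` on the
#' count, as the screening rule is stated).
#'
#' @param windows Output of [fst_windows()].
#' @param min_weighted_fst Weighted F_ST threshold (strict).
#' @param min_variants Minimum variant count (inclusive).
#' @return The passing windows; merged passing regions (overlapping windows
#'   collapsed) in `attr(, "regions")`.
#' @export
filter_fst_windows <- function(windows, min_weighted_fst = 0.6,
                               min_variants = 10L) {
  keep <- !is.na(windows$WEIGHTED_FST) &
    windows$WEIGHTED_FST > min_weighted_fst &
    windows$N_VARIANTS >= min_variants
  out <- windows[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "regions") <- merge_intervals(
    data.frame(chrom = out$CHROM, start = out$BIN_START, end = out$BIN_END))
  out
}
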