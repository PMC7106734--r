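# internal helpers shared across stages

# sliding-window grid anchored at position 1 of each chromosome.
# windows are 1-based inclusive [start, start + span - 1].
window_grid <- function(max_pos, span_bp, step_bp) {
  if (span_bp < step_bp) stop("window span must be >= step")
  starts <- seq.int(1L, max(1L, max_pos), by = step_bp)
  # drop trailing windows that start past the last position
  starts <- starts[starts <= max_pos]
  data.frame(start = starts, end = starts + span_bp - 1L)
}

# indices of windows (0-based k, start = k*step + 1) containing a position
window_index_range <- function(pos, span_bp, step_bp) {
  lo <- ceiling((pos - span_bp) / step_bp)
  lo <- pmax(0, lo)
  hi <- (pos - 1) %/% step_bp
  list(lo = lo, hi = hi)
}

# merge overlapping or bookended 1-based inclusive intervals per chromosome
merge_intervals <- function(df) {
  if (!nrow(df)) {
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  }
  out <- lapply(split(df, df$chrom), function(d) {
    d <- d[order(d$start, d$end), , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(d$start, d$end))
    data.frame(chrom = d$chrom[1], start = IRanges::start(ir),
               end = IRanges::end(ir))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

# TRUE where [s1,e1] on c1 overlaps any interval in (c2,s2,e2)
overlaps_any <- function(chrom, start, end, regions) {
  if (!nrow(regions)) return(rep(FALSE, length(start)))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  s <- GenomicRanges::GRanges(regions$chrom,
                              IRanges::IRanges(regions$start, regions$end))
  IRanges::overlapsAny(q, s)
}

# deterministic per-stage substream seed derived from the master seed;
# kept well below 2^31
stage_seed <- function(seed, stage) {
  offs <- c(positions = 101L, founders = 211L, drop = 307L, qc = 401L,
            missing = 503L, sequence = 601L, phenotype = 701L)
  if (!stage %in% names(offs)) stop("unknown RNG stage: ", stage)
  (as.integer(seed) %% 20000000L) * 100L + offs[[stage]]
}

# bi-allelic projection of a (possibly multi-allelic) genotype matrix:
# the most frequent non-reference allele at each site becomes allele 1,
# any other alternate allele is set to missing for that genotype.
project_biallelic <- function(g) {
  a1 <- g$a1; a2 <- g$a2
  mx <- pmax(max(a1, na.rm = TRUE), max(a2, na.rm = TRUE), 1L)
  if (mx <= 1L) return(g)
  for (i in seq_len(nrow(a1))) {
    r1 <- a1[i, ]; r2 <- a2[i, ]
    alts <- c(r1[!is.na(r1) & r1 > 0L], r2[!is.na(r2) & r2 > 0L])
    if (!length(alts)) next
    if (max(alts) <= 1L) next
    keep <- as.integer(names(which.max(table(alts))))
    drop1 <- !is.na(r1) & r1 > 0L & r1 != keep
    drop2 <- !is.na(r2) & r2 > 0L & r2 != keep
    bad <- drop1 | drop2
    r1[bad] <- NA_integer_; r2[bad] <- NA_integer_
    r1[!is.na(r1) & r1 == keep] <- 1L
    r2[!is.na(r2) & r2 == keep] <- 1L
    a1[i, ] <- r1; a2[i, ] <- r2
  }
  geno_matrix(a1, a2, g$phased, g$samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
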