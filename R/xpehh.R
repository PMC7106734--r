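#' Extended haplotype homozygosity along one flank
#'
#' EHH at a marker x is the probability that two haplotypes drawn at random
#' from the panel are identical at every site from the core out to x:
#' `EHH(x) = sum_h C(n_h, 2) / C(n, 2)` over the extended-haplotype classes
#' h at x. At the core itself EHH = 1 (the core allele does not partition
#' the panel). The walk truncates at the first marker where EHH drops below
#' `cutoff` (that marker is kept as the curve's last point); if the panel
#' runs off the supplied interval while still above the cutoff the curve is
#' flagged `edge = TRUE`.
#'
#' @param haplotypes Integer matrix, haplotypes x sites, phased and
#'   non-missing.
#' @param core_index Column index of the core site.
#' @param positions Physical positions (bp) of the columns.
#' @param direction `"right"` (increasing positions) or `"left"`.
#' @param cutoff Truncation threshold on EHH (default 0.05).
#' @param max_extend_bp Maximal extension of the walk from the core (bp);
#'   markers beyond it are not visited. In cohorts of close relatives EHH
#'   can plateau above the cutoff over chromosome-scale identical-by-descent
#'   segments, so scans bound the walk (the same device other EHH tools
#'   expose as a maximal extension). Default unbounded for curve inspection.
#' @return Data.frame `pos, dist, ehh` starting at the core, with attributes
#'   `truncated` and `edge`.
#' @export
ehh <- function(haplotypes, core_index, positions,
                direction = c("right", "left"), cutoff = 0.05,
                max_extend_bp = Inf) {
  direction <- match.arg(direction)
  n <- nrow(haplotypes)
  if (n < 2L) stop("EHH undefined for fewer than 2 haplotypes")
  if (anyNA(haplotypes)) stop("EHH requires non-missing haplotypes")
  S <- ncol(haplotypes)
  dir <- if (direction == "right") 1L else -1L
  cls <- rep(1L, n)
  j <- core_index + dir
  pos <- positions[core_index]; dist <- 0; val <- 1
  truncated <- FALSE
  while (j >= 1L && j <= S) {
    if (abs(positions[j] - positions[core_index]) > max_extend_bp) {
      truncated <- TRUE
      break
    }
    cls <- match(paste(cls, haplotypes[, j]), unique(paste(cls, haplotypes[, j])))
    cnt <- tabulate(cls)
    e <- sum(cnt * (cnt - 1)) / (n * (n - 1))
    pos <- c(pos, positions[j])
    dist <- c(dist, abs(positions[j] - positions[core_index]))
    val <- c(val, e)
    if (e < cutoff || e == 0) { truncated <- TRUE; break }
    j <- j + dir
  }
  structure(data.frame(pos = pos, dist = dist, ehh = val),
            truncated = truncated, edge = !truncated)
}

#' Integrated EHH of one flank
#'
#' Trapezoidal integral of the EHH curve against physical distance (bp)
#' from the core, over the (already truncated) curve. A zero-length flank
#' contributes 0.
#'
#' @param curve Output of [ehh()].
#' @return The flank area in EHH x bp units.
#' @export
ihh <- function(curve) {
  if (nrow(curve) < 2L) return(0)
  sum(diff(curve$dist) * (utils::head(curve$ehh, -1) + utils::tail(curve$ehh, -1)) / 2)
}

#' Cross-population EHH scan
#'
#' For every scanned SNP, integrates EHH over both flanks separately in the
#' case (affected) and control (unaffected) haplotype panels and reports
#' `raw = ln(iHH_case / iHH_control)` — positive where the affected group
#' carries unusually long shared haplotypes — and the genome-standardised
#' score `normalized = (raw - mean) / sd`, with the mean and SD taken over
#' all scored sites that did not hit a chromosome edge before decaying below
#' the EHH cutoff (those are flagged `edge_truncated` and excluded from the
#' normalisation statistics). Sites with `iHH_control = 0` or
#' `iHH_case = 0` are skipped and recorded in the `skipped` attribute.
#'
#' Only phased, non-missing SNP genotypes can be scanned; sites violating
#' this are excluded from the scan (and therefore also as flank markers).
#'
#' @param variants A [variant_table] (SNP rows are scanned).
#' @param genotypes Matching [geno_matrix].
#' @param ped A [pedigree].
#' @param cutoff EHH truncation threshold (default 0.05).
#' @param max_extend_bp Maximal EHH walk extension from the core (bp),
#'   see [ehh()]; default 200 kb.
#' @return Data.frame `CHROM, POS, IHH_CASE, IHH_CONTROL, RAW, NORMALIZED,
#'   FLAGS`, with skipped sites in `attr(, "skipped")`.
#' @export
xpehh_scan <- function(variants, genotypes, ped, cutoff = 0.05,
                       max_extend_bp = 200000) {
  stopifnot(nrow(variants) == nrow(genotypes$a1))
  g <- project_biallelic(genotypes)
  complete <- !rowSums(is.na(g$a1) | is.na(g$a2) | !g$phased)
  use <- variants$vclass == "SNP" & complete
  res <- list()
  skipped <- list()
  for (chr in unique(variants$chrom[use])) {
    idx <- which(use & variants$chrom == chr)
    if (length(idx) < 2L) next
    pos <- variants$pos[idx]
    hc <- hap_matrix(g, sites = idx, samples = intersect(case_ids(ped), g$samples))
    hu <- hap_matrix(g, sites = idx, samples = intersect(control_ids(ped), g$samples))
    if (nrow(hc) < 2L || nrow(hu) < 2L)
      stop("XP-EHH needs at least 2 haplotypes per group")
    m <- cpp_xpehh_ihh(hc, hu, as.numeric(pos), cutoff, max_extend_bp)
    ok <- m[, 1] > 0 & m[, 2] > 0
    raw <- ifelse(ok, log(m[, 1] / m[, 2]), NA_real_)
    edge <- (m[, 3] > 0) | (m[, 4] > 0)
    res[[chr]] <- data.frame(
      CHROM = chr, POS = pos, IHH_CASE = m[, 1], IHH_CONTROL = m[, 2],
      RAW = raw, FLAGS = ifelse(edge, "edge_truncated", ""))[ok, , drop = FALSE]
    if (any(!ok))
      skipped[[chr]] <- data.frame(CHROM = chr, POS = pos[!ok],
                                   reason = "zero iHH in a group")
  }
  out <- do.call(rbind, res) %||%
    data.frame(CHROM = character(), POS = integer(), IHH_CASE = numeric(),
               IHH_CONTROL = numeric(), RAW = numeric(), FLAGS = character())
  rownames(out) <- NULL
  norm_set <- out$FLAGS == ""
  if (sum(norm_set) >= 2L) {
    mu <- mean(out$RAW[norm_set]); sd <- stats::sd(out$RAW[norm_set])
    out$NORMALIZED <- if (sd > 0) (out$RAW - mu) / sd else 0
  } else out$NORMALIZED <- NA_real_
  out <- out[c("CHROM", "POS", "IHH_CASE", "IHH_CONTROL", "RAW",
               "NORMALIZED", "FLAGS")]
  attr(out, "skipped") <- do.call(rbind, skipped) %||%
    data.frame(CHROM = character(), POS = integer(), reason = character())
  out
}

#' Call candidate regions from XP-EHH scores
#'
#' Slides the standard window grid over the normalised scores and keeps
#' windows whose mean normalised XP-EHH is strictly greater than
#' `threshold`; overlapping passing windows are merged into regions.
#' Edge-flagged sites do not contribute to window means.
#'
#' @param scores Output of [xpehh_scan()].
#' @param span_bp,step_bp Window span and step (default 10 kb / 2 kb).
#' @param threshold Mean normalised score threshold (strict, default 2).
#' @param chrom_lengths Optional named chromosome lengths.
#' @return Data.frame of merged regions `chrom, start, end`; the passing
#'   windows are in `attr(, "windows")`.
#' @export
call_xpehh_regions <- function(scores, span_bp = 10000L, step_bp = 2000L,
                               threshold = 2.0, chrom_lengths = NULL) {
  if (span_bp < step_bp) stop("window span must be >= step")
  wins <- list()
  s0 <- scores[scores$FLAGS == "" & !is.na(scores$NORMALIZED), , drop = FALSE]
  for (chr in unique(s0$CHROM)) {
    s <- s0[s0$CHROM == chr, , drop = FALSE]
    len <- if (!is.null(chrom_lengths) && chr %in% names(chrom_lengths))
      chrom_lengths[[chr]] else max(s$POS)
    grid <- window_grid(len, span_bp, step_bp)
    nw <- nrow(grid)
    tot <- numeric(nw); n <- integer(nw)
    rng <- window_index_range(s$POS, span_bp, step_bp)
    for (i in seq_len(nrow(s))) {
      ks <- seq.int(rng$lo[i], min(rng$hi[i], nw - 1L)) + 1L
      tot[ks] <- tot[ks] + s$NORMALIZED[i]
      n[ks] <- n[ks] + 1L
    }
    keep <- n > 0 & (tot / n) > threshold
    if (any(keep))
      wins[[chr]] <- data.frame(CHROM = chr, BIN_START = grid$start[keep],
                                BIN_END = grid$end[keep],
                                N_SITES = n[keep],
                                MEAN_XPEHH = (tot / n)[keep])
  }
  wins <- do.call(rbind, wins) %||%
    data.frame(CHROM = character(), BIN_START = integer(), BIN_END = integer(),
               N_SITES = integer(), MEAN_XPEHH = numeric())
  rownames(wins) <- NULL
  regions <- merge_intervals(data.frame(chrom = wins$CHROM,
                                        start = wins$BIN_START,
                                        end = wins$BIN_END))
  attr(regions, "windows") <- wins
  regions
}
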