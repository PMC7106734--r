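#' Integrate evidence tracks over candidate regions and genes
#'
#' Intersects the four evidence tracks — XP-EHH regions, passing SNP F_ST
#' windows, passing INDEL F_ST windows and top-k association SNPs — by
#' genomic overlap, assigning regions to genes by interval overlap with the
#' gene model (plus an optional flank). Evidence intervals overlapping no
#' gene are reported as intergenic candidate regions. Every flag is
#' traceable to an upstream output row.
#'
#' @param xpehh_regions Regions from [call_xpehh_regions()].
#' @param fst_snp_windows Passing SNP windows from [filter_fst_windows()].
#' @param fst_indel_windows Passing INDEL windows, same shape.
#' @param assoc Association table from [assoc_scan()].
#' @param concord Concordance table from [concordance()].
#' @param annotations Annotation table from [classify_variants()], or NULL.
#' @param model A [gene_model].
#' @param top_k_assoc How many top association SNPs define the association
#'   evidence flag (default 10).
#' @param gene_flank_bp Flank added to gene intervals for evidence
#'   assignment (default 0).
#' @return An `evidence_table`: list with `candidates` (one row per
#'   candidate gene/region, flag columns and audit counts) and `variants`
#'   (per-variant association, concordance and annotation columns).
#' @export
integrate_evidence <- function(xpehh_regions, fst_snp_windows,
                               fst_indel_windows, assoc, concord,
                               annotations = NULL, model,
                               top_k_assoc = 10L, gene_flank_bp = 0L) {
  win2reg <- function(w) {
    if (is.null(w) || !nrow(w))
      return(data.frame(chrom = character(), start = integer(),
                        end = integer()))
    data.frame(chrom = w$CHROM, start = w$BIN_START, end = w$BIN_END)
  }
  xp <- if (!is.null(xpehh_regions) && nrow(xpehh_regions))
    xpehh_regions[c("chrom", "start", "end")] else win2reg(NULL)
  fs <- win2reg(fst_snp_windows)
  fi <- win2reg(fst_indel_windows)

  all_chr <- unique(c(xp$chrom, fs$chrom, fi$chrom, assoc$CHR))
  if (length(all_chr) && !is.null(model$genes) &&
      !any(all_chr %in% model$genes$chrom))
    stop("coordinate-system mismatch: no chromosome shared between ",
         "evidence tracks and the gene model")

  # per-variant table
  variants <- data.frame(chrom = assoc$CHR, pos = assoc$BP, id = assoc$SNP,
                         p = assoc$P, chisq = assoc$CHISQ)
  variants <- merge(variants,
                    data.frame(chrom = concord$chrom, pos = concord$pos,
                               concordant = concord$concordant),
                    by = c("chrom", "pos"), all.x = TRUE, sort = FALSE)
  if (!is.null(annotations)) {
    variants <- merge(variants,
                      annotations[c("chrom", "pos", "class", "gene",
                                    "aa_change")],
                      by = c("chrom", "pos"), all.x = TRUE, sort = FALSE)
  } else {
    variants$class <- rep(NA_character_, nrow(variants))
    variants$gene <- rep(NA_character_, nrow(variants))
    variants$aa_change <- rep(NA_character_, nrow(variants))
  }
  variants <- variants[order(variants$p, variants$chrom, variants$pos), ]
  rownames(variants) <- NULL
  topk <- utils::head(variants, top_k_assoc)

  genes <- model$genes
  cand <- data.frame(candidate = genes$gene_id, gene_id = genes$gene_id,
                     chrom = genes$chrom,
                     start = pmax(1L, genes$start - gene_flank_bp),
                     end = genes$end + gene_flank_bp)
  # intergenic candidate regions: merged evidence intervals hitting no gene
  ev_regions <- merge_intervals(rbind(xp, fs, fi))
  if (nrow(ev_regions)) {
    orphan <- !overlaps_any(ev_regions$chrom, ev_regions$start,
                            ev_regions$end, cand)
    if (any(orphan)) {
      o <- ev_regions[orphan, , drop = FALSE]
      cand <- rbind(cand, data.frame(
        candidate = paste0(o$chrom, ":", o$start, "-", o$end),
        gene_id = NA_character_, chrom = o$chrom, start = o$start,
        end = o$end))
    }
  }

  flag <- function(reg) overlaps_any(cand$chrom, cand$start, cand$end, reg)
  cand$xpehh_region <- flag(xp)
  cand$fst_snp_window <- flag(fs)
  cand$fst_indel_window <- flag(fi)
  inside <- function(v) v$chrom == cand$chrom[i] & v$pos >= cand$start[i] &
    v$pos <= cand$end[i]
  cand$assoc_top <- FALSE
  cand$best_assoc_p <- NA_real_
  cand$n_concordant <- 0L
  cand$has_nonsynonymous <- FALSE
  for (i in seq_len(nrow(cand))) {
    vin <- variants[inside(variants), , drop = FALSE]
    cand$assoc_top[i] <- any(inside(topk))
    if (nrow(vin)) {
      cand$best_assoc_p[i] <- min(vin$p, na.rm = TRUE)
      cand$n_concordant[i] <- sum(vin$concordant, na.rm = TRUE)
      cand$has_nonsynonymous[i] <-
        any(vin$class == "CDS_nonsynonymous", na.rm = TRUE)
    }
  }
  rownames(cand) <- NULL
  structure(list(candidates = cand, variants = variants,
                 top_k_assoc = top_k_assoc),
            class = "evidence_table")
}

#' Rank candidates and highlight putatively causal variants
#'
#' Ranks candidates by supporting-evidence count (number of the four flags
#' set, descending), then by best association p-value (ascending), then by
#' chromosome and position — a deterministic formalisation of
#' qualitative replication across evidence tracks. Variants within each
#' candidate are ranked by p. A variant is highlighted as putatively causal
#' iff it is concordant under the chosen inheritance model AND annotated
#' `CDS_nonsynonymous`; a candidate whose best variant fails concordance is
#' retained in the ranking but gets no causal flag.
#'
#' @param evidence An `evidence_table` from [integrate_evidence()].
#' @param top_k_assoc Length of the top-association listing in the report.
#' @return A `candidate_report`: list with ranked `candidates`,
#'   `top_variants` and `causal_variants`.
#' @export
rank_candidates <- function(evidence, top_k_assoc = evidence$top_k_assoc) {
  cand <- evidence$candidates
  cand$n_evidence <- cand$xpehh_region + cand$fst_snp_window +
    cand$fst_indel_window + cand$assoc_top
  ord <- order(-cand$n_evidence,
               ifelse(is.na(cand$best_assoc_p), Inf, cand$best_assoc_p),
               cand$chrom, cand$start)
  cand <- cand[ord, , drop = FALSE]
  cand$rank <- seq_len(nrow(cand))
  rownames(cand) <- NULL
  v <- evidence$variants
  causal <- v[!is.na(v$concordant) & v$concordant &
                !is.na(v$class) & v$class == "CDS_nonsynonymous", ,
              drop = FALSE]
  rownames(causal) <- NULL
  structure(list(candidates = cand,
                 top_variants = utils::head(v, top_k_assoc),
                 causal_variants = causal),
            class = "candidate_report")
}

#' @export
print.candidate_report <- function(x, ...) {
  cat("Candidate report:", nrow(x$candidates), "candidates\n")
  cols <- c("rank", "candidate", "n_evidence", "xpehh_region",
            "fst_snp_window", "fst_indel_window", "assoc_top", "best_assoc_p",
            "n_concordant", "has_nonsynonymous")
  print(utils::head(x$candidates[cols], 10L), row.names = FALSE)
  if (nrow(x$causal_variants)) {
    cat("\nPutatively causal (concordant + nonsynonymous) variants:\n")
    print(x$causal_variants[c("chrom", "pos", "id", "p", "gene",
                              "aa_change")], row.names = FALSE)
  }
  invisible(x)
}
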