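#' Variant site table
#'
#' Validates and classifies a table of variant records. Each row is one
#' bi- or multi-allelic site with 1-based coordinates, alleles, QC
#' annotations and a (possibly empty) set of failed-filter flags.
#'
#' @param df A data.frame with at least `chrom`, `pos`, `ref`, `alt`.
#'   Multi-allelic sites carry comma-separated `alt`. Optional columns:
#'   `id`, `qual`, the QC annotations `QD`, `MQ`, `FS`, `MQRankSum`,
#'   `ReadPosRankSum`, `MQ0`, `DP`, and `filter_flags`.
#' @return A `variant_table` data.frame with a `vclass` column
#'   (`"SNP"`/`"INDEL"`): a site is a SNP iff the reference and every
#'   alternate allele are single bases.
#' @export
variant_table <- function(df) {
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(df)))
    stop("variant table requires columns: ", paste(need, collapse = ", "))
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  if (any(df$pos < 1L)) stop("variant pos must be >= 1")
  if (any(!nzchar(df$ref)) || any(!nzchar(df$alt)))
    stop("ref and alt alleles must be non-empty")
  if (is.null(df$id)) df$id <- NA_character_
  if (is.null(df$qual)) df$qual <- NA_real_
  for (k in c("QD", "MQ", "FS", "MQRankSum", "ReadPosRankSum", "MQ0", "DP"))
    if (is.null(df[[k]])) df[[k]] <- NA_real_
  if (is.null(df$filter_flags)) df$filter_flags <- ""
  alts <- strsplit(df$alt, ",", fixed = TRUE)
  df$vclass <- ifelse(
    nchar(df$ref) == 1L & vapply(alts, function(a) all(nchar(a) == 1L), TRUE),
    "SNP", "INDEL")
  ord <- order(df$chrom, df$pos)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("variant_table", "data.frame")
  df
}

#' Read a phased multi-sample VCF
#'
#' Parses a VCF 4.x file (plain or gzipped) into a [variant_table] and a
#' [geno_matrix]. Records are returned in coordinate order; multi-allelic
#' sites and per-genotype phase are preserved; missing genotypes (`./.`)
#' become `NA` allele pairs and are excluded from all downstream allele
#' counts.
#'
#' @param path Path to the VCF.
#' @return A list with elements `variants` and `genotypes`.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such VCF: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("VCF parse error in ", path, ": ",
                                         conditionMessage(e)))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  df <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                   id = ifelse(fix$ID == ".", NA_character_, fix$ID),
                   ref = fix$REF, alt = fix$ALT,
                   qual = suppressWarnings(as.numeric(fix$QUAL)),
                   stringsAsFactors = FALSE)
  for (k in c("QD", "MQ", "FS", "MQRankSum", "ReadPosRankSum", "MQ0", "DP"))
    df[[k]] <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = k)))
  flt <- fix$FILTER
  df$filter_flags <- ifelse(is.na(flt) | flt %in% c(".", "PASS"), "", flt)
  variants <- variant_table(df)

  gt <- vcfR::extract.gt(v, element = "GT")
  # restore coordinate order applied by variant_table()
  ord <- order(fix$CHROM, as.integer(fix$POS))
  gt <- gt[ord, , drop = FALSE]
  gtv <- as.vector(gt)
  phased <- grepl("|", gtv, fixed = TRUE)
  parts <- strsplit(gtv, "[|/]")
  pick <- function(i) {
    x <- vapply(parts, function(p) if (length(p) >= i) p[i] else NA_character_, "")
    suppressWarnings(as.integer(x))
  }
  n <- nrow(gt)
  a1 <- matrix(pick(1L), n); a2 <- matrix(pick(2L), n)
  bad <- is.na(a1) | is.na(a2)
  a1[bad] <- NA_integer_; a2[bad] <- NA_integer_
  nalt <- lengths(strsplit(variants$alt, ",", fixed = TRUE))
  mxa <- suppressWarnings(pmax(apply(a1, 1, max, na.rm = TRUE),
                               apply(a2, 1, max, na.rm = TRUE)))
  if (any(mxa > nalt, na.rm = TRUE))
    stop("VCF genotype allele index exceeds the number of ALT alleles")
  genotypes <- geno_matrix(a1, a2, matrix(phased, n), colnames(gt))
  list(variants = variants, genotypes = genotypes)
}

#' Write a phased multi-sample VCF
#'
#' @param variants A [variant_table].
#' @param genotypes A [geno_matrix] with one row per variant.
#' @param path Output path.
#' @param contig_lengths Optional named vector of chromosome lengths for the
#'   header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, genotypes, path, contig_lengths = NULL) {
  stopifnot(nrow(variants) == nrow(genotypes$a1))
  info_keys <- c(QD = "Variant Confidence/Quality by Depth",
                 MQ = "RMS Mapping Quality",
                 FS = "Phred-scaled p-value using Fisher's exact test to detect strand bias",
                 MQRankSum = "Z-score from Wilcoxon rank sum test of Alt vs. Ref read mapping qualities",
                 ReadPosRankSum = "Z-score from Wilcoxon rank sum test of Alt vs. Ref read position bias",
                 MQ0 = "Total Mapping Quality Zero Reads",
                 DP = "Approximate read depth")
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##INFO=<ID=%s,Number=1,Type=%s,Description=\"%s\">",
                   names(info_keys),
                   ifelse(names(info_keys) %in% c("MQ0", "DP"), "Integer", "Float"),
                   info_keys),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  if (!is.null(contig_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), as.integer(contig_lengths)))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", genotypes$samples), collapse = "\t"))
  fmt_num <- function(x) ifelse(is.na(x), NA, formatC(x, format = "g", digits = 6))
  info <- vapply(seq_len(nrow(variants)), function(i) {
    vals <- c(QD = fmt_num(variants$QD[i]), MQ = fmt_num(variants$MQ[i]),
              FS = fmt_num(variants$FS[i]),
              MQRankSum = fmt_num(variants$MQRankSum[i]),
              ReadPosRankSum = fmt_num(variants$ReadPosRankSum[i]),
              MQ0 = ifelse(is.na(variants$MQ0[i]), NA,
                           format(as.integer(variants$MQ0[i]))),
              DP = ifelse(is.na(variants$DP[i]), NA,
                          format(as.integer(variants$DP[i]))))
    vals <- vals[!is.na(vals)]
    if (!length(vals)) "." else paste(names(vals), vals, sep = "=", collapse = ";")
  }, "")
  sep <- ifelse(genotypes$phased, "|", "/")
  gs <- function(a) ifelse(is.na(a), ".", as.character(a))
  gt <- matrix(paste0(gs(genotypes$a1), sep, gs(genotypes$a2)),
               nrow(genotypes$a1))
  body <- paste(variants$chrom, variants$pos,
                ifelse(is.na(variants$id), ".", variants$id),
                variants$ref, variants$alt,
                ifelse(is.na(variants$qual), ".", fmt_num(variants$qual)),
                ifelse(nzchar(variants$filter_flags), variants$filter_flags, "PASS"),
                info, "GT",
                apply(gt, 1, paste, collapse = "\t"),
                sep = "\t")
  con <- file(path, "wb")  # binary mode: byte-identical output across platforms
  on.exit(close(con))
  writeLines(c(hdr, body), con, sep = "\n")
  invisible(path)
}

# ---- hard filters -----------------------------------------------------------

make_clause <- function(name, fun) list(name = name, fun = fun)

# comparison where a missing annotation means "clause not evaluated"
cmp <- function(x, op, thr) {
  r <- switch(op, "<=" = x <= thr, "<" = x < thr, ">=" = x >= thr,
              ">" = x > thr, stop("bad operator ", op))
  r & !is.na(r)
}

#' Hard-filter definitions
#'
#' Returns the per-clause hard-filter set applied by [apply_hard_filters()].
#' The SNP expression is
#' `QUAL <= 40.0 || QD <= 2.0 || MQ <= 40.0 || FS >= 60.0 ||
#'  MQRankSum <= -12.5 || ReadPosRankSum < -8.0 ||
#'  (MQ0 >= 4 & MQ0/DP > 0.1)`
#' and the INDEL expression `QD < 2.0 || FS > 200.0 || ReadPosRankSum < -20.0`.
#' Operators are inclusive/exclusive exactly as written; a record missing the
#' annotation used by a clause skips that clause (the behaviour of the
#' variant-filtration tool whose expression syntax these rules follow).
#' Thresholds and operators can be overridden to build a custom filter set.
#'
#' @param mode `"SNP"` or `"INDEL"`.
#' @param overrides Named list: `list(QD = list(op = "<=", value = 2))`-style
#'   replacements for single-annotation clauses.
#' @return List of clauses, each `list(name=, fun=)`.
#' @export
default_hard_filters <- function(mode = c("SNP", "INDEL"), overrides = list()) {
  mode <- match.arg(mode)
  spec <- if (mode == "SNP") {
    list(QUAL = list(op = "<=", value = 40),
         QD = list(op = "<=", value = 2),
         MQ = list(op = "<=", value = 40),
         FS = list(op = ">=", value = 60),
         MQRankSum = list(op = "<=", value = -12.5),
         ReadPosRankSum = list(op = "<", value = -8))
  } else {
    list(QD = list(op = "<", value = 2),
         FS = list(op = ">", value = 200),
         ReadPosRankSum = list(op = "<", value = -20))
  }
  for (k in names(overrides)) spec[[k]] <- overrides[[k]]
  clauses <- lapply(names(spec), function(k) {
    s <- spec[[k]]
    field <- if (k == "QUAL") "qual" else k
    make_clause(k, local({
      f <- field; o <- s$op; v <- s$value
      function(df) cmp(df[[f]], o, v)
    }))
  })
  if (mode == "SNP")
    clauses <- c(clauses, list(make_clause("MQ0DP", function(df)
      cmp(df$MQ0, ">=", 4) & cmp(df$MQ0 / (1.0 * df$DP), ">", 0.1))))
  clauses
}

#' Apply hard filters to variant records
#'
#' Evaluates each filter clause independently and records the set of failed
#' clause names in `filter_flags` (semicolon-separated); a record with an
#' empty set passes. Existing flags are replaced.
#'
#' @param variants A [variant_table].
#' @param mode `"SNP"` or `"INDEL"`: which printed filter expression to apply.
#' @param filters Clause list, by default [default_hard_filters()] for `mode`.
#' @return The `variant_table` with updated `filter_flags`.
#' @export
apply_hard_filters <- function(variants, mode = c("SNP", "INDEL"),
                               filters = default_hard_filters(mode)) {
  mode <- match.arg(mode)
  fails <- vapply(filters, function(cl) cl$fun(variants),
                  logical(nrow(variants)))
  if (nrow(variants) == 1L) fails <- matrix(fails, nrow = 1L)
  nm <- vapply(filters, `[[`, "", "name")
  variants$filter_flags <- apply(fails, 1L, function(r)
    paste(nm[r], collapse = ";"))
  variants
}

#' Flag SNP clusters
#'
#' Flags every SNP lying in any window of `window_bp` consecutive bases that
#' contains at least `min_snps` SNPs (a variant-calling artifact heuristic;
#' default 3 SNPs in 10 bp). The flag `"SnpCluster"` is appended to
#' `filter_flags`. INDEL records are never flagged and do not count towards
#' clusters.
#'
#' @param variants A coordinate-sorted [variant_table].
#' @param window_bp Window width in bp.
#' @param min_snps Minimum SNP count for a cluster.
#' @return The `variant_table` with cluster flags appended.
#' @export
snp_cluster_filter <- function(variants, window_bp = 10L, min_snps = 3L) {
  flag <- rep(FALSE, nrow(variants))
  snp_i <- which(variants$vclass == "SNP")
  for (chr in unique(variants$chrom[snp_i])) {
    idx <- snp_i[variants$chrom[snp_i] == chr]
    pos <- variants$pos[idx]
    if (is.unsorted(pos)) stop("records must be coordinate-sorted")
    n <- length(pos)
    j <- 1L
    for (i in seq_len(n)) {
      if (j < i) j <- i
      while (j < n && pos[j + 1L] - pos[i] <= window_bp - 1L) j <- j + 1L
      if (j - i + 1L >= min_snps) flag[idx[i:j]] <- TRUE
    }
  }
  add <- flag & !grepl("\\bSnpCluster\\b", variants$filter_flags)
  variants$filter_flags[add] <- ifelse(
    nzchar(variants$filter_flags[add]),
    paste0(variants$filter_flags[add], ";SnpCluster"), "SnpCluster")
  variants
}

#' Keep only records passing all filters
#'
#' @param variants A [variant_table].
#' @return The subset with empty `filter_flags`.
#' @export
passing_variants <- function(variants) {
  out <- variants[!nzchar(variants$filter_flags), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- pedigree / gene model I/O ---------------------------------------------

#' Read a PED-like phenotype file
#'
#' Six whitespace-separated columns: family, individual, sire, dam, sex,
#' phenotype (1 = unaffected, 2 = affected, 0 = missing).
#'
#' @param path Path to the file (plain or gzipped).
#' @return A [pedigree].
#' @export
read_pedigree <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("fam", "id", "sire", "dam", "sex",
                                        "phenotype"))
  pedigree(df)
}

#' @rdname read_pedigree
#' @param ped A [pedigree] to write.
#' @export
write_pedigree <- function(ped, path) {
  con <- file(path, "wb"); on.exit(close(con))
  writeLines(apply(as.data.frame(ped), 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Gene model
#'
#' Builds a validated gene model from a feature table. When a gene has
#' several transcripts the one with the longest total CDS is used (and
#' recorded in the `transcript` column of `$genes`). Per chosen transcript
#' the total CDS length must be divisible by 3 and every CDS interval must
#' lie inside an exon. UTR intervals are derived as exon minus CDS.
#'
#' @param features A data.frame with columns `gene_id`, `transcript_id`,
#'   `type` (`"exon"`/`"CDS"`), `chrom`, `strand` (`"+"`/`"-"`), `start`,
#'   `end` (1-based inclusive).
#' @return A `gene_model` list with `genes`, `exons`, `cds`, `utr`
#'   data.frames (exons/cds/utr restricted to the chosen transcript).
#' @export
gene_model <- function(features) {
  need <- c("gene_id", "transcript_id", "type", "chrom", "strand", "start", "end")
  if (!all(need %in% names(features)))
    stop("gene model features require columns: ", paste(need, collapse = ", "))
  features <- features[features$type %in% c("exon", "CDS"), need]
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  genes <- list(); exons <- list(); cds <- list(); utr <- list()
  for (g in unique(features$gene_id)) {
    fg <- features[features$gene_id == g, , drop = FALSE]
    cds_len <- tapply(
      ifelse(fg$type == "CDS", fg$end - fg$start + 1L, 0L),
      fg$transcript_id, sum)
    tx <- names(cds_len)[order(-cds_len, names(cds_len))][1]
    ft <- fg[fg$transcript_id == tx, , drop = FALSE]
    ex <- ft[ft$type == "exon", , drop = FALSE]
    cd <- ft[ft$type == "CDS", , drop = FALSE]
    if (nrow(cd)) {
      if (sum(cd$end - cd$start + 1L) %% 3L != 0L)
        stop("gene ", g, ": CDS length of transcript ", tx,
             " not divisible by 3")
      exr <- IRanges::IRanges(ex$start, ex$end)
      cdr <- IRanges::IRanges(cd$start, cd$end)
      if (!all(IRanges::overlapsAny(cdr, exr)) ||
          sum(IRanges::width(IRanges::intersect(cdr, exr))) !=
          sum(IRanges::width(cdr)))
        stop("gene ", g, ": CDS not contained in exons")
      u <- IRanges::setdiff(exr, cdr)
      if (length(u))
        utr[[g]] <- data.frame(gene_id = g, chrom = fg$chrom[1],
                               strand = fg$strand[1],
                               start = IRanges::start(u), end = IRanges::end(u))
    }
    genes[[g]] <- data.frame(gene_id = g, transcript = tx,
                             chrom = fg$chrom[1], strand = fg$strand[1],
                             start = min(ft$start), end = max(ft$end))
    exons[[g]] <- cbind(ex, row.names = NULL)
    if (nrow(cd)) cds[[g]] <- cbind(cd, row.names = NULL)
  }
  rb <- function(l) if (length(l)) {
    x <- do.call(rbind, l); rownames(x) <- NULL; x
  } else NULL
  structure(list(genes = rb(genes), exons = rb(exons), cds = rb(cds),
                 utr = rb(utr) %||%
                   data.frame(gene_id = character(), chrom = character(),
                              strand = character(), start = integer(),
                              end = integer())),
            class = "gene_model")
}

#' Read a gene model from GTF
#'
#' @param path Path to a GTF 2.2 file (plain or gzipped).
#' @return A [gene_model].
#' @export
read_gene_model <- function(path) {
  gff <- as.data.frame(rtracklayer::readGFF(
    path, columns = c("seqid", "type", "start", "end", "strand"),
    tags = c("gene_id", "transcript_id")))
  df <- data.frame(gene_id = gff$gene_id, transcript_id = gff$transcript_id,
                   type = as.character(gff$type), chrom = as.character(gff$seqid),
                   strand = as.character(gff$strand),
                   start = gff$start, end = gff$end, stringsAsFactors = FALSE)
  gene_model(df[df$type %in% c("exon", "CDS"), , drop = FALSE])
}

#' Write a gene model to GTF
#'
#' Emits gene, transcript, exon and CDS features for the chosen transcript
#' of each gene.
#'
#' @param model A [gene_model].
#' @param path Output path.
#' @export
write_gene_model <- function(model, path) {
  att <- function(g, t) sprintf('gene_id "%s"; transcript_id "%s";', g, t)
  rows <- character()
  for (i in seq_len(nrow(model$genes))) {
    g <- model$genes[i, ]
    rows <- c(rows,
              paste(g$chrom, "ppdscan", "gene", g$start, g$end, ".", g$strand,
                    ".", sprintf('gene_id "%s";', g$gene_id), sep = "\t"),
              paste(g$chrom, "ppdscan", "transcript", g$start, g$end, ".",
                    g$strand, ".", att(g$gene_id, g$transcript), sep = "\t"))
    for (tab in c("exons", "cds")) {
      f <- model[[tab]]
      f <- f[f$gene_id == g$gene_id, , drop = FALSE]
      if (is.null(f) || !nrow(f)) next
      ty <- if (tab == "exons") "exon" else "CDS"
      frame <- "."
      rows <- c(rows, paste(f$chrom, "ppdscan", ty, f$start, f$end, ".",
                            f$strand, frame, att(g$gene_id, g$transcript),
                            sep = "\t"))
    }
  }
  con <- file(path, "wb"); on.exit(close(con))
  writeLines(rows, con)
  invisible(path)
}
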