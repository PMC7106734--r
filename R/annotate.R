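#' Classify variants by genomic context and coding effect
#'
#' Assigns each variant exactly one region class with precedence
#' CDS > UTR > intron > intergenic (the most specific functional
#' consequence when features overlap). For SNPs inside a CDS the affected
#' codon is rebuilt from the reference sequence with the alternate base
#' substituted, reverse-complemented for minus-strand genes, and translated
#' with the standard genetic code; the protein position is
#' `ceiling(CDS offset / 3)`. The result distinguishes `CDS_synonymous`
#' from `CDS_nonsynonymous` and reports the amino-acid change as an
#' `"I85T"`-style string. INDELs overlapping a CDS are classed
#' `CDS_nonsynonymous` with effect `coding_indel` and no protein
#' coordinates.
#'
#' @param variants A [variant_table].
#' @param model A [gene_model].
#' @param reference A [Biostrings::DNAStringSet] (names = chromosomes), or a
#'   path to a FASTA file.
#' @return Data.frame `chrom, pos, ref, alt, class, gene, aa_change, effect`.
#' @export
classify_variants <- function(variants, model, reference) {
  if (is.character(reference))
    reference <- Biostrings::readDNAStringSet(reference)
  names(reference) <- sub("\\s.*$", "", names(reference))
  bad <- !variants$chrom %in% names(reference)
  if (any(bad))
    stop("locus outside reference: chromosome ",
         paste(unique(variants$chrom[bad]), collapse = ", "))
  if (any(variants$pos > Biostrings::width(reference)[
        match(variants$chrom, names(reference))]))
    stop("locus outside reference: position past end of chromosome")

  vr <- GenomicRanges::GRanges(variants$chrom,
                               IRanges::IRanges(variants$pos, variants$pos))
  hit <- function(feat) {
    if (is.null(feat) || !nrow(feat)) return(rep(NA_integer_, length(vr)))
    fr <- GenomicRanges::GRanges(feat$chrom,
                                 IRanges::IRanges(feat$start, feat$end))
    ov <- GenomicRanges::findOverlaps(vr, fr, select = "first")
    as.integer(ov)
  }
  cds_hit <- hit(model$cds)
  utr_hit <- hit(model$utr)
  gene_hit <- hit(model$genes)

  cls <- rep("intergenic", nrow(variants))
  gene <- rep(NA_character_, nrow(variants))
  aa <- rep(NA_character_, nrow(variants))
  effect <- rep(NA_character_, nrow(variants))

  in_gene <- !is.na(gene_hit)
  cls[in_gene] <- "intron"
  gene[in_gene] <- model$genes$gene_id[gene_hit[in_gene]]
  in_utr <- !is.na(utr_hit)
  cls[in_utr] <- "UTR"
  gene[in_utr] <- model$utr$gene_id[utr_hit[in_utr]]
  in_cds <- !is.na(cds_hit)
  gene[in_cds] <- model$cds$gene_id[cds_hit[in_cds]]

  for (i in which(in_cds)) {
    g <- model$cds$gene_id[cds_hit[i]]
    if (variants$vclass[i] != "SNP") {
      cls[i] <- "CDS_nonsynonymous"
      effect[i] <- "coding_indel"
      next
    }
    ch <- codon_change(variants$chrom[i], variants$pos[i], variants$ref[i],
                       strsplit(variants$alt[i], ",", fixed = TRUE)[[1]][1],
                       model, g, reference)
    cls[i] <- if (ch$ref_aa == ch$alt_aa) "CDS_synonymous" else "CDS_nonsynonymous"
    aa[i] <- paste0(ch$ref_aa, ch$protein_pos, ch$alt_aa)
    effect[i] <- if (ch$ref_aa == ch$alt_aa) "synonymous" else "missense"
  }
  data.frame(chrom = variants$chrom, pos = variants$pos, ref = variants$ref,
             alt = variants$alt, class = cls, gene = gene, aa_change = aa,
             effect = effect)
}

# amino-acid change of a CDS SNP: rebuild the codon from the reference with
# the alternate substituted, on the coding strand
codon_change <- function(chrom, pos, ref, alt, model, gene_id, reference) {
  cd <- model$cds[model$cds$gene_id == gene_id, , drop = FALSE]
  strand <- cd$strand[1]
  # genomic positions of CDS bases in transcription order
  gpos <- unlist(lapply(
    if (strand == "+") order(cd$start) else order(-cd$start),
    function(k) {
      s <- seq.int(cd$start[k], cd$end[k])
      if (strand == "+") s else rev(s)
    }))
  off <- match(pos, gpos)                 # 1-based CDS offset
  if (is.na(off)) stop("position not in CDS of gene ", gene_id)
  prot_pos <- ceiling(off / 3)
  codon_gpos <- gpos[(3 * prot_pos - 2):(3 * prot_pos)]
  base_at <- function(p) as.character(Biostrings::subseq(
    reference[[chrom]], start = p, width = 1L))
  bases <- vapply(codon_gpos, base_at, "")
  gref <- base_at(pos)
  if (!identical(gref, ref))
    stop("reference allele mismatch at ", chrom, ":", pos,
         " (FASTA has ", gref, ", record says ", ref, ")")
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  to_coding <- function(b) if (strand == "+") b else unname(comp[b])
  codon_ref <- paste(to_coding(bases), collapse = "")
  bases_alt <- bases
  bases_alt[codon_gpos == pos] <- alt
  codon_alt <- paste(to_coding(bases_alt), collapse = "")
  translate1 <- function(cod) {
    aa <- Biostrings::GENETIC_CODE[[cod]]
    if (is.null(aa)) NA_character_ else aa
  }
  list(ref_aa = translate1(codon_ref), alt_aa = translate1(codon_alt),
       protein_pos = prot_pos, codon_ref = codon_ref, codon_alt = codon_alt)
}

#' Summarise annotation classes
#'
#' @param annotations Output of [classify_variants()].
#' @return Data.frame `class, n, proportion` over all five region classes;
#'   counts sum to the input size and proportions to 1 (all-zero for empty
#'   input).
#' @export
summarize_classes <- function(annotations) {
  lev <- c("CDS_synonymous", "CDS_nonsynonymous", "UTR", "intron", "intergenic")
  n <- table(factor(annotations$class, levels = lev))
  tot <- sum(n)
  data.frame(class = lev, n = as.integer(n),
             proportion = if (tot > 0) as.numeric(n) / tot else rep(0, 5L))
}
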