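#' Pipeline configuration
#'
#' All stage thresholds in one validated list. The defaults are the
#' screening constants of the analysis: 10 kb windows sliding by 2 kb,
#' weighted F_ST > 0.6 with >= 10 variants per window (SNP and INDEL
#' tracks), mean XP-EHH > 2 for region calling, per-site F_ST > 0.2 for
#' INDEL genotyping follow-up, EHH truncation at 0.05, top 10 association
#' SNPs, reference allele treated as ancestral, recessive concordance
#' model.
#'
#' @param ... Overrides for any default (unknown keys are an error).
#' @return A validated `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(span_bp = 10000L, step_bp = 2000L,
              fst_min_weighted = 0.6, fst_min_variants = 10L,
              indel_fst_min_weighted = 0.6, indel_fst_min_variants = 10L,
              indel_site_fst = 0.2,
              xpehh_threshold = 2.0, ehh_cutoff = 0.05,
              xpehh_max_extend_bp = 200000,
              top_k_assoc = 10L, gene_flank_bp = 0L,
              concordance_model = "recessive",
              ancestral_policy = "reference",
              snp_filter_overrides = list(),
              indel_filter_overrides = list(),
              cluster_window_bp = 10L, cluster_min_snps = 3L,
              seed = 1L)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown))
    stop("unknown run_config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  if (cfg$span_bp < cfg$step_bp) stop("span_bp must be >= step_bp")
  if (!cfg$concordance_model %in% c("recessive", "dominant"))
    stop("concordance_model must be 'recessive' or 'dominant'")
  class(cfg) <- "run_config"
  cfg
}

#' Run the full prioritization pipeline
#'
#' Executes filter -> annotate -> F_ST (SNP and INDEL) -> XP-EHH ->
#' association -> DAF -> concordance -> evidence integration -> ranking on
#' either a simulated dataset or files on disk, optionally persisting every
#' stage's tables plus a machine-readable JSON run summary.
#'
#' @param config A [run_config()].
#' @param dataset A `sim_dataset` from [simulate_ppd_cohort()]; or NULL to
#'   read from files.
#' @param vcf,ped,gtf,fasta Input paths (used when `dataset` is NULL).
#' @param out_dir Output directory for stage TSV/BED files and
#'   `summary.json`; NULL (default) keeps everything in memory.
#' @return A `ppd_run` list with every stage's output and the final
#'   [rank_candidates()] report.
#' @export
run_pipeline <- function(config = run_config(), dataset = NULL,
                         vcf = NULL, ped = NULL, gtf = NULL, fasta = NULL,
                         out_dir = NULL) {
  if (is.null(dataset)) {
    if (is.null(vcf) || is.null(ped))
      stop("either `dataset` or at least `vcf` + `ped` paths are required")
    inp <- read_vcf(vcf)
    dataset <- list(variants = inp$variants, genotypes = inp$genotypes,
                    pedigree = read_pedigree(ped),
                    gene_model = if (!is.null(gtf)) read_gene_model(gtf),
                    ref_seq = NULL, config = NULL)
    if (!is.null(fasta)) dataset$ref_fasta <- fasta
  }
  variants <- dataset$variants
  genotypes <- dataset$genotypes
  pedig <- dataset$pedigree
  model <- dataset$gene_model
  chrom_lengths <- if (!is.null(dataset$config))
    stats::setNames(dataset$config$chrom_length_bp, dataset$config$chrom)

  # 1. hard filters + SNP cluster rule, then keep passing records
  snp_rows <- variants$vclass == "SNP"
  variants[snp_rows, "filter_flags"] <- apply_hard_filters(
    variants[snp_rows, , drop = FALSE], "SNP",
    default_hard_filters("SNP", config$snp_filter_overrides))$filter_flags
  variants[!snp_rows, "filter_flags"] <- apply_hard_filters(
    variants[!snp_rows, , drop = FALSE], "INDEL",
    default_hard_filters("INDEL", config$indel_filter_overrides))$filter_flags
  variants <- snp_cluster_filter(variants, config$cluster_window_bp,
                                 config$cluster_min_snps)
  keep <- !nzchar(variants$filter_flags)
  pass <- variants[keep, , drop = FALSE]
  class(pass) <- c("variant_table", "data.frame")
  rownames(pass) <- NULL
  geno <- subset_geno(genotypes, sites = which(keep))

  is_snp <- pass$vclass == "SNP"
  snp_v <- pass[is_snp, , drop = FALSE]; class(snp_v) <- class(pass)
  ind_v <- pass[!is_snp, , drop = FALSE]; class(ind_v) <- class(pass)
  snp_g <- subset_geno(geno, sites = which(is_snp))
  ind_g <- subset_geno(geno, sites = which(!is_snp))

  # 2. annotation
  annotations <- NULL
  ref <- dataset$ref_seq %||% dataset$ref_fasta
  if (!is.null(model) && !is.null(ref)) {
    if (!is.null(dataset$ref_seq)) {
      ref <- Biostrings::DNAStringSet(dataset$ref_seq)
      names(ref) <- unique(pass$chrom)[1]
    }
    annotations <- classify_variants(pass, model, ref)
  }

  # 3. F_ST: per-site and windowed, SNP and INDEL tracks
  fst_snp_sites <- fst_scan(snp_v, snp_g, pedig)
  fst_snp_w <- fst_windows(fst_snp_sites, config$span_bp, config$step_bp,
                           chrom_lengths)
  fst_snp_pass <- filter_fst_windows(fst_snp_w, config$fst_min_weighted,
                                     config$fst_min_variants)
  fst_ind_sites <- if (nrow(ind_v)) fst_scan(ind_v, ind_g, pedig)
  fst_ind_w <- if (!is.null(fst_ind_sites))
    fst_windows(fst_ind_sites, config$span_bp, config$step_bp, chrom_lengths)
  fst_ind_pass <- if (!is.null(fst_ind_w))
    filter_fst_windows(fst_ind_w, config$indel_fst_min_weighted,
                       config$indel_fst_min_variants)
  indel_selected <- if (!is.null(fst_ind_sites))
    fst_ind_sites[!is.na(fst_ind_sites$fst) &
                    fst_ind_sites$fst > config$indel_site_fst, , drop = FALSE]

  # 4. XP-EHH scan and region calling (SNPs)
  xp_scores <- xpehh_scan(snp_v, snp_g, pedig, config$ehh_cutoff,
                          config$xpehh_max_extend_bp)
  xp_regions <- call_xpehh_regions(xp_scores, config$span_bp, config$step_bp,
                                   config$xpehh_threshold, chrom_lengths)

  # 5. association, DAF, concordance (SNPs)
  assoc <- assoc_scan(snp_v, snp_g, pedig)
  daf_tab <- daf(snp_v, snp_g, pedig, config$ancestral_policy)
  conc <- concordance(snp_v, snp_g, pedig, config$concordance_model)

  # 6. integrate and rank
  evidence <- integrate_evidence(xp_regions, fst_snp_pass, fst_ind_pass,
                                 assoc, conc, annotations, model,
                                 config$top_k_assoc, config$gene_flank_bp)
  report <- rank_candidates(evidence, config$top_k_assoc)

  run <- structure(list(
    config = config, variants = variants, pass = pass,
    annotations = annotations,
    fst_snp_sites = fst_snp_sites, fst_snp_windows = fst_snp_w,
    fst_snp_pass = fst_snp_pass,
    fst_indel_sites = fst_ind_sites, fst_indel_windows = fst_ind_w,
    fst_indel_pass = fst_ind_pass, indel_selected = indel_selected,
    xpehh = xp_scores, xpehh_regions = xp_regions,
    assoc = assoc, daf = daf_tab, concordance = conc,
    evidence = evidence, report = report,
    truth = dataset$truth), class = "ppd_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

# persist every stage table plus a JSON summary
write_run <- function(run, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  tsv <- function(df, name) {
    if (is.null(df)) return(invisible(NULL))
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  tsv(run$variants, "variants.filtered.tsv")
  tsv(run$annotations, "annotations.tsv")
  tsv(run$fst_snp_windows, "fst_snp_windows.tsv")
  tsv(run$fst_snp_pass, "fst_snp_windows.pass.tsv")
  tsv(run$fst_indel_windows, "fst_indel_windows.tsv")
  tsv(run$indel_selected, "fst_indel_selected_sites.tsv")
  tsv(run$xpehh, "xpehh_scores.tsv")
  tsv(run$assoc, "association.tsv")
  tsv(run$daf, "daf.tsv")
  tsv(run$concordance, "concordance.tsv")
  tsv(run$evidence$candidates, "evidence.tsv")
  tsv(run$report$candidates, "candidates.ranked.tsv")
  tsv(run$report$causal_variants, "causal_variants.tsv")
  bed <- function(df, name) {
    if (is.null(df) || !nrow(df)) return(invisible(NULL))
    utils::write.table(
      data.frame(df$chrom, df$start - 1L, df$end),
      file.path(out_dir, name), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  }
  bed(run$xpehh_regions, "xpehh_regions.bed")
  reg <- attr(run$fst_snp_pass, "regions")
  bed(reg, "fst_snp_regions.bed")
  summary <- list(
    thresholds = unclass(run$config),
    n_input_variants = nrow(run$variants),
    n_passing = nrow(run$pass),
    n_xpehh_regions = nrow(run$xpehh_regions),
    n_fst_snp_pass = nrow(run$fst_snp_pass),
    top_candidate = if (nrow(run$report$candidates))
      run$report$candidates$candidate[1] else NA,
    n_causal_variants = nrow(run$report$causal_variants))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.ppd_run <- function(x, ...) {
  cat("ppdscan run:", nrow(x$variants), "variants,",
      nrow(x$pass), "passing filters\n")
  cat("XP-EHH regions:", nrow(x$xpehh_regions),
      "| passing SNP F_ST windows:", nrow(x$fst_snp_pass), "\n\n")
  print(x$report)
  invisible(x)
}
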