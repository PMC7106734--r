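#' Default two-family study design for the simulator
#'
#' Encodes the sampling design the simulator emulates: a large family in
#' which one sire produced an affected litter (3 affected + 1 normal, dam a
#' carrier) and a second litter of 11 normals (dam a non-carrier), with the
#' sire the only sampled parent; plus a second, unrelated family
#' contributing a single affected individual whose (carrier) parents are
#' unsampled. Seventeen samples in total: 4 affected, 13 normal.
#'
#' `causal_target` conditions each meiosis at the causal site: 2 = the
#' offspring must be homozygous for the causal allele, 1 = exactly one
#' transmitted copy, 0 = none, `NA` = unconditioned. The defaults reproduce
#' the genotype configuration observed in the study population (cases all
#' homozygous derived; four heterozygous carriers among the 13 controls,
#' counting the obligate-carrier sire).
#'
#' @return A list of family specifications understood by [sim_config()].
#' @export
ppd_families <- function() {
  list(
    list(fam = "F1",
         founders = list(
           list(id = "F0-1", sex = 1L, carrier = TRUE, sampled = TRUE),
           list(id = "F0-2", sex = 2L, carrier = TRUE, sampled = FALSE),
           list(id = "F0-3", sex = 2L, carrier = FALSE, sampled = FALSE)),
         matings = list(
           list(sire = "F0-1", dam = "F0-2",
                offspring = c("F1-a1", "F1-a2", "F1-a3", "F1-a4"),
                causal_target = c(2L, 2L, 2L, 0L)),
           list(sire = "F0-1", dam = "F0-3",
                offspring = paste0("F1-b", 1:11),
                causal_target = c(1L, 1L, 1L, rep(0L, 8))))),
    list(fam = "F2",
         founders = list(
           list(id = "F2-s", sex = 1L, carrier = TRUE, sampled = FALSE),
           list(id = "F2-d", sex = 2L, carrier = TRUE, sampled = FALSE)),
         matings = list(
           list(sire = "F2-s", dam = "F2-d", offspring = "F0-4",
                causal_target = 2L))))
}

#' Default per-clause QC annotation noise
#'
#' Fraction of sites whose annotations are drawn from the fail-like mixture
#' component of each hard-filter clause (everything else draws pass-like
#' values). Zero everywhere means every emitted record passes
#' [apply_hard_filters()].
#'
#' @return List with numeric vectors `snp` and `indel`.
#' @export
default_qc_noise <- function() {
  list(snp = c(QUAL = 0.005, QD = 0.005, MQ = 0.005, FS = 0.005,
               MQRankSum = 0.005, ReadPosRankSum = 0.005, MQ0DP = 0.005),
       indel = c(QD = 0.005, FS = 0.005, ReadPosRankSum = 0.005))
}

#' Simulation configuration
#'
#' Study conditions for the synthetic pedigree generator: a single
#' chromosome segment carrying an implanted recessive causal missense
#' variant on a long shared haplotype, background SNPs and INDELs, and a
#' two-family pedigree with 4 affected and 13 normal sampled individuals.
#'
#' Defaults: a 5 Mb chromosome with ~20,000 background variants (16,000
#' SNPs + 4,000 INDELs, mirroring the ~4:1 genome-wide SNP:INDEL ratio of
#' deep pig resequencing), founder allele frequencies from a U-shaped
#' Beta(0.2, 0.2) law (drift-dominated livestock population), a 50 kb
#' implanted haplotype centred on the causal missense SNP, 100
#' carrier-private tag SNPs on the implanted haplotype (~2/kb), Haldane
#' recombination at 1e-8 per bp, full penetrance, and no missing genotypes
#' (the emulated input is post-phasing).
#'
#' @param chrom Chromosome name.
#' @param chrom_length_bp Chromosome length (bp).
#' @param n_background_snps,n_background_indels Background variant counts
#'   (before removal of sites monomorphic in the sampled cohort).
#' @param founder_allele_freq_beta Beta(a, b) parameters of founder allele
#'   frequencies.
#' @param recombination_rate_per_bp Per-bp crossover probability per meiosis.
#' @param causal_position_bp Position of the causal missense SNP.
#' @param causal_haplotype_length_bp Length of the implanted shared
#'   haplotype centred on the causal site.
#' @param n_causal_tag_snps Carrier-private derived SNPs implanted on the
#'   causal haplotype (outside CDS).
#' @param penetrance P(affected | homozygous causal).
#' @param families Family/mating design, see [ppd_families()].
#' @param qc_annotation_noise Per-clause fail fractions, see
#'   [default_qc_noise()].
#' @param missing_rate Per-genotype missingness (the causal site is never
#'   masked).
#' @param seed Master seed; identical seeds give byte-identical datasets.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(chrom = "SSC11",
                       chrom_length_bp = 5000000L,
                       n_background_snps = 16000L,
                       n_background_indels = 4000L,
                       founder_allele_freq_beta = c(0.2, 0.2),
                       recombination_rate_per_bp = 1e-8,
                       causal_position_bp = 2500000L,
                       causal_haplotype_length_bp = 50000L,
                       n_causal_tag_snps = 100L,
                       penetrance = 1,
                       families = ppd_families(),
                       qc_annotation_noise = default_qc_noise(),
                       missing_rate = 0,
                       seed = 1L) {
  cfg <- list(chrom = chrom,
              chrom_length_bp = as.integer(chrom_length_bp),
              n_background_snps = as.integer(n_background_snps),
              n_background_indels = as.integer(n_background_indels),
              founder_allele_freq_beta = as.numeric(founder_allele_freq_beta),
              recombination_rate_per_bp = recombination_rate_per_bp,
              causal_position_bp = as.integer(causal_position_bp),
              causal_haplotype_length_bp = as.integer(causal_haplotype_length_bp),
              n_causal_tag_snps = as.integer(n_causal_tag_snps),
              penetrance = penetrance,
              families = families,
              qc_annotation_noise = qc_annotation_noise,
              missing_rate = missing_rate,
              seed = as.integer(seed))
  bad <- function(field, why) stop("invalid sim_config field `", field, "`: ",
                                   why, call. = FALSE)
  if (cfg$chrom_length_bp < 1000L) bad("chrom_length_bp", "must be >= 1000")
  if (cfg$n_background_snps < 0L) bad("n_background_snps", "must be >= 0")
  if (cfg$n_background_indels < 0L) bad("n_background_indels", "must be >= 0")
  if (length(cfg$founder_allele_freq_beta) != 2L ||
      any(cfg$founder_allele_freq_beta <= 0))
    bad("founder_allele_freq_beta", "needs two positive Beta parameters")
  if (cfg$recombination_rate_per_bp < 0 || cfg$recombination_rate_per_bp > 1)
    bad("recombination_rate_per_bp", "must be a probability")
  if (cfg$causal_position_bp < 1L ||
      cfg$causal_position_bp > cfg$chrom_length_bp)
    bad("causal_position_bp", "must lie within [1, chrom_length_bp]")
  if (cfg$causal_haplotype_length_bp < 1L)
    bad("causal_haplotype_length_bp", "must be positive")
  if (cfg$n_causal_tag_snps < 0L) bad("n_causal_tag_snps", "must be >= 0")
  if (cfg$penetrance < 0 || cfg$penetrance > 1)
    bad("penetrance", "must be in [0, 1]")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    bad("missing_rate", "must be in [0, 1)")
  class(cfg) <- "sim_config"
  cfg
}

# deterministic gene model: the causal gene (minus strand, so that genomic
# A>G is coding T>C) centred so the causal SNP sits at codon 85 position 2
# of its third exon, plus two decoy genes elsewhere on the chromosome.
# Sizes (transcription order): exon1 = 200 bp 5'UTR + 120 bp CDS,
# exon2 = 120 bp CDS, exon3 = 660 bp CDS + 300 bp 3'UTR; introns 2 kb.
build_sim_gene_model <- function(config) {
  L <- config$chrom_length_bp; C <- config$causal_position_bp
  # minus-strand causal gene: CDS offset of the causal SNP must be 254
  # (codon 85, position 2). CDS offsets in cds3 run 241..900 downwards in
  # genomic coordinate from gene_end - 4440.
  ge <- C + 4453L
  minus_feats <- function(gid, tid, ge) {
    data.frame(gene_id = gid, transcript_id = tid,
               type = c("exon", "CDS", "exon", "CDS", "exon", "CDS"),
               chrom = config$chrom, strand = "-",
               start = c(ge - 319L, ge - 319L, ge - 2439L, ge - 2439L,
                         ge - 5399L, ge - 5099L),
               end = c(ge, ge - 200L, ge - 2320L, ge - 2320L,
                       ge - 4440L, ge - 4440L))
  }
  plus_feats <- function(gid, tid, gs) {
    data.frame(gene_id = gid, transcript_id = tid,
               type = c("exon", "CDS", "exon", "CDS", "exon", "CDS"),
               chrom = config$chrom, strand = "+",
               start = c(gs, gs + 200L, gs + 2320L, gs + 2320L,
                         gs + 4440L, gs + 4440L),
               end = c(gs + 319L, gs + 319L, gs + 2439L, gs + 2439L,
                       gs + 5399L, gs + 5099L))
  }
  feats <- rbind(plus_feats("SIMG1", "SIMG1.t1", max(1L, round(L * 0.2))),
                 minus_feats("SIMG2", "SIMG2.t1", ge),
                 plus_feats("SIMG3", "SIMG3.t1", min(L - 5400L, round(L * 0.8))))
  model <- gene_model(feats)
  attr(model, "causal_gene") <- "SIMG2"
  model
}

#' Simulate founder haplotypes
#'
#' Draws background variant positions and founder haplotypes (2 per
#' founder) with per-site allele frequencies from the configured Beta law,
#' builds the reference chromosome sequence and gene model, and implants
#' the shared causal haplotype: within the block of
#' `causal_haplotype_length_bp` centred on the causal SNP, every carrier
#' founder haplotype is an identical copy of one implanted haplotype that
#' carries the causal derived allele and `n_causal_tag_snps` carrier-private
#' tag SNPs (placed outside CDS).
#'
#' @param config A [sim_config()].
#' @return A `founder_panel` list: `variants`, `haps` (haplotypes x sites,
#'   rows `<founder>_1/2`), `founders`, `gene_model`, `ref_seq`, `block`,
#'   `config`.
#' @export
simulate_founder_haplotypes <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  L <- config$chrom_length_bp; C <- config$causal_position_bp
  model <- build_sim_gene_model(config)
  block_lo <- max(1L, C - config$causal_haplotype_length_bp %/% 2L)
  block_hi <- min(L, block_lo + config$causal_haplotype_length_bp - 1L)

  # reference sequence, then pin the causal codon so that the coding codon
  # is ATC (Ile) with the causal SNP at its middle base (genomic A, coding T)
  set.seed(stage_seed(config$seed, "sequence"))
  seq_chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  # minus strand: genomic C+1, C, C-1 are codon-85 bases in transcription
  # order; complement("T","A","G") = coding "ATC" (Ile)
  seq_chars[C + 1L] <- "T"
  seq_chars[C] <- "A"
  seq_chars[C - 1L] <- "G"

  set.seed(stage_seed(config$seed, "positions"))
  cds_pos <- unlist(mapply(seq.int, model$cds$start, model$cds$end,
                           SIMPLIFY = FALSE))
  excl <- unique(c(C, (C - 6L):(C + 6L)))
  avail <- setdiff(seq_len(L - 10L), excl)
  n_bg <- config$n_background_snps + config$n_background_indels
  bg_pos <- if (n_bg > 0) sort(sample(avail, n_bg)) else integer()
  is_indel <- rep(FALSE, n_bg)
  if (n_bg > 0 && config$n_background_indels > 0)
    is_indel[sample.int(n_bg, config$n_background_indels)] <- TRUE
  tag_avail <- setdiff(intersect(avail, seq.int(block_lo, block_hi)),
                       c(bg_pos, cds_pos))
  n_tag <- min(config$n_causal_tag_snps, length(tag_avail))
  tag_pos <- if (n_tag > 0) sort(sample(tag_avail, n_tag)) else integer()

  pos <- c(bg_pos, tag_pos, C)
  kind <- c(ifelse(is_indel, "bg_indel", "bg_snp"),
            rep("tag", n_tag), "causal")
  ord <- order(pos)
  pos <- pos[ord]; kind <- kind[ord]
  S <- length(pos)

  # alleles from the reference sequence
  ref <- seq_chars[pos]
  other <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L)
  alt <- vapply(ref, other, "")
  alt[kind == "causal"] <- "G"
  ins <- rep(FALSE, S)
  if (any(kind == "bg_indel")) {
    idx <- which(kind == "bg_indel")
    ins[idx] <- sample(c(TRUE, FALSE), length(idx), replace = TRUE)
    for (i in idx) {
      len <- sample(1:4, 1L)
      if (ins[i]) {
        alt[i] <- paste0(ref[i], paste(sample(c("A", "C", "G", "T"), len,
                                              replace = TRUE), collapse = ""))
      } else {
        ref[i] <- paste(seq_chars[pos[i]:(pos[i] + len)], collapse = "")
        alt[i] <- substr(ref[i], 1L, 1L)
      }
    }
  }

  founders <- do.call(rbind, lapply(config$families, function(f)
    do.call(rbind, lapply(f$founders, function(fo)
      data.frame(fam = f$fam, id = fo$id, sex = fo$sex,
                 carrier = fo$carrier, sampled = fo$sampled)))))

  set.seed(stage_seed(config$seed, "founders"))
  ab <- config$founder_allele_freq_beta
  freq <- stats::rbeta(S, ab[1], ab[2])
  freq[kind %in% c("tag", "causal")] <- 0   # carrier-private sites
  nh <- 2L * nrow(founders)
  haps <- matrix(stats::rbinom(S * nh, 1L, rep(freq, nh)), nrow = nh,
                 byrow = TRUE)
  # variant sites exist because they are polymorphic: condition background
  # sites on segregating among the founder haplotypes (ascertained SFS)
  bg <- kind %in% c("bg_snp", "bg_indel")
  for (iter in 1:100) {
    cs <- colSums(haps)
    mono <- bg & (cs == 0L | cs == nh)
    if (!any(mono)) break
    freq[mono] <- stats::rbeta(sum(mono), ab[1], ab[2])
    haps[, mono] <- stats::rbinom(nh * sum(mono), 1L,
                                  rep(freq[mono], each = nh))
  }
  rownames(haps) <- paste(rep(founders$id, each = 2L), 1:2, sep = "_")

  in_block <- pos >= block_lo & pos <= block_hi
  implant <- stats::rbinom(sum(in_block), 1L, freq[in_block])
  implant[kind[in_block] %in% c("tag", "causal")] <- 1L
  carrier_rows <- paste0(founders$id[founders$carrier], "_1")
  for (r in carrier_rows) haps[r, in_block] <- implant

  variants <- variant_table(data.frame(
    chrom = config$chrom, pos = pos, ref = ref, alt = alt,
    id = ifelse(kind == "causal", paste0(config$chrom, ":", C),
                NA_character_)))
  variants$kind <- kind  # positions already sorted; kept for truth
  structure(list(variants = variants, haps = haps, founders = founders,
                 gene_model = model, ref_seq = paste(seq_chars, collapse = ""),
                 block = c(start = block_lo, end = block_hi),
                 causal_index = which(pos == C), config = config),
            class = "founder_panel")
}

# one gamete from a parent's two haplotypes: Poisson(rate * (L-1)) crossovers
# (Haldane, no interference), uniform breakpoints, random starting strand.
# `force` (0/1) conditions the transmitted allele at site `force_site` by
# flipping the starting strand, which preserves the crossover process.
sim_gamete <- function(h1, h2, positions, L, rate, force = NA,
                       force_site = NA_integer_) {
  k <- stats::rpois(1L, rate * (L - 1))
  xp <- if (k > 0) sort(stats::runif(k, 1, L)) else numeric()
  s0 <- sample(1:2, 1L)
  strand <- 1L + (s0 - 1L + findInterval(positions, xp)) %% 2L
  if (!is.na(force)) {
    al <- if (strand[force_site] == 1L) h1[force_site] else h2[force_site]
    if (al != force) strand <- 3L - strand
  }
  out <- ifelse(strand == 1L, h1, h2)
  attr(out, "crossovers") <- k
  out
}

#' Drop founder haplotypes through a pedigree
#'
#' Transmits (possibly recombinant) parental haplotypes to every offspring
#' in the pedigree, parents before children. Crossovers per meiosis follow
#' the Haldane model (Poisson, no interference) at the configured per-bp
#' rate, and phase is recorded exactly. Offspring listed with a
#' `causal_target` in the family design have their meioses conditioned at
#' the causal site (by flipping the gamete's starting strand, which leaves
#' the crossover process untouched). Affected status is then drawn:
#' homozygous carriers are affected with probability `penetrance`, all
#' others are unaffected.
#'
#' @param panel A `founder_panel` from [simulate_founder_haplotypes()].
#' @param ped Optional [pedigree] (with optional `causal_target` column);
#'   defaults to the pedigree implied by `config$families`.
#' @param config The [sim_config()] (defaults to the panel's).
#' @return A `sim_cohort` list: `variants`, `haps` (all individuals),
#'   `pedigree`, `truth`, `gene_model`, `ref_seq`, `block`, `config`.
#' @export
gene_drop <- function(panel, ped = NULL, config = panel$config) {
  if (is.null(ped)) ped <- build_sim_pedigree(config)
  pos <- panel$variants$pos
  L <- config$chrom_length_bp
  ci <- panel$causal_index
  founder_ids <- panel$founders$id
  miss <- setdiff(ped$id[ped$sire == "0"], founder_ids)
  if (length(miss))
    stop("pedigree founder(s) missing from the haplotype panel: ",
         paste(miss, collapse = ", "))
  haps <- matrix(NA_integer_, 2L * nrow(ped), length(pos),
                 dimnames = list(paste(rep(ped$id, each = 2L), 1:2, sep = "_"),
                                 NULL))
  for (f in intersect(founder_ids, ped$id)) {
    haps[paste0(f, "_1"), ] <- panel$haps[paste0(f, "_1"), ]
    haps[paste0(f, "_2"), ] <- panel$haps[paste0(f, "_2"), ]
  }
  done <- ped$id %in% founder_ids
  if (any(!done & (ped$sire == "0" | ped$dam == "0")))
    stop("pedigree error: non-founder with a missing parent")
  set.seed(stage_seed(config$seed, "drop"))
  target <- if ("causal_target" %in% names(ped)) ped$causal_target
            else rep(NA_integer_, nrow(ped))
  n_cross <- 0L
  repeat {
    todo <- which(!done)
    if (!length(todo)) break
    progressed <- FALSE
    for (i in todo) {
      si <- ped$sire[i]; di <- ped$dam[i]
      if (!(si %in% ped$id[done]) || !(di %in% ped$id[done])) next
      tg <- target[i]
      # split a genotype target into per-gamete targets
      f1 <- f2 <- NA
      if (!is.na(tg)) {
        het <- function(pid) haps[paste0(pid, "_1"), ci] !=
                             haps[paste0(pid, "_2"), ci]
        if (tg == 2L) { f1 <- 1L; f2 <- 1L }
        else if (tg == 0L) {
          f1 <- if (het(si)) 0L else NA
          f2 <- if (het(di)) 0L else NA
        } else if (tg == 1L) {
          cands <- c(het(si), het(di))
          if (!any(cands)) stop("causal_target 1 needs a carrier parent for ",
                                ped$id[i])
          side <- if (all(cands)) sample(1:2, 1L) else which(cands)
          if (side == 1L) { f1 <- 1L; f2 <- if (het(di)) 0L else NA }
          else { f2 <- 1L; f1 <- if (het(si)) 0L else NA }
        }
      }
      g1 <- sim_gamete(haps[paste0(si, "_1"), ], haps[paste0(si, "_2"), ],
                       pos, L, config$recombination_rate_per_bp, f1, ci)
      g2 <- sim_gamete(haps[paste0(di, "_1"), ], haps[paste0(di, "_2"), ],
                       pos, L, config$recombination_rate_per_bp, f2, ci)
      n_cross <- n_cross + attr(g1, "crossovers") + attr(g2, "crossovers")
      haps[paste0(ped$id[i], "_1"), ] <- g1
      haps[paste0(ped$id[i], "_2"), ] <- g2
      done[i] <- TRUE
      progressed <- TRUE
    }
    if (!progressed)
      stop("pedigree error: cycle or missing parent among ",
           paste(ped$id[!done], collapse = ", "))
  }
  set.seed(stage_seed(config$seed, "phenotype"))
  hom <- haps[paste(rep(ped$id, each = 2L), 1:2, sep = "_"), ci]
  hom <- matrix(hom, ncol = 2L, byrow = TRUE)
  is_hom <- hom[, 1] == 1L & hom[, 2] == 1L
  ped$phenotype <- ifelse(is_hom & stats::runif(nrow(ped)) < config$penetrance,
                          2L, 1L)
  carrier <- data.frame(
    sample = rep(ped$id, each = 2L), hap = rep(1:2, nrow(ped)),
    carrier = haps[, ci] == 1L)[haps[, ci] == 1L, 1:2]
  rownames(carrier) <- NULL
  v <- panel$variants
  truth <- list(
    causal_variant_key = list(chrom = v$chrom[ci], pos = v$pos[ci],
                              ref = v$ref[ci], alt = v$alt[ci]),
    causal_gene = attr(panel$gene_model, "causal_gene"),
    block = panel$block,
    carrier_haplotypes = carrier,
    phenotype = stats::setNames(ped$phenotype, ped$id),
    n_crossovers = n_cross)
  structure(list(variants = panel$variants, haps = haps, pedigree = ped,
                 truth = truth, gene_model = panel$gene_model,
                 ref_seq = panel$ref_seq, block = panel$block,
                 causal_index = ci, config = config),
            class = "sim_cohort")
}

#' @rdname gene_drop
#' @export
build_sim_pedigree <- function(config) {
  rows <- list()
  for (f in config$families) {
    for (fo in f$founders)
      rows[[fo$id]] <- data.frame(fam = f$fam, id = fo$id, sire = "0",
                                  dam = "0", sex = fo$sex, phenotype = 1L,
                                  sampled = fo$sampled,
                                  causal_target = NA_integer_)
    for (m in f$matings) {
      tg <- m$causal_target %||% rep(NA_integer_, length(m$offspring))
      for (j in seq_along(m$offspring))
        rows[[m$offspring[j]]] <- data.frame(
          fam = f$fam, id = m$offspring[j], sire = m$sire, dam = m$dam,
          sex = ((j - 1L) %% 2L) + 1L, phenotype = 1L, sampled = TRUE,
          causal_target = tg[j])
    }
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  out <- pedigree(df[c("fam", "id", "sire", "dam", "sex", "phenotype")])
  out$sampled <- df$sampled
  out$causal_target <- df$causal_target
  out
}

#' Simulate a complete study cohort
#'
#' Convenience wrapper: founder haplotypes, gene drop, QC annotations,
#' optional missingness, and restriction to the sampled individuals.
#' Sites monomorphic among the sampled individuals are removed (a called
#' variant set only contains sites polymorphic in the cohort).
#'
#' @param config A [sim_config()] (or argument list for one).
#' @return A `sim_dataset` list: `variants` (with QC annotations),
#'   `genotypes` ([geno_matrix] over the 17 sampled individuals),
#'   `pedigree`, `gene_model`, `ref_seq`, `truth`, `config`.
#' @export
simulate_ppd_cohort <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  panel <- simulate_founder_haplotypes(config)
  cohort <- gene_drop(panel, config = config)
  ped <- cohort$pedigree
  sampled <- ped$id[ped$sampled]
  h1 <- t(cohort$haps[paste0(sampled, "_1"), , drop = FALSE])
  h2 <- t(cohort$haps[paste0(sampled, "_2"), , drop = FALSE])
  colnames(h1) <- colnames(h2) <- sampled
  variants <- cohort$variants
  variants <- annotate_qc(variants, config)
  ci <- cohort$causal_index
  # ascertainment: drop sites monomorphic among the sampled individuals
  ac <- rowSums(h1) + rowSums(h2)
  keep <- ac > 0L & ac < 2L * length(sampled)
  keep[ci] <- TRUE
  variants <- variants[keep, , drop = FALSE]
  class(variants) <- c("variant_table", "data.frame")
  rownames(variants) <- NULL
  h1 <- h1[keep, , drop = FALSE]; h2 <- h2[keep, , drop = FALSE]
  genotypes <- geno_matrix(h1, h2, TRUE, sampled)
  if (config$missing_rate > 0) {
    set.seed(stage_seed(config$seed, "missing"))
    m <- matrix(stats::runif(length(h1)) < config$missing_rate, nrow(h1))
    m[which(variants$pos == config$causal_position_bp), ] <- FALSE
    genotypes$a1[m] <- NA_integer_
    genotypes$a2[m] <- NA_integer_
  }
  structure(list(variants = variants, genotypes = genotypes,
                 pedigree = ped, gene_model = cohort$gene_model,
                 ref_seq = cohort$ref_seq, truth = cohort$truth,
                 config = config),
            class = "sim_dataset")
}

# draw QC annotation fields from a pass-like component, switching a
# configured fraction of sites per clause to a fail-like component that
# violates exactly that clause; the causal site always draws pass-like.
annotate_qc <- function(variants, config) {
  set.seed(stage_seed(config$seed, "qc"))
  S <- nrow(variants)
  u <- function(a, b) stats::runif(S, a, b)
  variants$qual <- u(60, 1500)
  variants$QD <- u(5, 30)
  variants$MQ <- u(45, 60)
  variants$FS <- u(0, 30)
  variants$MQRankSum <- u(-3, 3)
  variants$ReadPosRankSum <- u(-3, 3)
  variants$MQ0 <- rep(0, S)
  variants$DP <- round(u(300, 900))
  noise <- config$qc_annotation_noise
  snp <- variants$vclass == "SNP"
  causal <- variants$pos == config$causal_position_bp
  pickf <- function(rate, ok) which(stats::runif(S) < rate & ok & !causal)
  for (cl in names(noise$snp)) {
    i <- pickf(noise$snp[[cl]], snp)
    if (!length(i)) next
    switch(cl,
      QUAL = { variants$qual[i] <- stats::runif(length(i), 5, 40) },
      QD = { variants$QD[i] <- stats::runif(length(i), 0, 2) },
      MQ = { variants$MQ[i] <- stats::runif(length(i), 10, 40) },
      FS = { variants$FS[i] <- stats::runif(length(i), 60, 199) },
      MQRankSum = { variants$MQRankSum[i] <- stats::runif(length(i), -20, -12.5) },
      ReadPosRankSum = { variants$ReadPosRankSum[i] <-
        stats::runif(length(i), -19, -8.001) },
      MQ0DP = { variants$MQ0[i] <- pmax(4, round(0.2 * variants$DP[i])) })
  }
  for (cl in names(noise$indel)) {
    i <- pickf(noise$indel[[cl]], !snp)
    if (!length(i)) next
    switch(cl,
      QD = { variants$QD[i] <- stats::runif(length(i), 0, 1.99) },
      FS = { variants$FS[i] <- stats::runif(length(i), 200.01, 400) },
      ReadPosRankSum = { variants$ReadPosRankSum[i] <-
        stats::runif(length(i), -40, -20.01) })
  }
  variants
}

#' Write a simulated dataset to disk
#'
#' Emits the phased multi-sample VCF (with QC annotations in INFO and the
#' QUAL column), the PED-like phenotype file, the reference FASTA, the GTF
#' gene model and a tab-separated truth file. Re-running with the same
#' configuration (same seed) produces byte-identical files.
#'
#' @param dataset A `sim_dataset` from [simulate_ppd_cohort()].
#' @param dir Output directory (created if needed).
#' @param basename File stem (default `"sim"`).
#' @return Named vector of paths (`vcf`, `ped`, `fasta`, `gtf`, `truth`).
#' @export
emit_dataset <- function(dataset, dir, basename = "sim") {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir)
  paths <- c(vcf = file.path(dir, paste0(basename, ".vcf")),
             ped = file.path(dir, paste0(basename, ".ped")),
             fasta = file.path(dir, paste0(basename, ".fa")),
             gtf = file.path(dir, paste0(basename, ".gtf")),
             truth = file.path(dir, paste0(basename, ".truth.tsv")))
  cl <- stats::setNames(dataset$config$chrom_length_bp, dataset$config$chrom)
  write_vcf(dataset$variants, dataset$genotypes, paths["vcf"],
            contig_lengths = cl)
  ped <- dataset$pedigree
  ped$phenotype[!ped$sampled] <- 0L   # unsampled: phenotype missing
  write_pedigree(pedigree(ped[c("fam", "id", "sire", "dam", "sex",
                                "phenotype")]), paths["ped"])
  fa <- Biostrings::DNAStringSet(dataset$ref_seq)
  names(fa) <- dataset$config$chrom
  Biostrings::writeXStringSet(fa, paths["fasta"], width = 70L)
  write_gene_model(dataset$gene_model, paths["gtf"])
  tr <- dataset$truth
  con <- file(paths["truth"], "wb")
  writeLines(c(
    paste0("#causal_variant\t", tr$causal_variant_key$chrom, ":",
           tr$causal_variant_key$pos, "\t", tr$causal_variant_key$ref, ">",
           tr$causal_variant_key$alt),
    paste0("#causal_gene\t", tr$causal_gene),
    paste0("#block\t", tr$block["start"], "-", tr$block["end"]),
    "sample\thap\tcarrier",
    paste(tr$carrier_haplotypes$sample, tr$carrier_haplotypes$hap, "1",
          sep = "\t")), con)
  close(con)
  paths
}
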