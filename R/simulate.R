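#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: a five-exon gene
#' with a skippable internal exon, low-frequency variants of which a known
#' subset destroy planted SRE hexamers, junction read counts whose latent
#' PSI sits near 0.9 (the scale observed for a near-constitutive exon) and
#' is shifted in functional-variant carriers, CN/AD phenotype labels across
#' three brain regions in two cohorts, and an expression matrix with
#' planted fold-change DEGs between skipping groups.
#'
#' @param seed integer root seed; every stage derives its randomness from
#'   it.
#' @param n_samples number of samples (default 1000).
#' @param n_exons number of exons (default 5; the target is exon 2).
#' @param exon_len,intron_len,flank_len locus geometry in bp (each >= 6 so
#'   hexamers fit).
#' @param n_variants low-frequency SNVs planted inside the splicing unit
#'   (default 20).
#' @param n_common_variants additional common (non-low-frequency) SNVs
#'   planted so the MAF filter has something to remove (default 2).
#' @param fraction_functional fraction of the low-frequency variants
#'   planted to destroy an SRE hexamer (default 0.3).
#' @param maf_range range of minor allele frequencies for low-frequency
#'   variants (default 0.001-0.05).
#' @param common_maf_range MAF range for the common variants (default
#'   0.1-0.3).
#' @param psi_base latent PSI of non-carriers (default 0.90).
#' @param psi_sd Gaussian sd of per-sample latent PSI (default 0.02).
#' @param effect_delta latent PSI shift in functional-variant carriers
#'   (default -0.05).
#' @param effect_in where the effect applies: `"all"` carriers,
#'   `"AD_only"` carriers, or `"none"` (null data).
#' @param depth mean total junction reads per sample (Poisson; default
#'   100).
#' @param frac_ad fraction of samples labeled AD (default 0.67, the
#'   case-control balance of pooled frontal-lobe brain bank cohorts).
#' @param n_genes_expr,n_planted_degs,deg_fold expression matrix dimensions
#'   and planted differential signal (defaults 2000 genes, 50 DEGs,
#'   fold 4).
#' @param n_motifs_per_class random hexamers per SRE class (default 40).
#' @param strand gene strand of the simulated locus.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1, n_samples = 1000, n_exons = 5,
                       exon_len = 150, intron_len = 300, flank_len = 200,
                       n_variants = 20, n_common_variants = 2,
                       fraction_functional = 0.3,
                       maf_range = c(0.001, 0.05),
                       common_maf_range = c(0.10, 0.30),
                       psi_base = 0.90, psi_sd = 0.02, effect_delta = -0.05,
                       effect_in = c("all", "AD_only", "none"),
                       depth = 100, frac_ad = 0.67,
                       n_genes_expr = 2000, n_planted_degs = 50,
                       deg_fold = 4, n_motifs_per_class = 40,
                       strand = "+") {
  effect_in <- match.arg(effect_in)
  stopifnot(psi_base > 0, psi_base <= 1,
            psi_base + effect_delta >= 0, psi_base + effect_delta <= 1,
            fraction_functional >= 0, fraction_functional <= 1,
            frac_ad >= 0, frac_ad <= 1,
            maf_range[1] > 0, maf_range[2] <= 0.5, psi_sd >= 0)
  if (exon_len < 6 || intron_len < 6) {
    stop("exon and intron lengths must be >= 6 so hexamers fit")
  }
  if (depth <= 0) stop("depth must be positive")
  if (deg_fold <= 0) stop("deg_fold must be positive")
  structure(list(
    seed = as.integer(seed), n_samples = n_samples, n_exons = n_exons,
    exon_len = exon_len, intron_len = intron_len, flank_len = flank_len,
    n_variants = n_variants, n_common_variants = n_common_variants,
    fraction_functional = fraction_functional, maf_range = maf_range,
    common_maf_range = common_maf_range, psi_base = psi_base,
    psi_sd = psi_sd, effect_delta = effect_delta, effect_in = effect_in,
    depth = depth, frac_ad = frac_ad, n_genes_expr = n_genes_expr,
    n_planted_degs = n_planted_degs, deg_fold = deg_fold,
    n_motifs_per_class = n_motifs_per_class, strand = strand),
    class = "sim_config")
}

random_hexamers <- function(n, exclude = character()) {
  pool <- character(0)
  while (length(pool) < n) {
    h <- paste(sample(c("A", "C", "G", "T"), 6, replace = TRUE),
               collapse = "")
    if (!(h %in% pool) && !(h %in% exclude)) pool <- c(pool, h)
  }
  pool
}

#' Generate random SRE motif sets
#'
#' Draws disjoint random hexamer sets for the three SRE classes.
#'
#' @param cfg a `sim_config`.
#' @return an `sre_motifs` object.
#' @export
simulate_motifs <- function(cfg) {
  set.seed(cfg$seed + 11L)
  k <- cfg$n_motifs_per_class
  ese <- random_hexamers(k)
  ess <- random_hexamers(k, exclude = ese)
  ise <- random_hexamers(k, exclude = c(ese, ess))
  sre_motifs(ESE = ese, ESS = ess, ISE = ise)
}

#' Simulate the gene locus
#'
#' Random A/C/G/T reference with an alternating exon/intron gene model and
#' flanking sequence; the internal second exon is the skipping target.
#'
#' @param cfg a `sim_config`.
#' @return list with `seq` (chromosome sequence, character string),
#'   `model` (a `gene_model`), `chrom`.
#' @export
simulate_locus <- function(cfg) {
  set.seed(cfg$seed + 17L)
  if (cfg$n_exons < 3) stop("no internal exon: need >= 3 exons")
  lens <- integer(0)
  for (i in seq_len(cfg$n_exons)) {
    lens <- c(lens, cfg$exon_len)
    if (i < cfg$n_exons) lens <- c(lens, cfg$intron_len)
  }
  total <- cfg$flank_len * 2 + sum(lens)
  seq <- paste(sample(c("A", "C", "G", "T"), total, replace = TRUE),
               collapse = "")
  starts <- ends <- integer(cfg$n_exons)
  pos <- cfg$flank_len + 1L
  for (i in seq_len(cfg$n_exons)) {
    starts[i] <- pos
    ends[i] <- pos + cfg$exon_len - 1L
    pos <- ends[i] + 1L + cfg$intron_len
  }
  model <- gene_model("simGene", "chrSim", cfg$strand,
                      data.frame(start = starts, end = ends))
  list(seq = seq, model = model, chrom = "chrSim")
}

subst <- function(s, pos, base) {
  substr(s, pos, pos) <- base
  s
}

# Plant one functional variant: embed a motif of the applicable class at a
# window overlapping `pos`, then pick an ALT that breaks the match.
plant_functional_at <- function(seq, pos, region, motifs, unit) {
  classes <- applicable_classes(region)
  classes <- classes[vapply(motifs[classes], length, 1L) > 0]
  if (!length(classes)) stop("no motifs available for region class ", region)
  for (attempt in 1:50) {
    cl <- sample(classes, 1)
    m <- sample(motifs[[cl]], 1)
    off <- sample(-5:0, 1)
    s0 <- pos + off
    if (s0 < 1 || s0 + 5 > nchar(seq)) next
    cand <- seq
    substr(cand, s0, s0 + 5) <- m
    ref <- substr(cand, pos, pos)
    alts <- setdiff(c("A", "C", "G", "T"), ref)
    for (alt in sample(alts)) {
      broken <- subst(m, pos - s0 + 1, alt)
      if (broken %in% motifs[[cl]]) next
      ann <- annotate_variant(
        list(id = "probe", pos = pos, ref = ref, alt = alt), cand, unit,
        motifs)
      if (ann$functional) {
        return(list(seq = cand, ref = ref, alt = alt))
      }
    }
  }
  stop("could not plant a functional variant at position ", pos,
       " after bounded retries")
}

# Plant one neutral variant: pick an ALT whose scan shows no SRE loss.
plant_neutral_at <- function(seq, pos, motifs, unit) {
  ref <- substr(seq, pos, pos)
  for (alt in sample(setdiff(c("A", "C", "G", "T"), ref))) {
    ann <- annotate_variant(list(id = "probe", pos = pos, ref = ref,
                                 alt = alt), seq, unit, motifs)
    if (!ann$functional) return(list(ref = ref, alt = alt))
  }
  NULL
}

draw_genotypes <- function(n, maf, max_retry = 100) {
  for (i in seq_len(max_retry)) {
    g <- stats::rbinom(n, 2, maf)
    if (any(g > 0)) return(as.integer(g))
  }
  stop("could not draw a polymorphic genotype vector at maf ", maf)
}

#' Plant variants in the splicing unit
#'
#' Places `n_variants` low-frequency SNVs (plus `n_common_variants` common
#' ones) inside the splicing unit at mutually distant positions. A
#' `fraction_functional` subset is planted so the reference carries an SRE
#' hexamer of the applicable class that the alternative allele destroys;
#' the rest are verified by the scanner NOT to destroy any motif. Genotypes
#' are drawn per sample under Hardy-Weinberg at MAFs uniform in the
#' configured range (vectors observed monomorphic are redrawn so every
#' variant can define carriers).
#'
#' @param cfg a `sim_config`.
#' @param locus output of [simulate_locus] (its sequence is edited to embed
#'   the planted motifs).
#' @param unit the `splicing_unit` of the target exon.
#' @param motifs an `sre_motifs` object.
#' @return list with `seq` (edited chromosome sequence), `gm` (a
#'   `genotype_matrix`), `truth` (`functional_variant_ids`, `true_maf`,
#'   `carrier_functional_ids`, `carrier_any_ids`).
#' @export
plant_variants <- function(cfg, locus, unit, motifs) {
  set.seed(cfg$seed + 23L)
  if (!length(motifs$ESE) && !length(motifs$ESS) && !length(motifs$ISE)) {
    stop("motif sets are empty")
  }
  n_total <- cfg$n_variants + cfg$n_common_variants
  n_func <- round(cfg$n_variants * cfg$fraction_functional)
  span <- unit$span
  min_gap <- 17L  # variant hexamer windows must not interact
  positions <- integer(0)
  for (attempt in 1:2000) {
    p <- sample(span[1]:span[2], 1)
    if (all(abs(p - positions) >= min_gap)) positions <- c(positions, p)
    if (length(positions) == n_total) break
  }
  if (length(positions) < n_total) {
    stop("could not place ", n_total, " variants with spacing ", min_gap,
         " in a span of ", span[2] - span[1] + 1L, " bp")
  }
  is_func <- c(rep(TRUE, n_func), rep(FALSE, n_total - n_func))
  is_common <- c(rep(FALSE, cfg$n_variants), rep(TRUE, cfg$n_common_variants))
  seq <- locus$seq
  rows <- list()
  for (i in seq_len(n_total)) {
    pos <- positions[i]
    region <- classify_region(pos, unit)
    if (is_func[i]) {
      pl <- plant_functional_at(seq, pos, region, motifs, unit)
      seq <- pl$seq
      rows[[i]] <- data.frame(pos = pos, ref = pl$ref, alt = pl$alt,
                              functional = TRUE, stringsAsFactors = FALSE)
    } else {
      pl <- plant_neutral_at(seq, pos, motifs, unit)
      if (is.null(pl)) {
        # reference windows here hit a motif for every ALT; fall back to a
        # fresh position
        repeat {
          pos2 <- sample(span[1]:span[2], 1)
          if (!all(abs(pos2 - positions) >= min_gap)) next
          pl <- plant_neutral_at(seq, pos2, motifs, unit)
          if (!is.null(pl)) { pos <- pos2; positions[i] <- pos2; break }
        }
      }
      rows[[i]] <- data.frame(pos = pos, ref = pl$ref, alt = pl$alt,
                              functional = FALSE, stringsAsFactors = FALSE)
    }
  }
  vars <- do.call(rbind, rows)
  vars$common <- is_common
  ord <- order(vars$pos)
  vars <- vars[ord, ]
  vars$id <- sprintf("sv%02d", seq_len(n_total))

  maf <- ifelse(vars$common,
                stats::runif(n_total, cfg$common_maf_range[1],
                             cfg$common_maf_range[2]),
                stats::runif(n_total, cfg$maf_range[1], cfg$maf_range[2]))
  samples <- sprintf("S%04d", seq_len(cfg$n_samples))
  calls <- vapply(maf, function(m) draw_genotypes(cfg$n_samples, m),
                  integer(cfg$n_samples))
  rownames(calls) <- samples
  colnames(calls) <- vars$id
  af <- colSums(calls) / (2 * cfg$n_samples)
  variants <- data.frame(id = vars$id, chrom = locus$chrom, pos = vars$pos,
                         ref = vars$ref, alt = vars$alt, af = af,
                         maf = pmin(af, 1 - af), stringsAsFactors = FALSE)
  gm <- genotype_matrix(samples, variants, calls)

  # construction-then-verification: the scanner must agree with the plan
  ann <- annotate_all(gm, seq, unit, motifs)
  if (!identical(ann$functional, vars$functional)) {
    stop("planted functionality not recovered by the scanner; planting bug")
  }
  func_ids <- vars$id[vars$functional]
  carrier_func <- samples[rowSums(calls[, func_ids, drop = FALSE] > 0) > 0]
  lf_ids <- vars$id[!vars$common]
  carrier_any <- samples[rowSums(calls[, lf_ids, drop = FALSE] > 0) > 0]
  list(seq = seq, gm = gm,
       truth = list(functional_variant_ids = func_ids,
                    low_frequency_variant_ids = lf_ids,
                    true_maf = stats::setNames(maf, vars$id),
                    carrier_functional_ids = carrier_func,
                    carrier_any_ids = carrier_any))
}

#' Simulate the sample phenotype table
#'
#' CN/AD diagnosis labels, three frontal brain regions and the two cohorts
#' that contributed them.
#'
#' @param cfg a `sim_config`.
#' @param sample_ids sample ids (defaults to the generator's own naming).
#' @return data.frame `sample_id, diagnosis, region, cohort`.
#' @export
simulate_samples <- function(cfg, sample_ids = sprintf("S%04d",
                                                       seq_len(cfg$n_samples))) {
  set.seed(cfg$seed + 29L)
  n <- length(sample_ids)
  diagnosis <- ifelse(stats::runif(n) < cfg$frac_ad, "AD", "CN")
  region <- sample(c("DLPFC", "FP", "IF"), n, replace = TRUE,
                   prob = c(0.56, 0.23, 0.21))
  cohort <- ifelse(region == "DLPFC", "cohort1", "cohort2")
  data.frame(sample_id = sample_ids, diagnosis = diagnosis, region = region,
             cohort = cohort, stringsAsFactors = FALSE)
}

#' Simulate junction read counts
#'
#' Per sample, the latent PSI is `psi_base`, shifted by `effect_delta` for
#' functional-variant carriers (gated by `effect_in`), with clamped
#' Gaussian noise. Total junction reads are Poisson(`depth`); inclusion
#' reads are Binomial with success probability `2 psi / (1 + psi)`, so the
#' length-normalized PSI estimator is unbiased for the latent value (the
#' inclusion isoform feeds two junctions, the skipping isoform one).
#'
#' @param cfg a `sim_config`.
#' @param carrier_functional_ids sample ids carrying a functional variant.
#' @param sample_table phenotype table (used by `effect_in = "AD_only"`).
#' @return list with `counts` (data.frame `sample_id, ijc, sjc`) and
#'   `latent_psi` (named numeric).
#' @export
simulate_junctions <- function(cfg, carrier_functional_ids, sample_table) {
  set.seed(cfg$seed + 31L)
  ids <- sample_table$sample_id
  carrier <- ids %in% carrier_functional_ids
  gate <- switch(cfg$effect_in,
                 all = rep(TRUE, length(ids)),
                 AD_only = sample_table$diagnosis == "AD",
                 none = rep(FALSE, length(ids)))
  latent <- cfg$psi_base + cfg$effect_delta * (carrier & gate) +
    stats::rnorm(length(ids), 0, cfg$psi_sd)
  latent <- pmin(pmax(latent, 0), 1)
  total <- stats::rpois(length(ids), cfg$depth)
  p_inc <- 2 * latent / (1 + latent)
  ijc <- stats::rbinom(length(ids), total, p_inc)
  counts <- data.frame(sample_id = ids, ijc = ijc, sjc = total - ijc,
                       stringsAsFactors = FALSE)
  list(counts = counts, latent_psi = stats::setNames(latent, ids))
}

#' Simulate a gene expression matrix with planted DEGs
#'
#' Log-normal expression for all samples; `n_planted_degs` genes are
#' multiplied by `deg_fold` in the high-skipping group.
#'
#' @param cfg a `sim_config`.
#' @param high_ids sample ids of the high-skipping group (receive the
#'   fold change).
#' @param sample_ids all sample ids (matrix columns).
#' @return list with `expr` (genes x samples matrix) and
#'   `planted_deg_ids`.
#' @export
simulate_expression <- function(cfg, high_ids, sample_ids) {
  set.seed(cfg$seed + 37L)
  if (cfg$deg_fold <= 0) stop("deg_fold must be positive")
  g <- cfg$n_genes_expr
  genes <- sprintf("gene%04d", seq_len(g))
  expr <- matrix(stats::rlnorm(g * length(sample_ids), meanlog = 3,
                               sdlog = 1),
                 nrow = g, dimnames = list(genes, sample_ids))
  planted <- if (cfg$n_planted_degs > 0) {
    sample(genes, cfg$n_planted_degs)
  } else character(0)
  hi <- intersect(high_ids, sample_ids)
  expr[planted, hi] <- expr[planted, hi] * cfg$deg_fold
  list(expr = expr, planted_deg_ids = sort(planted))
}

#' Generate a complete ground-truthed synthetic dataset
#'
#' Runs every generator stage and returns all in-memory pieces plus the
#' ground truth; [write_dataset] serializes them to standard file formats.
#'
#' @param cfg a `sim_config`.
#' @param target_exon_index 1-based target exon (default 2).
#' @return list: `cfg`, `chrom`, `seq`, `model`, `unit`, `motifs`, `gm`,
#'   `sample_table`, `junctions`, `latent_psi`, `psi`, `skipping_groups`,
#'   `expr`, `truth`.
#' @export
simulate_dataset <- function(cfg, target_exon_index = 2L) {
  motifs <- simulate_motifs(cfg)
  locus <- simulate_locus(cfg)
  unit <- define_splicing_unit(locus$model, target_exon_index)
  pv <- plant_variants(cfg, locus, unit, motifs)
  sample_table <- simulate_samples(cfg)
  jx <- simulate_junctions(cfg, pv$truth$carrier_functional_ids, sample_table)
  psi <- psi_table(jx$counts)
  groups <- tryCatch(define_skipping_groups(psi), error = function(e) NULL)
  ex <- if (!is.null(groups)) {
    simulate_expression(cfg, groups$high_skipping, sample_table$sample_id)
  } else {
    simulate_expression(cfg, character(0), sample_table$sample_id)
  }
  truth <- c(pv$truth, list(latent_psi = jx$latent_psi,
                            planted_deg_ids = ex$planted_deg_ids))
  list(cfg = cfg, chrom = locus$chrom, seq = pv$seq, model = locus$model,
       unit = unit, motifs = motifs, gm = pv$gm,
       sample_table = sample_table, junctions = jx$counts,
       latent_psi = jx$latent_psi, psi = psi, skipping_groups = groups,
       expr = ex$expr, truth = truth)
}

write_gtf <- function(model, path, source = "spliceagg_sim") {
  attr_tx <- sprintf('gene_id "%s"; transcript_id "%s";', model$gene_id,
                     paste0(model$gene_id, ".t1"))
  lines <- c(
    sprintf("%s\t%s\ttranscript\t%d\t%d\t.\t%s\t.\t%s", model$chrom, source,
            min(model$exons$start), max(model$exons$end), model$strand,
            attr_tx),
    sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s", model$chrom, source,
            model$exons$start, model$exons$end, model$strand, attr_tx))
  writeLines(lines, path)
  invisible(path)
}

write_vcf <- function(gm, path, chrom_len = NULL) {
  v <- gm$variants
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(chrom_len))
             sprintf("##contig=<ID=%s,length=%d>", unique(v$chrom)[1],
                     chrom_len),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", gm$samples), collapse = "\t"))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[gm$calls + 1L],
                   nrow = nrow(gm$calls))
  gt_str[is.na(gm$calls)] <- "./."
  body <- vapply(seq_len(nrow(v)), function(j) {
    paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j], ".", "PASS",
            ".", "GT", gt_str[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

write_motif_files <- function(motifs, dir) {
  paths <- list(ese = file.path(dir, "motifs_ese.txt"),
                ess = file.path(dir, "motifs_ess.txt"),
                ise = file.path(dir, "motifs_ise.txt"))
  writeLines(motifs$ESE, paths$ese)
  writeLines(motifs$ESS, paths$ess)
  writeLines(motifs$ISE, paths$ise)
  paths
}

#' Write a simulated dataset to standard file formats
#'
#' Emits `reference.fa`, `gene.gtf`, `variants.vcf`, `junctions.tsv`,
#' `samples.tsv`, `expr.tsv`, `motifs_{ese,ess,ise}.txt` and
#' `ground_truth.json` under `dir`.
#'
#' @param sim output of [simulate_dataset].
#' @param dir output directory (created if missing).
#' @return named list of written paths, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- Biostrings::DNAStringSet(sim$seq)
  names(fa) <- sim$chrom
  paths <- list(fasta = file.path(dir, "reference.fa"),
                gtf = file.path(dir, "gene.gtf"),
                vcf = file.path(dir, "variants.vcf"),
                junctions = file.path(dir, "junctions.tsv"),
                samples = file.path(dir, "samples.tsv"),
                expr = file.path(dir, "expr.tsv"),
                truth = file.path(dir, "ground_truth.json"))
  Biostrings::writeXStringSet(fa, paths$fasta)
  write_gtf(sim$model, paths$gtf)
  write_vcf(sim$gm, paths$vcf, chrom_len = nchar(sim$seq))
  utils::write.table(sim$junctions, paths$junctions, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$sample_table, paths$samples, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expr_df <- data.frame(gene_id = rownames(sim$expr), sim$expr,
                        check.names = FALSE)
  utils::write.table(expr_df, paths$expr, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, write_motif_files(sim$motifs, dir))
  truth <- sim$truth
  truth$true_maf <- as.list(truth$true_maf)
  truth$latent_psi <- as.list(truth$latent_psi)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
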