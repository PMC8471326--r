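#' Read a reference chromosome sequence from FASTA
#'
#' @param fasta_path path to a FASTA file.
#' @param chrom sequence name to extract.
#' @return the sequence as an uppercase character string.
#' @export
read_reference_seq <- function(fasta_path, chrom) {
  fa <- Biostrings::readDNAStringSet(fasta_path)
  nm <- sub("\\s.*$", "", names(fa))
  i <- match(chrom, nm)
  if (is.na(i)) stop("sequence '", chrom, "' not found in ", fasta_path)
  toupper(as.character(fa[[i]]))
}

#' Read a pipeline run configuration
#'
#' YAML file with input paths (`fasta`, `gtf`, `vcf`, `junctions`,
#' `samples`, optional `expr` and `gmt`, `motifs: {ese, ess, ise}`),
#' analysis settings (`gene_id`, optional `transcript_id`,
#' `target_exon_index`, `maf_threshold`, `min_reads`, `permutations`,
#' `seed`, `covariates`) and `out_dir`.
#'
#' @param path path to the YAML config.
#' @return the config as a named list with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  fill_run_config(cfg)
}

fill_run_config <- function(cfg) {
  defaults <- list(target_exon_index = 2L, maf_threshold = 0.05,
                   min_reads = 10, length_normalize = TRUE,
                   permutations = 1000L, seed = 1L,
                   covariates = "region")
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  req <- c("fasta", "gtf", "vcf", "junctions", "samples", "motifs",
           "gene_id", "out_dir")
  miss <- setdiff(req, names(cfg))
  if (length(miss)) stop("run config missing fields: ",
                         paste(miss, collapse = ", "))
  cfg
}

stage <- function(name, expr) {
  message("[", name, "] ...")
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the splicing-guided aggregation pipeline end to end
#'
#' Executes annotate (gene model, splicing unit, variant filtering, SRE
#' scan), PSI quantification, carrier aggregation, the mega-analysis and
#' diagnosis-stratified association with the permutation validation, and —
#' when an expression matrix is configured — quartile skipping groups,
#' Wilcoxon differential expression and gene-set over-representation.
#' Per-stage TSVs and a machine-readable `summary.json` are written to
#' `out_dir`; the run is a pure function of the inputs and the seed.
#'
#' @param config a config list (see [read_run_config]) or a path to a YAML
#'   config file.
#' @return the summary list, invisibly; side effect: files under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- fill_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  model <- stage("gene_model", read_gene_model(cfg$gtf, cfg$gene_id,
                                               cfg$transcript_id))
  unit <- stage("splicing_unit",
                define_splicing_unit(model, cfg$target_exon_index))
  ref_seq <- stage("reference", read_reference_seq(cfg$fasta, model$chrom))
  gm_all <- stage("variants", read_variants(cfg$vcf, unit))
  message("  variants in unit: ", nrow(gm_all$variants))
  gm <- stage("maf_filter", filter_low_frequency(gm_all, cfg$maf_threshold))
  message("  low-frequency (0 < MAF < ", cfg$maf_threshold, "): ",
          nrow(gm$variants))
  motifs <- stage("motifs", read_sre_motifs(ese = cfg$motifs$ese,
                                            ess = cfg$motifs$ess,
                                            ise = cfg$motifs$ise))
  ann <- stage("sre_scan", annotate_all(gm, ref_seq, unit, motifs))
  message("  functional (SRE loss): ", sum(ann$functional))
  write_annotations(ann, file.path(cfg$out_dir, "annotations.tsv"))

  groups <- stage("grouping", assign_groups(gm, ann))
  write_tsv(groups, file.path(cfg$out_dir, "groups.tsv"))
  message("  variant group: ", sum(groups$carrier_any),
          "; functional variant group: ", sum(groups$carrier_functional))

  counts <- stage("junctions", read_junction_counts(cfg$junctions))
  psi <- stage("psi", psi_table(counts, min_reads = cfg$min_reads,
                                length_normalize = cfg$length_normalize))
  write_tsv(psi, file.path(cfg$out_dir, "psi.tsv"))
  sample_table <- stage("samples", read_sample_table(cfg$samples))

  assoc <- stage("association",
                 stratified_association(psi, groups, sample_table,
                                        indicator = "functional",
                                        covariates = cfg$covariates))
  assoc_any <- stage("association_any", tryCatch(
    fit_association(psi, groups, indicator = "any",
                    covariates = cfg$covariates,
                    sample_table = sample_table),
    error = function(e) NULL))
  perm <- stage("permutation",
                permutation_test(psi, groups, b = cfg$permutations,
                                 seed = cfg$seed,
                                 covariates = cfg$covariates,
                                 sample_table = sample_table))
  assoc_out <- assoc
  assoc_out$empirical_p <- ifelse(assoc_out$stratum == "all",
                                  perm$empirical_p, NA_real_)
  assoc_out$n_extreme <- ifelse(assoc_out$stratum == "all",
                                perm$n_extreme, NA_integer_)
  assoc_out$b <- ifelse(assoc_out$stratum == "all", perm$b, NA_integer_)
  assoc_out$seed <- cfg$seed
  write_tsv(assoc_out, file.path(cfg$out_dir, "association.tsv"))

  de_summary <- NULL
  enr_summary <- NULL
  if (!is.null(cfg$expr)) {
    expr <- stage("expression", read_expression(cfg$expr))
    sk <- stage("skipping_groups", define_skipping_groups(psi))
    deg <- stage("wilcoxon_de",
                 wilcoxon_de(expr, sk$high_skipping, sk$low_skipping))
    write_tsv(deg, file.path(cfg$out_dir, "deg_results.tsv"))
    de_summary <- list(q1 = sk$q1, q3 = sk$q3,
                       n_high_skipping = length(sk$high_skipping),
                       n_low_skipping = length(sk$low_skipping),
                       n_significant = sum(deg$significant))
    message("  DEGs (FDR<0.05, |FC|>2): ", sum(deg$significant))
    if (!is.null(cfg$gmt)) {
      sets <- stage("gene_sets", read_gmt(cfg$gmt))
      enr <- stage("enrichment",
                   enrichment(deg$gene_id[deg$significant], sets,
                              deg$gene_id))
      write_tsv(enr, file.path(cfg$out_dir, "enrichment.tsv"))
      enr_summary <- list(n_sets = length(sets),
                          n_significant = sum(enr$significant))
    }
  }

  psi_sm <- attr(psi, "summary")
  summary <- list(
    seed = cfg$seed,
    counts = list(
      n_samples = nrow(sample_table),
      n_variants_in_unit = nrow(gm_all$variants),
      n_low_frequency = nrow(gm$variants),
      n_functional = sum(ann$functional),
      n_variant_group = sum(groups$carrier_any),
      n_functional_group = sum(groups$carrier_functional)),
    psi = psi_sm,
    association = assoc_out,
    association_any = assoc_any,
    permutation = list(b = perm$b, n_extreme = perm$n_extreme,
                       empirical_p = perm$empirical_p),
    de = de_summary,
    enrichment = enr_summary)
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  invisible(summary)
}
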