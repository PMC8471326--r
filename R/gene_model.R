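#' Read a single-transcript gene model from a GTF file
#'
#' Builds the exon structure of one transcript. The analysis operates on a
#' single transcript model per run: the splicing unit of an internal exon is
#' defined by that transcript's exon boundaries.
#'
#' Coordinates are kept in the GTF convention (1-based, closed intervals),
#' the convention shared by VCF and the Bioconductor ranges stack, so no
#' conversion happens at this boundary.
#'
#' @param gtf_path path to a GTF file.
#' @param gene_id gene identifier to select (matched against the GTF
#'   `gene_id` attribute).
#' @param transcript_id transcript identifier; if `NULL`, the gene must have
#'   exactly one transcript.
#' @return an object of class `gene_model` with fields `gene_id`, `chrom`,
#'   `strand` (`"+"` or `"-"`) and `exons`, a data.frame of `start`/`end`
#'   sorted by genomic start.
#' @export
read_gene_model <- function(gtf_path, gene_id, transcript_id = NULL) {
  stopifnot(file.exists(gtf_path))
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  keep <- md$type == "exon" & md$gene_id == gene_id
  if (!is.null(transcript_id)) {
    keep <- keep & md$transcript_id == transcript_id
  }
  ex <- gr[which(keep)]
  if (length(ex) == 0L) {
    stop("transcript not found: gene_id=", gene_id,
         if (!is.null(transcript_id)) paste0(" transcript_id=", transcript_id))
  }
  tx <- unique(S4Vectors::mcols(ex)$transcript_id)
  if (length(tx) > 1L) {
    stop("gene ", gene_id, " has ", length(tx),
         " transcripts; pass transcript_id to select one")
  }
  ex <- ex[order(GenomicRanges::start(ex))]
  exons <- data.frame(start = GenomicRanges::start(ex),
                      end   = GenomicRanges::end(ex))
  validate_exons(exons)
  if (nrow(exons) < 3L) {
    stop("no internal exon: transcript has ", nrow(exons), " exons (need >= 3)")
  }
  structure(
    list(gene_id = gene_id,
         chrom = as.character(GenomicRanges::seqnames(ex))[1],
         strand = as.character(GenomicRanges::strand(ex))[1],
         exons = exons),
    class = "gene_model"
  )
}

validate_exons <- function(exons) {
  stopifnot(all(exons$end >= exons$start))
  if (nrow(exons) > 1L) {
    if (any(diff(exons$start) <= 0) ||
        any(exons$start[-1] <= exons$end[-nrow(exons)])) {
      stop("exons must be non-overlapping and sorted by genomic position")
    }
  }
  invisible(exons)
}

#' Construct a gene model directly from exon coordinates
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome/sequence name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with `start` and `end` columns, 1-based closed,
#'   sorted by genomic start, non-overlapping.
#' @return a `gene_model` object.
#' @export
gene_model <- function(gene_id, chrom, strand, exons) {
  stopifnot(strand %in% c("+", "-"))
  exons <- as.data.frame(exons)[, c("start", "end")]
  validate_exons(exons)
  if (nrow(exons) < 3L) stop("no internal exon: need >= 3 exons")
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = exons),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model:", x$gene_id, sprintf("(%s%s)", x$chrom, x$strand),
      nrow(x$exons), "exons\n")
  invisible(x)
}

#' Define the splicing unit of an internal exon
#'
#' The splicing unit is the genomic region within which variants can locally
#' affect splicing of the target exon: the target exon itself, its two
#' flanking introns, and the two neighboring exons.
#'
#' @param model a `gene_model`.
#' @param target_exon_index 1-based index of the target exon in genomic
#'   order; must be internal (neither first nor last).
#' @return an object of class `splicing_unit` with interval fields
#'   `upstream_exon`, `upstream_intron`, `target_exon`, `downstream_intron`,
#'   `downstream_exon` and `span` (each a length-2 integer `c(start, end)`,
#'   1-based closed), plus `chrom`, `strand`, `target_exon_index`.
#' @export
define_splicing_unit <- function(model, target_exon_index = 2L) {
  stopifnot(inherits(model, "gene_model"))
  i <- as.integer(target_exon_index)
  n <- nrow(model$exons)
  if (i <= 1L || i >= n) {
    stop("target exon must be internal: index ", i, " of ", n, " exons")
  }
  ex <- function(j) c(model$exons$start[j], model$exons$end[j])
  up <- ex(i - 1L); tg <- ex(i); dn <- ex(i + 1L)
  unit <- list(
    target_exon_index = i,
    chrom = model$chrom,
    strand = model$strand,
    upstream_exon = up,
    upstream_intron = c(up[2] + 1L, tg[1] - 1L),
    target_exon = tg,
    downstream_intron = c(tg[2] + 1L, dn[1] - 1L),
    downstream_exon = dn,
    span = c(up[1], dn[2])
  )
  structure(unit, class = "splicing_unit")
}

#' @export
print.splicing_unit <- function(x, ...) {
  cat(sprintf("splicing_unit: exon %d on %s%s, span %d-%d (%d bp)\n",
              x$target_exon_index, x$chrom, x$strand, x$span[1], x$span[2],
              x$span[2] - x$span[1] + 1L))
  invisible(x)
}

unit_intervals <- function(unit) {
  list(upstream_exon = unit$upstream_exon,
       upstream_intron = unit$upstream_intron,
       target_exon = unit$target_exon,
       downstream_intron = unit$downstream_intron,
       downstream_exon = unit$downstream_exon)
}

pos_in_interval <- function(pos, iv) pos >= iv[1] & pos <= iv[2]

#' Read variant genotypes within a splicing unit from a VCF file
#'
#' Parses a VCF (via [VariantAnnotation::readVcf]), keeps records whose POS
#' falls inside the unit span, splits multi-allelic records into one variant
#' per ALT allele, and computes allele frequencies from the genotype calls.
#' Missing genotypes are excluded from allele-frequency denominators.
#'
#' @param vcf_path path to a VCF file with a GT FORMAT field.
#' @param unit a `splicing_unit`; only records inside its span are kept.
#' @return an object of class `genotype_matrix`: `samples` (character),
#'   `variants` (data.frame `id, chrom, pos, ref, alt, af, maf`), and
#'   `calls`, an integer samples x variants matrix of ALT allele counts in
#'   {0, 1, 2, NA}.
#' @export
read_variants <- function(vcf_path, unit) {
  stopifnot(file.exists(vcf_path), inherits(unit, "splicing_unit"))
  vcf <- VariantAnnotation::readVcf(vcf_path, genome = "unknown")
  if (!"GT" %in% names(VariantAnnotation::geno(vcf))) {
    stop("VCF has no GT FORMAT field: ", vcf_path)
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  keep <- which(chrom == unit$chrom & pos >= unit$span[1] & pos <= unit$span[2])
  gt <- VariantAnnotation::geno(vcf)$GT  # variants x samples, character
  samples <- colnames(gt)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt_list <- VariantAnnotation::alt(vcf)
  ids <- names(rr)

  var_rows <- list()
  call_cols <- list()
  for (k in keep) {
    alts <- as.character(alt_list[[k]])
    gts <- gt[k, ]
    alleles <- strsplit(gts, "[/|]")
    for (ai in seq_along(alts)) {
      cnt <- vapply(alleles, function(a) {
        if (any(a == "." | a == "")) return(NA_integer_)
        sum(a == as.character(ai))
      }, integer(1))
      nm <- sum(!is.na(cnt))
      af <- if (nm > 0) sum(cnt, na.rm = TRUE) / (2 * nm) else NA_real_
      id <- ids[k]
      if (length(alts) > 1L) id <- paste0(id, "_", alts[ai])
      var_rows[[length(var_rows) + 1L]] <- data.frame(
        id = id, chrom = chrom[k], pos = pos[k], ref = ref[k], alt = alts[ai],
        af = af, maf = min(af, 1 - af), stringsAsFactors = FALSE)
      call_cols[[length(call_cols) + 1L]] <- cnt
    }
  }
  variants <- if (length(var_rows)) do.call(rbind, var_rows) else
    data.frame(id = character(), chrom = character(), pos = integer(),
               ref = character(), alt = character(), af = numeric(),
               maf = numeric(), stringsAsFactors = FALSE)
  calls <- if (length(call_cols)) do.call(cbind, call_cols) else
    matrix(integer(), nrow = length(samples), ncol = 0)
  if (length(call_cols)) {
    rownames(calls) <- samples
    colnames(calls) <- variants$id
  }
  genotype_matrix(samples, variants, calls)
}

#' Construct a genotype matrix object
#'
#' @param samples character vector of sample ids.
#' @param variants data.frame with columns `id, chrom, pos, ref, alt, af, maf`.
#' @param calls integer matrix, samples x variants, ALT allele counts
#'   (0/1/2/NA).
#' @return a `genotype_matrix`.
#' @export
genotype_matrix <- function(samples, variants, calls) {
  calls <- as.matrix(calls)
  if (nrow(variants) > 0L) {
    stopifnot(nrow(calls) == length(samples), ncol(calls) == nrow(variants))
    stopifnot(all(variants$ref != variants$alt))
  }
  structure(list(samples = samples, variants = variants, calls = calls),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$samples), "samples x",
      nrow(x$variants), "variants\n")
  invisible(x)
}

#' Keep polymorphic low-frequency variants
#'
#' Retains variants with `0 < maf < maf_threshold` (strict on both sides:
#' monomorphic variants cannot define carriers and are dropped). Order is
#' preserved.
#'
#' @param gm a `genotype_matrix`.
#' @param maf_threshold minor-allele-frequency cutoff (default 0.05, the
#'   conventional low-frequency bound).
#' @return a filtered `genotype_matrix`.
#' @export
filter_low_frequency <- function(gm, maf_threshold = 0.05) {
  stopifnot(inherits(gm, "genotype_matrix"))
  keep <- which(!is.na(gm$variants$maf) &
                gm$variants$maf > 0 & gm$variants$maf < maf_threshold)
  genotype_matrix(gm$samples,
                  gm$variants[keep, , drop = FALSE],
                  gm$calls[, keep, drop = FALSE])
}

#' Read a sample phenotype table
#'
#' Tab-separated table with header columns `sample_id`, `diagnosis`
#' (CN/AD), `region`, `cohort`.
#'
#' @param path path to the TSV file.
#' @return a data.frame; sample ids are checked unique.
#' @export
read_sample_table <- function(path) {
  st <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "diagnosis", "region", "cohort")
  miss <- setdiff(req, names(st))
  if (length(miss)) stop("sample table missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(st$sample_id)) stop("duplicate sample ids in sample table")
  st
}
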