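#' Read SRE hexamer motif sets
#'
#' Splicing regulatory elements (SREs) are hexameric cis-acting motifs
#' recruiting RNA-binding proteins that guide spliceosome recognition. Three
#' classes are used: exonic splicing enhancers (ESE), exonic splicing
#' silencers (ESS), and intronic splicing enhancers (ISE). Each motif file
#' holds one 6-mer per line; lines are upper-cased and deduplicated.
#'
#' @param ese,ess,ise paths to motif files (any may be `NULL` for an empty
#'   class).
#' @return an `sre_motifs` object: a named list of character vectors
#'   (`ESE`, `ESS`, `ISE`).
#' @export
read_sre_motifs <- function(ese = NULL, ess = NULL, ise = NULL) {
  read_one <- function(path) {
    if (is.null(path)) return(character())
    x <- toupper(trimws(readLines(path)))
    x <- x[nzchar(x)]
    validate_motifs(x)
  }
  sre_motifs(ESE = read_one(ese), ESS = read_one(ess), ISE = read_one(ise))
}

validate_motifs <- function(x) {
  x <- unique(toupper(x))
  bad <- x[nchar(x) != 6L | grepl("[^ACGT]", x)]
  if (length(bad)) stop("invalid hexamer motif(s): ",
                        paste(utils::head(bad, 5), collapse = ", "))
  x
}

#' Construct an SRE motif set from character vectors
#'
#' @param ESE,ESS,ISE character vectors of 6-mers over A/C/G/T.
#' @return an `sre_motifs` object.
#' @export
sre_motifs <- function(ESE = character(), ESS = character(),
                       ISE = character()) {
  structure(list(ESE = validate_motifs(ESE), ESS = validate_motifs(ESS),
                 ISE = validate_motifs(ISE)),
            class = "sre_motifs")
}

#' @export
print.sre_motifs <- function(x, ...) {
  cat(sprintf("sre_motifs: ESE=%d ESS=%d ISE=%d hexamers\n",
              length(x$ESE), length(x$ESS), length(x$ISE)))
  invisible(x)
}

# Motif classes scanned for a variant, by the compartment it falls in:
# exonic variants can destroy ESE or ESS motifs, intronic variants ISE motifs.
applicable_classes <- function(region_class) {
  switch(region_class, exonic = c("ESE", "ESS"), intronic = "ISE",
         stop("unknown region class: ", region_class))
}

#' Classify a variant position as exonic or intronic within a splicing unit
#'
#' @param pos 1-based genomic position (VCF POS).
#' @param unit a `splicing_unit`.
#' @return `"exonic"` if the position falls in the target or a neighboring
#'   exon, `"intronic"` if in a flanking intron.
#' @export
classify_region <- function(pos, unit) {
  stopifnot(inherits(unit, "splicing_unit"))
  if (pos < unit$span[1] || pos > unit$span[2]) {
    stop("variant position ", pos, " outside splicing unit span ",
         unit$span[1], "-", unit$span[2])
  }
  exonic <- pos_in_interval(pos, unit$upstream_exon) ||
    pos_in_interval(pos, unit$target_exon) ||
    pos_in_interval(pos, unit$downstream_exon)
  if (exonic) "exonic" else "intronic"
}

rev_comp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

comp_base <- function(b) chartr("ACGT", "TGCA", b)

#' Enumerate reference/alternative hexamer windows around an SNV
#'
#' Every 6-mer of the reference sequence overlapping the variant position is
#' paired with the same window carrying the alternative allele. Up to six
#' windows exist (window starts at offsets -5..0 from the position on the
#' gene strand); windows truncated by sequence ends are omitted. For
#' minus-strand genes the sequence and alleles are oriented to the
#' transcribed strand before windowing, so motif matching always happens in
#' the sense of the pre-mRNA.
#'
#' @param ref_seq the chromosome sequence as a single character string (plus
#'   strand of the reference).
#' @param pos 1-based position of the SNV on the reference.
#' @param ref,alt single-base reference and alternative alleles (plus-strand,
#'   as in the VCF).
#' @param strand gene strand, `"+"` (default) or `"-"`.
#' @return a data.frame with columns `offset` (window start relative to the
#'   variant position, gene-strand orientation, in -5..0), `ref_hexamer`,
#'   `alt_hexamer`.
#' @export
hexamer_windows <- function(ref_seq, pos, ref, alt, strand = "+") {
  if (nchar(ref) != 1L || nchar(alt) != 1L) {
    stop("hexamer windows are defined for SNVs only (got ", ref, ">", alt, ")")
  }
  n <- nchar(ref_seq)
  stopifnot(pos >= 1L, pos <= n)
  if (substr(ref_seq, pos, pos) != toupper(ref)) {
    stop("REF allele does not match FASTA at position ", pos, ": expected ",
         ref, ", found ", substr(ref_seq, pos, pos))
  }
  if (strand == "-") {
    ref_seq <- rev_comp(ref_seq)
    pos <- n - pos + 1L
    ref <- comp_base(toupper(ref))
    alt <- comp_base(toupper(alt))
  }
  out <- list()
  for (off in -5:0) {
    s <- pos + off
    if (s < 1L || s + 5L > n) next
    rh <- substr(ref_seq, s, s + 5L)
    ah <- rh
    substr(ah, 1L - off, 1L - off) <- toupper(alt)
    out[[length(out) + 1L]] <- data.frame(offset = off, ref_hexamer = rh,
                                          alt_hexamer = ah,
                                          stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(offset = integer(), ref_hexamer = character(),
               alt_hexamer = character(), stringsAsFactors = FALSE)
}

# Core loss test: for each window and each applicable motif class, a loss is
# recorded when the reference hexamer is in the class set and the alternative
# hexamer is not in that same set (no cross-class rescue).
hexamer_losses <- function(windows, motifs, classes) {
  out <- list()
  for (cl in classes) {
    set <- motifs[[cl]]
    if (!length(set)) next
    hit <- windows$ref_hexamer %in% set & !(windows$alt_hexamer %in% set)
    if (any(hit)) {
      w <- windows[hit, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        offset = w$offset, class_label = cl, ref_hexamer = w$ref_hexamer,
        alt_hexamer = w$alt_hexamer, stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(offset = integer(), class_label = character(),
               ref_hexamer = character(), alt_hexamer = character(),
               stringsAsFactors = FALSE)
}

#' Annotate one variant for SRE loss-of-function
#'
#' A variant is "functional" when its alternative allele destroys at least
#' one SRE hexamer present in the reference allele: some window's reference
#' 6-mer perfectly matches a motif of the applicable class (ESE/ESS for
#' exonic positions, ISE for intronic) while the same window with the
#' alternative allele no longer matches that class. Motif gain is not
#' considered. Non-SNVs are not scanned: they are marked non-functional with
#' a warning (hexamer windowing is defined for single-base substitutions).
#'
#' @param variant one-row data.frame (or list) with `id`, `pos`, `ref`,
#'   `alt`.
#' @param ref_seq chromosome sequence (plus strand) as a character string.
#' @param unit a `splicing_unit`.
#' @param motifs an `sre_motifs` object.
#' @return a one-row data.frame: `variant_id`, `pos`, `region_class`,
#'   `functional` (logical), `n_lost`, `lost_motifs` (list column of
#'   data.frames with `offset`, `class_label`, `ref_hexamer`,
#'   `alt_hexamer`).
#' @export
annotate_variant <- function(variant, ref_seq, unit, motifs) {
  stopifnot(inherits(unit, "splicing_unit"), inherits(motifs, "sre_motifs"))
  region <- classify_region(variant$pos, unit)
  if (nchar(variant$ref) != 1L || nchar(variant$alt) != 1L) {
    warning("variant ", variant$id,
            " is not an SNV; skipped by the SRE scanner (non-functional)")
    losses <- hexamer_losses(
      data.frame(offset = integer(), ref_hexamer = character(),
                 alt_hexamer = character()), motifs, character())
  } else {
    win <- hexamer_windows(ref_seq, variant$pos, variant$ref, variant$alt,
                           strand = unit$strand)
    losses <- hexamer_losses(win, motifs, applicable_classes(region))
  }
  res <- data.frame(variant_id = variant$id, pos = variant$pos,
                    region_class = region,
                    functional = nrow(losses) > 0L,
                    n_lost = nrow(losses), stringsAsFactors = FALSE)
  res$lost_motifs <- list(losses)
  res
}

#' Annotate all variants of a genotype matrix
#'
#' @param gm a `genotype_matrix` (typically already filtered to
#'   low-frequency variants inside the unit).
#' @param ref_seq chromosome sequence (plus strand) as a character string.
#' @param unit a `splicing_unit`.
#' @param motifs an `sre_motifs` object.
#' @return a data.frame with one row per variant in `gm$variants` order (see
#'   [annotate_variant]).
#' @export
annotate_all <- function(gm, ref_seq, unit, motifs) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (nrow(gm$variants) == 0L) {
    out <- data.frame(variant_id = character(), pos = integer(),
                      region_class = character(), functional = logical(),
                      n_lost = integer(), stringsAsFactors = FALSE)
    out$lost_motifs <- list()
    return(out)
  }
  rows <- lapply(seq_len(nrow(gm$variants)), function(i) {
    annotate_variant(gm$variants[i, ], ref_seq, unit, motifs)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a variant annotation table as TSV
#'
#' @param annotations output of [annotate_all].
#' @param path output path.
#' @export
write_annotations <- function(annotations, path) {
  flat <- annotations[, c("variant_id", "pos", "region_class", "functional")]
  flat$lost_motifs <- vapply(annotations$lost_motifs, function(l) {
    if (nrow(l) == 0L) return("")
    paste(sprintf("%s:%s>%s@%d", l$class_label, l$ref_hexamer, l$alt_hexamer,
                  l$offset), collapse = ",")
  }, character(1))
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
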