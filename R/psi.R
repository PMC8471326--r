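#' Percent spliced in from inclusion and skipping junction reads
#'
#' PSI is the fraction of transcripts including the target exon: 0 means
#' the exon is skipped in all transcripts (all reads support the skipping
#' junction), 1 means it is included in all transcripts (all reads support
#' the inclusion junctions). The inclusion isoform contributes two junctions
#' (upstream-target and target-downstream) against one for the skipping
#' isoform, so with `length_normalize = TRUE` (the rMATS junction-count
#' convention) inclusion reads are halved:
#' `psi = (ijc/2) / (ijc/2 + sjc)`; without normalization
#' `psi = ijc / (ijc + sjc)`. Samples with fewer than `min_reads` total
#' junction reads get `NA`.
#'
#' @param ijc,sjc non-negative inclusion and skipping junction read counts
#'   (vectorized).
#' @param min_reads minimum total junction reads to report a PSI
#'   (default 10).
#' @param length_normalize halve inclusion counts (default `TRUE`).
#' @return numeric vector of PSI values in `[0, 1]`, `NA` below coverage.
#' @export
compute_psi <- function(ijc, sjc, min_reads = 10, length_normalize = TRUE) {
  if (any(ijc < 0, na.rm = TRUE) || any(sjc < 0, na.rm = TRUE)) {
    stop("junction counts must be non-negative")
  }
  inc <- if (length_normalize) ijc / 2 else ijc
  psi <- inc / (inc + sjc)
  psi[ijc + sjc == 0] <- NA_real_
  psi[ijc + sjc < min_reads] <- NA_real_
  psi
}

#' Per-sample PSI table from junction counts
#'
#' @param counts data.frame with columns `sample_id`, `ijc`, `sjc` (one row
#'   per sample).
#' @param min_reads,length_normalize see [compute_psi].
#' @return data.frame `sample_id, ijc, sjc, total_support, psi`, with a
#'   `summary` attribute (n, n_quantified, mean, quartiles over non-missing
#'   PSI).
#' @export
psi_table <- function(counts, min_reads = 10, length_normalize = TRUE) {
  req <- c("sample_id", "ijc", "sjc")
  miss <- setdiff(req, names(counts))
  if (length(miss)) stop("junction count table missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(counts$sample_id)) {
    stop("duplicate sample ids in junction counts: ",
         paste(unique(counts$sample_id[duplicated(counts$sample_id)]),
               collapse = ", "))
  }
  psi <- compute_psi(counts$ijc, counts$sjc, min_reads = min_reads,
                     length_normalize = length_normalize)
  out <- data.frame(sample_id = counts$sample_id, ijc = counts$ijc,
                    sjc = counts$sjc, total_support = counts$ijc + counts$sjc,
                    psi = psi, stringsAsFactors = FALSE)
  ok <- !is.na(psi)
  if (!any(ok)) {
    warning("no sample reaches min_reads = ", min_reads,
            "; PSI summary is empty")
    smry <- list(n = nrow(out), n_quantified = 0L, mean = NA_real_,
                 q1 = NA_real_, median = NA_real_, q3 = NA_real_)
  } else {
    q <- stats::quantile(psi[ok], c(0.25, 0.5, 0.75), names = FALSE)
    smry <- list(n = nrow(out), n_quantified = sum(ok), mean = mean(psi[ok]),
                 q1 = q[1], median = q[2], q3 = q[3])
  }
  attr(out, "summary") <- smry
  out
}

#' Read a junction-count TSV
#'
#' Expects header `sample_id  ijc  sjc`; rMATS-style column names
#' (`IJC_SAMPLE_1`, `SJC_SAMPLE_1`) are also accepted and mapped.
#'
#' @param path path to the TSV.
#' @return data.frame with `sample_id`, `ijc`, `sjc`.
#' @export
read_junction_counts <- function(path) {
  jc <- utils::read.delim(path, stringsAsFactors = FALSE)
  nm <- names(jc)
  if ("IJC_SAMPLE_1" %in% nm) names(jc)[nm == "IJC_SAMPLE_1"] <- "ijc"
  if ("SJC_SAMPLE_1" %in% nm) names(jc)[nm == "SJC_SAMPLE_1"] <- "sjc"
  miss <- setdiff(c("sample_id", "ijc", "sjc"), names(jc))
  if (length(miss)) stop("junction count file missing columns: ",
                         paste(miss, collapse = ", "))
  jc
}
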