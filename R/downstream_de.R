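#' Define high- and low-skipping sample groups from PSI quartiles
#'
#' High-skipping samples have PSI below the first quartile (more exon
#' skipping = lower PSI); low-skipping samples have PSI at or above the
#' third quartile. The third quartile frequently equals the maximum (PSI =
#' 1) for near-constitutive exons, so the low-skipping comparison is `>=`
#' rather than strict. Quartiles use linear interpolation (the default
#' empirical quantile definition, type 7).
#'
#' @param psi PSI table (data.frame with `sample_id`, `psi`).
#' @return list with `high_skipping` and `low_skipping` sample id vectors
#'   and the quartiles `q1`, `q3`.
#' @export
define_skipping_groups <- function(psi) {
  ok <- !is.na(psi$psi)
  if (sum(ok) < 4L) stop("need >= 4 samples with non-missing PSI")
  v <- psi$psi[ok]
  ids <- psi$sample_id[ok]
  q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
  high <- ids[v < q[1]]
  low <- ids[v >= q[2]]
  if (length(high) == 0L || length(low) == 0L) {
    stop(sprintf(
      "degenerate PSI quartiles (q1 = %.4g, q3 = %.4g): high/low skipping groups %d/%d",
      q[1], q[2], length(high), length(low)))
  }
  list(high_skipping = high, low_skipping = low, q1 = q[1], q3 = q[2])
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH q-values with monotonicity enforcement; input order is
#' preserved.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1] with no missing values")
  }
  stats::p.adjust(p, method = "BH")
}

#' Wilcoxon rank-sum differential expression between skipping groups
#'
#' Per gene, compares expression of high-skipping vs low-skipping samples
#' with the Wilcoxon rank-sum test: exact two-sided p-values when both
#' groups have at most 8 samples and values are tie-free, otherwise the
#' normal approximation with tie correction and continuity correction. Fold
#' change is the pseudocount-stabilized ratio of group means (high over
#' low). Significance requires BH FDR q < `fdr_cutoff` and a two-fold change
#' in either direction.
#'
#' @param expr expression matrix (genes x samples; rownames gene ids,
#'   colnames sample ids; non-negative normalized values).
#' @param high_ids,low_ids sample ids of the high- and low-skipping groups.
#' @param pseudocount stabilizer added to both group means (default 1e-6).
#' @param fdr_cutoff,fc_cutoff significance thresholds (defaults 0.05 and
#'   2).
#' @return data.frame `gene_id, mean_high, mean_low, fold_change, w_stat,
#'   p_value, fdr_q, significant`.
#' @export
wilcoxon_de <- function(expr, high_ids, low_ids, pseudocount = 1e-6,
                        fdr_cutoff = 0.05, fc_cutoff = 2) {
  expr <- as.matrix(expr)
  if (any(expr < 0)) stop("expression matrix has negative entries")
  missing_ids <- setdiff(c(high_ids, low_ids), colnames(expr))
  if (length(missing_ids)) {
    stop("sample id(s) absent from expression matrix: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  }
  if (length(high_ids) < 2L || length(low_ids) < 2L) {
    stop("both groups need >= 2 samples")
  }
  hi <- expr[, high_ids, drop = FALSE]
  lo <- expr[, low_ids, drop = FALSE]
  n1 <- length(high_ids); n2 <- length(low_ids)
  res <- t(vapply(seq_len(nrow(expr)), function(i) {
    x <- hi[i, ]; y <- lo[i, ]
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = "two.sided",
                         exact = (n1 <= 8 && n2 <= 8), correct = TRUE))
    # a gene with fully tied values carries no rank information
    p <- if (is.nan(wt$p.value)) 1 else wt$p.value
    c(w = unname(wt$statistic), p = p)
  }, numeric(2)))
  mean_hi <- rowMeans(hi)
  mean_lo <- rowMeans(lo)
  fc <- (mean_hi + pseudocount) / (mean_lo + pseudocount)
  q <- bh_fdr(res[, "p"])
  data.frame(gene_id = rownames(expr),
             mean_high = mean_hi, mean_low = mean_lo, fold_change = fc,
             w_stat = res[, "w"], p_value = res[, "p"], fdr_q = q,
             significant = q < fdr_cutoff &
               (fc > fc_cutoff | fc < 1 / fc_cutoff),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Hypergeometric gene-set over-representation
#'
#' One-sided upper-tail hypergeometric test of each gene set's overlap with
#' the differentially expressed genes against a universe (all genes tested),
#' BH-corrected across sets; significance at q < 0.05. Gene sets are
#' intersected with the universe before testing.
#'
#' @param deg_ids character vector of significant gene ids (must be a
#'   subset of `universe_ids`).
#' @param gene_sets named list of character vectors (e.g. from
#'   [read_gmt]).
#' @param universe_ids background gene ids.
#' @param fdr_cutoff significance threshold on q (default 0.05).
#' @return data.frame `set_name, overlap, set_size, deg_size,
#'   universe_size, p_value, fdr_q, significant`.
#' @export
enrichment <- function(deg_ids, gene_sets, universe_ids, fdr_cutoff = 0.05) {
  universe_ids <- unique(universe_ids)
  if (length(universe_ids) == 0L) stop("empty gene universe")
  stray <- setdiff(deg_ids, universe_ids)
  if (length(stray)) {
    stop("DEG ids not in universe: ",
         paste(utils::head(stray, 5), collapse = ", "))
  }
  deg_ids <- unique(deg_ids)
  n_u <- length(universe_ids); n_d <- length(deg_ids)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe_ids)
    ov <- length(intersect(set, deg_ids))
    p <- stats::phyper(ov - 1, length(set), n_u - length(set), n_d,
                       lower.tail = FALSE)
    data.frame(set_name = nm, overlap = ov, set_size = length(set),
               deg_size = n_d, universe_size = n_u, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr_q <- bh_fdr(out$p_value)
  out$significant <- out$fdr_q < fdr_cutoff
  out[order(out$p_value), , drop = FALSE]
}

#' Read gene sets in GMT format
#'
#' @param path path to a GMT file (set name, description, member genes,
#'   tab-separated).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Read a gene x sample expression TSV
#'
#' First column holds gene ids; remaining columns are samples.
#'
#' @param path path to the TSV.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
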