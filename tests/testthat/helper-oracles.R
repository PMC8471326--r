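# Independent oracles and tiny fixture builders. These never call the
# implementation paths they are used to check.

# Brute-force SRE loss oracle: enumerate EVERY 6-mer substring of the full
# reference and alternative sequences; a loss exists when some position whose
# window overlaps the variant has a motif hit (of an applicable class) in the
# reference substring and no hit of that class at the same position in the
# alternative substring.
oracle_sre_loss <- function(seq, pos, ref, alt, motif_sets, classes,
                            strand = "+") {
  stopifnot(substr(seq, pos, pos) == ref)
  if (strand == "-") {
    rc <- function(s) {
      paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
    }
    n <- nchar(seq)
    seq <- rc(seq)
    pos <- n - pos + 1L
    ref <- chartr("ACGT", "TGCA", ref)
    alt <- chartr("ACGT", "TGCA", alt)
  }
  alt_seq <- seq
  substr(alt_seq, pos, pos) <- alt
  n <- nchar(seq)
  losses <- 0L
  for (cl in classes) {
    set <- motif_sets[[cl]]
    if (!length(set)) next
    for (i in seq_len(max(n - 5L, 0L))) {
      if (!(i <= pos && pos <= i + 5L)) next
      ref_hex <- substr(seq, i, i + 5L)
      alt_hex <- substr(alt_seq, i, i + 5L)
      if (ref_hex %in% set && !(alt_hex %in% set)) losses <- losses + 1L
    }
  }
  list(functional = losses > 0L, n_lost = losses)
}

# Step-up Benjamini-Hochberg from the definition: sort, q_(i) =
# min_{j >= i} p_(j) * m / j, map back to input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(ranked)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Exact two-sided Wilcoxon rank-sum p by full enumeration of all
# choose(n1+n2, n1) group labelings of the combined sample (tie-free data).
oracle_wilcoxon_exact <- function(x, y) {
  ranks <- rank(c(x, y))
  n1 <- length(x)
  w_obs <- sum(ranks[seq_len(n1)])
  mu <- n1 * (length(ranks) + 1) / 2
  combs <- utils::combn(seq_along(ranks), n1)
  w_all <- apply(combs, 2, function(idx) sum(ranks[idx]))
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Hypergeometric upper tail by direct summation.
oracle_hyper_tail <- function(overlap, set_size, deg_size, universe) {
  ks <- overlap:min(set_size, deg_size)
  sum(choose(set_size, ks) * choose(universe - set_size, deg_size - ks)) /
    choose(universe, deg_size)
}

# Internal helpers exercised directly by the suite (the package may be
# attached from an installed library, where only exports are visible).
random_hexamers <- spliceagg:::random_hexamers
applicable_classes <- spliceagg:::applicable_classes
hexamer_losses <- spliceagg:::hexamer_losses

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A hand-written three-exon gene model fixture used across IO tests.
toy_model <- function(strand = "+") {
  gene_model("g1", "chrT", strand,
             data.frame(start = c(101, 301, 501), end = c(200, 400, 600)))
}

write_toy_gtf <- function(path, exons = data.frame(start = c(101, 301, 501),
                                                   end = c(200, 400, 600)),
                          strand = "+", gene = "g1", tx = "g1.t1") {
  attr_s <- sprintf('gene_id "%s"; transcript_id "%s";', gene, tx)
  writeLines(sprintf("chrT\ttest\texon\t%d\t%d\t.\t%s\t.\t%s",
                     exons$start, exons$end, strand, attr_s), path)
  path
}

write_toy_vcf <- function(path, rows, samples) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    rows), path)
  path
}
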