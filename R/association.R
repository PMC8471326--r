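#' Assign carrier groups from genotypes and SRE annotations
#'
#' Splicing-guided aggregation: samples carrying at least one ALT allele at
#' at least one functional (SRE loss-of-function) low-frequency variant form
#' the functional variant group; samples with any low-frequency variant form
#' the variant group. The complements are the non-functional and non-variant
#' groups. Missing genotypes count as zero ALT alleles (conservative).
#'
#' @param gm a `genotype_matrix` of retained low-frequency variants.
#' @param annotations annotation table from [annotate_all]; must cover
#'   exactly the variants in `gm`.
#' @return data.frame `sample_id, carrier_any, carrier_functional,
#'   n_functional_variants`.
#' @export
assign_groups <- function(gm, annotations) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!identical(as.character(annotations$variant_id),
                 as.character(gm$variants$id))) {
    stop("annotations do not match genotype matrix variants")
  }
  calls <- gm$calls
  calls[is.na(calls)] <- 0L
  func <- annotations$functional
  carrier_any <- if (ncol(calls)) rowSums(calls > 0) > 0 else
    rep(FALSE, length(gm$samples))
  nf <- if (any(func)) rowSums(calls[, func, drop = FALSE] > 0) else
    rep(0L, length(gm$samples))
  data.frame(sample_id = gm$samples,
             carrier_any = as.logical(carrier_any),
             carrier_functional = nf > 0,
             n_functional_variants = as.integer(nf),
             stringsAsFactors = FALSE)
}

# Least-squares fit reporting inference for the group indicator (column 2 of
# the design). Shared by the observed fit and the permutation refits so both
# go through identical numerics.
ols_group_test <- function(y, X) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[-seq_len(qr_x$rank)]]
    stop("collinear design; offending column(s): ",
         paste(dropped, collapse = ", "))
  }
  coefs <- qr.coef(qr_x, y)
  res <- y - X %*% coefs
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  xtx_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * xtx_inv[2, 2])
  beta <- coefs[2]
  t_stat <- beta / se
  p <- 2 * stats::pt(-abs(t_stat), df)
  list(beta = unname(beta), se = unname(se), t_stat = unname(t_stat),
       p_value = unname(p), df = df)
}

# Assemble the response and design for one association fit. Covariates are
# taken from the sample table and expanded to indicator sets; covariate
# columns constant over the analyzed samples (e.g. diagnosis inside a
# diagnosis stratum) are dropped with a message.
build_design <- function(psi, groups, indicator, covariates, sample_table,
                         stratum) {
  dat <- merge(psi[, c("sample_id", "psi")], groups, by = "sample_id")
  if (!is.null(sample_table)) {
    dat <- merge(dat, sample_table, by = "sample_id")
  } else if (length(covariates) || stratum != "all") {
    stop("sample_table required for covariates or stratified analysis")
  }
  if (stratum != "all") dat <- dat[dat$diagnosis == stratum, , drop = FALSE]
  dat <- dat[!is.na(dat$psi), , drop = FALSE]
  g <- switch(indicator,
              functional = dat$carrier_functional,
              any = dat$carrier_any,
              stop("indicator must be 'functional' or 'any'"))
  if (indicator == "any") {
    # variant vs non-variant: whole sample splits on carrier_any
    dat$group <- as.integer(g)
  } else {
    dat$group <- as.integer(g)
  }
  used <- character()
  X <- cbind("(Intercept)" = rep(1, nrow(dat)), group = dat$group)
  for (cv in covariates) {
    if (!cv %in% names(dat)) stop("unknown covariate column: ", cv)
    v <- dat[[cv]]
    if (length(unique(v)) < 2L) {
      message("covariate '", cv, "' is constant in stratum '", stratum,
              "'; dropped")
      next
    }
    mm <- stats::model.matrix(~f, data.frame(f = factor(v)))[, -1, drop = FALSE]
    colnames(mm) <- paste0(cv, sub("^f", ":", colnames(mm)))
    X <- cbind(X, mm)
    used <- c(used, cv)
  }
  list(dat = dat, X = X, covariates_used = used)
}

#' Test the aggregated carrier group effect on PSI by linear regression
#'
#' Ordinary least squares of PSI on a 0/1 group indicator (functional vs
#' non-functional carriers, or variant vs non-variant) plus optional
#' categorical covariates. The mega-analysis pools samples across brain
#' regions and cohorts into one regression; `covariates = "region"` adjusts
#' for region-level PSI differences (region subsumes cohort when each
#' cohort contributes disjoint regions). Two-sided p-value from
#' the t distribution. Without covariates the fit reduces to the
#' pooled-variance two-sample t-test, and `beta` is the difference of group
#' means (group1 minus group0).
#'
#' @param psi PSI table (data.frame with `sample_id`, `psi`); missing PSI
#'   rows are excluded.
#' @param groups output of [assign_groups].
#' @param indicator `"functional"` (functional vs non-functional, the
#'   default) or `"any"` (variant vs non-variant).
#' @param covariates character vector of sample-table columns to adjust for
#'   (expanded to indicator sets).
#' @param sample_table phenotype table (required when covariates or a
#'   stratum are requested).
#' @param stratum `"all"` or a diagnosis level (`"AD"`, `"CN"`) to restrict
#'   the fit to.
#' @return one-row data.frame `stratum, indicator, n_group1, n_group0, beta,
#'   se, t_stat, p_value, covariates_used, testable`.
#' @export
fit_association <- function(psi, groups, indicator = "functional",
                            covariates = character(), sample_table = NULL,
                            stratum = "all") {
  d <- build_design(psi, groups, indicator, covariates, sample_table, stratum)
  n1 <- sum(d$dat$group == 1L); n0 <- sum(d$dat$group == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("degenerate grouping: group sizes ", n1, " vs ", n0,
         " in stratum '", stratum, "'")
  }
  if (n1 < 2L || n0 < 2L) {
    stop("need >= 2 samples per group with non-missing PSI (got ",
         n1, " vs ", n0, ")")
  }
  fit <- ols_group_test(d$dat$psi, d$X)
  data.frame(stratum = stratum, indicator = indicator,
             n_group1 = n1, n_group0 = n0,
             beta = fit$beta, se = fit$se, t_stat = fit$t_stat,
             p_value = fit$p_value,
             covariates_used = paste(d$covariates_used, collapse = ","),
             testable = TRUE, stringsAsFactors = FALSE)
}

#' Permutation validation of the functional-group association
#'
#' The functional label is re-assigned at random within the variant group:
#' each permutation draws, uniformly without replacement, as many
#' pseudo-functional samples from the variant group (carriers of any
#' retained low-frequency variant) as the observed functional group holds —
#' non-variant samples are never relabeled — and refits the identical
#' regression. The empirical p-value is `(n_extreme + 1) / (b + 1)` where
#' `n_extreme` counts permutations with p <= the observed p (ties count as
#' extreme).
#'
#' @param psi,groups,covariates,sample_table,stratum as in
#'   [fit_association] (the observed fit uses `indicator = "functional"`).
#' @param b number of permutations (default 1000).
#' @param seed integer seed; fixed seed gives a bit-identical result.
#' @return list of class `permutation_result`: `observed` (the observed
#'   association row), `b`, `n_extreme`, `empirical_p`, `seed`,
#'   `perm_p` (numeric vector of permuted p-values).
#' @export
permutation_test <- function(psi, groups, b = 1000, seed = NULL,
                             covariates = character(), sample_table = NULL,
                             stratum = "all") {
  if (b < 1) stop("number of permutations must be >= 1")
  observed <- fit_association(psi, groups, indicator = "functional",
                              covariates = covariates,
                              sample_table = sample_table, stratum = stratum)
  d <- build_design(psi, groups, "functional", covariates, sample_table,
                    stratum)
  pool <- which(d$dat$carrier_any)
  n_func <- sum(d$dat$carrier_functional)
  if (n_func < 1L) stop("no functional carriers to permute")
  if (n_func > length(pool)) {
    stop("functional group (", n_func, ") larger than variant group (",
         length(pool), ")")
  }
  if (!is.null(seed)) set.seed(seed)
  X <- d$X
  y <- d$dat$psi
  perm_p <- vapply(seq_len(b), function(i) {
    idx <- sample(pool, n_func)
    X[, "group"] <- 0
    X[idx, "group"] <- 1
    ols_group_test(y, X)$p_value
  }, numeric(1))
  n_extreme <- sum(perm_p <= observed$p_value)
  structure(list(observed = observed, b = as.integer(b),
                 n_extreme = as.integer(n_extreme),
                 empirical_p = (n_extreme + 1) / (b + 1),
                 seed = seed, perm_p = perm_p),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "permutation_result: observed p = %.4g, %d/%d permutations as extreme, empirical p = %.4g\n",
    x$observed$p_value, x$n_extreme, x$b, x$empirical_p))
  invisible(x)
}

#' Stratified association across diagnosis groups
#'
#' Fits the functional vs non-functional contrast in the pooled sample and
#' within each diagnosis stratum (AD, CN), mirroring the layout of a
#' stratified association table. A stratum in which one group is empty or
#' too small is reported with `testable = FALSE` rather than raising.
#'
#' @param psi,groups,covariates,sample_table as in [fit_association].
#' @param indicator `"functional"` or `"any"`.
#' @param strata character vector of strata (default `c("all", "AD",
#'   "CN")`).
#' @return data.frame with one row per stratum.
#' @export
stratified_association <- function(psi, groups, sample_table,
                                   indicator = "functional",
                                   covariates = character(),
                                   strata = c("all", "AD", "CN")) {
  rows <- lapply(strata, function(s) {
    res <- tryCatch(
      fit_association(psi, groups, indicator = indicator,
                      covariates = covariates, sample_table = sample_table,
                      stratum = s),
      error = function(e) {
        data.frame(stratum = s, indicator = indicator,
                   n_group1 = NA_integer_, n_group0 = NA_integer_,
                   beta = NA_real_, se = NA_real_, t_stat = NA_real_,
                   p_value = NA_real_, covariates_used = "",
                   testable = FALSE, stringsAsFactors = FALSE)
      })
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
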