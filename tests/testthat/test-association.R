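# Small in-memory fixture: genotype matrix + annotations with known carriers.
toy_assoc <- function() {
  samples <- paste0("s", 1:8)
  variants <- data.frame(id = c("f1", "n1"), chrom = "c", pos = c(10, 20),
                         ref = "A", alt = "C", af = c(0.1, 0.1),
                         maf = c(0.1, 0.1))
  calls <- matrix(0L, 8, 2, dimnames = list(samples, variants$id))
  calls["s1", "f1"] <- 1L      # functional carrier
  calls["s2", "f1"] <- 2L      # functional carrier (hom)
  calls["s3", "n1"] <- 1L      # non-functional carrier only
  calls["s4", "n1"] <- NA      # missing genotype -> non-carrier
  ann <- data.frame(variant_id = c("f1", "n1"), pos = c(10, 20),
                    region_class = "exonic", functional = c(TRUE, FALSE),
                    n_lost = c(1L, 0L))
  list(gm = genotype_matrix(samples, variants, calls), ann = ann)
}

test_that("carrier groups derive from genotypes and SRE annotations", {
  fx <- toy_assoc()
  g <- assign_groups(fx$gm, fx$ann)
  expect_equal(g$carrier_functional, c(TRUE, TRUE, rep(FALSE, 6)))
  expect_equal(g$carrier_any, c(TRUE, TRUE, TRUE, rep(FALSE, 5)))
  expect_equal(g$n_functional_variants[1:3], c(1L, 1L, 0L))
  # functional carriers are always variant carriers
  expect_true(all(!g$carrier_functional | g$carrier_any))
  # annotation mismatch is rejected
  expect_error(assign_groups(fx$gm, fx$ann[2:1, ]), "do not match")
})

test_that("two-group OLS reproduces the pooled-variance t-test", {
  set.seed(101)
  for (i in 1:30) {
    n1 <- sample(3:20, 1); n0 <- sample(3:20, 1)
    x1 <- rnorm(n1, 0.9, 0.05); x0 <- rnorm(n0, 0.92, 0.05)
    samples <- paste0("s", seq_len(n1 + n0))
    psi <- data.frame(sample_id = samples, psi = c(x1, x0))
    groups <- data.frame(sample_id = samples,
                         carrier_any = rep(c(TRUE, FALSE), c(n1, n0)),
                         carrier_functional = rep(c(TRUE, FALSE), c(n1, n0)),
                         n_functional_variants = rep(c(1L, 0L), c(n1, n0)))
    fit <- fit_association(psi, groups)
    tt <- t.test(x1, x0, var.equal = TRUE)
    expect_equal(fit$beta, mean(x1) - mean(x0), tolerance = 1e-12)
    expect_equal(fit$p_value, tt$p.value, tolerance = 1e-10)
    expect_equal(fit$n_group1, n1)
    expect_equal(fit$n_group0, n0)
  }
})

test_that("beta equals the difference of group means; identical groups give beta 0", {
  samples <- paste0("s", 1:4)
  psi <- data.frame(sample_id = samples, psi = c(0.9, 0.8, 0.95, 0.95))
  groups <- data.frame(sample_id = samples,
                       carrier_any = c(TRUE, TRUE, FALSE, FALSE),
                       carrier_functional = c(TRUE, TRUE, FALSE, FALSE),
                       n_functional_variants = c(1L, 1L, 0L, 0L))
  fit <- fit_association(psi, groups)
  expect_equal(fit$beta, -0.10)
  psi2 <- data.frame(sample_id = samples, psi = c(0.9, 0.9, 0.9, 0.9))
  expect_equal(fit_association(psi2, groups)$beta, 0)
})

test_that("degenerate and collinear designs are rejected with clear errors", {
  samples <- paste0("s", 1:6)
  psi <- data.frame(sample_id = samples, psi = seq(0.8, 0.95, length.out = 6))
  all_false <- data.frame(sample_id = samples, carrier_any = FALSE,
                          carrier_functional = FALSE,
                          n_functional_variants = 0L)
  expect_error(fit_association(psi, all_false), "degenerate grouping")

  groups <- data.frame(sample_id = samples,
                       carrier_any = rep(c(TRUE, FALSE), each = 3),
                       carrier_functional = rep(c(TRUE, FALSE), each = 3),
                       n_functional_variants = rep(c(1L, 0L), each = 3))
  st <- data.frame(sample_id = samples, diagnosis = "AD",
                   region = rep(c("A", "B"), 3),
                   cohort = rep(c("A", "B"), 3))  # cohort duplicates region
  expect_error(fit_association(psi, groups, covariates = c("region", "cohort"),
                               sample_table = st),
               "collinear.*cohort")
})

test_that("permutation relabels only within the variant group and is seed-stable", {
  cfg <- sim_config(seed = 13, n_samples = 250, n_genes_expr = 10,
                    n_planted_degs = 0)
  sim <- simulate_dataset(cfg)
  gm_lf <- filter_low_frequency(sim$gm)
  ann <- annotate_all(gm_lf, sim$seq, sim$unit, sim$motifs)
  groups <- assign_groups(gm_lf, ann)
  pr <- permutation_test(sim$psi, groups, b = 100, seed = 5)
  pr2 <- permutation_test(sim$psi, groups, b = 100, seed = 5)
  expect_identical(pr$perm_p, pr2$perm_p)
  expect_identical(pr$empirical_p, pr2$empirical_p)
  expect_equal(pr$empirical_p, (pr$n_extreme + 1) / 101)
  expect_gte(pr$empirical_p, 1 / 101)
  expect_lte(pr$empirical_p, 1)
  # strong planted effect: no permutation should beat the observed p
  expect_equal(pr$n_extreme, 0L)
  expect_error(permutation_test(sim$psi, groups, b = 0), ">= 1")
})

test_that("a null observed effect yields an empirical p near 1", {
  samples <- paste0("s", 1:40)
  psi <- data.frame(sample_id = samples, psi = rep(c(0.9, 0.8), 20))
  groups <- data.frame(sample_id = samples,
                       carrier_any = rep(TRUE, 40),
                       carrier_functional = rep(c(TRUE, FALSE), each = 20),
                       n_functional_variants = rep(c(1L, 0L), each = 20))
  # identical psi pattern in both groups -> observed beta 0, p = 1
  fit <- fit_association(psi, groups)
  expect_equal(fit$beta, 0)
  pr <- permutation_test(psi, groups, b = 99, seed = 1)
  expect_equal(pr$empirical_p, 1)
})

test_that("stratified analysis reports per-stratum rows and flags untestable strata", {
  samples <- paste0("s", 1:30)
  set.seed(7)
  psi <- data.frame(sample_id = samples, psi = rnorm(30, 0.9, 0.02))
  groups <- data.frame(sample_id = samples,
                       carrier_any = rep(c(TRUE, FALSE), c(10, 20)),
                       carrier_functional = rep(c(TRUE, FALSE), c(10, 20)),
                       n_functional_variants = rep(c(1L, 0L), c(10, 20)))
  # all functional carriers are AD: the CN stratum has an empty group
  st <- data.frame(sample_id = samples,
                   diagnosis = rep(c("AD", "CN"), c(15, 15)),
                   region = "DLPFC", cohort = "c1")
  res <- stratified_association(psi, groups, st)
  expect_equal(res$stratum, c("all", "AD", "CN"))
  expect_true(res$testable[res$stratum == "all"])
  expect_true(res$testable[res$stratum == "AD"])
  expect_false(res$testable[res$stratum == "CN"])
  # determinism: identical inputs give identical results
  expect_identical(res, stratified_association(psi, groups, st))
})
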