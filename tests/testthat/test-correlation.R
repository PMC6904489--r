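test_that("spearman_rho matches the rank formula and the oracle", {
  expect_equal(spearman_rho(1:3, c(10, 20, 30)), 1)
  expect_equal(spearman_rho(1:3, c(3, 2, 1)), -1)
  expect_equal(spearman_rho(1:5, c(2, 1, 4, 3, 5)), 0.8) # 1 - 6*4/120
  set.seed(11)
  for (i in 1:100) {
    n <- sample(5:30, 1)
    x <- rnorm(n)
    y <- if (i %% 3 == 0) sample(x) else rnorm(n) # include tied-free perms
    if (i %% 4 == 0) x <- round(x) # ties
    if (sd(x) == 0) next
    expect_equal(spearman_rho(x, y), cor(x, y, method = "spearman"),
                 tolerance = 1e-9)
  }
  expect_error(spearman_rho(rep(1, 5), 1:5),
               class = "phenoscreen_config_error")
})

test_that("spearman_rho is invariant under strictly monotone transforms", {
  set.seed(12)
  x <- rnorm(20)
  y <- rnorm(20)
  base <- spearman_rho(x, y)
  expect_equal(spearman_rho(exp(x), y), base)
  expect_equal(spearman_rho(x, 3 * atan(y) - 2), base)
})

test_that("pearson_r matches the covariance oracle", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  set.seed(13)
  for (i in 1:100) {
    n <- sample(4:40, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    expect_equal(pearson_r(x, y), cov(x, y) / (sd(x) * sd(y)),
                 tolerance = 1e-12)
  }
  # residualized y is exactly uncorrelated
  x <- rnorm(15)
  y <- resid(lm(rnorm(15) ~ x))
  expect_lt(abs(pearson_r(x, y)), 1e-12)
})

test_that("correlation_test uses the regression t with n - 2 df", {
  ct <- correlation_test(0.8, 29)
  expect_equal(ct$t, 0.8 * sqrt(27 / 0.36), tolerance = 1e-12) # 6.928
  expect_equal(ct$p, 2 * pt(-abs(ct$t), 27), tolerance = 1e-12)
  expect_equal(correlation_test(0, 10)$t, 0)
  expect_equal(correlation_test(0, 10)$p, 1)
  lim <- correlation_test(1, 10)
  expect_true(lim$limiting)
  expect_equal(lim$p, 0)
  # p decreases monotonically in |rho| at fixed n
  ps <- vapply(seq(0, 0.95, by = 0.05),
               function(r) correlation_test(r, 12)$p, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("bh_adjust reproduces the step-up procedure", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(14)
  for (i in 1:100) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q[order(p)] == cummax(q[order(p)]) | diff(range(p)) == 0))
  }
  # NA entries are preserved and excluded from m
  expect_equal(bh_adjust(c(0.02, NA, 0.04)),
               c(p.adjust(c(0.02, 0.04), "BH")[1], NA,
                 p.adjust(c(0.02, 0.04), "BH")[2]))
})

test_that("trait_gene_screen flags planted pairs and not wild-type ones", {
  cfg <- sim_config(seed = 31, n_genes = 60, n_signature = 12)
  co <- simulate_cohort(cfg)
  cts <- simulate_counts(co$truth,
                         dplyr::mutate(co$truth$animals, sample = animal), cfg)
  expr <- tibble::as_tibble(normalized_counts(cts), rownames = "gene") |>
    tidyr::pivot_longer(-gene, names_to = "animal", values_to = "value")
  traits <- dplyr::filter(co$phenotypes, timepoint == "wk13") |>
    dplyr::select(animal, genotype, trait, value)

  mut <- trait_gene_screen(dplyr::filter(traits, genotype == "mut"),
                           dplyr::semi_join(expr, dplyr::filter(traits, genotype == "mut"),
                                            by = "animal"))
  expect_equal(nrow(mut), 3 * 60)
  sig <- dplyr::filter(mut, gene %in% co$truth$signature_genes)
  expect_gt(mean(sig$star), 0.8)
  # an expression vector equal to the trait has rho 1 and a tilde flag
  tr1 <- dplyr::filter(traits, genotype == "mut", trait == "rotarod")
  self <- trait_gene_screen(tr1, dplyr::transmute(tr1, animal, gene = "self",
                                                  value = value))
  expect_equal(self$rho, 1)
  expect_true(self$tilde)

  wt <- trait_gene_screen(dplyr::filter(traits, genotype == "wt"),
                          dplyr::semi_join(expr, dplyr::filter(traits, genotype == "wt"),
                                           by = "animal"))
  wt_sig <- dplyr::filter(wt, gene %in% co$truth$signature_genes)
  expect_lte(mean(wt_sig$star), 0.12)
})

test_that("screen skips pairs with too few overlapping animals", {
  traits <- tibble::tibble(animal = sprintf("a%d", 1:8), trait = "t",
                           value = c(1:7, NA))
  expr <- tibble::tibble(animal = sprintf("a%d", 1:8),
                         gene = rep(c("g1", "g2"), each = 4),
                         value = rnorm(8))
  # g1 and g2 each overlap only 4 animals -> both skipped at min_n = 5
  expect_message(out <- trait_gene_screen(traits, expr, min_n = 5),
                 "skipped 2")
  expect_equal(nrow(out), 0)
  out2 <- trait_gene_screen(traits, expr, min_n = 3)
  expect_equal(nrow(out2), 2)
})

test_that("global family scope adjusts across panels jointly", {
  set.seed(15)
  traits <- tibble::tibble(animal = sprintf("a%d", 1:10),
                           genotype = rep(c("wt", "mut"), each = 5),
                           trait = "t", value = rnorm(10))
  expr <- tibble::tibble(animal = rep(sprintf("a%d", 1:10), 2),
                         gene = rep(c("g1", "g2"), each = 10),
                         value = rnorm(20))
  panel <- trait_gene_screen(traits, expr, min_n = 3)
  global <- trait_gene_screen(traits, expr, min_n = 3,
                              family_scope = "global")
  for (g in unique(panel$genotype)) {
    sub <- dplyr::filter(panel, genotype == g)
    expect_equal(sub$q, bh_adjust(sub$p))
  }
  expect_equal(global$q, bh_adjust(global$p))
})
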