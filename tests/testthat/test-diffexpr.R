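# A quick NB expression set with a known two-group design.
nb_counts <- function(seed, n_genes = 500, n_per_group = 4, alpha = 0.2,
                      base_mean = 100, lfc = 0, frac_de = 0,
                      lib = rep(1, 2 * n_per_group)) {
  withr::with_seed(seed, {
    mu0 <- rlnorm(n_genes, log(base_mean), 0.8)
    de_genes <- seq_len(floor(frac_de * n_genes))
    group <- rep(c("A", "B"), each = n_per_group)
    mu <- outer(mu0, lib)
    if (length(de_genes)) {
      mu[de_genes, group == "B"] <- mu[de_genes, group == "B"] * 2^lfc
    }
    counts <- matrix(
      if (alpha == 0) rpois(length(mu), mu) else
        rnbinom(length(mu), mu = mu, size = 1 / alpha),
      nrow = n_genes,
      dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                      sprintf("s%02d", seq_along(group)))
    )
    list(counts = counts, group = factor(group, levels = c("A", "B")),
         de_genes = rownames(counts)[de_genes])
  })
}

test_that("size factors implement median-of-ratios", {
  m <- matrix(c(2, 6, 4, 12), nrow = 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_equal(unname(size_factors(m)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-9)
  # identical columns -> all factors 1
  m2 <- matrix(rep(c(3, 7, 11), 4), nrow = 3,
               dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  expect_equal(unname(size_factors(m2)), rep(1, 4))
  # doubling one column doubles its factor relative to the others (factors
  # are defined up to the per-gene geometric-mean reference)
  sf <- size_factors(m2)
  m3 <- m2
  m3[, 2] <- m3[, 2] * 2L
  sf3 <- size_factors(m3)
  expect_equal(unname(sf3[2] / sf3[1]), 2 * unname(sf[2] / sf[1]),
               tolerance = 1e-9)
  expect_equal(unname(sf3[3] / sf3[1]), unname(sf[3] / sf[1]),
               tolerance = 1e-9)
  # a common scale cancels against the reference: factors are unchanged
  expect_equal(unname(size_factors(m2 * 3L)), unname(sf), tolerance = 1e-9)
  # gene order is irrelevant
  expect_equal(unname(size_factors(m2[c(3, 1, 2), ])), unname(sf))
  # no all-nonzero gene -> error pointing to the fallback
  m4 <- matrix(c(0, 5, 5, 0), nrow = 2,
               dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(size_factors(m4), "pseudo_reference",
               class = "phenoscreen_config_error")
  expect_silent(size_factors(m4, pseudo_reference = TRUE))
})

test_that("dispersion estimation recovers the simulation truth", {
  # Poisson data: raw method-of-moments median is at zero
  pois <- nb_counts(101, n_genes = 2000, n_per_group = 10, alpha = 0)
  a0 <- estimate_dispersion(pois$counts, pois$group, shrink = 0)
  expect_lte(median(a0, na.rm = TRUE), 0.01)
  # and the shrunk default stays essentially Poisson at this depth
  a0s <- estimate_dispersion(pois$counts, pois$group)
  expect_lte(median(a0s, na.rm = TRUE), 0.01)
  # NB alpha = 0.5 recovered within [0.3, 0.7] at n = 10/group
  nb <- nb_counts(102, n_genes = 2000, n_per_group = 10, alpha = 0.5)
  a5 <- estimate_dispersion(nb$counts, nb$group)
  expect_gte(median(a5, na.rm = TRUE), 0.3)
  expect_lte(median(a5, na.rm = TRUE), 0.7)
  # constant gene has zero raw dispersion
  m <- matrix(5L, nrow = 25, ncol = 6,
              dimnames = list(paste0("g", 1:25), paste0("s", 1:6)))
  araw <- estimate_dispersion(m, rep(c("A", "B"), each = 3), shrink = 0)
  expect_equal(unname(araw[1]), 0)
})

test_that("identical constant groups give zero fold change and p near 1", {
  m <- matrix(50L, nrow = 20, ncol = 8,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:8)))
  de <- nb_wald_test(m, rep(c("A", "B"), each = 4), dispersions = 0.1)
  expect_equal(de$log2fc, rep(0, 20), tolerance = 1e-6)
  expect_true(all(de$p > 0.99))
})

test_that("group-label swap negates log2fc and preserves p exactly", {
  nb <- nb_counts(103, n_genes = 300, frac_de = 0.1, lfc = 1.5,
                  lib = runif(8, 0.7, 1.4))
  disp <- estimate_dispersion(nb$counts, nb$group)
  d1 <- nb_wald_test(nb$counts, nb$group, disp)
  d2 <- nb_wald_test(nb$counts, factor(nb$group, levels = c("B", "A")), disp)
  expect_identical(d1$log2fc, -d2$log2fc)
  expect_identical(d1$p, d2$p)
  expect_identical(d1$se, d2$se)
})

test_that("all-zero genes are flagged untested, not dropped", {
  nb <- nb_counts(104, n_genes = 50)
  nb$counts[c(3, 7), ] <- 0L
  de <- nb_wald_test(nb$counts, nb$group,
                     estimate_dispersion(nb$counts, nb$group))
  expect_equal(nrow(de), 50)
  expect_equal(de$status[c(3, 7)], c("untested", "untested"))
  expect_true(all(is.na(de$p[c(3, 7)])))
  # BH family excludes untested genes
  expect_equal(de$q[de$status == "ok"],
               bh_adjust(de$p[de$status == "ok"]))
})

test_that("null simulation keeps raw type-I error calibrated", {
  rates <- vapply(1:5, function(i) {
    nb <- nb_counts(200 + i, n_genes = 1000)
    de <- de_analysis(nb$counts, nb$group)
    mean(de$p < 0.05, na.rm = TRUE)
  }, numeric(1))
  expect_gte(mean(rates), 0.03)
  expect_lte(mean(rates), 0.08)
})

test_that("planted fold changes are recovered with power and accuracy", {
  nb <- nb_counts(301, n_genes = 1000, frac_de = 0.1, lfc = 2)
  de <- de_analysis(nb$counts, nb$group)
  est <- de$log2fc[de$gene %in% nb$de_genes]
  expect_gte(mean(est), 1.6)
  expect_lte(mean(est), 2.4)
  degs <- call_degs(de, fdr = 0.05)
  expect_gte(length(intersect(degs$up, nb$de_genes)) / length(nb$de_genes),
             0.7)
})

test_that("call_degs partitions by sign at the FDR threshold", {
  de <- fake_de(paste0("g", 1:5), log2fc = c(2, -1, 0.5, -3, 1),
                q = c(0.01, 0.2, 0.001, 0.04, 1))
  degs <- call_degs(de, fdr = 0.05)
  expect_setequal(degs$up, c("g1", "g3"))
  expect_setequal(degs$down, "g4")
  expect_length(intersect(degs$up, degs$down), 0)
  # all q = 1 -> both empty
  none <- call_degs(fake_de("g1", 1, 1), 0.05)
  expect_length(none$up, 0)
  expect_length(none$down, 0)
})
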