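make_phen <- function(values, trait = "rotarod", genotype = "mut",
                      timepoint = "wk11") {
  tibble::tibble(
    animal = sprintf("m%02d", seq_along(values)), genotype = genotype,
    litter = "L1", trait = trait, timepoint = timepoint, value = values
  )
}

test_that("progression rate is the late-minus-early difference", {
  ph <- dplyr::bind_rows(
    make_phen(c(50, 10), timepoint = "wk11"),
    make_phen(c(30, 10), timepoint = "wk13")
  )
  d <- progression_rate(ph, "rotarod", "wk13", "wk11")
  expect_equal(d$delta, c(-20, 0))
  # one missing timepoint -> missing delta, reported
  ph_miss <- ph[-3, ]
  expect_message(d2 <- progression_rate(ph_miss, "rotarod", "wk13", "wk11"),
                 "1 animal")
  expect_true(is.na(d2$delta[d2$animal == "m01"]))
  expect_error(progression_rate(ph, "nope", "wk13", "wk11"),
               class = "phenoscreen_key_error")
  expect_error(progression_rate(ph, "rotarod", "wk20", "wk11"),
               class = "phenoscreen_key_error")
})

test_that("cv_summary matches hand-computed coefficients of variation", {
  ph <- dplyr::bind_rows(
    make_phen(c(10, 10, 10), trait = "a"),
    make_phen(c(5, 15), trait = "b")
  )
  cv <- cv_summary(ph)
  expect_equal(cv$by_trait$cv[cv$by_trait$trait == "a"], 0)
  expect_equal(cv$by_trait$cv[cv$by_trait$trait == "b"],
               100 * sd(c(5, 15)) / 10, tolerance = 1e-12) # 70.71%
  # median and IQR across traits by the linear-interpolation quantile rule
  ph3 <- dplyr::bind_rows(
    make_phen(c(90, 100, 110), trait = "t1"), # cv 10%
    make_phen(c(55, 100, 145), trait = "t2"), # cv 45%
    make_phen(c(20, 100, 180), trait = "t3") # cv 80%
  )
  cv3 <- cv_summary(ph3)
  expect_equal(cv3$by_trait$cv, c(10, 45, 80), tolerance = 1e-9)
  expect_equal(cv3$summary$median_cv, 45)
  expect_equal(c(cv3$summary$cv_q25, cv3$summary$cv_q75), c(27.5, 62.5))
  # zero mean is flagged undefined
  expect_warning(cv0 <- cv_summary(make_phen(c(-1, 0, 1), trait = "z")),
                 "undefined")
  expect_true(cv0$by_trait$undefined)
})

test_that("mann_whitney exact path reproduces enumeration", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$statistic, 0)
  expect_equal(mw$p.value, 0.1) # 2/20 rank assignments as extreme
  expect_match(mw$method, "exact")
  # identical multisets under the large-sample path
  x <- c(1, 2, 3, 4, 5)
  expect_equal(mann_whitney(x, x, exact = FALSE)$p.value, 1)
  # exact path equals the null U distribution on all small untied instances
  set.seed(401)
  for (i in 1:50) {
    n <- sample(2:5, 1)
    m <- sample(2:5, 1)
    vals <- sample(1000, n + m)
    x <- vals[1:n]
    y <- vals[-(1:n)]
    expect_equal(mann_whitney(x, y)$p.value, oracle_mw_exact(x, y),
                 tolerance = 1e-9)
  }
  expect_error(mann_whitney(numeric(0), 1:3),
               class = "phenoscreen_config_error")
})

test_that("z-scores standardize oriented values within groups", {
  specs <- dplyr::bind_rows(trait_spec("rotarod", orientation = 1),
                            trait_spec("clasping", orientation = -1))
  ph <- dplyr::bind_rows(
    make_phen(c(1, 2, 3), trait = "rotarod"),
    make_phen(c(0, 10, 20), trait = "clasping")
  )
  zs <- zscore_traits(ph, specs)
  rot <- dplyr::filter(zs$scores, trait == "rotarod") |>
    dplyr::arrange(animal)
  expect_equal(rot$z, c(-1, 0, 1))
  # orientation -1 flips the sign before standardizing
  cla <- dplyr::filter(zs$scores, trait == "clasping") |>
    dplyr::arrange(animal)
  expect_equal(cla$z, c(1, 0, -1))
  # each standardization group has mean 0 and sd 1
  grp <- dplyr::group_by(zs$scores, genotype, trait, timepoint) |>
    dplyr::summarise(m = mean(z), s = sd(z), .groups = "drop")
  expect_true(all(abs(grp$m) < 1e-9 & abs(grp$s - 1) < 1e-9))
  # location invariance
  zs_shift <- zscore_traits(dplyr::mutate(ph, value = value + 100), specs)
  expect_equal(zs_shift$scores$z, zs$scores$z)
  # degenerate group errors name the trait
  expect_error(zscore_traits(make_phen(c(1, 1, 1)), specs), "rotarod",
               class = "phenoscreen_config_error")
})

test_that("classification picks the k extremes per genotype deterministically", {
  specs <- trait_spec("rotarod", orientation = 1)
  ph <- make_phen(1:8)
  zs <- zscore_traits(ph, specs)
  labels <- classify_performers(zs, k = 4)
  expect_setequal(labels$animal[labels$label == "good"],
                  sprintf("m%02d", 5:8))
  expect_setequal(labels$animal[labels$label == "poor"],
                  sprintf("m%02d", 1:4))
  # row-order invariance
  zs_perm <- zscore_traits(ph[sample(nrow(ph)), ], specs)
  expect_equal(classify_performers(zs_perm, k = 4), labels)
  # k too large
  expect_error(classify_performers(zs, k = 5),
               class = "phenoscreen_config_error")
})

test_that("sign-count dominates mean z in the composite ranking", {
  # animal A: all six scores mildly positive; animal B: mixed signs with a
  # higher mean; A must rank first on the primary key
  zs <- structure(list(
    scores = tibble::tibble(),
    animals = tibble::tibble(
      animal = c("A", "B", "C", "D"),
      genotype = "mut",
      n_pos = c(6, 4, 2, 0), n_neg = c(0, 2, 4, 6), n_zero = 0,
      mean_z = c(0.2, 1.5, -0.1, -0.2),
      n_meas = 6, complete = TRUE
    ),
    n_expected = 6
  ), class = "zscore_table")
  labels <- classify_performers(zs, k = 1)
  expect_equal(labels$label[labels$animal == "A"], factor("good", levels = levels(labels$label)))
  expect_equal(labels$label[labels$animal == "D"], factor("poor", levels = levels(labels$label)))
})

test_that("classification is invariant to monotone rescaling of one trait", {
  co <- simulate_cohort(small_config(seed = 77))
  specs <- small_config(seed = 77)$traits
  zs <- zscore_traits(co$phenotypes, specs)
  base <- classify_performers(zs, k = 4)
  rescaled <- dplyr::mutate(
    co$phenotypes,
    value = ifelse(trait == "weight", 3.5 * value + 12, value)
  )
  expect_equal(classify_performers(zscore_traits(rescaled, specs), k = 4),
               base)
})

test_that("incomplete animals are left unlabelled", {
  specs <- trait_spec("rotarod", orientation = 1)
  ph <- dplyr::bind_rows(make_phen(1:8),
                         make_phen(c(5, 6, 7, 8, NA, 4, 3, 2),
                                   timepoint = "wk13"))
  expect_message(zs <- zscore_traits(ph, specs), "1 missing")
  expect_message(labels <- classify_performers(zs, k = 2), "1 animal")
  expect_true(is.na(labels$label[labels$animal == "m05"]))
})
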