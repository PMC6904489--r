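#' Per-animal progression rate of a trait
#'
#' The progression rate is the late-minus-early difference of a trait, in
#' trait units: e.g. week 13 minus week 11 for rotarod, clasping and weight,
#' or day 2 minus day 1 for rotarod learning. Animals missing either timepoint
#' get a missing delta and are reported.
#'
#' @param table A phenotype tibble (animal, genotype, litter, trait,
#'   timepoint, value).
#' @param trait Trait name.
#' @param t_late,t_early Timepoint labels.
#' @return A tibble with one row per animal: `animal`, `genotype`, `litter`
#'   (if present), and `delta`.
#' @examples
#' ph <- simulate_cohort(sim_config(seed = 1))$phenotypes
#' progression_rate(ph, "rotarod", "wk13", "wk11")
#' @export
progression_rate <- function(table, trait, t_late, t_early) {
  table <- as_tibble(table)
  if (!trait %in% table$trait) {
    abort(sprintf("unknown trait '%s'.", trait), class = "phenoscreen_key_error")
  }
  tps <- unique(table$timepoint)
  missing_tp <- setdiff(c(t_late, t_early), tps)
  if (length(missing_tp)) {
    abort(sprintf("unknown timepoint(s): %s.", paste(missing_tp, collapse = ", ")),
          class = "phenoscreen_key_error")
  }
  keep <- intersect(c("animal", "genotype", "litter"), names(table))
  wide <- table |>
    filter(.data$trait == !!trait, .data$timepoint %in% c(t_late, t_early)) |>
    tidyr::pivot_wider(id_cols = all_of(keep), names_from = "timepoint",
                       values_from = "value")
  for (tp in setdiff(c(t_late, t_early), names(wide))) wide[[tp]] <- NA_real_
  out <- wide |>
    mutate(delta = .data[[t_late]] - .data[[t_early]]) |>
    select(all_of(keep), "delta")
  n_miss <- sum(is.na(out$delta))
  if (n_miss > 0) {
    inform(sprintf("progression_rate: %d animal(s) missing a timepoint for '%s'; delta set to NA.",
                   n_miss, trait))
  }
  out
}

#' Coefficient-of-variation summary across traits
#'
#' The CV of a trait is the sample standard deviation divided by the mean,
#' reported as a percentage; the across-trait summary is the median and the
#' 25th-75th percentile range (linear-interpolation quantiles). Each
#' (trait, timepoint) cell is treated as one task. Traits with zero mean have
#' an undefined CV and are flagged.
#'
#' @param table A phenotype tibble.
#' @param traits Optional subset of trait names.
#' @param genotype Optional genotype to restrict to (`"wt"` or `"mut"`).
#' @return A list of class `cv_summary`: `by_trait` (tibble with n, mean, sd,
#'   cv in percent, `undefined` flag) and `summary` (median and IQR of the
#'   defined CVs, percent).
#' @export
cv_summary <- function(table, traits = NULL, genotype = NULL) {
  table <- as_tibble(table)
  if (!is.null(traits)) table <- filter(table, .data$trait %in% !!traits)
  if (!is.null(genotype)) table <- filter(table, .data$genotype %in% !!genotype)
  if (!nrow(table)) abort("no measurements left after filtering.",
                          class = "phenoscreen_key_error")
  by_trait <- table |>
    filter(is.finite(.data$value)) |>
    group_by(.data$trait, .data$timepoint) |>
    summarise(n = dplyr::n(), mean = mean(.data$value), sd = sd(.data$value),
              .groups = "drop") |>
    mutate(undefined = .data$mean == 0,
           cv = ifelse(.data$undefined, NA_real_, 100 * .data$sd / .data$mean))
  if (any(by_trait$undefined)) {
    warn(sprintf("cv_summary: CV undefined (mean = 0) for %d trait cell(s).",
                 sum(by_trait$undefined)))
  }
  cvs <- by_trait$cv[!by_trait$undefined]
  qs <- quantile(cvs, c(0.25, 0.5, 0.75), names = FALSE)
  structure(
    list(by_trait = by_trait,
         summary = tibble(median_cv = qs[2], cv_q25 = qs[1], cv_q75 = qs[3])),
    class = "cv_summary"
  )
}

#' @export
print.cv_summary <- function(x, ...) {
  cat(sprintf("<cv_summary> median CV %.1f%% (IQR %.1f-%.1f%%) over %d trait cells\n",
              x$summary$median_cv, x$summary$cv_q25, x$summary$cv_q75,
              nrow(x$by_trait)))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two groups. With `n + m <= 12` and no ties the
#' two-sided p-value is exact, computed by enumerating all `choose(n+m, n)`
#' equally likely rank assignments and counting those whose U deviates from
#' the null mean `nm/2` at least as much as observed. Otherwise a normal
#' approximation with tie correction is used (no continuity correction).
#'
#' @param x,y Numeric vectors (non-empty).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`,
#'   referring to `x` tending to smaller/larger values than `y`.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact path; `NULL`
#'   selects it automatically.
#' @return A list with `statistic` (U for `x`), `p.value` and `method`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p.value # exact: 0.1
#' @export
mann_whitney <- function(x, y, alternative = c("two.sided", "less", "greater"),
                         exact = NULL) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y) || anyNA(x) || anyNA(y)) {
    abort("both groups must be non-empty and free of missing values.",
          class = "phenoscreen_config_error")
  }
  n <- length(x); m <- length(y); N <- n + m
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2 # number of (x > y) pairs + ties/2
  has_ties <- anyDuplicated(pooled) > 0
  use_exact <- exact %||% (N <= 12 && !has_ties)
  if (use_exact && has_ties) {
    abort("exact path requires untied data.", class = "phenoscreen_config_error")
  }

  if (use_exact) {
    combos <- combn(N, n)
    us <- colSums(matrix(r[combos], nrow = n)) - n * (n + 1) / 2
    centre <- n * m / 2
    tol <- 1e-9
    p <- switch(alternative,
      two.sided = mean(abs(us - centre) >= abs(u - centre) - tol),
      less = mean(us <= u + tol),
      greater = mean(us >= u - tol)
    )
    method <- "exact enumeration"
  } else {
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n * m / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - n * m / 2) / sqrt(sigma2)
      p <- switch(alternative,
        two.sided = 2 * pnorm(-abs(z)),
        less = pnorm(z),
        greater = pnorm(z, lower.tail = FALSE)
      )
      p <- min(p, 1)
    }
    method <- "normal approximation with tie correction"
  }
  list(statistic = u, p.value = p, method = method)
}

#' Oriented trait Z-scores
#'
#' Each measurement is multiplied by its trait's orientation (so a positive
#' score always means better performance) and standardized as
#' `(value - average) / standard deviation` within its standardization group,
#' by default genotype x trait x timepoint. Per-animal summaries count
#' positive and negative scores and average the score over all included
#' measurements.
#'
#' @param table A phenotype tibble.
#' @param specs Trait specs with at least `trait` and `orientation` columns
#'   ([trait_spec()], [default_trait_specs()]); only listed traits enter.
#' @param group_by Columns defining the standardization group.
#' @param timepoints Optional subset of timepoints to include.
#' @return A list of class `zscore_table`: `scores` (per-measurement z) and
#'   `animals` (per-animal n_pos, n_neg, n_zero, mean_z, n_meas, complete).
#' @export
zscore_traits <- function(table, specs = default_trait_specs(),
                          group_by = c("genotype", "trait", "timepoint"),
                          timepoints = NULL) {
  table <- as_tibble(table)
  specs <- as_tibble(specs)
  stopifnot(all(c("trait", "orientation") %in% names(specs)))
  data <- table |>
    filter(.data$trait %in% specs$trait) |>
    left_join(select(specs, "trait", "orientation"), by = "trait")
  if (!is.null(timepoints)) {
    data <- filter(data, .data$timepoint %in% !!timepoints)
  }
  n_na <- sum(is.na(data$value))
  if (n_na > 0) {
    inform(sprintf("zscore_traits: dropping %d missing measurement(s).", n_na))
    data <- filter(data, !is.na(.data$value))
  }
  if (!nrow(data)) abort("no measurements to standardize.",
                         class = "phenoscreen_config_error")

  data <- data |>
    mutate(oriented = .data$orientation * .data$value) |>
    group_by(across(all_of(group_by)))
  sizes <- summarise(data, n = dplyr::n(), sd = sd(.data$oriented),
                     .groups = "drop")
  bad <- filter(sizes, .data$n < 3 | .data$sd <= 0 | is.na(.data$sd))
  if (nrow(bad)) {
    lab <- paste(apply(bad[group_by], 1, paste, collapse = "/"), collapse = "; ")
    abort(sprintf("standardization group(s) too small or degenerate (need n >= 3 and sd > 0): %s",
                  lab),
          class = "phenoscreen_config_error")
  }
  scores <- data |>
    mutate(z = (.data$oriented - mean(.data$oriented)) / sd(.data$oriented)) |>
    ungroup() |>
    select(any_of(c("animal", "genotype", "litter", "trait", "timepoint",
                    "value", "z")))

  n_expected <- nrow(specs) *
    length(unique(scores$timepoint))
  animals <- scores |>
    group_by(.data$animal, .data$genotype) |>
    summarise(n_pos = sum(.data$z > 0), n_neg = sum(.data$z < 0),
              n_zero = sum(.data$z == 0), mean_z = mean(.data$z),
              n_meas = dplyr::n(), .groups = "drop") |>
    mutate(complete = .data$n_meas == n_expected)

  structure(list(scores = scores, animals = animals, n_expected = n_expected),
            class = "zscore_table")
}

#' @export
print.zscore_table <- function(x, ...) {
  cat(sprintf("<zscore_table> %d measurements, %d animals (%d complete), %d expected measurements/animal\n",
              nrow(x$scores), nrow(x$animals), sum(x$animals$complete),
              x$n_expected))
  invisible(x)
}

#' @export
tidy.zscore_table <- function(x, ...) x$scores

#' @export
glance.zscore_table <- function(x, ...) {
  tibble(n_measurements = nrow(x$scores), n_animals = nrow(x$animals),
         n_complete = sum(x$animals$complete), n_expected = x$n_expected)
}

#' Classify extreme performers from composite Z-scores
#'
#' Within each genotype, animals with complete trait data are ranked first by
#' the number of positive minus negative scores (descending), then by the
#' average score (descending), with a deterministic lexicographic animal-id
#' tie-break. The top `k` are labelled `"good"`, the bottom `k` `"poor"`, and
#' the remainder `"average"`. Animals with incomplete data are not ranked and
#' get a missing label.
#'
#' @param zs A [zscore_traits()] result.
#' @param k Number of extreme animals per tail and genotype (default 4).
#' @return A tibble: `animal`, `genotype`, `label` (factor good/average/poor,
#'   NA when unranked).
#' @export
classify_performers <- function(zs, k = 4) {
  stopifnot(inherits(zs, "zscore_table"))
  k <- as.integer(k)
  if (k < 1) abort("`k` must be >= 1.", class = "phenoscreen_config_error")
  incomplete <- filter(zs$animals, !.data$complete)
  if (nrow(incomplete)) {
    inform(sprintf("classify_performers: %d animal(s) with incomplete data left unlabelled.",
                   nrow(incomplete)))
  }
  ranked <- zs$animals |>
    filter(.data$complete) |>
    group_by(.data$genotype) |>
    arrange(desc(.data$n_pos - .data$n_neg), desc(.data$mean_z), .data$animal,
            .by_group = TRUE)
  sizes <- summarise(ranked, n = dplyr::n(), .groups = "drop")
  if (any(k > floor(sizes$n / 2))) {
    abort(sprintf("`k` = %d exceeds floor(group size / 2) for genotype(s): %s",
                  k, paste(sizes$genotype[k > floor(sizes$n / 2)], collapse = ", ")),
          class = "phenoscreen_config_error")
  }
  labelled <- ranked |>
    mutate(rank = dplyr::row_number(), n = dplyr::n(),
           label = dplyr::case_when(
             rank <= k ~ "good",
             rank > n - k ~ "poor",
             TRUE ~ "average"
           )) |>
    ungroup() |>
    select("animal", "genotype", "label")
  out <- bind_rows(labelled,
                   tibble(animal = incomplete$animal,
                          genotype = incomplete$genotype,
                          label = NA_character_)) |>
    arrange(.data$genotype, .data$animal) |>
    mutate(label = factor(.data$label, levels = c("good", "average", "poor")))
  out
}
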