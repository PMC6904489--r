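#' Simulate a behavioural cohort with a planted severity factor
#'
#' Each mutant animal carries a latent severity score `s ~ N(0, 1)` (high =
#' favourable outcome) that loads onto every trait through the trait's
#' `loading`; wild-type animals carry no severity component. A trait value at
#' any timepoint is
#' `baseline + genotype_effect * is_mut + loading * s * is_mut + noise`.
#' Litters are assigned round-robin across the interleaved animal roster.
#'
#' @param config A [sim_config()].
#' @return A list with `phenotypes` (long tibble: animal, genotype, litter,
#'   trait, timepoint, value) and `truth`, a `ground_truth` object holding the
#'   animal roster, per-mutant severities, the signature gene set and per-gene
#'   planted log2 fold changes.
#' @examples
#' cohort <- simulate_cohort(sim_config(seed = 7))
#' head(cohort$phenotypes)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_stream(config$seed, "cohort", {
    animals <- tibble(
      animal = c(sprintf("wt%02d", seq_len(config$n_wt)),
                 sprintf("mut%02d", seq_len(config$n_mut))),
      genotype = rep(c("wt", "mut"), c(config$n_wt, config$n_mut))
    )
    # round-robin litters over the roster; each litter mixes both genotypes
    animals$litter <- sprintf(
      "L%d", (seq_len(nrow(animals)) - 1L) %% config$n_litters + 1L
    )

    severity <- tibble(
      animal = animals$animal[animals$genotype == "mut"],
      severity = rnorm(config$n_mut)
    )

    design <- tidyr::crossing(animals, config$traits,
                              timepoint = config$timepoints)
    design <- left_join(design, severity, by = "animal")
    is_mut <- as.numeric(design$genotype == "mut")
    sev <- tidyr::replace_na(design$severity, 0)
    design$value <- design$baseline +
      design$genotype_effect * is_mut +
      design$loading * sev * is_mut +
      rnorm(nrow(design), sd = design$noise_sd)

    phen <- design |>
      select("animal", "genotype", "litter", "trait", "timepoint", "value") |>
      arrange(.data$animal, .data$trait, .data$timepoint)

    gene_ids <- sprintf("g%05d", seq_len(config$n_genes))
    signature <- sort(sample(gene_ids, config$n_signature))
    planted <- tibble(
      gene = gene_ids,
      log2fc = ifelse(gene_ids %in% signature, config$effect_log2fc, 0)
    )

    truth <- structure(
      list(animals = select(animals, "animal", "genotype", "litter"),
           severity = severity,
           signature_genes = signature,
           planted_log2fc = planted,
           seed = config$seed),
      class = "ground_truth"
    )
    list(phenotypes = phen, truth = truth)
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>\n")
  cat(sprintf("  %d animals (%d mutant with latent severity)\n",
              nrow(x$animals), nrow(x$severity)))
  cat(sprintf("  %d signature genes of %d | seed %d\n",
              length(x$signature_genes), nrow(x$planted_log2fc), x$seed))
  invisible(x)
}
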