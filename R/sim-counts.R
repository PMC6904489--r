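#' Simulate negative-binomial counts tied to the planted severity
#'
#' Counts for sample `j`, gene `g` are drawn from a negative binomial with
#' mean `mu0_g * lib_j * 2^(planted_log2fc_g * is_mut_j + slope * s_j)` and
#' dispersion `alpha` (variance `m + alpha m^2`); `alpha = 0` falls back to
#' Poisson sampling. Only signature genes carry the planted fold change and
#' the severity term, and only in mutant samples; non-signature genes are
#' genotype-independent. Per-gene base means are log-normal around
#' `base_mean`; library factors are uniform on `lib_size_range`.
#'
#' @param truth A `ground_truth` from [simulate_cohort()].
#' @param samples Sample metadata tibble with columns `sample` and `animal`
#'   (they may coincide); every animal id must exist in the ground truth.
#' @param config The [sim_config()] used for the cohort.
#' @return An [expr_set()].
#' @export
simulate_counts <- function(truth, samples, config) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "sim_config"))
  samples <- as_tibble(samples)
  if (!"sample" %in% names(samples)) samples$sample <- samples$animal
  if (!"animal" %in% names(samples)) samples$animal <- samples$sample
  unknown <- setdiff(samples$animal, truth$animals$animal)
  if (length(unknown)) {
    abort(paste0("sample animal ids not in ground truth: ",
                 paste(unknown, collapse = ", ")),
          class = "phenoscreen_key_error")
  }
  samples <- left_join(samples,
                       select(truth$animals, "animal", truth_genotype = "genotype"),
                       by = "animal")
  if (!"genotype" %in% names(samples)) {
    samples$genotype <- samples$truth_genotype
  }
  samples$truth_genotype <- NULL

  with_stream(config$seed, "counts", {
    n_g <- config$n_genes
    n_s <- nrow(samples)
    gene_ids <- truth$planted_log2fc$gene
    mu0 <- rlnorm(n_g,
                  meanlog = log(config$base_mean) - config$gene_mean_sdlog^2 / 2,
                  sdlog = config$gene_mean_sdlog)
    libf <- runif(n_s, config$lib_size_range[1], config$lib_size_range[2])

    sev <- tidyr::replace_na(
      truth$severity$severity[match(samples$animal, truth$severity$animal)], 0)
    is_mut <- as.numeric(samples$animal %in% truth$severity$animal)
    sig <- gene_ids %in% truth$signature_genes

    # genes x samples matrix of log2 multipliers (signature x mutant only)
    lfc <- outer(truth$planted_log2fc$log2fc, is_mut) +
      outer(as.numeric(sig) * config$severity_slope, sev * is_mut)
    mu <- (mu0 %o% libf) * 2^lfc

    counts <- if (config$dispersion == 0) {
      rpois(length(mu), lambda = mu)
    } else {
      rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
    }
    counts <- matrix(as.integer(counts), nrow = n_g,
                     dimnames = list(gene_ids, samples$sample))
    expr_set(counts, samples)
  })
}
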