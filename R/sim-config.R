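#' Specify a behavioural trait for simulation and scoring
#'
#' A trait spec carries everything the simulator and the Z-score machinery need
#' to know about one behavioural readout: its sign convention (is a larger
#' value better or worse performance?), the baseline level in trait units, the
#' genotype main effect, how strongly the latent severity factor loads on it,
#' and the residual noise standard deviation.
#'
#' @param trait Trait name (e.g. `"rotarod"`).
#' @param orientation `+1` if a larger value means better performance (rotarod
#'   latency, body weight), `-1` if larger means worse (feet-clasping time).
#' @param baseline Baseline trait value in trait units (wild-type mean).
#' @param genotype_effect Additive shift applied to mutant animals, trait units.
#' @param loading Trait-units shift per standard deviation of the latent
#'   severity factor; applies to mutant animals only. Its sign should agree
#'   with `orientation` so that a high severity score means good outcome.
#' @param noise_sd Residual noise standard deviation, trait units.
#' @return A one-row tibble.
#' @export
trait_spec <- function(trait, orientation = 1, baseline = 0,
                       genotype_effect = 0, loading = 0, noise_sd = 1) {
  if (!orientation %in% c(-1, 1)) {
    abort("`orientation` must be +1 or -1.", class = "phenoscreen_config_error")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    abort("`noise_sd` must be >= 0.", class = "phenoscreen_config_error")
  }
  tibble(
    trait = as.character(trait), orientation = orientation,
    baseline = baseline, genotype_effect = genotype_effect,
    loading = loading, noise_sd = noise_sd
  )
}

#' Default trait battery: rotarod, feet clasping, weight
#'
#' The three traits that enter extreme-performer classification: accelerating
#' rotarod latency (s, larger = better), feet-clasping duration during tail
#' suspension (s, larger = worse) and body weight (g, larger = better). Each
#' trait's severity loading is `loading_scale` times its noise s.d., so
#' `loading_scale` is the per-trait signal-to-noise ratio of the latent
#' severity factor; `loading_scale = 0` gives a null battery.
#'
#' @param loading_scale Ratio of severity loading magnitude to noise s.d.
#' @return A tibble of trait specs.
#' @export
default_trait_specs <- function(loading_scale = 2) {
  bind_rows(
    trait_spec("rotarod", orientation = +1, baseline = 150,
               genotype_effect = -50, loading = +15 * loading_scale, noise_sd = 15),
    trait_spec("clasping", orientation = -1, baseline = 5,
               genotype_effect = +20, loading = -6 * loading_scale, noise_sd = 6),
    trait_spec("weight", orientation = +1, baseline = 30,
               genotype_effect = -4, loading = +1 * loading_scale, noise_sd = 1)
  )
}

#' Simulation configuration
#'
#' Bundles all parameters for the synthetic cohort: sample sizes matching the
#' study design (24 wild-type, 29 mutant males), the trait battery measured at
#' two timepoints, and the expression model (negative-binomial counts in which
#' a subset of "signature" genes carries a planted genotype fold change plus a
#' severity-linked component).
#'
#' @param seed Integer seed; a fixed seed gives byte-identical outputs.
#' @param n_wt,n_mut Animals per genotype (positive integers).
#' @param traits Tibble of trait specs, see [trait_spec()].
#' @param timepoints Ordered character vector of timepoint labels.
#' @param n_litters Number of litters; animals are assigned round-robin.
#' @param n_genes Number of genes in the expression universe.
#' @param n_signature Number of severity-linked signature genes
#'   (`<= n_genes`).
#' @param base_mean Mean count scale of the expression model.
#' @param gene_mean_sdlog Log-normal spread of per-gene base means.
#' @param dispersion Negative-binomial dispersion alpha (variance
#'   `m + alpha * m^2`); `0` degenerates to Poisson.
#' @param lib_size_range Multiplicative library-size factor range (positive,
#'   ascending).
#' @param effect_log2fc Planted genotype log2 fold change of signature genes;
#'   negative by default because the HD signature is downregulated.
#' @param severity_slope log2FC units per severity s.d. for signature genes
#'   (mutants only); positive means worse animals (low severity score) are more
#'   downregulated.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_wt = 24L, n_mut = 29L,
                       traits = default_trait_specs(),
                       timepoints = c("wk11", "wk13"),
                       n_litters = 6L,
                       n_genes = 2000L, n_signature = 200L,
                       base_mean = 100, gene_mean_sdlog = 1,
                       dispersion = 0.2, lib_size_range = c(0.7, 1.4),
                       effect_log2fc = -1, severity_slope = 0.75) {
  if (!is.numeric(n_wt) || !is.numeric(n_mut) || n_wt < 1 || n_mut < 1) {
    abort("`n_wt` and `n_mut` must be positive counts.",
          class = "phenoscreen_config_error")
  }
  if (!is.data.frame(traits) ||
      !all(c("trait", "orientation", "baseline", "genotype_effect",
             "loading", "noise_sd") %in% names(traits))) {
    abort("`traits` must be a tibble of trait specs (see trait_spec()).",
          class = "phenoscreen_config_error")
  }
  if (anyDuplicated(traits$trait)) {
    abort("trait names must be unique.", class = "phenoscreen_config_error")
  }
  if (n_signature > n_genes) {
    abort("`n_signature` must be <= `n_genes`.",
          class = "phenoscreen_config_error")
  }
  if (dispersion < 0) {
    abort("`dispersion` must be >= 0.", class = "phenoscreen_config_error")
  }
  if (length(lib_size_range) != 2L || any(lib_size_range <= 0) ||
      diff(lib_size_range) < 0) {
    abort("`lib_size_range` must be two positive ascending values.",
          class = "phenoscreen_config_error")
  }
  if (length(timepoints) < 1L || anyDuplicated(timepoints)) {
    abort("`timepoints` must be distinct labels.",
          class = "phenoscreen_config_error")
  }
  structure(
    list(
      seed = as.integer(seed), n_wt = as.integer(n_wt),
      n_mut = as.integer(n_mut), traits = traits,
      timepoints = as.character(timepoints), n_litters = as.integer(n_litters),
      n_genes = as.integer(n_genes), n_signature = as.integer(n_signature),
      base_mean = base_mean, gene_mean_sdlog = gene_mean_sdlog,
      dispersion = dispersion, lib_size_range = lib_size_range,
      effect_log2fc = effect_log2fc, severity_slope = severity_slope
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  seed %d | %d wt + %d mut | %d traits x %d timepoints\n",
              x$seed, x$n_wt, x$n_mut, nrow(x$traits), length(x$timepoints)))
  cat(sprintf("  %d genes (%d signature), base mean %.3g, dispersion %.3g\n",
              x$n_genes, x$n_signature, x$base_mean, x$dispersion))
  cat(sprintf("  planted log2FC %.3g, severity slope %.3g log2FC/s.d.\n",
              x$effect_log2fc, x$severity_slope))
  invisible(x)
}
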