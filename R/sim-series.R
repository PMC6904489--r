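#' Default CAG-length by age grid of the knock-in allelic series
#'
#' Knock-in strains Q80, Q92, Q111, Q140 and Q175 compared against Q20 at 2, 6
#' and 10 months of age.
#'
#' @return A tibble with `cag` and `age` columns, one row per grid cell.
#' @export
default_series_grid <- function() {
  tidyr::crossing(cag = c(80L, 92L, 111L, 140L, 175L), age = c(2L, 6L, 10L))
}

#' Default monotone effect scaling over the allelic-series grid
#'
#' Effect sizes grow linearly with the rank of the CAG length and of the age,
#' reaching `max_scale` (in z-score units) in the oldest, longest-repeat cell.
#'
#' @param grid A grid tibble as from [default_series_grid()].
#' @param max_scale Effect size in the most severe cell, z units.
#' @return `grid` with an added `scale` column.
#' @export
default_series_scaling <- function(grid = default_series_grid(), max_scale = 3) {
  cag_rank <- match(grid$cag, sort(unique(grid$cag)))
  age_rank <- match(grid$age, sort(unique(grid$age)))
  mutate(grid, scale = max_scale *
           (cag_rank / max(cag_rank)) * (age_rank / max(age_rank)))
}

#' Simulate external allelic-series differential-expression tables
#'
#' Emulates ranked DE tables (gene, log2 fold change, p-value) for each
#' CAG-length-by-age comparison against the Q20 control. Every gene gets a
#' latent z-score shared across all grid cells (so cells differ only through
#' planted effects); genes belonging to the designated progressive sets
#' additionally receive a signed effect equal to the cell's `scale` (negative
#' for "down" sets, positive for "up" sets) plus `noise_sd` Gaussian noise.
#' Two-sided normal p-values and a proportional log2 fold change are derived
#' from the z-scores, so ranking by ascending p within a direction follows the
#' planted effects; with `noise_sd = 0` presence is exactly monotone in the
#' scaling.
#'
#' @param sets Named list of gene-id sets (e.g. a [partition_gene_sets()]
#'   result); names must contain `"down"` or `"up"` to declare direction.
#' @param config A [sim_config()]; supplies the gene universe and seed.
#' @param grid Grid tibble of `(cag, age)` cells.
#' @param scaling Tibble `(cag, age, scale)`; defaults to
#'   [default_series_scaling()] on `grid`.
#' @param progressive Names of the sets that receive progressive effects.
#' @param noise_sd Per-cell effect noise s.d., z units.
#' @return A `de_series` tibble: `cag`, `age`, `gene`, `log2fc`, `p`.
#' @export
simulate_allelic_series <- function(sets, config,
                                    grid = default_series_grid(),
                                    scaling = NULL,
                                    progressive = c("down_poor", "up_good"),
                                    noise_sd = 0.5) {
  stopifnot(inherits(config, "sim_config"))
  sets <- as_gene_sets(sets)
  if (is.null(scaling)) scaling <- default_series_scaling(grid)
  if (!all(c("cag", "age", "scale") %in% names(scaling))) {
    abort("`scaling` must have columns cag, age, scale.",
          class = "phenoscreen_config_error")
  }
  grid <- inner_join(grid, scaling, by = c("cag", "age"))
  if (!nrow(grid)) {
    abort("`scaling` does not cover the grid.",
          class = "phenoscreen_config_error")
  }
  universe <- sprintf("g%05d", seq_len(config$n_genes))
  progressive <- intersect(progressive, names(sets))

  with_stream(config$seed, "series", {
    base_z <- rnorm(config$n_genes)
    cells <- purrr::pmap(grid, function(cag, age, scale) {
      eff <- numeric(config$n_genes)
      for (nm in progressive) {
        members <- match(intersect(sets[[nm]], universe), universe)
        if (!length(members)) next
        sign_dir <- if (grepl("down", nm)) -1 else 1
        noise <- if (noise_sd > 0) rnorm(length(members), sd = noise_sd) else 0
        eff[members] <- eff[members] + sign_dir * scale + noise
      }
      z <- base_z + eff
      tibble(cag = cag, age = age, gene = universe,
             log2fc = z / 4,
             p = pmax(2 * pnorm(-abs(z)), 1e-300))
    })
    out <- bind_rows(cells)
    class(out) <- c("de_series", class(out))
    out
  })
}

# Coerce a gene_set_partition / named list / character vector to a named list.
as_gene_sets <- function(sets) {
  if (inherits(sets, "gene_set_partition")) {
    return(unclass(sets)[c("down_poor", "down_good", "up_poor", "up_good",
                           "rest_down", "rest_up")])
  }
  if (is.character(sets)) {
    return(list(set = sets))
  }
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == "")) {
    abort("`sets` must be a named list of gene-id vectors.",
          class = "phenoscreen_config_error")
  }
  sets
}
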