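#' Relative expression from qPCR Ct values (delta-Ct method)
#'
#' For each (animal, tissue, gene) the expression relative to the reference
#' gene is `2^-(Ct_gene - Ct_ref)` (amplification efficiency fixed at 2).
#' Fold values are then scaled so that the baseline group (wild-type by
#' default) has geometric-mean fold 1 per (tissue, gene): folds are log-scale
#' quantities, so the geometric mean is the natural baseline. Because both
#' target and reference come from the same sample, a constant Ct shift of a
#' whole sample (plate effect) cancels.
#'
#' @param q A Ct tibble with columns `animal`, `tissue`, `gene`, `Ct`, and a
#'   `genotype` column (or supply `meta`).
#' @param reference_gene Reference gene name (e.g. `"Gapdh"`); its Ct must be
#'   present for every (animal, tissue).
#' @param baseline_group Genotype used as baseline (default `"wt"`).
#' @param meta Optional tibble (`animal`, `genotype`) when `q` lacks genotype.
#' @return A tibble `animal`, `tissue`, `gene`, `genotype`, `rel` (expression
#'   relative to the reference) and `fold` (relative to the baseline group);
#'   reference-gene rows are dropped.
#' @examples
#' ct <- tibble::tibble(
#'   animal = rep(c("a1", "a2"), each = 2), tissue = "striatum",
#'   gene = rep(c("Gapdh", "Penk"), 2), Ct = c(20, 24, 20, 25),
#'   genotype = c("wt", "wt", "mut", "mut")
#' )
#' relative_expression(ct) # mutant Penk fold = 0.5
#' @export
relative_expression <- function(q, reference_gene = "Gapdh",
                                baseline_group = "wt", meta = NULL) {
  q <- as_tibble(q)
  required <- c("animal", "tissue", "gene", "Ct")
  missing_col <- setdiff(required, names(q))
  if (length(missing_col)) {
    abort(sprintf("missing required column(s): %s",
                  paste(missing_col, collapse = ", ")),
          class = "phenoscreen_format_error")
  }
  if (!"genotype" %in% names(q)) {
    if (is.null(meta)) {
      abort("supply a `genotype` column or `meta`.",
            class = "phenoscreen_format_error")
    }
    q <- left_join(q, select(as_tibble(meta), "animal", "genotype"),
                   by = "animal")
  }
  if (any(!is.finite(q$Ct))) {
    abort("Ct values must be finite.", class = "phenoscreen_format_error")
  }

  ref <- q |>
    filter(.data$gene == reference_gene) |>
    select("animal", "tissue", ref_ct = "Ct")
  targets <- filter(q, .data$gene != reference_gene)
  merged <- left_join(targets, ref, by = c("animal", "tissue"))
  if (anyNA(merged$ref_ct)) {
    bad <- merged |>
      filter(is.na(.data$ref_ct)) |>
      distinct(.data$animal, .data$tissue)
    abort(sprintf("missing reference Ct (%s) for: %s", reference_gene,
                  paste(paste(bad$animal, bad$tissue, sep = "/"),
                        collapse = ", ")),
          class = "phenoscreen_format_error")
  }

  merged |>
    mutate(rel = 2^(-(.data$Ct - .data$ref_ct))) |>
    group_by(.data$tissue, .data$gene) |>
    mutate(fold = .data$rel /
             geometric_mean(.data$rel[.data$genotype == baseline_group])) |>
    ungroup() |>
    select("animal", "tissue", "gene", "genotype", "rel", "fold")
}
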