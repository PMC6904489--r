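#' Expression count container
#'
#' A minimal genes-by-samples container: a non-negative integer count matrix
#' with unique gene and sample ids, plus a sample metadata tibble (genotype and
#' optionally performer label, tissue, ...). [tidy()] turns it into a long
#' tibble for dplyr/ggplot work.
#'
#' @param counts Integer matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids).
#' @param samples Tibble with a `sample` column matching `colnames(counts)`.
#' @return An object of class `expr_set`.
#' @export
expr_set <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` needs gene rownames and sample colnames.",
          class = "phenoscreen_format_error")
  }
  if (anyDuplicated(rownames(counts))) {
    abort("gene ids must be unique.", class = "phenoscreen_format_error")
  }
  if (anyDuplicated(colnames(counts))) {
    abort("sample ids must be unique.", class = "phenoscreen_format_error")
  }
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(!is_wholenumber(counts))) {
    abort("counts must be finite non-negative integers.",
          class = "phenoscreen_format_error")
  }
  samples <- as_tibble(samples)
  if (!"sample" %in% names(samples)) {
    abort("`samples` must have a `sample` column.",
          class = "phenoscreen_format_error")
  }
  if (!setequal(samples$sample, colnames(counts)) ||
      anyDuplicated(samples$sample)) {
    abort("sample metadata must match count columns one-to-one.",
          class = "phenoscreen_format_error")
  }
  samples <- samples[match(colnames(counts), samples$sample), ]
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, samples = samples), class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf("<expr_set> %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  extra <- setdiff(names(x$samples), "sample")
  if (length(extra)) cat("  sample metadata:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_set <- function(x) dim(x$counts)

#' Long-format view of an expression set
#'
#' @param x An [expr_set()].
#' @param ... Unused.
#' @return A tibble with one row per (gene, sample) count, joined with the
#'   sample metadata.
#' @export
tidy.expr_set <- function(x, ...) {
  as_tibble(x$counts, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "sample", values_to = "count") |>
    left_join(x$samples, by = "sample")
}

#' Library-size-normalized counts
#'
#' Divides each column by its median-of-ratios size factor (see
#' [size_factors()]).
#'
#' @param x An [expr_set()] or a count matrix.
#' @param sf Optional precomputed size factors.
#' @return A numeric matrix of normalized counts.
#' @export
normalized_counts <- function(x, sf = NULL) {
  counts <- if (inherits(x, "expr_set")) x$counts else as.matrix(x)
  if (is.null(sf)) sf <- size_factors(counts)
  sweep(counts, 2, sf, "/")
}
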