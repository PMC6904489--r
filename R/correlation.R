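#' Spearman rank correlation
#'
#' Pearson product-moment correlation of average ranks; equal to
#' `1 - 6 * sum(d^2) / (n (n^2 - 1))` when there are no ties. Ties receive
#' average ranks. Invariant under strictly monotone transforms of either
#' argument.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, neither constant.
#' @return The rank correlation, in `[-1, 1]`.
#' @examples
#' spearman_rho(1:5, c(2, 1, 4, 3, 5)) # 0.8
#' @export
spearman_rho <- function(x, y) {
  check_cor_input(x, y)
  pearson_r(rank(x, ties.method = "average"), rank(y, ties.method = "average"))
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, neither constant.
#' @return The correlation coefficient, in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  check_cor_input(x, y)
  xc <- x - mean(x)
  yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

check_cor_input <- function(x, y) {
  if (length(x) != length(y)) {
    abort("`x` and `y` must have equal length.",
          class = "phenoscreen_config_error")
  }
  if (length(x) < 3) {
    abort("need at least 3 paired observations.",
          class = "phenoscreen_config_error")
  }
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y)))) {
    abort("inputs must be finite and free of missing values.",
          class = "phenoscreen_config_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined for a constant vector.",
          class = "phenoscreen_config_error")
  }
  invisible(TRUE)
}

#' t-test for a correlation coefficient
#'
#' Tests whether a correlation differs from zero via the regression t
#' statistic `t = rho * sqrt((n - 2) / (1 - rho^2))` with a two-sided p-value
#' from Student's t on `n - 2` degrees of freedom. `|rho| = 1` is returned as
#' the limiting case `p = 0` with `limiting = TRUE`.
#'
#' @param rho Correlation coefficient in `[-1, 1]`.
#' @param n Number of paired observations (`>= 3`).
#' @return A list with `t`, `p` and `limiting`.
#' @examples
#' correlation_test(0.8, 29)$t # 6.928
#' @export
correlation_test <- function(rho, n) {
  if (n < 3) abort("need n >= 3.", class = "phenoscreen_config_error")
  if (!is.finite(rho) || abs(rho) > 1 + 1e-12) {
    abort("`rho` must lie in [-1, 1].", class = "phenoscreen_config_error")
  }
  if (abs(rho) >= 1) {
    return(list(t = sign(rho) * Inf, p = 0, limiting = TRUE))
  }
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  list(t = t, p = 2 * pt(-abs(t), df = n - 2), limiting = FALSE)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Sorts ascending and takes `q_(i) = min_{j >= i} p_(j) * m / j`, capped at
#' 1, returned in the input order. `NA` entries are preserved and do not count
#' towards `m`.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Adjusted values, same length and order as the input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bh_adjust <- function(pvals) {
  ok <- !is.na(pvals)
  p <- pvals[ok]
  if (any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1].", class = "phenoscreen_config_error")
  }
  m <- length(p)
  out <- rep(NA_real_, length(pvals))
  if (m) {
    o <- order(p)
    q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
    q <- numeric(m)
    q[o] <- pmin(q_sorted, 1)
    out[ok] <- q
  }
  out
}

#' Screen traits against gene expression by rank correlation
#'
#' The per-panel trait-by-gene correlation screen: for every pair with at
#' least `min_n` overlapping animals it reports the Spearman and Pearson
#' coefficients, the regression t statistic and p-value for the Spearman
#' coefficient (the headline statistic), and Benjamini-Hochberg adjusted
#' values. The BH family is, by default, each (tissue, genotype) panel over
#' all its trait-by-gene tests (`family_scope = "panel"`); `"global"` adjusts
#' across all panels jointly. Flags: `tilde` for unadjusted p < `p_flag`,
#' `star` for adjusted p < `q_flag`.
#'
#' @param traits Tibble with `animal`, `trait`, `value`, optionally
#'   `genotype`.
#' @param expr Tibble with `animal`, `gene`, `value`, optionally `tissue`
#'   (qPCR folds or normalized counts; any monotone scale works for rho).
#' @param family_scope `"panel"` (default) or `"global"`.
#' @param min_n Minimum overlapping animals per pair (default 5).
#' @param p_flag,q_flag Flag thresholds (defaults 0.05 and 0.1).
#' @return A `screen_result` tibble: tissue, genotype, trait, gene, n, rho, r,
#'   t, p, q, tilde, star; skipped-pair count in attribute `skipped`.
#' @export
trait_gene_screen <- function(traits, expr, family_scope = c("panel", "global"),
                              min_n = 5, p_flag = 0.05, q_flag = 0.1) {
  family_scope <- match.arg(family_scope)
  traits <- as_tibble(traits)
  expr <- as_tibble(expr)
  stopifnot(all(c("animal", "trait", "value") %in% names(traits)),
            all(c("animal", "gene", "value") %in% names(expr)))
  if (!"genotype" %in% names(traits)) traits$genotype <- "all"
  if (!"tissue" %in% names(expr)) expr$tissue <- "all"

  merged <- inner_join(
    rename(traits, trait_value = "value"),
    rename(expr, expr_value = "value"),
    by = "animal", relationship = "many-to-many"
  )
  if (!nrow(merged)) {
    abort("no overlapping animals between traits and expression.",
          class = "phenoscreen_key_error")
  }

  res <- merged |>
    group_by(.data$tissue, .data$genotype, .data$trait, .data$gene) |>
    summarise(stats = list(pair_correlation(.data$trait_value,
                                            .data$expr_value, min_n)),
              .groups = "drop") |>
    tidyr::unnest_wider("stats")

  skipped <- sum(is.na(res$rho))
  if (skipped > 0) {
    inform(sprintf("trait_gene_screen: skipped %d pair(s) with < %d overlapping animals or constant values.",
                   skipped, min_n))
  }
  res <- filter(res, !is.na(.data$rho))

  res <- if (family_scope == "panel") {
    res |>
      group_by(.data$tissue, .data$genotype) |>
      mutate(q = bh_adjust(.data$p)) |>
      ungroup()
  } else {
    mutate(res, q = bh_adjust(.data$p))
  }
  res <- res |>
    mutate(tilde = .data$p < p_flag, star = .data$q < q_flag) |>
    arrange(.data$tissue, .data$genotype, .data$trait, .data$gene)
  attr(res, "skipped") <- skipped
  class(res) <- c("screen_result", class(res))
  res
}

# Correlations for one trait/gene pair on complete cases; NA row when the
# pair is unusable (too few animals or a constant vector).
pair_correlation <- function(tv, ev, min_n) {
  keep <- is.finite(tv) & is.finite(ev)
  tv <- tv[keep]
  ev <- ev[keep]
  n <- length(tv)
  empty <- list(n = n, rho = NA_real_, r = NA_real_, t = NA_real_,
                p = NA_real_)
  if (n < max(min_n, 3) || sd(tv) == 0 || sd(ev) == 0) return(empty)
  rho <- spearman_rho(tv, ev)
  ct <- correlation_test(rho, n)
  list(n = n, rho = rho, r = pearson_r(tv, ev), t = ct$t, p = ct$p)
}

#' @export
glance.screen_result <- function(x, ...) {
  tibble(n_pairs = nrow(x), n_tilde = sum(x$tilde), n_star = sum(x$star),
         n_skipped = attr(x, "skipped") %||% 0L)
}

#' @export
tidy.screen_result <- function(x, ...) as_tibble(x)
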