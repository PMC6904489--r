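#' Four-way severity partition of differentially expressed genes
#'
#' Combines the three contrasts of the extreme-performer design (mutant poor
#' vs pooled wild-type, mutant good vs pooled wild-type, poor vs good) into
#' four disjoint severity sets plus two "rest" sets. Candidate genes are
#' significant between poor and good (`q < fdr`) and vs wild-type in at least
#' one contrast; their direction is the sign of the vs-wild-type log2 fold
#' change (genes whose two vs-wild-type contrasts are both significant but
#' disagree in sign are excluded and counted). A candidate is assigned to
#' "poor" when its change vs wild-type is deeper in the poor contrast
#' (`by = "lfc"`: larger `|log2fc|`; `by = "pvalue"`: smaller p), else to
#' "good". The rest sets collect genes significant vs wild-type in both
#' contrasts with the same sign but not between poor and good.
#'
#' @param de_poor_wt,de_good_wt,de_poor_good `de_result` tibbles sharing one
#'   gene universe.
#' @param fdr Adjusted-p threshold (default 0.05).
#' @param by Depth metric for the poor/good assignment, `"lfc"` (default) or
#'   `"pvalue"`.
#' @return A `gene_set_partition`: list of gene-id vectors `down_poor`,
#'   `down_good`, `up_poor`, `up_good`, `rest_down`, `rest_up`, with the
#'   number of sign-conflict exclusions in attribute `conflicts`.
#' @export
partition_gene_sets <- function(de_poor_wt, de_good_wt, de_poor_good,
                                fdr = 0.05, by = c("lfc", "pvalue")) {
  by <- match.arg(by)
  for (de in list(de_poor_wt, de_good_wt, de_poor_good)) {
    stopifnot(is.data.frame(de),
              all(c("gene", "log2fc", "p", "q") %in% names(de)))
  }
  if (!setequal(de_poor_wt$gene, de_good_wt$gene) ||
      !setequal(de_poor_wt$gene, de_poor_good$gene)) {
    abort("the three DE results must share one gene universe.",
          class = "phenoscreen_key_error")
  }
  u <- de_poor_wt$gene
  pw <- de_poor_wt[match(u, de_poor_wt$gene), ]
  gw <- de_good_wt[match(u, de_good_wt$gene), ]
  pg <- de_poor_good[match(u, de_poor_good$gene), ]

  sig <- function(q) !is.na(q) & q < fdr
  sig_pw <- sig(pw$q)
  sig_gw <- sig(gw$q)
  sig_pg <- sig(pg$q)

  candidate <- sig_pg & (sig_pw | sig_gw)
  conflict <- candidate & sig_pw & sig_gw &
    sign(pw$log2fc) != sign(gw$log2fc)
  n_conflict <- sum(conflict)
  if (n_conflict > 0) {
    inform(sprintf("partition_gene_sets: excluded %d gene(s) with conflicting vs-wild-type directions.",
                   n_conflict))
  }
  candidate <- candidate & !conflict

  # direction from whichever vs-wt contrast is significant (they agree when both are)
  direction <- ifelse(sig_pw, sign(pw$log2fc), sign(gw$log2fc))
  deeper_poor <- if (by == "lfc") {
    # a gene untested in one vs-wt contrast is "deeper" in the other
    dplyr::coalesce(abs(pw$log2fc), -Inf) >= dplyr::coalesce(abs(gw$log2fc), -Inf)
  } else {
    dplyr::coalesce(pw$p, Inf) <= dplyr::coalesce(gw$p, Inf)
  }

  rest <- sig_pw & sig_gw & sign(pw$log2fc) == sign(gw$log2fc) & !sig_pg

  out <- structure(
    list(
      down_poor = sort(u[candidate & direction < 0 & deeper_poor]),
      down_good = sort(u[candidate & direction < 0 & !deeper_poor]),
      up_poor = sort(u[candidate & direction > 0 & deeper_poor]),
      up_good = sort(u[candidate & direction > 0 & !deeper_poor]),
      rest_down = sort(u[rest & sign(pw$log2fc) < 0]),
      rest_up = sort(u[rest & sign(pw$log2fc) > 0])
    ),
    class = "gene_set_partition"
  )
  attr(out, "conflicts") <- n_conflict
  attr(out, "fdr") <- fdr
  attr(out, "universe") <- u
  out
}

#' @export
print.gene_set_partition <- function(x, ...) {
  cat("<gene_set_partition>\n")
  for (nm in names(x)) cat(sprintf("  %-10s %d genes\n", nm, length(x[[nm]])))
  nc <- attr(x, "conflicts")
  if (!is.null(nc) && nc > 0) cat(sprintf("  (%d sign-conflict exclusions)\n", nc))
  invisible(x)
}

#' @export
tidy.gene_set_partition <- function(x, ...) {
  purrr::imap(unclass(x), \(genes, set) tibble(set = set, gene = genes)) |>
    bind_rows()
}

#' Presence of a gene set among the top-ranked DEGs of one comparison
#'
#' Ranks the same-direction genes of a DE table by ascending p-value (ties:
#' larger `|log2fc|` first, then gene id), takes the first `n_top`, and
#' reports the percentage of the set found among them. Set members absent
#' from the table count as non-present; the denominator is always the set
#' size.
#'
#' @param set Non-empty character vector of gene ids.
#' @param cell_table Tibble with `gene`, `log2fc`, `p` for one comparison.
#' @param n_top Number of top genes (default 684).
#' @param direction `"down"` or `"up"`.
#' @return Presence as a percentage in `[0, 100]`.
#' @export
top_deg_presence <- function(set, cell_table, n_top = 684,
                             direction = c("down", "up")) {
  direction <- match.arg(direction)
  if (!length(set)) abort("`set` is empty.", class = "phenoscreen_config_error")
  stopifnot(all(c("gene", "log2fc", "p") %in% names(cell_table)))
  same_dir <- if (direction == "down") {
    filter(cell_table, .data$log2fc < 0)
  } else {
    filter(cell_table, .data$log2fc > 0)
  }
  if (nrow(same_dir) < n_top) {
    warn(sprintf("only %d %s-direction genes available (< n_top = %d); using all of them.",
                 nrow(same_dir), direction, n_top))
  }
  top <- same_dir |>
    arrange(.data$p, desc(abs(.data$log2fc)), .data$gene) |>
    head(n_top)
  if (!any(set %in% cell_table$gene)) {
    warn("gene set is disjoint from the table's universe.")
  }
  100 * length(intersect(set, top$gene)) / length(set)
}

#' Presence progression of the severity sets across an allelic series
#'
#' Computes, for every gene set and grid cell, the presence percentage among
#' the top `n_top` same-direction DEGs ("down" sets against the
#' downregulated ranking, "up" sets against the upregulated one), and
#' summarises monotonicity as the Spearman correlation of presence against
#' CAG length at each age, and against age at each CAG length.
#'
#' @param sets A [partition_gene_sets()] result or named list of gene sets
#'   (names must contain `"down"` or `"up"`); empty sets are skipped.
#' @param series A `de_series` tibble (`cag`, `age`, `gene`, `log2fc`, `p`).
#' @param n_top Number of top genes per direction (default 684).
#' @return A `progression_profile`: `presence` tibble (set, cag, age,
#'   direction, presence) and `monotonicity` tibble (set, margin, level, rho).
#' @export
progression_profile <- function(sets, series, n_top = 684) {
  sets <- as_gene_sets(sets)
  sets <- sets[lengths(sets) > 0]
  if (!length(sets)) abort("all sets are empty.",
                           class = "phenoscreen_config_error")
  stopifnot(all(c("cag", "age", "gene", "log2fc", "p") %in% names(series)))

  cells <- series |>
    group_by(.data$cag, .data$age) |>
    tidyr::nest() |>
    ungroup()
  presence <- purrr::imap(sets, function(members, nm) {
    dir <- if (grepl("down", nm)) "down" else "up"
    tibble(
      set = nm, cag = cells$cag, age = cells$age, direction = dir,
      presence = purrr::map_dbl(cells$data, \(tab)
        top_deg_presence(members, tab, n_top = n_top, direction = dir))
    )
  }) |>
    bind_rows()

  mono_cag <- presence |>
    group_by(.data$set, .data$direction, level = .data$age) |>
    summarise(rho = safe_spearman(.data$cag, .data$presence),
              .groups = "drop") |>
    mutate(margin = "cag")
  mono_age <- presence |>
    group_by(.data$set, .data$direction, level = .data$cag) |>
    summarise(rho = safe_spearman(.data$age, .data$presence),
              .groups = "drop") |>
    mutate(margin = "age")
  monotonicity <- bind_rows(mono_cag, mono_age) |>
    select("set", "margin", "level", "rho")

  structure(list(presence = presence, monotonicity = monotonicity,
                 n_top = n_top),
            class = "progression_profile")
}

# Spearman that returns NA instead of erroring on degenerate input.
safe_spearman <- function(x, y) {
  tryCatch(spearman_rho(x, y), error = function(e) NA_real_)
}

#' @export
print.progression_profile <- function(x, ...) {
  cat(sprintf("<progression_profile> %d sets x %d cells, n_top = %d\n",
              length(unique(x$presence$set)),
              nrow(distinct(x$presence, .data$cag, .data$age)), x$n_top))
  invisible(x)
}

#' @export
tidy.progression_profile <- function(x, ...) x$presence

#' @export
glance.progression_profile <- function(x, ...) {
  x$monotonicity |>
    group_by(.data$set, .data$margin) |>
    summarise(mean_rho = mean(.data$rho, na.rm = TRUE), .groups = "drop")
}

#' Hypergeometric over-representation test
#'
#' Upper-tail hypergeometric test of the overlap between a gene set and an
#' annotation within a universe: `p = P(X >= k)` with universe size `N`,
#' annotation size `K` and `n = |set|` draws. With `ease = TRUE` the observed
#' overlap is decremented by one before the tail (the conservative
#' DAVID/EASE convention, applied only when `k >= 1`; `k = 0` keeps `p = 1`).
#'
#' @param set Character vector of gene ids (must lie in `universe`).
#' @param annotation Character vector of annotated genes (must lie in
#'   `universe`).
#' @param universe Character vector defining the gene universe.
#' @param ease Apply the EASE decrement (default `FALSE`).
#' @return A one-row tibble: `k` (overlap), `K`, `n`, `N`, `p`.
#' @examples
#' hypergeometric_ora(paste0("g", 1:4), paste0("g", c(1:3, 5, 6)),
#'                    paste0("g", 1:20))$p # 155/4845
#' @export
hypergeometric_ora <- function(set, annotation, universe, ease = FALSE) {
  set <- unique(set)
  annotation <- unique(annotation)
  universe <- unique(universe)
  offenders <- c(setdiff(set, universe), setdiff(annotation, universe))
  if (length(offenders)) {
    abort(sprintf("genes outside the universe: %s",
                  paste(unique(offenders), collapse = ", ")),
          class = "phenoscreen_key_error")
  }
  N <- length(universe)
  K <- length(annotation)
  n <- length(set)
  k <- length(intersect(set, annotation))
  k_eff <- if (ease && k >= 1) max(k - 1L, 1L) else k
  p <- if (k_eff == 0) 1 else phyper(k_eff - 1, K, N - K, n, lower.tail = FALSE)
  tibble(k = k, K = K, n = n, N = N, p = p)
}
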