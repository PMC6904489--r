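#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over genes of the ratio of
#' the sample's count to the gene's geometric mean across samples, computed
#' on genes with nonzero counts in every sample. If no such gene exists, set
#' `pseudo_reference = TRUE` to fall back to a reference built from positive
#' counts only (geometric mean over the samples where the gene is expressed).
#'
#' @param counts Count matrix (genes x samples) or an [expr_set()].
#' @param pseudo_reference Enable the positive-count fallback reference.
#' @return Named positive numeric vector, one factor per sample.
#' @examples
#' m <- matrix(c(2, 6, 4, 12), nrow = 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' size_factors(m) # 0.7071, 1.4142
#' @export
size_factors <- function(counts, pseudo_reference = FALSE) {
  if (inherits(counts, "expr_set")) counts <- counts$counts
  counts <- as.matrix(counts)
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (any(all_pos)) {
    loggeo <- rowMeans(log(counts[all_pos, , drop = FALSE]))
    ratios <- counts[all_pos, , drop = FALSE] / exp(loggeo)
    sf <- apply(ratios, 2, median)
  } else {
    if (!pseudo_reference) {
      abort(paste("no gene has nonzero counts in every sample;",
                  "re-run with pseudo_reference = TRUE."),
            class = "phenoscreen_config_error")
    }
    expressed <- rowSums(counts > 0) > 0
    sub <- counts[expressed, , drop = FALSE]
    loggeo <- apply(sub, 1, function(x) mean(log(x[x > 0])))
    ratios <- sub / exp(loggeo)
    ratios[sub == 0] <- NA
    sf <- apply(ratios, 2, median, na.rm = TRUE)
  }
  if (any(!is.finite(sf) | sf <= 0)) {
    abort("degenerate size factor(s); check for empty samples.",
          class = "phenoscreen_config_error")
  }
  setNames(sf, colnames(counts))
}

#' Per-gene negative-binomial dispersion estimates
#'
#' Method-of-moments estimate on size-factor-normalized counts pooled within
#' groups: with group means `m_g` and variances `s2_g`,
#' `alpha_raw = max(0, sum (n_g - 1)(s2_g - m_g) / sum (n_g - 1) m_g^2)`.
#' With `shrink > 0` a mean-dispersion trend is fitted by loess of the raw
#' estimates on log mean and used as a floor:
#' `alpha = trend + (1 - shrink) * max(0, raw - trend)`. Genes below the
#' trend are lifted to it and genes above keep part of their excess, which
#' protects the Wald test against the anticonservative direction (per-gene
#' underestimation) at small sample sizes. `shrink = 0` returns the raw
#' method-of-moments estimates untouched. Genes with zero counts everywhere
#' get `NA`.
#'
#' @param counts Count matrix (genes x samples) or [expr_set()].
#' @param groups Factor/vector of group membership, one entry per sample.
#' @param sf Optional size factors; computed if `NULL`.
#' @param shrink Weight of the trend floor in `[0, 1]` (default 0.5);
#'   `1` uses the trend alone, `0` disables the trend entirely.
#' @param span Loess span for the trend fit.
#' @return Named numeric vector of dispersions (`alpha >= 0`, NA for all-zero
#'   genes).
#' @export
estimate_dispersion <- function(counts, groups, sf = NULL, shrink = 0.5,
                                span = 0.5) {
  if (inherits(counts, "expr_set")) counts <- counts$counts
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  stopifnot(length(groups) == ncol(counts), shrink >= 0, shrink <= 1)
  if (any(table(groups) < 2)) {
    abort("need >= 2 samples per group to estimate dispersion.",
          class = "phenoscreen_config_error")
  }
  if (is.null(sf)) sf <- size_factors(counts, pseudo_reference = TRUE)
  norm <- sweep(counts, 2, sf, "/")

  num <- den <- numeric(nrow(counts))
  for (g in levels(groups)) {
    sub <- norm[, groups == g, drop = FALSE]
    n_g <- ncol(sub)
    m_g <- rowMeans(sub)
    s2_g <- rowSums((sub - m_g)^2) / (n_g - 1)
    num <- num + (n_g - 1) * (s2_g - m_g)
    den <- den + (n_g - 1) * m_g^2
  }
  raw <- ifelse(den > 0, pmax(0, num / den), NA_real_)
  base_mean <- rowMeans(norm)

  if (shrink == 0) {
    return(setNames(raw, rownames(counts)))
  }
  trend <- fit_dispersion_trend(base_mean, raw, span = span)
  alpha <- trend + (1 - shrink) * pmax(0, raw - trend)
  setNames(alpha, rownames(counts))
}

# Smooth mean-dispersion trend fitted on the raw (linear-scale) estimates so
# that the zero-truncated values keep the fit unbiased upward rather than
# dragging it down; falls back to the mean dispersion when too few genes are
# available for a loess fit.
fit_dispersion_trend <- function(base_mean, raw, span = 0.5, floor = 1e-8) {
  testable <- is.finite(raw)
  usable <- testable & base_mean > 0
  trend <- rep(NA_real_, length(raw))
  if (sum(usable) < 20) {
    trend[testable] <- mean(raw[testable], na.rm = TRUE)
    return(pmax(trend, floor))
  }
  lbm <- log(base_mean[usable])
  fit <- stats::loess(raw[usable] ~ lbm, span = span, degree = 1)
  # clamp to the fitted range: loess returns NA outside it
  rng <- range(lbm)
  newx <- pmin(pmax(log(pmax(base_mean[testable], 1e-12)), rng[1]), rng[2])
  trend[testable] <- predict(fit, newdata = newx)
  pmax(trend, floor)
}

#' Negative-binomial Wald test for a two-group contrast
#'
#' Fits, per gene, a negative-binomial generalized linear model with log link,
#' known dispersion and design intercept + group, by iteratively reweighted
#' least squares with log size factors as offsets. The group covariate is
#' coded -1/2, +1/2 so that swapping the group labels negates every log2 fold
#' change exactly. A small ridge penalty on the group coefficient
#' (configurable) keeps genes expressed in only one group finite. The Wald
#' statistic is log2fc / se with a two-sided normal p-value; adjusted p-values
#' are Benjamini-Hochberg over the tested genes. Genes with zero counts in
#' all samples are flagged `untested` (not dropped) and excluded from the BH
#' family.
#'
#' @param counts Count matrix (genes x samples) or [expr_set()].
#' @param groups Two-level factor/vector, one entry per sample; the first
#'   level is the reference (A) and the fold change is B over A. `>= 2`
#'   samples per group.
#' @param dispersions Per-gene alpha (scalar recycled); `0` gives Poisson
#'   weights.
#' @param sf Optional size factors (computed if `NULL`).
#' @param ridge Ridge precision on the group coefficient (default `1e-6`).
#' @param max_iter,tol IRLS iteration cap and convergence tolerance on the
#'   coefficients.
#' @return A `de_result` tibble: gene, base_mean, log2fc, se, wald, p, q,
#'   status (`"ok"`, `"not_converged"`, `"untested"`).
#' @export
nb_wald_test <- function(counts, groups, dispersions, sf = NULL,
                         ridge = 1e-6, max_iter = 50L, tol = 1e-8) {
  if (inherits(counts, "expr_set")) counts <- counts$counts
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) {
    abort("`groups` must have exactly two levels.",
          class = "phenoscreen_config_error")
  }
  if (any(table(groups) < 2)) {
    abort("need >= 2 samples per group.", class = "phenoscreen_config_error")
  }
  stopifnot(length(groups) == ncol(counts))
  n_genes <- nrow(counts)
  alpha <- rep_len(as.numeric(dispersions), n_genes)
  alpha[!is.finite(alpha)] <- 0
  if (is.null(sf)) sf <- size_factors(counts, pseudo_reference = TRUE)
  norm <- sweep(counts, 2, sf, "/")
  base_mean <- rowMeans(norm)

  x <- ifelse(groups == levels(groups)[2], 0.5, -0.5)
  offs <- log(sf)
  tested <- rowSums(counts) > 0
  Y <- counts[tested, , drop = FALSE]
  a <- alpha[tested]

  mA <- rowMeans(norm[tested, x < 0, drop = FALSE])
  mB <- rowMeans(norm[tested, x > 0, drop = FALSE])
  b1 <- log(mB + 0.5) - log(mA + 0.5)
  b0 <- 0.5 * (log(mB + 0.5) + log(mA + 0.5))

  offs_m <- matrix(offs, nrow = nrow(Y), ncol = ncol(Y), byrow = TRUE)
  converged <- rep(FALSE, nrow(Y))
  for (iter in seq_len(max_iter)) {
    eta <- b0 + outer(b1, x) + offs_m
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + a * mu)
    z <- (eta - offs_m) + (Y - mu) / mu
    S0 <- rowSums(w)
    Sx <- as.vector(w %*% x)
    Sxx <- as.vector(w %*% (x * x))
    Sz <- rowSums(w * z)
    Sxz <- rowSums(w * z * rep(x, each = nrow(Y)))
    det <- S0 * (Sxx + ridge) - Sx * Sx
    b0_new <- ((Sxx + ridge) * Sz - Sx * Sxz) / det
    b1_new <- (S0 * Sxz - Sx * Sz) / det
    step <- pmax(abs(b0_new - b0), abs(b1_new - b1))
    newly <- !converged & step < tol
    converged <- converged | newly
    b0 <- b0_new
    b1 <- b1_new
    if (all(converged)) break
  }
  # final information matrix at the solution
  eta <- pmin(pmax(b0 + outer(b1, x) + offs_m, -30), 30)
  mu <- exp(eta)
  w <- mu / (1 + a * mu)
  S0 <- rowSums(w)
  Sx <- as.vector(w %*% x)
  Sxx <- as.vector(w %*% (x * x))
  det <- S0 * (Sxx + ridge) - Sx * Sx
  se_nat <- sqrt(S0 / det)

  ln2 <- log(2)
  res <- tibble(
    gene = rownames(counts) %||% as.character(seq_len(n_genes)),
    base_mean = unname(base_mean),
    log2fc = NA_real_, se = NA_real_, wald = NA_real_,
    p = NA_real_, q = NA_real_,
    status = ifelse(unname(tested), "ok", "untested")
  )
  res$log2fc[tested] <- b1 / ln2
  res$se[tested] <- se_nat / ln2
  res$wald[tested] <- b1 / se_nat
  p <- 2 * pnorm(-abs(b1 / se_nat))
  p[!converged] <- NA_real_
  res$p[tested] <- p
  res$status[tested][!converged] <- "not_converged"
  res$q <- bh_adjust(res$p)
  attr(res, "contrast") <- paste(levels(groups)[2], "vs", levels(groups)[1])
  attr(res, "size_factors") <- sf
  class(res) <- c("de_result", class(res))
  res
}

#' Run the full two-group DE stage on an expression set
#'
#' Convenience wrapper chaining [size_factors()], [estimate_dispersion()] and
#' [nb_wald_test()] for one contrast.
#'
#' @param x An [expr_set()] or count matrix.
#' @param groups Two-level group vector per sample, or the name of a column
#'   of the sample metadata when `x` is an `expr_set`.
#' @param contrast Optional character pair `c(B, A)`: B over A.
#' @param shrink Dispersion shrinkage weight, see [estimate_dispersion()].
#' @param ... Passed to [nb_wald_test()].
#' @return A `de_result` tibble.
#' @export
de_analysis <- function(x, groups, contrast = NULL, shrink = 0.5, ...) {
  counts <- if (inherits(x, "expr_set")) x$counts else as.matrix(x)
  if (inherits(x, "expr_set") && is.character(groups) &&
      length(groups) == 1L && groups %in% names(x$samples)) {
    groups <- x$samples[[groups]]
  }
  groups <- as.character(groups)
  if (!is.null(contrast)) {
    keep <- groups %in% contrast
    counts <- counts[, keep, drop = FALSE]
    groups <- factor(groups[keep], levels = rev(contrast)) # A first, B second
  } else {
    groups <- as.factor(groups)
  }
  sf <- size_factors(counts, pseudo_reference = TRUE)
  disp <- estimate_dispersion(counts, groups, sf = sf, shrink = shrink)
  disp[is.na(disp)] <- 0
  nb_wald_test(counts, groups, disp, sf = sf, ...)
}

#' Call differentially expressed genes at an FDR threshold
#'
#' @param de A `de_result`.
#' @param fdr Adjusted-p threshold (default 0.05).
#' @return A list with disjoint character vectors `up` (`q < fdr`,
#'   `log2fc > 0`) and `down` (`q < fdr`, `log2fc < 0`).
#' @export
call_degs <- function(de, fdr = 0.05) {
  stopifnot(is.data.frame(de), all(c("gene", "log2fc", "q") %in% names(de)))
  sig <- !is.na(de$q) & de$q < fdr
  list(up = de$gene[sig & de$log2fc > 0],
       down = de$gene[sig & de$log2fc < 0])
}

#' @export
tidy.de_result <- function(x, ...) as_tibble(x)

#' @export
glance.de_result <- function(x, fdr = 0.05, ...) {
  degs <- call_degs(x, fdr)
  tibble(
    contrast = attr(x, "contrast") %||% NA_character_,
    n_genes = nrow(x),
    n_tested = sum(x$status != "untested"),
    n_up = length(degs$up), n_down = length(degs$down), fdr = fdr
  )
}
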