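# Readers and writers for every table the pipeline touches. Phenotype and
# qPCR tables travel as CSV, matrices and DE tables as TSV; every writer
# drops a "<path>.json" sidecar with the column schema and pipeline version.

write_sidecar <- function(path, columns, kind) {
  jsonlite::write_json(
    list(kind = kind, columns = as.list(columns),
         pipeline_version = pipeline_version()),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

check_columns <- function(df, required, path) {
  missing_col <- setdiff(required, names(df))
  if (length(missing_col)) {
    abort(sprintf("%s: missing required column(s): %s", path,
                  paste(missing_col, collapse = ", ")),
          class = "phenoscreen_format_error")
  }
  if (!nrow(df)) {
    abort(sprintf("%s: table is empty.", path),
          class = "phenoscreen_format_error")
  }
  invisible(df)
}

#' Read and validate a phenotype table
#'
#' Expects a CSV with columns `animal`, `genotype` (`wt`/`mut`), `litter`,
#' `trait`, `timepoint`, `value`. Empty value cells are allowed and carried
#' as explicit missing values; duplicate (animal, trait, timepoint) keys,
#' non-numeric values and unknown genotypes are rejected with row numbers.
#'
#' @param path CSV file path.
#' @return A validated phenotype tibble.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "phenoscreen_io_error")
  }
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  check_columns(df, c("animal", "genotype", "litter", "trait", "timepoint",
                      "value"), path)
  value <- suppressWarnings(as.numeric(df$value))
  bad_num <- which(!is.na(df$value) & is.na(value))
  if (length(bad_num)) {
    abort(sprintf("%s: non-numeric value in column 'value', row(s) %s", path,
                  paste(head(bad_num, 5), collapse = ", ")),
          class = "phenoscreen_format_error")
  }
  inf_rows <- which(!is.finite(value) & !is.na(value))
  if (length(inf_rows)) {
    abort(sprintf("%s: non-finite value in column 'value', row(s) %s", path,
                  paste(head(inf_rows, 5), collapse = ", ")),
          class = "phenoscreen_format_error")
  }
  bad_geno <- which(!df$genotype %in% c("wt", "mut"))
  if (length(bad_geno)) {
    abort(sprintf("%s: genotype must be 'wt' or 'mut', row(s) %s", path,
                  paste(head(bad_geno, 5), collapse = ", ")),
          class = "phenoscreen_format_error")
  }
  key <- paste(df$animal, df$trait, df$timepoint, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    abort(sprintf("%s: duplicate (animal, trait, timepoint) key, row(s) %s",
                  path, paste(head(dup, 5), collapse = ", ")),
          class = "phenoscreen_format_error")
  }
  df$value <- value
  df
}

#' Write a phenotype table (CSV plus schema sidecar)
#'
#' @param x Phenotype tibble.
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(x, path) {
  cols <- c("animal", "genotype", "litter", "trait", "timepoint", "value")
  readr::write_csv(select(as_tibble(x), all_of(cols)), path, progress = FALSE)
  write_sidecar(path, cols, "phenotypes")
  invisible(path)
}

#' Read a count matrix with sample metadata
#'
#' The counts TSV has gene ids in the first column (`gene`) and one column
#' per sample; the metadata CSV has columns `sample`, `genotype` and
#' optionally `label`, `tissue`, `animal`. Negative, non-integer or
#' non-numeric counts are rejected with the row and column named.
#'
#' @param path Counts TSV path.
#' @param meta_path Sample metadata CSV path.
#' @return An [expr_set()].
#' @export
read_counts <- function(path, meta_path) {
  for (p in c(path, meta_path)) {
    if (!file.exists(p)) {
      abort(sprintf("file not found: %s", p), class = "phenoscreen_io_error")
    }
  }
  df <- readr::read_tsv(path, col_types = readr::cols(
    gene = "c", .default = "d"), progress = FALSE)
  check_columns(df, "gene", path)
  if (ncol(df) < 2) {
    abort(sprintf("%s: no sample columns.", path),
          class = "phenoscreen_format_error")
  }
  if (anyDuplicated(df$gene)) {
    abort(sprintf("%s: duplicate gene id(s), e.g. '%s'", path,
                  df$gene[duplicated(df$gene)][1]),
          class = "phenoscreen_format_error")
  }
  m <- as.matrix(df[-1])
  bad <- which(is.na(m) | m < 0 | !is_wholenumber(m), arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf("%s: invalid count at row %d, column '%s' (must be a non-negative integer).",
                  path, bad[1, 1], colnames(m)[bad[1, 2]]),
          class = "phenoscreen_format_error")
  }
  rownames(m) <- df$gene
  meta <- readr::read_csv(meta_path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  check_columns(meta, c("sample", "genotype"), meta_path)
  expr_set(m, meta)
}

#' Write a count matrix and its sample metadata
#'
#' @param x An [expr_set()].
#' @param path Destination counts TSV path.
#' @param meta_path Destination metadata CSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, meta_path) {
  stopifnot(inherits(x, "expr_set"))
  df <- as_tibble(x$counts, rownames = "gene")
  readr::write_tsv(df, path, progress = FALSE)
  write_sidecar(path, names(df), "counts")
  readr::write_csv(x$samples, meta_path, progress = FALSE)
  write_sidecar(meta_path, names(x$samples), "sample_meta")
  invisible(path)
}

#' Read an allelic-series directory of ranked DE tables
#'
#' Expects one TSV per grid cell named `cag<Q>_age<M>.tsv` with columns
#' `gene`, `log2fc`, `p`; all cells must cover the same gene universe and
#' p-values must lie in (0, 1].
#'
#' @param dir Directory path.
#' @return A `de_series` tibble (`cag`, `age`, `gene`, `log2fc`, `p`).
#' @export
read_series <- function(dir) {
  if (!dir.exists(dir)) {
    abort(sprintf("directory not found: %s", dir),
          class = "phenoscreen_io_error")
  }
  files <- list.files(dir, pattern = "^cag[0-9]+_age[0-9]+\\.tsv$")
  if (!length(files)) {
    abort(sprintf("%s: no cag<Q>_age<M>.tsv files.", dir),
          class = "phenoscreen_format_error")
  }
  cells <- purrr::map(files, function(f) {
    meta <- as.integer(regmatches(f, gregexpr("[0-9]+", f))[[1]])
    tab <- readr::read_tsv(file.path(dir, f),
                           col_types = readr::cols(gene = "c", log2fc = "d",
                                                   p = "d"),
                           progress = FALSE)
    check_columns(tab, c("gene", "log2fc", "p"), f)
    bad_p <- which(is.na(tab$p) | tab$p <= 0 | tab$p > 1)
    if (length(bad_p)) {
      abort(sprintf("%s: p must lie in (0, 1], row(s) %s", f,
                    paste(head(bad_p, 5), collapse = ", ")),
            class = "phenoscreen_format_error")
    }
    mutate(tab, cag = meta[1], age = meta[2], .before = 1)
  })
  universes <- purrr::map(cells, \(x) sort(x$gene))
  if (length(unique(universes)) != 1L) {
    abort(sprintf("%s: cells do not share one gene universe.", dir),
          class = "phenoscreen_format_error")
  }
  out <- bind_rows(cells)
  class(out) <- c("de_series", class(out))
  out
}

#' Write an allelic series as one TSV per grid cell
#'
#' @param series A `de_series` tibble.
#' @param dir Destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_series <- function(series, dir) {
  stopifnot(all(c("cag", "age", "gene", "log2fc", "p") %in% names(series)))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  series |>
    group_by(.data$cag, .data$age) |>
    group_walk(function(tab, key) {
      f <- file.path(dir, sprintf("cag%d_age%d.tsv", key$cag, key$age))
      readr::write_tsv(tab, f, progress = FALSE)
      write_sidecar(f, names(tab), "de_series_cell")
    })
  invisible(dir)
}

#' Read a plain-text gene list
#'
#' One gene id per line; blank lines are dropped, duplicates are removed
#' with a warning.
#'
#' @param path File path.
#' @return A character vector of unique gene ids.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "phenoscreen_io_error")
  }
  genes <- trimws(readLines(path, warn = FALSE))
  genes <- genes[nzchar(genes)]
  if (!length(genes)) {
    abort(sprintf("%s: gene list is empty.", path),
          class = "phenoscreen_format_error")
  }
  n_dup <- sum(duplicated(genes))
  if (n_dup > 0) {
    warn(sprintf("%s: removed %d duplicate gene id(s).", path, n_dup))
  }
  unique(genes)
}

#' Write a plain-text gene list
#'
#' @param genes Character vector of gene ids.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}
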