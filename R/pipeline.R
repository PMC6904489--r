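#' Run the full phenotype-to-transcriptome pipeline on a synthetic cohort
#'
#' Executes the end-to-end recipe in order: cohort simulation, trait
#' Z-scoring and extreme-performer classification, the trait-by-gene
#' correlation screen on mutant animals, the three differential-expression
#' contrasts (poor vs pooled wild-type, good vs pooled wild-type, poor vs
#' good), the four-way severity gene-set partition, simulation of the
#' external allelic series and the presence progression profile. Every stage
#' logs its timing and headline counts; all tables, gene lists, the JSON and
#' the human-readable run reports are written under `out_dir`. Rerunning
#' with the same configuration reproduces every deterministic output
#' byte-identically (the report carries the only timestamp).
#'
#' @param config A [sim_config()]; its seed drives every random stream.
#' @param out_dir Output directory (created; must be empty or
#'   `overwrite = TRUE`).
#' @param k Extreme animals per tail and genotype (default 4).
#' @param fdr DEG threshold on adjusted p (default 0.05).
#' @param n_top Top-DEG cut for presence (default 684).
#' @param p_flag,q_flag Correlation-screen flag thresholds.
#' @param screen_timepoint Timepoint whose trait values enter the screen;
#'   `NULL` (default) averages each animal's trait over all timepoints.
#' @param grid Allelic-series grid tibble.
#' @param overwrite Allow writing into a non-empty directory.
#' @return Invisibly, a list with all stage objects and the report.
#' @export
run_pipeline <- function(config = sim_config(), out_dir, k = 4, fdr = 0.05,
                         n_top = 684, p_flag = 0.05, q_flag = 0.1,
                         screen_timepoint = NULL,
                         grid = default_series_grid(), overwrite = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !overwrite) {
    abort(sprintf("output directory %s is not empty (set overwrite = TRUE).",
                  out_dir),
          class = "phenoscreen_io_error")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "sets"), showWarnings = FALSE)

  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
            class = "phenoscreen_stage_error")
    })
    inform(sprintf("[%s] done in %.2fs", name,
                   as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  cohort <- stage("simulate", simulate_cohort(config))
  write_phenotypes(cohort$phenotypes, file.path(out_dir, "phenotypes.csv"))

  zs <- stage("classify", zscore_traits(cohort$phenotypes, config$traits))
  labels <- classify_performers(zs, k = k)
  readr::write_csv(labels, file.path(out_dir, "labels.csv"), progress = FALSE)

  counts <- stage("counts", simulate_counts(
    config = config, truth = cohort$truth,
    samples = left_join(cohort$truth$animals, labels,
                        by = c("animal", "genotype")) |>
      mutate(sample = .data$animal)
  ))
  write_counts(counts, file.path(out_dir, "counts.tsv"),
               file.path(out_dir, "samples.csv"))

  # trait score for the screen: a single timepoint, or (default) the
  # animal's mean over all timepoints of the trait
  screen_tp <- screen_timepoint %||% "all"
  screen <- stage("correlate", {
    traits_tbl <- cohort$phenotypes |>
      filter(.data$genotype == "mut")
    if (screen_tp != "all") {
      traits_tbl <- filter(traits_tbl, .data$timepoint == screen_tp)
    }
    traits_tbl <- traits_tbl |>
      summarise(value = mean(.data$value),
                .by = c("animal", "genotype", "trait"))
    expr_tbl <- as_tibble(normalized_counts(counts), rownames = "gene") |>
      tidyr::pivot_longer(-"gene", names_to = "animal", values_to = "value") |>
      filter(.data$animal %in% traits_tbl$animal) |>
      mutate(tissue = "striatum")
    trait_gene_screen(traits_tbl, expr_tbl, p_flag = p_flag, q_flag = q_flag)
  })
  readr::write_tsv(as_tibble(screen), file.path(out_dir, "screen.tsv"),
                   progress = FALSE)

  de <- stage("de", {
    smp <- counts$samples |>
      mutate(group = dplyr::case_when(
        .data$genotype == "wt" & !is.na(.data$label) ~ "wt_pool",
        .data$genotype == "mut" & .data$label == "poor" ~ "mut_poor",
        .data$genotype == "mut" & .data$label == "good" ~ "mut_good",
        TRUE ~ NA_character_
      ))
    sub <- function(contrast) {
      keep <- !is.na(smp$group) & smp$group %in% contrast
      de_analysis(counts$counts[, keep, drop = FALSE], smp$group[keep],
                  contrast = contrast)
    }
    list(poor_wt = sub(c("mut_poor", "wt_pool")),
         good_wt = sub(c("mut_good", "wt_pool")),
         poor_good = sub(c("mut_poor", "mut_good")))
  })
  purrr::iwalk(de, \(tab, nm) readr::write_tsv(
    as_tibble(tab), file.path(out_dir, sprintf("de_%s.tsv", nm)),
    progress = FALSE))

  sets <- stage("partition", partition_gene_sets(
    de$poor_wt, de$good_wt, de$poor_good, fdr = fdr))
  purrr::iwalk(unclass(sets), \(genes, nm) write_gene_list(
    genes, file.path(out_dir, "sets", paste0(nm, ".txt"))))

  series <- stage("series", simulate_allelic_series(sets, config, grid = grid))
  write_series(series, file.path(out_dir, "series"))

  profile <- stage("progression", {
    nonempty <- names(which(lengths(unclass(sets)) > 0))
    if (!length(nonempty)) {
      inform("[progression] all sets empty; skipping profile.")
      NULL
    } else {
      progression_profile(sets, series, n_top = n_top)
    }
  })
  if (!is.null(profile)) {
    readr::write_tsv(profile$presence, file.path(out_dir, "presence.tsv"),
                     progress = FALSE)
    jsonlite::write_json(profile$monotonicity,
                         file.path(out_dir, "monotonicity.json"),
                         dataframe = "rows", digits = NA, pretty = TRUE)
  }

  report <- list(
    pipeline_version = pipeline_version(),
    seed = config$seed,
    parameters = list(k = k, fdr = fdr, n_top = n_top, p_flag = p_flag,
                      q_flag = q_flag, screen_timepoint = screen_tp),
    cohort = list(n_wt = config$n_wt, n_mut = config$n_mut,
                  n_genes = config$n_genes,
                  n_signature = config$n_signature),
    labels = as.list(table(labels$genotype, labels$label) |>
                       as.data.frame() |>
                       mutate(key = paste(.data$Var1, .data$Var2, sep = "_")) |>
                       (\(d) setNames(as.list(d$Freq), d$key))()),
    screen = as.list(glance(screen)),
    degs = purrr::map(de, \(tab) as.list(glance(tab, fdr = fdr))),
    set_sizes = lapply(unclass(sets), length),
    presence = if (!is.null(profile)) profile$presence else NULL
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, dataframe = "rows", digits = NA,
                       pretty = TRUE, null = "null")
  writeLines(c(
    sprintf("phenoscreen run report (version %s)", report$pipeline_version),
    sprintf("generated: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("seed: %d | cohort: %d wt + %d mut | genes: %d (%d signature)",
            config$seed, config$n_wt, config$n_mut, config$n_genes,
            config$n_signature),
    sprintf("screen: %d pairs, %d tilde (p < %.3g), %d star (q < %.3g)",
            report$screen$n_pairs, report$screen$n_tilde, p_flag,
            report$screen$n_star, q_flag),
    sprintf("DEGs (q < %.3g): %s", fdr,
            paste(sprintf("%s %d up / %d down", names(report$degs),
                          purrr::map_int(report$degs, "n_up"),
                          purrr::map_int(report$degs, "n_down")),
                  collapse = "; ")),
    sprintf("sets: %s",
            paste(sprintf("%s=%d", names(report$set_sizes),
                          unlist(report$set_sizes)), collapse = ", "))
  ), file.path(out_dir, "report.txt"))

  invisible(list(cohort = cohort, zscores = zs, labels = labels,
                 counts = counts, screen = screen, de = de, sets = sets,
                 series = series, profile = profile, report = report,
                 out_dir = out_dir))
}
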