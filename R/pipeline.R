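#' Configuration for a full pipeline run
#'
#' @param genome,gff3,samples Paths to the genome FASTA, GFF3 annotation,
#'   and sample sheet TSV; all must exist.
#' @param outdir Output directory for tables and the summary.
#' @param params [calling_params()].
#' @param ext_bp,fallback_bp 3' UTR extension lengths (see
#'   [read_annotation()]).
#' @param alpha Adjusted-p significance threshold used throughout.
#' @param min_total Expression floor for specific/inducible event calls.
#' @param min_mapq Mapping-quality cutoff for SAM/BAM tag input.
#' @param tag_format Tag file format (`NULL` = by extension).
#' @param seed Seed for the run's stochastic components (Monte-Carlo
#'   chi-square fallback).
#' @return A validated `run_config` list.
#' @export
run_config <- function(genome, gff3, samples, outdir = NULL,
                       params = calling_params(), ext_bp = 200L,
                       fallback_bp = 218L, alpha = 0.05, min_total = 10L,
                       min_mapq = 10L, tag_format = NULL, seed = 1L) {
  cfg <- as.list(environment())
  for (f in c("genome", "gff3", "samples")) {
    if (!file.exists(cfg[[f]])) {
      abort(paste0("config error: ", f, " file does not exist: ", cfg[[f]]))
    }
  }
  structure(cfg, class = "run_config")
}

#' Run the full APA pipeline
#'
#' Executes the fixed stage order -- PAC calling (internal-priming filter,
#' clustering, assignment, support filter), PAC- and gene-level
#' differential expression, 3' UTR dynamics, APA event calls -- and
#' assembles the report tables: PAC/gene totals, APA-gene fraction overall
#' and per condition (per-condition fractions re-call PACs on each
#' condition's samples alone, with identical parameters), PAC region
#' distribution, DE counts with gene-set overlaps, 3' UTR class and
#' expression-quadrant counts, and event counts. When `config$outdir` is
#' set, every table is written as TSV together with a human-readable
#' summary and the echoed configuration. A failing stage aborts with the
#' stage named; tables written before the failure are retained.
#'
#' @param config A [run_config()].
#' @return An `apa_run` object with elements `pacs`, `matrix`, `de_pac`,
#'   `de_gene`, `utr`, `events`, and `report` (a named list of tibbles).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)),
            parent = e)
    })
  }

  genome <- stage("io", read_genome(config$genome))
  gm <- stage("io", read_annotation(config$gff3, config$ext_bp,
                                    config$fallback_bp))
  design <- stage("io", read_sample_sheet(config$samples))
  tags <- stage("io", load_tags(design, format = config$tag_format,
                                min_mapq = config$min_mapq))

  flt <- stage("callpac", filter_internal_priming(tags, genome, config$params))
  pacs <- stage("callpac", {
    flt$kept |>
      cluster_tags(config$params, strict = TRUE) |>
      assign_pacs(gm) |>
      filter_min_support(config$params)
  })

  mat <- stage("de", pac_matrix(pacs, design))
  de_pac <- stage("de", nb_test(mat, alpha = config$alpha))
  gene_mat <- stage("de", gene_expression(mat))
  de_gene <- stage("de", nb_test(gene_mat, alpha = config$alpha))
  utr <- stage("utr", utr_dynamics(pacs, design, alpha = config$alpha))
  classified <- stage("utr", classify_genes(utr, de_gene))
  events <- stage("events", call_apa_events(mat, de_pac,
                                            alpha = config$alpha,
                                            min_total = config$min_total))

  report <- stage("report", build_report(pacs, flt, design, de_pac, de_gene,
                                         utr, classified, events, gm, config))
  run <- structure(list(config = config, pacs = pacs, matrix = mat,
                        de_pac = de_pac, de_gene = de_gene, utr = utr,
                        classified = classified, events = events,
                        report = report),
                   class = "apa_run")
  if (!is.null(config$outdir)) write_report(run, config$outdir)
  run
}

build_report <- function(pacs, flt, design, de_pac, de_gene, utr, classified,
                         events, gm, config) {
  apa_tab <- apa_gene_table(pacs)

  # per-condition APA-gene ratio: re-call PACs on each condition's samples
  # alone with the same parameters
  per_cond <- purrr::map(c("CK", "ST"), function(cond) {
    sub <- flt$kept |>
      filter(.data$sample_id %in% design$sample_id[design$condition == cond])
    attr(sub, "ip_filtered") <- TRUE
    sub_apa <- sub |>
      cluster_tags(config$params, strict = TRUE) |>
      assign_pacs(gm) |>
      filter_min_support(config$params) |>
      apa_gene_table()
    tibble(condition = cond, n_genes = nrow(sub_apa),
           n_apa_genes = sum(sub_apa$is_apa),
           apa_fraction = if (nrow(sub_apa)) mean(sub_apa$is_apa) else NA_real_)
  }) |> purrr::list_rbind()

  de_pac_tbl <- tidy(de_pac); de_gene_tbl <- tidy(de_gene)
  de_pac_genes <- unique(de_pac_tbl$gene_id[de_pac_tbl$is_de &
                                              !is.na(de_pac_tbl$gene_id)])
  de_genes <- de_gene_tbl$unit_id[de_gene_tbl$is_de]
  de_apa_genes <- intersect(de_pac_genes,
                            apa_tab$gene_id[apa_tab$n_pacs > 1])

  list(
    totals = tibble(
      n_tags_kept = nrow(flt$kept), n_tags_removed_ip = nrow(flt$removed),
      n_pacs = nrow(pacs), n_genes_with_pac = nrow(apa_tab),
      n_apa_genes = sum(apa_tab$is_apa),
      apa_fraction = if (nrow(apa_tab)) sum(apa_tab$is_apa) / nrow(apa_tab)
                     else NA_real_),
    apa_by_condition = per_cond,
    region_distribution = region_distribution(pacs),
    de_counts = tibble(
      n_de_pacs = sum(de_pac_tbl$is_de, na.rm = TRUE),
      n_de_pac_genes = length(de_pac_genes),
      n_de_genes = length(de_genes),
      n_de_apa_genes = length(de_apa_genes)),
    de_overlaps = overlap_sets(de_genes, de_pac_genes, de_apa_genes),
    utr_classes = glance(utr),
    utr_quadrants = classified$quadrants,
    event_counts = tibble(
      n_switching_genes = nrow(events$switching$genes),
      n_st_specific_pacs = nrow(events$specific_st),
      n_st_specific_genes = length(unique(events$specific_st$gene_id[
        !is.na(events$specific_st$gene_id)])),
      n_ck_specific_pacs = nrow(events$specific_ck),
      n_inducible_genes = nrow(events$inducible))
  )
}

write_report <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_pacs(run$pacs, file.path(outdir, "pacs.bed"),
             file.path(outdir, "pacs.tsv"))
  readr::write_tsv(tidy(run$de_pac), file.path(outdir, "de_pac.tsv"))
  readr::write_tsv(tidy(run$de_gene), file.path(outdir, "de_gene.tsv"))
  readr::write_tsv(run$classified$genes, file.path(outdir, "utr_dynamics.tsv"))
  readr::write_tsv(run$events$switching$genes,
                   file.path(outdir, "events_switching.tsv"))
  readr::write_tsv(run$events$specific_st,
                   file.path(outdir, "events_st_specific.tsv"))
  readr::write_tsv(run$events$inducible,
                   file.path(outdir, "events_inducible.tsv"))
  for (nm in names(run$report)) {
    readr::write_tsv(run$report[[nm]], file.path(outdir, paste0(nm, ".tsv")))
  }
  cfg <- run$config
  cfg_lines <- c(
    paste0("genome\t", cfg$genome), paste0("gff3\t", cfg$gff3),
    paste0("samples\t", cfg$samples), paste0("alpha\t", cfg$alpha),
    paste0("min_total\t", cfg$min_total), paste0("seed\t", cfg$seed),
    paste0("ext_bp\t", cfg$ext_bp), paste0("fallback_bp\t", cfg$fallback_bp),
    paste0(names(unclass(cfg$params)), "\t", unlist(cfg$params)))
  writeLines(cfg_lines, file.path(outdir, "config_echo.tsv"))
  writeLines(summary_lines(run), file.path(outdir, "summary.txt"))
  invisible(outdir)
}

summary_lines <- function(run) {
  r <- run$report
  c(
    "APA pipeline summary",
    "====================",
    sprintf("Tags kept / removed (internal priming): %d / %d",
            r$totals$n_tags_kept, r$totals$n_tags_removed_ip),
    sprintf("PACs: %d in %d genes; APA genes: %d (%.1f%%)",
            r$totals$n_pacs, r$totals$n_genes_with_pac,
            r$totals$n_apa_genes, 100 * r$totals$apa_fraction),
    sprintf("APA fraction by condition: CK %.1f%%, ST %.1f%%",
            100 * r$apa_by_condition$apa_fraction[1],
            100 * r$apa_by_condition$apa_fraction[2]),
    sprintf("DE-PACs: %d in %d genes; DE genes: %d; DE-APA genes: %d",
            r$de_counts$n_de_pacs, r$de_counts$n_de_pac_genes,
            r$de_counts$n_de_genes, r$de_counts$n_de_apa_genes),
    sprintf("3' UTR classes: %d lengthen, %d shorten, %d unchanged",
            r$utr_classes$n_lengthen, r$utr_classes$n_shorten,
            r$utr_classes$n_unchanged),
    sprintf("Events: %d switching genes, %d ST-specific PACs (%d genes), %d inducible-APA genes",
            r$event_counts$n_switching_genes, r$event_counts$n_st_specific_pacs,
            r$event_counts$n_st_specific_genes, r$event_counts$n_inducible_genes)
  )
}

#' @export
print.apa_run <- function(x, ...) {
  cat(paste(summary_lines(x), collapse = "\n"), "\n")
  invisible(x)
}
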