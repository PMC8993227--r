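#' Compare pipeline calls against simulation ground truth
#'
#' Matches called PAC summits to planted cleavage sites (a call is a true
#' positive when its summit lies within `tolerance_nt` of a genuine
#' planted site on the same chromosome and strand) and scores event calls
#' per planted class.
#'
#' @param pacs Assigned, filtered PAC tibble from the pipeline.
#' @param sim An `apa_sim` object from [simulate_apa_experiment()].
#' @param utr Optional `utr_dynamics` object for class recovery.
#' @param events Optional `apa_events` object from [call_apa_events()].
#' @param tolerance_nt Matching tolerance in nt (default 24, the cluster
#'   window).
#' @return A `truth_summary` list:
#'   \describe{
#'     \item{sites}{one-row tibble: called/true site counts, PAC-level
#'       `precision` and `recall`, and the mean absolute weighted-length
#'       error (nt) over eligible genes when `utr` is given.}
#'     \item{apa}{planted vs recovered APA-gene fraction.}
#'     \item{events}{per planted class: `planted`, `recovered` (planted
#'       genes recovered with the matching call), `recall`, and
#'       `false_calls` (calls on genes not planted with that class;
#'       inducible false calls exclude ST-specific genes, whose extra
#'       ST-only PAC makes them genuinely inducible as well).}
#'   }
#' @export
truth_compare <- function(pacs, sim, utr = NULL, events = NULL,
                          tolerance_nt = 24L) {
  stopifnot(inherits(sim, "apa_sim"))
  true_sites <- sim$truth_sites |> filter(!.data$is_artifact)
  called <- pacs |> select("pac_id", "chrom", "strand", "summit")

  matched <- match_sites(called, true_sites, tolerance_nt)
  precision <- if (nrow(called)) mean(matched$call_hit) else NA_real_
  recall <- if (nrow(true_sites)) mean(matched$site_hit) else NA_real_

  apa_rec <- apa_gene_table(pacs)
  n_genes <- nrow(sim$truth_genes)
  apa <- tibble(
    planted_fraction = mean(sim$truth_genes$event != "SINGLE"),
    recovered_fraction = sum(apa_rec$is_apa) / n_genes,
    n_genes = n_genes,
    n_genes_detected = nrow(apa_rec)
  )

  ev <- NULL
  truth_ev <- sim$truth_genes |> select("gene_id", "event")
  if (!is.null(utr)) {
    cls <- tidy(utr) |> select("gene_id", "class")
    ev <- bind_rows(ev, purrr::map(
      c(LENGTHEN = "LENGTHEN", SHORTEN = "SHORTEN"), function(lab) {
        planted_g <- truth_ev$gene_id[truth_ev$event == lab]
        called_g <- cls$gene_id[cls$class == lab]
        tibble(planted = length(planted_g),
               recovered = length(intersect(planted_g, called_g)),
               false_calls = length(setdiff(called_g, planted_g)))
      }) |> purrr::list_rbind(names_to = "class"))
  }
  if (!is.null(events)) {
    # genes with no planted expression change at any PAC: a switching call
    # on one of these is unambiguously false (a strong planted usage shift,
    # e.g. lengthening, genuinely contains opposite-signed PAC changes and
    # can satisfy the switching definition)
    null_genes <- sim$truth_sites |>
      filter(!.data$is_artifact) |>
      group_by(.data$gene_id) |>
      summarise(is_null = all(.data$mu_ck == .data$mu_st), .groups = "drop") |>
      filter(.data$is_null) |>
      pull("gene_id")
    sw_called <- events$switching$genes$gene_id
    sw_planted <- truth_ev$gene_id[truth_ev$event == "SWITCH"]
    ind_called <- events$inducible$gene_id
    ind_planted <- truth_ev$gene_id[truth_ev$event == "INDUCIBLE"]
    spe_planted_genes <- truth_ev$gene_id[truth_ev$event == "SPECIFIC"]

    # a planted ST-specific site is recovered when an ST-specific PAC call
    # sits within tolerance of it
    spe_sites <- sim$truth_sites |>
      filter(.data$st_only, .data$gene_id %in% spe_planted_genes)
    spe_calls <- pacs |>
      filter(.data$pac_id %in% events$specific_st$pac_id) |>
      select("pac_id", "chrom", "strand", "summit")
    spe_match <- match_sites(spe_calls, spe_sites, tolerance_nt)
    # inducible genes' ST-only PACs are genuinely ST-specific too: false
    # specific calls are those matching no planted ST-only site at all
    spe_all <- sim$truth_sites |> filter(.data$st_only)
    spe_match_all <- match_sites(spe_calls, spe_all, tolerance_nt)

    ev <- bind_rows(ev, tibble(
      class = c("SWITCH", "SPECIFIC_PAC", "INDUCIBLE"),
      planted = c(length(sw_planted), nrow(spe_sites), length(ind_planted)),
      recovered = c(length(intersect(sw_called, sw_planted)),
                    sum(spe_match$site_hit),
                    length(intersect(ind_called, ind_planted))),
      false_calls = c(length(intersect(sw_called, null_genes)),
                      sum(!spe_match_all$call_hit),
                      length(setdiff(ind_called,
                                     c(ind_planted, spe_planted_genes))))))
  }
  if (!is.null(ev)) {
    ev <- ev |> mutate(recall = ifelse(.data$planted > 0,
                                       .data$recovered / .data$planted, NA))
  }

  wul_err <- NA_real_
  if (!is.null(utr)) {
    truth_wul <- true_utr_lengths(sim)
    obs <- tidy(utr) |> inner_join(truth_wul, by = "gene_id")
    if (nrow(obs)) {
      wul_err <- mean(abs(obs$wul_ck - obs$true_wul_ck), na.rm = TRUE)
    }
  }

  structure(list(
    sites = tibble(n_called = nrow(called), n_true = nrow(true_sites),
                   precision = precision, recall = recall,
                   mean_wul_error_nt = wul_err),
    apa = apa, events = ev
  ), class = "truth_summary")
}

# symmetric tolerance matching on (chrom, strand)
match_sites <- function(called, true_sites, tol) {
  if (nrow(called) == 0 || nrow(true_sites) == 0) {
    return(list(call_hit = logical(nrow(called)),
                site_hit = logical(nrow(true_sites))))
  }
  call_gr <- GenomicRanges::GRanges(
    called$chrom,
    IRanges::IRanges(called$summit + 1L - tol, called$summit + 1L + tol),
    strand = called$strand)
  site_gr <- GenomicRanges::GRanges(
    true_sites$chrom, IRanges::IRanges(true_sites$pos + 1L, width = 1L),
    strand = true_sites$strand)
  hits <- GenomicRanges::findOverlaps(call_gr, site_gr, ignore.strand = FALSE)
  list(
    call_hit = seq_len(nrow(called)) %in% S4Vectors::queryHits(hits),
    site_hit = seq_len(nrow(true_sites)) %in% S4Vectors::subjectHits(hits)
  )
}

# expected condition-level weighted 3' UTR length per eligible planted gene
true_utr_lengths <- function(sim) {
  sim$truth_sites |>
    filter(!.data$is_artifact, .data$region == "UTR3") |>
    group_by(.data$gene_id) |>
    filter(n() >= 2, sum(.data$mu_ck) > 0, sum(.data$mu_st) > 0) |>
    summarise(
      true_wul_ck = sum(.data$utr_length * .data$mu_ck) / sum(.data$mu_ck),
      true_wul_st = sum(.data$utr_length * .data$mu_st) / sum(.data$mu_st),
      .groups = "drop")
}

#' @export
print.truth_summary <- function(x, ...) {
  cat("<truth_summary> PAC precision ", round(x$sites$precision, 3),
      ", recall ", round(x$sites$recall, 3),
      "; APA fraction planted ", round(x$apa$planted_fraction, 3),
      " vs recovered ", round(x$apa$recovered_fraction, 3), "\n", sep = "")
  if (!is.null(x$events)) print(x$events)
  invisible(x)
}
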