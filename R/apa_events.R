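#' Call APA switching genes
#'
#' A gene is an APA switching gene when, between conditions, at least one
#' of its PACs is significantly upregulated and another significantly
#' downregulated (adjusted p below `alpha` with opposite-signed log2 fold
#' changes). All up/down PAC pairs are recorded.
#'
#' @param de_pac An `apa_de` object at PAC level (or its `tidy()` tibble
#'   with `unit_id`, `gene_id`, `log2fc`, `padj`).
#' @param alpha Significance threshold (default 0.05).
#' @return List with `genes` (tibble `gene_id`, `n_up`, `n_down`) and
#'   `pairs` (tibble `gene_id`, `up_pac`, `down_pac`).
#' @export
call_switching <- function(de_pac, alpha = 0.05) {
  de <- if (inherits(de_pac, "apa_de")) tidy(de_pac) else de_pac
  sig <- de |>
    filter(!is.na(.data$gene_id), !is.na(.data$padj), .data$padj < alpha)
  per_gene <- sig |>
    group_by(.data$gene_id) |>
    summarise(n_up = sum(.data$log2fc > 0), n_down = sum(.data$log2fc < 0),
              .groups = "drop") |>
    filter(.data$n_up >= 1, .data$n_down >= 1)
  pairs <- sig |>
    filter(.data$gene_id %in% per_gene$gene_id) |>
    group_by(.data$gene_id) |>
    group_map(function(g, key) {
      tidyr::expand_grid(up_pac = g$unit_id[g$log2fc > 0],
                         down_pac = g$unit_id[g$log2fc < 0]) |>
        mutate(gene_id = key$gene_id, .before = 1)
    }) |>
    purrr::list_rbind()
  if (nrow(per_gene) == 0) {
    pairs <- tibble(gene_id = character(), up_pac = character(),
                    down_pac = character())
  }
  list(genes = per_gene, pairs = pairs)
}

#' Call condition-specific PACs
#'
#' A PAC is specific to a condition when its raw count is zero in *every*
#' replicate of the other condition (strict-zero rule; relax with
#' `max_other`) and its total in the named condition reaches `min_total`
#' (default 10, mirroring the PAC support filter).
#'
#' @param mat A PAC-level `pac_matrix`.
#' @param condition `"ST"` (default) or `"CK"`: the condition the PAC must
#'   be expressed in.
#' @param min_total Minimum raw total in the named condition.
#' @param max_other Maximum tolerated raw total in the other condition
#'   (default 0, the strict-zero rule).
#' @return Tibble of specific PACs: `pac_id`, `gene_id`, `region`,
#'   `total_in`, `total_other`.
#' @export
call_specific_pacs <- function(mat, condition = "ST", min_total = 10L,
                               max_other = 0L) {
  stopifnot(inherits(mat, "pac_matrix"), condition %in% c("CK", "ST"))
  sel <- mat$design$condition == condition
  tot_in <- rowSums(mat$counts[, sel, drop = FALSE])
  tot_other <- rowSums(mat$counts[, !sel, drop = FALSE])
  keep <- tot_other <= max_other & tot_in >= min_total
  mat$meta[keep, ] |>
    rename(pac_id = "unit_id") |>
    mutate(condition = condition, total_in = tot_in[keep],
           total_other = tot_other[keep])
}

#' Call condition-inducible APA genes
#'
#' A gene shows treatment-inducible APA when it expresses at most one PAC
#' under CK but two or more under ST, where a PAC counts as expressed in a
#' condition when its raw total there reaches `min_total` (and is nonzero:
#' at `min_total = 0` every PAC with any count is expressed).
#'
#' @param mat A PAC-level `pac_matrix`.
#' @param min_total Expression floor per condition (default 10).
#' @return Tibble `gene_id`, `n_expressed_ck`, `n_expressed_st`.
#' @export
call_inducible_apa <- function(mat, min_total = 10L) {
  stopifnot(inherits(mat, "pac_matrix"))
  ck <- rowSums(mat$counts[, mat$design$condition == "CK", drop = FALSE])
  st <- rowSums(mat$counts[, mat$design$condition == "ST", drop = FALSE])
  floor_ <- max(min_total, 1L)
  tibble(gene_id = mat$meta$gene_id, region = mat$meta$region,
         expr_ck = ck >= floor_, expr_st = st >= floor_) |>
    filter(!is.na(.data$gene_id), .data$region != "INTERGENIC" | is.na(.data$region)) |>
    group_by(.data$gene_id) |>
    summarise(n_expressed_ck = sum(.data$expr_ck),
              n_expressed_st = sum(.data$expr_st), .groups = "drop") |>
    filter(.data$n_expressed_ck <= 1, .data$n_expressed_st >= 2)
}

#' Overlap of two gene sets through a homolog map
#'
#' Homology is input data (a user-supplied many-to-many id pairing), not
#' computed. Reports how many genes in each set have at least one homolog
#' in the other set, and the symmetric intersection: the number of homolog
#' pairs with both members present. Ids absent from the map count as
#' non-overlapping.
#'
#' @param set_a,set_b Character vectors of gene ids (from the two runs or
#'   species).
#' @param homolog_map Tibble/data frame with columns `id_a`, `id_b`.
#' @return One-row tibble: `n_a`, `n_b`, `n_a_with_homolog_in_b`,
#'   `n_b_with_homolog_in_a`, `n_pairs_shared`, `n_a_unmapped`,
#'   `n_b_unmapped`.
#' @export
homolog_overlap <- function(set_a, set_b, homolog_map) {
  stopifnot(all(c("id_a", "id_b") %in% names(homolog_map)))
  set_a <- unique(set_a); set_b <- unique(set_b)
  map <- as_tibble(homolog_map)
  hits <- map |> filter(.data$id_a %in% set_a, .data$id_b %in% set_b)
  unmapped_a <- setdiff(set_a, map$id_a)
  unmapped_b <- setdiff(set_b, map$id_b)
  if (length(unmapped_a) || length(unmapped_b)) {
    inform(paste0(length(unmapped_a), " set_a and ", length(unmapped_b),
                  " set_b gene(s) absent from the homolog map"))
  }
  tibble(n_a = length(set_a), n_b = length(set_b),
         n_a_with_homolog_in_b = length(unique(hits$id_a)),
         n_b_with_homolog_in_a = length(unique(hits$id_b)),
         n_pairs_shared = nrow(distinct(hits)),
         n_a_unmapped = length(unmapped_a),
         n_b_unmapped = length(unmapped_b))
}

#' Call all APA events in one step
#'
#' @param mat PAC-level `pac_matrix`.
#' @param de_pac PAC-level `apa_de` from [nb_test()].
#' @param alpha Significance threshold for switching.
#' @param min_total Expression floor for specific/inducible calls.
#' @return An `apa_events` list: `switching`, `specific_st`, `specific_ck`,
#'   `inducible`.
#' @export
call_apa_events <- function(mat, de_pac, alpha = 0.05, min_total = 10L) {
  structure(list(
    switching = call_switching(de_pac, alpha = alpha),
    specific_st = call_specific_pacs(mat, "ST", min_total = min_total),
    specific_ck = call_specific_pacs(mat, "CK", min_total = min_total),
    inducible = call_inducible_apa(mat, min_total = min_total)
  ), class = "apa_events")
}

#' @export
print.apa_events <- function(x, ...) {
  cat("<apa_events> ", nrow(x$switching$genes), " switching genes, ",
      nrow(x$specific_st), " ST-specific PACs, ",
      nrow(x$specific_ck), " CK-specific PACs, ",
      nrow(x$inducible), " inducible-APA genes\n", sep = "")
  invisible(x)
}
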