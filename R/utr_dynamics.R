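#' Usage-weighted 3' UTR length
#'
#' The weighted 3' UTR length of a gene is the usage-share-weighted mean of
#' its per-PAC 3' UTR lengths: `sum(usage_i * length_i)` with usage shares
#' summing to 1.
#'
#' @param pac_lengths Per-PAC 3' UTR lengths in nt (positive).
#' @param usage Per-PAC usage shares; non-negative, summing to 1 (within
#'   1e-9).
#' @return The weighted length in nt.
#' @export
weighted_utr_length <- function(pac_lengths, usage) {
  stopifnot(length(pac_lengths) == length(usage))
  if (any(usage < 0) || abs(sum(usage) - 1) > 1e-9) {
    abort("usage shares must be non-negative and sum to 1")
  }
  if (any(pac_lengths <= 0)) abort("pac_lengths must be positive")
  sum(usage * pac_lengths)
}

#' Direction statistic for 3' UTR length change
#'
#' Per sample, the weighted 3' UTR length is computed from that sample's
#' PAC counts; the statistic `r` is the Pearson correlation across samples
#' between the condition indicator (CK = 0, ST = 1) and the per-sample
#' weighted length. `r > 0` indicates a 3' UTR lengthening tendency under
#' ST, `r < 0` shortening. Samples with zero total count for the gene are
#' dropped; degenerate cases (zero variance in lengths or fewer than one
#' sample per condition remaining) return `r = 0` with `degenerate = TRUE`.
#'
#' @param counts Matrix of per-PAC (rows) by per-sample (columns) counts
#'   for one gene's 3' UTR PACs.
#' @param pac_lengths Per-PAC 3' UTR lengths (row order of `counts`).
#' @param condition Character vector (`"CK"`/`"ST"`) per column.
#' @return List with `r` and `degenerate`.
#' @export
direction_statistic <- function(counts, pac_lengths, condition) {
  counts <- as.matrix(counts)
  tot <- colSums(counts)
  use <- tot > 0
  if (sum(use & condition == "CK") < 1 || sum(use & condition == "ST") < 1) {
    return(list(r = 0, degenerate = TRUE))
  }
  wul <- colSums(counts[, use, drop = FALSE] * pac_lengths) / tot[use]
  ind <- as.numeric(condition[use] == "ST")
  if (stats::sd(wul) == 0 || stats::sd(ind) == 0) {
    return(list(r = 0, degenerate = TRUE))
  }
  list(r = cor(ind, wul), degenerate = FALSE)
}

#' Chi-square test for a 3' UTR usage shift
#'
#' Classical Pearson chi-square on the 2 x k contingency table of pooled
#' per-condition PAC totals (conditions as rows, PACs as columns). When any
#' expected cell is below 5 the asymptotic p value is unreliable and a
#' Monte-Carlo p value (conditional on the margins, `mc_b` replicates,
#' driven by the session RNG) is used instead; the statistic itself is
#' unchanged.
#'
#' @param gene_counts_ck,gene_counts_st Per-PAC total counts in each
#'   condition (same PAC order; k >= 2 PACs, each PAC nonzero in at least
#'   one condition).
#' @param mc_b Monte-Carlo replicates for the small-count fallback.
#' @return List with `statistic`, `df`, `p_value`, `monte_carlo`.
#' @export
chi_square_shift <- function(gene_counts_ck, gene_counts_st, mc_b = 2000) {
  k <- length(gene_counts_ck)
  if (k < 2 || length(gene_counts_st) != k) {
    abort("chi_square_shift needs a 2 x k table with k >= 2 PACs")
  }
  tbl <- rbind(CK = gene_counts_ck, ST = gene_counts_st)
  if (any(colSums(tbl) == 0)) abort("every PAC must have a nonzero total")
  expected <- outer(rowSums(tbl), colSums(tbl)) / sum(tbl)
  if (all(expected >= 5)) {
    ct <- suppressWarnings(chisq.test(tbl, correct = FALSE))
    list(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = unname(ct$p.value), monte_carlo = FALSE)
  } else {
    ct <- suppressWarnings(chisq.test(tbl, simulate.p.value = TRUE, B = mc_b))
    list(statistic = unname(ct$statistic), df = k - 1L,
         p_value = unname(ct$p.value), monte_carlo = TRUE)
  }
}

#' Per-gene 3' UTR length dynamics between conditions
#'
#' For every gene with at least two PACs in its 3' UTR (annotated 3' UTR or
#' downstream extension), computes the pooled weighted 3' UTR length per
#' condition, the direction statistic `r`, and the chi-square usage-shift
#' test; chi-square p values are Benjamini-Hochberg adjusted across all
#' eligible genes. Genes whose PAC set differs between conditions keep the
#' union of PACs, with zero counts where a PAC is absent, which keeps the
#' contingency table well-formed. Genes with zero total 3' UTR counts in a
#' condition are flagged and excluded.
#'
#' @param pacs Assigned, filtered PAC tibble (with `utr_length`).
#' @param design Sample sheet tibble.
#' @param alpha Significance threshold on the adjusted chi-square p value.
#' @param mc_b Monte-Carlo replicates for small-count chi-square tables.
#' @return A `utr_dynamics` object; `tidy()` gives the per-gene tibble
#'   (`gene_id`, `n_utr_pacs`, `wul_ck`, `wul_st`, `r`, `degenerate`,
#'   `chi2`, `chi2_p`, `chi2_padj`, `class`), `glance()` the class counts.
#' @export
utr_dynamics <- function(pacs, design, alpha = 0.05, mc_b = 2000) {
  validate_design(design)
  utr <- pacs |>
    filter(.data$region %in% c("UTR3", "EXTENDED_UTR3"), !is.na(.data$gene_id))
  eligible <- utr |> count(.data$gene_id) |> filter(.data$n >= 2)
  utr <- utr |> filter(.data$gene_id %in% eligible$gene_id)

  ck_cols <- paste0("n_", design$sample_id[design$condition == "CK"])
  st_cols <- paste0("n_", design$sample_id[design$condition == "ST"])
  all_cols <- paste0("n_", design$sample_id)

  rows <- utr |>
    group_by(.data$gene_id) |>
    group_map(function(g, key) {
      ck <- rowSums(g[, ck_cols, drop = FALSE])
      st <- rowSums(g[, st_cols, drop = FALSE])
      keep <- ck + st > 0
      if (sum(ck) == 0 || sum(st) == 0 || sum(keep) < 2) {
        return(tibble(gene_id = key$gene_id, n_utr_pacs = nrow(g),
                      wul_ck = NA_real_, wul_st = NA_real_, r = NA_real_,
                      degenerate = TRUE, chi2 = NA_real_, chi2_p = NA_real_))
      }
      lens <- g$utr_length[keep]
      dirs <- direction_statistic(as.matrix(g[keep, all_cols]), lens,
                                  design$condition)
      cs <- chi_square_shift(ck[keep], st[keep], mc_b = mc_b)
      tibble(gene_id = key$gene_id, n_utr_pacs = nrow(g),
             wul_ck = weighted_utr_length(lens, ck[keep] / sum(ck)),
             wul_st = weighted_utr_length(lens, st[keep] / sum(st)),
             r = dirs$r, degenerate = dirs$degenerate,
             chi2 = cs$statistic, chi2_p = cs$p_value)
    }) |>
    purrr::list_rbind()

  if (nrow(rows) == 0) {
    rows <- tibble(gene_id = character(), n_utr_pacs = integer(),
                   wul_ck = double(), wul_st = double(), r = double(),
                   degenerate = logical(), chi2 = double(), chi2_p = double())
  }
  rows <- rows |>
    mutate(chi2_padj = p.adjust(.data$chi2_p, method = "BH"),
           class = case_when(
             is.na(.data$chi2_padj) ~ "UNCHANGED",
             .data$chi2_padj < alpha & .data$r > 0 ~ "LENGTHEN",
             .data$chi2_padj < alpha & .data$r < 0 ~ "SHORTEN",
             TRUE ~ "UNCHANGED"))
  structure(list(genes = rows, alpha = alpha), class = "utr_dynamics")
}

#' @export
print.utr_dynamics <- function(x, ...) {
  n <- table(factor(x$genes$class, c("LENGTHEN", "SHORTEN", "UNCHANGED")))
  cat("<utr_dynamics> ", nrow(x$genes), " eligible genes: ",
      n[["LENGTHEN"]], " lengthen, ", n[["SHORTEN"]], " shorten, ",
      n[["UNCHANGED"]], " unchanged (padj < ", x$alpha, ")\n", sep = "")
  invisible(x)
}

#' @rdname utr_dynamics
#' @param x A `utr_dynamics` object.
#' @param ... Unused.
#' @method tidy utr_dynamics
#' @export
tidy.utr_dynamics <- function(x, ...) x$genes

#' @rdname utr_dynamics
#' @method glance utr_dynamics
#' @export
glance.utr_dynamics <- function(x, ...) {
  tibble(n_eligible = nrow(x$genes),
         n_lengthen = sum(x$genes$class == "LENGTHEN"),
         n_shorten = sum(x$genes$class == "SHORTEN"),
         n_unchanged = sum(x$genes$class == "UNCHANGED"),
         alpha = x$alpha)
}

#' Join 3' UTR classes with gene-level expression changes
#'
#' Adds each gene's log2 fold change (gene-level DE) to the length-change
#' table and tabulates the class-by-direction quadrants (for example
#' lengthen-and-up versus lengthen-and-down).
#'
#' @param dynamics A `utr_dynamics` object.
#' @param de_gene An `apa_de` object at gene level (or its `tidy()` tibble).
#' @return List with `genes` (joined per-gene tibble), `class_counts`, and
#'   `quadrants` (class x expression-direction counts for significantly DE
#'   genes).
#' @export
classify_genes <- function(dynamics, de_gene) {
  stopifnot(inherits(dynamics, "utr_dynamics"))
  de <- if (inherits(de_gene, "apa_de")) tidy(de_gene) else de_gene
  joined <- dynamics$genes |>
    left_join(de |> select(gene_id = "unit_id", "log2fc", de_padj = "padj",
                           "is_de"),
              by = "gene_id")
  quadrants <- joined |>
    filter(.data$class != "UNCHANGED", !is.na(.data$is_de), .data$is_de) |>
    mutate(expression = ifelse(.data$log2fc > 0, "UP", "DOWN")) |>
    count(.data$class, .data$expression)
  list(genes = joined,
       class_counts = glance(dynamics),
       quadrants = quadrants)
}
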