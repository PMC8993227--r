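#' Build a PAC-by-sample count matrix with its design
#'
#' @param pacs Assigned PAC tibble (count columns `n_<sample_id>`).
#' @param design Sample sheet tibble (`sample_id`, `condition`,
#'   `replicate`); every sample must have a count column.
#' @return A `pac_matrix`: list with `counts` (integer matrix, units x
#'   samples), `meta` (unit_id, gene_id, region), and `design`.
#' @export
pac_matrix <- function(pacs, design) {
  validate_design(design)
  cols <- paste0("n_", design$sample_id)
  missing <- setdiff(cols, names(pacs))
  if (length(missing)) {
    abort(paste0("no count column for sample(s): ",
                 paste(sub("^n_", "", missing), collapse = ", ")))
  }
  counts <- as.matrix(pacs[, cols])
  dimnames(counts) <- list(pacs$pac_id, design$sample_id)
  meta <- tibble(
    unit_id = pacs$pac_id,
    gene_id = if ("gene_id" %in% names(pacs)) pacs$gene_id else NA_character_,
    region = if ("region" %in% names(pacs)) pacs$region else NA_character_)
  structure(list(counts = counts, meta = meta, design = design),
            class = "pac_matrix")
}

#' @export
print.pac_matrix <- function(x, ...) {
  cat("<pac_matrix> ", nrow(x$counts), " units x ", ncol(x$counts),
      " samples (", sum(x$design$condition == "CK"), " CK, ",
      sum(x$design$condition == "ST"), " ST)\n", sep = "")
  invisible(x)
}

#' Median-of-ratios normalization
#'
#' Size factor of sample j is the median over units of
#' `count[i, j] / geometric_mean_i(count[i, ])`, computed over units with
#' all-positive counts. When no unit is positive in every sample, the
#' geometric mean falls back to the positive entries of each unit and the
#' median is taken over the positive ratios (documented fallback for
#' sparse matrices). Doubling one sample's counts doubles its size factor;
#' scaling the whole matrix rescales the geometric means too and leaves
#' the size factors unchanged, so normalization only removes *relative*
#' depth differences between samples.
#'
#' @param mat A `pac_matrix` or a bare count matrix.
#' @return List with `size_factors` (named, per sample) and `normalized`
#'   (matrix of counts divided by their sample's size factor).
#' @export
normalize_median_of_ratios <- function(mat) {
  counts <- if (inherits(mat, "pac_matrix")) mat$counts else as.matrix(mat)
  if (all(counts == 0)) abort("cannot normalize an all-zero count matrix")
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (any(all_pos)) {
    sub <- counts[all_pos, , drop = FALSE]
    geo <- exp(rowMeans(log(sub)))
    sf <- apply(sub / geo, 2, median)
  } else {
    geo <- exp(apply(counts, 1, function(r) mean(log(r[r > 0]))))
    ratios <- counts / geo
    ratios[counts == 0] <- NA
    sf <- apply(ratios, 2, median, na.rm = TRUE)
  }
  if (any(!is.finite(sf) | sf <= 0)) {
    abort("degenerate size factors; check for samples with all-zero counts")
  }
  list(size_factors = sf, normalized = sweep(counts, 2, sf, "/"))
}

#' Moderated negative-binomial test for differential expression
#'
#' Tests each unit (PAC or gene) for a difference in normalized counts
#' between the ST and CK conditions. Per unit, a pooled method-of-moments
#' NB dispersion is estimated from the within-condition mean and variance
#' of normalized counts, then shrunk toward the trimmed mean dispersion
#' across all units (empirical-Bayes moderation with `prior_df` prior
#' degrees of freedom; information sharing across units is what makes a
#' two-vs-three-replicate design testable). The Wald statistic for
#' `log2fc != 0` is referred to a t distribution with residual + prior
#' degrees of freedom. Units whose moderated dispersion hits the floor
#' (1e-8) are Poisson-like and switch to an exact conditional binomial test
#' of the ST count sum given the total. p values are Benjamini-Hochberg
#' adjusted across all tested units; units with zero counts everywhere are
#' excluded before testing.
#'
#' log2 fold changes are `log2((mean_ST + 0.5) / (mean_CK + 0.5))` on
#' normalized counts (the 0.5 pseudocount keeps fully-off units finite);
#' no shrinkage or independent filtering is applied, so numerical parity
#' with heavier DE engines is not expected.
#'
#' @param mat A `pac_matrix` (from [pac_matrix()] or [gene_expression()]).
#' @param alpha Significance threshold on the adjusted p value
#'   (default 0.05).
#' @param prior_df Prior degrees of freedom for dispersion moderation
#'   (default 10).
#' @return An `apa_de` object; `tidy()` returns the per-unit results
#'   tibble (`unit_id`, `gene_id`, `base_mean`, `log2fc`, `stat`,
#'   `pvalue`, `padj`, `is_de`), `glance()` a one-row summary.
#' @export
nb_test <- function(mat, alpha = 0.05, prior_df = 10) {
  stopifnot(inherits(mat, "pac_matrix"))
  design <- mat$design
  validate_design(design)
  n_per <- table(design$condition)
  if (any(n_per < 2)) abort("need >= 2 replicates per condition for nb_test")

  nonzero <- rowSums(mat$counts) > 0
  counts <- mat$counts[nonzero, , drop = FALSE]
  meta <- mat$meta[nonzero, ]
  nrm <- normalize_median_of_ratios(counts)
  x <- nrm$normalized
  st <- design$condition == "ST"
  n0 <- sum(!st); n1 <- sum(st)

  m0 <- rowMeans(x[, !st, drop = FALSE]); m1 <- rowMeans(x[, st, drop = FALSE])
  v0 <- matrixStats_rowVars(x[, !st, drop = FALSE])
  v1 <- matrixStats_rowVars(x[, st, drop = FALSE])
  a0 <- (v0 - m0) / m0^2; a1 <- (v1 - m1) / m1^2
  disp <- ((n0 - 1) * a0 + (n1 - 1) * a1) / (n0 + n1 - 2)
  disp[!is.finite(disp)] <- 0
  d_resid <- n0 + n1 - 2
  prior <- mean(disp, trim = 0.05)
  disp_mod <- pmax((d_resid * disp + prior_df * prior) / (d_resid + prior_df),
                   1e-8)

  pseudo <- 0.5
  log2fc <- log2((m1 + pseudo) / (m0 + pseudo))
  se <- sqrt((1 / (m0 + pseudo) + disp_mod) / n0 +
             (1 / (m1 + pseudo) + disp_mod) / n1) / log(2)
  stat <- log2fc / se
  pvalue <- 2 * pt(-abs(stat), df = d_resid + prior_df)

  # Poisson-like units: exact conditional binomial test on raw count sums
  at_floor <- disp_mod <= 1e-8
  if (any(at_floor)) {
    s_st <- sum(nrm$size_factors[st]); s_tot <- sum(nrm$size_factors)
    for (i in which(at_floor)) {
      k1 <- sum(counts[i, st]); k <- sum(counts[i, ])
      pvalue[i] <- if (k == 0) 1 else
        binom.test(k1, k, p = s_st / s_tot)$p.value
      stat[i] <- NA_real_
    }
  }

  res <- meta |>
    mutate(base_mean = unname(rowMeans(x)), log2fc = unname(log2fc),
           stat = unname(stat), pvalue = unname(pvalue),
           padj = p.adjust(.data$pvalue, method = "BH")) |>
    mutate(is_de = .data$padj < alpha)

  structure(list(results = res, size_factors = nrm$size_factors,
                 dispersion = tibble(unit_id = meta$unit_id, raw = disp,
                                     moderated = disp_mod),
                 prior_dispersion = prior, alpha = alpha,
                 prior_df = prior_df, n_excluded = sum(!nonzero)),
            class = "apa_de")
}

matrixStats_rowVars <- function(x) {
  m <- rowMeans(x)
  rowSums((x - m)^2) / (ncol(x) - 1)
}

#' @export
print.apa_de <- function(x, ...) {
  cat("<apa_de> ", nrow(x$results), " units tested, ",
      sum(x$results$is_de, na.rm = TRUE), " differential at padj < ",
      x$alpha, "\n", sep = "")
  invisible(x)
}

#' @rdname nb_test
#' @param x An `apa_de` object.
#' @param ... Unused.
#' @method tidy apa_de
#' @export
tidy.apa_de <- function(x, ...) x$results

#' @rdname nb_test
#' @method glance apa_de
#' @export
glance.apa_de <- function(x, ...) {
  tibble(n_units = nrow(x$results), n_de = sum(x$results$is_de, na.rm = TRUE),
         n_excluded = x$n_excluded, alpha = x$alpha,
         prior_dispersion = x$prior_dispersion,
         median_size_factor = median(x$size_factors))
}

#' Aggregate PAC counts to gene-level expression
#'
#' Gene expression is the total count of poly(A) tags located in the gene:
#' per sample, PAC counts are summed over each gene. Intergenic PACs and
#' PACs without a resolved gene are excluded; ambiguous (`AMB`) PACs count
#' for their resolved gene. The result is a gene-level `pac_matrix`, so
#' [nb_test()] applies unchanged.
#'
#' @param mat A PAC-level `pac_matrix`.
#' @return A gene-level `pac_matrix` (unit ids are gene ids).
#' @export
gene_expression <- function(mat) {
  stopifnot(inherits(mat, "pac_matrix"))
  keep <- !is.na(mat$meta$gene_id) & mat$meta$region != "INTERGENIC"
  counts <- mat$counts[keep, , drop = FALSE]
  genes <- mat$meta$gene_id[keep]
  agg <- rowsum(counts, group = genes)
  agg <- agg[order(rownames(agg)), , drop = FALSE]
  structure(list(counts = agg,
                 meta = tibble(unit_id = rownames(agg),
                               gene_id = rownames(agg),
                               region = NA_character_),
                 design = mat$design),
            class = "pac_matrix")
}

#' Overlaps between DE gene sets
#'
#' Pairwise intersections and differences between the differentially
#' expressed gene set, the DE-PAC gene set (genes containing a
#' differential PAC) and the DE-APA gene set (DE-PAC genes with more than
#' one PAC), plus the fraction of DE genes falling in each other set.
#'
#' @param de_genes,de_pac_genes,de_apa_genes Character vectors of gene ids.
#' @return Tibble with one row per set pair: sizes, intersection,
#'   set differences, and `fraction_of_first` = |A intersect B| / |A|.
#' @export
overlap_sets <- function(de_genes, de_pac_genes, de_apa_genes) {
  sets <- list(DE_genes = unique(de_genes),
               DE_PAC_genes = unique(de_pac_genes),
               DE_APA_genes = unique(de_apa_genes))
  pairs <- utils::combn(names(sets), 2, simplify = FALSE)
  purrr::list_rbind(purrr::map(pairs, function(p) {
    a <- sets[[p[1]]]; b <- sets[[p[2]]]
    tibble(set_a = p[1], set_b = p[2],
           n_a = length(a), n_b = length(b),
           n_intersect = length(intersect(a, b)),
           n_a_only = length(setdiff(a, b)),
           n_b_only = length(setdiff(b, a)),
           fraction_of_first = if (length(a)) length(intersect(a, b)) / length(a) else 0)
  }))
}
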