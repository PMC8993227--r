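#' Parameters for poly(A) cluster calling
#'
#' @param cluster_window Maximum gap, in nt, between consecutive tag
#'   positions merged into one poly(A) cluster (single-linkage gap rule;
#'   default 24 nt).
#' @param min_pats Minimum total tag support (summed over all samples) for
#'   a PAC to be kept; clusters with fewer tags are discarded (default 10).
#' @param ip_window Length, in nt, of the genomic window immediately
#'   downstream of a putative cleavage site inspected for internal-priming
#'   evidence (default 10).
#' @param ip_max_a A tag is called an internal-priming artifact when the
#'   downstream window contains at least this many A's on the tag's sense
#'   strand (default 7)...
#' @param ip_run_a ... or when the window begins with a run of at least
#'   this many consecutive A's (default 6).
#' @return A `calling_params` list.
#' @export
calling_params <- function(cluster_window = 24L, min_pats = 10L,
                           ip_window = 10L, ip_max_a = 7L, ip_run_a = 6L) {
  p <- list(cluster_window = as.integer(cluster_window),
            min_pats = as.integer(min_pats),
            ip_window = as.integer(ip_window),
            ip_max_a = as.integer(ip_max_a),
            ip_run_a = as.integer(ip_run_a))
  if (any(vapply(p, function(x) is.na(x) || x <= 0, logical(1)))) {
    abort("all calling parameters must be positive integers")
  }
  structure(p, class = "calling_params")
}

#' Remove internal-priming artifacts
#'
#' In oligo(dT)-primed 3' end libraries, the primer can anneal to a genomic
#' A-rich tract instead of a true poly(A) tail, creating a false cleavage
#' signal. A tag is removed when the `ip_window`-nt genomic window
#' immediately downstream of its cleavage position, read in transcriptional
#' orientation on the tag's sense strand, contains `>= ip_max_a` A's or
#' begins with a run of `>= ip_run_a` consecutive A's. Windows truncated by
#' a chromosome end use only the available bases.
#'
#' @param tags Tag tibble from [read_tags()]/[load_tags()].
#' @param genome `DNAStringSet` from [read_genome()]; must cover every tag
#'   chromosome.
#' @param params [calling_params()].
#' @return A list with tibbles `kept` and `removed` (a disjoint partition
#'   of the input). `kept` is flagged so [cluster_tags()] in strict mode
#'   accepts it.
#' @export
filter_internal_priming <- function(tags, genome, params = calling_params()) {
  missing_chr <- setdiff(unique(tags$chrom), names(genome))
  if (length(missing_chr)) {
    abort(paste0("chromosome absent from genome: ",
                 paste(missing_chr, collapse = ", ")))
  }
  if (nrow(tags) == 0) {
    kept <- tags
    attr(kept, "ip_filtered") <- TRUE
    return(list(kept = kept, removed = tags))
  }
  win <- downstream_windows(tags, genome, params$ip_window)
  n_a <- stringr::str_count(win, "A")
  run_a <- nchar(stringr::str_extract(win, "^A*"))
  artifact <- n_a >= params$ip_max_a | run_a >= params$ip_run_a
  kept <- tags[!artifact, , drop = FALSE]
  removed <- tags[artifact, , drop = FALSE]
  attr(kept, "ip_filtered") <- TRUE
  inform(paste0("internal-priming filter: kept ", nrow(kept),
                ", removed ", nrow(removed), " tags"))
  list(kept = kept, removed = removed)
}

# sense-strand sequence of the w-nt window downstream of each cleavage pos;
# vectorised per chromosome via substring on the raw sequence
downstream_windows <- function(tags, genome, w) {
  out <- character(nrow(tags))
  for (chr in unique(tags$chrom)) {
    idx <- which(tags$chrom == chr)
    s <- toupper(as.character(genome[[chr]]))
    len <- nchar(s)
    pos <- tags$pos[idx]
    plus <- tags$strand[idx] == "+"
    res <- character(length(idx))
    # + strand: 0-based [pos+1, pos+1+w) -> 1-based substring(pos+2, pos+1+w)
    if (any(plus)) {
      p <- pos[plus]
      res[plus] <- substring(s, pmin(p + 2L, len + 1L), pmin(p + 1L + w, len))
    }
    # - strand: 0-based [pos-w, pos) read 3'->5', i.e. revcomp of the
    # forward 1-based range [pos-w+1, pos]
    if (any(!plus)) {
      p <- pos[!plus]
      fw <- substring(s, pmax(p - w + 1L, 1L), pmax(p, 0L))
      res[!plus] <- revcomp_chr(fw)
    }
    out[idx] <- res
  }
  out
}

#' Cluster poly(A) tags into poly(A) clusters (PACs)
#'
#' Single-linkage gap clustering per (chromosome, strand): tag positions
#' are sorted and a new cluster starts whenever the gap to the previous
#' position exceeds `cluster_window`. The result is independent of input
#' order. Each PAC records its genomic span, per-sample tag counts, and a
#' summit -- the position carrying the most tags, ties broken toward the
#' most distal position in transcriptional orientation (downstream-most:
#' highest coordinate on `+`, lowest on `-`).
#'
#' @param tags Tag tibble (samples may be mixed).
#' @param params [calling_params()].
#' @param strict When `TRUE`, refuse tags that have not passed
#'   [filter_internal_priming()]; the pipeline order (filter, then cluster)
#'   is fixed.
#' @return A PAC tibble: `pac_id`, `chrom`, `strand`, `start`, `end`
#'   (0-based half-open span of member tag positions), `summit`, `n_tags`,
#'   plus one count column per sample (named `n_<sample_id>`).
#' @export
cluster_tags <- function(tags, params = calling_params(), strict = FALSE) {
  if (strict && !isTRUE(attr(tags, "ip_filtered"))) {
    abort("strict mode: tags must pass filter_internal_priming() before clustering")
  }
  samples <- sort(unique(tags$sample_id))
  if (nrow(tags) == 0) return(empty_pacs(samples))
  clustered <- tags |>
    arrange(.data$chrom, .data$strand, .data$pos) |>
    group_by(.data$chrom, .data$strand) |>
    mutate(cluster = cumsum(c(1L, diff(.data$pos) > params$cluster_window))) |>
    ungroup()

  per_pos <- clustered |>
    count(.data$chrom, .data$strand, .data$cluster, .data$pos, name = "pos_n")
  summits <- per_pos |>
    group_by(.data$chrom, .data$strand, .data$cluster) |>
    summarise(summit = summit_pos(.data$pos, .data$pos_n, .data$strand[1]),
              start = min(.data$pos), end = max(.data$pos) + 1L,
              n_tags = sum(.data$pos_n), .groups = "drop")

  counts <- clustered |>
    count(.data$chrom, .data$strand, .data$cluster, .data$sample_id) |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "n",
                       values_fill = 0L, names_prefix = "n_",
                       names_sort = TRUE)

  pacs <- summits |>
    left_join(counts, by = c("chrom", "strand", "cluster")) |>
    arrange(.data$chrom, .data$start, .data$strand) |>
    mutate(pac_id = sprintf("PAC%06d", row_number()), .before = 1) |>
    select(-"cluster")
  pacs
}

summit_pos <- function(pos, n, strand) {
  top <- pos[n == max(n)]
  if (strand == "+") max(top) else min(top)
}

empty_pacs <- function(samples = character(0)) {
  out <- tibble(pac_id = character(), chrom = character(), strand = character(),
                summit = integer(), start = integer(), end = integer(),
                n_tags = integer())
  for (s in samples) out[[paste0("n_", s)]] <- integer()
  out
}

count_cols <- function(pacs) grep("^n_", names(pacs), value = TRUE)

#' Assign PACs to genes and genomic regions
#'
#' Each PAC is assigned by its summit. All (gene, region) hits on the
#' matching strand are collected over 3' UTR, CDS, intron, 5' UTR and the
#' downstream 3' UTR extension. Exactly one hit gives that gene and region
#' (extension hits are labelled `EXTENDED_UTR3`; reports pool them with
#' `UTR3`). Hits in more than one region or gene give region `AMB`
#' (ambiguous) with the gene carrying a 3' UTR hit when there is one
#' (lowest gene id on ties). No hit gives `INTERGENIC` with no gene.
#'
#' @param pacs PAC tibble from [cluster_tags()].
#' @param gene_models From [read_annotation()].
#' @return The PAC tibble with `gene_id` and `region` columns added, plus
#'   `utr_length`: the 3' UTR length in nt implied by the summit (distance
#'   from the gene's 3' UTR anchor to the summit, transcriptional
#'   orientation) for `UTR3`/`EXTENDED_UTR3` PACs, `NA` otherwise.
#' @export
assign_pacs <- function(pacs, gene_models) {
  if (nrow(pacs) == 0) {
    return(pacs |> mutate(gene_id = character(), region = character(),
                          utr_length = integer()))
  }
  reg <- gene_models$regions
  reg_gr <- GenomicRanges::GRanges(reg$chrom,
                                   IRanges::IRanges(reg$start + 1L, reg$end),
                                   strand = reg$strand)
  sum_gr <- GenomicRanges::GRanges(pacs$chrom,
                                   IRanges::IRanges(pacs$summit + 1L, width = 1L),
                                   strand = pacs$strand)
  hits <- GenomicRanges::findOverlaps(sum_gr, reg_gr, ignore.strand = FALSE)
  hit_tbl <- tibble(
    pac = S4Vectors::queryHits(hits),
    gene_id = reg$gene_id[S4Vectors::subjectHits(hits)],
    region = reg$region[S4Vectors::subjectHits(hits)]
  ) |> distinct()

  assignment <- hit_tbl |>
    group_by(.data$pac) |>
    summarise(
      gene_id = resolve_gene(.data$gene_id, .data$region),
      region = if (n() == 1) .data$region[1] else "AMB",
      .groups = "drop")

  pacs$gene_id <- NA_character_
  pacs$region <- "INTERGENIC"
  pacs$gene_id[assignment$pac] <- assignment$gene_id
  pacs$region[assignment$pac] <- assignment$region

  anchors <- gene_models$genes |> select("gene_id", "utr3_anchor")
  pacs |>
    left_join(anchors, by = "gene_id") |>
    mutate(utr_length = ifelse(
      .data$region %in% c("UTR3", "EXTENDED_UTR3"),
      ifelse(.data$strand == "+",
             .data$summit - .data$utr3_anchor + 1L,
             .data$utr3_anchor - .data$summit + 1L),
      NA_integer_)) |>
    select(-"utr3_anchor")
}

# gene for a (possibly ambiguous) hit set: single hit -> its gene; else the
# gene with a 3' UTR (or extension) hit, lowest id on ties, NA when none
resolve_gene <- function(gene_id, region) {
  if (length(gene_id) == 1) return(gene_id)
  utr_genes <- sort(gene_id[region == "UTR3"])
  if (!length(utr_genes)) utr_genes <- sort(gene_id[region == "EXTENDED_UTR3"])
  if (length(utr_genes)) utr_genes[1] else NA_character_
}

#' Drop PACs below the minimum tag support
#'
#' Keeps PACs whose total tag count across all samples is at least
#' `min_pats` (default 10; a PAC with exactly `min_pats` tags survives).
#'
#' @param pacs PAC tibble.
#' @param params [calling_params()].
#' @return The filtered PAC tibble; the number removed is reported.
#' @export
filter_min_support <- function(pacs, params = calling_params()) {
  keep <- pacs$n_tags >= params$min_pats
  inform(paste0("support filter: removed ", sum(!keep), " PAC(s) with < ",
                params$min_pats, " tags"))
  pacs[keep, , drop = FALSE]
}

#' Per-gene PAC counts and APA-gene calls
#'
#' A gene is an APA (alternatively polyadenylated) gene when more than one
#' PAC is assigned to it. PACs without a gene or labelled `INTERGENIC` are
#' not counted; `AMB` PACs count for their resolved gene when one is set.
#'
#' @param pacs Assigned, support-filtered PAC tibble.
#' @return Tibble `gene_id`, `n_pacs`, `is_apa`.
#' @export
apa_gene_table <- function(pacs) {
  pacs |>
    filter(!is.na(.data$gene_id), .data$region != "INTERGENIC") |>
    count(.data$gene_id, name = "n_pacs") |>
    mutate(is_apa = .data$n_pacs > 1L)
}

#' Call PACs from tags in one step
#'
#' Runs the fixed pipeline order: internal-priming filter, single-linkage
#' clustering, gene/region assignment, minimum-support filter.
#'
#' @param tags Tag tibble (all samples).
#' @param genome From [read_genome()].
#' @param gene_models From [read_annotation()].
#' @param params [calling_params()].
#' @return Assigned, filtered PAC tibble.
#' @export
call_pacs <- function(tags, genome, gene_models, params = calling_params()) {
  flt <- filter_internal_priming(tags, genome, params)
  flt$kept |>
    cluster_tags(params, strict = TRUE) |>
    assign_pacs(gene_models) |>
    filter_min_support(params)
}

#' Write PACs to BED6 and TSV
#'
#' The BED6 uses the 0-based half-open PAC span, the PAC id as name, the
#' total tag count (capped at 1000) as score, and the strand. The TSV holds
#' the full table (one count column per sample plus gene and region) and
#' round-trips exactly through [read_pacs()].
#'
#' @param pacs PAC tibble.
#' @param bed_path,tsv_path Output paths.
#' @export
write_pacs <- function(pacs, bed_path, tsv_path) {
  bed <- pacs |>
    transmute(.data$chrom, .data$start, .data$end, name = .data$pac_id,
              score = pmin(.data$n_tags, 1000L), .data$strand)
  readr::write_tsv(bed, bed_path, col_names = FALSE)
  readr::write_tsv(pacs, tsv_path, na = "NA")
  invisible(list(bed = bed_path, tsv = tsv_path))
}

#' Read back a PAC TSV written by [write_pacs()]
#' @param tsv_path Path to the TSV.
#' @return The PAC tibble.
#' @export
read_pacs <- function(tsv_path) {
  readr::read_tsv(tsv_path, show_col_types = FALSE,
                  col_types = readr::cols(
                    pac_id = "c", chrom = "c", strand = "c",
                    gene_id = "c", region = "c", .default = "i"))
}

#' PAC distribution among genomic regions
#'
#' Tabulates PAC counts per region; extension hits are pooled into `UTR3`
#' for reporting. The counts are a partition: they sum to the number of
#' PACs.
#'
#' @param pacs Assigned PAC tibble.
#' @return Tibble `region`, `n`, `fraction`.
#' @export
region_distribution <- function(pacs) {
  lev <- c("UTR3", "CDS", "INTRON", "UTR5", "INTERGENIC", "AMB")
  pacs |>
    mutate(region = ifelse(.data$region == "EXTENDED_UTR3", "UTR3", .data$region),
           region = factor(.data$region, levels = lev)) |>
    count(.data$region, .drop = FALSE) |>
    mutate(region = as.character(.data$region),
           fraction = if (sum(.data$n) > 0) .data$n / sum(.data$n) else 0)
}
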