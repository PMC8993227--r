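#' Read a GFF3 gene annotation into gene models
#'
#' Parses gene / mRNA / exon / CDS / UTR features from a GFF3 file and
#' builds one gene model per gene, on the package's internal 0-based
#' half-open coordinate convention (GFF3 1-based closed coordinates are
#' converted at this boundary and nowhere else).
#'
#' For genes with several transcripts, the representative transcript is the
#' one with the longest annotated 3' UTR, falling back to the longest
#' transcript; introns are the gaps between its consecutive exons.
#'
#' Every gene receives a downstream *3' UTR extension* interval used to
#' rescue cleavage sites falling past the annotated gene end: `ext_bp`
#' (default 200 nt) appended at the annotated 3' UTR end when a
#' `three_prime_UTR` feature exists, and `ext_bp + fallback_bp` (default
#' 200 + 218 nt) anchored at the gene's 3' end when it does not.
#'
#' @param path Path to a GFF3 file.
#' @param ext_bp 3' UTR extension length in nt.
#' @param fallback_bp Extra extension, in nt, for genes lacking an annotated
#'   3' UTR (218 nt by default, a typical average 3' UTR length in
#'   crucifers).
#' @return A `gene_models` object: a list with
#'   \describe{
#'     \item{genes}{tibble with one row per gene: `gene_id`, `chrom`,
#'       `strand`, `start`, `end` (0-based half-open gene span),
#'       `has_utr3`, and `utr3_anchor`, the 0-based coordinate of the first
#'       3' UTR base in transcriptional orientation (the first base after
#'       the gene when no 3' UTR is annotated) from which 3' UTR lengths
#'       are measured.}
#'     \item{regions}{tibble of region intervals per gene: `gene_id`,
#'       `chrom`, `strand`, `region` (one of `UTR5`, `CDS`, `INTRON`,
#'       `UTR3`, `EXTENDED_UTR3`), `start`, `end`.}
#'   }
#' @export
read_annotation <- function(path, ext_bp = 200L, fallback_bp = 218L) {
  if (!file.exists(path)) abort(paste0("GFF3 file not found: ", path))
  gr <- rtracklayer::import(path, format = "gff3")
  feats <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    id = as.character(gr$ID %||% NA_character_),
    parent = vapply(as.list(gr$Parent %||% replicate(length(gr), character(0))),
                    function(p) if (length(p)) p[[1]] else NA_character_,
                    character(1))
  )

  genes <- feats |> filter(.data$type == "gene")
  if (anyDuplicated(genes$id)) {
    abort(paste0("duplicate gene_id in annotation: ",
                 paste(unique(genes$id[duplicated(genes$id)]), collapse = ", ")))
  }
  no_strand <- genes$strand %in% c("*", ".", NA)
  if (any(no_strand)) {
    warn(paste0("skipping ", sum(no_strand), " gene(s) with no strand: ",
                paste(head(genes$id[no_strand], 5), collapse = ", ")))
    genes <- genes[!no_strand, ]
  }

  tx <- feats |> filter(.data$type %in% c("mRNA", "transcript"))
  kids <- feats |>
    filter(.data$type %in% c("exon", "CDS", "three_prime_UTR", "five_prime_UTR"))

  models <- purrr::map(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    gtx <- tx |> filter(.data$parent == g$id)
    rep_tx <- representative_tx(gtx, kids)
    k <- if (is.na(rep_tx)) kids[0, ] else kids |> filter(.data$parent == rep_tx)
    utr3 <- k |> filter(.data$type == "three_prime_UTR")
    utr5 <- k |> filter(.data$type == "five_prime_UTR")
    cds <- k |> filter(.data$type == "CDS")
    exons <- k |> filter(.data$type == "exon") |> arrange(.data$start)
    introns <- if (nrow(exons) >= 2) {
      tibble(start = exons$end[-nrow(exons)], end = exons$start[-1]) |>
        filter(.data$end > .data$start)
    } else tibble(start = integer(), end = integer())

    has_utr3 <- nrow(utr3) > 0
    if (g$strand == "+") {
      anchor_end <- if (has_utr3) max(utr3$end) else g$end
      ext_len <- if (has_utr3) ext_bp else ext_bp + fallback_bp
      ext <- c(anchor_end, anchor_end + ext_len)
      utr3_anchor <- if (has_utr3) min(utr3$start) else g$end
    } else {
      anchor_start <- if (has_utr3) min(utr3$start) else g$start
      ext_len <- if (has_utr3) ext_bp else ext_bp + fallback_bp
      ext <- c(max(0L, anchor_start - ext_len), anchor_start)
      utr3_anchor <- if (has_utr3) max(utr3$end) - 1L else g$start - 1L
    }

    regions <- bind_rows(
      utr5 |> transmute(region = "UTR5", .data$start, .data$end),
      cds |> transmute(region = "CDS", .data$start, .data$end),
      introns |> mutate(region = "INTRON", .before = 1),
      utr3 |> transmute(region = "UTR3", .data$start, .data$end),
      tibble(region = "EXTENDED_UTR3", start = ext[1], end = ext[2])
    ) |>
      filter(.data$end > .data$start) |>
      mutate(gene_id = g$id, chrom = g$chrom, strand = g$strand, .before = 1)

    list(
      gene = tibble(gene_id = g$id, chrom = g$chrom, strand = g$strand,
                    start = g$start, end = g$end,
                    has_utr3 = has_utr3, utr3_anchor = utr3_anchor),
      regions = regions
    )
  })

  out <- list(
    genes = purrr::list_rbind(purrr::map(models, "gene")),
    regions = purrr::list_rbind(purrr::map(models, "regions")),
    ext_bp = as.integer(ext_bp), fallback_bp = as.integer(fallback_bp)
  )
  structure(out, class = "gene_models")
}

# pick the transcript with the longest total annotated 3' UTR,
# falling back to the longest transcript (total exon length, then span)
representative_tx <- function(gtx, kids) {
  if (nrow(gtx) == 0) return(NA_character_)
  if (nrow(gtx) == 1) return(gtx$id)
  score <- purrr::map_dbl(gtx$id, function(txid) {
    k <- kids |> filter(.data$parent == txid)
    u3 <- sum((k$end - k$start)[k$type == "three_prime_UTR"])
    ex <- sum((k$end - k$start)[k$type == "exon"])
    u3 * 1e9 + ex
  })
  span <- gtx$end - gtx$start
  gtx$id[order(-score, -span, gtx$id)][1]
}

#' @export
print.gene_models <- function(x, ...) {
  cat("<gene_models> ", nrow(x$genes), " genes, ",
      sum(x$genes$has_utr3), " with annotated 3' UTR; extension ",
      x$ext_bp, " nt (+", x$fallback_bp, " nt fallback)\n", sep = "")
  invisible(x)
}
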