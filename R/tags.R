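#' Read a sample sheet
#'
#' The sample sheet is a TSV with header
#' `sample_id	path	condition	replicate` mapping each tag file to its
#' experimental condition (`CK` control or `ST` treatment) and replicate
#' index. Relative paths are resolved against the sheet's own directory.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `sample_id`, `path`, `condition`,
#'   `replicate`.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             sample_id = "c", path = "c",
                             condition = "c", replicate = "i"))
  validate_design(sheet)
  rel <- !file.exists(sheet$path) & !grepl("^/", sheet$path)
  sheet$path[rel] <- file.path(dirname(path), sheet$path[rel])
  sheet
}

validate_design <- function(design) {
  stopifnot(all(c("sample_id", "condition") %in% names(design)))
  if (anyDuplicated(design$sample_id)) abort("sample_ids must be unique")
  bad <- setdiff(unique(design$condition), c("CK", "ST"))
  if (length(bad)) abort(paste0("unknown condition(s): ", paste(bad, collapse = ", "),
                                " (expected CK/ST)"))
  if (!all(c("CK", "ST") %in% design$condition)) {
    abort("need at least one sample per condition (CK and ST)")
  }
  invisible(design)
}

#' Read aligned poly(A) tags
#'
#' Reads one sample's poly(A) tags from a SAM/BAM alignment file or a BED6
#' file of pre-extracted cleavage sites, and reduces each record to its
#' single-nucleotide cleavage coordinate: the 3'-most *aligned* base of the
#' read in transcriptional orientation (the reference-space alignment end
#' on `+`, the alignment start on `-`; soft-clipped bases, which are
#' oligo(dT)/adaptor sequence rather than genomic evidence, are excluded).
#' All coordinates are 0-based.
#'
#' @param path Input file.
#' @param format One of `"sam"`, `"bam"`, `"bed"`. Defaults to the file
#'   extension.
#' @param min_mapq Minimum mapping quality (SAM/BAM only); records below it,
#'   or with missing MAPQ, are dropped. The default of 10 is a configurable
#'   package choice.
#' @param sample_id Sample identifier attached to every tag.
#' @return A tibble of poly(A) tags: `chrom`, `pos` (0-based cleavage
#'   coordinate), `strand`, `sample_id`. The number of dropped low-MAPQ
#'   records is reported via a message and the `n_dropped` attribute.
#' @export
read_tags <- function(path, format = NULL, min_mapq = 10L, sample_id = "sample1") {
  if (!file.exists(path)) abort(paste0("tag file not found: ", path))
  format <- tolower(format %||% tools::file_ext(path))
  switch(format,
    bed = read_tags_bed(path, sample_id),
    sam = ,
    bam = read_tags_bam(path, format, min_mapq, sample_id),
    abort(paste0("unknown tag format: '", format, "' (expected sam, bam or bed)"))
  )
}

read_tags_bed <- function(path, sample_id) {
  gr <- rtracklayer::import(path, format = "BED")
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) {
    abort("BED tag input must carry a strand column (BED6); found unstranded records")
  }
  tags <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    pos = ifelse(strand == "+", GenomicRanges::end(gr) - 1L,
                 GenomicRanges::start(gr) - 1L),
    strand = strand,
    sample_id = sample_id
  )
  attr(tags, "n_dropped") <- 0L
  tags
}

read_tags_bam <- function(path, format, min_mapq, sample_id) {
  if (format == "sam") {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = TRUE)
  }
  aln <- GenomicAlignments::readGAlignments(
    path, param = Rsamtools::ScanBamParam(what = "mapq"))
  mapq <- S4Vectors::mcols(aln)$mapq
  keep <- !is.na(mapq) & mapq >= min_mapq
  n_dropped <- sum(!keep)
  aln <- aln[keep]
  strand <- as.character(GenomicRanges::strand(aln))
  tags <- tibble(
    chrom = as.character(GenomicRanges::seqnames(aln)),
    pos = ifelse(strand == "+", GenomicAlignments::end(aln) - 1L,
                 GenomicAlignments::start(aln) - 1L),
    strand = strand,
    sample_id = sample_id
  )
  inform(paste0(sample_id, ": kept ", nrow(tags), " tags, dropped ",
                n_dropped, " below MAPQ ", min_mapq))
  attr(tags, "n_dropped") <- n_dropped
  tags
}

#' Read tags for every sample in a sample sheet
#'
#' @param sheet Sample sheet tibble from [read_sample_sheet()].
#' @param format,min_mapq Passed to [read_tags()].
#' @return One tibble of tags for all samples, rows in sheet order.
#' @export
load_tags <- function(sheet, format = NULL, min_mapq = 10L) {
  purrr::list_rbind(purrr::map(seq_len(nrow(sheet)), function(i) {
    read_tags(sheet$path[i], format = format, min_mapq = min_mapq,
              sample_id = sheet$sample_id[i])
  }))
}

#' Write a bedGraph coverage track of tag 3' ends
#'
#' Writes per-base counts of tag cleavage sites for one sample,
#' strand-collapsed, sorted by chromosome then start. Adjacent single-base
#' intervals are written separately even when their values are equal (no
#' merging), which keeps the export a plain per-base histogram.
#'
#' @param tags Tag tibble (one sample).
#' @param sample_id Track name written into the bedGraph header.
#' @param path Output path.
#' @export
write_coverage <- function(tags, sample_id, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (nrow(tags) == 0) return(invisible(path))
  writeLines(paste0("track type=bedGraph name=", sample_id), con)
  cov <- tags |>
    count(.data$chrom, .data$pos) |>
    arrange(.data$chrom, .data$pos)
  writeLines(paste(cov$chrom, cov$pos, cov$pos + 1L, cov$n, sep = "\t"), con)
  invisible(path)
}
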