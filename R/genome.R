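#' Read a genome FASTA file
#'
#' Loads a genome into memory as a [Biostrings::DNAStringSet] with sequence
#' names truncated at the first whitespace (the usual FASTA-header
#' convention), uppercased so downstream base counting is case-insensitive.
#'
#' @param path Path to a (plain-text) FASTA file.
#' @return A `DNAStringSet`, one entry per chromosome/contig.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) abort(paste0("genome FASTA not found: ", path))
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Extract a genomic window in transcriptional orientation
#'
#' Coordinates are 0-based half-open, the package-wide internal convention.
#' Windows are clipped to chromosome bounds: bases outside the chromosome
#' are absent from the returned string, never fabricated. For `strand ==
#' "-"` the reverse complement is returned, so the first character is always
#' the 5'-most base in transcriptional orientation.
#'
#' @param genome A `DNAStringSet` from [read_genome()].
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open window.
#' @param strand `"+"` or `"-"`.
#' @return A single character string (possibly shorter than `end - start`
#'   after clipping, possibly empty).
#' @export
genome_window <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) {
    abort(paste0("chromosome absent from genome: ", chrom))
  }
  len <- length(genome[[chrom]])
  s <- max(0L, as.integer(start)); e <- min(len, as.integer(end))
  if (e <= s) return("")
  out <- as.character(Biostrings::subseq(genome[[chrom]], start = s + 1L, end = e))
  out <- toupper(out)
  if (identical(strand, "-")) out <- revcomp_chr(out)
  out
}

# reverse complement on plain character vectors (vectorised, N-safe)
revcomp_chr <- function(x) {
  chartr("ACGTN", "TGCAN", stringi::stri_reverse(x))
}

# lengths of all chromosomes as a named integer vector
chrom_lengths <- function(genome) {
  setNames(Biostrings::width(genome), names(genome))
}
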