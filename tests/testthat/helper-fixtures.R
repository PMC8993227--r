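# shared in-code fixtures: tiny genomes, tag tables, gene models

make_tags <- function(pos, chrom = "c1", strand = "+", sample_id = "s1") {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), strand = strand,
                 sample_id = sample_id)
}

# mark a tag table as having passed the internal-priming filter
as_filtered <- function(tags) {
  attr(tags, "ip_filtered") <- TRUE
  tags
}

mini_genome <- function(...) {
  Biostrings::DNAStringSet(c(...))
}

# hand-built gene_models object (internal 0-based half-open intervals)
make_gene_models <- function(genes, regions, ext_bp = 200L, fallback_bp = 218L) {
  structure(list(genes = genes, regions = regions,
                 ext_bp = ext_bp, fallback_bp = fallback_bp),
            class = "gene_models")
}

mini_design <- function(n_rep = 3) {
  tibble::tibble(
    sample_id = c(paste0("CK_", seq_len(n_rep)), paste0("ST_", seq_len(n_rep))),
    condition = rep(c("CK", "ST"), each = n_rep),
    replicate = rep(seq_len(n_rep), 2))
}

# pac_matrix straight from a count matrix (units x 6 samples)
counts_to_mat <- function(counts, design = mini_design(),
                          gene_id = NULL, region = NULL) {
  n <- nrow(counts)
  pacs <- tibble::tibble(pac_id = sprintf("P%03d", seq_len(n)))
  if (!is.null(gene_id)) pacs$gene_id <- gene_id
  if (!is.null(region)) pacs$region <- region
  for (j in seq_len(ncol(counts))) {
    pacs[[paste0("n_", design$sample_id[j])]] <- as.integer(counts[, j])
  }
  patapa::pac_matrix(pacs, design)
}

# two-gene GFF3 (one per strand, minus-strand gene lacks a 3' UTR),
# written to a temp file; coordinates are 1-based closed as per GFF3
write_mini_gff <- function(path = tempfile(fileext = ".gff3")) {
  lines <- c(
    "##gff-version 3",
    # + strand gene: [1,1000] with 3' UTR [801,1000]
    "c1\ttest\tgene\t1\t1000\t.\t+\t.\tID=gplus",
    "c1\ttest\tmRNA\t1\t1000\t.\t+\t.\tID=gplus.1;Parent=gplus",
    "c1\ttest\texon\t1\t400\t.\t+\t.\tID=gplus.1.e1;Parent=gplus.1",
    "c1\ttest\texon\t501\t1000\t.\t+\t.\tID=gplus.1.e2;Parent=gplus.1",
    "c1\ttest\tfive_prime_UTR\t1\t100\t.\t+\t.\tID=gplus.1.u5;Parent=gplus.1",
    "c1\ttest\tCDS\t101\t400\t.\t+\t.\tID=gplus.1.c1;Parent=gplus.1",
    "c1\ttest\tCDS\t501\t800\t.\t+\t.\tID=gplus.1.c2;Parent=gplus.1",
    "c1\ttest\tthree_prime_UTR\t801\t1000\t.\t+\t.\tID=gplus.1.u3;Parent=gplus.1",
    # - strand gene with no 3' UTR annotation, gene span [3001,4000]
    "c1\ttest\tgene\t3001\t4000\t.\t-\t.\tID=gminus",
    "c1\ttest\tmRNA\t3001\t4000\t.\t-\t.\tID=gminus.1;Parent=gminus",
    "c1\ttest\texon\t3001\t4000\t.\t-\t.\tID=gminus.1.e1;Parent=gminus.1",
    "c1\ttest\tCDS\t3001\t3900\t.\t-\t.\tID=gminus.1.c1;Parent=gminus.1"
  )
  writeLines(lines, path)
  path
}

# small SAM with mixed strands, a soft clip and a low-MAPQ record
write_mini_sam <- function(path = tempfile(fileext = ".sam")) {
  lines <- c(
    "@HD\tVN:1.6\tSO:unknown",
    "@SQ\tSN:c1\tLN:10000",
    # + strand [100,150) 0-based -> POS 101, 50M
    "r1\t0\tc1\t101\t60\t50M\t*\t0\t0\t*\t*",
    # - strand [100,150) 0-based -> flag 16
    "r2\t16\tc1\t101\t60\t50M\t*\t0\t0\t*\t*",
    # + strand with 10 soft-clipped bases: reference span [200,240)
    "r3\t0\tc1\t201\t60\t10S40M\t*\t0\t0\t*\t*",
    # low MAPQ, should be dropped at min_mapq 10
    "r4\t0\tc1\t301\t5\t50M\t*\t0\t0\t*\t*"
  )
  writeLines(lines, path)
  path
}
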