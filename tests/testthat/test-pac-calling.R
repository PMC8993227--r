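test_that("internal-priming filter applies the A-count and A-run rules", {
  # tag at pos 9 on +: downstream window is bases [10, 20)
  win_genome <- function(win) {
    mini_genome(c1 = paste0(strrep("C", 10), win, strrep("C", 10)))
  }
  tag <- make_tags(9)
  removed <- function(win) {
    nrow(suppressMessages(
      filter_internal_priming(tag, win_genome(win)))$removed) == 1
  }
  expect_true(removed("AAAAAAAAAA"))   # maximal A-richness
  expect_false(removed("CGTACGTACG"))  # zero A
  # 6-A leading run but only 6 A total: removed via the run rule alone
  expect_true(removed("AAAAAACGTC"))
  expect_false(removed("AAAAACGTCC")) # 5-run, 5 A: both rules miss
  expect_false(removed("AGAACAAAGC")) # 6 scattered A, leading run 1
  expect_true(removed("AACAAACAAA"))  # 8 A >= 7 via the count rule

  # kept/removed partition the input
  tags <- make_tags(c(9, 9, 9))
  res <- suppressMessages(filter_internal_priming(tags, win_genome("AAAAAAAAAA")))
  expect_equal(nrow(res$kept) + nrow(res$removed), 3L)
  expect_error(filter_internal_priming(make_tags(9, chrom = "cX"),
                                       win_genome("ACGT")), "cX")
})

test_that("internal-priming filter is strand-aware and truncation-safe", {
  # - strand tag at pos 20: downstream window is [10, 20) reverse-complemented;
  # sense A's are genomic T's
  g <- mini_genome(c1 = paste0(strrep("C", 10), "TTTTTTTTTT", strrep("C", 10)))
  res <- suppressMessages(
    filter_internal_priming(make_tags(20, strand = "-"), g))
  expect_equal(nrow(res$removed), 1L)
  # same tag on + reads C's: kept
  res <- suppressMessages(filter_internal_priming(make_tags(20), g))
  expect_equal(nrow(res$kept), 1L)
  # window truncated by the chromosome end: too short to trigger either rule
  g2 <- mini_genome(c1 = paste0(strrep("C", 28), "AA"))
  res <- suppressMessages(filter_internal_priming(make_tags(27), g2))
  expect_equal(nrow(res$kept), 1L)
})

test_that("internal-priming rule matches the brute-force checker on random windows", {
  set.seed(401)
  wins <- vapply(seq_len(500), function(i) {
    paste(sample(c("A", "C", "G", "T"), 10, replace = TRUE,
                 prob = c(0.5, 0.2, 0.2, 0.1)), collapse = "")
  }, character(1))
  stride <- 40L
  seq <- paste(vapply(wins, function(w)
    paste0(strrep("G", 10), w, strrep("G", stride - 20)), character(1)),
    collapse = "")
  tags <- make_tags(stride * (seq_along(wins) - 1L) + 9L)
  res <- suppressMessages(filter_internal_priming(tags, mini_genome(c1 = seq)))
  got <- tags$pos %in% res$removed$pos
  want <- vapply(wins, oracle_ip_artifact, logical(1))
  expect_equal(unname(got), unname(want))
})

test_that("gap clustering matches the transitive-closure oracle and is order-invariant", {
  expect_cluster_equal <- function(pos, window = 24) {
    tags <- as_filtered(make_tags(pos))
    pacs <- cluster_tags(tags, calling_params(cluster_window = window))
    imp <- lapply(seq_len(nrow(pacs)), function(i)
      sort(pos[pos >= pacs$start[i] & pos < pacs$end[i]]))
    ora <- unname(lapply(split(pos, oracle_cluster(pos, window)), sort))
    imp <- imp[order(vapply(imp, min, numeric(1)))]
    ora <- ora[order(vapply(ora, min, numeric(1)))]
    expect_equal(imp, ora)
  }
  expect_cluster_equal(c(100, 110, 150))        # {100,110} | {150}
  expect_cluster_equal(c(0, 24, 48, 72))        # one chained cluster
  set.seed(402)
  for (i in 1:20) expect_cluster_equal(sample(0:4999, 400, replace = TRUE))

  # input order never matters
  set.seed(403)
  pos <- sample(0:2000, 300, replace = TRUE)
  a <- cluster_tags(as_filtered(make_tags(pos)))
  b <- cluster_tags(as_filtered(make_tags(sample(pos))))
  expect_equal(a, b)
})

test_that("summits take the modal position, ties broken toward the distal end", {
  tags <- as_filtered(make_tags(c(100, 100, 105, 110, 110)))
  expect_equal(cluster_tags(tags)$summit, 110L)
  tags_m <- as_filtered(make_tags(c(100, 100, 105, 110, 110), strand = "-"))
  expect_equal(cluster_tags(tags_m)$summit, 100L)

  # per-sample counts tally correctly
  tags2 <- as_filtered(dplyr::bind_rows(
    make_tags(c(10, 12), sample_id = "a"), make_tags(14, sample_id = "b")))
  pacs <- cluster_tags(tags2)
  expect_equal(pacs$n_a, 2L)
  expect_equal(pacs$n_b, 1L)
  expect_equal(pacs$n_tags, 3L)
})

test_that("re-clustering PAC summits never merges separated PACs", {
  set.seed(404)
  pos <- sample(0:20000, 800, replace = TRUE)
  pacs <- cluster_tags(as_filtered(make_tags(pos)))
  again <- cluster_tags(as_filtered(make_tags(pacs$summit)))
  expect_equal(nrow(again), nrow(pacs))
})

test_that("strict mode refuses unfiltered tags", {
  expect_error(cluster_tags(make_tags(1:3), strict = TRUE),
               "filter_internal_priming")
  expect_silent(cluster_tags(as_filtered(make_tags(1:3)), strict = TRUE))
})

test_that("summit-based assignment resolves regions, ambiguity and intergenic", {
  genes <- tibble::tibble(
    gene_id = c("gA", "gB"), chrom = "c1", strand = "+",
    start = c(0L, 150L), end = c(1000L, 1200L),
    has_utr3 = TRUE, utr3_anchor = c(800L, 900L))
  regions <- tibble::tibble(
    gene_id = c("gA", "gA", "gA", "gB", "gB"),
    chrom = "c1", strand = "+",
    region = c("CDS", "UTR3", "EXTENDED_UTR3", "CDS", "UTR3"),
    start = c(100L, 800L, 1000L, 150L, 900L),
    end = c(800L, 1000L, 1200L, 900L, 1200L))
  gm <- make_gene_models(genes, regions)
  pacs <- tibble::tibble(
    pac_id = sprintf("P%d", 1:5), chrom = "c1", strand = "+",
    summit = c(850L, 1100L, 5000L, 500L, 950L),
    start = c(840L, 1090L, 4990L, 490L, 940L),
    end = c(860L, 1110L, 5010L, 510L, 960L),
    n_tags = 20L, n_s1 = 20L)
  out <- assign_pacs(pacs, gm)
  # single 3' UTR hit
  expect_equal(out$region[1], "AMB") # gA UTR3 + gB CDS overlap -> ambiguous
  expect_equal(out$gene_id[1], "gA") # 3' UTR priority
  # extension of gA overlaps UTR3 of gB -> ambiguous, UTR3 gene wins
  expect_equal(out$region[2], "AMB")
  expect_equal(out$gene_id[2], "gB")
  expect_equal(out$region[3], "INTERGENIC")
  expect_true(is.na(out$gene_id[3]))
  expect_equal(out$region[4], "AMB") # CDS of gA and CDS of gB
  expect_true(is.na(out$gene_id[4])) # no 3' UTR hit to prioritize
  expect_equal(out$region[5], "AMB")
  # ambiguous PACs carry no 3' UTR length (they stay out of UTR dynamics)
  expect_true(is.na(out$utr_length[2]))
})

test_that("unambiguous assignment yields the region itself and a UTR length", {
  genes <- tibble::tibble(gene_id = "g", chrom = "c1", strand = "-",
                          start = 1000L, end = 2000L, has_utr3 = TRUE,
                          utr3_anchor = 1199L)
  regions <- tibble::tibble(
    gene_id = "g", chrom = "c1", strand = "-",
    region = c("UTR3", "EXTENDED_UTR3", "CDS"),
    start = c(1000L, 800L, 1200L), end = c(1200L, 1000L, 1900L))
  gm <- make_gene_models(genes, regions)
  pacs <- tibble::tibble(pac_id = c("P1", "P2", "P3"), chrom = "c1",
                         strand = "-", summit = c(1100L, 900L, 1100L),
                         start = c(1090L, 890L, 1090L),
                         end = c(1110L, 910L, 1110L),
                         n_tags = 15L, n_s1 = 15L)
  pacs$strand[3] <- "+"  # opposite strand: no hit
  out <- assign_pacs(pacs, gm)
  expect_equal(out$region, c("UTR3", "EXTENDED_UTR3", "INTERGENIC"))
  # minus strand: length runs from the anchor downward
  expect_equal(out$utr_length[1], 1199L - 1100L + 1L)
  expect_equal(out$utr_length[2], 1199L - 900L + 1L)
})

test_that("support filter keeps PACs at exactly the threshold", {
  pacs <- tibble::tibble(pac_id = c("a", "b", "c"), n_tags = c(10L, 9L, 30L))
  out <- suppressMessages(filter_min_support(pacs))
  expect_equal(out$pac_id, c("a", "c"))
  # a one-line filter oracle on a random set
  set.seed(405)
  n <- sample(5:15, 30, replace = TRUE)
  pacs <- tibble::tibble(pac_id = as.character(seq_along(n)), n_tags = n)
  expect_equal(suppressMessages(filter_min_support(pacs))$pac_id,
               as.character(which(n >= 10)))
})

test_that("APA gene table counts gene-assigned PACs only", {
  pacs <- tibble::tibble(
    pac_id = sprintf("P%d", 1:5),
    gene_id = c("g1", "g1", "g2", NA, "g3"),
    region = c("CDS", "UTR3", "UTR3", "INTERGENIC", "AMB"))
  tab <- apa_gene_table(pacs)
  expect_equal(tab$n_pacs[tab$gene_id == "g1"], 2L)
  expect_true(tab$is_apa[tab$gene_id == "g1"])
  expect_false(tab$is_apa[tab$gene_id == "g2"])
  expect_equal(tab$n_pacs[tab$gene_id == "g3"], 1L) # AMB counts for its gene
})

test_that("region distribution is a partition pooling extensions into UTR3", {
  pacs <- tibble::tibble(region = c("UTR3", "EXTENDED_UTR3", "CDS", "AMB",
                                    "INTERGENIC", "UTR3"))
  d <- region_distribution(pacs)
  expect_equal(sum(d$n), nrow(pacs))
  expect_equal(d$n[d$region == "UTR3"], 3L)
  expect_equal(sum(d$fraction), 1)
})

test_that("zero-length extension turns extension-rescued PACs intergenic", {
  gff <- write_mini_gff()
  gm0 <- read_annotation(gff, ext_bp = 0, fallback_bp = 0)
  gm200 <- read_annotation(gff)
  # summit 150 nt past the annotated 3' UTR end of the + strand gene
  pacs <- tibble::tibble(pac_id = "P1", chrom = "c1", strand = "+",
                         summit = 1150L, start = 1140L, end = 1160L,
                         n_tags = 12L, n_s1 = 12L)
  expect_equal(assign_pacs(pacs, gm200)$region, "EXTENDED_UTR3")
  expect_equal(assign_pacs(pacs, gm200)$gene_id, "gplus")
  expect_equal(assign_pacs(pacs, gm0)$region, "INTERGENIC")
})
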