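test_that("config validation rejects inconsistent fractions before writing", {
  expect_error(sim_config(apa_fraction = 0.1, lengthen_fraction = 0.2),
               "apa_fraction")
  expect_error(sim_config(dispersion = 0.01, n_genes = 0), "positive")
  expect_error(sim_config(pacs_per_apa_gene = c(`2` = 0.5, `3` = 0.4,
                                                `4` = 0.05, `5` = 0.01)),
               "sum to 1")
  # invalid configs never reach the writer: construction itself fails,
  # so no output directory can come into being
  out <- tempfile()
  expect_error(simulate_apa_experiment(
    sim_config(apa_fraction = 0.05, switch_fraction = 0.2), out))
  expect_false(dir.exists(out))
})

test_that("simulation is bit-identical for a fixed seed", {
  cfg <- sim_config(n_genes = 40, seed = 99)
  d1 <- tempfile(); d2 <- tempfile()
  s1 <- simulate_apa_experiment(cfg, d1)
  s2 <- simulate_apa_experiment(cfg, d2)
  expect_identical(s1$tags, s2$tags)
  expect_identical(s1$truth_sites, s2$truth_sites)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # a different seed gives different data
  s3 <- simulate_apa_experiment(sim_config(n_genes = 40, seed = 100))
  expect_false(identical(s1$tags, s3$tags))
})

test_that("apa_fraction 0 yields single-site genes and 0% recovered APA", {
  cfg <- sim_config(n_genes = 50, apa_fraction = 0, lengthen_fraction = 0,
                    shorten_fraction = 0, switch_fraction = 0,
                    st_specific_fraction = 0, inducible_fraction = 0,
                    seed = 5)
  sim <- simulate_apa_experiment(cfg)
  expect_true(all(table(sim$truth_sites$gene_id[!sim$truth_sites$is_artifact]) == 1))
  pacs <- suppressMessages(
    call_pacs(sim$tags, sim$genome, sim$gene_models))
  expect_equal(sum(apa_gene_table(pacs)$is_apa), 0L)
})

test_that("with no planted tracts the priming filter removes under 1% of tags", {
  cfg <- sim_config(n_genes = 80, ip_tract_rate = 0, seed = 21)
  sim <- simulate_apa_experiment(cfg)
  res <- suppressMessages(filter_internal_priming(sim$tags, sim$genome))
  expect_lt(nrow(res$removed) / nrow(sim$tags), 0.01)
})

test_that("planted artifact tags sit on A-rich tracts and are filtered out", {
  cfg <- sim_config(n_genes = 60, ip_tract_rate = 0.5, seed = 31)
  sim <- simulate_apa_experiment(cfg)
  art <- sim$truth_sites[sim$truth_sites$is_artifact, ]
  expect_gt(nrow(art), 5)
  # downstream window of each artifact position is all A in sense orientation
  for (i in seq_len(min(5, nrow(art)))) {
    win <- genome_window(sim$genome, art$chrom[i],
                         ifelse(art$strand[i] == "+", art$pos[i] + 1,
                                art$pos[i] - 10),
                         ifelse(art$strand[i] == "+", art$pos[i] + 11,
                                art$pos[i]),
                         strand = art$strand[i])
    expect_equal(win, strrep("A", 10))
  }
  res <- suppressMessages(filter_internal_priming(sim$tags, sim$genome))
  removed_pos <- paste(res$removed$chrom, res$removed$pos)
  art_pos <- paste(art$chrom, art$pos)
  expect_true(all(art_pos %in% removed_pos))
})

test_that("emitted counts match configured usage shares at large n", {
  cfg <- sim_config(n_genes = 200, jitter_sd = 1, seed = 41)
  sim <- simulate_apa_experiment(cfg)
  ts <- sim$truth_sites[!sim$truth_sites$is_artifact, ]
  # pick high-expression multi-site null genes and check CK usage shares
  per_gene <- split(ts, ts$gene_id)
  checked <- 0
  for (g in per_gene) {
    if (nrow(g) < 2 || sum(g$mu_ck) < 80) next
    tags_g <- sim$tags[sim$tags$chrom == g$chrom[1] &
                         sim$tags$strand == g$strand[1] &
                         grepl("^CK", sim$tags$sample_id), ]
    cnt <- vapply(g$pos, function(p)
      sum(abs(tags_g$pos - p) <= 20), numeric(1))
    if (sum(cnt) < 200) next
    expect_equal(cnt / sum(cnt), g$mu_ck / sum(g$mu_ck), tolerance = 0.12)
    checked <- checked + 1
    if (checked >= 10) break
  }
  expect_gte(checked, 5)
})

test_that("the written annotation parses back to the in-memory gene models", {
  d <- tempfile()
  sim <- simulate_apa_experiment(sim_config(n_genes = 30, seed = 13), d)
  gm <- read_annotation(file.path(d, "annotation.gff3"))
  expect_equal(
    as.data.frame(dplyr::arrange(gm$genes, gene_id)),
    as.data.frame(dplyr::arrange(sim$gene_models$genes, gene_id)))
  expect_equal(
    as.data.frame(dplyr::arrange(gm$regions, gene_id, region, start)),
    as.data.frame(dplyr::arrange(sim$gene_models$regions, gene_id, region,
                                 start)))
  # sample sheet round-trips with resolvable relative paths
  sheet <- read_sample_sheet(file.path(d, "samples.tsv"))
  expect_true(all(file.exists(sheet$path)))
  tags <- read_tags(sheet$path[1], sample_id = sheet$sample_id[1])
  expect_gt(nrow(tags), 0)
})
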