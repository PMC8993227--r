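test_that("weighted 3' UTR length is the usage dot product", {
  expect_equal(weighted_utr_length(c(100, 300), c(0.75, 0.25)), 150)
  expect_equal(weighted_utr_length(500, 1), 500)

  set.seed(601)
  for (i in 1:20) {
    len <- runif(5, 50, 600)
    u <- runif(5); u <- u / sum(u)
    expect_equal(weighted_utr_length(len, u), sum(u * len), tolerance = 1e-12)
    # permutation invariance
    p <- sample(5)
    expect_equal(weighted_utr_length(len[p], u[p]),
                 weighted_utr_length(len, u), tolerance = 1e-12)
  }
  expect_error(weighted_utr_length(c(100, 200), c(0.6, 0.6)), "sum to 1")
  expect_error(weighted_utr_length(c(-5, 200), c(0.5, 0.5)), "positive")
  # count scaling leaves usage shares, hence the length, unchanged
  counts <- c(30, 10)
  expect_equal(weighted_utr_length(c(100, 300), counts / sum(counts)),
               weighted_utr_length(c(100, 300), 5 * counts / sum(5 * counts)))
})

test_that("direction statistic separates lengthening from degenerate cases", {
  cond <- rep(c("CK", "ST"), each = 3)
  # CK uses only the 100 nt PAC, ST only the 200 nt PAC -> r = 1
  counts <- rbind(c(10, 12, 11, 0, 0, 0), c(0, 0, 0, 9, 13, 10))
  d <- direction_statistic(counts, c(100, 200), cond)
  expect_equal(d$r, 1)
  expect_false(d$degenerate)
  # reversed usage -> r = -1
  expect_equal(direction_statistic(counts[2:1, ], c(100, 200), cond)$r, -1)
  # identical lengths in every sample: flagged zero-variance
  flat <- rbind(rep(6, 6), rep(6, 6))
  d0 <- direction_statistic(flat, c(100, 200), cond)
  expect_equal(d0$r, 0)
  expect_true(d0$degenerate)
  # a whole condition with zero counts: degenerate
  z <- rbind(c(0, 0, 0, 5, 5, 5), c(0, 0, 0, 5, 5, 5))
  expect_true(direction_statistic(z, c(100, 200), cond)$degenerate)
})

test_that("chi-square matches the hand value and the formula oracle", {
  expect_equal(chi_square_shift(c(50, 50), c(50, 50))$statistic, 0)
  expect_equal(chi_square_shift(c(50, 50), c(50, 50))$p_value, 1)

  hand <- chi_square_shift(c(90, 10), c(10, 90))
  expect_equal(hand$statistic, 128.0, tolerance = 1e-12)
  expect_equal(hand$df, 1)

  set.seed(602)
  for (i in 1:40) {
    tbl <- matrix(sample(20:200, 6), nrow = 2)
    got <- chi_square_shift(tbl[1, ], tbl[2, ])
    expect_equal(got$statistic, oracle_chisq(tbl), tolerance = 1e-10)
  }
  expect_error(chi_square_shift(10, 20), "k >= 2")
  expect_error(chi_square_shift(c(0, 10), c(0, 20)), "nonzero")
})

test_that("small expected counts fall back to a Monte-Carlo p value", {
  set.seed(603)
  out <- chi_square_shift(c(3, 2), c(2, 4))
  expect_true(out$monte_carlo)
  expect_gt(out$p_value, 0.05)
})

test_that("swapping condition labels negates r and keeps the chi-square", {
  set.seed(604)
  design <- mini_design()
  pacs <- tibble::tibble(
    pac_id = c("P1", "P2", "P3"), chrom = "c1", strand = "+",
    summit = c(100L, 300L, 500L), start = c(95L, 295L, 495L),
    end = c(105L, 305L, 505L), n_tags = 0L,
    gene_id = "g1", region = "UTR3", utr_length = c(60L, 260L, 460L))
  cnt <- matrix(rnbinom(18, mu = c(40, 70, 25), size = 50), nrow = 3)
  for (j in 1:6) pacs[[paste0("n_", design$sample_id[j])]] <- cnt[, j]
  pacs$n_tags <- as.integer(rowSums(cnt))

  fwd <- tidy(utr_dynamics(pacs, design))
  swapped <- design
  swapped$condition <- c(CK = "ST", ST = "CK")[design$condition]
  rev <- tidy(utr_dynamics(pacs, swapped))
  expect_equal(rev$r, -fwd$r)
  expect_equal(rev$chi2, fwd$chi2)
  expect_equal(rev$wul_ck, fwd$wul_st)
})

test_that("chi-square p values are uniform under multinomial null usage", {
  set.seed(605)
  n_genes <- 400
  p_vals <- vapply(seq_len(n_genes), function(i) {
    k <- sample(2:4, 1)
    shares <- runif(k, 0.2, 1); shares <- shares / sum(shares)
    ck <- as.vector(stats::rmultinom(1, 300, shares))
    st <- as.vector(stats::rmultinom(1, 300, shares))
    if (any(ck + st == 0)) return(NA_real_)
    chi_square_shift(ck, st)$p_value
  }, numeric(1))
  frac <- mean(p_vals < 0.05, na.rm = TRUE)
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.08)
})

test_that("classification gates on both the direction sign and significance", {
  design <- mini_design()
  mk_gene <- function(id, ck_counts, st_counts, lens, base = 200L) {
    k <- length(lens)
    p <- tibble::tibble(
      pac_id = paste0(id, "_", seq_len(k)), chrom = "c1", strand = "+",
      summit = base + seq_len(k) * 100L, start = base + seq_len(k) * 100L - 5L,
      end = base + seq_len(k) * 100L + 5L, n_tags = 0L, gene_id = id,
      region = "UTR3", utr_length = lens)
    for (j in 1:3) {
      p[[paste0("n_CK_", j)]] <- ck_counts
      p[[paste0("n_ST_", j)]] <- st_counts
    }
    p$n_tags <- as.integer(3L * (ck_counts + st_counts))
    p
  }
  pacs <- dplyr::bind_rows(
    mk_gene("strong_lengthen", c(90L, 10L), c(10L, 90L), c(100L, 400L)),
    mk_gene("weak", c(52L, 48L), c(48L, 52L), c(100L, 400L)))
  dyn <- utr_dynamics(pacs, design)
  cls <- tidy(dyn)
  expect_equal(cls$class[cls$gene_id == "strong_lengthen"], "LENGTHEN")
  expect_gt(cls$r[cls$gene_id == "strong_lengthen"], 0)
  expect_equal(cls$class[cls$gene_id == "weak"], "UNCHANGED")
  # shortening is the mirror image
  pacs_s <- dplyr::bind_rows(
    mk_gene("strong_shorten", c(10L, 90L), c(90L, 10L), c(100L, 400L)),
    mk_gene("weak", c(52L, 48L), c(48L, 52L), c(100L, 400L)))
  cls_s <- tidy(utr_dynamics(pacs_s, design))
  expect_equal(cls_s$class[cls_s$gene_id == "strong_shorten"], "SHORTEN")
  expect_lt(cls_s$r[cls_s$gene_id == "strong_shorten"], 0)
  # weighted lengths stay within the planted range
  expect_true(all(cls$wul_ck >= 100 & cls$wul_ck <= 400))
})

test_that("genes below two 3' UTR PACs are excluded from dynamics", {
  design <- mini_design()
  pacs <- tibble::tibble(
    pac_id = c("P1", "P2"), chrom = "c1", strand = "+",
    summit = c(100L, 300L), start = c(95L, 295L), end = c(105L, 305L),
    n_tags = 60L, gene_id = c("single_utr", "single_utr"),
    region = c("UTR3", "CDS"), utr_length = c(60L, NA))
  for (s in design$sample_id) pacs[[paste0("n_", s)]] <- 10L
  dyn <- utr_dynamics(pacs, design)
  expect_equal(nrow(tidy(dyn)), 0L)
})

test_that("classify_genes joins gene-level fold changes into quadrants", {
  dyn <- structure(list(genes = tibble::tibble(
    gene_id = c("g1", "g2", "g3"), n_utr_pacs = 2L,
    wul_ck = c(100, 200, 150), wul_st = c(200, 100, 150),
    r = c(0.9, -0.9, 0.1), degenerate = FALSE,
    chi2 = c(50, 40, 0.1), chi2_p = c(1e-8, 1e-6, 0.9),
    chi2_padj = c(3e-8, 2e-6, 0.9),
    class = c("LENGTHEN", "SHORTEN", "UNCHANGED")), alpha = 0.05),
    class = "utr_dynamics")
  de <- tibble::tibble(unit_id = c("g1", "g2", "g3"),
                       log2fc = c(1.5, -2, 0.1),
                       padj = c(0.001, 0.003, 0.8),
                       is_de = c(TRUE, TRUE, FALSE))
  out <- classify_genes(dyn, de)
  expect_equal(out$quadrants$n[out$quadrants$class == "LENGTHEN" &
                                 out$quadrants$expression == "UP"], 1L)
  expect_equal(out$quadrants$n[out$quadrants$class == "SHORTEN" &
                                 out$quadrants$expression == "DOWN"], 1L)
  expect_equal(out$class_counts$n_lengthen, 1L)
})
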