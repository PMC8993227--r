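#' Configuration for the synthetic PAT-seq experiment generator
#'
#' Defines a toy genome of regularly spaced gene loci with planted poly(A)
#' sites, replicate NB-distributed tag counts per condition, and planted
#' APA dynamics, providing ground truth for every pipeline stage.
#'
#' Event classes are architecturally separated so each planted mechanism is
#' detected by exactly one caller: lengthening/shortening genes carry two
#' or more 3' UTR PACs with a distal/proximal usage shift under ST;
#' switching genes switch between a CDS PAC and a 3' UTR PAC (opposite
#' 4-fold changes); ST-specific and ST-inducible genes carry one
#' constitutive 3' UTR PAC plus coding-region PACs expressed only under ST.
#' Genes in the last three classes therefore have fewer than two 3' UTR
#' PACs and stay out of the UTR-dynamics eligible set.
#'
#' @param n_genes Number of genes (default 1000).
#' @param apa_fraction Fraction of genes with two or more poly(A) sites
#'   (default 0.5).
#' @param pacs_per_apa_gene Probability weights over 2..5 sites per APA
#'   gene.
#' @param mean_expression Median expected tag count per gene per sample;
#'   per-gene means are log-normal around it (sdlog 0.5), emulating the
#'   expression-level spread of a real library.
#' @param dispersion NB dispersion of replicate counts (default 0.01,
#'   i.e. ~10% biological CV -- the high replicate reproducibility typical
#'   of 3' tag counting in controlled growth-chamber experiments).
#' @param n_reps_per_condition Replicates per condition (default 3).
#' @param lengthen_fraction,shorten_fraction,switch_fraction,st_specific_fraction,inducible_fraction
#'   Planted event rates as fractions of all genes; their sum must not
#'   exceed `apa_fraction`.
#' @param usage_shift Usage share moved from the most proximal to the most
#'   distal 3' UTR PAC under ST for lengthening genes (reversed for
#'   shortening; default 0.2).
#' @param jitter_sd SD, in nt, of Gaussian positional noise of tag
#'   cleavage coordinates around the true site (default 5 nt, well inside
#'   the 24-nt cluster window).
#' @param ip_tract_rate Fraction of genes carrying a planted genomic
#'   A-rich tract that emits internal-priming artifact tags (default 0.1).
#'   Artifact tags sit exactly at the tract's 5' edge: the mispriming
#'   position is fixed by oligo(dT) annealing, so cleavage jitter does not
#'   apply.
#' @param no_utr3_fraction Fraction of genes whose annotation omits the
#'   3' UTR feature, exercising the extension fallback (default 0.1).
#' @param cds_site_fraction Fraction of non-event APA genes carrying one
#'   site in the CDS, intron or 5' UTR instead of the 3' UTR, populating
#'   the non-UTR rows of the region table (default 0.05).
#' @param seed Integer seed; all outputs are reproducible bit-for-bit.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 1000L, apa_fraction = 0.5,
                       pacs_per_apa_gene = c(`2` = 0.55, `3` = 0.25,
                                             `4` = 0.15, `5` = 0.05),
                       mean_expression = 100, dispersion = 0.01,
                       n_reps_per_condition = 3L,
                       lengthen_fraction = 0.10, shorten_fraction = 0.02,
                       switch_fraction = 0.03, st_specific_fraction = 0.03,
                       inducible_fraction = 0.016,
                       usage_shift = 0.2, jitter_sd = 5,
                       ip_tract_rate = 0.1, no_utr3_fraction = 0.1,
                       cds_site_fraction = 0.05, seed = 1L) {
  cfg <- as.list(environment())
  fr <- c(apa_fraction, lengthen_fraction, shorten_fraction, switch_fraction,
          st_specific_fraction, inducible_fraction, ip_tract_rate,
          no_utr3_fraction, cds_site_fraction)
  if (any(fr < 0 | fr > 1)) abort("fractions must lie in [0, 1]")
  ev <- lengthen_fraction + shorten_fraction + switch_fraction +
    st_specific_fraction + inducible_fraction
  if (ev > apa_fraction + 1e-9) {
    abort("planted event fractions sum above apa_fraction: events need >= 2 sites")
  }
  if (n_genes < 1 || n_reps_per_condition < 1) {
    abort("n_genes and n_reps_per_condition must be positive")
  }
  if (abs(sum(pacs_per_apa_gene) - 1) > 1e-9 ||
      !identical(names(pacs_per_apa_gene), c("2", "3", "4", "5"))) {
    abort("pacs_per_apa_gene must be named '2'..'5' and sum to 1")
  }
  structure(cfg, class = "sim_config")
}

# fixed locus geometry, transcription offsets from the gene 5' end:
# 5'UTR [0,100) | CDS1 [100,400) | intron [400,550) | CDS2 [550,850) |
# 3'UTR [850,1200); 200 nt 5' flank and 800 nt 3' flank per locus
sim_geom <- list(
  flank5 = 200L, locus_len = 2200L,
  utr5 = c(0L, 100L), cds1 = c(100L, 400L), intron = c(400L, 550L),
  cds2 = c(550L, 850L), utr3 = c(850L, 1200L),
  gene_len_utr = 1200L, gene_len_noutr = 850L,
  utr_slots = c(60L, 160L, 260L, 360L, 460L),
  cds_slot = 250L, intron_slot = 475L, utr5_slot = 50L,
  artifact_slot = 700L, tract_len = 12L
)

# transcription offset -> genomic 0-based position within the chromosome
sim_off2pos <- function(locus_start, strand, off) {
  n <- max(length(locus_start), length(strand), length(off))
  locus_start <- rep_len(locus_start, n)
  off <- rep_len(off, n)
  plus <- rep_len(strand == "+", n)
  as.integer(locus_start +
    ifelse(plus, sim_geom$flank5 + off,
           sim_geom$locus_len - sim_geom$flank5 - 1L - off))
}

# transcription-offset interval [a,b) -> genomic 0-based half-open interval
sim_int2span <- function(locus_start, strand, a, b) {
  s <- ifelse(strand == "+", locus_start + sim_geom$flank5 + a,
              locus_start + sim_geom$locus_len - sim_geom$flank5 - b)
  tibble(start = as.integer(s), end = as.integer(s + (b - a)))
}

#' Simulate a PAT-seq APA experiment with ground truth
#'
#' Generates a toy genome (uniform base composition except planted A-rich
#' tracts), a GFF3-style annotation, per-sample poly(A) tag sets with NB
#' replicate counts and Gaussian positional jitter, and the ground-truth
#' tables describing every planted site and event. All randomness is
#' driven by `config$seed`; two runs with the same config are identical.
#'
#' @param config A [sim_config()].
#' @param outdir Optional output directory; when given, writes
#'   `genome.fa`, `annotation.gff3`, one `tags_<sample>.bed` per sample,
#'   `samples.tsv`, `truth_genes.tsv` and `truth_sites.tsv`.
#' @return An `apa_sim` list: `config`, `genome` (DNAStringSet),
#'   `gene_models`, `design`, `tags` (all samples, artifact tags
#'   included), `truth_genes`, `truth_sites`, and `paths` when files were
#'   written.
#' @export
simulate_apa_experiment <- function(config = sim_config(), outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, sim_run(config, outdir))
}

sim_run <- function(cfg, outdir) {
  g <- sim_geom
  n <- cfg$n_genes

  n_len <- round(cfg$lengthen_fraction * n)
  n_shr <- round(cfg$shorten_fraction * n)
  n_swi <- round(cfg$switch_fraction * n)
  n_spe <- round(cfg$st_specific_fraction * n)
  n_ind <- round(cfg$inducible_fraction * n)
  n_apa <- round(cfg$apa_fraction * n)
  n_null_apa <- n_apa - (n_len + n_shr + n_swi + n_spe + n_ind)
  if (n_null_apa < 0) abort("rounding left more event genes than APA genes")
  event <- sample(c(rep("LENGTHEN", n_len), rep("SHORTEN", n_shr),
                    rep("SWITCH", n_swi), rep("SPECIFIC", n_spe),
                    rep("INDUCIBLE", n_ind), rep("NULL_APA", n_null_apa),
                    rep("SINGLE", n - n_apa)))

  per_chrom <- ceiling(n / 2)
  genes <- tibble(
    gene_id = sprintf("G%04d", seq_len(n)),
    event = event,
    chrom = rep(c("chrS1", "chrS2"), each = per_chrom)[seq_len(n)],
    locus_start = (c(seq_len(per_chrom), seq_len(n - per_chrom)) - 1L) *
      g$locus_len,
    strand = sample(c("+", "-"), n, replace = TRUE),
    gene_mean = stats::rlnorm(n, log(cfg$mean_expression), 0.5)
  )

  # sites in the 3' UTR: event classes fix their own architecture
  n_utr_sites <- integer(n)
  apa_k <- sample(2:5, n, replace = TRUE, prob = cfg$pacs_per_apa_gene)
  n_utr_sites[event %in% c("LENGTHEN", "SHORTEN", "NULL_APA")] <-
    apa_k[event %in% c("LENGTHEN", "SHORTEN", "NULL_APA")]
  n_utr_sites[event %in% c("SWITCH", "SPECIFIC", "INDUCIBLE", "SINGLE")] <- 1L

  # a minority of non-event APA genes trade one 3' UTR site for a
  # CDS/intron/5' UTR site so the region table has non-UTR rows
  aux_region <- rep(NA_character_, n)
  cand <- which(event == "NULL_APA" & n_utr_sites >= 3)
  n_aux <- min(length(cand), round(cfg$cds_site_fraction * n))
  aux <- if (n_aux > 0) sample(cand, n_aux) else integer(0)
  aux_region[aux] <- sample(c("CDS", "INTRON", "UTR5"), length(aux),
                            replace = TRUE, prob = c(0.6, 0.25, 0.15))
  n_utr_sites[aux] <- n_utr_sites[aux] - 1L

  # annotation drops the 3' UTR only where every planted UTR site still
  # falls inside the shorter fallback extension window
  max_slot <- g$utr_slots[pmax(n_utr_sites, 1L)]
  can_drop <- max_slot <= 260L
  p_drop <- min(1, cfg$no_utr3_fraction / max(mean(can_drop), 1e-9))
  genes$has_utr3 <- !(can_drop & runif(n) < p_drop)
  genes$n_utr_sites <- n_utr_sites
  genes$aux_region <- aux_region

  sites <- sim_plant_sites(genes, cfg)
  gm <- sim_gene_models(genes, cfg)
  genome <- sim_genome(genes, sites, cfg)
  design <- tibble(
    sample_id = c(paste0("CK_", seq_len(cfg$n_reps_per_condition)),
                  paste0("ST_", seq_len(cfg$n_reps_per_condition))),
    condition = rep(c("CK", "ST"), each = cfg$n_reps_per_condition),
    replicate = rep(seq_len(cfg$n_reps_per_condition), 2)
  )
  tags <- sim_tags(sites, design, cfg, chrom_lengths(genome))

  out <- list(config = cfg, genome = genome, gene_models = gm,
              design = design, tags = tags,
              truth_genes = genes |>
                select("gene_id", "event", "chrom", "strand", "locus_start",
                       "has_utr3", "n_utr_sites", "gene_mean"),
              truth_sites = sites)
  if (!is.null(outdir)) out$paths <- sim_write(out, outdir)
  structure(out, class = "apa_sim")
}

#' @export
print.apa_sim <- function(x, ...) {
  cat("<apa_sim> ", nrow(x$truth_genes), " genes, ",
      sum(!x$truth_sites$is_artifact), " true sites, ",
      sum(x$truth_sites$is_artifact), " artifact sites, ",
      nrow(x$tags), " tags across ", nrow(x$design), " samples\n", sep = "")
  invisible(x)
}

# plant true and artifact sites with per-condition expected counts
sim_plant_sites <- function(genes, cfg) {
  g <- sim_geom
  rows <- purrr::map(seq_len(nrow(genes)), function(i) {
    gn <- genes[i, ]
    k <- gn$n_utr_sites
    slots <- if (gn$event == "SINGLE") g$utr_slots[sample(1:3, 1)] else
      g$utr_slots[seq_len(k)]
    utr <- tibble(region = "UTR3", offset = g$utr3[1] + slots - 1L,
                  utr_length = slots, st_only = FALSE)
    extra <- switch(gn$event,
      SWITCH = tibble(region = "CDS", offset = g$cds_slot,
                      utr_length = NA_integer_, st_only = FALSE),
      SPECIFIC = tibble(region = "CDS", offset = g$cds_slot,
                        utr_length = NA_integer_, st_only = TRUE),
      INDUCIBLE = {
        m <- sample(1:3, 1)
        reg <- c("CDS", "INTRON", "UTR5")[seq_len(m)]
        off <- c(g$cds_slot, g$intron_slot, g$utr5_slot)[seq_len(m)]
        tibble(region = reg, offset = off, utr_length = NA_integer_,
               st_only = TRUE)
      },
      NULL_APA = if (!is.na(gn$aux_region)) {
        off <- switch(gn$aux_region, CDS = g$cds_slot,
                      INTRON = g$intron_slot, UTR5 = g$utr5_slot)
        tibble(region = gn$aux_region, offset = off,
               utr_length = NA_integer_, st_only = FALSE)
      } else NULL,
      NULL)
    st <- bind_rows(utr, extra)

    # usage shares / expected per-sample counts per condition
    kk <- nrow(st)
    base <- runif(kk, 0.5, 1.5); base[st$st_only] <- 0
    share_ck <- base / sum(base)
    share_st <- share_ck
    if (gn$event %in% c("LENGTHEN", "SHORTEN")) {
      iu <- which(st$region == "UTR3")
      prox <- iu[which.min(st$utr_length[iu])]
      dist <- iu[which.max(st$utr_length[iu])]
      from <- if (gn$event == "LENGTHEN") prox else dist
      to <- if (gn$event == "LENGTHEN") dist else prox
      moved <- min(cfg$usage_shift, share_ck[from] - 0.02)
      share_st[from] <- share_ck[from] - moved
      share_st[to] <- share_ck[to] + moved
    }
    mu_ck <- gn$gene_mean * share_ck
    mu_st <- gn$gene_mean * share_st
    if (gn$event == "SWITCH") {
      up <- sample(1:2, 1)  # which of (UTR3, CDS) rises 4-fold under ST
      mu_st <- mu_ck * ifelse(seq_len(kk) == up, 4, 0.25)
    }
    if (gn$event == "SPECIFIC") mu_st[st$st_only] <- 0.4 * gn$gene_mean
    if (gn$event == "INDUCIBLE") mu_st[st$st_only] <- 0.3 * gn$gene_mean

    st |>
      mutate(gene_id = gn$gene_id, chrom = gn$chrom, strand = gn$strand,
             pos = sim_off2pos(gn$locus_start, gn$strand, .data$offset),
             mu_ck = mu_ck, mu_st = mu_st, is_artifact = FALSE,
             .before = 1)
  })
  sites <- purrr::list_rbind(rows)

  # planted internal-priming artifacts: one A-tract mid-CDS2 per chosen gene
  art_idx <- which(runif(nrow(genes)) < cfg$ip_tract_rate)
  art <- genes[art_idx, ] |>
    mutate(pos = sim_off2pos(.data$locus_start, .data$strand, sim_geom$artifact_slot)) |>
    transmute(gene_id = .data$gene_id, chrom = .data$chrom,
              strand = .data$strand, pos = .data$pos, region = "ARTIFACT",
              offset = sim_geom$artifact_slot, utr_length = NA_integer_,
              st_only = FALSE, mu_ck = 0.3 * .data$gene_mean,
              mu_st = 0.3 * .data$gene_mean, is_artifact = TRUE)
  sites <- bind_rows(sites, art)
  sites$site_id <- sprintf("S%05d", seq_len(nrow(sites)))
  sites
}

# gene models equivalent to what read_annotation() builds from the GFF3
sim_gene_models <- function(genes, cfg) {
  g <- sim_geom
  gene_len <- ifelse(genes$has_utr3, g$gene_len_utr, g$gene_len_noutr)
  span <- sim_int2span(genes$locus_start, genes$strand, 0L, gene_len)
  anchor_off <- g$utr3[1]
  gtab <- genes |>
    mutate(start = span$start, end = span$end,
           utr3_anchor = sim_off2pos(.data$locus_start, .data$strand,
                                     anchor_off)) |>
    select("gene_id", "chrom", "strand", "start", "end", "has_utr3",
           "utr3_anchor")

  region_span <- function(int, keep = rep(TRUE, nrow(genes)), label) {
    sp <- sim_int2span(genes$locus_start, genes$strand, int[1], int[2])
    tibble(gene_id = genes$gene_id, chrom = genes$chrom,
           strand = genes$strand, region = label,
           start = sp$start, end = sp$end)[keep, ]
  }
  ext_len <- ifelse(genes$has_utr3, 200L, 418L)
  ext_from <- ifelse(genes$has_utr3, g$utr3[2], g$utr3[1])
  ext_sp <- sim_int2span(genes$locus_start, genes$strand, ext_from,
                         ext_from + ext_len)
  regions <- bind_rows(
    region_span(g$utr5, label = "UTR5"),
    region_span(g$cds1, label = "CDS"),
    region_span(g$intron, label = "INTRON"),
    region_span(g$cds2, label = "CDS"),
    region_span(g$utr3, genes$has_utr3, "UTR3"),
    tibble(gene_id = genes$gene_id, chrom = genes$chrom,
           strand = genes$strand, region = "EXTENDED_UTR3",
           start = ext_sp$start, end = ext_sp$end)
  ) |> arrange(.data$gene_id, .data$start)
  structure(list(genes = gtab, regions = regions, ext_bp = 200L,
                 fallback_bp = 218L), class = "gene_models")
}

# uniform-composition genome with A-rich tracts written downstream of
# artifact positions (sense-strand A = forward T for minus-strand genes)
sim_genome <- function(genes, sites, cfg) {
  g <- sim_geom
  seqs <- purrr::map(split(genes, genes$chrom), function(gc) {
    len <- max(gc$locus_start) + g$locus_len
    base <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    art <- sites |> filter(.data$is_artifact, .data$chrom == gc$chrom[1])
    for (i in seq_len(nrow(art))) {
      p <- art$pos[i]
      if (art$strand[i] == "+") {
        base[(p + 2):(p + 1 + g$tract_len)] <- "A"
      } else {
        base[(p - g$tract_len + 1):p] <- "T"
      }
    }
    paste(base, collapse = "")
  })
  Biostrings::DNAStringSet(unlist(seqs))
}

# NB replicate counts per site x sample, then jittered tag positions
sim_tags <- function(sites, design, cfg, chrom_len) {
  grid <- tidyr::expand_grid(site = seq_len(nrow(sites)),
                             sample = seq_len(nrow(design)))
  mu <- ifelse(design$condition[grid$sample] == "ST",
               sites$mu_st[grid$site], sites$mu_ck[grid$site])
  nn <- rnbinom(nrow(grid), mu = mu, size = 1 / cfg$dispersion)
  idx <- rep(seq_len(nrow(grid)), nn)
  site_i <- grid$site[idx]
  jitter <- ifelse(sites$is_artifact[site_i], 0L,
                   as.integer(round(rnorm(length(idx), 0, cfg$jitter_sd))))
  pos <- sites$pos[site_i] + jitter
  lim <- unname(chrom_len[sites$chrom[site_i]]) - 1L
  tibble(chrom = sites$chrom[site_i],
         pos = pmax(0L, pmin(pos, lim)),
         strand = sites$strand[site_i],
         sample_id = design$sample_id[grid$sample[idx]])
}

sim_write <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    genome = file.path(outdir, "genome.fa"),
    gff3 = file.path(outdir, "annotation.gff3"),
    samples = file.path(outdir, "samples.tsv"),
    truth_genes = file.path(outdir, "truth_genes.tsv"),
    truth_sites = file.path(outdir, "truth_sites.tsv")
  )
  Biostrings::writeXStringSet(sim$genome, paths$genome, width = 80L)
  sim_write_gff3(sim, paths$gff3)
  design <- sim$design |>
    mutate(path = paste0("tags_", .data$sample_id, ".bed"))
  for (s in design$sample_id) {
    tg <- sim$tags |> filter(.data$sample_id == s)
    bed <- tibble(chrom = tg$chrom, start = tg$pos, end = tg$pos + 1L,
                  name = ".", score = 0L, strand = tg$strand) |>
      arrange(.data$chrom, .data$start)
    readr::write_tsv(bed, file.path(outdir, paste0("tags_", s, ".bed")),
                     col_names = FALSE)
  }
  readr::write_tsv(design |> select("sample_id", "path", "condition",
                                    "replicate"), paths$samples)
  readr::write_tsv(sim$truth_genes, paths$truth_genes)
  readr::write_tsv(sim$truth_sites, paths$truth_sites)
  paths$tags <- file.path(outdir, design$path)
  paths
}

# minimal but standard-conforming GFF3 (1-based closed coordinates)
sim_write_gff3 <- function(sim, path) {
  g <- sim_geom
  genes <- sim$truth_genes
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(genes))) {
    gn <- genes[i, ]
    gene_len <- if (gn$has_utr3) g$gene_len_utr else g$gene_len_noutr
    span <- function(a, b) sim_int2span(gn$locus_start, gn$strand, a, b)
    feat <- function(type, sp, attr) {
      sprintf("%s\tsim\t%s\t%d\t%d\t.\t%s\t.\t%s",
              gn$chrom, type, sp$start + 1L, sp$end, gn$strand, attr)
    }
    gid <- gn$gene_id; tid <- paste0(gid, ".1")
    parts <- c(
      feat("gene", span(0L, gene_len), paste0("ID=", gid)),
      feat("mRNA", span(0L, gene_len), paste0("ID=", tid, ";Parent=", gid)),
      feat("exon", span(0L, g$intron[1]), paste0("ID=", tid, ".e1;Parent=", tid)),
      feat("exon", span(g$intron[2], gene_len), paste0("ID=", tid, ".e2;Parent=", tid)),
      feat("five_prime_UTR", span(g$utr5[1], g$utr5[2]),
           paste0("ID=", tid, ".u5;Parent=", tid)),
      feat("CDS", span(g$cds1[1], g$cds1[2]), paste0("ID=", tid, ".c1;Parent=", tid)),
      feat("CDS", span(g$cds2[1], g$cds2[2]), paste0("ID=", tid, ".c2;Parent=", tid)),
      if (gn$has_utr3) feat("three_prime_UTR", span(g$utr3[1], g$utr3[2]),
                            paste0("ID=", tid, ".u3;Parent=", tid))
    )
    lines <- c(lines, parts)
  }
  writeLines(lines, path)
}
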