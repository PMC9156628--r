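# Generators: structural guarantees, determinism, truth-label
# soundness, and calibration of the planted rates.

test_that("minimal gene is start + stop", {
  cfg <- sim_config(n_genes = 1, gene_length_codons = 2, seed = 5,
                    n_chromosomes = 1, chrom_length_bp = 1e5,
                    markers_per_chromosome = 5)
  sq <- gen_gene_sequences(cfg)
  expect_equal(nchar(sq$cds[[1]]), 6)
  expect_equal(substr(sq$cds[[1]], 1, 3), "ATG")
  expect_true(substr(sq$cds[[1]], 4, 6) %in% haplosel:::stop_codons())
})

test_that("generated CDS are structurally valid and deterministic", {
  cfg <- small_cfg(n_genes = 100, seed = 7)
  cfg$gene_length_codons <- c(100, 100)
  sq <- gen_gene_sequences(cfg)
  expect_length(sq$cds, 100)
  expect_true(all(nchar(sq$cds) == 300))
  stops <- haplosel:::stop_codons()
  for (s in sq$cds) {
    codons <- haplosel:::codon_split(s)
    expect_equal(substr(s, 1, 3), "ATG")
    expect_true(codons[length(codons)] %in% stops)
    expect_false(any(codons[-length(codons)] %in% stops))
  }
  # byte-identical FASTA on re-run
  t1 <- withr::local_tempfile(); t2 <- withr::local_tempfile()
  write_fasta(gen_gene_sequences(cfg)$cds, t1)
  write_fasta(gen_gene_sequences(cfg)$cds, t2)
  expect_identical(readLines(t1), readLines(t2))
  expect_error(sim_config(gene_length_codons = 1),
               class = "haplosel_config_error")
})

test_that("zero rates give empty variant tables", {
  cfg <- small_cfg(n_genes = 10, theta_s = 0, div_s = 0)
  sq <- gen_gene_sequences(cfg)
  vd <- gen_variant_data(cfg, sq)
  expect_equal(nrow(vd$variants), 0)
  expect_equal(nrow(vd$outgroup), 0)
  expect_true(all(vd$truth$genes[, c("ps", "pn", "ds", "dn")] == 0))
})

test_that("omega_poly = 0 plants only synonymous polymorphisms", {
  cfg <- small_cfg(n_genes = 30, div_s = 0,
                   class_params = data.frame(
                     class = c("haploid_biased", "diploid_biased",
                               "constitutive", "unclassified"),
                     omega_poly = 0, omega_div = 0,
                     stringsAsFactors = FALSE))
  sq <- gen_gene_sequences(cfg)
  vd <- gen_variant_data(cfg, sq)
  tv <- vd$truth$variants
  expect_true(all(tv$effect == "synonymous"))
  # re-classify each against the codon table
  for (i in seq_len(nrow(tv))) {
    g <- sq$genes[sq$genes$gene_id == tv$gene_id[i], ]
    ctx <- extract_codon_context(g, sq$cds[[tv$gene_id[i]]], tv$pos[i],
                                 tv$ref[i], tv$alt[i])
    expect_identical(classify_change(ctx$codon, ctx$offset, ctx$alt),
                     "synonymous")
  }
})

test_that("every planted effect label is sound under re-classification", {
  cfg <- small_cfg(n_genes = 120, seed = 11)
  sq <- gen_gene_sequences(cfg)
  vd <- gen_variant_data(cfg, sq)
  tv <- vd$truth$variants
  expect_gt(nrow(tv), 500)
  mism <- 0
  for (i in seq_len(nrow(tv))) {
    g <- sq$genes[sq$genes$gene_id == tv$gene_id[i], ]
    ctx <- extract_codon_context(g, sq$cds[[tv$gene_id[i]]], tv$pos[i],
                                 tv$ref[i], tv$alt[i])
    if (classify_change(ctx$codon, ctx$offset, ctx$alt) != tv$effect[i])
      mism <- mism + 1
  }
  expect_equal(mism, 0)
  # no site carries more than one event
  expect_false(any(duplicated(paste(tv$chrom, tv$pos))))
  # determinism of the whole variant set
  vd2 <- gen_variant_data(cfg, sq)
  expect_identical(vd$variants, vd2$variants)
  expect_identical(vd$outgroup, vd2$outgroup)
})

test_that("allele frequencies follow the 1/i neutral spectrum", {
  cfg <- sim_config(n_genes = 400, gene_length_codons = c(200, 200),
                    theta_s = 0.05, div_s = 0, seed = 13,
                    n_chromosomes = 4, markers_per_chromosome = 10,
                    chrom_length_bp = 5e6)
  sq <- gen_gene_sequences(cfg)
  vd <- gen_variant_data(cfg, sq)
  ac <- vd$truth$variants$ac
  ac <- ac[!is.na(ac)]
  expect_gt(length(ac), 1e4)
  n <- cfg$n_chromosomes_sampled
  p_exp <- (1 / seq_len(n - 1)) / sum(1 / seq_len(n - 1))
  obs <- tabulate(ac, n - 1)
  gof <- suppressWarnings(stats::chisq.test(obs, p = p_exp))
  expect_gt(gof$p.value, 0.001)
})

test_that("planted polymorphism ratio recovers omega_poly", {
  cfg <- sim_config(n_genes = 500, gene_length_codons = c(100, 500),
                    theta_s = 0.02, div_s = 0, seed = 17,
                    n_chromosomes = 4, markers_per_chromosome = 10,
                    chrom_length_bp = 2e7,
                    class_params = data.frame(
                      class = c("haploid_biased", "diploid_biased",
                                "constitutive", "unclassified"),
                      omega_poly = 0.5, omega_div = 0.5,
                      stringsAsFactors = FALSE))
  sq <- gen_gene_sequences(cfg)
  vd <- gen_variant_data(cfg, sq)
  tg <- vd$truth$genes
  # aggregate ratio of planted counts, rescaled by site totals
  omega_hat <- (sum(tg$pn) / sum(tg$ps)) * (sum(tg$Ls) / sum(tg$Ln))
  se_rel <- sqrt(1 / sum(tg$pn) + 1 / sum(tg$ps))
  expect_lt(abs(omega_hat - 0.5), 3 * se_rel * 0.5)
})

test_that("gene without synonymous sites warns and is skipped", {
  cfg <- small_cfg(n_genes = 1, theta_s = 0.5, div_s = 0)
  seqgen <- list(cds = c(gX = "ATGTGGTAA"),
                 genes = data.frame(gene_id = "gX", chrom = "chr1",
                                    start = 1L, end = 9L, strand = "+",
                                    stringsAsFactors = FALSE))
  seqgen$genes$cds <- list(cbind(start = 1L, end = 9L))
  cfg$class_assignments <- "unclassified"
  expect_warning(gen_variant_data(cfg, seqgen), "no synonymous sites")
})

test_that("expression counts are deterministic with planted bias", {
  cfg <- small_cfg(n_genes = 200, seed = 19)
  ex1 <- gen_expression_counts(cfg)
  ex2 <- gen_expression_counts(cfg)
  expect_identical(ex1$counts, ex2$counts)
  expect_true(all(ex1$counts >= 0))
  validate_sample_meta(ex1$meta)
  # planted male-biased genes have larger male/female group-mean ratio
  # than unplanted genes in the tissue they were planted in
  tr <- ex1$truth
  planted <- tr$gene_id[tr$class == "haploid_biased" & nzchar(tr$pattern)]
  expect_gt(length(planted), 5)
  meta <- ex1$meta
  hits <- 0
  for (g in planted) {
    pat <- tr$pattern[tr$gene_id == g]
    tis <- sub("^male_", "", pat)
    male <- mean(ex1$counts[g, meta$sex == "male" & meta$tissue == tis])
    female <- mean(ex1$counts[g, meta$sex == "female" & meta$tissue == tis])
    null_ratio <- stats::median(
      rowMeans(ex1$counts[tr$class == "unclassified",
                          meta$sex == "male" & meta$tissue == tis]) /
      (rowMeans(ex1$counts[tr$class == "unclassified",
                           meta$sex == "female" & meta$tissue == tis]) + 1))
    if ((male + 1) / (female + 1) > null_ratio) hits <- hits + 1
  }
  expect_gte(hits / length(planted), 0.95)
})

test_that("fold = 1 plants no bias", {
  cfg <- small_cfg(n_genes = 20, expr = list(fold = 1))
  ex <- gen_expression_counts(cfg)
  expect_true(all(ex$truth$pattern == ""))
  expect_true(all(ex$truth$fold == 1))
})

test_that("linkage maps are valid, sized, and linear when asked", {
  cfg <- sim_config(n_genes = 10, n_chromosomes = 16,
                    markers_per_chromosome = 125, seed = 23)
  lmap <- gen_linkage_map(cfg)
  expect_equal(nrow(lmap), 2000)
  expect_silent(validate_linkage_map(lmap))
  cfg2 <- small_cfg(n_genes = 5, recomb_constant = TRUE,
                    recomb_rate_cM_per_Mb = 23)
  lm2 <- gen_linkage_map(cfg2)
  for (ch in unique(lm2$chrom)) {
    sub <- lm2[lm2$chrom == ch, ]
    slope <- diff(sub$cM) / diff(sub$bp) * 1e6
    expect_true(all(abs(slope - 23) < 1e-9))
  }
})

test_that("simulate_all writes a complete, re-readable input set", {
  dir <- withr::local_tempdir()
  cfg <- small_cfg(n_genes = 25, seed = 29)
  sim <- simulate_all(cfg, dir = dir)
  expect_true(all(file.exists(unlist(sim$paths))))
  back <- read_vcf(sim$paths$vcf)
  expect_equal(nrow(back), nrow(sim$variants))
  ord <- order(sim$variants$chrom, sim$variants$pos)
  expect_equal(back$pos, sim$variants$pos[ord])
  expect_equal(back$ac, sim$variants$ac[ord])
  expect_identical(read_fasta(sim$paths$fasta), sim$cds)
})
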