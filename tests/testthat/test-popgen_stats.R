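# Diversity, divergence counting, and the brute-force oracle.

test_that("site_pi matches the unbiased pairwise formula", {
  expect_equal(site_pi(1, 2), 1)
  expect_equal(site_pi(0, 22), 0)
  expect_equal(site_pi(22, 22), 0)
  expect_equal(site_pi(11, 22), (22 / 21) * 0.5)
  # oracle: average difference over all C(22,2) sequence pairs
  alleles <- c(rep(1, 11), rep(0, 11))
  diffs <- outer(alleles, alleles, "!=")
  mean_pair <- sum(diffs[upper.tri(diffs)]) / choose(22, 2)
  expect_equal(site_pi(11, 22), mean_pair)
  expect_error(site_pi(1, 1))
  expect_error(site_pi(5, 4))
})

test_that("gene_pi applies the MAF filter and handles edge cases", {
  expect_equal(gene_pi(data.frame(ac = integer(0), an = integer(0),
                                  effect = character(0)), 10, 20),
               list(piS = 0, piNS = 0))
  v <- data.frame(ac = 1, an = 110, effect = "synonymous")
  expect_equal(gene_pi(v, 10, 20)$piS, 0)  # p = 1/110 <= 0.01 excluded
  v <- data.frame(ac = c(5, 3), an = 22, effect = c("synonymous",
                                                    "nonsynonymous"))
  res <- gene_pi(v, 10, 20)
  expect_equal(res$piS, site_pi(5, 22) / 10)
  expect_equal(res$piNS, site_pi(3, 22) / 20)
  expect_error(gene_pi(data.frame(ac = 1, an = 22, effect = "weird"),
                       10, 20))
})

test_that("gene_pi equals brute-force pairwise differences on toys", {
  # 5-codon gene, 6 sampled sequences, several variants
  cds <- "ATGAAATTTCCCTAA"
  sites <- gene_site_counts(cds)
  set.seed(99)
  for (rep in 1:10) {
    n <- 6
    k <- sample(2:4, 1)
    pos <- sample(4:12, k)  # skip ATG start and the stop codon
    vars <- lapply(pos, function(p) {
      ci <- (p - 1) %/% 3 + 1
      off <- (p - 1) %% 3
      codon <- substr(cds, (ci - 1) * 3 + 1, ci * 3)
      refb <- substr(cds, p, p)
      alt <- sample(setdiff(c("A", "C", "G", "T"), refb), 1)
      ac <- sample(1:(n - 1), 1)
      data.frame(pos = p, ac = ac, an = n,
                 effect = classify_change(codon, off, alt),
                 stringsAsFactors = FALSE)
    })
    vars <- do.call(rbind, vars)
    res <- gene_pi(vars, sites$Ls, sites$Ln, maf_min = 0)
    # oracle: build explicit haplotypes and average pairwise differences
    hap <- matrix(0L, n, nrow(vars))
    for (j in seq_len(nrow(vars)))
      hap[sample(n, vars$ac[j]), j] <- 1L
    bf <- brute_force_pi(hap, vars$effect, sites$Ls, sites$Ln)
    # brute force uses realised (biased) pair counts; rescale to the
    # unbiased estimator by n/(n-1) per site identity:
    # site_pi = 2p q n/(n-1) while mean pairwise = 2 p q n/(n-1) too
    expect_equal(res$piS, bf$piS, tolerance = 1e-12)
    expect_equal(res$piNS, bf$piNS, tolerance = 1e-12)
  }
})

test_that("MAF filter is monotone", {
  set.seed(7)
  v <- data.frame(ac = sample(1:21, 40, replace = TRUE), an = 22,
                  effect = sample(c("synonymous", "nonsynonymous"), 40,
                                  replace = TRUE))
  prev_s <- Inf; prev_n <- Inf
  for (maf in c(0, 0.05, 0.1, 0.2, 0.4)) {
    res <- gene_pi(v, 10, 30, maf_min = maf)
    expect_lte(res$piS, prev_s)
    expect_lte(res$piNS, prev_n)
    prev_s <- res$piS; prev_n <- res$piNS
  }
})

test_that("count_divergence follows the definitions", {
  g <- data.frame(gene_id = "g1", chrom = "c", start = 1L, end = 9L,
                  strand = "+", stringsAsFactors = FALSE)
  g$cds <- list(cbind(start = 1L, end = 9L))
  cds <- "ATGCCATAA"
  # outgroup differs at pos 6 (CCA -> CCG, Pro -> Pro): Ds = 1
  og <- data.frame(chrom = "c", pos = 6L, allele = "G")
  novar <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      ac = integer(0), an = integer(0))
  dv <- count_divergence(novar, og, g, cds)
  expect_equal(dv$Ds, 1)
  expect_equal(dv$Dn, 0)
  # a polymorphic site never contributes to D
  v <- data.frame(chrom = "c", pos = 6L, ref = "A", alt = "G",
                  ac = 5L, an = 22L, stringsAsFactors = FALSE)
  dv <- count_divergence(v, og, g, cds)
  expect_equal(dv$Ds + dv$Dn, 0)
  # ingroup-fixed alt with outgroup ancestral: divergence on the
  # ingroup branch, classified in the ingroup codon context
  v <- data.frame(chrom = "c", pos = 5L, ref = "C", alt = "A",
                  ac = 22L, an = 22L, stringsAsFactors = FALSE)
  og2 <- data.frame(chrom = "c", pos = 5L, allele = "C")
  dv <- count_divergence(v, og2, g, cds)
  expect_equal(dv$Dn, 1)  # CCA -> CAA is Pro -> Gln
  expect_equal(dv$Ds, 0)
  # fixed alt without an outgroup call is skipped and logged
  empty_og <- data.frame(chrom = character(0), pos = integer(0),
                         allele = character(0))
  dv <- count_divergence(v, empty_og, g, cds)
  expect_equal(dv$skipped, 1)
  expect_equal(dv$Dn + dv$Ds, 0)
})

test_that("planted divergence is recovered exactly from the truth table", {
  cfg <- small_cfg(n_genes = 40, seed = 31)
  sim <- simulate_all(cfg)
  gt <- popgen_gene_table(sim$cds, sim$genes, sim$variants, sim$outgroup)
  tg <- sim$truth$genes[match(gt$gene_id, sim$truth$genes$gene_id), ]
  expect_equal(gt$Dn, tg$dn)
  expect_equal(gt$Ds, tg$ds)
  expect_equal(gt$Pn, tg$pn)
  expect_equal(gt$Ps, tg$ps)
  expect_equal(gt$Ls, tg$Ls)
  expect_equal(gt$Ln, tg$Ln)
})

test_that("mean piS recovers theta_s within Monte-Carlo error", {
  cfg <- sim_config(n_genes = 500, gene_length_codons = c(100, 500),
                    theta_s = 0.02, div_s = 0, seed = 37,
                    n_chromosomes = 4, markers_per_chromosome = 10,
                    chrom_length_bp = 2e7)
  sq <- gen_gene_sequences(cfg)
  vd <- gen_variant_data(cfg, sq)
  gt <- popgen_gene_table(sq$cds, sq$genes, vd$variants, vd$outgroup)
  pis <- gt$piS[!is.na(gt$piS)]
  se <- stats::sd(pis) / sqrt(length(pis))
  expect_lt(abs(mean(pis) - 0.02), 3 * se)
})

test_that("annotate_variants flags non-coding and handles strand", {
  genes <- toy_genes()
  cds <- toy_cds()
  v <- data.frame(chrom = "chrA",
                  pos = c(4L, 50L, 115L),
                  ref = c("A", "T", "T"), alt = c("G", "C", "C"),
                  ac = c(3L, 3L, 3L), an = 22L, stringsAsFactors = FALSE)
  ann <- annotate_variants(v, genes, cds)
  expect_true(ann$coding[1])
  expect_false(ann$coding[2])
  expect_true(ann$coding[3])
  expect_equal(ann$gene_id[3], "gminus")
  expect_equal(ann$codon[3], "ATG")  # minus-strand codon
  expect_equal(ann$effect[3], "nonsynonymous")
})
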