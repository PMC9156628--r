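# Low-count filtering, normalization, pairwise tests, BH, and the
# classification logic.

test_that("filter_low_counts keeps genes with row sum >= threshold", {
  m <- matrix(c(0, 0, 4, 5, 5, 5, 6, 5, 50, 50), 5, 2, byrow = TRUE,
              dimnames = list(paste0("g", 1:5), c("a", "b")))
  # row sums 0, 9, 10, 11, 100
  expect_equal(rownames(filter_low_counts(m, 10)), c("g3", "g4", "g5"))
  expect_equal(filter_low_counts(m, 0), m)
  expect_warning(filter_low_counts(m, 1e6), "no genes")
})

test_that("median-of-ratios normalization has the stated symmetries", {
  m <- matrix(c(10, 10, 20, 20, 40, 40), 3, 2, byrow = TRUE)
  nm <- normalize_median_of_ratios(m)
  expect_equal(unname(nm$size_factors), c(1, 1))
  # sample B = 2 x sample A: factors in ratio 2, normalized equal
  m2 <- cbind(a = c(10, 20, 40), b = c(20, 40, 80))
  nm2 <- normalize_median_of_ratios(m2)
  expect_equal(nm2$size_factors[["b"]] / nm2$size_factors[["a"]], 2)
  expect_equal(nm2$normalized[, "a"], nm2$normalized[, "b"])
  # scale equivariance: multiplying one sample by c is absorbed by the
  # size factors, leaving relative expression unchanged (the normalized
  # matrix is recovered up to a single global rescaling)
  m3 <- m2; m3[, 2] <- m3[, 2] * 7
  nm3 <- normalize_median_of_ratios(m3)
  expect_equal(nm3$normalized / nm3$normalized[1, 1],
               nm2$normalized / nm2$normalized[1, 1])
  expect_equal(nm3$size_factors[["b"]] / nm3$size_factors[["a"]], 14)
  expect_error(normalize_median_of_ratios(matrix(c(0, 1, 1, 0), 2, 2)))
})

test_that("test_upregulation computes Welch tests on the log scale", {
  mA <- matrix(rep(c(10, 20, 40), 2), 3, 2)
  de <- test_upregulation(mA, mA)
  expect_equal(de$log2fc, rep(0, 3))
  expect_equal(de$p, rep(1, 3))
  mB <- matrix(0, 1, 2)
  de <- test_upregulation(matrix(100, 1, 2), mB)
  expect_equal(de$log2fc, log2(101))
  expect_error(test_upregulation(matrix(1, 2, 1), matrix(1, 2, 2)))
})

test_that("null simulation keeps the q < 0.01 fraction near nominal", {
  set.seed(123)
  frac <- replicate(3, {
    m <- matrix(rnbinom(2000 * 10, mu = 100, size = 10), 2000, 10)
    de <- test_upregulation(m[, 1:5], m[, 6:10])
    mean(de$q < 0.01)
  })
  expect_lt(mean(frac), 0.01 + 3 * sqrt(0.01 * 0.99 / 6000))
})

test_that("bh_fdr matches hand computation and p.adjust", {
  expect_equal(bh_fdr(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_fdr(c(0.5, 1.2)))
  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(1:200, 1))
    expect_equal(bh_fdr(p), stats::p.adjust(p, method = "BH"))
  }
  # step-up monotonicity in p-rank
  p <- runif(100)
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_equal(q[which.max(p)], max(p))  # rank-m element: q = p
})

make_de <- function(gene_id, focal, other, lfc, q) {
  data.frame(gene_id = gene_id, comparison = paste0(focal, "_vs_", other),
             focal = focal, other = other, log2fc = lfc, p = q, q = q,
             stringsAsFactors = FALSE)
}

adult_groups <- function() {
  data.frame(group = c("male_gonad", "male_soma", "female_gonad",
                       "female_soma"),
             sex = c("male", "male", "female", "female"),
             tissue = c("gonad", "soma", "gonad", "soma"),
             stringsAsFactors = FALSE)
}

test_that("classification logic follows the pairwise up-regulation rule", {
  # gene up in male_gonad in both required comparisons -> haploid_biased
  de <- rbind(
    make_de("g1", "male_gonad", "female_gonad", 2, 0.001),
    make_de("g1", "male_soma", "female_soma", 0, 0.9),
    make_de("g1", "male_gonad", "male_soma", 2, 0.001),
    make_de("g1", "female_gonad", "female_soma", 0, 0.9))
  cls <- classify_genes(de, adult_groups(), alpha = 0.01)
  expect_equal(cls$label, "haploid_biased")
  expect_equal(cls$tissue_sets, "male_gonad")
  # q = 0.02 everywhere at alpha 0.01 -> unclassified
  de$q <- 0.02
  cls <- classify_genes(de, adult_groups(), alpha = 0.01)
  expect_equal(cls$label, "unclassified")
  # up-regulated in male_gonad and female_soma -> constitutive
  de <- rbind(
    make_de("g1", "male_gonad", "female_gonad", 2, 0.001),
    make_de("g1", "male_soma", "female_soma", -2, 0.001),
    make_de("g1", "male_gonad", "male_soma", 2, 0.001),
    make_de("g1", "female_gonad", "female_soma", -2, 0.001))
  cls <- classify_genes(de, adult_groups(), alpha = 0.01)
  expect_equal(cls$label, "constitutive")
  expect_setequal(strsplit(cls$tissue_sets, ",")[[1]],
                  c("male_gonad", "female_soma"))
  # missing comparison is a configuration error
  expect_error(classify_genes(de[-1, ], adult_groups()),
               class = "haplosel_config_error")
})

test_that("merging datasets resolves conflicts to unclassified", {
  a <- data.frame(gene_id = c("g1", "g2"),
                  label = c("haploid_biased", "haploid_biased"),
                  tissue_sets = c("male_gonad", "male_gonad"),
                  stringsAsFactors = FALSE)
  b <- data.frame(gene_id = c("g1", "g2"),
                  label = c("diploid_biased", "unclassified"),
                  tissue_sets = c("female_larva", ""),
                  stringsAsFactors = FALSE)
  expect_warning(m <- merge_classifications(a, b), "conflict")
  expect_equal(m$label[m$gene_id == "g1"], "unclassified")
  expect_equal(m$label[m$gene_id == "g2"], "haploid_biased")
})

test_that("intersection counts partition the classified genes", {
  cls <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                    label = c("haploid_biased", "haploid_biased",
                              "constitutive", "unclassified"),
                    tissue_sets = c("male_gonad", "male_gonad",
                                    "female_soma,male_gonad", ""),
                    stringsAsFactors = FALSE)
  ic <- intersection_counts(cls)
  expect_equal(sum(ic$n), 3)
  expect_equal(ic$n[ic$combination == "male_gonad"], 2)
  expect_equal(ic$n[ic$combination == "female_soma,male_gonad"], 1)
  empty <- intersection_counts(cls[cls$label == "nope", ])
  expect_equal(nrow(empty), 0)
})

test_that("planted expression classes are recovered on synthetic data", {
  cfg <- small_cfg(n_genes = 600, seed = 101)
  ex <- gen_expression_counts(cfg)
  res <- classify_expression(ex$counts, ex$meta, alpha = 0.01)
  tr <- ex$truth
  m <- merge(res$classification, tr, by = "gene_id")
  # every gene gets exactly one label
  expect_equal(nrow(m), cfg$n_genes)
  expect_true(all(m$label %in% c("haploid_biased", "diploid_biased",
                                 "constitutive", "unclassified")))
  planted_h <- m[m$class == "haploid_biased", ]
  sens <- mean(planted_h$label == "haploid_biased")
  expect_gte(sens, 0.9)
  # cross-sex mislabeling is rare
  expect_lte(sum(planted_h$label == "diploid_biased"),
             max(1, 0.05 * nrow(planted_h)))
  planted_c <- m[m$class == "constitutive", ]
  expect_gte(mean(planted_c$label == "constitutive"), 0.8)
})

test_that("a null expression matrix yields almost no biased calls", {
  fracs <- vapply(c(7, 8, 9), function(s) {
    cfg <- small_cfg(n_genes = 400, seed = s, expr = list(fold = 1))
    ex <- gen_expression_counts(cfg)
    res <- classify_expression(ex$counts, ex$meta, alpha = 0.01)
    mean(res$classification$label == "haploid_biased")
  }, numeric(1))
  expect_lte(mean(fracs), 0.01 + 3 * sqrt(0.01 * 0.99 / 1200))
})
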