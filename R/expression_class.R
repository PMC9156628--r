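# Sex-/tissue-biased expression classification: low-count filtering,
# median-of-ratios normalization, pairwise Welch tests on log2
# normalized counts with Benjamini-Hochberg FDR within each comparison,
# and the pairwise up-regulation logic that labels genes haploid-biased
# (male), diploid-biased (female), constitutive (up-regulated in both
# sexes) or unclassified.

#' Remove genes with low total counts
#' @param m count matrix (genes x samples)
#' @param min_total keep genes with row sum >= min_total (default 10,
#'   i.e. drop genes with fewer than ten reads across all samples)
#' @return filtered matrix
#' @export
filter_low_counts <- function(m, min_total = 10) {
  if (min_total < 0) hs_error("min_total must be >= 0")
  keep <- rowSums(m) >= min_total
  if (!any(keep)) warning("no genes pass the low-count filter")
  m[keep, , drop = FALSE]
}

#' Median-of-ratios size factors and normalized matrix
#'
#' DESeq-style normalization: per sample, the size factor is the median
#' over genes (nonzero in every sample) of the ratio of the gene's count
#' to its geometric mean across samples.
#'
#' @param m count matrix
#' @return list(size_factors, normalized)
#' @export
normalize_median_of_ratios <- function(m) {
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos))
    hs_error("no gene has nonzero counts in all samples")
  lg <- log(m[pos, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(lg, 2, function(col) exp(stats::median(col - geo)))
  list(size_factors = sf,
       normalized = sweep(m, 2, sf, "/"))
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up adjustment: q_(i) = min over j >= i of p_(j) * m / j,
#' clipped to 1.
#'
#' @param p p-values in [0, 1]
#' @return q-values, same order as `p`
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    hs_error("p-values must be in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / seq(m, 1) * p[o]))[ro]
}

#' Pairwise up-regulation test between two sample groups
#'
#' Two-sided Welch t-test on log2(normalized + 1) per gene; log2 fold
#' change is the difference of log2(group mean + 1) (group A over group
#' B); q-values by Benjamini-Hochberg within the comparison.
#'
#' @param mA,mB normalized count submatrices for the two groups (same
#'   genes, >= 2 samples each)
#' @return data.frame(gene_id, log2fc, p, q)
#' @export
test_upregulation <- function(mA, mB) {
  if (ncol(mA) < 2 || ncol(mB) < 2)
    hs_error("need >= 2 samples per group")
  if (nrow(mA) != nrow(mB)) hs_error("gene sets differ between groups")
  lA <- log2(mA + 1)
  lB <- log2(mB + 1)
  nA <- ncol(mA); nB <- ncol(mB)
  meanA <- rowMeans(lA); meanB <- rowMeans(lB)
  varA <- rowSums((lA - meanA)^2) / (nA - 1)
  varB <- rowSums((lB - meanB)^2) / (nB - 1)
  se2 <- varA / nA + varB / nB
  t_stat <- ifelse(se2 > 0, (meanA - meanB) / sqrt(se2), NA_real_)
  df <- ifelse(se2 > 0,
               se2^2 / ((varA / nA)^2 / (nA - 1) + (varB / nB)^2 / (nB - 1)),
               NA_real_)
  p <- ifelse(is.na(t_stat),
              ifelse(meanA == meanB, 1, 0),
              2 * stats::pt(abs(t_stat), df, lower.tail = FALSE))
  lfc <- log2(rowMeans(mA) + 1) - log2(rowMeans(mB) + 1)
  data.frame(gene_id = rownames(mA) %||% as.character(seq_len(nrow(mA))),
             log2fc = lfc, p = p, q = bh_fdr(p),
             stringsAsFactors = FALSE)
}

# Required pairwise comparisons for a set of groups within one dataset
# (adult or larval): each group against the opposite-sex group of the
# same tissue and against same-sex groups of other tissues.
required_comparisons <- function(groups) {
  focal <- character(0); other <- character(0)
  for (i in seq_len(nrow(groups))) {
    g <- groups[i, ]
    oth <- groups$group[(groups$tissue == g$tissue & groups$sex != g$sex) |
                        (groups$sex == g$sex & groups$tissue != g$tissue)]
    focal <- c(focal, rep(g$group, length(oth)))
    other <- c(other, oth)
  }
  data.frame(focal = focal, other = other, stringsAsFactors = FALSE)
}

#' Run all pairwise up-regulation tests for a dataset
#'
#' @param counts raw count matrix
#' @param meta sample metadata (sample, sex, tissue, stage)
#' @param stage "adult" or "larva"; comparisons are run within stage
#' @param min_total low-count filter threshold
#' @return data.frame(gene_id, comparison, focal, other, log2fc, p, q)
#' @export
run_de <- function(counts, meta, stage, min_total = 10) {
  sel <- meta$stage == stage
  if (!any(sel)) hs_error(paste0("no samples at stage ", stage))
  meta <- meta[sel, , drop = FALSE]
  counts <- counts[, meta$sample, drop = FALSE]
  counts <- filter_low_counts(counts, min_total)
  norm <- normalize_median_of_ratios(counts)$normalized
  meta$group <- paste0(meta$sex, "_", meta$tissue)
  groups <- unique(meta[, c("group", "sex", "tissue")])
  req <- required_comparisons(groups)
  pairs <- unique(t(apply(req[, c("focal", "other")], 1, sort)))
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    de <- test_upregulation(norm[, meta$sample[meta$group == a], drop = FALSE],
                            norm[, meta$sample[meta$group == b], drop = FALSE])
    de$comparison <- paste0(a, "_vs_", b)
    de$focal <- a
    de$other <- b
    de
  })
  do.call(rbind, res)
}

#' Classify genes from pairwise DE results
#'
#' A gene joins a (sex, tissue) set iff, in every required pairwise
#' comparison for that group, its fold change points toward the group
#' and q < alpha. Labels: haploid_biased = member of >= 1 male set and
#' no female set; diploid_biased symmetric; constitutive = member of
#' sets of both sexes; otherwise unclassified.
#'
#' @param de output of [run_de()] (one dataset/stage)
#' @param groups data.frame(group, sex, tissue) of the dataset's groups
#' @param alpha q-value threshold, default 0.01
#' @return data.frame(gene_id, label, tissue_sets)
#' @export
classify_genes <- function(de, groups, alpha = 0.01) {
  req <- required_comparisons(groups)
  ids <- unique(de$gene_id)
  membership <- matrix(FALSE, length(ids), nrow(groups),
                       dimnames = list(ids, groups$group))
  have <- unique(de$comparison)
  for (g in groups$group) {
    need <- req[req$focal == g, , drop = FALSE]
    ok <- rep(TRUE, length(ids))
    for (j in seq_len(nrow(need))) {
      a <- g; b <- need$other[j]
      cmp_ab <- paste0(a, "_vs_", b)
      cmp_ba <- paste0(b, "_vs_", a)
      if (cmp_ab %in% have) {
        sub <- de[de$comparison == cmp_ab, ]
        up <- sub$log2fc > 0 & sub$q < alpha
      } else if (cmp_ba %in% have) {
        sub <- de[de$comparison == cmp_ba, ]
        up <- sub$log2fc < 0 & sub$q < alpha
      } else {
        hs_error(paste0("missing comparison ", cmp_ab),
                 class = "haplosel_config_error")
      }
      up <- up[match(ids, sub$gene_id)]
      up[is.na(up)] <- FALSE
      ok <- ok & up
    }
    membership[, g] <- ok
  }
  sex_of <- stats::setNames(groups$sex, groups$group)
  male_any <- rowSums(membership[, sex_of[colnames(membership)] == "male",
                                 drop = FALSE]) > 0
  female_any <- rowSums(membership[, sex_of[colnames(membership)] == "female",
                                   drop = FALSE]) > 0
  label <- ifelse(male_any & female_any, "constitutive",
           ifelse(male_any, "haploid_biased",
           ifelse(female_any, "diploid_biased", "unclassified")))
  tissue_sets <- apply(membership, 1, function(r)
    paste(colnames(membership)[r], collapse = ","))
  data.frame(gene_id = ids, label = label, tissue_sets = tissue_sets,
             stringsAsFactors = FALSE)
}

#' Merge classifications from separately analysed datasets
#'
#' Labels are recomputed from the union of tissue-set memberships,
#' except that a gene called haploid-biased in one dataset and
#' diploid-biased in another is set to unclassified with a warning.
#'
#' @param ... classification data.frames from [classify_genes()]
#' @return merged classification
#' @export
merge_classifications <- function(...) {
  parts <- list(...)
  ids <- unique(unlist(lapply(parts, `[[`, "gene_id")))
  labels <- vapply(parts, function(p)
    stats::setNames(p$label, p$gene_id)[ids], character(length(ids)))
  sets <- vapply(parts, function(p)
    stats::setNames(p$tissue_sets, p$gene_id)[ids], character(length(ids)))
  if (length(ids) == 1) {
    labels <- matrix(labels, nrow = 1)
    sets <- matrix(sets, nrow = 1)
  }
  out_label <- character(length(ids))
  out_sets <- character(length(ids))
  n_conflict <- 0L
  for (i in seq_along(ids)) {
    li <- labels[i, ]
    li[is.na(li)] <- "unclassified"
    si <- sets[i, ]
    si <- si[!is.na(si) & nzchar(si)]
    out_sets[i] <- paste(unique(unlist(strsplit(si, ","))), collapse = ",")
    if ("haploid_biased" %in% li && "diploid_biased" %in% li) {
      out_label[i] <- "unclassified"
      n_conflict <- n_conflict + 1L
    } else if ("constitutive" %in% li) {
      out_label[i] <- "constitutive"
    } else if ("haploid_biased" %in% li) {
      out_label[i] <- "haploid_biased"
    } else if ("diploid_biased" %in% li) {
      out_label[i] <- "diploid_biased"
    } else {
      out_label[i] <- "unclassified"
    }
  }
  if (n_conflict > 0)
    warning(n_conflict, " gene(s) with conflicting sex bias between ",
            "datasets set to unclassified")
  data.frame(gene_id = ids, label = out_label, tissue_sets = out_sets,
             stringsAsFactors = FALSE)
}

#' Set-intersection counts of tissue-set memberships
#'
#' For every observed combination of (sex, tissue) memberships, the
#' number of genes in exactly that combination (the numbers an UpSet
#' plot displays). Counts sum to the number of classified genes.
#'
#' @param cls classification data.frame with `tissue_sets`
#' @return data.frame(combination, n)
#' @export
intersection_counts <- function(cls) {
  member <- cls$tissue_sets[nzchar(cls$tissue_sets)]
  if (length(member) == 0)
    return(data.frame(combination = character(0), n = integer(0),
                      stringsAsFactors = FALSE))
  norm <- vapply(strsplit(member, ","), function(s)
    paste(sort(s), collapse = ","), character(1))
  tab <- table(norm)
  data.frame(combination = names(tab), n = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' End-to-end classification: adult and larval datasets, merged
#'
#' @param counts raw count matrix
#' @param meta sample metadata
#' @param alpha FDR threshold (default 0.01)
#' @param min_total low-count filter (default 10)
#' @return list(classification, de, intersections)
#' @export
classify_expression <- function(counts, meta, alpha = 0.01, min_total = 10) {
  stages <- intersect(c("adult", "larva"), unique(meta$stage))
  parts <- list(); des <- list()
  for (st in stages) {
    sub_meta <- meta[meta$stage == st, , drop = FALSE]
    groups <- unique(data.frame(
      group = paste0(sub_meta$sex, "_", sub_meta$tissue),
      sex = sub_meta$sex, tissue = sub_meta$tissue,
      stringsAsFactors = FALSE))
    de <- run_de(counts, meta, st, min_total = min_total)
    des[[st]] <- de
    parts[[st]] <- classify_genes(de, groups, alpha = alpha)
  }
  cls <- if (length(parts) == 1) parts[[1]]
         else do.call(merge_classifications, unname(parts))
  # genes filtered out of every dataset stay unclassified
  missing <- setdiff(rownames(counts), cls$gene_id)
  if (length(missing))
    cls <- rbind(cls, data.frame(gene_id = missing, label = "unclassified",
                                 tissue_sets = "", stringsAsFactors = FALSE))
  cls <- cls[order(cls$gene_id), ]
  rownames(cls) <- NULL
  list(classification = cls, de = do.call(rbind, des),
       intersections = intersection_counts(cls))
}
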