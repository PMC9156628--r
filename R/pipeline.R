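# Pipeline orchestration: simulate -> classify -> popgen -> MK ->
# recombination -> expectations -> comparisons, with per-stage gene-drop
# accounting and a JSON run manifest.

#' Build a pipeline configuration
#'
#' Either `sim` (a [sim_config()]) or `inputs` (named paths: fasta, gff,
#' vcf, outgroup, counts, meta, linkage, and optionally dnds and gamma
#' side tables) must be given.
#'
#' @param sim optional [sim_config()] describing inputs to generate
#' @param inputs optional named list of input paths
#' @param out_dir output directory (created); NULL keeps results in
#'   memory only
#' @param alpha_fdr FDR threshold for up-regulation calls (default 0.01)
#' @param min_total low-count filter (default 10)
#' @param maf MAF threshold for diversity (default 0.01)
#' @param mk_p,dos_min positive-selection flag thresholds
#' @param relax_factor,H expectation-model parameters
#' @param seed integer seed
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(sim = NULL, inputs = NULL, out_dir = NULL,
                            alpha_fdr = 0.01, min_total = 10, maf = 0.01,
                            mk_p = 0.05, dos_min = 0,
                            relax_factor = 0.5, H = 13.984, seed = 1) {
  if (is.null(sim) && is.null(inputs))
    hs_error("either a simulation config or input paths are required",
             class = "haplosel_config_error")
  if (!is.null(inputs)) {
    need <- c("fasta", "gff", "vcf", "outgroup", "counts", "meta", "linkage")
    miss <- setdiff(need, names(inputs))
    if (length(miss))
      hs_error(paste0("missing input path(s): ", paste(miss, collapse = ", ")),
               class = "haplosel_config_error")
    gone <- unlist(inputs)[!file.exists(unlist(inputs))]
    if (length(gone))
      hs_error(paste0("input file(s) not found: ",
                      paste(gone, collapse = ", ")),
               class = "haplosel_config_error")
  }
  stopifnot(alpha_fdr > 0, alpha_fdr < 1, maf >= 0, mk_p > 0, mk_p <= 1)
  structure(list(sim = sim, inputs = inputs, out_dir = out_dir,
                 alpha_fdr = alpha_fdr, min_total = min_total, maf = maf,
                 mk_p = mk_p, dos_min = dos_min,
                 relax_factor = relax_factor, H = H,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# drop genes whose reference CDS carries a premature internal stop
drop_internal_stops <- function(cds) {
  bad <- vapply(cds, function(s) {
    codons <- codon_split(s)
    any(codons[-length(codons)] %in% stop_codons())
  }, logical(1))
  if (any(bad))
    warning(sum(bad), " gene(s) with internal stop codons excluded")
  cds[!bad]
}

#' Run the full pipeline
#'
#' @param cfg a [pipeline_config()]
#' @return list(master, classification, de, intersections, class_summary,
#'   expectations, comparisons, manifest, checksum)
#' @export
run_pipeline <- function(cfg) {
  drops <- list()
  if (!is.null(cfg$sim)) {
    sim_dir <- if (!is.null(cfg$out_dir))
      file.path(cfg$out_dir, "inputs") else tempfile("haplosel_sim_")
    sim <- simulate_all(cfg$sim, dir = sim_dir)
    paths <- sim$paths
  } else {
    paths <- cfg$inputs
  }
  # read everything back from disk so the run always exercises the
  # documented formats
  cds <- read_fasta(paths$fasta)
  n0 <- length(cds)
  cds <- drop_internal_stops(cds)
  drops$internal_stop <- n0 - length(cds)
  genes <- read_gff(paths$gff)
  genes <- genes[genes$gene_id %in% names(cds), , drop = FALSE]
  variants <- read_vcf(paths$vcf)
  outgroup <- read_outgroup(paths$outgroup)
  counts <- read_counts(paths$counts)
  meta <- read_sample_meta(paths$meta)
  lmap <- read_linkage_map(paths$linkage)

  hs_log("classifying expression for ", nrow(counts), " genes")
  expr <- classify_expression(counts, meta, alpha = cfg$alpha_fdr,
                              min_total = cfg$min_total)
  drops$low_count <- nrow(counts) -
    sum(rowSums(counts) >= cfg$min_total)

  hs_log("computing population-genetic statistics for ", nrow(genes),
         " genes")
  gt <- popgen_gene_table(cds, genes, variants, outgroup,
                          maf_min = cfg$maf)
  gt <- mk_table(gt, p_max = cfg$mk_p, dos_min = cfg$dos_min)

  fit <- fit_marey(lmap)
  rr <- gene_recomb_rate(genes, fit)
  names(rr)[names(rr) == "rate"] <- "recomb_rate"
  names(rr)[names(rr) == "status"] <- "recomb_status"
  drops$outside_map <- sum(rr$recomb_status == "outside_map")

  # log2 expression bias: male over female group means of normalized
  # counts (haploid- vs diploid-biased expression)
  bias <- tryCatch({
    keep <- rowSums(counts) >= cfg$min_total
    norm <- normalize_median_of_ratios(counts[keep, , drop = FALSE])$normalized
    male <- rowMeans(norm[, meta$sample[meta$sex == "male"], drop = FALSE])
    female <- rowMeans(norm[, meta$sample[meta$sex == "female"],
                            drop = FALSE])
    data.frame(gene_id = rownames(norm),
               log2_bias = log2(male + 1) - log2(female + 1),
               stringsAsFactors = FALSE)
  }, error = function(e) data.frame(gene_id = character(0),
                                    log2_bias = numeric(0)))

  master <- merge(gt, expr$classification, by = "gene_id", all.x = TRUE)
  names(master)[names(master) == "label"] <- "class"
  master$class[is.na(master$class)] <- "unclassified"
  master <- merge(master, rr, by = "gene_id", all.x = TRUE)
  master <- merge(master, bias, by = "gene_id", all.x = TRUE)
  for (side in c("dnds", "gamma")) {
    if (!is.null(paths[[side]]) && file.exists(paths[[side]])) {
      st <- utils::read.delim(paths[[side]], stringsAsFactors = FALSE)
      master <- merge(master, st, by = "gene_id", all.x = TRUE)
    }
  }
  master <- master[order(master$gene_id), ]
  rownames(master) <- NULL

  summary_tab <- summarize_by_class(master)
  const <- master[master$class == "constitutive", , drop = FALSE]
  pnps_const <- if (sum(const$Ps) > 0)
    (sum(const$Pn) / sum(const$Ps)) * (sum(const$Ls) / sum(const$Ln))
  else NA_real_
  omega_const <- if (sum(const$Ds) > 0)
    (sum(const$Dn) / sum(const$Ds)) * (sum(const$Ls) / sum(const$Ln))
  else NA_real_
  expectations <- if (!is.na(omega_const) && omega_const > 0)
    expectation_table(pnps_const, omega_const,
                      relax_factor = cfg$relax_factor, H = cfg$H)
  else NULL
  comp <- compare_classes(master)

  manifest <- list(package = "haplosel",
                   version = as.character(utils::packageVersion("haplosel")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   seed = cfg$seed,
                   thresholds = list(alpha_fdr = cfg$alpha_fdr,
                                     min_total = cfg$min_total,
                                     maf = cfg$maf, mk_p = cfg$mk_p,
                                     dos_min = cfg$dos_min,
                                     relax_factor = cfg$relax_factor,
                                     H = cfg$H),
                   n_genes = nrow(master),
                   drops = drops)

  out <- list(master = master, classification = expr$classification,
              de = expr$de, intersections = expr$intersections,
              class_summary = summary_tab, expectations = expectations,
              comparisons = comp, manifest = manifest)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(df, name) {
      if (is.null(df)) return(invisible(NULL))
      utils::write.table(df, file.path(cfg$out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    wt(master, "master.tsv")
    wt(expr$classification, "classification.tsv")
    wt(expr$de, "de_results.tsv")
    wt(expr$intersections, "intersections.tsv")
    wt(summary_tab, "class_summary.tsv")
    wt(expectations, "expectations.tsv")
    wt(comp, "comparisons.tsv")
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    out$checksum <- unname(tools::md5sum(file.path(cfg$out_dir,
                                                   "master.tsv")))
    manifest$master_md5 <- out$checksum
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  } else {
    tf <- tempfile(fileext = ".tsv")
    utils::write.table(master, tf, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$checksum <- unname(tools::md5sum(tf))
    unlink(tf)
  }
  out
}

#' Class-level summary of the master table
#'
#' @param master per-gene master table
#' @param stats statistic columns to summarise
#' @return one row per gene class: n, mean/median of each statistic,
#'   fraction MK-positive, and fraction gamma > 1 when a gamma column is
#'   present
#' @export
summarize_by_class <- function(master,
                               stats = c("gc", "cpg_oe", "recomb_rate",
                                         "piS", "piNS", "pnps", "dos")) {
  stats <- intersect(stats, names(master))
  rows <- lapply(GENE_CLASSES, function(cl) {
    sub <- master[master$class == cl, , drop = FALSE]
    row <- data.frame(class = cl, n = nrow(sub), stringsAsFactors = FALSE)
    for (s in stats) {
      row[[paste0("mean_", s)]] <- if (nrow(sub))
        mean(sub[[s]], na.rm = TRUE) else NA_real_
      row[[paste0("median_", s)]] <- if (nrow(sub))
        stats::median(sub[[s]], na.rm = TRUE) else NA_real_
    }
    row$frac_mk_positive <- if (nrow(sub) && "positive" %in% names(sub))
      mean(sub$positive, na.rm = TRUE) else NA_real_
    row$frac_gamma_pos <- if (nrow(sub) && "gamma" %in% names(sub))
      mean(sub$gamma > 1, na.rm = TRUE) else NA_real_
    row
  })
  do.call(rbind, rows)
}

#' One-command synthetic demo
#'
#' Generates the default synthetic world (2,000 genes) and runs the full
#' pipeline on it.
#'
#' @param seed integer seed
#' @param out_dir optional output directory
#' @param n_genes number of genes, default 2000
#' @return the [run_pipeline()] result bundle
#' @export
demo_pipeline <- function(seed = 1, out_dir = NULL, n_genes = 2000) {
  sim <- sim_config(n_genes = n_genes, seed = seed)
  cfg <- pipeline_config(sim = sim, out_dir = out_dir, seed = seed)
  run_pipeline(cfg)
}
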