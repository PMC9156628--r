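# Synthetic-data generators: coding sequences, polymorphism/divergence
# data with known per-variant effect labels, negative-binomial expression
# counts with planted sex-/tissue-bias, and linkage maps. Everything is
# deterministic under (seed, config), and every planted event carries a
# ground-truth record so downstream estimators can be validated.

#' Build a simulation configuration
#'
#' Defaults describe a honey-bee-like world: ~2,000 protein-coding genes
#' of 100-500 codons on 16 chromosomes, synonymous diversity
#' theta_s = 0.02 among 22 sampled allele copies (11 diploid ingroup
#' samples), synonymous divergence 0.05 to a single haploid outgroup
#' allele, a ~2,000-marker linkage map averaging 23 cM/Mb, and an
#' expression design of 5 samples per (sex x tissue) group at baseline
#' mean 200 and NB dispersion 0.1 with planted 8-fold bias. Per-class
#' selection intensities follow the relaxed-selection null world:
#' constitutive genes at (omega_poly 0.10, omega_div 0.092), sex-biased
#' genes at the two-fold relaxed (0.20, 0.37).
#'
#' @param n_genes number of genes
#' @param gene_length_codons single length or c(min, max) range, in
#'   codons including start and stop
#' @param theta_s expected synonymous pairwise diversity per synonymous
#'   site
#' @param div_s expected synonymous substitutions per synonymous site
#' @param n_chromosomes_sampled ingroup allele copies per site (>= 2)
#' @param class_fractions named fractions over the four gene classes
#' @param class_params data.frame(class, omega_poly, omega_div)
#' @param class_assignments optional explicit per-gene class vector
#' @param expr list(baseline_mean, dispersion, fold, n_per_group)
#' @param n_chromosomes,chrom_length_bp,markers_per_chromosome,
#'   recomb_rate_cM_per_Mb,recomb_constant linkage-map parameters
#' @param seed integer seed; identical (seed, config) give byte-identical
#'   outputs
#' @return a `sim_config` list
#' @export
sim_config <- function(n_genes = 2000,
                       gene_length_codons = c(100, 500),
                       theta_s = 0.02,
                       div_s = 0.05,
                       n_chromosomes_sampled = 22,
                       class_fractions = c(haploid_biased = 0.16,
                                           diploid_biased = 0.22,
                                           constitutive = 0.25,
                                           unclassified = 0.37),
                       class_params = data.frame(
                         class = c("haploid_biased", "diploid_biased",
                                   "constitutive", "unclassified"),
                         omega_poly = c(0.20, 0.20, 0.10, 0.15),
                         omega_div = c(0.37, 0.37, 0.092, 0.15),
                         stringsAsFactors = FALSE),
                       class_assignments = NULL,
                       expr = list(baseline_mean = 200, dispersion = 0.1,
                                   fold = 8, n_per_group = 5),
                       n_chromosomes = 16,
                       chrom_length_bp = 14e6,
                       markers_per_chromosome = 125,
                       recomb_rate_cM_per_Mb = 23,
                       recomb_constant = FALSE,
                       seed = 1) {
  if (length(gene_length_codons) == 1)
    gene_length_codons <- rep(gene_length_codons, 2)
  if (any(gene_length_codons < 2))
    hs_error("gene_length_codons must be >= 2",
             class = "haplosel_config_error")
  if (gene_length_codons[1] > gene_length_codons[2])
    hs_error("invalid gene length range", class = "haplosel_config_error")
  if (theta_s < 0 || div_s < 0)
    hs_error("rates must be >= 0", class = "haplosel_config_error")
  if (any(class_params$omega_poly < 0) || any(class_params$omega_div < 0))
    hs_error("omega values must be >= 0", class = "haplosel_config_error")
  if (n_chromosomes_sampled < 2)
    hs_error("n_chromosomes_sampled must be >= 2",
             class = "haplosel_config_error")
  ex <- utils::modifyList(list(baseline_mean = 200, dispersion = 0.1,
                               fold = 8, n_per_group = 5), expr)
  if (ex$dispersion <= 0)
    hs_error("dispersion must be positive", class = "haplosel_config_error")
  if (ex$n_per_group < 2)
    hs_error("need >= 2 samples per group", class = "haplosel_config_error")
  if (!setequal(names(class_fractions), GENE_CLASSES))
    hs_error("class_fractions must name all four gene classes",
             class = "haplosel_config_error")
  cfg <- list(n_genes = n_genes, gene_length_codons = gene_length_codons,
              theta_s = theta_s, div_s = div_s,
              n_chromosomes_sampled = n_chromosomes_sampled,
              class_fractions = class_fractions[GENE_CLASSES],
              class_params = class_params, expr = ex,
              n_chromosomes = n_chromosomes,
              chrom_length_bp = chrom_length_bp,
              markers_per_chromosome = markers_per_chromosome,
              recomb_rate_cM_per_Mb = recomb_rate_cM_per_Mb,
              recomb_constant = recomb_constant,
              seed = as.integer(seed))
  cfg$class_assignments <- class_assignments %||% with_seed(cfg$seed + 11L, {
    k <- round(cfg$class_fractions * n_genes)
    k[["unclassified"]] <- n_genes - sum(k[setdiff(GENE_CLASSES,
                                                   "unclassified")])
    sample(rep(GENE_CLASSES, times = k[GENE_CLASSES]))
  })
  if (length(cfg$class_assignments) != n_genes)
    hs_error("class_assignments length must equal n_genes",
             class = "haplosel_config_error")
  class(cfg) <- "sim_config"
  cfg
}

gene_ids <- function(n) sprintf("g%05d", seq_len(n))

#' Generate coding sequences and gene models
#'
#' Each CDS starts with ATG, ends with a stop codon, has no internal
#' stop, and has length divisible by 3. Genes are laid out on plus-strand
#' single-interval loci spread across the configured chromosomes, inside
#' the span of the generated linkage map.
#'
#' @param cfg a [sim_config()]
#' @return list(cds = named character vector, genes = gene-model table)
#' @export
gen_gene_sequences <- function(cfg) {
  with_seed(cfg$seed + 101L, {
    n <- cfg$n_genes
    ids <- gene_ids(n)
    lens <- if (cfg$gene_length_codons[1] == cfg$gene_length_codons[2])
      rep(cfg$gene_length_codons[1], n)
    else sample(cfg$gene_length_codons[1]:cfg$gene_length_codons[2], n,
                replace = TRUE)
    sense <- sense_codons()
    stops <- stop_codons()
    cds <- vapply(lens, function(L) {
      mid <- if (L > 2) sample(sense, L - 2, replace = TRUE) else character(0)
      paste0("ATG", paste(mid, collapse = ""), sample(stops, 1))
    }, character(1))
    names(cds) <- ids
    # round-robin chromosome assignment; evenly spaced slots with jitter,
    # kept inside [5%, 95%] of the chromosome so genes sit within the
    # linkage-map span
    chrom_idx <- rep_len(seq_len(cfg$n_chromosomes), n)
    per <- tabulate(chrom_idx, cfg$n_chromosomes)
    start <- integer(n)
    for (ch in seq_len(cfg$n_chromosomes)) {
      sel <- which(chrom_idx == ch)
      span <- 0.9 * cfg$chrom_length_bp
      slot <- span / max(1, length(sel))
      base <- 0.05 * cfg$chrom_length_bp + (seq_along(sel) - 1) * slot
      start[sel] <- as.integer(round(base + stats::runif(length(sel), 0,
                                                         slot * 0.2)) + 1)
    }
    genes <- data.frame(gene_id = ids,
                        chrom = paste0("chr", chrom_idx),
                        start = start,
                        end = start + lens * 3L - 1L,
                        strand = "+",
                        stringsAsFactors = FALSE)
    genes$cds <- lapply(seq_len(n), function(i)
      cbind(start = genes$start[i], end = genes$end[i]))
    validate_gene_models(genes)
    list(cds = cds, genes = genes)
  })
}

#' Generate ingroup variants and outgroup alleles with known truth
#'
#' Per gene, synonymous/nonsynonymous polymorphism counts are Poisson
#' with means theta_s*Ls*a1 and theta_s*omega_poly*Ln*a1, where a1 is the
#' harmonic number sum(1/i, i = 1..n-1) bridging Watterson's theta to
#' expected pi under a 1/i neutral frequency spectrum. Substitution
#' counts are Poisson(div_s*Ls) and Poisson(div_s*omega_div*Ln). Events
#' are placed by sampling, per gene, among the single-nucleotide changes
#' whose effect class is the intended one, with at most one event per
#' site and at most one substitution per codon, so truth labels are
#' exact.
#'
#' @param cfg a [sim_config()]
#' @param seqgen output of [gen_gene_sequences()]
#' @return list(variants, outgroup, truth = list(genes, variants))
#' @export
gen_variant_data <- function(cfg, seqgen) {
  with_seed(cfg$seed + 202L, {
    n_alleles <- cfg$n_chromosomes_sampled
    a1 <- sum(1 / seq_len(n_alleles - 1))
    sfs_p <- (1 / seq_len(n_alleles - 1))
    sfs_p <- sfs_p / sum(sfs_p)
    chg <- codon_change_table()
    chg_idx <- split(seq_len(nrow(chg)), chg$codon)
    cp <- cfg$class_params
    var_rows <- vector("list", cfg$n_genes)
    og_rows <- vector("list", cfg$n_genes)
    truth_var <- vector("list", cfg$n_genes)
    truth_gene <- vector("list", cfg$n_genes)
    for (gi in seq_len(cfg$n_genes)) {
      id <- seqgen$genes$gene_id[gi]
      cds <- seqgen$cds[[id]]
      g0 <- seqgen$genes$start[gi]
      cls <- cfg$class_assignments[gi]
      op <- cp$omega_poly[cp$class == cls]
      od <- cp$omega_div[cp$class == cls]
      sites <- gene_site_counts(cds)
      codons <- sites$codons
      sense <- which(!codons %in% stop_codons())
      if (sites$Ls == 0 && cfg$theta_s > 0) {
        warning("gene ", id, " has no synonymous sites; skipped for ",
                "synonymous planting")
      }
      rows <- unlist(chg_idx[codons[sense]], use.names = FALSE)
      codon_of <- rep(sense, lengths(chg_idx[codons[sense]]))
      pos_in <- chg$pos[rows]
      alt_of <- chg$alt[rows]
      syn_of <- chg$syn[rows]
      stopg_of <- chg$stop_gain[rows]
      site_of <- (codon_of - 1L) * 3L + pos_in
      n_ps <- stats::rpois(1, cfg$theta_s * sites$Ls * a1)
      n_pn <- stats::rpois(1, cfg$theta_s * op * sites$Ln * a1)
      n_ds <- stats::rpois(1, cfg$div_s * sites$Ls)
      n_dn <- stats::rpois(1, cfg$div_s * od * sites$Ln)
      used_site <- integer(0)
      used_sub_codon <- integer(0)
      pick <- function(want_syn, k, one_per_codon = FALSE) {
        if (k == 0) return(integer(0))
        cand <- which(syn_of == want_syn & !site_of %in% used_site)
        if (one_per_codon) {
          # substitutions: one per codon, and never stop-gaining (a
          # fixed nonsense difference would not be a functional gene)
          cand <- cand[!codon_of[cand] %in% used_sub_codon &
                       !stopg_of[cand]]
        }
        if (length(cand) == 0) return(integer(0))
        perm <- if (length(cand) == 1) cand else sample(cand)
        keep <- !duplicated(site_of[perm])
        if (one_per_codon) keep <- keep & !duplicated(codon_of[perm])
        sel <- perm[keep]
        utils::head(sel, k)
      }
      sel_ds <- pick(TRUE, n_ds, one_per_codon = TRUE)
      used_site <- c(used_site, site_of[sel_ds])
      used_sub_codon <- c(used_sub_codon, codon_of[sel_ds])
      sel_dn <- pick(FALSE, n_dn, one_per_codon = TRUE)
      used_site <- c(used_site, site_of[sel_dn])
      used_sub_codon <- c(used_sub_codon, codon_of[sel_dn])
      sel_ps <- pick(TRUE, n_ps)
      used_site <- c(used_site, site_of[sel_ps])
      sel_pn <- pick(FALSE, n_pn)
      used_site <- c(used_site, site_of[sel_pn])
      sel <- c(sel_ds, sel_dn, sel_ps, sel_pn)
      if (length(sel) == 0) {
        truth_gene[[gi]] <- data.frame(
          gene_id = id, class = cls, omega_poly = op, omega_div = od,
          ps = 0L, pn = 0L, ds = 0L, dn = 0L, Ls = sites$Ls, Ln = sites$Ln,
          stringsAsFactors = FALSE)
        next
      }
      kind <- rep(c("sub_s", "sub_n", "poly_s", "poly_n"),
                  c(length(sel_ds), length(sel_dn),
                    length(sel_ps), length(sel_pn)))
      s <- site_of[sel]
      gpos <- g0 + s - 1L
      ref <- substring(cds, s, s)
      alt <- alt_of[sel]
      is_poly <- kind %in% c("poly_s", "poly_n")
      ac <- integer(length(sel))
      ac[is_poly] <- sample(seq_len(n_alleles - 1), sum(is_poly),
                            replace = TRUE, prob = sfs_p)
      branch <- rep(NA_character_, length(sel))
      branch[!is_poly] <- sample(c("ingroup", "outgroup"), sum(!is_poly),
                                 replace = TRUE)
      ac[!is_poly & branch == "ingroup"] <- n_alleles
      in_vcf <- is_poly | (branch == "ingroup" & !is_poly)
      in_vcf[is.na(in_vcf)] <- FALSE
      var_rows[[gi]] <- data.frame(
        chrom = rep(seqgen$genes$chrom[gi], sum(in_vcf)),
        pos = gpos[in_vcf], ref = ref[in_vcf], alt = alt[in_vcf],
        ac = ac[in_vcf], an = rep(n_alleles, sum(in_vcf)),
        stringsAsFactors = FALSE)
      og_allele <- ifelse(!is_poly & branch == "outgroup", alt, ref)
      og_rows[[gi]] <- data.frame(
        chrom = seqgen$genes$chrom[gi], pos = gpos, allele = og_allele,
        stringsAsFactors = FALSE)
      truth_var[[gi]] <- data.frame(
        gene_id = id, chrom = seqgen$genes$chrom[gi], pos = gpos,
        ref = ref, alt = alt, kind = kind,
        effect = ifelse(kind %in% c("poly_s", "sub_s"),
                        "synonymous", "nonsynonymous"),
        ac = ifelse(is_poly, ac, NA_integer_),
        branch = branch, stringsAsFactors = FALSE)
      truth_gene[[gi]] <- data.frame(
        gene_id = id, class = cls, omega_poly = op, omega_div = od,
        ps = length(sel_ps), pn = length(sel_pn),
        ds = length(sel_ds), dn = length(sel_dn),
        Ls = sites$Ls, Ln = sites$Ln, stringsAsFactors = FALSE)
    }
    variants <- as.data.frame(data.table::rbindlist(var_rows))
    if (nrow(variants) == 0)
      variants <- data.frame(chrom = character(0), pos = integer(0),
                             ref = character(0), alt = character(0),
                             ac = integer(0), an = integer(0),
                             stringsAsFactors = FALSE)
    outgroup <- as.data.frame(data.table::rbindlist(og_rows))
    if (nrow(outgroup) == 0)
      outgroup <- data.frame(chrom = character(0), pos = integer(0),
                             allele = character(0), stringsAsFactors = FALSE)
    tv <- as.data.frame(data.table::rbindlist(truth_var))
    validate_variant_table(variants)
    list(variants = variants, outgroup = outgroup,
         truth = list(genes = as.data.frame(data.table::rbindlist(truth_gene)),
                      variants = tv))
  })
}

# Declared expression groups for the default design: adult gonad and
# soma for both sexes, plus one larval group per sex.
expression_groups <- function() {
  data.frame(group = c("male_gonad", "male_soma", "female_gonad",
                       "female_soma", "male_larva", "female_larva"),
             sex = c("male", "male", "female", "female", "male", "female"),
             tissue = c("gonad", "soma", "gonad", "soma", "larva", "larva"),
             stage = c("adult", "adult", "adult", "adult", "larva", "larva"),
             stringsAsFactors = FALSE)
}

#' Generate an expression count matrix with planted sex/tissue bias
#'
#' Counts are negative binomial with gene-specific lognormal baselines,
#' sample-specific size factors, and a planted fold change: haploid-
#' biased genes are elevated in one male group, diploid-biased genes in
#' one female group, and constitutive genes in one male and one
#' complementary female adult group (so they are up-regulated in both
#' sexes under pairwise comparison logic).
#'
#' @param cfg a [sim_config()]
#' @return list(counts, meta, truth) where truth records the planted
#'   up-regulation pattern per gene
#' @export
gen_expression_counts <- function(cfg) {
  with_seed(cfg$seed + 303L, {
    grp <- expression_groups()
    npg <- cfg$expr$n_per_group
    meta <- do.call(rbind, lapply(seq_len(nrow(grp)), function(i) {
      data.frame(sample = paste0(grp$group[i], "_", seq_len(npg)),
                 sex = grp$sex[i], tissue = grp$tissue[i],
                 stage = grp$stage[i], stringsAsFactors = FALSE)
    }))
    validate_sample_meta(meta)
    n <- cfg$n_genes
    ids <- gene_ids(n)
    cls <- cfg$class_assignments
    fold <- cfg$expr$fold
    pattern <- character(n)
    for (i in seq_len(n)) {
      pattern[i] <- if (fold == 1) "" else switch(
        cls[i],
        haploid_biased = paste0("male_", sample(TISSUES, 1)),
        diploid_biased = paste0("female_", sample(TISSUES, 1)),
        constitutive = if (stats::runif(1) < 0.5)
          "male_gonad,female_soma" else "male_soma,female_gonad",
        "")
    }
    base_mu <- stats::rlnorm(n, log(cfg$expr$baseline_mean), 1)
    sf <- stats::rlnorm(nrow(meta), 0, 0.1)
    sample_group <- paste0(meta$sex, "_", meta$tissue)
    counts <- matrix(0L, n, nrow(meta),
                     dimnames = list(ids, meta$sample))
    size <- 1 / cfg$expr$dispersion
    pat_list <- strsplit(pattern, ",")
    for (j in seq_len(nrow(meta))) {
      up <- vapply(pat_list, function(p) sample_group[j] %in% p, logical(1))
      mu <- base_mu * ifelse(up, fold, 1) * sf[j]
      counts[, j] <- stats::rnbinom(n, mu = mu, size = size)
    }
    truth <- data.frame(gene_id = ids, class = cls, pattern = pattern,
                        fold = ifelse(nzchar(pattern), fold, 1),
                        stringsAsFactors = FALSE)
    list(counts = counts, meta = meta, truth = truth)
  })
}

#' Generate a linkage map
#'
#' Markers per chromosome at strictly increasing physical positions with
#' non-decreasing genetic positions. With `recomb_constant = TRUE` the
#' map is exactly linear at `recomb_rate_cM_per_Mb`; otherwise segment
#' rates vary lognormally around that average.
#'
#' @param cfg a [sim_config()]
#' @return linkage-map data.frame(chrom, bp, cM)
#' @export
gen_linkage_map <- function(cfg) {
  with_seed(cfg$seed + 404L, {
    rows <- lapply(seq_len(cfg$n_chromosomes), function(ch) {
      m <- cfg$markers_per_chromosome
      if (m < 2) hs_error("need >= 2 markers per chromosome",
                          class = "haplosel_config_error")
      inner <- sort(sample(seq(2, cfg$chrom_length_bp - 1), m - 2))
      bp <- unique(c(1, inner, cfg$chrom_length_bp))
      while (length(bp) < m) {
        extra <- sample(seq(2, cfg$chrom_length_bp - 1), m - length(bp))
        bp <- sort(unique(c(bp, extra)))
      }
      if (cfg$recomb_constant) {
        cm <- (bp - 1) * cfg$recomb_rate_cM_per_Mb / 1e6
      } else {
        seg_rate <- cfg$recomb_rate_cM_per_Mb *
          stats::rlnorm(length(bp) - 1, -0.125, 0.5)
        cm <- c(0, cumsum(diff(bp) * seg_rate / 1e6))
      }
      data.frame(chrom = paste0("chr", ch), bp = bp, cM = cm,
                 stringsAsFactors = FALSE)
    })
    lmap <- do.call(rbind, rows)
    validate_linkage_map(lmap)
    lmap
  })
}

#' Run every generator and optionally write all pipeline inputs to disk
#'
#' @param cfg a [sim_config()]
#' @param dir output directory; when NULL nothing is written
#' @return list(cds, genes, variants, outgroup, counts, meta, linkage_map,
#'   truth, paths)
#' @export
simulate_all <- function(cfg, dir = NULL) {
  seqgen <- gen_gene_sequences(cfg)
  vd <- gen_variant_data(cfg, seqgen)
  ex <- gen_expression_counts(cfg)
  lmap <- gen_linkage_map(cfg)
  truth <- list(genes = merge(vd$truth$genes,
                              ex$truth[, c("gene_id", "pattern", "fold")],
                              by = "gene_id"),
                variants = vd$truth$variants)
  out <- list(cds = seqgen$cds, genes = seqgen$genes,
              variants = vd$variants, outgroup = vd$outgroup,
              counts = ex$counts, meta = ex$meta, linkage_map = lmap,
              truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    p <- list(fasta = file.path(dir, "cds.fasta"),
              gff = file.path(dir, "genes.gff3"),
              vcf = file.path(dir, "ingroup.vcf"),
              outgroup = file.path(dir, "outgroup.tsv"),
              counts = file.path(dir, "counts.tsv"),
              meta = file.path(dir, "samples.tsv"),
              linkage = file.path(dir, "linkage_map.tsv"),
              truth_genes = file.path(dir, "truth_genes.tsv"),
              truth_variants = file.path(dir, "truth_variants.tsv"))
    write_fasta(out$cds, p$fasta)
    write_gff3(out$genes, p$gff)
    write_vcf(out$variants, p$vcf)
    write_outgroup(out$outgroup, p$outgroup)
    write_counts(out$counts, p$counts)
    write_sample_meta(out$meta, p$meta)
    write_linkage_map(out$linkage_map, p$linkage)
    utils::write.table(truth$genes, p$truth_genes, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(truth$variants, p$truth_variants, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    out$paths <- p
  }
  out
}
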