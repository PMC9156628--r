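# Codon-aware polymorphism, divergence and composition statistics per
# gene: per-site pi, MAF-filtered piS/piNS, Pn/Ps/Dn/Ds counting against
# a single-allele outgroup, GC content and CpGo/e.

#' Unbiased per-site nucleotide diversity
#'
#' pi = (an/(an-1)) * (1 - p^2 - q^2), the mean pairwise difference per
#' site among `an` sampled allele copies of which `ac` carry the
#' alternate allele.
#'
#' @param ac alternate allele count (vectorised)
#' @param an total called alleles (>= 2)
#' @return per-site diversity
#' @export
site_pi <- function(ac, an) {
  if (any(an < 2)) hs_error("an must be >= 2")
  if (any(ac < 0 | ac > an)) hs_error("need 0 <= ac <= an")
  p <- ac / an
  (an / (an - 1)) * (1 - p^2 - (1 - p)^2)
}

#' Per-gene synonymous and nonsynonymous diversity
#'
#' Sums [site_pi()] over classified polymorphic variants whose minor
#' allele frequency exceeds `maf_min`, divided by the NG86 synonymous
#' (Ls) and nonsynonymous (Ln) site totals.
#'
#' @param variants data.frame with columns `ac`, `an`, `effect`
#'   ("synonymous"/"nonsynonymous"); fixed or monomorphic rows
#'   (ac == 0 or ac == an) contribute nothing
#' @param Ls,Ln site totals from [gene_site_counts()]
#' @param maf_min minimum minor-allele frequency (exclusive), default 0.01
#' @return list(piS, piNS); NA for a class whose site total is 0
#' @export
gene_pi <- function(variants, Ls, Ln, maf_min = 0.01) {
  if (nrow(variants) == 0)
    return(list(piS = if (Ls > 0) 0 else NA_real_,
                piNS = if (Ln > 0) 0 else NA_real_))
  if (!all(variants$effect %in% c("synonymous", "nonsynonymous")))
    hs_error("unclassified variant passed to gene_pi")
  p <- variants$ac / variants$an
  maf <- pmin(p, 1 - p)
  keep <- maf > maf_min & variants$ac > 0 & variants$ac < variants$an
  v <- variants[keep, , drop = FALSE]
  pis <- site_pi(v$ac, v$an)
  syn <- v$effect == "synonymous"
  list(piS = if (Ls > 0) sum(pis[syn]) / Ls else NA_real_,
       piNS = if (Ln > 0) sum(pis[!syn]) / Ln else NA_real_)
}

#' Annotate variants with gene, codon context, and effect class
#'
#' Variants falling outside every CDS are retained with `coding = FALSE`.
#' Effect classification applies the focal variant alone to the
#' reference codon (per-variant classification, no pathway enumeration).
#'
#' @param variants a variant table
#' @param genes gene-model table
#' @param cds named vector of coding sequences
#' @return variants with columns gene_id, coding, codon, offset, effect
#' @export
annotate_variants <- function(variants, genes, cds) {
  n <- nrow(variants)
  out <- variants
  out$gene_id <- NA_character_
  out$coding <- FALSE
  out$codon <- NA_character_
  out$offset <- NA_integer_
  out$effect <- NA_character_
  if (n == 0) return(out)
  lev <- unique(c(genes$chrom, variants$chrom))
  cds_gr <- GenomicRanges::GRanges(
    seqnames = factor(rep(genes$chrom, vapply(genes$cds, nrow, integer(1))),
                      levels = lev),
    ranges = IRanges::IRanges(
      start = unlist(lapply(genes$cds, function(m) m[, 1])),
      end = unlist(lapply(genes$cds, function(m) m[, 2]))))
  gene_of <- rep(seq_len(nrow(genes)), vapply(genes$cds, nrow, integer(1)))
  v_gr <- GenomicRanges::GRanges(factor(variants$chrom, levels = lev),
                                 IRanges::IRanges(variants$pos, variants$pos))
  hits <- GenomicRanges::findOverlaps(v_gr, cds_gr, select = "first")
  chg <- codon_change_table()
  syn_of <- stats::setNames(chg$syn, paste(chg$codon, chg$pos - 1L, chg$alt))
  hit_gene <- ifelse(is.na(hits), NA_integer_, gene_of[hits])
  for (gi in unique(hit_gene[!is.na(hit_gene)])) {
    idx <- which(hit_gene == gi)
    g <- genes[gi, ]
    seq_g <- cds[[g$gene_id]]
    if (nchar(seq_g) %% 3 != 0)
      hs_error(paste0("gene ", g$gene_id, ": CDS length not divisible by 3"))
    pos_map <- cds_genomic_positions(g)
    cp <- match(variants$pos[idx], pos_map)
    ok <- !is.na(cp)
    idx <- idx[ok]; cp <- cp[ok]
    if (!length(idx)) next
    ref <- variants$ref[idx]; alt <- variants$alt[idx]
    if (g$strand == "-") {
      ref <- chartr("ACGT", "TGCA", ref)
      alt <- chartr("ACGT", "TGCA", alt)
    }
    cds_ref <- substring(seq_g, cp, cp)
    bad <- nzchar(ref) & cds_ref != ref
    if (any(bad))
      hs_error(paste0("reference allele mismatch at ", g$gene_id, ":",
                      paste(variants$pos[idx[bad]], collapse = ",")))
    ci <- (cp - 1L) %/% 3L + 1L
    offset <- (cp - 1L) %% 3L
    codon <- substring(seq_g, (ci - 1L) * 3L + 1L, ci * 3L)
    out$gene_id[idx] <- g$gene_id
    out$codon[idx] <- codon
    out$offset[idx] <- offset
    stops <- codon %in% stop_codons()
    out$coding[idx] <- !stops  # reference stop codons are excluded
    syn <- unname(syn_of[paste(codon, offset, alt)])
    out$effect[idx[!stops]] <- ifelse(syn[!stops] %in% TRUE,
                                      "synonymous", "nonsynonymous")
  }
  out
}

#' Count fixed differences against a single-allele outgroup
#'
#' A site contributes to divergence iff the ingroup is monomorphic there
#' (absent from the VCF, or AC == 0, or AC == AN) and the ingroup allele
#' differs from the outgroup allele. Codons with several fixed
#' differences are counted by NG86 pathway averaging
#' ([codon_path_counts()]). Polymorphic sites never contribute.
#'
#' @param variants variant table rows falling in this gene's CDS
#' @param outgroup outgroup rows (chrom, pos, allele) in this gene's CDS
#' @param gene one row of a gene-model table
#' @param cds the gene's coding sequence
#' @return list(Dn, Ds, skipped) where skipped counts ingroup-fixed
#'   sites lacking an outgroup allele
#' @export
count_divergence <- function(variants, outgroup, gene, cds) {
  L <- nchar(cds)
  pos_all <- cds_genomic_positions(gene)
  if (length(pos_all) != L)
    hs_error(paste0("gene ", gene$gene_id,
                    ": CDS length does not match gene model"))
  v <- variants[variants$pos %in% pos_all, , drop = FALSE]
  og <- outgroup[outgroup$pos %in% pos_all, , drop = FALSE]
  ref_nt <- strsplit(cds, "")[[1]]
  in_nt <- ref_nt
  poly <- rep(FALSE, L)
  skipped <- 0L
  if (nrow(v)) {
    cp <- match(v$pos, pos_all)
    a <- if (gene$strand == "-") revcomp(v$alt) else v$alt
    fixed <- v$ac == v$an
    in_nt[cp[fixed]] <- a[fixed]
    poly[cp[v$ac > 0 & !fixed]] <- TRUE
  }
  out_nt <- in_nt
  og_has <- rep(FALSE, L)
  if (nrow(og)) {
    cp <- match(og$pos, pos_all)
    a <- if (gene$strand == "-") revcomp(og$allele) else og$allele
    out_nt[cp] <- a
    og_has[cp] <- TRUE
  }
  # ingroup-fixed-alt sites with no outgroup call cannot be polarised
  fixed_alt <- which(in_nt != ref_nt & !og_has)
  if (length(fixed_alt)) {
    skipped <- length(fixed_alt)
    hs_log("gene ", gene$gene_id, ": ", skipped,
           " ingroup-fixed site(s) lack an outgroup allele; skipped")
    out_nt[fixed_alt] <- in_nt[fixed_alt]
  }
  out_nt[poly] <- in_nt[poly] <- ref_nt[poly]  # polymorphic sites never in D
  dn <- 0; ds <- 0
  n_codon <- L %/% 3L
  for (ci in seq_len(n_codon)) {
    idx <- ((ci - 1L) * 3L + 1L):(ci * 3L)
    ic <- paste(in_nt[idx], collapse = "")
    oc <- paste(out_nt[idx], collapse = "")
    if (ic == oc) next
    if (is_stop_codon(ic)) {
      hs_log("gene ", gene$gene_id, ": ingroup stop codon at codon ", ci,
             "; skipped for divergence")
      next
    }
    cnt <- codon_path_counts(ic, oc)
    dn <- dn + cnt[["nd"]]
    ds <- ds + cnt[["sd"]]
  }
  list(Dn = dn, Ds = ds, skipped = skipped)
}

#' Per-gene GC content and CpG observed/expected ratio
#' @param cds named vector of coding sequences
#' @return data.frame(gene_id, gc, cpg_oe)
#' @export
gene_seq_stats <- function(cds) {
  data.frame(gene_id = names(cds),
             gc = vapply(cds, gc_content, numeric(1), USE.NAMES = FALSE),
             cpg_oe = vapply(cds, cpg_oe, numeric(1), USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}

#' Full per-gene population-genetic summary
#'
#' Combines NG86 site totals, polymorphism counts, MAF-filtered
#' diversities, fixed differences against the outgroup, and sequence
#' composition into the per-gene table that feeds the MK/DoS stage.
#'
#' @param cds named vector of coding sequences
#' @param genes gene-model table
#' @param variants variant table
#' @param outgroup outgroup allele table
#' @param maf_min MAF threshold (exclusive) applied to pi, default 0.01
#' @param maf_filter_counts also apply the MAF filter to Pn/Ps
#'   (default FALSE: the threshold applies to diversity only)
#' @return data.frame, one row per gene
#' @export
popgen_gene_table <- function(cds, genes, variants, outgroup,
                              maf_min = 0.01, maf_filter_counts = FALSE) {
  ann <- annotate_variants(variants, genes, cds)
  ann <- ann[ann$coding & !is.na(ann$effect), , drop = FALSE]
  by_gene <- split(seq_len(nrow(ann)), ann$gene_id)
  # assign raw variant and outgroup rows to genes once, by CDS overlap
  lev <- unique(c(genes$chrom, variants$chrom, outgroup$chrom))
  gene_gr <- GenomicRanges::GRanges(factor(genes$chrom, levels = lev),
                                    IRanges::IRanges(genes$start, genes$end))
  v_of <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(factor(variants$chrom, levels = lev),
                           IRanges::IRanges(variants$pos, variants$pos)),
    gene_gr, select = "first")
  og_of <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(factor(outgroup$chrom, levels = lev),
                           IRanges::IRanges(outgroup$pos, outgroup$pos)),
    gene_gr, select = "first")
  v_split <- split(seq_len(nrow(variants)), v_of)
  og_split <- split(seq_len(nrow(outgroup)), og_of)
  comp <- gene_seq_stats(cds)
  rows <- lapply(seq_len(nrow(genes)), function(gi) {
    g <- genes[gi, ]
    sites <- gene_site_counts(cds[[g$gene_id]])
    idx <- by_gene[[g$gene_id]] %||% integer(0)
    va <- ann[idx, , drop = FALSE]
    pol <- va[va$ac > 0 & va$ac < va$an, , drop = FALSE]
    if (maf_filter_counts && nrow(pol)) {
      maf <- pmin(pol$ac / pol$an, 1 - pol$ac / pol$an)
      pol <- pol[maf > maf_min, , drop = FALSE]
    }
    pi <- gene_pi(va, sites$Ls, sites$Ln, maf_min = maf_min)
    dv <- count_divergence(
      variants[v_split[[as.character(gi)]] %||% integer(0), , drop = FALSE],
      outgroup[og_split[[as.character(gi)]] %||% integer(0), , drop = FALSE],
      g, cds[[g$gene_id]])
    data.frame(gene_id = g$gene_id,
               Ls = sites$Ls, Ln = sites$Ln,
               Pn = sum(pol$effect == "nonsynonymous"),
               Ps = sum(pol$effect == "synonymous"),
               Dn = dv$Dn, Ds = dv$Ds,
               piS = pi$piS, piNS = pi$piNS,
               pnps = if (!is.na(pi$piS) && pi$piS > 0) pi$piNS / pi$piS
                      else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  merge(out, comp, by = "gene_id", sort = TRUE)
}
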