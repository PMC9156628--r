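# Readers/writers for the external formats the pipeline touches, with
# strict validation. Coordinates are 1-based inclusive throughout (VCF /
# GFF convention).

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# ---- FASTA ------------------------------------------------------------

#' Read a FASTA file of coding sequences
#' @param path FASTA file
#' @return named character vector of sequences
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) hs_error(paste0("file not found: ", path))
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write sequences to FASTA
#' @param seqs named character vector
#' @param path output file
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

# ---- Gene models (GFF3 / BED) ----------------------------------------

#' Validate a gene-model table
#'
#' A gene-model table has one row per gene with columns `gene_id`,
#' `chrom`, `start`, `end`, `strand` and a list column `cds` of 2-column
#' (start, end) matrices of CDS intervals, sorted and non-overlapping,
#' with total length divisible by 3.
#'
#' @param gm gene-model data.frame
#' @return `gm`, invisibly, after validation
#' @export
validate_gene_models <- function(gm) {
  need <- c("gene_id", "chrom", "start", "end", "strand", "cds")
  if (!all(need %in% names(gm)))
    hs_error(paste0("gene models missing column(s): ",
                    paste(setdiff(need, names(gm)), collapse = ", ")))
  if (any(gm$start > gm$end)) hs_error("gene model with start > end")
  if (!all(gm$strand %in% c("+", "-"))) hs_error("strand must be + or -")
  for (i in seq_len(nrow(gm))) {
    iv <- gm$cds[[i]]
    if (is.null(dim(iv)) || ncol(iv) != 2)
      hs_error(paste0("gene ", gm$gene_id[i], ": cds must be a 2-col matrix"))
    if (any(iv[, 1] > iv[, 2]))
      hs_error(paste0("gene ", gm$gene_id[i], ": CDS interval start > end"))
    if (nrow(iv) > 1) {
      o <- order(iv[, 1])
      iv <- iv[o, , drop = FALSE]
      if (any(iv[-1, 1] <= iv[-nrow(iv), 2]))
        hs_error(paste0("gene ", gm$gene_id[i], ": overlapping CDS intervals"))
    }
    if (sum(iv[, 2] - iv[, 1] + 1) %% 3 != 0)
      hs_error(paste0("gene ", gm$gene_id[i],
                      ": CDS length not divisible by 3"))
  }
  invisible(gm)
}

#' Write gene models to GFF3
#' @param gm gene-model table (see [validate_gene_models()])
#' @param path output file
#' @export
write_gff3 <- function(gm, path) {
  validate_gene_models(gm)
  n_iv <- vapply(gm$cds, nrow, integer(1))
  rep_g <- rep(seq_len(nrow(gm)), n_iv)
  gr <- GenomicRanges::GRanges(
    seqnames = c(gm$chrom, gm$chrom[rep_g]),
    ranges = IRanges::IRanges(
      start = c(gm$start, unlist(lapply(gm$cds, function(m) m[, 1]))),
      end = c(gm$end, unlist(lapply(gm$cds, function(m) m[, 2])))),
    strand = c(gm$strand, gm$strand[rep_g]))
  S4Vectors::mcols(gr)$type <- c(rep("gene", nrow(gm)), rep("CDS", sum(n_iv)))
  S4Vectors::mcols(gr)$ID <- c(gm$gene_id,
                               paste0(gm$gene_id[rep_g], ".cds",
                                      unlist(lapply(n_iv, seq_len))))
  S4Vectors::mcols(gr)$Parent <- c(rep(NA_character_, nrow(gm)),
                                   gm$gene_id[rep_g])
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  # suppress the benign "phase information missing" note
  suppressWarnings(rtracklayer::export(gr, path, format = "gff3"))
  invisible(path)
}

#' Read gene models from GFF3
#' @param path GFF3 file with gene and CDS features
#' @return gene-model table
#' @export
read_gff <- function(path) {
  if (!file.exists(path)) hs_error(paste0("file not found: ", path))
  gr <- rtracklayer::import(path, format = "gff3")
  cds <- gr[gr$type == "CDS"]
  if (length(cds) == 0) hs_error(paste0("no CDS features in ", path))
  parent <- as.character(cds$Parent)
  df <- data.frame(parent = parent,
                   chrom = as.character(GenomicRanges::seqnames(cds)),
                   start = GenomicRanges::start(cds),
                   end = GenomicRanges::end(cds),
                   strand = as.character(GenomicRanges::strand(cds)),
                   stringsAsFactors = FALSE)
  ids <- unique(parent)
  sp <- split(df, factor(df$parent, levels = ids))
  gm <- data.frame(
    gene_id = ids,
    chrom = vapply(sp, function(s) s$chrom[1], character(1)),
    start = vapply(sp, function(s) min(s$start), numeric(1)),
    end = vapply(sp, function(s) max(s$end), numeric(1)),
    strand = vapply(sp, function(s) s$strand[1], character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  gm$cds <- lapply(sp, function(s) {
    iv <- cbind(start = s$start, end = s$end)
    iv[order(iv[, 1]), , drop = FALSE]
  })
  validate_gene_models(gm)
  gm
}

#' Read gene models from BED (single-interval CDS per gene)
#' @param path BED file (chrom, start, end, name, score, strand)
#' @return gene-model table
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) hs_error(paste0("file not found: ", path))
  gr <- rtracklayer::import(path, format = "bed")
  gm <- data.frame(gene_id = gr$name,
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  gm$strand[!gm$strand %in% c("+", "-")] <- "+"
  gm$cds <- lapply(seq_len(nrow(gm)),
                   function(i) cbind(start = gm$start[i], end = gm$end[i]))
  validate_gene_models(gm)
  gm
}

# ---- VCF --------------------------------------------------------------

#' Validate a variant table
#'
#' Columns: `chrom`, `pos` (1-based), `ref`, `alt` (single nucleotides),
#' `ac` (alt allele count), `an` (total called alleles).
#' @param vt data.frame
#' @return `vt` invisibly
#' @export
validate_variant_table <- function(vt) {
  need <- c("chrom", "pos", "ref", "alt", "ac", "an")
  if (!all(need %in% names(vt)))
    hs_error(paste0("variant table missing column(s): ",
                    paste(setdiff(need, names(vt)), collapse = ", ")))
  if (nrow(vt) == 0) return(invisible(vt))
  if (any(nchar(vt$ref) != 1 | nchar(vt$alt) != 1))
    hs_error("only single-nucleotide alleles are supported")
  if (any(vt$ref == vt$alt)) hs_error("ref == alt in variant table")
  if (any(vt$ac < 0 | vt$ac > vt$an))
    hs_error("AC must satisfy 0 <= AC <= AN")
  invisible(vt)
}

#' Write a variant table as VCF v4.2
#' @param vt variant table (see [validate_variant_table()])
#' @param path output file
#' @export
write_vcf <- function(vt, path) {
  validate_variant_table(vt)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=haplosel",
           paste0("##INFO=<ID=AC,Number=A,Type=Integer,",
                  "Description=\"Alternate allele count\">"),
           paste0("##INFO=<ID=AN,Number=1,Type=Integer,",
                  "Description=\"Total called alleles\">"),
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", sep = "\t"))
  o <- order(vt$chrom, vt$pos)
  vt <- vt[o, , drop = FALSE]
  body <- if (nrow(vt)) {
    paste(vt$chrom, vt$pos, ".", vt$ref, vt$alt, ".", "PASS",
          paste0("AC=", vt$ac, ";AN=", vt$an), sep = "\t")
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF into a variant table
#'
#' Multi-allelic records are split into independent biallelic records
#' (per-alt AC). AC/AN are taken from INFO, or computed from genotypes
#' when absent.
#'
#' @param path VCF file (plain text or bgzipped)
#' @return validated variant table
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) hs_error(paste0("file not found: ", path))
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  ref <- as.character(rr$REF)
  alt <- as.character(rr$ALT)
  ac <- info$AC
  an <- info$AN
  if (is.null(ac) || is.null(an)) {
    gt <- tryCatch(VariantAnnotation::geno(vcf)$GT, error = function(e) NULL)
    if (is.null(gt))
      hs_error(paste0(path, ": INFO AC/AN absent and no genotypes to ",
                      "compute them from"))
    alleles <- apply(gt, 1, function(g) unlist(strsplit(g, "[/|]")))
    ac <- vapply(seq_len(nrow(gt)),
                 function(i) sum(alleles[, i] == "1"), integer(1))
    an <- vapply(seq_len(nrow(gt)),
                 function(i) sum(alleles[, i] %in% c("0", "1")), integer(1))
  }
  vt <- data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
                   pos = GenomicRanges::start(rr),
                   ref = ref, alt = alt,
                   ac = as.integer(unlist(ac)), an = as.integer(unlist(an)),
                   stringsAsFactors = FALSE)
  keep <- nchar(vt$ref) == 1 & nchar(vt$alt) == 1
  if (any(!keep)) {
    hs_log(sum(!keep), " non-SNV record(s) dropped from ", basename(path))
    vt <- vt[keep, , drop = FALSE]
  }
  rownames(vt) <- NULL
  validate_variant_table(vt)
  vt
}

#' Read / write an outgroup allele table
#'
#' Three-column TSV: chrom, pos (1-based), allele — a single haploid
#' outgroup allele column.
#' @param path TSV file
#' @return data.frame(chrom, pos, allele)
#' @export
read_outgroup <- function(path) {
  if (!file.exists(path)) hs_error(paste0("file not found: ", path))
  og <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "allele")
  if (!all(need %in% names(og)))
    hs_error(paste0(path, ": outgroup table needs columns chrom, pos, allele"))
  if (nrow(og) && any(!og$allele %in% BASES))
    hs_error(paste0(path, ": outgroup alleles must be single bases"))
  og
}

#' @rdname read_outgroup
#' @param og outgroup table
#' @export
write_outgroup <- function(og, path) {
  utils::write.table(og[order(og$chrom, og$pos), ], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- Expression counts and sample metadata ---------------------------

#' Read a gene x sample count matrix from TSV
#' @param path TSV with a `gene_id` column followed by sample columns
#' @return integer matrix with gene rownames
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) hs_error(paste0("file not found: ", path))
  dt <- data.table::fread(path, sep = "\t", data.table = FALSE)
  if (!"gene_id" %in% names(dt))
    hs_error(paste0(path, ": counts TSV needs a gene_id column"))
  m <- as.matrix(dt[, setdiff(names(dt), "gene_id"), drop = FALSE])
  rownames(m) <- dt$gene_id
  storage.mode(m) <- "integer"
  if (any(m < 0, na.rm = TRUE)) hs_error(paste0(path, ": negative counts"))
  if (anyNA(m)) hs_error(paste0(path, ": missing counts"))
  m
}

#' @rdname read_counts
#' @param m count matrix
#' @export
write_counts <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read / validate sample metadata
#' @param path TSV with columns sample, sex, tissue, stage
#' @return data.frame
#' @export
read_sample_meta <- function(path) {
  if (!file.exists(path)) hs_error(paste0("file not found: ", path))
  sm <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_sample_meta(sm)
  sm
}

#' @rdname read_sample_meta
#' @param sm sample metadata data.frame
#' @export
validate_sample_meta <- function(sm) {
  need <- c("sample", "sex", "tissue", "stage")
  if (!all(need %in% names(sm)))
    hs_error(paste0("sample metadata needs columns ",
                    paste(need, collapse = ", ")))
  if (!all(sm$sex %in% SEXES)) hs_error("sex must be male or female")
  if (!all(sm$tissue %in% TISSUES))
    hs_error(paste0("tissue must be one of ", paste(TISSUES, collapse = ", ")))
  if (anyNA(sm)) hs_error("sample metadata has missing fields")
  invisible(sm)
}

#' @rdname read_sample_meta
#' @export
write_sample_meta <- function(sm, path) {
  utils::write.table(sm, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- Linkage map ------------------------------------------------------

#' Read and validate a linkage map
#'
#' TSV columns: `chrom`, `bp` (physical position), `cM` (genetic
#' position). Per chromosome, physical positions must be strictly
#' increasing and genetic positions non-decreasing.
#'
#' @param path TSV file
#' @return data.frame(chrom, bp, cM)
#' @export
read_linkage_map <- function(path) {
  if (!file.exists(path)) hs_error(paste0("file not found: ", path))
  lm <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_linkage_map(lm)
  lm
}

#' @rdname read_linkage_map
#' @param lmap linkage-map data.frame
#' @export
validate_linkage_map <- function(lmap) {
  need <- c("chrom", "bp", "cM")
  if (!all(need %in% names(lmap)))
    hs_error("linkage map needs columns chrom, bp, cM")
  for (ch in unique(lmap$chrom)) {
    sub <- lmap[lmap$chrom == ch, ]
    sub <- sub[order(sub$bp), ]
    if (any(duplicated(sub$bp)))
      hs_error(paste0("chromosome ", ch, ": duplicated physical positions"))
    if (is.unsorted(sub$cM))
      hs_error(paste0("chromosome ", ch, ": genetic positions decrease"))
  }
  invisible(lmap)
}

#' @rdname read_linkage_map
#' @export
write_linkage_map <- function(lmap, path) {
  utils::write.table(lmap[order(lmap$chrom, lmap$bp), ], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- Codon context ----------------------------------------------------

#' Map a genomic position to its CDS coordinate within a gene
#'
#' @param gene one row of a gene-model table (list or 1-row data.frame)
#' @param pos genomic position (1-based)
#' @return 1-based position in the spliced, strand-oriented CDS, or NA
#'   when the position is not coding
#' @export
cds_position <- function(gene, pos) {
  iv <- gene$cds[[1]]
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  hit <- which(pos >= iv[, 1] & pos <= iv[, 2])
  if (length(hit) == 0) return(NA_integer_)
  before <- if (hit > 1) sum(iv[seq_len(hit - 1), 2] -
                             iv[seq_len(hit - 1), 1] + 1) else 0L
  plus_pos <- before + (pos - iv[hit, 1] + 1L)
  total <- sum(iv[, 2] - iv[, 1] + 1)
  if (gene$strand == "+") as.integer(plus_pos)
  else as.integer(total - plus_pos + 1L)
}

#' Map a CDS coordinate back to the genomic position
#' @param gene one row of a gene-model table
#' @param cds_pos 1-based CDS coordinate
#' @return genomic position (1-based)
#' @export
genomic_position <- function(gene, cds_pos) {
  iv <- gene$cds[[1]]
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  total <- sum(iv[, 2] - iv[, 1] + 1)
  if (cds_pos < 1 || cds_pos > total) hs_error("cds_pos outside the CDS")
  plus_pos <- if (gene$strand == "+") cds_pos else total - cds_pos + 1L
  lens <- iv[, 2] - iv[, 1] + 1
  cum <- cumsum(lens)
  hit <- which(plus_pos <= cum)[1]
  before <- if (hit > 1) cum[hit - 1] else 0L
  as.integer(iv[hit, 1] + (plus_pos - before) - 1L)
}

#' Genomic positions of every CDS coordinate of a gene, in CDS order
#' @param gene one row of a gene-model table
#' @return integer vector: element i is the genomic position of CDS
#'   coordinate i (strand-aware)
#' @export
cds_genomic_positions <- function(gene) {
  iv <- gene$cds[[1]]
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  pos <- unlist(lapply(seq_len(nrow(iv)),
                       function(i) seq.int(iv[i, 1], iv[i, 2])))
  if (gene$strand == "-") rev(pos) else pos
}

#' Extract the codon context of a variant
#'
#' Returns the reference codon containing the variant, the 0-based offset
#' of the variant within that codon, and the strand-adjusted alleles
#' (reverse-complemented for minus-strand genes).
#'
#' @param gene one row of a gene-model table
#' @param cds the gene's coding sequence (coding strand)
#' @param pos genomic position of the variant
#' @param ref,alt alleles as reported on the reference (plus) strand
#' @return list(codon, offset, ref, alt, codon_index) or NULL when the
#'   position is not coding
#' @export
extract_codon_context <- function(gene, cds, pos, ref, alt) {
  if (nchar(cds) %% 3 != 0) hs_error("CDS length not divisible by 3")
  cp <- cds_position(gene, pos)
  if (is.na(cp)) return(NULL)
  if (gene$strand == "-") {
    ref <- revcomp(ref)
    alt <- revcomp(alt)
  }
  cds_ref <- substr(cds, cp, cp)
  if (nzchar(ref) && cds_ref != ref)
    hs_error(paste0("reference allele mismatch at ", gene$gene_id, ":", pos,
                    " (CDS has ", cds_ref, ", VCF says ", ref, ")"))
  codon_index <- (cp - 1L) %/% 3L + 1L
  offset <- (cp - 1L) %% 3L
  codon <- substr(cds, (codon_index - 1L) * 3L + 1L, codon_index * 3L)
  list(codon = codon, offset = offset, ref = ref, alt = alt,
       codon_index = codon_index)
}
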