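options(haplosel.quiet = TRUE)

# small simulation config for fast tests
small_cfg <- function(n_genes = 50, seed = 42, ...) {
  sim_config(n_genes = n_genes, gene_length_codons = c(50, 150),
             n_chromosomes = 4, markers_per_chromosome = 20,
             chrom_length_bp = 2e6, seed = seed, ...)
}

# a hand-built two-gene fixture: one plus-strand, one minus-strand gene
# with a two-interval CDS, for coordinate arithmetic tests
toy_genes <- function() {
  gm <- data.frame(gene_id = c("gplus", "gminus"),
                   chrom = c("chrA", "chrA"),
                   start = c(1L, 101L), end = c(9L, 115L),
                   strand = c("+", "-"),
                   stringsAsFactors = FALSE)
  gm$cds <- list(cbind(start = 1L, end = 9L),
                 cbind(start = c(101L, 110L), end = c(106L, 115L)))
  gm
}

# CDS sequences for toy_genes(); gminus genomic plus-strand sequence is
# the reverse complement of its CDS laid over the two intervals
toy_cds <- function() {
  c(gplus = "ATGAAATAA",
    gminus = "ATGCCAGTTTGA")  # 4 codons, 12 nt over 2 intervals of 6
}

# brute-force average pairwise difference partitioned by effect class;
# the independent oracle for gene_pi
brute_force_pi <- function(haplotypes, effects, Ls, Ln) {
  n <- nrow(haplotypes)
  stopifnot(n >= 2, length(effects) == ncol(haplotypes))
  diff_s <- 0; diff_n <- 0
  pairs <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- haplotypes[i, ] != haplotypes[j, ]
      diff_s <- diff_s + sum(d & effects == "synonymous")
      diff_n <- diff_n + sum(d & effects == "nonsynonymous")
      pairs <- pairs + 1
    }
  }
  list(piS = diff_s / pairs / Ls, piNS = diff_n / pairs / Ln)
}
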