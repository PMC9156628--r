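# Codon-level machinery: the standard genetic code, Nei-Gojobori (1986)
# equal-weight site counting, per-change effect classification, and
# pathway-averaged counting for codons separated by multiple substitutions.

BASES <- c("A", "C", "G", "T")

.codon_tables <- local({
  gc_tab <- Biostrings::GENETIC_CODE
  codons <- names(gc_tab)
  aa <- unname(gc_tab)
  stops <- codons[aa == "*"]
  # Every single-nucleotide change of every codon, classified once.
  chg <- do.call(rbind, lapply(codons, function(cod) {
    nt <- strsplit(cod, "")[[1]]
    out <- expand.grid(pos = 1:3, alt = BASES, stringsAsFactors = FALSE)
    out <- out[out$alt != nt[out$pos], ]
    to <- vapply(seq_len(nrow(out)), function(i) {
      mut <- nt
      mut[out$pos[i]] <- out$alt[i]
      paste(mut, collapse = "")
    }, character(1))
    data.frame(codon = cod, pos = out$pos, alt = out$alt, to = to,
               stringsAsFactors = FALSE)
  }))
  chg$syn <- unname(gc_tab[chg$codon] == gc_tab[chg$to]) &
    unname(gc_tab[chg$to] != "*")
  chg$stop_gain <- unname(gc_tab[chg$to] == "*")
  # stop -> stop treated as neither (reference stops are excluded anyway);
  # sense -> stop is nonsynonymous by convention.
  sense <- codons[aa != "*"]
  ls <- vapply(sense, function(cod) {
    sum(chg$syn[chg$codon == cod]) / 3
  }, numeric(1))
  list(codons = codons, aa = stats::setNames(aa, codons), stops = stops,
       sense = sense, changes = chg,
       ls = stats::setNames(ls, sense),
       ln = stats::setNames(3 - ls, sense))
})

is_stop_codon <- function(codon) codon %in% .codon_tables$stops

translate_codon <- function(codon) {
  aa <- .codon_tables$aa[codon]
  if (any(is.na(aa))) hs_error(paste0("invalid codon: ",
                                      paste(codon[is.na(aa)], collapse = ", ")))
  unname(aa)
}

#' Nei-Gojobori synonymous/nonsynonymous site counts for one codon
#'
#' Counts the fraction of the three positions of a codon at which
#' single-nucleotide changes are synonymous, under equal weighting of the
#' nine possible changes (NG86). Changes creating a stop codon count as
#' nonsynonymous; reference stop codons are excluded from counting
#' entirely and raise a classed condition.
#'
#' @param codon a 3-letter string over A, C, G, T
#' @return named numeric vector `c(ls = , ln = )` with `ls + ln == 3`
#' @examples
#' codon_site_counts("TTT")  # ls = 1/3
#' @export
codon_site_counts <- function(codon) {
  if (!is.character(codon) || length(codon) != 1L || nchar(codon) != 3L ||
      grepl("[^ACGT]", codon))
    hs_error(paste0("codon must be a 3-letter ACGT string, got '",
                    codon, "'"))
  if (is_stop_codon(codon))
    hs_error(paste0("stop codon '", codon, "' is excluded from site counting"),
             class = "haplosel_stop_codon")
  ls <- .codon_tables$ls[[codon]]
  c(ls = ls, ln = 3 - ls)
}

#' Classify a single-nucleotide change as synonymous or nonsynonymous
#'
#' @param codon reference codon (sense codon, coding strand)
#' @param offset 0-based position of the change within the codon (0, 1, 2)
#' @param alt_base replacement base, distinct from the reference base
#' @return `"synonymous"` or `"nonsynonymous"`
#' @examples
#' classify_change("TTT", 2, "C")  # synonymous (Phe -> Phe)
#' @export
classify_change <- function(codon, offset, alt_base) {
  if (!offset %in% 0:2) hs_error("offset must be 0, 1 or 2")
  if (is_stop_codon(codon))
    hs_error("reference stop codons are excluded",
             class = "haplosel_stop_codon")
  nt <- strsplit(codon, "")[[1]]
  if (is.na(.codon_tables$aa[codon])) hs_error(paste0("invalid codon ", codon))
  if (!alt_base %in% BASES) hs_error("alt base must be one of A, C, G, T")
  if (alt_base == nt[offset + 1L])
    hs_error("alt base equals the reference base")
  mut <- nt
  mut[offset + 1L] <- alt_base
  mut <- paste(mut, collapse = "")
  if (.codon_tables$aa[mut] == "*") return("nonsynonymous")
  if (.codon_tables$aa[mut] == .codon_tables$aa[codon]) "synonymous"
  else "nonsynonymous"
}

#' Pathway-averaged substitution counts between two codons (NG86)
#'
#' For codons differing at k positions, averages synonymous and
#' nonsynonymous step counts over the k! minimal mutational paths.
#' Paths passing through an intermediate stop codon are excluded; if all
#' paths are blocked, all are used with stop-creating steps counted as
#' nonsynonymous.
#'
#' @param from,to codon strings (coding strand)
#' @return named numeric vector `c(nd = , sd = )`
#' @export
codon_path_counts <- function(from, to) {
  nt_from <- strsplit(from, "")[[1]]
  nt_to <- strsplit(to, "")[[1]]
  diff_pos <- which(nt_from != nt_to)
  k <- length(diff_pos)
  if (k == 0L) return(c(nd = 0, sd = 0))
  aa <- .codon_tables$aa
  perms <- if (k == 1L) list(diff_pos) else {
    if (k == 2L) list(diff_pos, rev(diff_pos))
    else {
      idx <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
      lapply(idx, function(o) diff_pos[o])
    }
  }
  walk <- function(order) {
    cur <- nt_from
    nd <- 0; sd <- 0; blocked <- FALSE
    for (p in order) {
      nxt <- cur
      nxt[p] <- nt_to[p]
      a1 <- aa[paste(cur, collapse = "")]
      a2 <- aa[paste(nxt, collapse = "")]
      if (a2 == "*" && paste(nxt, collapse = "") != to) blocked <- TRUE
      if (!is.na(a1) && !is.na(a2) && a1 == a2 && a2 != "*") sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    list(nd = nd, sd = sd, blocked = blocked)
  }
  res <- lapply(perms, walk)
  ok <- !vapply(res, `[[`, logical(1), "blocked")
  use <- if (any(ok)) res[ok] else res
  nd <- mean(vapply(use, `[[`, numeric(1), "nd"))
  sd <- mean(vapply(use, `[[`, numeric(1), "sd"))
  c(nd = nd, sd = sd)
}

#' Per-gene NG86 site totals
#'
#' Splits a CDS into codons, drops stop codons (terminal or internal) from
#' all denominators, and sums synonymous (Ls) and nonsynonymous (Ln) site
#' counts.
#'
#' @param cds coding sequence string, length divisible by 3
#' @return list with `Ls`, `Ln`, and per-codon vectors `ls`, `ln`
#'   (stop codons carry NA)
#' @export
gene_site_counts <- function(cds) {
  if (nchar(cds) %% 3 != 0)
    hs_error("CDS length must be divisible by 3")
  codons <- codon_split(cds)
  ls <- unname(.codon_tables$ls[codons])
  ln <- unname(.codon_tables$ln[codons])
  bad <- is.na(ls) & !codons %in% .codon_tables$stops
  if (any(bad)) hs_error(paste0("ambiguous or invalid codon(s): ",
                                paste(unique(codons[bad]), collapse = ", ")))
  list(Ls = sum(ls, na.rm = TRUE), Ln = sum(ln, na.rm = TRUE),
       ls = ls, ln = ln, codons = codons)
}

codon_split <- function(cds) {
  substring(cds, seq(1, nchar(cds), by = 3), seq(3, nchar(cds), by = 3))
}

#' GC content of a sequence
#' @param seq DNA string (A, C, G, T only)
#' @return fraction of G + C
#' @export
gc_content <- function(seq) {
  if (!nzchar(seq)) hs_error("empty sequence")
  if (grepl("[^ACGT]", seq)) hs_error("sequence must contain only A, C, G, T")
  nt <- strsplit(seq, "")[[1]]
  mean(nt %in% c("G", "C"))
}

#' Observed/expected CpG dinucleotide ratio
#'
#' CpGo/e = (#CG dinucleotides * L) / (#C * #G). Depressed values are the
#' classic footprint of germline cytosine methylation. Undefined (NA) when
#' the sequence contains no C or no G.
#'
#' @param seq DNA string (A, C, G, T only)
#' @return ratio, or NA when undefined
#' @export
cpg_oe <- function(seq) {
  if (!nzchar(seq)) hs_error("empty sequence")
  if (grepl("[^ACGT]", seq)) hs_error("sequence must contain only A, C, G, T")
  nt <- strsplit(seq, "")[[1]]
  n_c <- sum(nt == "C"); n_g <- sum(nt == "G")
  if (n_c * n_g == 0) return(NA_real_)
  n_cg <- sum(nt[-length(nt)] == "C" & nt[-1] == "G")
  n_cg * length(nt) / (n_c * n_g)
}

# Internal: matrix of all single-nt changes for fast candidate lookup in
# the simulator. One row per (codon, pos, alt).
codon_change_table <- function() .codon_tables$changes
sense_codons <- function() .codon_tables$sense
stop_codons <- function() .codon_tables$stops
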