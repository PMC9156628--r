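# McDonald-Kreitman test, Direction of Selection, and proportion
# comparisons between gene classes.

#' Direction of Selection
#'
#' DoS = Dn/(Dn + Ds) - Pn/(Pn + Ps). Positive under adaptive evolution,
#' zero under neutrality, negative when slightly deleterious variants
#' segregate. Undefined (NA) when either denominator is zero.
#'
#' @param Dn,Ds fixed nonsynonymous/synonymous differences
#' @param Pn,Ps polymorphic nonsynonymous/synonymous counts
#' @return DoS in [-1, 1], or NA (vectorised)
#' @export
dos <- function(Dn, Ds, Pn, Ps) {
  if (any(c(Dn, Ds, Pn, Ps) < 0, na.rm = TRUE))
    hs_error("counts must be >= 0")
  d_tot <- Dn + Ds
  p_tot <- Pn + Ps
  ifelse(d_tot == 0 | p_tot == 0, NA_real_, Dn / d_tot - Pn / p_tot)
}

#' McDonald-Kreitman chi-squared test
#'
#' Pearson chi-squared (df = 1) on the 2x2 table [[Dn, Ds], [Pn, Ps]],
#' without continuity correction by default. Degenerate margins (a zero
#' row or column total) give chi2 = 0, p = 1.
#'
#' @param Dn,Ds,Pn,Ps the four MK counts
#' @param correct apply the Yates continuity correction
#' @return list(chi2, p)
#' @export
mk_chi2 <- function(Dn, Ds, Pn, Ps, correct = FALSE) {
  if (any(c(Dn, Ds, Pn, Ps) < 0)) hs_error("counts must be >= 0")
  a <- Dn; b <- Ds; c_ <- Pn; d <- Ps
  n <- a + b + c_ + d
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; c2 <- b + d
  if (n < 1 || r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0)
    return(list(chi2 = 0, p = 1))
  delta <- abs(a * d - b * c_)
  if (correct) delta <- max(0, delta - n / 2)
  chi2 <- n * delta^2 / (r1 * r2 * c1 * c2)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Flag a gene as showing evidence of positive selection
#'
#' True iff the MK p-value is below `p_max` and DoS is defined and above
#' `dos_min`. The DoS threshold defaults to 0 (an excess of fixed
#' nonsynonymous differences), since DoS is bounded in [-1, 1].
#'
#' @param mk_p MK test p-value(s)
#' @param dos_value DoS value(s)
#' @param p_max significance threshold, default 0.05
#' @param dos_min DoS threshold, default 0
#' @return logical (vectorised); FALSE when DoS is undefined
#' @export
flag_positive <- function(mk_p, dos_value, p_max = 0.05, dos_min = 0) {
  !is.na(dos_value) & !is.na(mk_p) & mk_p < p_max & dos_value > dos_min
}

#' Per-gene MK/DoS table
#'
#' @param gt per-gene table with columns Pn, Ps, Dn, Ds (e.g. from
#'   [popgen_gene_table()])
#' @param p_max,dos_min thresholds for [flag_positive()]
#' @param correct Yates correction flag for [mk_chi2()]
#' @return `gt` with columns dos, mk_chi2, mk_p, positive appended
#' @export
mk_table <- function(gt, p_max = 0.05, dos_min = 0, correct = FALSE) {
  gt$dos <- dos(gt$Dn, gt$Ds, gt$Pn, gt$Ps)
  mk <- lapply(seq_len(nrow(gt)), function(i)
    mk_chi2(gt$Dn[i], gt$Ds[i], gt$Pn[i], gt$Ps[i], correct = correct))
  gt$mk_chi2 <- vapply(mk, `[[`, numeric(1), "chi2")
  gt$mk_p <- vapply(mk, `[[`, numeric(1), "p")
  gt$positive <- flag_positive(gt$mk_p, gt$dos, p_max, dos_min)
  gt
}

#' Two-proportion chi-squared test
#'
#' Pearson chi-squared (df = 1, no continuity correction) comparing
#' k1/n1 against k2/n2 via the 2x2 success/failure table.
#'
#' @param k1,n1 successes and trials in group 1
#' @param k2,n2 successes and trials in group 2
#' @return list(chi2, p)
#' @export
compare_proportions <- function(k1, n1, k2, n2) {
  if (n1 < 1 || n2 < 1) hs_error("n must be >= 1")
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2)
    hs_error("need 0 <= k <= n")
  mk_chi2(k1, n1 - k1, k2, n2 - k2)
}
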