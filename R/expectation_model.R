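# Relaxed-selection null-expectation model for haplodiploids: the
# Kimura relative fixation rate maps a scaled selection coefficient
# gamma = 2*Ne*s to an expected dN/dS; an exposure coefficient in (0, 1]
# scales gamma to reflect the fraction of selection a gene class "sees"
# (constitutive genes 1, sex-limited genes 1/2 by default, genes under
# postcopulatory sexual selection between the two as a function of the
# harmonic mean mate number H).

#' Expected dN/dS from a scaled selection coefficient
#'
#' omega(g) = g / (1 - exp(-g)) with g = exposure * gamma, the classic
#' relative fixation rate of a new semidominant mutation; omega(0) = 1
#' by continuity.
#'
#' @param gamma scaled selection strength 2*Ne*s (vectorised)
#' @param exposure coefficient in (0, 1] scaling gamma
#' @return expected dN/dS
#' @export
omega_from_gamma <- function(gamma, exposure = 1) {
  if (exposure <= 0 || exposure > 1) hs_error("exposure must be in (0, 1]")
  g <- exposure * gamma
  out <- numeric(length(g))
  small <- abs(g) < 1e-8
  out[small] <- 1
  big_pos <- g > 700
  big_neg <- g < -700
  out[big_pos] <- g[big_pos]
  out[big_neg] <- 0
  mid <- !small & !big_pos & !big_neg
  out[mid] <- g[mid] / (-expm1(-g[mid]))
  out
}

#' Invert the fixation-rate map: gamma from an observed dN/dS
#'
#' Bisection of [omega_from_gamma()] over g in [-1000, 1000] to
#' tolerance 1e-10; the round trip reproduces omega to better than 1e-8.
#'
#' @param omega_obs observed dN/dS (> 0)
#' @param exposure exposure coefficient in (0, 1]
#' @return gamma_hat such that omega_from_gamma(gamma_hat, exposure)
#'   equals `omega_obs`
#' @export
gamma_from_omega <- function(omega_obs, exposure = 1) {
  if (!is.finite(omega_obs) || omega_obs <= 0)
    hs_error("omega_obs must be > 0")
  if (abs(omega_obs - 1) < 1e-12) return(0)
  f <- function(g) omega_from_gamma(g, exposure = exposure) - omega_obs
  lo <- -1000; hi <- 1000
  if (f(lo) > 0 || f(hi) < 0) hs_error("omega_obs outside invertible range")
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) <= 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-10) break
  }
  (lo + hi) / 2
}

#' Null-expected Pn/Ps (or piNS/piS) for sex-biased genes
#'
#' Under the relaxed-selection null for arrhenotokous species, sex-
#' limited genes see half the selection of constitutive genes, doubling
#' the expected ratio: returns 2 x the constitutive value.
#'
#' @param pnps_constitutive observed constitutive-gene ratio (>= 0)
#' @return two-fold relaxed expectation
#' @export
expected_sex_biased_pnps <- function(pnps_constitutive) {
  if (any(pnps_constitutive < 0)) hs_error("input must be >= 0")
  2 * pnps_constitutive
}

#' Null-expected dN/dS for sex-biased genes
#'
#' Infers gamma from the observed constitutive dN/dS at full exposure,
#' then maps it back through the fixation-rate form at reduced exposure
#' (`relax_factor`, default 1/2, mirroring the two-fold polymorphism
#' relaxation).
#'
#' @param omega_constitutive observed constitutive-gene dN/dS (> 0)
#' @param relax_factor exposure of sex-biased genes relative to
#'   constitutive genes, in (0, 1]
#' @return expected sex-biased dN/dS
#' @export
expected_sex_biased_omega <- function(omega_constitutive,
                                      relax_factor = 0.5) {
  gamma_hat <- gamma_from_omega(omega_constitutive, exposure = 1)
  omega_from_gamma(gamma_hat, exposure = relax_factor)
}

#' Harmonic mean
#' @param mate_counts positive numeric vector (e.g. mates per female)
#' @return n / sum(1/x)
#' @export
harmonic_mean <- function(mate_counts) {
  if (length(mate_counts) == 0) hs_error("empty input")
  if (any(mate_counts <= 0)) hs_error("counts must be > 0")
  length(mate_counts) / sum(1 / mate_counts)
}

#' Exposure coefficient for genes under postcopulatory sexual selection
#'
#' Selection efficacy on PCSS genes rises with the harmonic mean number
#' of mates per female, H: exposure = exposure_sex * H / (H + 1),
#' strictly increasing in H and saturating at the sex-limited exposure.
#' With the honey-bee H of about 14 this leaves PCSS genes barely more
#' exposed than other sex-limited genes.
#'
#' @param H harmonic mean mate number (>= 1)
#' @param exposure_sex exposure of sex-limited genes, default 0.5
#' @return PCSS exposure coefficient
#' @export
pcss_exposure <- function(H, exposure_sex = 0.5) {
  if (any(H < 1)) hs_error("H must be >= 1")
  exposure_sex * H / (H + 1)
}

#' Class-level null expectations table
#'
#' @param pnps_constitutive observed constitutive Pn/Ps or piNS/piS
#' @param omega_constitutive observed constitutive dN/dS
#' @param relax_factor sex-biased exposure, default 0.5
#' @param H harmonic mean mate number for the PCSS class, default 14
#' @return data.frame(class, expected_pnps, expected_omega, gamma_hat)
#' @export
expectation_table <- function(pnps_constitutive, omega_constitutive,
                              relax_factor = 0.5, H = 14) {
  gamma_hat <- gamma_from_omega(omega_constitutive, exposure = 1)
  data.frame(
    class = c("constitutive", "haploid_biased", "diploid_biased", "pcss"),
    expected_pnps = c(pnps_constitutive,
                      rep(expected_sex_biased_pnps(pnps_constitutive), 2),
                      expected_sex_biased_pnps(pnps_constitutive)),
    expected_omega = c(omega_constitutive,
                       rep(omega_from_gamma(gamma_hat, relax_factor), 2),
                       omega_from_gamma(gamma_hat,
                                        pcss_exposure(H, relax_factor))),
    gamma_hat = gamma_hat,
    stringsAsFactors = FALSE)
}
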