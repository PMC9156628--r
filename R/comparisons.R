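# Group-comparison statistics: one-way ANOVA, ANCOVA with a covariate
# (type-II F for the group factor), Tukey HSD, and OLS regression of a
# per-gene statistic on log2 expression bias.

#' One-way ANOVA across groups
#'
#' @param groups named list of numeric vectors (NA dropped)
#' @return list(F, df, p, means)
#' @export
anova_oneway <- function(groups) {
  groups <- lapply(groups, function(x) x[!is.na(x)])
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2) hs_error("need >= 2 non-empty groups")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups) %||% seq_along(groups), lengths(groups)))
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - mean(y))^2))
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  df1 <- nlevels(g) - 1L
  df2 <- length(y) - nlevels(g)
  if (df2 < 1) hs_error("need >= 2 observations in some group")
  if (ssw == 0 && ssb == 0) return(list(F = 0, df = c(df1, df2), p = 1,
                                        means = tapply(y, g, mean)))
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, df = c(df1, df2),
       p = stats::pf(f, df1, df2, lower.tail = FALSE),
       means = tapply(y, g, mean))
}

#' ANCOVA: group effect controlling for a covariate
#'
#' Fits response ~ covariate + group and reports the type-II F for the
#' group factor (sum of squares of group given the covariate). A
#' constant covariate reduces to plain ANOVA with a warning.
#'
#' @param groups named list of numeric response vectors
#' @param covariate list of covariate vectors aligned with `groups`
#' @return list(F, df, p, slope)
#' @export
ancova_with_covariate <- function(groups, covariate) {
  y <- unlist(groups, use.names = FALSE)
  x <- unlist(covariate, use.names = FALSE)
  if (length(y) != length(x)) hs_error("covariate not aligned with groups")
  g <- factor(rep(names(groups) %||% seq_along(groups), lengths(groups)))
  keep <- !is.na(y) & !is.na(x)
  y <- y[keep]; x <- x[keep]; g <- droplevels(g[keep])
  if (stats::var(x) == 0) {
    warning("constant covariate; reducing to one-way ANOVA")
    sp <- split(y, g)
    a <- anova_oneway(sp)
    return(list(F = a$F, df = a$df, p = a$p, slope = NA_real_))
  }
  fit <- stats::lm(y ~ x + g)
  tab <- stats::anova(fit)  # sequential; covariate first = type II for group
  list(F = tab["g", "F value"],
       df = c(tab["g", "Df"], tab["Residuals", "Df"]),
       p = tab["g", "Pr(>F)"],
       slope = stats::coef(fit)[["x"]])
}

#' Tukey honestly-significant-difference pairwise comparisons
#'
#' @param groups named list of numeric vectors
#' @return data.frame(pair, diff, p_adj)
#' @export
tukey_hsd <- function(groups) {
  groups <- lapply(groups, function(x) x[!is.na(x)])
  groups <- groups[lengths(groups) > 1]
  if (length(groups) < 2) hs_error("need >= 2 groups with >= 2 values")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)))
  tk <- stats::TukeyHSD(stats::aov(y ~ g))$g
  data.frame(pair = rownames(tk), diff = tk[, "diff"],
             p_adj = tk[, "p adj"], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' OLS regression of a per-gene statistic on log2 expression bias
#'
#' @param stat per-gene statistic
#' @param bias per-gene log2 fold haploid/diploid expression
#' @return list(beta, p, n)
#' @export
regress_on_bias <- function(stat, bias) {
  keep <- !is.na(stat) & !is.na(bias)
  stat <- stat[keep]; bias <- bias[keep]
  if (length(stat) < 3) hs_error("need >= 3 complete observations")
  if (stats::var(bias) == 0) hs_error("zero variance in bias")
  fit <- stats::lm(stat ~ bias)
  s <- summary(fit)$coefficients
  list(beta = s["bias", "Estimate"], p = s["bias", "Pr(>|t|)"],
       n = length(stat))
}

#' Run the standard battery of class comparisons on a master table
#'
#' For each response, compares gene classes by one-way ANOVA, ANCOVA
#' with the GC covariate, and Tukey HSD, and regresses the response on
#' log2 expression bias when available. Undefined responses are dropped
#' pairwise; the n used is reported.
#'
#' @param master per-gene master table with a `class` column
#' @param responses response column names
#' @param classes classes to compare
#' @param covariate covariate column, default "gc"
#' @return data.frame of comparison results
#' @export
compare_classes <- function(master,
                            responses = c("gc", "cpg_oe", "recomb_rate",
                                          "piS", "piNS", "pnps", "dos"),
                            classes = c("haploid_biased", "diploid_biased",
                                        "constitutive"),
                            covariate = "gc") {
  sub <- master[master$class %in% classes, , drop = FALSE]
  rows <- lapply(responses, function(resp) {
    if (!resp %in% names(sub)) return(NULL)
    groups <- split(sub[[resp]], sub$class)
    ns <- vapply(groups, function(x) sum(!is.na(x)), integer(1))
    if (sum(ns > 1) < 2) return(NULL)
    groups <- groups[ns > 1]
    a <- anova_oneway(groups)
    res <- data.frame(response = resp, test = "anova",
                      F = a$F, df1 = a$df[1], df2 = a$df[2], p = a$p,
                      slope = NA_real_, n = sum(ns),
                      stringsAsFactors = FALSE)
    if (resp != covariate && covariate %in% names(sub)) {
      cov <- split(sub[[covariate]], sub$class)[names(groups)]
      ac <- ancova_with_covariate(groups, cov)
      res <- rbind(res, data.frame(response = resp, test = "ancova_gc",
                                   F = ac$F, df1 = ac$df[1], df2 = ac$df[2],
                                   p = ac$p, slope = ac$slope, n = sum(ns),
                                   stringsAsFactors = FALSE))
    }
    if ("log2_bias" %in% names(sub)) {
      rb <- tryCatch(regress_on_bias(sub[[resp]], sub$log2_bias),
                     error = function(e) NULL)
      if (!is.null(rb))
        res <- rbind(res, data.frame(response = resp, test = "bias_ols",
                                     F = NA_real_, df1 = NA_real_,
                                     df2 = NA_real_, p = rb$p,
                                     slope = rb$beta, n = rb$n,
                                     stringsAsFactors = FALSE))
    }
    res
  })
  do.call(rbind, rows)
}
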