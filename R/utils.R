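#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so generators are
#' deterministic without clobbering the session stream.
#'
#' @param seed integer seed
#' @param code expression to evaluate
#' @return the value of `code`
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single non-missing number")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a classed validation error
#' @keywords internal
#' @noRd
hs_error <- function(msg, class = "haplosel_validation_error", ...) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

hs_log <- function(...) {
  if (isTRUE(getOption("haplosel.quiet", FALSE))) return(invisible(NULL))
  message("[haplosel] ", ...)
}

# Package-level valid labels, reused by several modules.
GENE_CLASSES <- c("haploid_biased", "diploid_biased", "constitutive",
                  "unclassified")
SEXES <- c("male", "female")
TISSUES <- c("gonad", "soma", "larva")
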