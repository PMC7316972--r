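#' Lower median
#'
#' Median that, for an even number of values, returns the lower of the two
#' middle order statistics instead of interpolating. Used wherever a median
#' of integer quantities (coordinates, allele counts) must stay on the input
#' lattice and be deterministic.
#'
#' @param x numeric vector; `NA`s are dropped.
#' @return a single value from `x`, or `NA` if `x` is empty.
#' @export
medianLower <- function(x) {
  x <- sort(x[!is.na(x)])
  if (length(x) == 0L) return(NA_real_)
  x[ceiling(length(x) / 2)]
}

# modal value; ties broken toward the smallest value
modalValue <- function(x) {
  ux <- sort(unique(x))
  ux[which.max(tabulate(match(x, ux)))]
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items,
#' e.g. recovered sub-clone groups versus simulated clone truth. 1 means
#' identical partitions, 0 is the expected value for independent labelings.
#'
#' @param a,b vectors of equal length, coercible to factors.
#' @return a number in \[-1, 1\].
#' @export
adjustedRand <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# condition constructors: the pipeline distinguishes configuration errors
# (exit code 2 in the CLI wrapper) from data-contract errors (exit code 3)
configError <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("sccnv_config_error", "error", "condition"),
                      call = call))
}

dataError <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("sccnv_data_error", "error", "condition"),
                      call = call))
}

# seeds derived from a master seed must stay below .Machine$integer.max
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 100 + offset) %% .Machine$integer.max)
}
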