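# Chi-square goodness-of-fit test for Mendelian segregation ratios.

#' Chi-square test of a Mendelian segregation ratio
#'
#' Tests observed per-class counts against hypothesised proportions such as
#' 3:1. The statistic is the classic `sum((O - E)^2 / E)` without
#' continuity correction; Yates' correction is available behind a flag but
#' off by default (for the 135:44 worked example the uncorrected statistic
#' is 0.0168, the corrected one 0.0006).
#'
#' @param observed Non-negative integer counts per phenotype class
#'   (>= 2 classes, positive total).
#' @param ratio Expected ratio weights, e.g. `c(3, 1)`; scale-invariant
#'   (`c(3, 1)` and `c(6, 2)` are equivalent).
#' @param correct Apply Yates' continuity correction (default `FALSE`).
#' @return A `segregation_test` list: `chi2`, `df` (classes - 1), `p_value`
#'   (upper tail), `expected`, `observed`, `ratio`.
#' @examples
#' chi_square_segregation(c(135, 44), c(3, 1))
#' @export
chi_square_segregation <- function(observed, ratio = c(3, 1), correct = FALSE) {
  if (length(observed) < 2) stop("need at least two classes", call. = FALSE)
  if (length(ratio) != length(observed)) {
    stop("ratio must have one weight per class", call. = FALSE)
  }
  if (any(observed < 0)) stop("counts must be non-negative", call. = FALSE)
  if (sum(observed) <= 0) stop("total observed count must be positive", call. = FALSE)
  if (any(ratio <= 0)) stop("ratio weights must be positive", call. = FALSE)
  expected <- sum(observed) * ratio / sum(ratio)
  if (any(expected == 0)) stop("expected count of zero", call. = FALSE)
  dev <- abs(observed - expected)
  if (correct) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / expected)
  df <- length(observed) - 1L
  structure(list(chi2 = chi2, df = df,
                 p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
                 expected = expected, observed = observed, ratio = ratio),
            class = "segregation_test")
}

#' @export
print.segregation_test <- function(x, ...) {
  cat("Chi-square segregation test\n")
  cat("  observed: ", paste(x$observed, collapse = " : "), "\n", sep = "")
  cat("  ratio:    ", paste(x$ratio, collapse = " : "), "\n", sep = "")
  cat("  expected: ", paste(format(x$expected, trim = TRUE), collapse = " : "),
      "\n", sep = "")
  cat(sprintf("  chi2 = %.4g, df = %d, p = %.4g\n", x$chi2, x$df, x$p_value))
  invisible(x)
}

#' Parse a ratio string like "3:1"
#'
#' @param text Ratio string with `:`-separated positive weights.
#' @return Numeric vector of weights.
#' @export
parse_ratio <- function(text) {
  parts <- suppressWarnings(as.numeric(strsplit(text, ":", fixed = TRUE)[[1]]))
  if (length(parts) < 2 || anyNA(parts) || any(parts <= 0)) {
    stop("cannot parse ratio '", text, "'; expected e.g. \"3:1\"",
         call. = FALSE)
  }
  parts
}
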