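#' Pearson chi-square test of a 2x2 response table
#'
#' Uncorrected Pearson statistic (no Yates continuity correction), df = 1,
#' upper-tail p-value.  On the deafening-validation table (5/20 responders
#' versus 0/20) this gives Q = 4.5.
#'
#' @param table 2x2 matrix of nonnegative integer counts; both margins must
#'   be positive.
#' @return list of class \code{chi2_result} with \code{q}, \code{df},
#'   \code{p}.
#' @examples
#' pearson_chi2(matrix(c(5, 20, 0, 20), nrow = 2, byrow = TRUE))
#' @export
pearson_chi2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L)))
    stop("a 2x2 table is required", call. = FALSE)
  if (any(!is.finite(tab)) || any(tab < 0) || any(tab != round(tab)))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("all row and column margins must be positive", call. = FALSE)
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  structure(list(q = unname(ct$statistic), df = unname(ct$parameter),
                 p = ct$p.value),
            class = "chi2_result")
}

#' @export
print.chi2_result <- function(x, ...) {
  cat(sprintf("Pearson chi-square: Q = %.4g, df = %d, p = %.4g\n",
              x$q, x$df, x$p))
  invisible(x)
}

#' Compare the probability of egg-laying between two sets of nights
#'
#' Each arena-night is labelled laid / not-laid before any exclusion; the
#' two proportions are compared by Fisher's exact two-sided test (the exact
#' two-proportion construction; the method label is carried in the output).
#'
#' @param nights_a,nights_b data frames of night records, or logical
#'   vectors of laid indicators.
#' @return list with \code{prop_a}, \code{prop_b}, \code{n_a}, \code{n_b},
#'   \code{p}, \code{method}.
#' @examples
#' laying_probability_comparison(rep(c(TRUE, FALSE), c(68, 32)),
#'                               rep(c(TRUE, FALSE), c(54, 46)))
#' @export
laying_probability_comparison <- function(nights_a, nights_b) {
  laid <- function(x) {
    if (is.data.frame(x)) x$clusters_treatment + x$clusters_control > 0
    else as.logical(x)
  }
  a <- laid(nights_a); b <- laid(nights_b)
  if (!length(a) || !length(b)) stop("both groups must be non-empty", call. = FALSE)
  tab <- rbind(c(sum(a), sum(!a)), c(sum(b), sum(!b)))
  p <- fisher.test(tab, alternative = "two.sided")$p.value
  list(prop_a = mean(a), prop_b = mean(b), n_a = length(a), n_b = length(b),
       p = p, method = "Fisher exact two-sided two-proportion test")
}
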