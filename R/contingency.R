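#' @include AllClasses.R AllGenerics.R
NULL

.as2x2 <- function(tab) {
  if (is.data.frame(tab)) tab <- as.matrix(tab)
  if (length(tab) == 4L && is.null(dim(tab))) tab <- matrix(tab, 2L, 2L, byrow = TRUE)
  if (!is.matrix(tab) || !identical(dim(tab), c(2L, 2L)))
    stop("expected a 2x2 table")
  if (any(tab < 0) || any(tab != floor(tab))) stop("cells must be nonnegative integers")
  storage.mode(tab) <- "integer"
  tab
}

.odds <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  if (b * c == 0) { if (a * d == 0) NA_real_ else Inf } else (a * d) / (b * c)
}

#' One-sided Fisher exact test on a 2x2 table
#'
#' Tests enrichment of the first-row/first-column cell against the
#' hypergeometric null with all margins fixed: the p-value is the upper tail
#' `P(X >= a)` where X is hypergeometric. Degenerate margins (an empty row or
#' column) give p = 1.
#'
#' @param tab 2x2 table `(a, b; c, d)`, as a matrix or a length-4 vector read
#'   row-wise.
#' @return a [ContingencyResult-class] with method `fisher_one_sided_greater`.
#' @examples
#' pValue(fisherExact2x2(c(5, 0, 0, 5)))  # 1 / choose(10, 5)
#' @export
fisherExact2x2 <- function(tab) {
  tab <- .as2x2(tab)
  if (sum(tab) == 0L) stop("all-zero table")
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  p <- if ((a + b) == 0L || (a + c) == 0L) 1
       else stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
  new("ContingencyResult", table = tab, statistic = NA_real_,
      pValue = min(max(p, .Machine$double.xmin), 1),
      method = "fisher_one_sided_greater", oddsRatio = .odds(tab))
}

#' Chi-square test of independence on a 2x2 table
#'
#' Computes the classical statistic `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`
#' (optionally Yates-corrected) with its 1-df chi-square p-value. All four
#' margins must be positive.
#'
#' @inheritParams fisherExact2x2
#' @param correct apply the Yates continuity correction (default FALSE).
#' @return a [ContingencyResult-class] with method `chi_square`.
#' @export
chiSquare2x2 <- function(tab, correct = FALSE) {
  tab <- .as2x2(tab)
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- sum(tab)
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0L)) stop("zero margin in 2x2 table")
  dev <- abs(a * d - b * c)
  if (correct) dev <- max(0, dev - n / 2)
  stat <- n * dev^2 / prod(as.numeric(margins))
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  new("ContingencyResult", table = tab, statistic = stat,
      pValue = min(max(p, .Machine$double.xmin), 1),
      method = "chi_square", oddsRatio = .odds(tab))
}

#' EASE score: jackknifed one-sided Fisher exact enrichment p-value
#'
#' A conservative variant of the Fisher exact test used for functional
#' annotation enrichment: one gene is removed from the hit cell before
#' computing the one-sided p, so a single-hit overlap is never significant
#' (k = 1 gives p = 1). The jackknifed table is `(k-1, n-k; K-k+1, M-n-K+k)`,
#' preserving the population totals.
#'
#' @param k term genes in the query list.
#' @param n query-list size.
#' @param K term genes in the population.
#' @param M population size.
#' @return a [ContingencyResult-class] with method `ease`.
#' @examples
#' pValue(easeScore(1, 10, 10, 100))   # 1 by construction
#' @export
easeScore <- function(k, n, K, M) {
  k <- .assertCount(k, "k", min = 0L); n <- .assertCount(n, "n", min = 0L)
  K <- .assertCount(K, "K", min = 0L); M <- .assertCount(M, "M")
  if (k > min(n, K) || n > M || K > M)
    stop("inconsistent counts: need k <= min(n, K), n <= M, K <= M")
  kj <- max(k - 1L, 0L)
  tab <- matrix(c(kj, max(n - k, 0L), K - kj, M - max(n - 1L, 0L) - (K - kj)),
                2L, 2L, byrow = TRUE)
  storage.mode(tab) <- "integer"
  p <- if (k == 0L) 1
       else stats::phyper(kj - 1, K, M - K, max(n - 1L, 0L), lower.tail = FALSE)
  new("ContingencyResult", table = tab, statistic = NA_real_,
      pValue = min(max(p, .Machine$double.xmin), 1),
      method = "ease", oddsRatio = .odds(tab))
}
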