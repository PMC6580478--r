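# Study-level statistics: the uncorrected Pearson chi-squared arm comparison,
# classical two-proportion sample-size planning, and Pugh-chart weighted
# design scoring.

#' 2x2 contingency table
#'
#' Counts for a two-arm comparison of a binary outcome:
#' arm 1 success/failure (\code{a}, \code{b}), arm 2 success/failure
#' (\code{c}, \code{d}).
#'
#' @param a,b,c,d Non-negative integer counts.
#' @return An object of class \code{contingency_2x2}.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  counts <- c(a = unname(a)[1], b = unname(b)[1], c = unname(c)[1],
              d = unname(d)[1])
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_earsift("counts must be non-negative integers", "invalid_argument")
  }
  if (sum(counts) <= 0) {
    stop_earsift("the table must contain at least one observation",
                 "invalid_argument")
  }
  structure(as.list(counts), class = "contingency_2x2")
}

#' Uncorrected chi-squared test on a 2x2 table
#'
#' Pearson chi-squared without continuity correction, 1 degree of freedom,
#' via the closed form
#' \deqn{\chi^2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)),}
#' with the p-value from the upper tail of the chi-squared distribution.
#' A zero margin leaves the statistic undefined and signals an error.
#'
#' @param table A [contingency_2x2()] or numeric length-4 vector (a, b, c, d).
#' @return A list with \code{statistic}, \code{p_value}, \code{df = 1}.
#' @export
chi2_uncorrected <- function(table) {
  if (inherits(table, "contingency_2x2")) {
    v <- unlist(table[c("a", "b", "c", "d")])
  } else {
    v <- as.numeric(table)
  }
  stopifnot(length(v) == 4)
  a <- v[1]; b <- v[2]; cc <- v[3]; d <- v[4]
  n <- a + b + cc + d
  margins <- c(a + b, cc + d, a + cc, b + d)
  if (any(margins == 0)) {
    stop_earsift("a zero margin leaves the chi-squared test undefined",
                 "undefined_test")
  }
  stat <- n * (a * d - b * cc)^2 / prod(margins)
  list(statistic = unname(stat),
       p_value = unname(pchisq(stat, df = 1, lower.tail = FALSE)),
       df = 1L)
}

#' Two-proportion sample size (normal approximation)
#'
#' Per-group sample size for detecting a difference between two proportions
#' at two-sided level \code{alpha} with the given power, using the classical
#' normal-approximation formula with pooled variance under the null and
#' unpooled variance under the alternative:
#' \deqn{n = \frac{\left(z_{1-\alpha/2}\sqrt{2\bar p(1-\bar p)} +
#'   z_{1-\beta}\sqrt{p_1(1-p_1) + p_2(1-p_2)}\right)^2}{(p_1-p_2)^2},}
#' with \eqn{\bar p = (p_1 + p_2)/2}, rounded up.
#'
#' @param p1,p2 The two proportions, in (0, 1), \code{p1 != p2}.
#' @param alpha Two-sided type-I error rate.
#' @param power Target power (1 - beta).
#' @return Integer sample size per group.
#' @export
two_proportion_sample_size <- function(p1, p2, alpha = 0.05, power = 0.80) {
  if (p1 <= 0 || p1 >= 1 || p2 <= 0 || p2 >= 1) {
    stop_earsift("proportions must lie strictly in (0, 1)", "invalid_argument")
  }
  if (p1 == p2) {
    stop_earsift("p1 and p2 must differ", "invalid_argument")
  }
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stop_earsift("alpha and power must lie strictly in (0, 1)",
                 "invalid_argument")
  }
  pbar <- (p1 + p2) / 2
  za <- qnorm(1 - alpha / 2)
  zb <- qnorm(power)
  n <- (za * sqrt(2 * pbar * (1 - pbar)) +
          zb * sqrt(p1 * (1 - p1) + p2 * (1 - p2)))^2 / (p1 - p2)^2
  as.integer(ceiling(n - 1e-9))
}

#' Pugh chart
#'
#' A weighted decision matrix comparing design concepts against a baseline:
#' each criterion carries a positive integer weight and each concept a mark
#' in \{-1, 0, +1\} per criterion (the baseline concept is all-zero by
#' convention).
#'
#' @param criteria Character vector of criterion names.
#' @param weights Positive integer weights, parallel to \code{criteria}.
#' @param marks Numeric matrix (criteria x concepts) with entries in
#'   \{-1, 0, 1\}; column names are the concept names.
#' @return An object of class \code{pugh_chart}.
#' @export
pugh_chart <- function(criteria, weights, marks) {
  marks <- as.matrix(marks)
  if (length(criteria) != length(weights) || nrow(marks) != length(criteria)) {
    stop_earsift("criteria, weights and mark rows must be parallel",
                 "invalid_argument")
  }
  if (any(weights <= 0) || any(weights != round(weights))) {
    stop_earsift("weights must be positive integers", "invalid_argument")
  }
  if (!all(marks %in% c(-1, 0, 1))) {
    stop_earsift("marks must be -1, 0 or +1", "invalid_argument")
  }
  rownames(marks) <- criteria
  structure(list(criteria = criteria, weights = as.numeric(weights),
                 marks = marks),
            class = "pugh_chart")
}

#' Score a Pugh chart
#'
#' Each concept's total is the weight-weighted sum of its marks; an all-zero
#' (baseline) column totals 0 by construction.
#'
#' @param chart A [pugh_chart()].
#' @return Named numeric vector of totals, one per concept.
#' @export
pugh_score <- function(chart) {
  stopifnot(inherits(chart, "pugh_chart"))
  totals <- drop(crossprod(chart$marks, chart$weights))
  stats::setNames(as.numeric(totals), colnames(chart$marks))
}

#' Read a Pugh chart from CSV
#'
#' Expected columns: \code{criterion}, \code{weight}, then one column per
#' concept with cells in \code{+}, \code{0}, \code{-} (or +1/0/-1).
#'
#' @param path CSV path.
#' @return A [pugh_chart()].
#' @export
read_pugh_csv <- function(path) {
  tab <- read.csv(path, check.names = FALSE, colClasses = "character")
  if (!all(c("criterion", "weight") %in% names(tab))) {
    stop_earsift("Pugh CSV needs 'criterion' and 'weight' columns",
                 "format_error")
  }
  concepts <- setdiff(names(tab), c("criterion", "weight"))
  parse_mark <- function(x) {
    switch(trimws(x), "+" = 1, "-" = -1, "0" = 0,
           "+1" = 1, "-1" = -1, "1" = 1,
           stop_earsift(sprintf("invalid Pugh mark: '%s'", x), "format_error"))
  }
  marks <- vapply(concepts, function(cn) vapply(tab[[cn]], parse_mark,
                                                numeric(1)),
                  numeric(nrow(tab)))
  marks <- matrix(marks, nrow = nrow(tab),
                  dimnames = list(tab$criterion, concepts))
  pugh_chart(tab$criterion, as.numeric(tab$weight), marks)
}

#' The device-lighting Pugh chart
#'
#' The weighted decision matrix used to choose the capture device's internal
#' lighting design (three concepts scored against a diffused-LED baseline on
#' shadow reduction, power, shape, sourcing and price), shipped with the
#' package as \code{extdata/lighting_pugh.csv}.
#'
#' @return A [pugh_chart()].
#' @export
lighting_pugh_chart <- function() {
  read_pugh_csv(system.file("extdata", "lighting_pugh.csv",
                            package = "earsift"))
}
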