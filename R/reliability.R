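# Double-measurement reproducibility statistics: Dahlberg method error and a
# paired t test, the standard pair in cephalometric reliability analysis.

check_pairs <- function(first, second) {
  if (length(first) != length(second))
    validation_error("first/second measurement vectors must have equal length")
  if (!length(first)) validation_error("no measurement pairs supplied")
  if (any(!is.finite(first)) || any(!is.finite(second)))
    validation_error("measurements must be finite")
  first - second
}

#' Dahlberg method error
#'
#' SE = sqrt(sum(d^2) / (2n)) over paired double measurements, where d is the
#' within-pair difference and n the number of pairs. Scales linearly with the
#' measurement unit and is invariant to pair order and to swapping the two
#' measurements within every pair.
#'
#' @param first,second numeric vectors of the repeated measurements, matched
#'   by position (mm).
#' @return the method error in mm.
#' @export
#' @examples
#' dahlberg_error(c(1, 0), c(0, 1))  # sqrt(2/4) = 0.7071
dahlberg_error <- function(first, second) {
  d <- check_pairs(first, second)
  sqrt(sum(d^2) / (2 * length(d)))
}

#' Paired t test between double measurements
#'
#' Standard two-sided paired t test on the within-pair differences. Requires
#' at least two pairs and non-zero variance of the differences; exactly
#' identical measurement series are reported as an error rather than a
#' degenerate t statistic.
#'
#' @param first,second numeric vectors of the repeated measurements.
#' @return list with \code{t_statistic}, \code{p_value}, \code{df}, \code{n}.
#' @export
#' @examples
#' paired_t_test(c(1, 2, 3), c(0, 0, 0))  # t = 3.4641, p = 0.0742
paired_t_test <- function(first, second) {
  d <- check_pairs(first, second)
  n <- length(d)
  if (n < 2) validation_error("paired t test requires at least 2 pairs")
  if (stats::var(d) == 0)
    validation_error("zero variance of differences: t statistic undefined (measurements identical up to a constant shift)")
  tt <- stats::t.test(first, second, paired = TRUE)
  list(t_statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), n = n)
}

#' Reliability report from two repeated measurement series
#'
#' Matches two profiles (or plain named vectors) by landmark and computes the
#' Dahlberg method error and paired t test over the matched values. By
#' default pairs the signed index values; set \code{use = "magnitude"} to
#' pair unsigned magnitudes instead.
#'
#' @param m1,m2 \code{asymmetry_profile}s, or named numeric vectors.
#' @param use \code{"signed_value"} or \code{"magnitude"} (profiles only).
#' @return list with \code{dahlberg_se}, \code{t_statistic}, \code{p_value},
#'   \code{df}, \code{n}.
#' @export
reliability_report <- function(m1, m2, use = c("signed_value", "magnitude")) {
  use <- match.arg(use)
  to_vec <- function(m) {
    if (inherits(m, "asymmetry_profile")) stats::setNames(m[[use]], m$landmark)
    else if (is.numeric(m) && !is.null(names(m))) m
    else validation_error("reliability inputs must be profiles or named numeric vectors")
  }
  v1 <- to_vec(m1); v2 <- to_vec(m2)
  shared <- intersect(names(v1), names(v2))
  if (!length(shared)) validation_error("no shared landmarks between the two measurement series")
  t_res <- paired_t_test(v1[shared], v2[shared])
  c(list(dahlberg_se = dahlberg_error(v1[shared], v2[shared])), t_res)
}
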