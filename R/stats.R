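# Group-level statistics: mean +/- SD summaries and the two-sample
# Student's t-test between normal and injured groups.

#' Summarize one group of specimen values
#'
#' @param values numeric vector (one value per specimen).
#' @param label optional group label.
#' @return Data frame with \code{label}, \code{n}, \code{mean}, \code{sd}
#'   (sample SD, n - 1 denominator; NA when n < 2).
#' @export
summarizeGroup <- function(values, label = NA_character_) {
  if (length(values) < 1L) stop("empty group")
  data.frame(label = label, n = length(values), mean = mean(values),
             sd = if (length(values) >= 2L) stats::sd(values) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Two-sample Student's t-test
#'
#' Pooled-variance, two-sided by default (Welch's correction available via
#' \code{welch = TRUE}). Degenerate inputs with zero pooled variance return
#' t = 0, p = 1 when the means agree and are an error otherwise (the test
#' statistic is undefined).
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param alpha significance level for the \code{significant} flag.
#' @param welch use the unequal-variance (Welch) test.
#' @return A list: \code{t}, \code{df}, \code{p}, \code{significant},
#'   \code{mean_a}, \code{mean_b}.
#' @export
twoSampleTTest <- function(a, b, alpha = 0.05, welch = FALSE) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = length(a) + length(b) - 2L, p = 1,
                  significant = FALSE, mean_a = mean(a), mean_b = mean(b)))
    }
    stop("zero pooled variance with unequal means: t-test undefined")
  }
  ht <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, significant = ht$p.value < alpha,
       mean_a = mean(a), mean_b = mean(b))
}

.reportMetrics <- function(report) {
  c(VV_mm3 = report@vvMm3, VN = report@vn, VNN = report@vnn,
    VD_um = if (nrow(report@segments))
      mean(report@segments$diameter_um, na.rm = TRUE) else NA_real_)
}

#' Compare morphometry between two arms
#'
#' One pooled t-test per metric (VV in cubic millimeters, VN, VNN, mean VD),
#' mirroring the normal-vs-injury table layout: means +/- SD per arm with a
#' significance flag. No multiple-testing correction is applied across the
#' metrics (a documented limitation of the reporting convention this
#' mirrors).
#'
#' @param normal,injured lists of \linkS4class{MorphometryReport} objects
#'   (>= 2 per arm).
#' @param alpha significance level.
#' @param welch use Welch's test instead of the pooled test.
#' @return Data frame: metric, mean/sd per arm, t, df, p, significant.
#' @export
compareMorphometry <- function(normal, injured, alpha = 0.05,
                               welch = FALSE) {
  stopifnot(length(normal) >= 2L, length(injured) >= 2L)
  mN <- t(vapply(normal, .reportMetrics, numeric(4)))
  mI <- t(vapply(injured, .reportMetrics, numeric(4)))
  if (!identical(colnames(mN), colnames(mI)))
    stop("mismatched metric sets between arms")
  rows <- lapply(colnames(mN), function(m) {
    a <- mN[, m]; b <- mI[, m]
    # both arms constant with unequal means: the t statistic is undefined;
    # report the means with NA test columns rather than failing the table
    tt <- tryCatch(twoSampleTTest(a, b, alpha = alpha, welch = welch),
                   error = function(e) list(t = NA_real_, df = NA_real_,
                                            p = NA_real_, significant = NA))
    data.frame(metric = m,
               mean_normal = mean(a), sd_normal = stats::sd(a),
               mean_injured = mean(b), sd_injured = stats::sd(b),
               t = tt$t, df = tt$df, p = tt$p,
               significant = tt$significant, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
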