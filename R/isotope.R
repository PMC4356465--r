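#' Summarize an isotope measurement group
#'
#' Either pass the replicate delta-15N values (per-mil) and have the
#' summary derived, or pass the summary statistics directly.
#'
#' @param label Group label.
#' @param values Optional numeric replicate values.
#' @param mean,sd,n Summary statistics, used when \code{values} is
#'   \code{NULL}.
#' @return List with \code{label}, \code{mean}, \code{sd}, \code{n}.
#' @export
isotopeGroup <- function(label, values = NULL, mean = NULL, sd = NULL,
                         n = NULL) {
    if (!is.null(values)) {
        if (length(values) < 2L) stop("need at least 2 replicates")
        out <- list(label = label, mean = base::mean(values),
                    sd = stats::sd(values), n = length(values))
    } else {
        if (is.null(mean) || is.null(sd) || is.null(n))
            stop("supply either replicate values or mean, sd and n")
        if (n < 2L) stop("n must be >= 2")
        if (sd < 0) stop("sd must be >= 0")
        out <- list(label = label, mean = mean, sd = sd, n = as.integer(n))
    }
    out
}

#' Two-sample t-test from group summaries
#'
#' Two-sided two-sample t-test on delta-15N group summaries, as used to
#' judge whether tracer exposure shifted the isotope signature. The
#' Welch variant (default) uses unpooled variances with the
#' Welch-Satterthwaite degrees of freedom; the Student variant pools
#' the variances with \code{n1 + n2 - 2} degrees of freedom. When both
#' SDs are zero the statistic is degenerate: equal means give p = 1,
#' unequal means are an error.
#'
#' @param g1,g2 Groups from \code{\link{isotopeGroup}}.
#' @param variant \code{"welch"} (default) or \code{"student"}.
#' @param alpha Significance threshold for the call (default 0.05).
#' @return List with \code{t}, \code{df}, \code{p} (two-sided),
#'   \code{call} (\code{"significant"} or \code{"not_significant"}) and
#'   \code{variant}.
#' @examples
#' exposed <- isotopeGroup("exposed", mean = -5.501, sd = 0.717, n = 3)
#' control <- isotopeGroup("unexposed", mean = -6.083, sd = 0.336, n = 3)
#' isotopeTTest(exposed, control)
#' @export
isotopeTTest <- function(g1, g2, variant = c("welch", "student"),
                         alpha = 0.05) {
    variant <- match.arg(variant)
    m1 <- g1$mean; s1 <- g1$sd; n1 <- g1$n
    m2 <- g2$mean; s2 <- g2$sd; n2 <- g2$n
    if (n1 < 2L || n2 < 2L) stop("both groups need n >= 2")
    if (s1 == 0 && s2 == 0) {
        if (m1 == m2)
            return(list(t = 0, df = n1 + n2 - 2, p = 1,
                        call = significanceCall(1, alpha),
                        variant = variant))
        stop("degenerate test: both SDs zero with unequal means")
    }
    if (variant == "welch") {
        se2 <- s1^2 / n1 + s2^2 / n2
        t <- (m1 - m2) / sqrt(se2)
        df <- se2^2 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
    } else {
        sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
        t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
        df <- n1 + n2 - 2
    }
    p <- 2 * stats::pt(-abs(t), df)
    list(t = t, df = df, p = p, call = significanceCall(p, alpha),
         variant = variant)
}

#' Significance call at a strict threshold
#'
#' @param p A p-value in [0, 1].
#' @param alpha Threshold (default 0.05); significance requires
#'   \code{p < alpha} strictly.
#' @return \code{"significant"} or \code{"not_significant"}.
#' @export
significanceCall <- function(p, alpha = 0.05) {
    if (p < 0 || p > 1) stop("p must lie in [0, 1]")
    if (p < alpha) "significant" else "not_significant"
}
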