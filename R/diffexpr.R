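# Differential expression on a log2 matrix: per-gene two-sided t-test and
# a signed linear fold-change threshold, the classical "+/-2-fold and
# P < 0.05" criterion.

#' Differential expression calls
#'
#' Per gene, `delta = mean(log2 +LPS) - mean(log2 -LPS)`; the linear fold
#' change is reported with the signed convention `+2^delta` for induction
#' and `-2^(-delta)` for repression, so `|FC| >= 1` always. The p-value is
#' a two-sided t-test on the log2 replicate values (equal-variance Student
#' by default, Welch by flag). A gene is called `up` when
#' `FC >= fc_threshold` and `p < alpha`, `down` when `FC <= -fc_threshold`
#' and `p < alpha`, otherwise `null`. Degenerate genes with zero variance
#' in both groups get `p = 0` when the means differ (logged) and `p = 1`
#' when they agree. No multiple-testing correction is applied by default
#' (`adjust = "BH"` switches the threshold to Benjamini-Hochberg adjusted
#' p-values).
#'
#' @param m An `ExpressionMatrix`.
#' @param fc_threshold Linear fold-change threshold (default 2).
#' @param alpha Significance level (default 0.05).
#' @param test `"student"` (pooled variance) or `"welch"`.
#' @param adjust `"none"` or `"BH"`.
#' @return A data.frame of class `de_result`: gene_id, delta_log2,
#'   fold_change, p_value, call.
#' @export
differential_expression <- function(m, fc_threshold = 2, alpha = 0.05,
                                    test = c("student", "welch"),
                                    adjust = c("none", "BH")) {
  test <- match.arg(test)
  adjust <- match.arg(adjust)
  stopifnot(inherits(m, "ExpressionMatrix"))
  xm <- m$values[, m$condition == "minus_LPS", drop = FALSE]
  xp <- m$values[, m$condition == "plus_LPS", drop = FALSE]
  n1 <- ncol(xm); n2 <- ncol(xp)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 replicates per condition")
  m1 <- rowMeans(xm); m2 <- rowMeans(xp)
  v1 <- apply(xm, 1, var); v2 <- apply(xp, 1, var)
  delta <- m2 - m1
  if (test == "student") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(delta))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  p <- 2 * pt(-abs(delta / se), df)
  degen <- se == 0
  if (any(degen)) {
    p[degen] <- ifelse(delta[degen] == 0, 1, 0)
    if (any(degen & delta != 0)) {
      message("differential_expression: ", sum(degen & delta != 0),
              " gene(s) with zero variance and nonzero difference; p set to 0")
    }
  }
  fc <- ifelse(delta >= 0, 2^delta, -2^(-delta))
  p_crit <- if (adjust == "BH") stats::p.adjust(p, "BH") else p
  call <- ifelse(fc >= fc_threshold & p_crit < alpha, "up",
                 ifelse(fc <= -fc_threshold & p_crit < alpha, "down", "null"))
  out <- data.frame(gene_id = rownames(m$values), delta_log2 = delta,
                    fold_change = fc, p_value = p, call = call,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("de_result", "data.frame")
  out
}

#' Summarize differential expression calls
#'
#' @param results A `de_result`.
#' @return List with `n_up`, `n_down`, and the up/down gene-id vectors.
#' @export
summarize_de <- function(results) {
  list(n_up = sum(results$call == "up"),
       n_down = sum(results$call == "down"),
       up_genes = results$gene_id[results$call == "up"],
       down_genes = results$gene_id[results$call == "down"])
}
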