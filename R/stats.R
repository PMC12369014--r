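#' Two-tailed independent two-sample t test
#'
#' Pooled-variance Student t by default (the two film conditions are
#' compared assuming a common variance), with Welch's unequal-variance
#' form available. Degenerate inputs follow fixed conventions: when both
#' groups have zero variance, equal means give p = 1 and unequal means
#' give p = 0 (flagged with a warning).
#'
#' @param a,b Numeric vectors, each of length >= 2, finite.
#' @param pooled Use the pooled-variance (Student) statistic? `FALSE`
#'   gives Welch.
#' @return A list of class `ttest_result` with `t_statistic`, `df`,
#'   `p_value`.
#' @examples
#' ttest_ind(c(1, 2, 3, 4), c(3, 4, 5, 6))  # t = -2.449, df = 6
#' @export
ttest_ind <- function(a, b, pooled = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) >= 2, length(b) >= 2,
            all(is.finite(a)), all(is.finite(b)))
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  md <- mean(a) - mean(b)
  if (va == 0 && vb == 0) {
    if (md == 0) {
      res <- list(t_statistic = 0, df = na + nb - 2, p_value = 1)
    } else {
      warning("zero variance in both groups with unequal means; p = 0 limit")
      res <- list(t_statistic = sign(md) * Inf, df = na + nb - 2, p_value = 0)
    }
    class(res) <- "ttest_result"
    return(res)
  }
  if (pooled) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- md / se
  res <- list(t_statistic = t, df = df,
              p_value = 2 * stats::pt(-abs(t), df))
  class(res) <- "ttest_result"
  res
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("t = %.4g, df = %.4g, two-tailed p = %.4g\n",
              x$t_statistic, x$df, x$p_value))
  invisible(x)
}

#' Balanced two-way ANOVA with interaction
#'
#' Sequential (Type I) sums of squares for a balanced two-factor design —
#' treatment (hydro-softened vs unsoftened) crossed with adhesion
#' morphology (single vs aggregate) — which in the balanced case coincide
#' with the unique orthogonal decomposition
#' `SS_total = SS_A + SS_B + SS_AB + SS_residual`. Unbalanced layouts are
#' refused rather than silently resolved to one of the competing
#' sum-of-squares conventions.
#'
#' @param table Data frame with columns `treatment`, `morphology`,
#'   `count` (or set `factor_a`, `factor_b`, `response`).
#' @param factor_a,factor_b,response Column names.
#' @return Data frame of class `anova_table`: rows for the two main
#'   effects, interaction and residual, with columns `term`, `SS`, `df`,
#'   `MS`, `F`, `p`.
#' @export
anova_two_way <- function(table, factor_a = "treatment",
                          factor_b = "morphology", response = "count") {
  stopifnot(is.data.frame(table),
            all(c(factor_a, factor_b, response) %in% names(table)))
  A <- factor(table[[factor_a]])
  B <- factor(table[[factor_b]])
  y <- as.numeric(table[[response]])
  stopifnot(all(is.finite(y)))
  cell_n <- table(A, B)
  if (length(unique(as.vector(cell_n))) != 1L)
    stop("unbalanced design: this ANOVA requires equal cell counts ",
         "(the study design is balanced)")
  n_cell <- cell_n[1, 1]
  if (n_cell < 2L) stop("need at least 2 observations per cell")
  grand <- mean(y)
  mA <- tapply(y, A, mean)
  mB <- tapply(y, B, mean)
  mAB <- tapply(y, list(A, B), mean)
  a <- nlevels(A); b <- nlevels(B)
  SS_A <- n_cell * b * sum((mA - grand)^2)
  SS_B <- n_cell * a * sum((mB - grand)^2)
  SS_AB <- n_cell * sum((mAB - outer(mA, rep(1, b)) -
                           outer(rep(1, a), mB) + grand)^2)
  SS_res <- sum((y - mAB[cbind(A, B)])^2)
  df <- c(a - 1, b - 1, (a - 1) * (b - 1), length(y) - a * b)
  SS <- c(SS_A, SS_B, SS_AB, SS_res)
  MS <- SS / df
  Fv <- c(MS[1:3] / MS[4], NA)
  p <- c(stats::pf(Fv[1:3], df[1:3], df[4], lower.tail = FALSE), NA)
  out <- data.frame(term = c(factor_a, factor_b,
                             paste(factor_a, factor_b, sep = ":"),
                             "residual"),
                    SS = SS, df = df, MS = MS, F = Fv, p = p)
  class(out) <- c("anova_table", "data.frame")
  out
}
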