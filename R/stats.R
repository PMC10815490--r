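# Statistical battery: normality screening with a tie-robust fallback,
# two-group comparisons with an automatic route, Sidak and Holm-Sidak
# adjustment, two-way ANOVA with Sidak-adjusted genotype contrasts, and
# mean +- SEM / percent-change summaries.

#' D'Agostino-Pearson omnibus normality test
#'
#' The K-squared omnibus test combining z-transformed sample skewness
#' and kurtosis; K2 is chi-squared with 2 df under normality. Unlike
#' Shapiro-Wilk it remains usable when a sample contains repeated
#' values, which is why it serves as the tie fallback in
#' [normalityScreen()]. Requires n >= 8 for the kurtosis
#' transformation to be defined.
#'
#' @param x numeric sample (n >= 8).
#' @return list with \code{statistic} (K2), \code{p.value}, \code{n}.
#' @references D'Agostino, Belanger & D'Agostino Jr (1990), The American
#'   Statistician 44(4), 316-321.
#' @export
dagostinoPearsonTest <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8L) stop("D'Agostino-Pearson test requires n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("sample has zero variance")
  g1 <- mean((x - m)^3) / m2^1.5
  g2 <- mean((x - m)^4) / m2^2 - 3
  # skewness z (D'Agostino 1970)
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  Z1 <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))
  # kurtosis z (Anscombe & Glynn 1983)
  Eg2 <- -6 / (n + 1)
  Vg2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - Eg2) / sqrt(Vg2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  Z2 <- ((1 - 2 / (9 * A)) -
         ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) *
    sqrt(9 * A / 2)
  K2 <- Z1^2 + Z2^2
  list(statistic = K2, p.value = stats::pchisq(K2, 2, lower.tail = FALSE),
       n = n)
}

#' Screen a sample for normality
#'
#' Shapiro-Wilk by default; when the sample contains repeated values and
#' the tie fallback is on, the D'Agostino-Pearson omnibus test is used
#' instead, because Shapiro-Wilk is inaccurate with multiple identical
#' data points (as arise when measurements are quantized onto an
#' observation grid).
#'
#' @param x numeric sample.
#' @param tiesRule use the D'Agostino-Pearson fallback when ties are
#'   present (default TRUE).
#' @return list with \code{test} ("shapiro_wilk" or
#'   "dagostino_pearson"), \code{statistic}, \code{p.value}, \code{n}.
#' @details Minimum n: 3 for Shapiro-Wilk, 8 for D'Agostino-Pearson.
#' @export
normalityScreen <- function(x, tiesRule = TRUE) {
  x <- x[is.finite(x)]
  n <- length(x)
  hasTies <- anyDuplicated(x) > 0L
  if (tiesRule && hasTies) {
    if (n < 8L)
      stop("D'Agostino-Pearson fallback requires n >= 8 (have ", n, ")")
    res <- dagostinoPearsonTest(x)
    return(list(test = "dagostino_pearson", statistic = res$statistic,
                p.value = res$p.value, n = n))
  }
  if (n < 3L) stop("Shapiro-Wilk requires n >= 3 (have ", n, ")")
  sw <- stats::shapiro.test(x)
  list(test = "shapiro_wilk", statistic = unname(sw$statistic),
       p.value = sw$p.value, n = n)
}

#' Compare two independent groups
#'
#' The automatic route applies Student's unpaired t-test when both
#' samples pass the normality screen at alpha = 0.05, and the
#' Mann-Whitney U test otherwise; either test can also be forced. All
#' tests are two-sided. Mann-Whitney p-values are exact for small
#' samples (min n <= 8, no ties) and use the normal approximation with
#' tie correction otherwise.
#'
#' @param a,b numeric samples (n >= 2 each).
#' @param route \code{"auto"}, \code{"t"} or \code{"mann_whitney"}.
#' @param tiesRule passed to [normalityScreen()] on the auto route.
#' @return list with \code{test}, \code{statistic}, \code{p.value},
#'   \code{n} (per group), \code{normality_route} (p-values of the
#'   screens, auto route only) and \code{flag} (degenerate-case note or
#'   NA).
#' @examples
#' compareTwo(c(1, 2, 3), c(101, 102, 103), route = "mann_whitney")
#' @export
compareTwo <- function(a, b, route = c("auto", "t", "mann_whitney"),
                       tiesRule = TRUE) {
  route <- match.arg(route)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs n >= 2")
  flag <- NA_character_
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
    return(list(test = "degenerate", statistic = NA_real_, p.value = 1,
                n = c(length(a), length(b)), normality_route = NULL,
                flag = "both groups constant and equal; p = 1 by convention"))
  }
  normRoute <- NULL
  if (route == "auto") {
    pa <- normalityScreen(a, tiesRule)$p.value
    pb <- normalityScreen(b, tiesRule)$p.value
    normRoute <- c(a = pa, b = pb)
    route <- if (pa > 0.05 && pb > 0.05) "t" else "mann_whitney"
  }
  if (route == "t") {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    res <- list(test = "student_t", statistic = unname(tt$statistic),
                p.value = tt$p.value)
  } else {
    exact <- min(length(a), length(b)) <= 8L &&
      anyDuplicated(c(a, b)) == 0L
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                              correct = !exact))
    res <- list(test = "mann_whitney", statistic = unname(wt$statistic),
                p.value = wt$p.value)
  }
  c(res, list(n = c(length(a), length(b)), normality_route = normRoute,
              flag = flag))
}

#' Sidak and Holm-Sidak multiple-comparison adjustments
#'
#' Sidak: \code{1 - (1 - p)^m} for each of m comparisons. Holm-Sidak:
#' step-down Sidak - p-values are ranked ascending, the i-th smallest is
#' adjusted with exponent \code{m - i + 1}, and a running maximum
#' enforces monotonicity. Input order is preserved in the output.
#'
#' @param p numeric p-values in \[0, 1\].
#' @param m number of comparisons (defaults to \code{length(p)}).
#' @return adjusted p-values, same order as the input, capped at 1.
#' @examples
#' sidakAdjust(0.02, m = 2)             # 1 - 0.98^2
#' holmSidakAdjust(c(0.01, 0.04))
#' @export
sidakAdjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  pmin(1, 1 - (1 - p)^m)
}

#' @rdname sidakAdjust
#' @export
holmSidakAdjust <- function(p) {
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  ord <- order(p)
  adj <- 1 - (1 - p[ord])^(m - seq_len(m) + 1)
  adj <- cummax(adj)
  out <- numeric(m)
  out[ord] <- pmin(1, adj)
  out
}

#' Two-way ANOVA with Sidak-adjusted genotype contrasts
#'
#' Fits \code{value ~ genotype * treatment} and reports Type II main
#' effects and the interaction, Sidak-adjusted genotype contrasts within
#' each treatment level (the comparison of interest in a
#' genotype-by-drug design), and Shapiro-Wilk normality of the
#' residuals.
#'
#' @param table data.frame with the response and two factor columns.
#' @param response name of the response column.
#' @param genotype,treatment names of the two factor columns.
#' @return list with \code{anova} (data.frame: term, F, p),
#'   \code{contrasts} (data.frame: treatment level, estimate, t, raw and
#'   Sidak-adjusted p), \code{residual_normality} (Shapiro-Wilk W and
#'   p), \code{sum_of_squares} ("type_II").
#' @details Every genotype x treatment cell must contain at least 2
#'   observations; an empty or singleton cell is an error naming the
#'   cell.
#' @export
twoWayAnova <- function(table, response = "value", genotype = "genotype",
                        treatment = "treatment") {
  need <- c(response, genotype, treatment)
  missing <- setdiff(need, names(table))
  if (length(missing))
    stop("table is missing columns: ", paste(missing, collapse = ", "))
  df <- data.frame(value = table[[response]],
                   genotype = factor(table[[genotype]]),
                   treatment = factor(table[[treatment]]))
  counts <- table(df$genotype, df$treatment)
  if (any(counts < 2L)) {
    bad <- which(counts < 2L, arr.ind = TRUE)[1, ]
    stop("cell (", rownames(counts)[bad[1]], ", ",
         colnames(counts)[bad[2]], ") has ",
         counts[bad[1], bad[2]], " observation(s); need >= 2")
  }
  terms <- c("genotype", "treatment", "genotype:treatment")
  if (stats::sd(df$value) == 0) {
    # a flat table carries no effects: null statistics by convention
    lv <- levels(df$treatment)
    return(list(
      anova = data.frame(term = terms, F = 0, p = 1),
      contrasts = data.frame(treatment = lv,
                             contrast = paste(levels(df$genotype),
                                              collapse = " - "),
                             estimate = 0, t = 0, p.raw = 1, p.sidak = 1),
      residual_normality = c(W = NA_real_, p = NA_real_),
      sum_of_squares = "type_II"))
  }
  fit <- stats::lm(value ~ genotype * treatment, data = df)
  aovTab <- car::Anova(fit, type = 2)
  keep <- rownames(aovTab) != "Residuals"
  anovaDf <- data.frame(term = rownames(aovTab)[keep],
                        F = aovTab[keep, "F value"],
                        p = aovTab[keep, "Pr(>F)"],
                        row.names = NULL)
  emm <- emmeans::emmeans(fit, ~ genotype | treatment)
  ct <- summary(emmeans::contrast(emm, method = "pairwise",
                                  adjust = "none"))
  rawP <- ct$p.value
  contrasts <- data.frame(treatment = ct$treatment,
                          contrast = as.character(ct$contrast),
                          estimate = ct$estimate,
                          t = ct$t.ratio,
                          p.raw = rawP,
                          p.sidak = sidakAdjust(rawP, m = length(rawP)))
  res <- stats::residuals(fit)
  sw <- if (stats::sd(res) > 0) stats::shapiro.test(res)
        else list(statistic = NA_real_, p.value = NA_real_)
  list(anova = anovaDf, contrasts = contrasts,
       residual_normality = c(W = unname(sw$statistic),
                              p = unname(sw$p.value)),
       sum_of_squares = "type_II")
}

#' Mean, SEM and n of a sample
#'
#' @param x numeric sample.
#' @return named numeric \code{c(mean =, sem =, n =)}.
#' @export
summarizeSample <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  c(mean = mean(x), sem = stats::sd(x) / sqrt(n), n = n)
}

#' Percent change of a comparison mean relative to a reference mean
#'
#' \code{100 * (reference - comparison) / reference}, rounded to one
#' decimal: positive when the comparison is smaller than the reference
#' (a reduction), negative when larger.
#'
#' @param referenceMean reference group mean (nonzero).
#' @param comparisonMean comparison group mean.
#' @return percent change, one decimal.
#' @examples
#' percentChange(152.9, 105.6)   # 30.9 percent faster / smaller
#' @export
percentChange <- function(referenceMean, comparisonMean) {
  if (any(referenceMean == 0)) stop("reference mean must be nonzero")
  round(100 * (referenceMean - comparisonMean) / referenceMean, 1)
}
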