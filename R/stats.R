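# Rate-of-change computation, distributional checks and transforms, and the
# correlation machinery (partial correlations, Fisher-z comparison, ICC).

#' Two-visit rate of change
#'
#' `RoC = (Y(t2) - Y(t1)) / (t2 - t1)`, the per-year slope surrogate between
#' two visits; normalizing by the elapsed time makes subjects with different
#' inter-visit intervals comparable.
#'
#' @param y1,y2 Values at the first and second visit (vectorized).
#' @param t1,t2 Visit times in years; `t2 > t1` elementwise.
#' @param subject_id,variable Optional identifiers carried into the result.
#' @return A data frame with columns `subject_id`, `variable`, `y1`, `y2`,
#'   `delta_t`, `roc` (units of the variable per year).
#' @export
rate_of_change <- function(y1, y2, t1, t2, subject_id = NA_character_,
                           variable = NA_character_) {
  if (any(t2 <= t1)) stop("`t2` must be strictly greater than `t1`", call. = FALSE)
  delta_t <- t2 - t1
  data.frame(
    subject_id = subject_id, variable = variable,
    y1 = y1, y2 = y2, delta_t = delta_t,
    roc = (y2 - y1) / delta_t,
    stringsAsFactors = FALSE
  )
}

#' Normality-gated transformation
#'
#' Tests departure from normality with the Lilliefors test at alpha = 0.05.
#' If rejected and all values are positive, a log10 transform is tried; if
#' normality is still rejected (or the data contain non-positive values), a
#' rank transform is applied instead so parametric models remain usable.
#'
#' @param values Numeric vector, `n >= 8`.
#' @param alpha Rejection level for the Lilliefors gate.
#' @return A list with `values` (transformed), `transform`
#'   (`"none"|"log10"|"rank"`), and `normality_p` (Lilliefors p of the
#'   untransformed data).
#' @export
check_and_transform <- function(values, alpha = 0.05) {
  values <- as.numeric(values)
  if (sum(is.finite(values)) < 8L) stop("need n >= 8 finite values", call. = FALSE)
  p0 <- nortest::lillie.test(values)$p.value
  if (p0 >= alpha) {
    return(list(values = values, transform = "none", normality_p = p0))
  }
  if (all(values > 0)) {
    lv <- log10(values)
    p1 <- nortest::lillie.test(lv)$p.value
    if (p1 >= alpha) {
      return(list(values = lv, transform = "log10", normality_p = p0))
    }
  }
  list(values = rank(values, ties.method = "average"),
       transform = "rank", normality_p = p0)
}

#' Levene's test of equal group variances
#'
#' Mean-centered variant (absolute deviations from group means), via
#' `car::leveneTest`.
#'
#' @param values Numeric outcome.
#' @param groups Grouping factor with >= 2 levels, each with n >= 2.
#' @return A list with `statistic`, `df`, and `p`.
#' @export
levene_test <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2L)) stop("every group needs n >= 2", call. = FALSE)
  lt <- suppressWarnings(car::leveneTest(values ~ groups, center = mean))
  list(statistic = lt[1, "F value"], df = c(lt[1, "Df"], lt[2, "Df"]),
       p = lt[1, "Pr(>F)"])
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjustment across a family of p-values; used to correct the
#' regional analyses by the number of structures.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param q Control level.
#' @return A list with `adjusted` (BH-adjusted p) and `rejected` (logical).
#' @export
fdr_correct <- function(p_values, q = 0.05) {
  if (length(p_values) == 0L) stop("empty p-value vector", call. = FALSE)
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  adj <- p.adjust(p_values, method = "BH")
  list(adjusted = adj, rejected = !is.na(adj) & adj <= q)
}

#' Linear partial correlation
#'
#' Correlation of the least-squares residuals of `x` and `y` after both are
#' regressed on the covariates; the t test uses `n - q - 2` degrees of
#' freedom, `q` the number of covariates.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional data frame or matrix of covariates (numeric or
#'   factor columns); `NULL` gives the plain Pearson correlation.
#' @return A list with `r`, `p`, `n`, and `q`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  ok <- is.finite(x) & is.finite(y)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    ok <- ok & complete.cases(covariates)
  }
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0L) {
    q <- 0L
    rx <- x; ry <- y
  } else {
    covariates <- droplevels(as.data.frame(covariates)[ok, , drop = FALSE])
    X <- model.matrix(~ ., data = covariates)
    if (qr(X)$rank < ncol(X)) stop("collinear covariates", call. = FALSE)
    q <- ncol(X) - 1L
    rx <- lm.fit(X, x)$residuals
    ry <- lm.fit(X, y)$residuals
  }
  if (n <= q + 3L) stop("need n > q + 3", call. = FALSE)
  r <- cor(rx, ry)
  df <- n - q - 2L
  tval <- r * sqrt(df) / sqrt(1 - r^2)
  list(r = r, p = 2 * pt(-abs(tval), df), n = n, q = q)
}

#' Compare two partial correlations with the Fisher z test
#'
#' Applies the Fisher transform `z = ln((1+r)/(1-r))/2` to each coefficient
#' and tests their difference with
#' `Z = (z1 - z2) / sqrt(1/(n1-q-3) + 1/(n2-q-3))`, where `q` is the number
#' of covariates in the partial correlations; two-sided p from the standard
#' normal.
#'
#' @param r1,r2 Partial correlation coefficients, `|r| < 1`.
#' @param n1,n2 Sample sizes.
#' @param q Number of covariates (same for both samples).
#' @return A list with `r1`, `r2`, `z1`, `z2`, `Z`, `p`, `n1`, `n2`, `q`.
#' @export
compare_correlations <- function(r1, n1, r2, n2, q = 0L) {
  for (r in c(r1, r2)) {
    if (!is.finite(r) || abs(r) >= 1) stop("|r| must be < 1", call. = FALSE)
  }
  if (n1 - q - 3 <= 0 || n2 - q - 3 <= 0) {
    stop("need n - q - 3 > 0 for both samples", call. = FALSE)
  }
  fisher_z <- function(r) log((1 + r) / (1 - r)) / 2
  z1 <- fisher_z(r1); z2 <- fisher_z(r2)
  Z <- (z1 - z2) / sqrt(1 / (n1 - q - 3) + 1 / (n2 - q - 3))
  list(r1 = r1, r2 = r2, z1 = z1, z2 = z2, Z = Z,
       p = 2 * pnorm(-abs(Z)), n1 = n1, n2 = n2, q = q)
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measure: the
#' Shrout-Fleiss ICC(2,1) computed from the two-way ANOVA mean squares, with
#' an F-based confidence interval.
#'
#' @param measurements Numeric matrix, subjects in rows and sessions in
#'   columns; >= 5 subjects, >= 2 sessions, no missing cells.
#' @param conf_level Confidence level for the interval.
#' @return A list of class `icc_result` with `icc`, `ci` (length 2), `n`,
#'   `k`, `ms` (mean squares), and `undefined` (TRUE for constant data).
#' @export
icc <- function(measurements, conf_level = 0.95) {
  m <- as.matrix(measurements)
  if (any(!is.finite(m))) stop("missing cells are not supported", call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  if (n < 5L || k < 2L) stop("need >= 5 subjects and >= 2 sessions", call. = FALSE)
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (ss_tot == 0) {
    out <- list(icc = NA_real_, ci = c(NA_real_, NA_real_), n = n, k = k,
                ms = c(msr = msr, msc = msc, mse = mse), undefined = TRUE)
    class(out) <- "icc_result"
    return(out)
  }
  val <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))

  # Shrout & Fleiss F-based interval for ICC(2,1)
  alpha <- 1 - conf_level
  a <- (k * val) / (n * (1 - val))
  b <- 1 + (k * val * (n - 1)) / (n * (1 - val))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- qf(1 - alpha / 2, n - 1, v)
  f_u <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  out <- list(icc = val, ci = c(lower, upper), n = n, k = k,
              ms = c(msr = msr, msc = msc, mse = mse), undefined = FALSE)
  class(out) <- "icc_result"
  out
}

#' @export
print.icc_result <- function(x, ...) {
  if (x$undefined) {
    cat("<icc_result> undefined (constant data)\n")
  } else {
    cat(sprintf("<icc_result> ICC(2,1) = %.3f [%.3f, %.3f], n=%d subjects, k=%d sessions\n",
                x$icc, x$ci[1], x$ci[2], x$n, x$k))
  }
  invisible(x)
}
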