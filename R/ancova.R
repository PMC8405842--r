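# ANCOVA with type-III sums of squares, omega-squared effect sizes, and
# post hoc cell comparisons.

#' Two-factor ANCOVA with type-III sums of squares
#'
#' Fits `outcome ~ covariates + apoe4 * progression` (sum-to-zero contrasts)
#' and reports F, p and the omega-squared effect size for the two main
#' effects and their interaction, using type-III sums of squares as
#' appropriate for unbalanced covariate-adjusted designs. Unless
#' `transform = "none"`, the outcome is first passed through the
#' normality gate of [check_and_transform()]; if Levene's test across the
#' four design cells still rejects homogeneity on untransformed data, a
#' log10 (or rank) transform is applied.
#'
#' @param data Data frame containing the outcome, factor and covariate
#'   columns.
#' @param outcome Name of the outcome column.
#' @param factors Length-2 character vector naming the two crossed factors
#'   (default `c("apoe4", "progression")`).
#' @param covariates Character vector of covariate column names (numeric or
#'   factor).
#' @param transform `"auto"` (normality/variance-gated) or `"none"`.
#' @return A data frame of class `ancova_result` with one row per effect
#'   (`apoe4`, `progression`, `interaction`): `F`, `df1`, `df2`, `p`,
#'   `omega_sq` (clamped at 0), `transform`, `levene_p`.
#' @export
ancova <- function(data, outcome, factors = c("apoe4", "progression"),
                   covariates = character(), transform = "auto") {
  stopifnot(length(factors) == 2L)
  cols <- c(outcome, factors, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  d <- data[cols]
  d <- d[complete.cases(d), , drop = FALSE]
  for (f in factors) d[[f]] <- droplevels(as.factor(d[[f]]))
  if (any(table(d[[factors[1]]], d[[factors[2]]]) == 0L)) {
    stop("empty design cell", call. = FALSE)
  }

  y <- as.numeric(d[[outcome]])
  tag <- "none"
  if (identical(transform, "auto")) {
    ct <- check_and_transform(y)
    y <- ct$values; tag <- ct$transform
  }
  cells <- interaction(d[[factors[1]]], d[[factors[2]]], drop = TRUE)
  lev <- levene_test(y, cells)
  if (identical(transform, "auto") && lev$p < 0.05 && tag == "none") {
    if (all(y > 0)) {
      y <- log10(y); tag <- "log10"
    } else {
      y <- rank(y, ties.method = "average"); tag <- "rank"
    }
    lev <- levene_test(y, cells)
  }
  d$.y <- y

  fml <- stats::reformulate(c(covariates, paste(factors, collapse = " * ")),
                            response = ".y")
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  fit <- lm(fml, data = d)
  if (fit$rank < ncol(model.matrix(fit))) stop("rank-deficient design", call. = FALSE)

  ss_tot_y <- sum((y - mean(y))^2)
  if (stats::deviance(fit) <= 1e-10 * max(ss_tot_y, 1)) {
    # outcome perfectly explained (e.g. equals a covariate): nothing left
    # for the factors
    res <- data.frame(
      effect = c("apoe4", "progression", "interaction"),
      F = 0, df1 = 1L, df2 = df.residual(fit), p = 1, omega_sq = 0,
      transform = tag, levene_p = lev$p, stringsAsFactors = FALSE
    )
    class(res) <- c("ancova_result", "data.frame")
    return(res)
  }
  a3 <- car::Anova(fit, type = 3)

  rn <- rownames(a3)
  ix_term <- paste(factors, collapse = ":")
  wanted <- c(factors[1], factors[2], ix_term)
  labels <- c("apoe4", "progression", "interaction")
  ss_err <- a3[rn == "Residuals", "Sum Sq"]
  df_err <- a3[rn == "Residuals", "Df"]
  ms_err <- ss_err / df_err
  ss_tot <- sum((y - mean(y))^2)

  res <- do.call(rbind, lapply(seq_along(wanted), function(i) {
    row <- a3[rn == wanted[i], , drop = FALSE]
    ss <- row[["Sum Sq"]]; dfe <- row[["Df"]]
    om <- (ss - dfe * ms_err) / (ss_tot + ms_err)
    data.frame(
      effect = labels[i], F = row[["F value"]], df1 = dfe, df2 = df_err,
      p = row[["Pr(>F)"]], omega_sq = max(0, om),
      transform = tag, levene_p = lev$p,
      stringsAsFactors = FALSE
    )
  }))
  class(res) <- c("ancova_result", "data.frame")
  res
}

#' Post hoc pairwise comparisons between design cells
#'
#' Pairwise comparisons between group (cell) means with Tukey's HSD,
#' Bonferroni-corrected pooled t tests, or the Games-Howell procedure
#' (Welch degrees of freedom, studentized-range reference; appropriate when
#' equal cell variances are not assumed).
#'
#' @param values Numeric outcome.
#' @param groups Factor of cell membership (>= 2 cells).
#' @param method `"tukey"`, `"bonferroni"`, or `"games_howell"`.
#' @return A data frame with `group1`, `group2`, `estimate` (mean
#'   difference), and `p` (corrected).
#' @export
posthoc <- function(values, groups, method = c("tukey", "bonferroni",
                                               "games_howell")) {
  method <- match.arg(method)
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L) stop("need at least 2 cells", call. = FALSE)
  lev <- levels(groups)
  ng <- length(lev)
  means <- tapply(values, groups, mean)
  vars <- tapply(values, groups, var)
  ns <- tapply(values, groups, length)
  pairs <- utils::combn(lev, 2)

  if (method == "tukey") {
    tk <- stats::TukeyHSD(aov(values ~ groups))$groups
    key <- paste(pairs[2, ], pairs[1, ], sep = "-")
    out <- data.frame(
      group1 = pairs[1, ], group2 = pairs[2, ],
      estimate = tk[key, "diff"], p = tk[key, "p adj"],
      stringsAsFactors = FALSE
    )
    rownames(out) <- NULL
    return(out)
  }

  est <- means[pairs[2, ]] - means[pairs[1, ]]
  if (method == "bonferroni") {
    df <- sum(ns) - ng
    mse <- sum((ns - 1) * vars) / df
    se <- sqrt(mse * (1 / ns[pairs[1, ]] + 1 / ns[pairs[2, ]]))
    tval <- est / se
    p <- pmin(1, 2 * pt(-abs(tval), df) * ncol(pairs))
  } else {  # games_howell
    v1 <- vars[pairs[1, ]] / ns[pairs[1, ]]
    v2 <- vars[pairs[2, ]] / ns[pairs[2, ]]
    se <- sqrt(v1 + v2)
    tval <- est / se
    df <- (v1 + v2)^2 / (v1^2 / (ns[pairs[1, ]] - 1) + v2^2 / (ns[pairs[2, ]] - 1))
    p <- ptukey(abs(tval) * sqrt(2), ng, df, lower.tail = FALSE)
  }
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
             estimate = as.numeric(est), p = as.numeric(p),
             stringsAsFactors = FALSE)
}
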