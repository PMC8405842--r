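# Cohort-level statistical battery tying rate-of-change, ANCOVA, regional
# FDR, and association analyses together.

default_ancova_covariates <- c("age", "sex", "education", "field_strength",
                               "handedness", "gm_volume")
default_assoc_covariates <- c("age", "sex", "education", "tiv")
global_metric_names <- c("clux", "charpath", "eglobal", "gconnect",
                         "gamma", "lambda", "sigma", "sparsity")

#' Run the full group analysis over a cohort's metric tables
#'
#' Executes the statistical battery on per-subject network metrics:
#' \itemize{
#'   \item a gate test for group effects on network size, connection density
#'     and mean degree (ANCOVA at alpha = 0.05); significant ones are added
#'     as covariates for the metric ANCOVAs,
#'   \item baseline (visit 1) ANCOVAs per global metric with ApoE4,
#'     progression and their interaction plus covariates,
#'   \item rate-of-change ANCOVAs per global metric,
#'   \item per-region ANCOVAs on nodal normalized clustering with regional
#'     gray-matter volume and nodal degree as extra covariates and
#'     Benjamini-Hochberg correction across regions,
#'   \item partial-correlation association analyses between baseline metrics
#'     and phenotypes with FDR correction, and carrier-vs-noncarrier
#'     Fisher-z comparisons of those partial correlations.
#' }
#'
#' @param cohort Data frame with one row per subject: `subject_id`, factors
#'   `apoe4`/`progression`, the covariates, visit times `t1`/`t2`, and
#'   phenotype columns.
#' @param metrics Data frame with columns `subject_id`, `visit`, and global
#'   metric columns (any of `clux`, `charpath`, `eglobal`, `gconnect`,
#'   `gamma`, `lambda`, `sigma`, `sparsity`, `size`, `mean_degree`).
#' @param regional Optional long data frame with `subject_id`, `visit`,
#'   `region`, `value` (nodal normalized clustering), and optionally
#'   `region_gm_volume` and `nodal_degree` covariate columns.
#' @param phenotypes Phenotype column names present in `cohort` used for the
#'   association analyses.
#' @param covariates Covariates for the ANCOVAs.
#' @param assoc_covariates Covariates for the partial correlations.
#' @param q FDR level for the regional and association families.
#' @param seed Recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return A list with data frames `gate`, `baseline`, `roc`, `regional`,
#'   `associations`, `comparisons`, and a `manifest` list (config hash,
#'   seed, n subjects).
#' @export
run_group_analysis <- function(cohort, metrics, regional = NULL,
                               phenotypes = c("mmse", "adni_mem", "abeta42",
                                              "ttau", "ptau"),
                               covariates = default_ancova_covariates,
                               assoc_covariates = default_assoc_covariates,
                               q = 0.05, seed = NULL) {
  covariates <- intersect(covariates, names(cohort))
  covariates <- covariates[vapply(covariates, function(v)
    length(unique(cohort[[v]])) > 1L, logical(1))]
  phenotypes <- intersect(phenotypes, names(cohort))

  m1 <- metrics[metrics$visit == 1L, , drop = FALSE]
  m2 <- metrics[metrics$visit == 2L, , drop = FALSE]
  base <- merge(cohort, m1, by = "subject_id")
  if (nrow(base) == 0L) stop("no visit-1 metrics match the cohort", call. = FALSE)
  metric_cols <- intersect(global_metric_names, names(metrics))

  # an ANCOVA that fails on a degenerate metric (e.g. undefined normalized
  # values dropping a whole cell) is skipped with a warning, not fatal
  safe_ancova <- function(d, v, covs) {
    tryCatch(cbind(variable = v, ancova(d, v, covariates = covs)),
             error = function(e) {
               warning(sprintf("skipping ANCOVA for `%s`: %s", v,
                               conditionMessage(e)), call. = FALSE)
               NULL
             })
  }

  # gate: do size / density / degree differ between groups?
  gate_vars <- intersect(c("size", "sparsity", "mean_degree"), names(metrics))
  gate <- do.call(rbind, lapply(gate_vars, function(v)
    safe_ancova(base, v, covariates)))
  gated_covs <- character()
  if (!is.null(gate)) {
    sig <- unique(gate$variable[gate$p < 0.05])
    gated_covs <- setdiff(sig, "")  # add as covariates downstream
  }

  baseline <- do.call(rbind, lapply(metric_cols, function(v) {
    extra <- setdiff(gated_covs, v)
    safe_ancova(base, v, c(covariates, extra))
  }))

  # rate of change of each metric
  roc_tab <- NULL
  roc_res <- NULL
  if (nrow(m2) > 0L) {
    both <- merge(m1, m2, by = "subject_id", suffixes = c("_v1", "_v2"))
    both <- merge(both, cohort[c("subject_id", "t1", "t2")], by = "subject_id")
    roc_tab <- do.call(rbind, lapply(metric_cols, function(v) {
      rate_of_change(both[[paste0(v, "_v1")]], both[[paste0(v, "_v2")]],
                     both$t1, both$t2, subject_id = both$subject_id,
                     variable = v)
    }))
    roc_res <- do.call(rbind, lapply(metric_cols, function(v) {
      rv <- roc_tab[roc_tab$variable == v, c("subject_id", "roc")]
      d <- merge(cohort, rv, by = "subject_id")
      res <- tryCatch(ancova(d, "roc", covariates = covariates),
                      error = function(e) {
                        warning(sprintf("skipping RoC ANCOVA for `%s`: %s", v,
                                        conditionMessage(e)), call. = FALSE)
                        NULL
                      })
      if (is.null(res)) NULL else cbind(variable = v, res)
    }))
  }

  # per-region ANCOVA on nodal normalized clustering, FDR across regions
  regional_res <- NULL
  if (!is.null(regional)) {
    reg1 <- regional[regional$visit == 1L, , drop = FALSE]
    extra_reg <- intersect(c("region_gm_volume", "nodal_degree"), names(reg1))
    regs <- sort(unique(reg1$region))
    rows <- lapply(regs, function(rid) {
      d <- merge(cohort, reg1[reg1$region == rid, , drop = FALSE],
                 by = "subject_id")
      d <- d[is.finite(d$value), , drop = FALSE]
      if (nrow(d) < 12L) return(NULL)
      res <- tryCatch(ancova(d, "value", covariates = c(covariates, extra_reg)),
                      error = function(e) NULL)
      if (is.null(res)) return(NULL)
      cbind(region = rid, res)
    })
    regional_res <- do.call(rbind, rows)
    if (!is.null(regional_res)) {
      regional_res$p_fdr <- NA_real_
      regional_res$rejected <- NA
      for (eff in unique(regional_res$effect)) {
        sel <- regional_res$effect == eff
        fc <- fdr_correct(regional_res$p[sel], q)
        regional_res$p_fdr[sel] <- fc$adjusted
        regional_res$rejected[sel] <- fc$rejected
      }
    }
  }

  # associations: partial correlations metric ~ phenotype
  assoc <- NULL
  compare <- NULL
  ac <- intersect(assoc_covariates, names(cohort))
  if (length(phenotypes)) {
    grid <- expand.grid(metric = metric_cols, phenotype = phenotypes,
                        stringsAsFactors = FALSE)
    assoc <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
      v <- grid$metric[i]; ph <- grid$phenotype[i]
      tryCatch({
        pc <- partial_correlation(base[[v]], base[[ph]], base[ac])
        data.frame(metric = v, phenotype = ph, r = pc$r, p = pc$p,
                   n = pc$n, q_covariates = pc$q, stringsAsFactors = FALSE)
      }, error = function(e) {
        warning(sprintf("skipping association %s ~ %s: %s", v, ph,
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
    }))
    if (!is.null(assoc)) {
      fc <- fdr_correct(assoc$p, q)
      assoc$p_fdr <- fc$adjusted
      assoc$rejected <- fc$rejected
    }

    # carrier vs non-carrier comparison of each partial correlation
    compare <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
      v <- grid$metric[i]; ph <- grid$phenotype[i]
      out <- tryCatch({
        g1 <- base[base$apoe4 == "carrier", , drop = FALSE]
        g2 <- base[base$apoe4 == "noncarrier", , drop = FALSE]
        p1 <- partial_correlation(g1[[v]], g1[[ph]], g1[ac])
        p2 <- partial_correlation(g2[[v]], g2[[ph]], g2[ac])
        cc <- compare_correlations(p1$r, p1$n, p2$r, p2$n, q = p1$q)
        data.frame(metric = v, phenotype = ph, r_carrier = cc$r1,
                   r_noncarrier = cc$r2, Z = cc$Z, p = cc$p,
                   stringsAsFactors = FALSE)
      }, error = function(e) NULL)
      out
    }))
  }

  manifest <- list(
    n_subjects = nrow(cohort), seed = seed, fdr_q = q,
    covariates = covariates, gated_covariates = gated_covs,
    config_hash = object_md5(list(covariates = covariates,
                                  assoc_covariates = ac,
                                  phenotypes = phenotypes, q = q, seed = seed))
  )
  list(gate = gate, baseline = baseline, roc = roc_res, roc_table = roc_tab,
       regional = regional_res, associations = assoc, comparisons = compare,
       manifest = manifest)
}
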