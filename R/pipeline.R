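# Pipeline orchestration: one config drives simulate -> extract -> metrics
# -> roc/stats -> reliability, with per-stage seeds fanned out from a single
# global seed and a manifest recording config hash and output checksums.

# retest session data: fresh i.i.d. noise (SD = noise_frac x tissue signal
# SD) inside the tissue mask; background voxels stay exactly zero
retest_volume_data <- function(v1, noise_frac, seed) {
  mask <- v1$data > 0
  noise_sd <- noise_frac * sd(v1$data[mask])
  f2 <- v1$data
  f2[mask] <- with_seed(seed, f2[mask] + rnorm(sum(mask), 0, noise_sd))
  pmin(1, pmax(0, f2))
}

pipeline_defaults <- function() {
  list(
    out_dir = "ssgmnet-run",
    seed = 1L,
    simulate = list(n_per_cell = 5L, shape = c(30L, 30L, 30L),
                    n_regions = 114L, zero_effects = FALSE),
    extract = list(cube_size = 3L, variance_eps = 0, q = 0.05,
                   n_perm = 10000L),
    metrics = list(n_rand = 20L),
    analysis = list(q = 0.05, run_regional = TRUE,
                    covariates = default_ancova_covariates,
                    assoc_covariates = default_assoc_covariates),
    reliability = list(enabled = FALSE, n_subjects = 10L, noise_frac = 0.02)
  )
}

#' Load and validate a pipeline configuration
#'
#' Accepts a YAML path or a nested list, rejects unknown keys, and fills in
#' defaults for anything unset.
#'
#' @param config Path to a YAML file, or a list.
#' @return A validated config list of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or YAML path", call. = FALSE)
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (stage in names(config)) {
    if (is.list(defaults[[stage]]) && is.list(config[[stage]])) {
      bad <- setdiff(names(config[[stage]]), names(defaults[[stage]]))
      if (length(bad)) {
        stop(sprintf("unknown config keys under `%s`: %s", stage,
                     paste(bad, collapse = ", ")), call. = FALSE)
      }
    }
  }
  out <- modifyList(defaults, config)
  class(out) <- c("run_config", "list")
  out
}

#' Validate pipeline inputs
#'
#' Checks volume/atlas grid agreement, cohort completeness, density range
#' and CSF phenotype assay ranges. Never raises: all findings are returned
#' as a report.
#'
#' @param cohort Cohort data frame (or `NULL`).
#' @param volumes Per-subject list of `v1`/`v2` [gm_volume()]s (or `NULL`).
#' @param atlas A [gm_atlas()] (or `NULL`).
#' @return A data frame with columns `level` (`"error"`/`"warning"`),
#'   `item`, `message`; zero rows when everything is clean.
#' @export
validate_inputs <- function(cohort = NULL, volumes = NULL, atlas = NULL) {
  rows <- list()
  note <- function(level, item, msg) {
    rows[[length(rows) + 1L]] <<- data.frame(level = level, item = item,
                                             message = msg,
                                             stringsAsFactors = FALSE)
  }
  if (!is.null(volumes) && !is.null(atlas)) {
    for (sid in names(volumes)) {
      for (vis in c("v1", "v2")) {
        vol <- volumes[[sid]][[vis]]
        if (is.null(vol)) next
        if (!identical(dim(vol$data), dim(atlas$labels))) {
          note("error", paste(sid, vis), "volume/atlas shape mismatch")
        }
        if (min(vol$data) < 0 || max(vol$data) > 1) {
          note("error", paste(sid, vis), "density outside [0, 1]")
        }
      }
    }
  }
  if (!is.null(cohort)) {
    need <- c("subject_id", "apoe4", "progression", "t1", "t2")
    miss <- setdiff(need, names(cohort))
    if (length(miss)) {
      note("error", "cohort", paste("missing columns:", paste(miss, collapse = ", ")))
    }
    if (all(c("t1", "t2") %in% names(cohort)) && any(cohort$t2 <= cohort$t1)) {
      note("error", "cohort", "t2 must exceed t1 for every subject")
    }
    for (ph in names(csf_bounds)) {
      if (ph %in% names(cohort)) {
        b <- csf_bounds[[ph]]
        n_out <- sum(cohort[[ph]] < b[1] | cohort[[ph]] > b[2], na.rm = TRUE)
        if (n_out > 0L) {
          note("warning", ph,
               sprintf("%d values outside assay range [%g, %g] pg/ml",
                       n_out, b[1], b[2]))
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(level = character(), item = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Extract one subject-visit's network and all its metrics
#'
#' Convenience composition used by the pipeline: network extraction,
#' normalized global metrics (including GConnect from the unthresholded
#' similarity matrix), and regional aggregation of nodal normalized
#' clustering.
#'
#' @param volume A [gm_volume()].
#' @param atlas Optional [gm_atlas()] for regional aggregation.
#' @param cube_size,variance_eps,q,n_perm Passed to [extract_network()].
#' @param n_rand Reference networks for normalization.
#' @param seed Integer seed (permutation null and randomizations).
#' @return A list with `global` (one-row data frame), `regional` (data frame
#'   or `NULL`), and `extraction` (the [extract_network()] result).
#' @export
subject_metrics <- function(volume, atlas = NULL, cube_size = 3L,
                            variance_eps = 0, q = 0.05, n_perm = 10000L,
                            n_rand = 20L, seed = NULL) {
  ex <- extract_network(volume, cube_size = cube_size,
                        variance_eps = variance_eps, q = q, n_perm = n_perm,
                        seed = seed)
  gm <- normalized_metrics(ex$network, sim = ex$similarity, n_rand = n_rand,
                           seed = derive_seed(seed, 777))
  gm$subject_id <- volume$subject_id
  gm$visit <- volume$visit
  regional <- NULL
  if (!is.null(atlas)) {
    nn <- nodal_normalized_clustering(ex$network, n_rand = n_rand,
                                      seed = derive_seed(seed, 778))
    regional <- aggregate_regional(nn$nodal_clux_normalized,
                                   ex$similarity$origins, atlas,
                                   cube_size = cube_size)
    regional$subject_id <- volume$subject_id
    regional$visit <- volume$visit
    # per-region covariates for the regional ANCOVA
    centers <- ex$similarity$origins + cube_size %/% 2L
    lab <- atlas$labels[centers + 1L]
    deg <- rowSums(ex$network$adjacency)
    regional$nodal_degree <- vapply(regional$region, function(id) {
      sel <- lab == id
      if (!any(sel)) NA_real_ else mean(deg[sel])
    }, numeric(1))
    vol_mean <- vapply(regional$region, function(id)
      mean(volume$data[atlas$labels == id]), numeric(1))
    regional$region_gm_volume <- vol_mean
  }
  list(global = gm, regional = regional, extraction = ex)
}

#' Run the full pipeline from a single configuration
#'
#' Simulates a cohort, extracts every subject-visit network, computes global
#' and regional metrics, runs the rate-of-change and group statistics, and
#' (optionally) a test-retest reliability stage. All outputs are written as
#' CSV under `config$out_dir` along with a JSON manifest carrying the config
#' hash, per-stage seeds and output checksums; re-running an unchanged
#' config reproduces identical checksums.
#'
#' @param config A [run_config()], list, or YAML path.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)
  message("[simulate] cohort of ", 4L * cfg$simulate$n_per_cell, " subjects")
  spec <- effect_spec(zero = isTRUE(cfg$simulate$zero_effects))
  atlas <- generate_atlas(cfg$simulate$shape, cfg$simulate$n_regions)
  sim <- generate_cohort(cfg$simulate$n_per_cell, spec,
                         shape = cfg$simulate$shape,
                         seed = derive_seed(seed, 1), atlas = atlas)
  report <- validate_inputs(sim$cohort, sim$volumes, sim$atlas)
  if (any(report$level == "error")) {
    stop("[simulate] invalid inputs: ",
         paste(report$message[report$level == "error"], collapse = "; "),
         call. = FALSE)
  }

  message("[extract+metrics] ", 2L * nrow(sim$cohort), " volumes")
  glb <- list(); reg <- list()
  for (i in seq_len(nrow(sim$cohort))) {
    for (vis in c(1L, 2L)) {
      vol <- sim$volumes[[i]][[paste0("v", vis)]]
      sm <- subject_metrics(
        vol, atlas = sim$atlas, cube_size = cfg$extract$cube_size,
        variance_eps = cfg$extract$variance_eps, q = cfg$extract$q,
        n_perm = cfg$extract$n_perm, n_rand = cfg$metrics$n_rand,
        seed = derive_seed(seed, 100L + 2L * i + vis)
      )
      glb[[length(glb) + 1L]] <- sm$global
      reg[[length(reg) + 1L]] <- sm$regional
    }
  }
  metrics <- do.call(rbind, glb)
  regional <- do.call(rbind, reg)

  message("[stats] group analysis")
  res <- run_group_analysis(sim$cohort, metrics,
                            regional = if (isTRUE(cfg$analysis$run_regional)) regional,
                            covariates = cfg$analysis$covariates,
                            assoc_covariates = cfg$analysis$assoc_covariates,
                            q = cfg$analysis$q, seed = seed)

  rel_tab <- NULL
  if (isTRUE(cfg$reliability$enabled)) {
    message("[reliability] ICC(2,1) on retest volumes")
    n_rel <- min(cfg$reliability$n_subjects, nrow(sim$cohort))
    sess <- lapply(seq_len(n_rel), function(i) {
      v1 <- sim$volumes[[i]]$v1
      f2 <- retest_volume_data(v1, cfg$reliability$noise_frac,
                               derive_seed(seed, 5000L + i))
      v2 <- gm_volume(array(f2, dim = dim(v1$data)),
                      subject_id = v1$subject_id, visit = 2L)
      lapply(list(v1, v2), function(v)
        subject_metrics(v, cube_size = cfg$extract$cube_size,
                        q = cfg$extract$q, n_perm = cfg$extract$n_perm,
                        n_rand = cfg$metrics$n_rand,
                        seed = derive_seed(seed, 6000L + i))$global)
    })
    attrs <- c("clux", "charpath", "gamma", "lambda", "sigma", "eglobal",
               "gconnect")
    rel_tab <- do.call(rbind, lapply(attrs, function(a) {
      m <- t(vapply(sess, function(s) c(s[[1]][[a]], s[[2]][[a]]), numeric(2)))
      ic <- icc(m)
      data.frame(attribute = a, icc = ic$icc, ci_lower = ic$ci[1],
                 ci_upper = ic$ci[2], n = ic$n, k = ic$k,
                 stringsAsFactors = FALSE)
    }))
  }

  # write outputs + manifest
  paths <- c(
    cohort = "cohort.csv", metrics = "global_metrics.csv",
    regional = "regional_metrics.csv", baseline = "ancova_baseline.csv",
    roc = "ancova_roc.csv", roc_table = "roc_values.csv",
    regional_stats = "ancova_regional.csv", associations = "associations.csv",
    comparisons = "correlation_comparisons.csv", reliability = "reliability.csv"
  )
  objects <- list(sim$cohort, metrics, regional, res$baseline, res$roc,
                  res$roc_table, res$regional, res$associations,
                  res$comparisons, rel_tab)
  written <- character()
  for (i in seq_along(objects)) {
    if (is.null(objects[[i]])) next
    fp <- file.path(cfg$out_dir, paths[[i]])
    write.csv(objects[[i]], fp, row.names = FALSE)
    written[paths[[i]]] <- file_md5(fp)
  }
  manifest <- list(
    config = unclass(cfg)[setdiff(names(cfg), "out_dir")],
    config_hash = object_md5(unclass(cfg)[setdiff(names(cfg), "out_dir")]),
    seed = seed,
    stage_seeds = list(
      simulate = derive_seed(seed, 1),
      extract_metrics = sprintf("derive_seed(seed, 100 + 2*subject + visit), subjects 1..%d",
                                nrow(sim$cohort)),
      metrics_reference = "derive_seed(stage_seed, 777)",
      reliability = if (isTRUE(cfg$reliability$enabled))
        "derive_seed(seed, 5000 + subject) / derive_seed(seed, 6000 + subject)"
    ),
    outputs = as.list(written)
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
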