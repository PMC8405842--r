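# Synthetic gray-matter volumes, atlases and two-visit cohorts.
#
# Volumes are synthesized directly as density fields (no simulated T1
# contrast or segmentation step): network extraction consumes density only.
# The field emulates the two features of segmented gray matter that the
# cube-similarity method depends on: a curved tissue sheet (cortex-like
# ribbon, realized as a Gaussian profile around the level set of a smooth
# random field) giving cubes sharp, high-detail patterns that are continuous
# between neighbors, and voxel-level segmentation noise. Background voxels
# are exactly zero, so cubes without tissue are excluded by the
# zero-variance rule just as off-brain cubes are in real data.

#' Generate a gray-matter-like density volume
#'
#' Draws a Gaussian random field (i.i.d. voxel noise smoothed by an
#' isotropic Gaussian kernel with SD `smoothness` voxels, periodic
#' boundaries, FFT convolution), standardizes it, and maps it through a
#' ribbon profile `exp(-(phi/tissue_width)^2)`: density is ~1 on the curved
#' sheet where the field crosses zero and decays to 0 away from it.
#' Multiplicative voxel noise emulates segmentation noise, values below
#' `floor` are set to exactly 0 (background), and per-region multiplicative
#' atrophy factors can be applied.
#'
#' @param shape Integer triple; every element must be >= 9.
#' @param smoothness Gaussian kernel SD in voxels (>= 0) of the underlying
#'   field; 0 gives i.i.d. voxels (a pure-noise null volume).
#' @param atrophy_map Optional named numeric vector of per-region
#'   multiplicative factors in (0, 1\], named by atlas label; requires
#'   `atlas`.
#' @param seed Integer seed; identical arguments give bitwise-identical
#'   volumes.
#' @param atlas Optional [gm_atlas()] matching `shape`, needed when
#'   `atrophy_map` is given.
#' @param tissue_width Ribbon width on the standardized field scale; larger
#'   values give a thicker sheet covering more of the volume.
#' @param voxel_noise SD of the multiplicative voxel noise.
#' @param floor Density below which voxels are set to exactly 0.
#' @param subject_id,visit Identifiers for the returned volume.
#' @return A [gm_volume()].
#' @export
generate_gm_volume <- function(shape, smoothness = 2, atrophy_map = NULL,
                               seed = NULL, atlas = NULL,
                               tissue_width = 0.6, voxel_noise = 0.03,
                               floor = 0.02,
                               subject_id = "synthetic", visit = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 9L)) {
    stop("`shape` must be three integers >= 9", call. = FALSE)
  }
  stopifnot_scalar_number(smoothness, "smoothness")
  if (smoothness < 0) stop("`smoothness` must be >= 0", call. = FALSE)
  if (voxel_noise < 0) stop("`voxel_noise` must be >= 0", call. = FALSE)
  if (tissue_width <= 0) stop("`tissue_width` must be > 0", call. = FALSE)

  field <- with_seed(seed, {
    phi <- array(rnorm(prod(shape)), dim = shape)
    if (smoothness > 0) phi <- gaussian_smooth3d(phi, smoothness)
    phi <- phi / sd(phi)
    f <- exp(-(phi / tissue_width)^2)
    if (voxel_noise > 0) {
      f <- f * (1 + voxel_noise * array(rnorm(prod(shape)), dim = shape))
    }
    f
  })
  field[field < floor] <- 0
  field <- array(pmin(1, pmax(0, field)), dim = shape)

  if (!is.null(atrophy_map)) {
    if (is.null(atlas)) stop("`atrophy_map` requires an `atlas`", call. = FALSE)
    if (!identical(dim(atlas$labels), shape)) {
      stop("atlas shape does not match `shape`", call. = FALSE)
    }
    if (any(atrophy_map <= 0) || any(atrophy_map > 1)) {
      stop("atrophy factors must lie in (0, 1]", call. = FALSE)
    }
    for (lab in names(atrophy_map)) {
      idx <- atlas$labels == as.integer(lab)
      field[idx] <- field[idx] * atrophy_map[[lab]]
    }
  }
  gm_volume(field, subject_id = subject_id, visit = visit)
}

# Isotropic Gaussian smoothing with periodic boundaries via FFT convolution.
gaussian_smooth3d <- function(x, sigma) {
  d <- dim(x)
  k1 <- function(n) {
    i <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    w <- exp(-i^2 / (2 * sigma^2))
    w / sum(w)
  }
  kern <- outer(outer(k1(d[1]), k1(d[2])), k1(d[3]))
  dim(kern) <- d
  Re(fft(fft(x) * fft(kern), inverse = TRUE)) / prod(d)
}

#' Generate a blocky atlas tiling a voxel grid
#'
#' Partitions the grid into `n_regions` contiguous axis-aligned boxes by
#' recursive bisection (always splitting the currently largest box along its
#' longest axis), so that every region is nonempty and the regions tile the
#' whole volume.
#'
#' @param shape Integer triple of grid dimensions.
#' @param n_regions Number of regions, between 1 and `prod(shape)`.
#' @param seed Accepted for interface symmetry; the construction is
#'   deterministic.
#' @return A [gm_atlas()] with labels `1..n_regions`.
#' @export
generate_atlas <- function(shape, n_regions = 114L, seed = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) {
    stop("`shape` must be three positive integers", call. = FALSE)
  }
  n_regions <- as.integer(n_regions)
  if (n_regions < 1L || n_regions > prod(shape)) {
    stop("`n_regions` must be between 1 and the voxel count", call. = FALSE)
  }
  # boxes as rows: x0, x1, y0, y1, z0, z1 (inclusive, 1-based)
  boxes <- list(c(1L, shape[1], 1L, shape[2], 1L, shape[3]))
  box_n <- function(b) (b[2] - b[1] + 1L) * (b[4] - b[3] + 1L) * (b[6] - b[5] + 1L)
  while (length(boxes) < n_regions) {
    sizes <- vapply(boxes, box_n, integer(1))
    # split the largest box that can still be split
    ord <- order(sizes, decreasing = TRUE)
    split_done <- FALSE
    for (j in ord) {
      b <- boxes[[j]]
      lens <- c(b[2] - b[1], b[4] - b[3], b[6] - b[5]) + 1L
      if (all(lens == 1L)) next
      ax <- which.max(lens)
      lo <- b[2 * ax - 1]; hi <- b[2 * ax]
      mid <- lo + (hi - lo) %/% 2L
      b1 <- b; b2 <- b
      b1[2 * ax] <- mid
      b2[2 * ax - 1] <- mid + 1L
      boxes[[j]] <- b1
      boxes[[length(boxes) + 1L]] <- b2
      split_done <- TRUE
      break
    }
    if (!split_done) stop("cannot split further", call. = FALSE)  # unreachable given pre
  }
  labels <- array(0L, dim = shape)
  for (i in seq_along(boxes)) {
    b <- boxes[[i]]
    labels[b[1]:b[2], b[3]:b[4], b[5]:b[6]] <- i
  }
  gm_atlas(labels)
}

#' Effect specification for the cohort generator
#'
#' Collects the injected group effects, noise levels and coupling strengths
#' that [generate_cohort()] realizes. Defaults describe a 2x2 ApoE4-carrier
#' by MCI-progression design with converter-dominated atrophy, a
#' carrier-linked shift in the spatial covariance of the density field, and
#' CSF/cognitive phenotypes in their assay ranges.
#'
#' @param base_smoothness Mean Gaussian-field smoothness (voxels) across
#'   subjects; sets the spatial covariance scale of the density field.
#' @param smoothness_sd Between-subject SD of smoothness (voxels).
#' @param covariance_effect Additive smoothness shift for ApoE4 carriers
#'   (voxels); a nonzero value injects a carrier-vs-noncarrier difference in
#'   regional density covariance and hence in network topology.
#' @param atrophy_rate Named vector `c(nonconverter=, converter=)`: fractional
#'   gray-matter density loss per year.
#' @param apoe4_atrophy_mult Named vector `c(noncarrier=, carrier=)`:
#'   multiplier on the atrophy rate for carriers.
#' @param affected_region_frac Fraction of atlas regions carrying the full
#'   atrophy rate; the remaining regions atrophy at half rate.
#' @param retest_noise_frac SD of fresh visit-2 noise, as a fraction of the
#'   visit-1 field SD.
#' @param phenotype_coupling_r Correlation between each phenotype and the
#'   subject's latent network driver (the standardized smoothness deviation).
#' @param phenotype_means,phenotype_sds Named lists of baseline phenotype
#'   means/SDs; CSF means may be length-2 `c(noncarrier, carrier)`.
#' @param cognitive_roc Named list of per-year change for `mmse` and
#'   `adni_mem`, each length-2 `c(nonconverter, converter)`.
#' @param zero If `TRUE`, all group differences and couplings are set to
#'   zero (noise levels kept), giving a null cohort.
#' @param seed Default seed used by [generate_cohort()] when none is given.
#' @return A list of class `effect_spec`. A spec saved as YAML or JSON can
#'   be rebuilt with `do.call(effect_spec, yaml::read_yaml(path))`.
#' @export
effect_spec <- function(base_smoothness = 2,
                        smoothness_sd = 0.2,
                        covariance_effect = 0.5,
                        atrophy_rate = c(nonconverter = 0.005, converter = 0.015),
                        apoe4_atrophy_mult = c(noncarrier = 1, carrier = 1.3),
                        affected_region_frac = 0.5,
                        retest_noise_frac = 0.02,
                        phenotype_coupling_r = 0.4,
                        phenotype_means = list(
                          mmse = 27.4, adni_mem = 0.3,
                          abeta42 = c(noncarrier = 950, carrier = 720),
                          ttau = c(noncarrier = 280, carrier = 360),
                          ptau = c(noncarrier = 28, carrier = 40)),
                        phenotype_sds = list(
                          mmse = 1.7, adni_mem = 0.6,
                          abeta42 = 220, ttau = 120, ptau = 13),
                        cognitive_roc = list(
                          mmse = c(nonconverter = -0.1, converter = -2.5),
                          adni_mem = c(nonconverter = -0.05, converter = -0.45)),
                        zero = FALSE,
                        seed = NULL) {
  spec <- list(
    base_smoothness = base_smoothness, smoothness_sd = smoothness_sd,
    covariance_effect = covariance_effect, atrophy_rate = atrophy_rate,
    apoe4_atrophy_mult = apoe4_atrophy_mult,
    affected_region_frac = affected_region_frac,
    retest_noise_frac = retest_noise_frac,
    phenotype_coupling_r = phenotype_coupling_r,
    phenotype_means = phenotype_means, phenotype_sds = phenotype_sds,
    cognitive_roc = cognitive_roc, seed = seed
  )
  if (zero) {
    spec$covariance_effect <- 0
    spec$atrophy_rate <- c(nonconverter = 0.005, converter = 0.005)
    spec$apoe4_atrophy_mult <- c(noncarrier = 1, carrier = 1)
    spec$phenotype_coupling_r <- 0
    m <- spec$phenotype_means
    for (p in c("abeta42", "ttau", "ptau")) m[[p]] <- mean(m[[p]])
    spec$phenotype_means <- m
    spec$cognitive_roc <- lapply(spec$cognitive_roc,
                                 function(v) c(nonconverter = mean(v), converter = mean(v)))
  }
  if (spec$smoothness_sd < 0 || spec$retest_noise_frac < 0) {
    stop("noise SDs must be >= 0", call. = FALSE)
  }
  if (spec$base_smoothness < 0) stop("smoothness must be >= 0", call. = FALSE)
  class(spec) <- "effect_spec"
  spec
}

# assay bounds used to truncate CSF phenotypes (pg/ml)
csf_bounds <- list(abeta42 = c(200, 1700), ttau = c(80, 1300), ptau = c(8, 120))

#' Generate a two-visit 2x2 cohort with volumes
#'
#' Builds `4 * n_per_cell` subjects crossing ApoE4 carriage with MCI
#' progression. Each subject gets a visit-1 density volume (smooth Gaussian
#' field; smoothness varies between subjects and carries the injected
#' covariance effect) and a visit-2 volume derived from visit 1 by per-cell
#' regional atrophy factors over the inter-visit interval plus fresh retest
#' noise, so the ground-truth rate of change is known exactly. Phenotypes are
#' drawn within their assay ranges and linearly coupled to the subject's
#' latent network driver.
#'
#' @param n_per_cell Subjects per design cell (>= 2).
#' @param spec An [effect_spec()].
#' @param shape Volume grid dimensions.
#' @param seed Integer seed (defaults to `spec$seed`).
#' @param atlas Optional [gm_atlas()]; defaults to `generate_atlas(shape)`.
#' @param volumes If `FALSE`, skip volume synthesis and return only the
#'   cohort table (for statistics-only simulations).
#' @return A list with `cohort` (data frame, one row per subject), `volumes`
#'   (per subject, a list with elements `v1` and `v2`, or `NULL`), `atlas`,
#'   and `truth` (the per-cell atrophy rates and regional weights realized).
#' @export
generate_cohort <- function(n_per_cell, spec = effect_spec(), shape = c(30, 30, 30),
                            seed = NULL, atlas = NULL, volumes = TRUE) {
  stopifnot(inherits(spec, "effect_spec"))
  n_per_cell <- as.integer(n_per_cell)
  if (n_per_cell < 2L) stop("`n_per_cell` must be >= 2", call. = FALSE)
  if (is.null(seed)) seed <- spec$seed
  shape <- as.integer(shape)
  if (is.null(atlas)) atlas <- generate_atlas(shape)
  if (!identical(dim(atlas$labels), shape)) {
    stop("atlas shape does not match `shape`", call. = FALSE)
  }

  cells <- expand.grid(apoe4 = c("carrier", "noncarrier"),
                       progression = c("converter", "nonconverter"),
                       stringsAsFactors = FALSE)
  n <- 4L * n_per_cell
  apoe4 <- rep(cells$apoe4, each = n_per_cell)
  progression <- rep(cells$progression, each = n_per_cell)

  region_ids <- sort(unique(as.integer(atlas$labels)))
  region_ids <- region_ids[region_ids > 0L]
  n_affected <- max(1L, ceiling(spec$affected_region_frac * length(region_ids)))
  affected <- region_ids[seq_len(n_affected)]
  region_weight <- setNames(ifelse(region_ids %in% affected, 1, 0.5),
                            region_ids)

  cohort <- with_seed(seed, {
    delta_t <- pmax(0.5, rnorm(n, 2, 0.25))
    smooth_dev <- rnorm(n)
    smoothness <- pmax(0.5, spec$base_smoothness +
                         spec$smoothness_sd * smooth_dev +
                         ifelse(apoe4 == "carrier", spec$covariance_effect, 0))
    driver <- smooth_dev  # latent network driver phenotypes couple to
    r <- spec$phenotype_coupling_r
    couple <- function(mu, s) mu + s * (r * driver + sqrt(1 - r^2) * rnorm(n))
    group_mean <- function(m) {
      if (length(m) == 2L) ifelse(apoe4 == "carrier", m[["carrier"]], m[["noncarrier"]])
      else rep(m, n)
    }
    pm <- spec$phenotype_means; ps <- spec$phenotype_sds
    clip <- function(x, b) pmin(b[2], pmax(b[1], x))
    roc_of <- function(v) ifelse(progression == "converter",
                                 v[["converter"]], v[["nonconverter"]])
    mmse <- pmin(30, couple(group_mean(pm$mmse), ps$mmse))
    adni_mem <- couple(group_mean(pm$adni_mem), ps$adni_mem)
    data.frame(
      subject_id = sprintf("sub-%03d", seq_len(n)),
      apoe4 = apoe4, progression = progression,
      age = rnorm(n, 75.5, 7.5),
      sex = sample(c("male", "female"), n, replace = TRUE, prob = c(0.72, 0.28)),
      education = pmax(8, rnorm(n, 16, 2.7)),
      field_strength = sample(c(1.5, 3), n, replace = TRUE),
      handedness = sample(c("right", "left"), n, replace = TRUE, prob = c(0.9, 0.1)),
      tiv = rnorm(n, 1590, 185),
      gm_volume = rnorm(n, 590, 75),
      t1 = 0, t2 = delta_t, delta_t = delta_t,
      smoothness = smoothness, driver = driver,
      mmse = mmse,
      adni_mem = adni_mem,
      abeta42 = clip(couple(group_mean(pm$abeta42), ps$abeta42), csf_bounds$abeta42),
      ttau = clip(couple(group_mean(pm$ttau), ps$ttau), csf_bounds$ttau),
      ptau = clip(couple(group_mean(pm$ptau), ps$ptau), csf_bounds$ptau),
      mmse_v2 = pmin(30, mmse + roc_of(spec$cognitive_roc$mmse) * delta_t +
                       rnorm(n, 0, 0.5)),
      adni_mem_v2 = adni_mem + roc_of(spec$cognitive_roc$adni_mem) * delta_t +
        rnorm(n, 0, 0.1),
      stringsAsFactors = FALSE
    )
  })

  rate <- spec$atrophy_rate[ifelse(progression == "converter",
                                   "converter", "nonconverter")] *
    spec$apoe4_atrophy_mult[ifelse(apoe4 == "carrier", "carrier", "noncarrier")]
  cohort$atrophy_rate <- as.numeric(rate)

  vols <- NULL
  if (volumes) {
    vols <- lapply(seq_len(n), function(i) {
      s1 <- derive_seed(seed, 10000 + i)
      v1 <- generate_gm_volume(shape, smoothness = cohort$smoothness[i],
                               seed = s1, subject_id = cohort$subject_id[i],
                               visit = 1L)
      factors <- 1 - cohort$atrophy_rate[i] * region_weight * cohort$delta_t[i]
      f2 <- v1$data
      for (lab in names(factors)) {
        idx <- atlas$labels == as.integer(lab)
        f2[idx] <- f2[idx] * factors[[lab]]
      }
      # fresh retest noise within the tissue mask only: background voxels
      # stay exactly zero so excluded cubes agree across visits
      mask <- v1$data > 0
      noise_sd <- spec$retest_noise_frac * sd(v1$data[mask])
      f2[mask] <- with_seed(derive_seed(seed, 20000 + i),
                            f2[mask] + rnorm(sum(mask), 0, noise_sd))
      f2 <- pmin(1, pmax(0, f2))
      v2 <- gm_volume(array(f2, dim = shape),
                      subject_id = cohort$subject_id[i], visit = 2L)
      list(v1 = v1, v2 = v2)
    })
    names(vols) <- cohort$subject_id
  }

  list(cohort = cohort, volumes = vols, atlas = atlas,
       truth = list(region_weight = region_weight,
                    atrophy_rate = setNames(cohort$atrophy_rate, cohort$subject_id)))
}
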