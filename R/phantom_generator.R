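#' Specify a synthetic liver/lesion phantom
#'
#' The phantom generator is the package's stand-in for clinical data: an
#' ellipsoidal liver containing spherical or (axis-aligned) ellipsoidal
#' lesions of known position and size, rasterized on an anisotropic grid
#' emulating abdominal DWI geometry (default 1.5 mm in plane, 4 mm slices).
#' Because lesions are analytic solids, their true diameters, volumes and
#' any longitudinal change are known exactly, which is what makes parameter
#' recovery testable.
#'
#' @param grid_shape Integer length-3 array shape (default `c(96, 96, 24)`).
#' @param spacing Voxel spacing in mm (default `c(1.5, 1.5, 4)`), slice axis
#'   inferred as the largest-spacing axis.
#' @param liver List with `center_mm` and `semiaxes_mm` (length-3 each) for
#'   the liver ellipsoid; default fills most of the grid.
#' @param lesions List of lesions, each a list with `center_mm`,
#'   `diameter_mm` and optional `shape` (`"sphere"`, default, or
#'   `"ellipsoid"` with `semiaxes_mm`).
#' @param seed Integer recorded in the spec (generation itself is
#'   deterministic; the seed matters for [random_longitudinal_spec()]).
#' @return A validated `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 24),
                         spacing = c(1.5, 1.5, 4),
                         liver = NULL,
                         lesions = list(),
                         seed = 0L) {
  grid_shape <- as.integer(grid_shape)
  spacing <- as.numeric(spacing)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 4L),
            length(spacing) == 3L, all(spacing > 0))
  extent <- (grid_shape - 1) * spacing
  if (is.null(liver))
    liver <- list(center_mm = extent / 2, semiaxes_mm = extent * 0.42)
  stopifnot(length(liver$center_mm) == 3L, length(liver$semiaxes_mm) == 3L,
            all(liver$semiaxes_mm > 0))
  lesions <- lapply(lesions, normalize_lesion_spec)
  spec <- structure(
    list(grid_shape = grid_shape, spacing = spacing, liver = liver,
         lesions = lesions, seed = as.integer(seed)),
    class = "phantom_spec"
  )
  validate_phantom_spec(spec)
  spec
}

normalize_lesion_spec <- function(l) {
  stopifnot(length(l$center_mm) == 3L)
  if (is.null(l$shape)) l$shape <- "sphere"
  l$shape <- match.arg(l$shape, c("sphere", "ellipsoid"))
  if (l$shape == "sphere") {
    stopifnot(is.numeric(l$diameter_mm), l$diameter_mm > 0)
    l$semiaxes_mm <- rep(l$diameter_mm / 2, 3)
  } else {
    stopifnot(length(l$semiaxes_mm) == 3L, all(l$semiaxes_mm > 0))
    l$diameter_mm <- NULL  # derived below per slice axis
  }
  l
}

# True longest axial diameter of an axis-aligned ellipsoid lesion: the widest
# in-plane Feret of the central cross-section, i.e. twice the larger
# in-plane semi-axis.
lesion_true_diameter <- function(l, slice_axis) {
  inplane <- setdiff(1:3, slice_axis)
  2 * max(l$semiaxes_mm[inplane])
}

lesion_true_volume <- function(l) 4 / 3 * pi * prod(l$semiaxes_mm)

validate_phantom_spec <- function(spec) {
  L <- spec$liver
  gap_mm <- 2 * max(spec$spacing)   # >= 2 voxels between lesion surfaces
  for (i in seq_along(spec$lesions)) {
    l <- spec$lesions[[i]]
    r <- max(l$semiaxes_mm)
    shrunk <- L$semiaxes_mm - r
    if (any(shrunk <= 0) ||
        sum(((l$center_mm - L$center_mm) / shrunk)^2) > 1)
      stop(sprintf("lesion %d does not fit inside the liver ellipsoid", i))
    if (i > 1L) for (j in seq_len(i - 1L)) {
      lj <- spec$lesions[[j]]
      sep <- sqrt(sum((l$center_mm - lj$center_mm)^2)) -
        max(l$semiaxes_mm) - max(lj$semiaxes_mm)
      if (sep < gap_mm)
        stop(sprintf("lesions %d and %d are closer than the 2-voxel gap", j, i))
    }
  }
  invisible(spec)
}

#' Rasterize a phantom into liver and tumour masks
#'
#' A voxel is foreground iff its center lies inside the analytic solid
#' (voxel-center inclusion), the same convention every measurement in the
#' package uses, so the recorded analytic ground truth is directly
#' comparable to measured values.
#'
#' @param spec A [phantom_spec()].
#' @return List with `liver` and `tumor` ([label_volume]s) and `truth`:
#'   per-lesion analytic `diameter_mm` and `volume_mm3` plus the grid
#'   geometry.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape; sp <- spec$spacing
  ax <- lapply(1:3, function(a) (seq_len(d[a]) - 1) * sp[a])
  slice_axis <- which.max(sp)

  liver_vox <- ellipsoid_mask(ax, spec$liver$center_mm, spec$liver$semiaxes_mm)
  tumor_vox <- array(FALSE, dim = d)
  for (l in spec$lesions)
    tumor_vox <- tumor_vox | ellipsoid_mask(ax, l$center_mm, l$semiaxes_mm)

  truth <- list(
    n_lesions = length(spec$lesions),
    diameters_mm = vapply(spec$lesions, lesion_true_diameter, 0, slice_axis),
    volumes_mm3 = vapply(spec$lesions, lesion_true_volume, 0),
    spacing = sp, grid_shape = d, slice_axis = slice_axis)

  list(liver = label_volume(array(as.integer(liver_vox), dim = d), sp, slice_axis),
       tumor = label_volume(array(as.integer(tumor_vox), dim = d), sp, slice_axis),
       truth = truth)
}

# Membership test over the tensor grid, evaluated separably per axis.
ellipsoid_mask <- function(ax, center, semiaxes) {
  u1 <- ((ax[[1]] - center[1]) / semiaxes[1])^2
  u2 <- ((ax[[2]] - center[2]) / semiaxes[2])^2
  u3 <- ((ax[[3]] - center[3]) / semiaxes[3])^2
  outer(outer(u1, u2, `+`), u3, `+`) <= 1
}

#' Specify a longitudinal (baseline / follow-up) phantom case
#'
#' The follow-up is the baseline with each lesion rescaled about its center
#' by a per-lesion factor (0 removes it), optionally with lesions added.
#' The implied true RECIST category is computed at specification time by
#' running the response rules on the analytic diameters, and must match
#' `true_category` when one is requested; near-threshold geometries (true
#' percent change within `margin_pct` of a decision threshold) are refused
#' so voxelization cannot flip the label.
#'
#' @param baseline A [phantom_spec()].
#' @param scale_factors Numeric vector, one per baseline lesion; diameter
#'   scale factor for the follow-up (0 = lesion disappeared).
#' @param lesions_added List of lesion specs present only at follow-up.
#' @param true_category Optional requested category (`"CR"`, `"PR"`, `"SD"`,
#'   `"PD"`); checked against the analytic truth.
#' @param cfg [recist_config()] under which the truth is evaluated.
#' @param margin_pct Refusal margin around the PR/PD thresholds (default 5
#'   percentage points).
#' @return A `longitudinal_spec` with the analytic `truth` (per-timepoint
#'   diameters, target sums, percent change, new-lesion flag, category).
#' @export
longitudinal_spec <- function(baseline, scale_factors, lesions_added = list(),
                              true_category = NULL, cfg = recist_config(),
                              margin_pct = 5) {
  stopifnot(inherits(baseline, "phantom_spec"),
            length(scale_factors) == length(baseline$lesions),
            all(scale_factors >= 0))
  slice_axis <- which.max(baseline$spacing)

  followup_lesions <- list()
  for (i in seq_along(baseline$lesions)) {
    if (scale_factors[i] <= 0) next
    l <- baseline$lesions[[i]]
    l$semiaxes_mm <- l$semiaxes_mm * scale_factors[i]
    if (!is.null(l$diameter_mm)) l$diameter_mm <- l$diameter_mm * scale_factors[i]
    followup_lesions <- c(followup_lesions, list(l))
  }
  lesions_added <- lapply(lesions_added, normalize_lesion_spec)
  followup_lesions <- c(followup_lesions, lesions_added)

  followup <- phantom_spec(baseline$grid_shape, baseline$spacing,
                           baseline$liver, followup_lesions,
                           seed = baseline$seed)

  truth <- analytic_truth(baseline, followup, slice_axis, cfg)
  near <- !truth$new_lesions && truth$followup_sum_mm > 0 &&
    min(abs(truth$percent_change - c(cfg$pr_threshold_pct,
                                     cfg$pd_threshold_pct))) < margin_pct
  if (!is.null(true_category)) {
    if (near)
      stop(sprintf(
        "near-threshold case refused: true change %+.1f%% is within %g points of a threshold",
        truth$percent_change, margin_pct))
    if (truth$category != true_category)
      stop(sprintf("requested true_category %s but analytic truth is %s",
                   true_category, truth$category))
  }

  structure(list(baseline = baseline, followup = followup, truth = truth),
            class = "longitudinal_spec")
}

# Run the RECIST rules on analytic diameters (the generator and the engine
# must agree on the rules; the geometry is the only thing left to measure).
analytic_truth <- function(baseline, followup, slice_axis, cfg) {
  dia_b <- vapply(baseline$lesions, lesion_true_diameter, 0, slice_axis)
  dia_f <- vapply(followup$lesions, lesion_true_diameter, 0, slice_axis)
  tgt <- function(d) {
    d <- d[d >= cfg$min_measurable_diameter_mm]
    d <- sort(d, decreasing = TRUE)
    utils::head(d, cfg$max_targets)
  }
  tb <- tgt(dia_b); tf <- tgt(dia_f)
  if (sum(tb) <= 0) stop("baseline spec has no measurable lesion")
  newles <- detect_new_lesions(length(tb), length(tf))
  change <- percent_change(sum(tb), sum(tf))
  category <- if (newles) "PD"
  else if (sum(tf) == 0) "CR"
  else if (change >= cfg$pd_threshold_pct &&
           (sum(tf) - sum(tb)) >= cfg$pd_min_absolute_increase_mm) "PD"
  else if (change <= cfg$pr_threshold_pct) "PR"
  else "SD"
  list(baseline_diameters_mm = dia_b, followup_diameters_mm = dia_f,
       baseline_sum_mm = sum(tb), followup_sum_mm = sum(tf),
       n_baseline_targets = length(tb), n_followup_targets = length(tf),
       percent_change = change, new_lesions = newles, category = category)
}

#' Rasterize a longitudinal case
#'
#' @param spec A [longitudinal_spec()].
#' @return List with `baseline` and `followup` (each holding `liver` and
#'   `tumor` [label_volume]s) and the analytic `truth`.
#' @export
make_longitudinal_case <- function(spec) {
  stopifnot(inherits(spec, "longitudinal_spec"))
  b <- make_phantom(spec$baseline)
  f <- make_phantom(spec$followup)
  list(baseline = list(liver = b$liver, tumor = b$tumor),
       followup = list(liver = f$liver, tumor = f$tumor),
       truth = spec$truth)
}

#' Draw a random longitudinal case of a requested category
#'
#' Samples a baseline phantom of well-separated spherical lesions and a
#' follow-up change consistent with the requested category, comfortably away
#' from the decision thresholds and from the 10 mm measurability boundary
#' (so voxelization cannot flip either the category or a lesion's
#' measurability): complete disappearance for CR, uniform shrinkage to
#' 50-62% for PR (baseline lesions 24-30 mm, so every scaled lesion stays
#' at or above 12 mm), 90-108% for SD, and for PD either growth to at least
#' 135% with a guaranteed 7.5 mm absolute increase of the diameter sum, or
#' an unchanged baseline of at most four lesions plus one new 14-20 mm
#' lesion (the count-based rule). Fully seeded and reproducible.
#'
#' @param true_category One of `"CR"`, `"PR"`, `"SD"`, `"PD"`.
#' @param seed Integer seed.
#' @param cfg [recist_config()] the truth is evaluated under.
#' @param grid_shape,spacing Grid geometry (defaults as [phantom_spec()]).
#' @return A `longitudinal_spec`.
#' @export
random_longitudinal_spec <- function(true_category = c("CR", "PR", "SD", "PD"),
                                     seed = 1L, cfg = recist_config(),
                                     grid_shape = c(96, 96, 24),
                                     spacing = c(1.5, 1.5, 4)) {
  true_category <- match.arg(true_category)
  with_local_seed(seed, {
    pd_by_new <- true_category == "PD" && stats::runif(1) < 0.5
    base <- switch(true_category,
      PR = random_phantom_spec(grid_shape, spacing, seed,
                               n_range = c(1L, 3L),
                               diameter_range_mm = c(24, 30)),
      PD = random_phantom_spec(grid_shape, spacing, seed,
                               n_range = c(1L, if (pd_by_new) 4L else 5L),
                               diameter_range_mm = c(14, 30)),
      random_phantom_spec(grid_shape, spacing, seed))
    n <- length(base$lesions)
    slice_axis <- which.max(spacing)
    sum_b <- sum(vapply(base$lesions, lesion_true_diameter, 0, slice_axis))
    added <- list()
    if (true_category == "PD" && pd_by_new) {
      new_lesion <- tryCatch(
        place_random_lesion(base, stats::runif(1, 14, 20), headroom = 1.05),
        error = function(e) NULL)
      if (is.null(new_lesion)) pd_by_new <- FALSE  # crowded liver: grow instead
      else added <- list(new_lesion)
    }
    factors <- switch(true_category,
      CR = rep(0, n),
      PR = rep(stats::runif(1, 0.50, 0.62), n),
      SD = rep(stats::runif(1, 0.90, 1.08), n),
      PD = if (pd_by_new) rep(1, n)
           else rep(stats::runif(1, max(1.35, 1 + 7.5 / sum_b), 1.60), n))
    longitudinal_spec(base, factors, added, true_category, cfg)
  })
}

# Baseline with 1-5 well-separated spherical lesions, all measurable.
random_phantom_spec <- function(grid_shape, spacing, seed,
                                n_range = c(1L, 5L),
                                diameter_range_mm = c(14, 34)) {
  extent <- (grid_shape - 1) * spacing
  liver <- list(center_mm = extent / 2, semiaxes_mm = extent * 0.42)
  n <- sample(seq(n_range[1], n_range[2]), 1L)
  lesions <- list()
  spec <- phantom_spec(grid_shape, spacing, liver, lesions, seed)
  for (i in seq_len(n)) {
    dia <- stats::runif(1, diameter_range_mm[1], diameter_range_mm[2])
    l <- tryCatch(place_random_lesion(spec, dia), error = function(e) NULL)
    if (is.null(l)) next
    lesions <- c(lesions, list(l))
    spec <- phantom_spec(grid_shape, spacing, liver, lesions, seed)
  }
  if (length(spec$lesions) == 0L) {
    # guaranteed central lesion as a fallback
    spec <- phantom_spec(grid_shape, spacing, liver,
                         list(list(center_mm = liver$center_mm,
                                   diameter_mm = mean(diameter_range_mm))),
                         seed)
  }
  spec
}

# Rejection-sample a sphere center such that the lesion fits in the liver
# with growth headroom (factor 1.6) and keeps the 2-voxel gap to existing
# lesions.
place_random_lesion <- function(spec, diameter_mm, max_tries = 200L,
                                headroom = 1.6) {
  L <- spec$liver
  r <- diameter_mm / 2 * headroom
  gap_mm <- 2 * max(spec$spacing)
  for (t in seq_len(max_tries)) {
    u <- stats::runif(3, -1, 1)
    if (sum(u^2) > 1) next
    center <- L$center_mm + u * pmax(L$semiaxes_mm - r, 0)
    shrunk <- L$semiaxes_mm - r
    if (any(shrunk <= 0) || sum(((center - L$center_mm) / shrunk)^2) > 1) next
    clear <- TRUE
    for (lj in spec$lesions) {
      sep <- sqrt(sum((center - lj$center_mm)^2)) -
        r - max(lj$semiaxes_mm) * headroom
      if (sep < gap_mm) { clear <- FALSE; break }
    }
    if (clear)
      return(list(center_mm = center, diameter_mm = diameter_mm,
                  shape = "sphere"))
  }
  stop("could not place lesion: liver too crowded")
}

#' Split a cohort into train / validation / test partitions
#'
#' Seeded shuffle followed by a largest-remainder apportionment of the ratio
#' (the first component absorbs remainder surplus first), so partitions are
#' disjoint, exhaustive, and reproducible. 86 ids at ratio 6:2:2 give
#' 52 / 17 / 17.
#'
#' @param case_ids Vector of at least 3 unique ids.
#' @param ratio Positive length-3 proportions (default `c(6, 2, 2)`).
#' @param seed Integer seed for the shuffle.
#' @return List with `train`, `validation`, `test` id vectors.
#' @export
split_cohort <- function(case_ids, ratio = c(6, 2, 2), seed = 1L) {
  if (length(case_ids) == 0L) stop("empty id list")
  stopifnot(length(case_ids) >= 3L, length(ratio) == 3L, all(ratio > 0))
  n <- length(case_ids)
  prop <- ratio / sum(ratio)
  base <- floor(prop * n)
  rem <- prop * n - base
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(-rem, seq_along(rem))  # largest remainder, train-first ties
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1L
  }
  shuffled <- with_local_seed(seed, sample(case_ids))
  list(train = shuffled[seq_len(base[1])],
       validation = shuffled[base[1] + seq_len(base[2])],
       test = shuffled[base[1] + base[2] + seq_len(base[3])])
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
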