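# Independent brute-force oracles used to validate the production
# implementations. These are deliberately the most literal possible
# renderings of each definition, sharing no code with the package.

# Flood-fill connected-component labelling over a binary 3D array.
oracle_label_components <- function(fg, connectivity = 26) {
  d <- dim(fg)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  deg <- rowSums(abs(offs))
  offs <- offs[deg > 0 & switch(as.character(connectivity),
                                "6" = deg == 1, "18" = deg <= 2,
                                "26" = rep(TRUE, length(deg))), , drop = FALSE]
  lab <- array(0L, dim = d)
  cur <- 0L
  for (v in which(fg > 0)) {
    if (lab[v] != 0L) next
    cur <- cur + 1L
    queue <- v
    lab[v] <- cur
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      pc <- arrayInd(p, d)
      for (r in seq_len(nrow(offs))) {
        q <- pc + offs[r, ]
        if (any(q < 1) || any(q > d)) next
        ql <- q[1] + (q[2] - 1) * d[1] + (q[3] - 1) * d[1] * d[2]
        if (fg[ql] > 0 && lab[ql] == 0L) {
          lab[ql] <- cur
          queue <- c(queue, ql)
        }
      }
    }
  }
  lab
}

# All-pairs in-plane Feret diameter, one slice at a time.
oracle_diameter <- function(vox, spacing, slice_axis) {
  inplane <- setdiff(1:3, slice_axis)
  best <- 0
  for (s in unique(vox[, slice_axis])) {
    pts <- vox[vox[, slice_axis] == s, inplane, drop = FALSE]
    if (nrow(pts) < 2) next
    for (i in seq_len(nrow(pts) - 1)) for (j in (i + 1):nrow(pts)) {
      dx <- (pts[i, 1] - pts[j, 1]) * spacing[inplane[1]]
      dy <- (pts[i, 2] - pts[j, 2]) * spacing[inplane[2]]
      best <- max(best, sqrt(dx^2 + dy^2))
    }
  }
  best
}

# Symmetric set Hausdorff distance by exhaustive nearest-point search over
# physical coordinates (rows of a and b, in mm).
oracle_hausdorff <- function(a, b) {
  directed <- function(from, to) {
    worst <- 0
    for (i in seq_len(nrow(from))) {
      dmin <- min(sqrt(colSums((t(to) - from[i, ])^2)))
      worst <- max(worst, dmin)
    }
    worst
  }
  max(directed(a, b), directed(b, a))
}

# Mann-Whitney AUC by exhaustive concordant/discordant pair counting.
oracle_auc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# Cohen's kappa straight from the observed/expected agreement definition.
oracle_kappa <- function(reference, rater) {
  cats <- c("CR", "PR", "SD", "PD")
  po <- mean(reference == rater)
  pe <- sum(vapply(cats, function(k)
    mean(reference == k) * mean(rater == k), numeric(1)))
  (po - pe) / (1 - pe)
}

# Random binary volume with roughly `p` foreground fraction.
random_mask_volume <- function(d, p = 0.05, spacing = c(1.5, 1.5, 4)) {
  label_volume(array(as.integer(stats::runif(prod(d)) < p), dim = d), spacing)
}

# Minimal lesion_set with prescribed diameters/volumes, for rule-engine
# tests that do not need voxel data.
fake_lesion_set <- function(diameters_mm, volumes_mm3 = diameters_mm^3) {
  lesions <- lapply(seq_along(diameters_mm), function(i)
    structure(list(lesion_id = i,
                   voxel_indices = matrix(c(i, 1, 1), 1),
                   volume_mm3 = volumes_mm3[i],
                   longest_axial_diameter_mm = diameters_mm[i],
                   diameter_slice = 1L,
                   centroid_mm = c(0, 0, 0)),
              class = "lesion"))
  structure(list(lesions = lesions,
                 geometry = list(shape = c(1L, 1L, 1L), spacing = c(1, 1, 1),
                                 slice_axis = 3L)),
            class = "lesion_set")
}

# Two-level intensity phantom (bright lesions in a dim liver) for network
# smoke tests.
contrast_phantom_case <- function(seed, noise_sd = 0.05) {
  sp <- random_longitudinal_spec("SD", seed = seed)$baseline
  ph <- make_phantom(sp)
  d <- dim(ph$liver$voxels)
  vol <- 0.2 * (ph$liver$voxels > 0) + 1.0 * (ph$tumor$voxels > 0) +
    array(stats::rnorm(prod(d), sd = noise_sd), d)
  list(volume = vol, tumor = ph$tumor$voxels, liver = ph$liver$voxels,
       spacing = ph$liver$spacing)
}
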