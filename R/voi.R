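#' Hotspot-confirmation parameters
#'
#' Controls the consecutive-slice confirmation that guards hotspot VOIs
#' against single-slice coincidences: a candidate maximum is only accepted
#' when each of `k` consecutive slices on at least one side shows similarly
#' increased uptake (in-muscle maximum within in-plane radius `r_mm` of the
#' candidate at least `tau` times the candidate SUV).
#'
#' @param k number of consecutive confirming slices per side (>= 1).
#' @param tau similarity fraction in (0, 1].
#' @param r_mm in-plane search radius in mm.
#' @param axis confirmation axis (3 = axial).
#' @return a `hotspot_params` list.
#' @export
hotspot_params <- function(k = 2L, tau = 0.8, r_mm = 15, axis = 3L) {
  stopifnot(k >= 1L, tau > 0, tau <= 1, r_mm > 0, axis %in% 1:3)
  structure(list(k = as.integer(k), tau = tau, r_mm = r_mm, axis = as.integer(axis)),
            class = "hotspot_params")
}

# order candidate centers: distance to desired, then distance to centroid,
# then distance from the midsagittal plane (so exact ties resolve to mirror
# images on mirror-image anatomy), then lexicographic; returns permutation
order_candidates <- function(xyz, desired, centroid, mid_x) {
  d1 <- (xyz[, 1] - desired[1])^2 + (xyz[, 2] - desired[2])^2 + (xyz[, 3] - desired[3])^2
  d2 <- (xyz[, 1] - centroid[1])^2 + (xyz[, 2] - centroid[2])^2 + (xyz[, 3] - centroid[3])^2
  order(round(d1, 9), round(d2, 9), round(abs(xyz[, 1] - mid_x), 9),
        xyz[, 2], xyz[, 3], xyz[, 1])
}

atlas_mid_x <- function(atlas) atlas$shape[1] * atlas$spacing / 2

voi_row <- function(muscle, side, method, center, diameter, adjusted, note = NA_character_) {
  tibble::tibble(
    muscle = muscle, side = side, method = method,
    x = center[1], y = center[2], z = center[3],
    diameter_mm = diameter, adjusted = adjusted, note = note
  )
}

#' Place a fixed anatomical VOI
#'
#' Realizes the fixed-position procedure: the target plane is orthogonal to
#' the bone axis at a fixed fraction of the proximal-to-distal distance (50%
#' for biceps, triceps, quadriceps and hamstrings; 10% from the proximal
#' humerus end for the deltoid) or passes through the lumbosacral L5-S1
#' landmark for the psoas. The VOI center starts at the centroid of the
#' muscle cross-section in that plane and is then moved the minimal
#' Euclidean distance (ties toward the centroid, then toward the
#' midsagittal plane so mirror-image muscles resolve to mirror-image
#' centers, then lexicographically) to a voxel center whose whole sphere
#' lies in-muscle and clear of vessels. Deterministic.
#'
#' @param atlas a [muscle_atlas()].
#' @param muscle,side compartment selector.
#' @param diameter sphere diameter in mm; defaults to
#'   [default_voi_diameter()] for the muscle.
#' @param axis_band feasible centers must project within `axis_band` of
#'   bone length from the target plane (default 10%).
#' @return one-row VOI tibble (`muscle`, `side`, `method`, center `x,y,z`
#'   in mm, `diameter_mm`, `adjusted`, `note`).
#' @export
place_fixed_voi <- function(atlas, muscle, side, diameter = NULL, axis_band = 0.1) {
  label <- atlas_label(atlas, muscle, side)
  diameter <- diameter %||% default_voi_diameter(muscle)
  lm <- atlas$landmarks[atlas$landmarks$label == label, ]
  prox <- c(lm$prox_x, lm$prox_y, lm$prox_z)
  dst <- c(lm$dist_x, lm$dist_y, lm$dist_z)
  u <- dst - prox
  L <- sqrt(sum(u^2))
  u <- u / L
  t_mm <- if (lm$voi_rule == "point") {
    sum((c(lm$point_x, lm$point_y, lm$point_z) - prox) * u)
  } else {
    lm$voi_fraction * L
  }

  mv <- muscle_voxels(atlas, label)
  proj <- (mv$xyz[, 1] - prox[1]) * u[1] + (mv$xyz[, 2] - prox[2]) * u[2] +
    (mv$xyz[, 3] - prox[3]) * u[3]
  half <- atlas$spacing / 2
  slab <- abs(proj - t_mm) <= half + 1e-9
  if (!any(slab)) slab <- abs(proj - t_mm) <= atlas$spacing + 1e-9
  if (!any(slab)) {
    abort(sprintf("No muscle cross-section at the target plane for '%s %s'.", muscle, side))
  }
  centroid <- colMeans(mv$xyz[slab, , drop = FALSE])

  feas <- feasible_centers(atlas, label, diameter)
  if (nrow(feas$xyz) == 0L) {
    abort(sprintf("VOI of %g mm cannot be placed inside muscle '%s %s'.",
                  diameter, muscle, side))
  }
  fproj <- (feas$xyz[, 1] - prox[1]) * u[1] + (feas$xyz[, 2] - prox[2]) * u[2] +
    (feas$xyz[, 3] - prox[3]) * u[3]
  band <- abs(fproj - t_mm) <= axis_band * L + 1e-9
  if (!any(band)) {
    abort(sprintf(
      "No feasible VOI center within %.0f%% of bone length of the target plane for '%s %s'.",
      100 * axis_band, muscle, side
    ))
  }
  xyz <- feas$xyz[band, , drop = FALSE]
  mid_x <- atlas_mid_x(atlas)
  ord <- order_candidates(xyz, centroid, centroid, mid_x)
  center <- xyz[ord[1L], ]
  # adjusted = feasibility pushed the center off the nearest in-muscle voxel
  nearest <- mv$xyz[order_candidates(mv$xyz, centroid, centroid, mid_x)[1L], ]
  moved <- sqrt(sum((center - nearest)^2)) > 1e-9
  voi_row(muscle, side, "fixed", center, diameter, adjusted = moved)
}

#' Confirm a hotspot candidate on consecutive slices
#'
#' Pure predicate behind [place_hotspot_voi()]: a candidate voxel at slice
#' `s` along the confirmation axis is confirmed when `k` nearby slices all
#' show similar increased uptake - every slice's in-muscle maximum SUV
#' within in-plane radius `r_mm` of the candidate must reach `tau` times
#' the candidate SUV. The `k` slices may be taken entirely before `s`,
#' entirely after `s`, or split as evenly as possible across both sides
#' (for the default `k = 2`: the slice before and the slice after). The
#' split window matters in thin muscles, where a lesion on the middle
#' slice is visible on both neighbours but no `k`-slice run on one side
#' stays inside it. A window that leaves the grid is not evaluable; if no
#' window is, the candidate is rejected.
#'
#' @param suv an `suv_volume`.
#' @param candidate integer(3) voxel index of the candidate.
#' @param atlas,muscle,side compartment whose voxels are searched.
#' @param params a [hotspot_params()].
#' @return `TRUE` or `FALSE`.
#' @export
confirm_candidate <- function(suv, candidate, atlas, muscle, side,
                              params = hotspot_params()) {
  label <- atlas_label(atlas, muscle, side)
  mv <- muscle_voxels(atlas, label)
  slices <- muscle_slices(atlas, label, params$axis)
  confirm_candidate_impl(suv, candidate, mv, slices, params, dim(suv$data))
}

confirm_candidate_impl <- function(suv, candidate, mv, slices, params, dims) {
  ax <- params$axis
  inplane <- setdiff(1:3, ax)
  s <- candidate[ax]
  cand_xyz <- vox_to_world(matrix(as.numeric(candidate), 1L), suv$spacing)
  cval <- suv$data[candidate[1L], candidate[2L], candidate[3L]]
  thr <- params$tau * cval
  k <- params$k
  windows <- list(
    s - seq_len(k),
    s + seq_len(k),
    c(s - seq_len(ceiling(k / 2)), s + seq_len(floor(k / 2)))
  )
  slice_ok <- function(si) {
    rows <- slices[[as.character(si)]]
    if (is.null(rows)) return(FALSE)
    xy <- mv$xyz[rows, inplane, drop = FALSE]
    d2 <- (xy[, 1] - cand_xyz[inplane[1]])^2 + (xy[, 2] - cand_xyz[inplane[2]])^2
    near <- d2 <= params$r_mm^2 + 1e-9
    if (!any(near)) return(FALSE)
    max(suv$data[mv$lin[rows][near]]) >= thr - 1e-12
  }
  for (ss in windows) {
    if (any(ss < 1L | ss > dims[ax])) next
    if (all(vapply(ss, slice_ok, TRUE))) return(TRUE)
  }
  FALSE
}

#' Place a hotspot VOI
#'
#' Realizes the hotspot procedure: in-muscle voxels are ranked by SUV
#' (descending) and the highest-ranked candidate that passes
#' consecutive-slice confirmation ([confirm_candidate()]) becomes the
#' target; the VOI center is then adjusted exactly as in
#' [place_fixed_voi()] - minimal Euclidean move to a voxel center with the
#' sphere fully in-muscle and vessel-free. When several confirmed
#' candidates tie for the highest SUV (exact ties arise in noiseless
#' fields with symmetric lesions), the tie is broken by the SUVpeak of the
#' resulting VOI and then lexicographically by voxel index, so the
#' procedure lands on the hottest measurable spot. If no candidate is
#' confirmed the global in-muscle maximum is used and a warning recorded,
#' so the procedure never fails on a non-empty muscle.
#'
#' @param suv an `suv_volume` on the atlas grid.
#' @param atlas a [muscle_atlas()].
#' @param muscle,side compartment selector.
#' @param diameter sphere diameter in mm; default [default_voi_diameter()].
#' @param params a [hotspot_params()].
#' @param max_candidates cap on ranked candidates examined before falling
#'   back to the global maximum.
#' @param d_peak SUVpeak kernel diameter (mm) used only to break exact
#'   candidate ties.
#' @return one-row VOI tibble as in [place_fixed_voi()].
#' @export
place_hotspot_voi <- function(suv, atlas, muscle, side, diameter = NULL,
                              params = hotspot_params(), max_candidates = 500L,
                              d_peak = 12) {
  stopifnot(inherits(suv, "suv_volume"))
  label <- atlas_label(atlas, muscle, side)
  diameter <- diameter %||% default_voi_diameter(muscle)
  mv <- muscle_voxels(atlas, label)
  slices <- muscle_slices(atlas, label, params$axis)
  dims <- dim(suv$data)

  vals <- suv$data[mv$lin]
  mid_x <- atlas_mid_x(atlas)
  ord <- order(-vals, round(abs(mv$xyz[, 1] - mid_x), 9),
               mv$xyz[, 2], mv$xyz[, 3], mv$xyz[, 1])
  targets <- NULL
  note <- NA_character_
  ranked <- utils::head(ord, max_candidates)
  best_val <- NA_real_
  tie_limit <- 16L # exact ties beyond this share the same geometry anyway
  for (pos in ranked) {
    if (!is.na(best_val) &&
        (vals[pos] < best_val * (1 - 1e-9) - 1e-12 || nrow(targets) >= tie_limit)) break
    cand <- mv$ijk[pos, ]
    if (confirm_candidate_impl(suv, cand, mv, slices, params, dims)) {
      if (is.na(best_val)) best_val <- vals[pos]
      targets <- rbind(targets, mv$xyz[pos, ])
    }
  }
  if (is.null(targets)) {
    targets <- mv$xyz[ord[1L], , drop = FALSE]
    note <- "unconfirmed: fell back to global in-muscle maximum"
    warn(sprintf("No confirmed hotspot in '%s %s'; using global maximum.", muscle, side))
  }

  feas <- feasible_centers(atlas, label, diameter)
  if (nrow(feas$xyz) == 0L) {
    abort(sprintf("VOI of %g mm cannot be placed inside muscle '%s %s'.",
                  diameter, muscle, side))
  }
  centroid <- colMeans(mv$xyz)
  best <- NULL
  best_peak <- -Inf
  for (t in seq_len(nrow(targets))) {
    target <- targets[t, ]
    ord2 <- order_candidates(feas$xyz, target, centroid, mid_x)
    center <- feas$xyz[ord2[1L], ]
    peak <- if (nrow(targets) > 1L) {
      suv_stats(suv, center, diameter, d_peak = d_peak)$suv_peak
    } else {
      0
    }
    if (is.null(best) || peak > best_peak + 1e-12) {
      best <- list(center = center, target = target)
      best_peak <- peak
    }
  }
  moved <- sqrt(sum((best$center - best$target)^2)) > 1e-9
  voi_row(muscle, side, "hotspot", best$center, diameter, adjusted = moved, note = note)
}
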