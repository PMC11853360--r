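#' Build a stylized whole-body muscle atlas
#'
#' Constructs the digital-phantom anatomy on a regular voxel grid: twelve
#' muscle compartments (deltoid, biceps brachii, triceps brachii, psoas,
#' quadriceps, hamstrings; left and right), a vessel mask (aorta plus a
#' femoral rod carved through each quadriceps), a mediastinal blood-pool
#' reference compartment, and the bone-axis landmarks that drive fixed VOI
#' placement (humerus for the arm muscles, femur for the thigh muscles, the
#' lumbosacral L5-S1 junction for the psoas).
#'
#' Geometry is deliberately stylized - cylinders on a torso-and-limbs layout,
#' mirror-symmetric about the midsagittal plane - and scales proportionally
#' with the physical grid extent. Voxel `i` has world coordinate
#' `(i - 0.5) * spacing` mm along each axis; the third axis is axial
#' (feet at z = 0).
#'
#' @param shape integer(3), grid size in voxels. Default `c(48, 32, 100)`.
#' @param spacing isotropic voxel size in mm. Default 4.
#' @return A `muscle_atlas`: list with `shape`, `spacing`, `labels`
#'   (integer array, 0 = background), `muscles` (tibble of compartments),
#'   `landmarks` (tibble of bone axes and VOI rules), `vessel` and
#'   `reference` (logical arrays), and an internal cache environment.
#' @examples
#' atlas <- muscle_atlas()
#' atlas$muscles
#' @export
muscle_atlas <- function(shape = c(48L, 32L, 100L), spacing = 4) {
  check_scalar_pos(spacing, "spacing")
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 2L))
  ext <- shape * spacing
  # reference design is 192 x 128 x 400 mm; scale positions with extent
  sx <- ext[1] / 192; sy <- ext[2] / 128; sz <- ext[3] / 400
  sr <- min(sx, sy)
  mid <- ext[1] / 2

  dims <- shape
  centers <- lapply(1:3, function(a) vox_to_world(seq_len(dims[a]), spacing))
  X <- array(centers[[1]], dims)
  Y <- array(rep(centers[[2]], each = dims[1]), dims)
  Z <- array(rep(centers[[3]], each = dims[1] * dims[2]), dims)

  cyl <- function(x0, y0, r, z0, z1) {
    (X - x0)^2 + (Y - y0)^2 <= r^2 + 1e-9 & Z >= z0 - 1e-9 & Z <= z1 + 1e-9
  }

  side_x <- function(off, side) if (side == "L") mid - off * sx else mid + off * sx

  spec <- tibble::tribble(
    ~muscle, ~dx, ~y0, ~r, ~z0, ~z1, ~bone, ~voi_rule, ~voi_fraction,
    "quadriceps", 40, 88, 22, 24, 176, "femur", "fraction", 0.5,
    "hamstrings", 40, 40, 22, 24, 176, "femur", "fraction", 0.5,
    "psoas", 16, 56, 12, 196, 260, "lumbar", "point", NA,
    "biceps", 74, 78, 10, 252, 320, "humerus", "fraction", 0.5,
    "triceps", 74, 50, 10, 252, 320, "humerus", "fraction", 0.5,
    "deltoid", 74, 64, 14, 324, 344, "humerus", "fraction", 0.1
  )

  bone_z <- list(femur = c(180, 20), humerus = c(344, 240), lumbar = c(260, 196))
  l5s1_z <- 208 * sz

  labels <- array(0L, dims)
  vessel <- array(FALSE, dims)
  muscles <- list()
  landmarks <- list()
  code <- 0L
  for (s in c("L", "R")) {
    for (row in seq_len(nrow(spec))) {
      code <- code + 1L
      m <- spec[row, ]
      x0 <- side_x(m$dx, s)
      mask <- cyl(x0, m$y0 * sy, m$r * sr, m$z0 * sz, m$z1 * sz)
      if (!any(mask)) {
        abort(sprintf("Grid too small to embed compartment '%s %s'.", m$muscle, s))
      }
      labels[mask] <- code
      bz <- bone_z[[m$bone]] * sz
      prox <- c(x0, m$y0 * sy, bz[1])
      dist <- c(x0, m$y0 * sy, bz[2])
      voi_point <- if (m$voi_rule == "point") c(x0, m$y0 * sy, l5s1_z) else c(NA_real_, NA_real_, NA_real_)
      muscles[[code]] <- tibble::tibble(
        muscle = m$muscle, side = s, label = code, n_vox = sum(mask)
      )
      landmarks[[code]] <- tibble::tibble(
        muscle = m$muscle, side = s, label = code, bone = m$bone,
        prox_x = prox[1], prox_y = prox[2], prox_z = prox[3],
        dist_x = dist[1], dist_y = dist[2], dist_z = dist[3],
        voi_rule = m$voi_rule, voi_fraction = m$voi_fraction,
        point_x = voi_point[1], point_y = voi_point[2], point_z = voi_point[3]
      )
    }
  }

  # femoral vessel rod carved through each quadriceps (medial offset), aorta
  # below the blood pool. Carving keeps labels and vessel disjoint.
  for (s in c("L", "R")) {
    x0 <- side_x(40, s) + (if (s == "L") 10 else -10) * sx
    rod <- cyl(x0, 88 * sy, 4.5 * sr, 24 * sz, 176 * sz)
    vessel <- vessel | rod
  }
  vessel <- vessel | cyl(mid, 64 * sy, 5 * sr, 240 * sz, 298 * sz)
  labels[vessel] <- 0L

  reference <- cyl(mid, 64 * sy, 10 * sr, 300 * sz, 356 * sz)
  labels[reference] <- 0L

  muscles <- dplyr::bind_rows(muscles)
  # recount after carving
  muscles$n_vox <- tabulate(labels[labels > 0L], nbins = code)[muscles$label]
  if (any(muscles$n_vox == 0L)) {
    abort("Grid too small to embed all muscle compartments.")
  }
  landmarks <- dplyr::bind_rows(landmarks)

  atlas <- structure(
    list(
      shape = dims, spacing = spacing, labels = labels,
      muscles = muscles, landmarks = landmarks,
      vessel = vessel, reference = reference,
      cache = new.env(parent = emptyenv())
    ),
    class = "muscle_atlas"
  )
  atlas
}

#' @export
print.muscle_atlas <- function(x, ...) {
  cat(sprintf(
    "<muscle_atlas> %d x %d x %d voxels @ %g mm, %d compartments\n",
    x$shape[1], x$shape[2], x$shape[3], x$spacing, nrow(x$muscles)
  ))
  invisible(x)
}

# --- internal cached lookups ---------------------------------------------

atlas_label <- function(atlas, muscle, side) {
  row <- atlas$muscles[atlas$muscles$muscle == muscle & atlas$muscles$side == side, ]
  if (nrow(row) != 1L) {
    abort(sprintf("Unknown muscle compartment '%s %s'.", muscle, side))
  }
  row$label
}

# voxel (i,j,k) matrix + world coords of one compartment, cached
muscle_voxels <- function(atlas, label) {
  key <- sprintf("vox_%d", label)
  if (!is.null(atlas$cache[[key]])) return(atlas$cache[[key]])
  lin <- which(atlas$labels == label)
  ijk <- lin_to_ijk(lin, atlas$shape)
  out <- list(lin = lin, ijk = ijk, xyz = vox_to_world(ijk, atlas$spacing))
  atlas$cache[[key]] <- out
  out
}

# Feasible VOI centers for a compartment and diameter: voxel centers whose
# whole sphere (voxel-center membership) lies inside the muscle mask and
# touches no vessel voxel. Cached per (label, diameter).
feasible_centers <- function(atlas, label, diameter_mm) {
  key <- sprintf("feas_%d_%g", label, diameter_mm)
  if (!is.null(atlas$cache[[key]])) return(atlas$cache[[key]])
  mv <- muscle_voxels(atlas, label)
  offs <- sphere_offsets(diameter_mm / 2, atlas$spacing)
  dims <- atlas$shape
  ok <- rep(TRUE, nrow(mv$ijk))
  inmask <- atlas$labels == label & !atlas$vessel
  for (o in seq_len(nrow(offs))) {
    nb <- cbind(
      mv$ijk[, 1L] + offs[o, 1L],
      mv$ijk[, 2L] + offs[o, 2L],
      mv$ijk[, 3L] + offs[o, 3L]
    )
    inside <- nb[, 1L] >= 1L & nb[, 1L] <= dims[1L] &
      nb[, 2L] >= 1L & nb[, 2L] <= dims[2L] &
      nb[, 3L] >= 1L & nb[, 3L] <= dims[3L]
    good <- inside
    if (any(inside)) {
      good[inside] <- inmask[ijk_to_lin(nb[inside, , drop = FALSE], dims)]
    }
    ok <- ok & good
    if (!any(ok)) break
  }
  out <- list(ijk = mv$ijk[ok, , drop = FALSE], xyz = mv$xyz[ok, , drop = FALSE])
  atlas$cache[[key]] <- out
  out
}

# per-axial-slice split of a compartment's voxels, cached
muscle_slices <- function(atlas, label, axis = 3L) {
  key <- sprintf("slice_%d_%d", label, axis)
  if (!is.null(atlas$cache[[key]])) return(atlas$cache[[key]])
  mv <- muscle_voxels(atlas, label)
  out <- split(seq_len(nrow(mv$ijk)), mv$ijk[, axis])
  atlas$cache[[key]] <- out
  out
}

# Default VOI diameter rule: large spheres for the big thigh muscles,
# small for deltoid/biceps/triceps/psoas.
#' Default VOI diameter for a muscle
#'
#' Thigh muscles (quadriceps, hamstrings) take the large sphere, all other
#' compartments the small one.
#'
#' @param muscle character vector of muscle names.
#' @param large,small sphere diameters in mm.
#' @return numeric vector of diameters.
#' @export
default_voi_diameter <- function(muscle, large = 20, small = 10) {
  ifelse(muscle %in% c("quadriceps", "hamstrings"), large, small)
}
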