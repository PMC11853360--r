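#' Convert an activity volume to body-weight SUV
#'
#' The standardised uptake value normalizes the tissue activity concentration
#' by the injected dose per body mass: `SUV = C * W / D`, with `C` in kBq/mL,
#' `W` in kg and `D` in MBq. Units cancel under the conventional 1 g/mL
#' tissue-density assumption, so SUV is dimensionless.
#'
#' @param activity 3D numeric array of activity concentration (kBq/mL), or a
#'   `pet_phantom` (in which case `dose_mbq`/`weight_kg`/`spacing` are taken
#'   from its subject metadata).
#' @param dose_mbq injected dose in MBq (> 0).
#' @param weight_kg body weight in kg (> 0).
#' @param spacing voxel size in mm (kept on the result for VOI extraction).
#' @return An `suv_volume`: list with `data` (3D array) and `spacing`.
#' @examples
#' v <- array(5, c(2, 2, 2))
#' s <- to_suv(v, dose_mbq = 350, weight_kg = 70, spacing = 4)
#' s$data[1, 1, 1] # 1.0
#' @export
to_suv <- function(activity, dose_mbq, weight_kg, spacing = NULL) {
  if (inherits(activity, "pet_phantom")) {
    ph <- activity
    return(to_suv(ph$activity, ph$subject$dose_mbq, ph$subject$weight_kg,
                  spacing = ph$atlas$spacing))
  }
  check_scalar_pos(dose_mbq, "dose_mbq")
  check_scalar_pos(weight_kg, "weight_kg")
  stopifnot(is.array(activity), length(dim(activity)) == 3L)
  structure(
    list(data = activity * weight_kg / dose_mbq, spacing = spacing %||% 1),
    class = "suv_volume"
  )
}

#' @export
print.suv_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<suv_volume> %d x %d x %d @ %g mm, range [%.3g, %.3g]\n",
              d[1], d[2], d[3], x$spacing, min(x$data), max(x$data)))
  invisible(x)
}

#' Voxels of a spherical VOI
#'
#' Returns every voxel whose center lies within `diameter/2` (inclusive) of a
#' world-coordinate center. Membership is by voxel center with no
#' partial-volume weighting, so results are bit-reproducible.
#'
#' @param center numeric(3), sphere center in world mm.
#' @param diameter sphere diameter in mm (> 0).
#' @param shape integer(3) grid size.
#' @param spacing voxel size in mm.
#' @return tibble with voxel indices `i, j, k`, linear index `lin`, and world
#'   coordinates `x, y, z`, in lexicographic (x, y, z) order.
#' @examples
#' sphere_voxels(c(6, 6, 6), diameter = 8, shape = c(3, 3, 3), spacing = 4)
#' @export
sphere_voxels <- function(center, diameter, shape, spacing) {
  check_scalar_pos(diameter, "diameter")
  stopifnot(length(center) == 3L)
  r <- diameter / 2
  shape <- as.integer(shape)
  lo <- pmax(1L, as.integer(ceiling((center - r) / spacing + 0.5 - 1e-9)))
  hi <- pmin(shape, as.integer(floor((center + r) / spacing + 0.5 + 1e-9)))
  if (any(lo > hi)) {
    abort("Sphere lies entirely outside the grid.")
  }
  g <- expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3])
  xyz <- vox_to_world(as.matrix(g), spacing)
  d2 <- (xyz[, 1] - center[1])^2 + (xyz[, 2] - center[2])^2 + (xyz[, 3] - center[3])^2
  keep <- d2 <= r^2 + 1e-9
  if (!any(keep)) {
    abort("Sphere lies entirely outside the grid (no voxel center inside).")
  }
  g <- g[keep, , drop = FALSE]
  xyz <- xyz[keep, , drop = FALSE]
  ord <- lex_order(xyz)
  tibble::tibble(
    i = g$i[ord], j = g$j[ord], k = g$k[ord],
    lin = ijk_to_lin(as.matrix(g)[ord, , drop = FALSE], shape),
    x = xyz[ord, 1], y = xyz[ord, 2], z = xyz[ord, 3]
  )
}

#' SUV statistics for a spherical VOI
#'
#' Extracts `suv_max`, `suv_mean` and `suv_peak` from a sphere. `suv_peak`
#' follows the peak-sphere convention: a small sphere of diameter `d_peak`
#' is positioned at every VOI voxel where it fits entirely inside the VOI,
#' and `suv_peak` is the largest mean it encloses. Because the peak sphere
#' stays inside the VOI, `suv_peak <= suv_max` holds for every input, no
#' position gains a spurious advantage from averaging a partial sphere, and
#' uptake just outside the VOI (for example an adjacent vessel the
#' placement rules deliberately avoided) never contaminates the peak. When
#' the peak sphere cannot fit anywhere inside the VOI (a `d_peak` at least
#' as large as the VOI diameter), the sphere is centered on the VOI center
#' and its mean over the VOI voxels it covers is reported. With `d_peak`
#' small enough that the sphere holds only one voxel, `suv_peak` equals
#' `suv_max`.
#'
#' @param suv an `suv_volume`.
#' @param center sphere center, world mm.
#' @param diameter VOI sphere diameter, mm.
#' @param d_peak neighbourhood sphere diameter for SUVpeak, mm. The 12 mm
#'   default approximates the common ~1 mL spherical peak kernel.
#' @return one-row tibble: `suv_max`, `suv_mean`, `suv_peak`, `n_vox`,
#'   `d_peak`.
#' @examples
#' v <- array(1, c(3, 3, 3)); v[2, 2, 2] <- 2
#' s <- structure(list(data = v, spacing = 4), class = "suv_volume")
#' suv_stats(s, center = c(6, 6, 6), diameter = 24, d_peak = 8)
#' @export
suv_stats <- function(suv, center, diameter, d_peak = 12) {
  stopifnot(inherits(suv, "suv_volume"))
  shape <- dim(suv$data)
  vox <- sphere_voxels(center, diameter, shape, suv$spacing)
  vals <- suv$data[vox$lin]
  peak <- suv_peak_at(suv, as.matrix(vox[, c("i", "j", "k")]), vox$lin, center, d_peak)
  tibble::tibble(
    suv_max = max(vals),
    suv_mean = mean(vals),
    suv_peak = peak,
    n_vox = nrow(vox),
    d_peak = d_peak
  )
}

# Peak-sphere value: max over VOI voxels whose whole d_peak sphere lies
# inside the VOI of that sphere's mean; when no position qualifies, the
# sphere is centered on the VOI center and averaged over the VOI voxels it
# covers. Both variants average only VOI voxels, so suv_peak <= suv_max.
suv_peak_at <- function(suv, ijk, voi_lin, center, d_peak) {
  shape <- dim(suv$data)
  offs <- sphere_offsets(d_peak / 2, suv$spacing)
  n_off <- nrow(offs)
  vals <- suv$data[voi_lin]
  if (n_off == 1L) return(max(vals))
  n <- nrow(ijk)
  sums <- numeric(n)
  fits <- rep(TRUE, n)
  for (o in seq_len(n_off)) {
    nb <- cbind(ijk[, 1L] + offs[o, 1L], ijk[, 2L] + offs[o, 2L], ijk[, 3L] + offs[o, 3L])
    ok <- nb[, 1L] >= 1L & nb[, 1L] <= shape[1L] &
      nb[, 2L] >= 1L & nb[, 2L] <= shape[2L] &
      nb[, 3L] >= 1L & nb[, 3L] <= shape[3L]
    nb_lin <- rep(NA_integer_, n)
    nb_lin[ok] <- ijk_to_lin(nb[ok, , drop = FALSE], shape)
    in_voi <- ok & nb_lin %in% voi_lin
    fits <- fits & in_voi
    sums[in_voi] <- sums[in_voi] + suv$data[nb_lin[in_voi]]
  }
  if (any(fits)) {
    return(max(sums[fits]) / n_off)
  }
  # fallback: sphere centered on the VOI center, averaged over VOI voxels
  xyz <- vox_to_world(ijk, suv$spacing)
  d2 <- (xyz[, 1] - center[1])^2 + (xyz[, 2] - center[2])^2 + (xyz[, 3] - center[3])^2
  covered <- d2 <= (d_peak / 2)^2 + 1e-9
  if (!any(covered)) covered <- rep(TRUE, length(vals))
  mean(vals[covered])
}
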