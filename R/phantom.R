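#' Subject metadata for a phantom
#'
#' @param weight_kg body weight in kg (> 0).
#' @param dose_mbq injected dose in MBq (> 0).
#' @param group cohort group label.
#' @param multiplier dimensionless group uptake multiplier applied to every
#'   muscle baseline (> 0).
#' @param baseline_suv named or scalar per-muscle baseline SUV.
#' @param blood_suv blood-pool reference SUV (mediastinal analog and vessel
#'   activity). Default 1.5.
#' @return one-row tibble of subject parameters.
#' @export
subject_params <- function(weight_kg = 75, dose_mbq = 3.5 * weight_kg,
                           group = "control", multiplier = 1,
                           baseline_suv = 0.8, blood_suv = 1.5) {
  check_scalar_pos(weight_kg, "weight_kg")
  check_scalar_pos(dose_mbq, "dose_mbq")
  check_scalar_pos(multiplier, "multiplier")
  tibble::tibble(
    weight_kg = weight_kg, dose_mbq = dose_mbq, group = group,
    multiplier = multiplier, baseline_suv = baseline_suv, blood_suv = blood_suv
  )
}

#' Uptake-pattern specification for one muscle compartment
#'
#' Describes the spatial uptake pattern inserted into a compartment:
#' `homogeneous` (no foci), `unifocal` (one focus), `multifocal` (two or
#' more) or `diffuse` (many low-amplitude foci). A focus is a spherical
#' plateau with a hotter core: the full `amplitude` (SUV units above
#' baseline) within `core_mm` of the center and `shoulder * amplitude` out
#' to `radius_mm`. The core gives every focus a unique, recoverable maximum
#' exactly equal to baseline plus amplitude at the recorded center; the
#' shoulder makes the focus visible on the neighbouring axial slices, as a
#' partial-volume-tapered lesion would be. Overlapping foci add.
#'
#' @param pattern one of `"homogeneous"`, `"unifocal"`, `"multifocal"`,
#'   `"diffuse"`.
#' @param n_foci number of foci; defaults to 0 / 1 / 3 / 8 by pattern.
#' @param amplitude focus amplitude in SUV units above baseline (default
#'   1.8; the diffuse default 0.75 stays below half the unifocal default).
#' @param radius_mm focus radius in mm.
#' @param core_mm radius of the full-amplitude core, mm.
#' @param shoulder fraction of `amplitude` carried by the plateau outside
#'   the core.
#' @param clearance_mm random focus centers keep a fully in-muscle,
#'   vessel-free sphere of this radius around them (the plateau beyond may
#'   clip at the compartment boundary, as a real lesion would). Defaults to
#'   `radius_mm` so the whole focus fits.
#' @param centers optional numeric matrix (n_foci x 3) of world-mm focus
#'   centers; when `NULL` the centers are drawn uniformly among voxel
#'   positions with the required clearance (unifocal and multifocal foci
#'   additionally keep a separation of two radii where the compartment
#'   allows it, so distinct foci stay distinct).
#' @return one-row tibble (with `centers` as a list column).
#' @export
pattern_spec <- function(pattern = c("homogeneous", "unifocal", "multifocal", "diffuse"),
                         n_foci = NULL, amplitude = NULL, radius_mm = 8,
                         core_mm = 2, shoulder = 0.8, clearance_mm = NULL,
                         centers = NULL) {
  pattern <- match.arg(pattern)
  n_default <- c(homogeneous = 0L, unifocal = 1L, multifocal = 3L, diffuse = 8L)
  n_foci <- as.integer(n_foci %||% n_default[[pattern]])
  amplitude <- amplitude %||% (if (pattern == "diffuse") 0.75 else 1.8)
  ok <- switch(pattern,
    homogeneous = n_foci == 0L,
    unifocal = n_foci == 1L,
    multifocal = n_foci >= 2L,
    diffuse = n_foci >= 5L
  )
  if (!ok) {
    abort(sprintf("Focus count %d is invalid for a %s pattern.", n_foci, pattern))
  }
  if (pattern == "diffuse" && amplitude > 0.5 * 1.8 + 1e-9) {
    abort("Diffuse focus amplitude must not exceed half the unifocal default (0.9).")
  }
  if (!is.null(centers)) {
    centers <- as.matrix(centers)
    stopifnot(ncol(centers) == 3L, nrow(centers) == n_foci)
  }
  tibble::tibble(
    pattern = pattern, n_foci = n_foci, amplitude = amplitude,
    radius_mm = radius_mm, core_mm = core_mm, shoulder = shoulder,
    clearance_mm = clearance_mm %||% radius_mm,
    centers = list(centers)
  )
}

# greedy uniform draw of n centers, keeping min_sep where possible;
# falls back to unconstrained draws when the pool runs dry
sample_separated <- function(cand, n, min_sep) {
  picked <- matrix(numeric(0), 0L, 3L)
  pool <- seq_len(nrow(cand))
  for (f in seq_len(n)) {
    if (length(pool) == 0L) {
      idx <- sample.int(nrow(cand), 1L)
      picked <- rbind(picked, cand[idx, , drop = FALSE])
      next
    }
    idx <- pool[[sample.int(length(pool), 1L)]]
    p <- cand[idx, , drop = FALSE]
    picked <- rbind(picked, p)
    d2 <- (cand[pool, 1] - p[1])^2 + (cand[pool, 2] - p[2])^2 + (cand[pool, 3] - p[3])^2
    pool <- pool[d2 > min_sep^2]
  }
  picked
}

# voxel centers where a focus sphere of given radius fits inside the muscle
focus_candidates <- function(atlas, label, radius_mm) {
  key <- sprintf("focus_%d_%g", label, radius_mm)
  if (!is.null(atlas$cache[[key]])) return(atlas$cache[[key]])
  mv <- muscle_voxels(atlas, label)
  offs <- sphere_offsets(radius_mm, atlas$spacing)
  dims <- atlas$shape
  inmask <- atlas$labels == label
  ok <- rep(TRUE, nrow(mv$ijk))
  for (o in seq_len(nrow(offs))) {
    nb <- cbind(mv$ijk[, 1L] + offs[o, 1L], mv$ijk[, 2L] + offs[o, 2L],
                mv$ijk[, 3L] + offs[o, 3L])
    inside <- nb[, 1L] >= 1L & nb[, 1L] <= dims[1L] &
      nb[, 2L] >= 1L & nb[, 2L] <= dims[2L] &
      nb[, 3L] >= 1L & nb[, 3L] <= dims[3L]
    good <- inside
    if (any(inside)) good[inside] <- inmask[ijk_to_lin(nb[inside, , drop = FALSE], dims)]
    ok <- ok & good
    if (!any(ok)) break
  }
  out <- mv$xyz[ok, , drop = FALSE]
  atlas$cache[[key]] <- out
  out
}

#' Generate a digital PET phantom
#'
#' Builds a noiseless SUV field from per-muscle baselines, the group
#' multiplier and the per-muscle pattern foci, converts it to an activity
#' concentration (the inverse of the SUV formula, `C = SUV * D / W`), then
#' applies an isotropic Gaussian point-spread blur and
#' activity-proportional Gaussian noise (variance = `noise_coef` times the
#' local activity, clipped at zero). Ground truth - true pattern class,
#' focus centers and the noiseless pre-blur maximum SUV per muscle - is
#' recorded before blur and noise.
#'
#' @param atlas a [muscle_atlas()].
#' @param subject a [subject_params()] row.
#' @param patterns either a single [pattern_spec()] applied to every muscle,
#'   or a tibble with columns `muscle`, `side` plus the pattern-spec columns.
#' @param fwhm_mm PSF full width at half maximum in mm (0 = no blur).
#' @param noise_coef noise variance per unit activity (kBq/mL); 0 = noiseless.
#' @param seed integer RNG seed; identical seeds give bit-identical phantoms.
#' @return A `pet_phantom`: list with `activity` (kBq/mL array), `atlas`,
#'   `subject`, `ground_truth` (tibble, one row per compartment), `fwhm_mm`,
#'   `noise_coef`, `seed`.
#' @examples
#' atlas <- muscle_atlas()
#' ph <- generate_phantom(atlas, subject_params(),
#'   patterns = pattern_spec("homogeneous"), fwhm_mm = 0, noise_coef = 0, seed = 1)
#' max(ph$activity) > 0
#' @export
generate_phantom <- function(atlas, subject, patterns = pattern_spec("homogeneous"),
                             fwhm_mm = 6, noise_coef = 0.05, seed = 1L) {
  stopifnot(inherits(atlas, "muscle_atlas"))
  if (!("muscle" %in% names(patterns))) {
    patterns <- tidyr::crossing(atlas$muscles[, c("muscle", "side")], patterns)
  }
  patterns <- dplyr::inner_join(
    patterns, atlas$muscles[, c("muscle", "side", "label")],
    by = c("muscle", "side")
  )
  if (nrow(patterns) != nrow(atlas$muscles)) {
    abort("`patterns` must cover every muscle compartment exactly once.")
  }

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(as.integer(seed))

  dims <- atlas$shape
  suv <- array(0, dims)
  suv[atlas$vessel] <- subject$blood_suv
  suv[atlas$reference] <- subject$blood_suv

  base <- subject$baseline_suv[[1]]
  gt_centers <- vector("list", nrow(patterns))
  gt_max <- numeric(nrow(patterns))
  gt_base <- numeric(nrow(patterns))
  for (r in seq_len(nrow(patterns))) {
    p <- patterns[r, ]
    label <- p$label
    mv <- muscle_voxels(atlas, label)
    b <- (if (!is.null(names(base))) base[[p$muscle]] else base[1]) * subject$multiplier
    field <- rep(b, nrow(mv$ijk))
    centers <- p$centers[[1]]
    if (p$n_foci > 0L) {
      if (is.null(centers)) {
        cand <- focus_candidates(atlas, label, p$clearance_mm)
        if (nrow(cand) == 0L) {
          abort(sprintf(
            "Focus radius %g mm exceeds the extent of muscle '%s %s'.",
            p$radius_mm, p$muscle, p$side
          ))
        }
        min_sep <- if (p$pattern == "diffuse") 0 else 2 * p$radius_mm
        centers <- sample_separated(cand, p$n_foci, min_sep)
      }
      for (f in seq_len(nrow(centers))) {
        d2 <- (mv$xyz[, 1] - centers[f, 1])^2 + (mv$xyz[, 2] - centers[f, 2])^2 +
          (mv$xyz[, 3] - centers[f, 3])^2
        in_focus <- d2 <= p$radius_mm^2 + 1e-9
        in_core <- d2 <= p$core_mm^2 + 1e-9
        field <- field + p$amplitude *
          (in_core + p$shoulder * (in_focus & !in_core))
      }
    }
    suv[mv$lin] <- field
    gt_centers[r] <- list(centers)
    gt_max[r] <- max(field)
    gt_base[r] <- b
  }
  gt <- tibble::tibble(
    muscle = patterns$muscle, side = patterns$side, label = patterns$label,
    true_pattern = patterns$pattern, n_foci = patterns$n_foci,
    amplitude = patterns$amplitude, radius_mm = patterns$radius_mm,
    centers = gt_centers, true_max_suv = gt_max, true_baseline_suv = gt_base
  )

  activity <- suv * subject$dose_mbq / subject$weight_kg
  activity <- gaussian_blur(activity, fwhm_mm, atlas$spacing)
  if (noise_coef > 0) {
    noise <- rnorm(length(activity), sd = sqrt(noise_coef * pmax(activity, 0)))
    activity <- pmax(activity + noise, 0)
  }

  structure(
    list(
      activity = activity, atlas = atlas, subject = subject,
      ground_truth = gt,
      fwhm_mm = fwhm_mm, noise_coef = noise_coef, seed = as.integer(seed)
    ),
    class = "pet_phantom"
  )
}

#' @export
print.pet_phantom <- function(x, ...) {
  cat(sprintf(
    "<pet_phantom> group=%s W=%.1f kg D=%.0f MBq, FWHM=%g mm, noise=%g, seed=%d\n",
    x$subject$group, x$subject$weight_kg, x$subject$dose_mbq,
    x$fwhm_mm, x$noise_coef, x$seed
  ))
  invisible(x)
}
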