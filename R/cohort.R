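#' Cohort configuration
#'
#' Study conditions for a synthetic cohort: group sizes and uptake
#' multipliers (control < RA < OA < IIM), the probability of a heterogeneous
#' pattern per muscle class and group, the heterogeneous subtype mix, and
#' the acquisition-like nuisance parameters (PSF width, noise level).
#'
#' Default heterogeneity probabilities echo the structure of published
#' qualitative scoring in rheumatic-disease cohorts: thigh muscles
#' (quadriceps, hamstrings) are heterogeneous in most subjects of every
#' group, while arm muscles and psoas are mostly homogeneous in controls
#' and mixed in patients.
#'
#' @param group_sizes named integer vector of subjects per group.
#' @param multipliers named numeric vector of group uptake multipliers.
#' @param prob_hetero_thigh,prob_hetero_other per-group probability that a
#'   thigh / non-thigh compartment is heterogeneous.
#' @param subtype_probs probabilities of unifocal/multifocal/diffuse given
#'   heterogeneous.
#' @param baseline_suv per-muscle baseline SUV before the group multiplier.
#' @param baseline_sd between-subject SD of the baseline SUV.
#' @param blood_suv blood-pool reference SUV.
#' @param weight_mean,weight_sd,dose_per_kg subject weight distribution (kg,
#'   clipped to 45-120) and dose scaling (MBq per kg).
#' @param fwhm_mm,noise_coef PSF width (mm) and noise coefficient passed to
#'   [generate_phantom()].
#' @param focus_radius_thigh,focus_radius_other focus radius (mm) by muscle
#'   class.
#' @param mirror_lr if `TRUE`, the left pattern is mirrored onto the right
#'   side (identical class and mirrored focus centers), giving perfectly
#'   symmetric noiseless subjects.
#' @param seed master seed; per-subject seeds derive deterministically.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(group_sizes = c(control = 8L, RA = 11L, OA = 10L, IIM = 10L),
                          multipliers = c(control = 1.0, RA = 1.1, OA = 1.4, IIM = 2.0),
                          prob_hetero_thigh = c(control = 0.75, RA = 1, OA = 1, IIM = 0.925),
                          prob_hetero_other = c(control = 0.15, RA = 0.65, OA = 0.55, IIM = 0.65),
                          subtype_probs = c(unifocal = 0.3, multifocal = 0.5, diffuse = 0.2),
                          baseline_suv = 0.8, baseline_sd = 0.05, blood_suv = 1.5,
                          weight_mean = 75, weight_sd = 12, dose_per_kg = 3.5,
                          fwhm_mm = 6, noise_coef = 0.05,
                          focus_radius_thigh = 15, focus_radius_other = 8,
                          mirror_lr = FALSE, seed = 1L) {
  stopifnot(all(group_sizes >= 1L), all(multipliers > 0),
            all(prob_hetero_thigh >= 0 & prob_hetero_thigh <= 1),
            all(prob_hetero_other >= 0 & prob_hetero_other <= 1))
  groups <- names(group_sizes)
  stopifnot(!is.null(groups), setequal(groups, names(multipliers)))
  structure(
    list(
      group_sizes = group_sizes, multipliers = multipliers,
      prob_hetero_thigh = prob_hetero_thigh, prob_hetero_other = prob_hetero_other,
      subtype_probs = subtype_probs / sum(subtype_probs),
      baseline_suv = baseline_suv, baseline_sd = baseline_sd, blood_suv = blood_suv,
      weight_mean = weight_mean, weight_sd = weight_sd, dose_per_kg = dose_per_kg,
      fwhm_mm = fwhm_mm, noise_coef = noise_coef,
      focus_radius_thigh = focus_radius_thigh, focus_radius_other = focus_radius_other,
      mirror_lr = mirror_lr, seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

derive_seed <- function(master, i) {
  as.integer((as.numeric(master) * 1009 + i * 7919) %% (.Machine$integer.max - 1L)) + 1L
}

mirror_x <- function(xyz, atlas) {
  out <- xyz
  out[, 1] <- atlas$shape[1] * atlas$spacing - xyz[, 1]
  out
}

# sample one pattern-spec row for a compartment; focus centers keep the
# VOI radius of clearance so both placement methods can measure any focus
sample_pattern_row <- function(config, group, muscle, side) {
  thigh <- muscle %in% c("quadriceps", "hamstrings")
  p_het <- if (thigh) config$prob_hetero_thigh[[group]] else config$prob_hetero_other[[group]]
  radius <- if (thigh) config$focus_radius_thigh else config$focus_radius_other
  clearance <- default_voi_diameter(muscle) / 2
  if (stats::runif(1) < p_het) {
    subtype <- sample(names(config$subtype_probs), 1L, prob = config$subtype_probs)
    spec <- pattern_spec(subtype, radius_mm = radius, clearance_mm = clearance)
  } else {
    spec <- pattern_spec("homogeneous", radius_mm = radius, clearance_mm = clearance)
  }
  dplyr::bind_cols(tibble::tibble(muscle = muscle, side = side), spec)
}

#' Generate a synthetic cohort of phantoms
#'
#' Draws per-subject weight, dose and per-compartment uptake patterns from a
#' [cohort_config()] and generates one phantom per subject. Per-subject seeds
#' derive deterministically from the master seed, so an identical
#' configuration reproduces the cohort bit for bit.
#'
#' @param config a [cohort_config()].
#' @param atlas a [muscle_atlas()]; built with defaults when omitted.
#' @return list with `phantoms` (list of `pet_phantom`), `subjects` (tibble)
#'   and `ground_truth` (tibble: per scan and muscle, the true pattern class
#'   and true pre-blur maximum SUV).
#' @examples
#' \donttest{
#' coh <- generate_cohort(cohort_config(group_sizes = c(control = 2L, IIM = 2L),
#'   multipliers = c(control = 1, IIM = 2), seed = 7))
#' coh$subjects
#' }
#' @export
generate_cohort <- function(config = cohort_config(), atlas = muscle_atlas()) {
  stopifnot(inherits(config, "cohort_config"))
  groups <- rep(names(config$group_sizes), config$group_sizes)
  n <- length(groups)
  phantoms <- vector("list", n)
  subjects <- vector("list", n)
  gts <- vector("list", n)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)

  for (i in seq_len(n)) {
    seed_i <- derive_seed(config$seed, i)
    set.seed(seed_i)
    w <- min(max(rnorm(1, config$weight_mean, config$weight_sd), 45), 120)
    base_i <- max(rnorm(1, config$baseline_suv, config$baseline_sd), 0.1)
    subj <- subject_params(
      weight_kg = w, dose_mbq = config$dose_per_kg * w, group = groups[i],
      multiplier = config$multipliers[[groups[i]]],
      baseline_suv = base_i, blood_suv = config$blood_suv
    )
    ms <- atlas$muscles
    rows <- vector("list", nrow(ms))
    for (r in seq_len(nrow(ms))) {
      if (config$mirror_lr && ms$side[r] == "R") next
      rows[[r]] <- sample_pattern_row(config, groups[i], ms$muscle[r], ms$side[r])
    }
    patterns <- dplyr::bind_rows(rows)
    if (config$mirror_lr) {
      # realize left-side focus centers now so the right side mirrors them
      patterns <- realize_centers(patterns, atlas)
      mirrored <- patterns
      mirrored$side <- "R"
      mirrored$centers <- lapply(mirrored$centers, function(cc) {
        if (is.null(cc)) NULL else mirror_x(cc, atlas)
      })
      patterns <- dplyr::bind_rows(patterns, mirrored)
    }
    ph <- generate_phantom(
      atlas, subj, patterns,
      fwhm_mm = config$fwhm_mm, noise_coef = config$noise_coef,
      seed = derive_seed(seed_i, 1L)
    )
    scan_id <- sprintf("%s_%02d", groups[i], i)
    phantoms[[i]] <- ph
    subjects[[i]] <- dplyr::bind_cols(tibble::tibble(scan_id = scan_id, seed = seed_i), subj)
    gts[[i]] <- dplyr::bind_cols(
      tibble::tibble(scan_id = scan_id, group = groups[i]), ph$ground_truth
    )
  }
  list(
    phantoms = phantoms,
    subjects = dplyr::bind_rows(subjects),
    ground_truth = dplyr::bind_rows(gts)
  )
}

# draw explicit focus centers for pattern rows that lack them
realize_centers <- function(patterns, atlas) {
  for (r in seq_len(nrow(patterns))) {
    p <- patterns[r, ]
    if (p$n_foci > 0L && is.null(p$centers[[1]])) {
      label <- atlas_label(atlas, p$muscle, p$side)
      cand <- focus_candidates(atlas, label, p$clearance_mm)
      if (nrow(cand) == 0L) {
        abort(sprintf("Focus radius %g mm exceeds the extent of muscle '%s %s'.",
                      p$radius_mm, p$muscle, p$side))
      }
      min_sep <- if (p$pattern == "diffuse") 0 else 2 * p$radius_mm
      patterns$centers[[r]] <- sample_separated(cand, p$n_foci, min_sep)
    }
  }
  patterns
}
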