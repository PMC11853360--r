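# Shared fixtures. The default atlas is expensive enough to build once; the
# cache environment memoizes it and the heavier simulation summaries so
# several test files (and several acceptance blocks) can share them.

.fixtures <- new.env(parent = emptyenv())

test_atlas <- function() {
  if (is.null(.fixtures$atlas)) .fixtures$atlas <- muscle_atlas()
  .fixtures$atlas
}

# bare suv_volume from an array
as_suv <- function(a, spacing = 4) {
  structure(list(data = a, spacing = spacing), class = "suv_volume")
}

# noiseless phantom with every compartment heterogeneous: separated foci
# (unifocal in the small muscles, mixed in the thighs) so that every
# candidate hotspot is confirmable
hetero_phantom <- function(atlas, seed, multiplier = 1.4, fwhm_mm = 6) {
  withr::with_seed(seed, {
    pats <- dplyr::bind_rows(lapply(seq_len(nrow(atlas$muscles)), function(r) {
      m <- atlas$muscles[r, ]
      thigh <- m$muscle %in% c("quadriceps", "hamstrings")
      dplyr::bind_cols(
        tibble::tibble(muscle = m$muscle, side = m$side),
        pattern_spec(
          if (thigh) sample(c("unifocal", "multifocal"), 1) else "unifocal",
          radius_mm = if (thigh) 15 else 8,
          clearance_mm = default_voi_diameter(m$muscle) / 2
        )
      )
    }))
    generate_phantom(atlas, subject_params(multiplier = multiplier), pats,
                     fwhm_mm = fwhm_mm, noise_coef = 0, seed = seed)
  })
}

# fixed/hotspot SUVpeak per compartment for one phantom
peak_by_method <- function(phantom, config = study_config()) {
  q <- quantify_phantom(phantom, config, scan_id = "x")
  tidyr::pivot_wider(
    dplyr::select(q$suv, muscle, side, method, suv_peak),
    names_from = "method", values_from = "suv_peak"
  )
}

# 20-seed summaries of the default cohort study, computed once
default_cohort_summaries <- function(n_seeds = 20L) {
  key <- sprintf("cohort_%d", n_seeds)
  if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
  atlas <- test_atlas()
  res <- lapply(seq_len(n_seeds), function(s) {
    st <- run_study(study_config(cohort = cohort_config(seed = s)), atlas)
    pooled <- dplyr::filter(st$method_comparison$summary, muscle == "pooled")
    hot <- dplyr::filter(st$averaged, method == "hotspot")
    ord <- hot |>
      dplyr::group_by(muscle, group) |>
      dplyr::summarise(m = mean(suv_peak), .groups = "drop") |>
      dplyr::filter(muscle %in% c("psoas", "hamstrings", "quadriceps")) |>
      dplyr::group_by(muscle) |>
      dplyr::summarise(iim_top = group[which.max(m)] == "IIM")
    kw_sig <- vapply(
      c("psoas", "hamstrings", "quadriceps"),
      function(m) st$group_tests[[m]]$p < 0.05, TRUE
    )
    tibble::tibble(
      seed = s, pooled_bias = pooled$bias, pearson_r2 = pooled$pearson_r2,
      iim_top_all = all(ord$iim_top), kw_sig_count = sum(kw_sig)
    )
  })
  out <- dplyr::bind_rows(res)
  .fixtures[[key]] <- out
  out
}
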