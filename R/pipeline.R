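#' Study configuration
#'
#' Bundles every tunable the full study needs: cohort conditions, VOI
#' diameters, hotspot confirmation, SUVpeak kernel, classifier thresholds.
#'
#' @param cohort a [cohort_config()].
#' @param diameter_large,diameter_small VOI sphere diameters in mm for the
#'   thigh muscles and the smaller muscles.
#' @param hotspot a [hotspot_params()].
#' @param d_peak SUVpeak neighbourhood diameter, mm.
#' @param cv_threshold,z_thresh pattern-classifier thresholds.
#' @param seed master seed (overrides the cohort seed when given).
#' @return a `study_config` list.
#' @export
study_config <- function(cohort = cohort_config(), diameter_large = 20,
                         diameter_small = 10, hotspot = hotspot_params(),
                         d_peak = 12, cv_threshold = 0.15, z_thresh = 2,
                         seed = NULL) {
  if (!is.null(seed)) cohort$seed <- as.integer(seed)
  structure(
    list(
      cohort = cohort, diameter_large = diameter_large,
      diameter_small = diameter_small, hotspot = hotspot, d_peak = d_peak,
      cv_threshold = cv_threshold, z_thresh = z_thresh
    ),
    class = "study_config"
  )
}

#' Quantify one phantom with both VOI methods
#'
#' Converts the phantom to SUV, places the fixed and hotspot VOIs in every
#' compartment and extracts SUV statistics, and scores positivity and the
#' uptake pattern per compartment against the blood-pool reference (mean
#' SUV over the reference mask).
#'
#' @param phantom a `pet_phantom`.
#' @param config a [study_config()].
#' @param scan_id identifier copied onto the output rows.
#' @param methods which VOI methods to run.
#' @return list with `suv` (tibble: one row per compartment x method) and
#'   `patterns` (tibble: one row per compartment).
#' @export
quantify_phantom <- function(phantom, config = study_config(), scan_id = "scan",
                             methods = c("fixed", "hotspot")) {
  stopifnot(inherits(phantom, "pet_phantom"))
  atlas <- phantom$atlas
  suv <- to_suv(phantom)
  reference <- mean(suv$data[atlas$reference])
  ms <- atlas$muscles
  suv_rows <- list()
  pat_rows <- vector("list", nrow(ms))
  for (r in seq_len(nrow(ms))) {
    muscle <- ms$muscle[r]; side <- ms$side[r]
    diameter <- default_voi_diameter(muscle, config$diameter_large, config$diameter_small)
    for (method in methods) {
      voi <- if (method == "fixed") {
        place_fixed_voi(atlas, muscle, side, diameter = diameter)
      } else {
        place_hotspot_voi(suv, atlas, muscle, side, diameter = diameter,
                          params = config$hotspot, d_peak = config$d_peak)
      }
      st <- suv_stats(suv, c(voi$x, voi$y, voi$z), diameter, d_peak = config$d_peak)
      suv_rows[[length(suv_rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(scan_id = scan_id, group = phantom$subject$group),
        voi, st
      )
    }
    cls <- classify_pattern(suv, atlas, muscle, side,
                            cv_threshold = config$cv_threshold,
                            z_thresh = config$z_thresh)
    pat_rows[[r]] <- dplyr::bind_cols(
      tibble::tibble(scan_id = scan_id, group = phantom$subject$group), cls
    )
  }
  suv_tbl <- dplyr::bind_rows(suv_rows)
  patterns <- dplyr::bind_rows(pat_rows)
  # positivity from the hotspot SUVpeak (visual-analog criterion)
  hs <- dplyr::filter(suv_tbl, .data$method == "hotspot")
  if (nrow(hs) > 0L) {
    patterns <- dplyr::left_join(
      patterns,
      dplyr::select(hs, "scan_id", "muscle", "side", "suv_peak"),
      by = c("scan_id", "muscle", "side")
    ) |>
      dplyr::mutate(
        reference_suv = reference,
        positivity = positivity(.data$suv_peak, reference)
      ) |>
      dplyr::select(-"suv_peak")
  }
  list(suv = suv_tbl, patterns = patterns)
}

#' Average left and right sides and test symmetry
#'
#' Per scan, muscle and method the left/right mean is formed (the available
#' side when one is missing, with a flag); per muscle and method a paired
#' t-test of left versus right across scans quantifies symmetry. Averaging
#' is performed regardless of the symmetry-test outcome.
#'
#' @param suv_tbl tibble with columns `scan_id`, `muscle`, `side`, `method`
#'   and the value column.
#' @param value column (tidy-eval) to average; default `suv_peak`.
#' @return list with `averaged` (tibble: scan_id, group, muscle, method,
#'   value, n_sides, flagged) and `symmetry` (tibble: muscle, method,
#'   mean_diff, t, df, p, n, stars).
#' @export
average_lr <- function(suv_tbl, value = suv_peak) {
  qv <- rlang::enquo(value)
  vname <- rlang::as_name(qv)
  wide <- suv_tbl |>
    dplyr::select("scan_id", dplyr::any_of("group"), "muscle", "side", "method",
                  value = !!qv) |>
    tidyr::pivot_wider(names_from = "side", values_from = "value")
  if (!all(c("L", "R") %in% names(wide))) {
    for (s in setdiff(c("L", "R"), names(wide))) wide[[s]] <- NA_real_
  }
  both <- !is.na(wide$L) & !is.na(wide$R)
  none <- is.na(wide$L) & is.na(wide$R)
  if (any(none)) {
    warn(sprintf("%d scan-muscle rows missing on both sides were excluded.", sum(none)))
    wide <- wide[!none, ]
    both <- both[!none]
  }
  averaged <- wide |>
    dplyr::mutate(
      value = dplyr::coalesce((.data$L + .data$R) / 2, .data$L, .data$R),
      n_sides = (!is.na(.data$L)) + (!is.na(.data$R)),
      flagged = .data$n_sides < 2L
    ) |>
    dplyr::select(-"L", -"R")
  names(averaged)[names(averaged) == "value"] <- vname

  symmetry <- wide[both, ] |>
    dplyr::group_by(.data$muscle, .data$method) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 2L || stats::sd(d$L - d$R) == 0) {
        return(tibble::tibble(mean_diff = mean(d$L - d$R), t = NA_real_,
                              df = NA_real_, p = NA_real_, n = nrow(d)))
      }
      paired_t(d$L, d$R)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(stars = p_stars(.data$p))
  list(averaged = averaged, symmetry = symmetry)
}

#' Compare fixed and hotspot VOI methods
#'
#' Pairs the two methods per scan and muscle (on left/right-averaged
#' values), then reports Pearson and Spearman correlation and Bland-Altman
#' agreement (differences oriented fixed minus hotspot) per muscle and
#' pooled over all muscles.
#'
#' @param averaged tibble from [average_lr()] (columns `scan_id`, `muscle`,
#'   `method`, value).
#' @param value column (tidy-eval) holding the quantity; default `suv_peak`.
#' @return a `method_comparison`: list with `summary` (tibble, one row per
#'   muscle plus `"pooled"`) and `bland_altman` (named list of
#'   [bland_altman()] objects).
#' @export
compare_methods <- function(averaged, value = suv_peak) {
  qv <- rlang::enquo(value)
  wide <- averaged |>
    dplyr::select("scan_id", "muscle", "method", value = !!qv) |>
    tidyr::pivot_wider(names_from = "method", values_from = "value") |>
    dplyr::filter(!is.na(.data$fixed) & !is.na(.data$hotspot))
  one <- function(d, label) {
    ba <- bland_altman(d$fixed, d$hotspot)
    constant <- stats::sd(d$fixed) == 0 || stats::sd(d$hotspot) == 0
    pe <- if (constant) NULL else method_correlation(d$fixed, d$hotspot, "pearson")
    sp <- if (constant) NULL else method_correlation(d$fixed, d$hotspot, "spearman")
    list(
      row = tibble::tibble(
        muscle = label, n = nrow(d),
        pearson_r = if (constant) NA_real_ else pe$r,
        pearson_r2 = if (constant) NA_real_ else pe$r_squared,
        pearson_p = if (constant) NA_real_ else pe$p,
        spearman_r = if (constant) NA_real_ else sp$r,
        spearman_r2 = if (constant) NA_real_ else sp$r_squared,
        spearman_p = if (constant) NA_real_ else sp$p,
        bias = ba$bias, sd_diff = ba$sd,
        loa_lower = ba$lower, loa_upper = ba$upper
      ),
      ba = ba
    )
  }
  res <- lapply(split(wide, wide$muscle), function(d) one(d, d$muscle[1]))
  pooled <- one(wide, "pooled")
  res <- c(res, list(pooled = pooled))
  structure(
    list(
      summary = dplyr::bind_rows(lapply(res, `[[`, "row")),
      bland_altman = lapply(res, `[[`, "ba")
    ),
    class = "method_comparison"
  )
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("<method_comparison>\n")
  print(x$summary, ...)
  invisible(x)
}

#' Run the full phantom study
#'
#' Orchestrates the complete analysis on a synthetic cohort: simulate,
#' quantify both VOI methods, test and average left/right, score patterns
#' and positivity, compare methods (correlation and Bland-Altman) and
#' compare groups (gated omnibus with Dunn's post-hoc, on the
#' left/right-averaged hotspot SUVpeak per muscle). Fully deterministic
#' given the master seed.
#'
#' @param config a [study_config()].
#' @param atlas a [muscle_atlas()]; defaults are used when omitted.
#' @param out_dir optional directory; when given, the result tables are
#'   written there as CSV files.
#' @return a `muscle_study`: list with `suv`, `patterns`, `averaged`,
#'   `symmetry`, `pattern_table`, `method_comparison`, `group_tests`
#'   (named list per muscle), `recovery`, `subjects`, `ground_truth`,
#'   `config`.
#' @export
run_study <- function(config = study_config(), atlas = muscle_atlas(),
                      out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  coh <- generate_cohort(config$cohort, atlas)
  n <- nrow(coh$subjects)
  suv_list <- vector("list", n)
  pat_list <- vector("list", n)
  for (i in seq_len(n)) {
    q <- quantify_phantom(coh$phantoms[[i]], config, scan_id = coh$subjects$scan_id[i])
    suv_list[[i]] <- q$suv
    pat_list[[i]] <- q$patterns
  }
  suv_tbl <- dplyr::bind_rows(suv_list)
  patterns <- dplyr::bind_rows(pat_list)

  lr <- average_lr(suv_tbl, value = suv_peak)
  comparison <- compare_methods(lr$averaged, value = suv_peak)
  pattern_table <- tabulate_patterns(patterns)

  hot <- dplyr::filter(lr$averaged, .data$method == "hotspot")
  group_tests <- lapply(split(hot, hot$muscle), function(d) {
    compare_groups(d, value = suv_peak, group = group)
  })

  recovery <- recovery_summary(suv_tbl, patterns, coh$ground_truth, atlas)

  study <- structure(
    list(
      suv = suv_tbl, patterns = patterns,
      averaged = lr$averaged, symmetry = lr$symmetry,
      pattern_table = pattern_table, method_comparison = comparison,
      group_tests = group_tests, recovery = recovery,
      subjects = coh$subjects, ground_truth = coh$ground_truth,
      config = config
    ),
    class = "muscle_study"
  )
  if (!is.null(out_dir)) write_study(study, out_dir)
  study
}

#' @export
print.muscle_study <- function(x, ...) {
  cat(sprintf("<muscle_study> %d scans, %d VOI rows\n",
              nrow(x$subjects), nrow(x$suv)))
  pooled <- dplyr::filter(x$method_comparison$summary, .data$muscle == "pooled")
  cat(sprintf("  pooled fixed-hotspot bias %.3f [%.3f, %.3f], Pearson R^2 %.3f\n",
              pooled$bias, pooled$loa_lower, pooled$loa_upper, pooled$pearson_r2))
  cat(sprintf("  heterogeneous in %s: %d%%\n",
              paste(x$pattern_table$subset, collapse = "+"),
              x$pattern_table$aggregate_pct))
  invisible(x)
}

#' Ground-truth recovery metrics
#'
#' For heterogeneous compartments, the distance from the hotspot VOI center
#' to the nearest true focus center; for every compartment, the hotspot
#' SUVpeak error against the true pre-blur maximum SUV and the
#' pattern-classification confusion (predicted vs true class).
#'
#' @param suv_tbl per-VOI tibble (needs hotspot rows with centers).
#' @param patterns per-compartment pattern scores.
#' @param ground_truth cohort ground-truth tibble.
#' @param atlas the atlas the cohort was generated on.
#' @return list with `per_muscle` (tibble with `center_error_mm`,
#'   `suv_peak_error`, `pattern_correct`), `median_center_error_mm`,
#'   `pattern_accuracy` and `confusion` (tibble).
#' @export
recovery_summary <- function(suv_tbl, patterns, ground_truth, atlas) {
  hs <- dplyr::filter(suv_tbl, .data$method == "hotspot")
  gt <- ground_truth |>
    dplyr::mutate(true_class = ifelse(.data$true_pattern == "homogeneous",
                                      "homogeneous", "heterogeneous"))
  per <- dplyr::left_join(
    hs, dplyr::select(gt, "scan_id", "muscle", "side", "true_pattern",
                      "true_class", "centers", "true_max_suv"),
    by = c("scan_id", "muscle", "side")
  )
  per$center_error_mm <- vapply(seq_len(nrow(per)), function(r) {
    cc <- per$centers[[r]]
    if (is.null(cc) || nrow(cc) == 0L) return(NA_real_)
    min(sqrt((cc[, 1] - per$x[r])^2 + (cc[, 2] - per$y[r])^2 + (cc[, 3] - per$z[r])^2))
  }, 1.0)
  per$suv_peak_error <- per$suv_peak - per$true_max_suv
  per <- dplyr::select(per, "scan_id", "group", "muscle", "side", "true_pattern",
                       "true_class", "center_error_mm", "suv_peak_error")
  pred <- dplyr::select(patterns, "scan_id", "muscle", "side",
                        pred_pattern = "pattern", pred_subtype = "subtype")
  per <- dplyr::left_join(per, pred, by = c("scan_id", "muscle", "side")) |>
    dplyr::mutate(pattern_correct = .data$pred_pattern == .data$true_class)
  confusion <- per |>
    dplyr::count(.data$true_pattern, .data$pred_pattern, .data$pred_subtype)
  list(
    per_muscle = per,
    median_center_error_mm = stats::median(per$center_error_mm, na.rm = TRUE),
    pattern_accuracy = mean(per$pattern_correct),
    confusion = confusion
  )
}

write_study <- function(study, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(study$suv |> dplyr::select(-dplyr::any_of("note")),
                   file.path(out_dir, "suv_voi.csv"), row.names = FALSE)
  utils::write.csv(study$patterns, file.path(out_dir, "patterns.csv"), row.names = FALSE)
  utils::write.csv(study$averaged, file.path(out_dir, "suv_averaged.csv"), row.names = FALSE)
  utils::write.csv(study$symmetry, file.path(out_dir, "symmetry.csv"), row.names = FALSE)
  utils::write.csv(study$pattern_table$counts, file.path(out_dir, "pattern_table.csv"),
                   row.names = FALSE)
  utils::write.csv(study$method_comparison$summary,
                   file.path(out_dir, "method_comparison.csv"), row.names = FALSE)
  omni <- dplyr::bind_rows(lapply(names(study$group_tests), function(m) {
    gt <- study$group_tests[[m]]
    tibble::tibble(muscle = m, test = gt$test, statistic = gt$statistic,
                   p = gt$p, stars = p_stars(gt$p))
  }))
  utils::write.csv(omni, file.path(out_dir, "group_tests.csv"), row.names = FALSE)
  invisible(out_dir)
}
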