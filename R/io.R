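#' Write a phantom to NIfTI volumes with a JSON sidecar
#'
#' Writes the activity volume (float, kBq/mL), the integer label map, the
#' vessel mask and the blood-pool reference mask as `.nii.gz` files with
#' isotropic spacing in mm (RAS-style axes, world coordinate of voxel `i`
#' at `(i - 0.5) * spacing`), plus a JSON sidecar holding subject metadata,
#' landmarks and the ground truth.
#'
#' @param phantom a `pet_phantom`.
#' @param dir output directory (created if needed).
#' @param name file stem. Default `"phantom"`.
#' @return the directory, invisibly.
#' @export
write_phantom <- function(phantom, dir, name = "phantom") {
  stopifnot(inherits(phantom, "pet_phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- phantom$atlas$spacing
  wr <- function(data, file) {
    img <- RNifti::asNifti(data, pixdim = rep(sp, 3))
    RNifti::writeNifti(img, file.path(dir, file))
  }
  wr(phantom$activity, paste0(name, "_activity.nii.gz"))
  wr(phantom$atlas$labels, paste0(name, "_labels.nii.gz"))
  wr(array(as.integer(phantom$atlas$vessel), dim(phantom$activity)),
     paste0(name, "_vessel.nii.gz"))
  wr(array(as.integer(phantom$atlas$reference), dim(phantom$activity)),
     paste0(name, "_reference.nii.gz"))

  gt <- phantom$ground_truth
  gt$centers <- lapply(gt$centers, function(cc) if (is.null(cc)) list() else unname(apply(cc, 1, as.list, simplify = FALSE)))
  sidecar <- list(
    weight_kg = phantom$subject$weight_kg,
    dose_MBq = phantom$subject$dose_mbq,
    group = phantom$subject$group,
    multiplier = phantom$subject$multiplier,
    blood_suv = phantom$subject$blood_suv,
    seed = phantom$seed,
    fwhm_mm = phantom$fwhm_mm,
    noise_coef = phantom$noise_coef,
    spacing_mm = sp,
    shape = phantom$atlas$shape,
    landmarks = phantom$atlas$landmarks,
    ground_truth = gt
  )
  jsonlite::write_json(sidecar, file.path(dir, paste0(name, ".json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a phantom written by [write_phantom()]
#'
#' Restores the activity array, masks and sidecar metadata. The atlas is
#' rebuilt from the label map, masks and sidecar landmarks, so VOI placement
#' and quantification work on the round-tripped object.
#'
#' @param dir directory containing the files.
#' @param name file stem used at write time.
#' @return a `pet_phantom`.
#' @export
read_phantom <- function(dir, name = "phantom") {
  rd <- function(file) {
    img <- RNifti::readNifti(file.path(dir, file))
    array(as.vector(img), dim(img))
  }
  activity <- rd(paste0(name, "_activity.nii.gz"))
  labels <- rd(paste0(name, "_labels.nii.gz"))
  storage.mode(labels) <- "integer"
  vessel <- rd(paste0(name, "_vessel.nii.gz")) > 0
  reference <- rd(paste0(name, "_reference.nii.gz")) > 0
  sc <- jsonlite::read_json(file.path(dir, paste0(name, ".json")), simplifyVector = TRUE)

  lm <- tibble::as_tibble(sc$landmarks)
  codes <- sort(unique(labels[labels > 0L]))
  muscles <- lm[match(codes, lm$label), c("muscle", "side", "label")]
  muscles$n_vox <- tabulate(labels[labels > 0L], nbins = max(codes))[codes]
  atlas <- structure(
    list(
      shape = dim(labels), spacing = sc$spacing_mm, labels = labels,
      muscles = tibble::as_tibble(muscles), landmarks = lm,
      vessel = vessel, reference = reference,
      cache = new.env(parent = emptyenv())
    ),
    class = "muscle_atlas"
  )
  gt <- tibble::as_tibble(sc$ground_truth)
  if ("centers" %in% names(gt)) {
    gt$centers <- lapply(gt$centers, function(cc) {
      if (is.null(cc) || length(cc) == 0L) return(NULL)
      do.call(rbind, lapply(cc, function(p) unlist(p)))
    })
  }
  structure(
    list(
      activity = activity,
      atlas = atlas,
      subject = subject_params(
        weight_kg = sc$weight_kg, dose_mbq = sc$dose_MBq, group = sc$group,
        multiplier = sc$multiplier, blood_suv = sc$blood_suv
      ),
      ground_truth = gt,
      fwhm_mm = sc$fwhm_mm, noise_coef = sc$noise_coef, seed = sc$seed
    ),
    class = "pet_phantom"
  )
}
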