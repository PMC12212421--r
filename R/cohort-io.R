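#' Write a cohort to disk
#'
#' CT and GTVp mask are written per patient as NIfTI (`.nii.gz`) with the
#' voxel spacing encoded in the affine/pixdim; clinical covariates and
#' time-to-event endpoints are written as CSV tables; simulation metadata
#' (persistent-disease flag, latent risk) goes into a JSON manifest so that
#' a round-trip read reproduces the records field-for-field.
#'
#' @param cohort An `hn_cohort`.
#' @param directory Output directory (created if absent).
#' @return The manifest, invisibly.
#' @export
write_cohort <- function(cohort, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(cohort, function(r) {
    ct_file <- file.path(directory, paste0(r$patient_id, "_ct.nii.gz"))
    mk_file <- file.path(directory, paste0(r$patient_id, "_mask.nii.gz"))
    pd <- c(-1, r$spacing, 0, 0, 0, 0)
    RNifti::writeNifti(RNifti::asNifti(r$ct, list(pixdim = pd)), ct_file)
    RNifti::writeNifti(RNifti::asNifti(r$gtvp_mask, list(pixdim = pd)), mk_file)
    list(patient_id = r$patient_id,
         ct = basename(ct_file), mask = basename(mk_file),
         persistent_disease = r$persistent_disease,
         latent_risk = r$latent_risk,
         truth = r$truth)
  })
  utils::write.csv(cohort_clinical_table(cohort),
                   file.path(directory, "clinical.csv"), row.names = FALSE)
  utils::write.csv(cohort_endpoint_table(cohort),
                   file.path(directory, "endpoints.csv"), row.names = FALSE)
  cfg <- attr(cohort, "config")
  cfg_out <- NULL
  if (!is.null(cfg)) {
    cfg_out <- unclass(cfg)
    # named vectors serialize as bare arrays; keep the names via a list
    cfg_out$risk_coefficients <- as.list(cfg_out$risk_coefficients)
  }
  manifest <- list(config = cfg_out, patients = entries)
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a cohort from disk
#'
#' Inverse of [write_cohort()]. Validates that CT and mask share grid shape
#' and spacing and that categorical clinical values are legal.
#'
#' @param directory Directory written by [write_cohort()].
#' @return An `hn_cohort`.
#' @export
read_cohort <- function(directory) {
  manifest <- jsonlite::read_json(file.path(directory, "manifest.json"))
  clin <- utils::read.csv(file.path(directory, "clinical.csv"),
                          stringsAsFactors = FALSE)
  endp <- utils::read.csv(file.path(directory, "endpoints.csv"),
                          stringsAsFactors = FALSE)
  bad_hpv <- setdiff(unique(stats::na.omit(clin$hpv)),
                     c("positive", "negative", "unknown"))
  if (length(bad_hpv))
    stop("unknown HPV category in clinical.csv: ",
         paste(bad_hpv, collapse = ", "), call. = FALSE)

  records <- lapply(manifest$patients, function(e) {
    ct_img <- RNifti::readNifti(file.path(directory, e$ct))
    mk_img <- RNifti::readNifti(file.path(directory, e$mask))
    if (!identical(dim(ct_img), dim(mk_img)))
      stop(sprintf("grid shape mismatch between CT and mask for %s",
                   e$patient_id), call. = FALSE)
    sp_ct <- RNifti::pixdim(ct_img); sp_mk <- RNifti::pixdim(mk_img)
    if (max(abs(sp_ct - sp_mk)) > 1e-6)
      stop(sprintf("spacing mismatch between CT and mask for %s",
                   e$patient_id), call. = FALSE)
    cl <- clin[clin$patient_id == e$patient_id, , drop = FALSE]
    ep <- endp[endp$patient_id == e$patient_id, , drop = FALSE]
    endpoints <- lapply(split(ep, ep$endpoint), function(x)
      list(time_months = x$time_months, event = x$event))
    endpoints <- endpoints[c("OS", "LRC", "FFDM")]
    structure(list(
      patient_id = e$patient_id,
      ct = array(as.numeric(ct_img), dim = dim(ct_img)),
      gtvp_mask = array(as.integer(mk_img), dim = dim(mk_img)),
      spacing = as.numeric(sp_ct),
      clinical = list(age = cl$age, sex = cl$sex, t_stage = cl$t_stage,
                      n_stage = cl$n_stage, hpv = cl$hpv, chemo = cl$chemo),
      endpoints = endpoints,
      persistent_disease = e$persistent_disease,
      latent_risk = e$latent_risk,
      truth = e$truth
    ), class = "patient_record")
  })
  cfg <- NULL
  if (!is.null(manifest$config)) {
    cf <- lapply(manifest$config, function(x) if (is.list(x)) unlist(x) else x)
    cfg <- do.call(cohort_config, cf)
  }
  structure(records, class = "hn_cohort", config = cfg)
}
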