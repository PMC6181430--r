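#' Read and write decoded-trial tables
#'
#' Decoded samples travel as plain CSV with columns
#' `trial, level_A, level_B, decoded_value`; activity-pattern tables use the
#' same leading columns followed by one numeric column per measure.
#'
#' @param data A data frame of decoded trials (or patterns).
#' @param path File path.
#' @return `read_decoded_csv()` returns a tibble; `write_decoded_csv()`
#'   returns `path` invisibly.
#' @export
write_decoded_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_decoded_csv
#' @export
read_decoded_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' Serialize package objects to JSON
#'
#' Encoding models, linear decoders, measurement models and worlds
#' round-trip through a tagged JSON document, so that a simulation run can
#' be archived and re-loaded exactly.
#'
#' @param object An `encoding_model`, `linear_decoder`,
#'   `measurement_model` or `ddsep_world`.
#' @param path File path (`.json`).
#' @return `ddsep_write_json()` returns `path` invisibly;
#'   `ddsep_read_json()` returns the reconstructed object.
#' @export
ddsep_write_json <- function(object, path) {
  doc <- to_doc(object)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

to_doc <- function(object) {
  if (inherits(object, "encoding_model")) {
    list(type = "encoding_model",
         levels_A = object$grid$levels_A, levels_B = object$grid$levels_B,
         labels_A = object$grid$labels_A, labels_B = object$grid$labels_B,
         tuning = unname(object$tuning),
         noise_cov = lapply(object$noise_cov, unname))
  } else if (inherits(object, "linear_decoder")) {
    list(type = "linear_decoder", beta = object$beta,
         weights = object$weights, trained_on = object$trained_on)
  } else if (inherits(object, "measurement_model")) {
    list(type = "measurement_model",
         mixing = unname(object$mixing), error_cov = unname(object$error_cov))
  } else if (inherits(object, "ddsep_world")) {
    list(type = "world", regime = object$regime,
         n_channels = object$n_channels, effect_size = object$effect_size,
         noise_sd = object$noise_sd,
         measurement_error_sd = object$measurement_error_sd,
         seed = object$seed)
  } else {
    abort("unsupported object type for JSON serialization")
  }
}

#' @rdname ddsep_write_json
#' @export
ddsep_read_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  switch(doc$type,
    encoding_model = {
      grid <- stimulus_grid(doc$levels_A, doc$levels_B,
                            doc$labels_A, doc$labels_B)
      tuning <- as.matrix(doc$tuning)
      noise_cov <- if (is.list(doc$noise_cov)) {
        lapply(doc$noise_cov, as.matrix)
      } else {  # uniform covariances simplify to a 3-D array on read
        lapply(seq_len(dim(doc$noise_cov)[1]),
               function(k) as.matrix(doc$noise_cov[k, , ]))
      }
      encoding_model(grid, tuning, noise_cov)
    },
    linear_decoder = linear_decoder(doc$weights, doc$beta, doc$trained_on),
    measurement_model = measurement_model(as.matrix(doc$mixing),
                                           as.matrix(doc$error_cov)),
    world = make_world(doc$regime, n_channels = doc$n_channels,
                       effect_size = doc$effect_size,
                       noise_sd = doc$noise_sd,
                       measurement_error_sd = doc$measurement_error_sd,
                       seed = doc$seed),
    abort(sprintf("unknown document type '%s'", doc$type)))
}

#' Read and write volumetric data as NIfTI-1
#'
#' Writes the 4-D data, 3-D mask and trial table of a [volume_dataset()]
#' (or a [searchlight_dds()] map) to NIfTI-1 / CSV files, and reads them
#' back.  Affines are carried through untouched.
#'
#' @param ds A `volume_dataset`.
#' @param prefix Output path prefix; writes `<prefix>_data.nii.gz`,
#'   `<prefix>_mask.nii.gz` and `<prefix>_trials.csv`.
#' @return The file paths, invisibly.
#' @export
write_volume_nifti <- function(ds, prefix) {
  stopifnot(inherits(ds, "volume_dataset"))
  paths <- c(data = paste0(prefix, "_data.nii.gz"),
             mask = paste0(prefix, "_mask.nii.gz"),
             trials = paste0(prefix, "_trials.csv"))
  RNifti::writeNifti(RNifti::asNifti(ds$data), paths["data"])
  RNifti::writeNifti(RNifti::asNifti(ds$mask + 0L), paths["mask"])
  utils::write.csv(as.data.frame(ds$trial_table), paths["trials"],
                   row.names = FALSE)
  invisible(paths)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(prefix) {
  dat <- RNifti::readNifti(paste0(prefix, "_data.nii.gz"))
  mask <- RNifti::readNifti(paste0(prefix, "_mask.nii.gz"))
  trials <- read_decoded_csv(paste0(prefix, "_trials.csv"))
  volume_dataset(array(as.numeric(dat), dim = dim(dat)),
                 array(as.integer(mask), dim = dim(mask)), trials)
}

#' @rdname write_volume_nifti
#' @param map A `searchlight_map`.
#' @param path Output NIfTI path; a JSON sidecar with the map's settings is
#'   written next to it.
#' @export
write_map_nifti <- function(map, path) {
  stopifnot(inherits(map, "searchlight_map"))
  RNifti::writeNifti(RNifti::asNifti(map$values), path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(map$metadata, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(path, sidecar))
}
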