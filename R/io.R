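#' Read a CT slice from disk
#'
#' Supported formats: NIfTI (`.nii` / `.nii.gz`, spacing taken from the
#' header pixdim) and CSV (plain value matrix; spacing from a JSON sidecar
#' written by [write_slice()], else the `pixel_spacing` argument).  A 3-D
#' NIfTI volume requires an explicit `slice` index.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"nifti"` or `"csv"`.
#' @param slice slice index for 3-D volumes.
#' @param pixel_spacing fallback spacing in mm when the file carries none.
#' @param modality modality tag for the returned image.
#' @return a [slice_image()].
#' @export
read_slice <- function(path, format = c("auto", "nifti", "csv"), slice = NULL,
                       pixel_spacing = NULL, modality = "unknown") {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort_mvmar(sprintf("file not found: %s", path), "mvmar_io_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.nii(\\.gz)?$", path)) "nifti" else
      if (grepl("\\.csv$", path)) "csv" else
        abort_mvmar(sprintf("cannot infer format of '%s'", path), "mvmar_io_error")
  }
  if (format == "nifti") {
    vol <- RNifti::readNifti(path)
    spacing <- RNifti::pixdim(vol)[1]
    arr <- as.array(vol)
    arr <- array(as.numeric(arr), dim(arr)) # plain array, no NIfTI attributes
    if (length(dim(arr)) == 3) {
      if (dim(arr)[3] == 1) {
        arr <- arr[, , 1]
      } else if (is.null(slice)) {
        abort_mvmar("3-D volume: pass an explicit slice index via `slice` (CLI flag --slice)",
                    "mvmar_validation_error")
      } else {
        arr <- arr[, , slice]
      }
    }
    slice_image(arr, pixel_spacing %||% spacing, modality)
  } else {
    vals <- as.matrix(utils::read.csv(path, header = FALSE))
    sidecar <- paste0(path, ".json")
    meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
    slice_image(unname(vals),
                pixel_spacing %||% meta$pixel_spacing %||% 1,
                meta$modality %||% modality)
  }
}

#' Write a CT slice to disk
#'
#' @param img a [slice_image()].
#' @param path output path; `.nii`/`.nii.gz` writes NIfTI with the spacing
#'   in the header, `.csv` writes the value matrix plus a JSON sidecar with
#'   spacing and modality.
#' @return the path, invisibly.
#' @export
write_slice <- function(img, path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    vol <- RNifti::asNifti(img$values)
    RNifti::pixdim(vol) <- c(img$pixel_spacing, img$pixel_spacing)
    RNifti::writeNifti(vol, path, datatype = "double")
  } else if (grepl("\\.csv$", path)) {
    utils::write.table(format(img$values, digits = 17, scientific = TRUE, trim = TRUE),
                       path, sep = ",", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    jsonlite::write_json(list(pixel_spacing = img$pixel_spacing,
                              modality = img$modality),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  } else {
    abort_mvmar(sprintf("unknown slice format for '%s'", path), "mvmar_io_error")
  }
  invisible(path)
}

#' DICOM-style rescale to Hounsfield units
#'
#' Applies `HU = slope * stored + intercept`, the rescale convention of CT
#' DICOM files, to raw stored values.
#'
#' @param stored numeric stored values.
#' @param slope,intercept rescale parameters.
#' @return HU values.
#' @examples
#' apply_rescale(1024, 1, -1024) # 0 HU
#' @export
apply_rescale <- function(stored, slope = 1, intercept = 0) {
  slope * stored + intercept
}

#' Window/level display presets
#'
#' Standard head display windows: `bone` (level 450 / width 1600), `soft`
#' (40 / 400), `lung` (-400 / 1500).
#'
#' @format named list of `c(level, width)` pairs.
#' @export
wl_presets <- list(
  bone = c(level = 450, width = 1600),
  soft = c(level = 40, width = 400),
  lung = c(level = -400, width = 1500)
)

#' Write a slice as a windowed PNG
#'
#' @param img a [slice_image()].
#' @param path output PNG path.
#' @param window preset name from [wl_presets] or `c(level, width)`.
#' @return the path, invisibly.
#' @export
write_png_slice <- function(img, path, window = "soft") {
  wl <- if (is.character(window)) {
    if (!window %in% names(wl_presets)) {
      abort_mvmar(sprintf("unknown window preset '%s'", window), "mvmar_config_error")
    }
    wl_presets[[window]]
  } else window
  lo <- wl[1] - wl[2] / 2; hi <- wl[1] + wl[2] / 2
  g <- pmin(pmax((img$values - lo) / (hi - lo), 0), 1)
  png::writePNG(g, path)
  invisible(path)
}

#' Write a label PNG of tissue masks
#'
#' Encodes M3/M2/M1 as gray levels 1/2/3 (of 3) with background metal-free
#' coding preserved for quick visual checks.
#'
#' @param masks a [tissue_masks()].
#' @param path output PNG path.
#' @return the path, invisibly.
#' @export
write_mask_png <- function(masks, path) {
  lab <- masks$m3 * 1 + masks$m2 * 2 + masks$m1 * 3
  png::writePNG(lab / 3, path)
  invisible(path)
}

# Provenance sidecar: everything needed to regenerate an artifact (config
# echo, seed, package version).  Deliberately excludes timestamps so
# repeated runs with the same seed are bit-identical.
write_provenance <- function(path, payload) {
  payload$package <- "mvmar"
  payload$version <- as.character(utils::packageVersion("mvmar"))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
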