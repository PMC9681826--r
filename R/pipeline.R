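# End-to-end orchestration: calibrate? -> index -> detect -> evaluate? ->
# vectorize -> prescription, with a JSON manifest recording every parameter,
# input checksum and output so a manually tuned run is reproducible.

#' Validate a pipeline configuration
#'
#' Checks structure and types before any I/O. Required fields: `input`
#' (multispectral raster path), `index` (index name), `output_dir`. Optional:
#' `calibration` (`panel_reflectance`, `panel_dn`), `band_map` (`index`,
#' `center`, `half_width`), `detection` (fields of [detection_config()]),
#' `reference` (reference mask path), `prescription` (`cell_size`, `theta`).
#'
#' @param config named list (e.g. parsed from YAML).
#' @return The config with defaults filled in; errors on the first defect.
#' @export
validate_pipeline_config <- function(config) {
  if (!is.list(config)) stop("config must be a list", call. = FALSE)
  for (field in c("input", "index", "output_dir")) {
    if (is.null(config[[field]])) {
      stop("config is missing required field '", field, "'", call. = FALSE)
    }
  }
  known <- c("NDVI", "GNDVI", "LCI", "NDRE", "OSAVI", "WDVI_NIR",
             paste0("WDVI", 1:5))
  if (!config$index %in% known) {
    stop("unknown index '", config$index, "'; expected one of ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  if (!is.null(config$calibration)) {
    cal <- config$calibration
    if (is.null(cal$panel_reflectance) || is.null(cal$panel_dn)) {
      stop("calibration needs panel_reflectance and panel_dn", call. = FALSE)
    }
  }
  det <- config$detection %||% list()
  config$detection <- detection_config(
    levels = det$levels %||% 256L,
    range = det$range,
    slice = det$slice %||% c(0L, 5L),
    weed_inside = det$weed_inside %||% TRUE,
    majority = det$majority %||% 27L,
    clump_kernels = if (!is.null(det$clump_kernels))
      as.integer(unlist(det$clump_kernels)) else c(3L, 3L)
  )
  pres <- config$prescription %||% list()
  config$prescription <- list(cell_size = pres$cell_size %||% 1,
                              theta = pres$theta %||% 0)
  if (config$prescription$cell_size <= 0) {
    stop("prescription cell_size must be positive", call. = FALSE)
  }
  config
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file mirroring the [validate_pipeline_config()] schema.
#' @return validated config list.
#' @export
read_pipeline_config <- function(path) {
  validate_pipeline_config(yaml::read_yaml(path))
}

#' Run the full weed-mapping pipeline
#'
#' Executes calibration (if configured), index computation, the detection
#' chain, evaluation against a reference (if given), vectorization and
#' prescription gridding, writing all products and a `manifest.json` under
#' `config$output_dir`. Any stage failure aborts with the stage name; stages
#' completed so far are flagged in the manifest.
#'
#' @param config list per [validate_pipeline_config()], or a YAML file path.
#' @return the manifest, invisibly (list with `parameters`, `inputs`,
#'   `stages`, `outputs` and `evaluation` when a reference was supplied).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_pipeline_config(config)
  if (!file.exists(config$input)) {
    stop("input raster '", config$input, "' does not exist", call. = FALSE)
  }
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    parameters = config[setdiff(names(config), "output_dir")],
    inputs = list(input = list(path = config$input,
                               md5 = unname(tools::md5sum(config$input)))),
    stages = list(), outputs = list()
  )
  done <- function(stage, ...) {
    manifest$stages[[length(manifest$stages) + 1L]] <<-
      c(list(stage = stage, status = "ok"), list(...))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      manifest$stages[[length(manifest$stages) + 1L]] <<-
        list(stage = stage, status = "failed", error = conditionMessage(e))
      manifest$partial <<- TRUE
      write_manifest(manifest, out_dir)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  bm <- if (!is.null(config$band_map)) {
    do.call(band_map, lapply(config$band_map, unlist))
  } else band_map()

  image <- run_stage("read", read_multispectral(config$input, band_map = bm))
  done("read", pixels = prod(dim(image)), valid = sum(image$valid_mask))

  if (!is.null(config$calibration)) {
    cal <- panel_calibration(config$calibration$panel_reflectance,
                             unlist(config$calibration$panel_dn))
    image <- run_stage("calibrate", calibrate_reflectance(image, cal))
    done("calibrate", panel_reflectance = cal$panel_reflectance)
  }

  idx <- run_stage("index", compute_index(image, config$index))
  idx_path <- file.path(out_dir, "index.tif")
  write_raster(idx, path = idx_path)
  done("index", name = idx$index_name, valid = sum(idx$valid_mask))
  manifest$outputs$index <- idx_path

  mask <- run_stage("detect", detect(idx, config$detection))
  mask_path <- file.path(out_dir, "mask.tif")
  write_raster(mask, path = mask_path)
  done("detect", weed_pixels = sum(mask$values),
       provenance = mask$provenance)
  manifest$outputs$mask <- mask_path

  if (!is.null(config$reference)) {
    ref <- run_stage("evaluate", load_reference_mask(config$reference))
    report <- run_stage("evaluate", evaluate_mask(mask, ref))
    manifest$evaluation <- report[c("tp", "fp", "fn", "tn", "n_evaluated",
                                    "overall_accuracy", "kappa")]
    report_path <- file.path(out_dir, "report.json")
    jsonlite::write_json(manifest$evaluation, report_path, auto_unbox = TRUE,
                         digits = NA)
    done("evaluate", overall_accuracy = report$overall_accuracy,
         kappa = report$kappa)
    manifest$outputs$report <- report_path
  }

  polys <- run_stage("vectorize", vectorize_mask(mask))
  vec_path <- file.path(out_dir, "weeds.geojson")
  write_vector(polys, vec_path, crs = mask$crs)
  done("vectorize", n_polygons = length(polys))
  manifest$outputs$vector <- vec_path

  grid <- run_stage("prescription",
                    resample_to_grid(mask,
                                     cell_size = config$prescription$cell_size,
                                     theta = config$prescription$theta))
  pres_path <- file.path(out_dir, "prescription.tif")
  write_prescription(grid, pres_path, format = "GeoTIFF")
  pres_vec <- file.path(out_dir, "prescription.geojson")
  write_prescription(grid, pres_vec, format = "GeoJSON")
  done("prescription", spray_cells = sum(grid$spray, na.rm = TRUE),
       cells = sum(!is.na(grid$spray)))
  manifest$outputs$prescription <- pres_path
  manifest$outputs$prescription_cells <- pres_vec

  manifest$outputs <- lapply(manifest$outputs, function(p) {
    list(path = p, md5 = unname(tools::md5sum(p)))
  })
  write_manifest(manifest, out_dir)
  invisible(manifest)
}

#' @noRd
write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
}
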