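## Re-importable settings: one JSON file carries the full configuration of
## the pipeline (filters, binarization, sensing, tracing, tracking, cell
## events, export toggles), with a schema version and strict unknown-key
## checking, so a single-file analysis is reproducible in batch mode.

SETTINGS_SCHEMA_VERSION <- 1L

#' Default analysis settings
#'
#' @param pipeline `fs_pipeline` filter pipeline.
#' @param binarization list `(method, params)`.
#' @param sensor `fs_sensor_settings`.
#' @param tracer `fs_tracer_settings`.
#' @param tracking `fs_tracking_settings`.
#' @param cell_events list `(min_area, intersect_tolerance)`.
#' @param export list of toggles `(filaments, cells, tracking, events,
#'   overlays)` and `tracking_layout`.
#' @param mode `"curved"` or `"straight"` detection mode.
#' @return list of class `fs_settings`.
#' @export
fs_settings <- function(pipeline = filter_pipeline(),
                        binarization = list(method = "global_otsu",
                                            params = list()),
                        sensor = sensor_settings(),
                        tracer = tracer_settings(),
                        tracking = tracking_settings(),
                        cell_events = list(min_area = 50,
                                           intersect_tolerance = 0.2),
                        export = list(filaments = TRUE, cells = TRUE,
                                      tracking = TRUE, events = TRUE,
                                      overlays = FALSE,
                                      tracking_layout = "by_frame"),
                        mode = c("curved", "straight")) {
  mode <- match.arg(mode)
  structure(list(schema_version = SETTINGS_SCHEMA_VERSION,
                 pipeline = pipeline, binarization = binarization,
                 sensor = sensor, tracer = tracer, tracking = tracking,
                 cell_events = cell_events, export = export, mode = mode),
            class = "fs_settings")
}

#' Save settings to JSON
#' @param s `fs_settings`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_settings <- function(s, path) {
  stopifnot(inherits(s, "fs_settings"))
  payload <- list(
    schema_version = s$schema_version,
    pipeline = lapply(s$pipeline, function(st)
      list(name = st$name, params = st$params)),
    binarization = s$binarization,
    sensor = unclass(s$sensor),
    tracer = unclass(s$tracer),
    tracking = unclass(s$tracking),
    cell_events = s$cell_events,
    export = s$export,
    mode = s$mode
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load settings from JSON
#'
#' Strict: an unsupported schema version or any unknown key is an error
#' naming the offender. `load_settings(save_settings(s)) == s` field for
#' field.
#'
#' @param path settings JSON path.
#' @return `fs_settings`.
#' @export
load_settings <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  known_top <- c("schema_version", "pipeline", "binarization", "sensor",
                 "tracer", "tracking", "cell_events", "export", "mode")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown))
    stop("unknown settings key(s): ", paste(unknown, collapse = ", "))
  if (is.null(raw$schema_version) ||
      raw$schema_version != SETTINGS_SCHEMA_VERSION)
    stop("unsupported settings schema version: ",
         if (is.null(raw$schema_version)) "<missing>" else raw$schema_version)
  check_keys <- function(x, allowed, where) {
    unknown <- setdiff(names(x), allowed)
    if (length(unknown))
      stop("unknown settings key(s) in ", where, ": ",
           paste(unknown, collapse = ", "))
  }
  check_keys(raw$sensor, names(formals(sensor_settings)), "sensor")
  check_keys(raw$tracer, names(formals(tracer_settings)), "tracer")
  check_keys(raw$tracking, names(formals(tracking_settings)), "tracking")
  check_keys(raw$cell_events, c("min_area", "intersect_tolerance"),
             "cell_events")
  num <- function(x) lapply(x, function(v) if (is.logical(v)) v else as.numeric(v))
  pipe <- do.call(filter_pipeline, lapply(raw$pipeline, function(st)
    list(name = st$name, params = lapply(st$params, as.numeric))))
  fs_settings(
    pipeline = pipe,
    binarization = list(method = raw$binarization$method,
                        params = lapply(raw$binarization$params, as.numeric)),
    sensor = do.call(sensor_settings, num(raw$sensor)),
    tracer = do.call(tracer_settings, num(raw$tracer)),
    tracking = do.call(tracking_settings, num(raw$tracking)),
    cell_events = lapply(raw$cell_events, as.numeric),
    export = lapply(raw$export, function(v)
      if (is.character(v)) v else as.logical(v)),
    mode = raw$mode
  )
}
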