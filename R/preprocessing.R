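## Preprocessing: image loading, a registry-backed filter pipeline, and
## binarization.  The pipeline mirrors the "saveable and importable filter
## list" idea: filters are registered by name with a parameter schema, the
## pipeline itself is a plain ordered list serializable to JSON, and adding
## a filter never touches the pipeline machinery.

#' Load a grayscale image plane
#'
#' Reads TIFF (single or multi-page, uncompressed grayscale) or PNG. RGB PNG
#' input is reduced to one plane by Rec. 601 luminance, or a single channel
#' when `channel` is given — fluorescence channels are semantically distinct,
#' so channel selection is explicit rather than silent.
#'
#' @param path image file path.
#' @param frame_index 1-based page of a multi-page stack (default first).
#' @param channel optional channel index (1..3) for RGB input; default uses
#'   luminance `0.299 R + 0.587 G + 0.114 B`.
#' @return numeric matrix of intensities.
#' @export
load_image <- function(path, frame_index = NULL, channel = NULL) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    read_tiff(path, frame_index = if (is.null(frame_index)) 1L else frame_index)
  } else if (ext == "png") {
    if (!is.null(frame_index) && frame_index != 1L)
      stop("frame_index ", frame_index, " out of range (PNG has 1 page)")
    read_png(path)
  } else stop("unsupported image format: .", ext)
  if (is.array(img) && length(dim(img)) == 3L) {
    img <- if (!is.null(channel)) {
      stopifnot(channel >= 1L, channel <= dim(img)[3])
      img[, , channel]
    } else {
      0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    }
  }
  storage.mode(img) <- "double"
  img
}

## ---------------------------------------------------------------------------
## Filter registry

.filter_registry <- new.env(parent = emptyenv())

#' Register an image filter
#'
#' @param name filter name used in pipelines.
#' @param fun function `(img, params)` returning a same-shape matrix.
#' @param params named list of parameter schemas, each
#'   `list(default =, min =, max =)`.
#' @export
register_filter <- function(name, fun, params = list()) {
  assign(name, list(fun = fun, params = params), envir = .filter_registry)
  invisible(name)
}

#' List registered filter names
#' @return character vector.
#' @export
list_filters <- function() sort(ls(.filter_registry))

## 2D convolution, zero-padded, via FFT; kernel dims must be odd.
conv2 <- function(img, kern) {
  kh <- nrow(kern); kw <- ncol(kern)
  ph <- nrow(img) + kh - 1L; pw <- ncol(img) + kw - 1L
  a <- matrix(0, ph, pw); a[seq_len(nrow(img)), seq_len(ncol(img))] <- img
  b <- matrix(0, ph, pw); b[seq_len(kh), seq_len(kw)] <- kern
  full <- Re(fft(fft(a) * fft(b), inverse = TRUE)) / (ph * pw)
  oy <- (kh - 1L) %/% 2L; ox <- (kw - 1L) %/% 2L
  full[oy + seq_len(nrow(img)), ox + seq_len(ncol(img)), drop = FALSE]
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  g <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

local({
  register_filter("gaussian", function(img, params) {
    conv2(img, gaussian_kernel(params$sigma))
  }, params = list(sigma = list(default = 1, min = 0.2, max = 50)))

  register_filter("box_mean", function(img, params) {
    k <- as.integer(params$size)
    conv2(img, matrix(1 / k^2, k, k))
  }, params = list(size = list(default = 3, min = 1, max = 99)))

  ## 4-neighbor discrete Laplacian; zero response on constant images.
  register_filter("laplace", function(img, params) {
    kern <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
    conv2(img, kern)
  }, params = list())

  register_filter("invert", function(img, params) {
    max(img) - img
  }, params = list())

  ## affine rescale to [0, scale]
  register_filter("normalize", function(img, params) {
    rng <- range(img)
    if (diff(rng) == 0) return(img * 0)
    (img - rng[1]) / diff(rng) * params$scale
  }, params = list(scale = list(default = 255, min = 1, max = 65535)))
})

#' Construct a filter pipeline
#'
#' @param ... filter steps, each `list(name = "gaussian", params = list(...))`
#'   or just a filter name for all-default parameters.
#' @return object of class `fs_pipeline` (ordered list of steps).
#' @export
filter_pipeline <- function(...) {
  steps <- lapply(list(...), function(s) {
    if (is.character(s)) s <- list(name = s, params = list())
    if (is.null(s$params)) s$params <- list()
    validate_filter_step(s)
    s
  })
  structure(steps, class = "fs_pipeline")
}

validate_filter_step <- function(step) {
  if (!exists(step$name, envir = .filter_registry))
    stop("unknown filter name: '", step$name, "' (registered: ",
         paste(list_filters(), collapse = ", "), ")")
  reg <- get(step$name, envir = .filter_registry)
  for (p in names(step$params)) {
    schema <- reg$params[[p]]
    if (is.null(schema)) stop("filter '", step$name, "' has no parameter '", p, "'")
    v <- step$params[[p]]
    if (!is.numeric(v) || v < schema$min || v > schema$max)
      stop("parameter '", p, "' of filter '", step$name, "' out of range [",
           schema$min, ", ", schema$max, "]")
  }
  invisible(TRUE)
}

#' Apply a filter pipeline to an image
#'
#' The empty pipeline is the identity. Application is associative with
#' pipeline concatenation.
#'
#' @param img numeric matrix.
#' @param pipe `fs_pipeline` object.
#' @return filtered matrix, same shape.
#' @export
apply_pipeline <- function(img, pipe) {
  stopifnot(inherits(pipe, "fs_pipeline"))
  dims <- dim(img)
  for (step in pipe) {
    reg <- get(step$name, envir = .filter_registry)
    params <- lapply(reg$params, function(s) s$default)
    params[names(step$params)] <- step$params
    img <- reg$fun(img, params)
    stopifnot(identical(dim(img), dims))
  }
  img
}

#' Concatenate filter pipelines
#' @param a,b `fs_pipeline` objects.
#' @return combined `fs_pipeline`.
#' @export
concat_pipelines <- function(a, b) {
  structure(c(unclass(a), unclass(b)), class = "fs_pipeline")
}

#' Serialize / parse a filter pipeline as JSON
#'
#' The on-disk form is a JSON array of `{"name": ..., "params": {...}}`,
#' re-importable across runs and into batch mode.
#'
#' @param pipe `fs_pipeline`.
#' @param path file path.
#' @return `pipeline_to_json` returns `path` invisibly;
#'   `pipeline_from_json` returns an `fs_pipeline`.
#' @export
pipeline_to_json <- function(pipe, path) {
  steps <- lapply(pipe, function(s)
    list(name = jsonlite::unbox(s$name), params = lapply(s$params, jsonlite::unbox)))
  jsonlite::write_json(steps, path, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_to_json
#' @export
pipeline_from_json <- function(path) {
  steps <- jsonlite::read_json(path, simplifyVector = FALSE)
  do.call(filter_pipeline, lapply(steps, function(s)
    list(name = s$name, params = lapply(s$params, as.numeric))))
}

## ---------------------------------------------------------------------------
## Binarization

#' Binarize a grayscale image
#'
#' Methods: `global_otsu` (256-bin Otsu threshold; a constant image yields an
#' empty foreground), `local_mean` (pixel brighter than the mean of its
#' `size`-neighborhood plus `offset`), `fixed_threshold` (foreground strictly
#' above `t`). Deterministic for fixed input and parameters.
#'
#' @param img numeric matrix.
#' @param method one of `"global_otsu"`, `"local_mean"`, `"fixed_threshold"`.
#' @param params method parameters (`t` for fixed_threshold; `size`, `offset`
#'   for local_mean).
#' @return logical matrix, `TRUE` = foreground.
#' @export
binarize <- function(img, method = "global_otsu", params = list()) {
  switch(method,
    fixed_threshold = {
      t <- params$t
      if (is.null(t)) stop("fixed_threshold requires parameter 't'")
      img > t
    },
    global_otsu = {
      rng <- range(img)
      if (diff(rng) == 0) return(matrix(FALSE, nrow(img), ncol(img)))
      img > otsu_threshold(img)
    },
    local_mean = {
      size <- if (is.null(params$size)) 15L else as.integer(params$size)
      offset <- if (is.null(params$offset)) 0 else params$offset
      if (size %% 2L == 0L) size <- size + 1L
      mu <- conv2(img, matrix(1 / size^2, size, size))
      img > mu + offset
    },
    stop("unknown binarization method: ", method)
  )
}

## Otsu's between-class-variance maximizing threshold over 256 bins spanning
## the intensity range; returns a value in intensity units.
otsu_threshold <- function(img) {
  rng <- range(img)
  nb <- 256L
  bins <- pmin(nb, 1L + floor((img - rng[1]) / diff(rng) * nb))
  h <- tabulate(bins, nbins = nb)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nb))
  mu_t <- mu[nb]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b)  # first maximum: deterministic tie-break
  rng[1] + k / nb * diff(rng)
}
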