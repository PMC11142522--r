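#' Acquired image series
#'
#' An `image_series` is a 4D stack (x, y, z, measurement) of magnitude or
#' complex volumes together with the metadata describing the measurement
#' axis: echo times, inversion times, flip angles, a diffusion scheme, or
#' the magnetization-transfer saturation condition of each volume.
#'
#' @param data 4D numeric or complex array (x, y, z, measurement).
#' @param axis_kind One of `"te_ms"`, `"ti_ms"`, `"flip_deg"`, `"diffusion"`,
#'   `"mt_condition"`.
#' @param axis_values Numeric vector (TE/TI/flip), a list with `bvalues` and
#'   `directions` (diffusion), or a character vector of MT conditions from
#'   `c("S0", "S+", "S-", "S+-", "S-+")`; its length must equal the fourth
#'   array dimension.
#' @param voxel_mm Voxel size, three positive reals.
#' @param tr_ms Optional repetition time in ms (needed by steady-state fits).
#' @return An object of class `image_series`.
#' @export
image_series <- function(data, axis_kind, axis_values, voxel_mm = c(1, 1, 1),
                         tr_ms = NULL) {
  stopifnot(length(dim(data)) == 4)
  axis_kind <- match.arg(axis_kind,
                         c("te_ms", "ti_ms", "flip_deg", "diffusion",
                           "mt_condition"))
  n <- dim(data)[4]
  len <- if (axis_kind == "diffusion") length(axis_values$bvalues)
         else length(axis_values)
  if (len != n) {
    stop("measurement axis metadata length (", len,
         ") does not match the series length (", n, ")", call. = FALSE)
  }
  if (!is.complex(data) && any(data < 0, na.rm = TRUE)) {
    stop("magnitude series must be non-negative", call. = FALSE)
  }
  structure(list(data = data, axis_kind = axis_kind, axis_values = axis_values,
                 voxel_mm = as.numeric(voxel_mm), tr_ms = tr_ms),
            class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_series> %dx%dx%d x %d [%s, %s]\n", d[1], d[2], d[3],
              d[4], x$axis_kind, if (is.complex(x$data)) "complex" else "magnitude"))
  invisible(x)
}

# Flatten the spatial dimensions: returns nvox x nmeas matrix.
series_matrix <- function(series) {
  d <- dim(series$data)
  matrix(series$data, prod(d[1:3]), d[4])
}

# Rebuild a 3D volume from a per-voxel vector.
vec_to_vol <- function(v, dim3) array(v, dim3)

#' Fitted quantitative parameter map
#'
#' A 3D parameter volume with its map type, physical units and a validity
#' mask. Invalid voxels carry `NA` in `data` and `FALSE` in `valid`.
#'
#' @param data 3D numeric array of parameter values.
#' @param map_type One of `"T1"`, `"T2"`, `"T2star"`, `"QSM"`, `"WF"`,
#'   `"MTVF"`, `"MD"`, `"FA"`, `"MTR"`, `"ihMTR"`, `"B1"`.
#' @param valid Optional 3D logical array; defaults to `is.finite(data)`.
#' @return An object of class `quantitative_map`.
#' @export
quantitative_map <- function(data, map_type, valid = NULL) {
  map_type <- match.arg(map_type, MAP_TYPES)
  if (is.null(valid)) valid <- is.finite(data)
  stopifnot(identical(dim(data), dim(valid)))
  data[!valid] <- NA_real_
  structure(list(map_type = map_type, data = data,
                 units = map_units(map_type), valid = valid),
            class = "quantitative_map")
}

#' @export
print.quantitative_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<quantitative_map %s [%s]> %dx%dx%d, %d valid voxels\n",
              x$map_type, x$units, d[1], d[2], d[3], sum(x$valid)))
  invisible(x)
}
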