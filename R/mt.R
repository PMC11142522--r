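#' Five-image inhomogeneous magnetization-transfer set
#'
#' Holds the unsaturated volume S0 and the four saturated volumes of an
#' ihMT acquisition: single-offset positive (S+), single-offset negative
#' (S-), and the two alternated dual-offset volumes (S+-, S-+), all on a
#' common grid.
#'
#' @param s0,s_plus,s_minus,s_dual_pm,s_dual_mp 3D non-negative arrays of
#'   identical dimension.
#' @return An object of class `ihmt_set`.
#' @export
ihmt_set <- function(s0, s_plus, s_minus, s_dual_pm, s_dual_mp) {
  vols <- list(s0 = s0, s_plus = s_plus, s_minus = s_minus,
               s_dual_pm = s_dual_pm, s_dual_mp = s_dual_mp)
  d <- dim(s0)
  for (nm in names(vols)) {
    if (!identical(dim(vols[[nm]]), d)) {
      stop("ihMT volume '", nm, "' does not match the S0 grid", call. = FALSE)
    }
    if (any(vols[[nm]] < 0, na.rm = TRUE)) {
      stop("ihMT volumes must be non-negative", call. = FALSE)
    }
  }
  structure(vols, class = "ihmt_set")
}

# Build an ihmt_set from an image_series carrying mt_condition labels.
ihmt_set_from_series <- function(series) {
  stopifnot(inherits(series, "image_series"),
            series$axis_kind == "mt_condition")
  cond <- series$axis_values
  pick <- function(lab) {
    i <- match(lab, cond)
    if (is.na(i)) stop("missing MT condition: ", lab, call. = FALSE)
    series$data[, , , i]
  }
  ihmt_set(pick("S0"), pick("S+"), pick("S-"), pick("S+-"), pick("S-+"))
}

#' Magnetization-transfer ratio maps
#'
#' Voxel-wise evaluation of MTR = 1 - S+/S0 and
#' ihMTR = ((S+ + S-) - (S+- + S-+)) / S0, both expressed in percent.
#' Voxels with S0 = 0 are invalid. Both ratios are invariant to a common
#' positive scaling of all five images. Optionally also returns the
#' dual-saturation ratio MTRd = 1 - S+-/S0.
#'
#' @param set An [ihmt_set()].
#' @param mtrd Also compute the dual-saturation MTR (off by default).
#' @return List with `mtr` and `ihmtr` [quantitative_map()]s in percent
#'   (and `mtrd`, a plain 3D array, when requested).
#' @export
compute_mtr_ihmtr <- function(set, mtrd = FALSE) {
  stopifnot(inherits(set, "ihmt_set"))
  ok <- is.finite(set$s0) & set$s0 > 0
  s0 <- ifelse(ok, set$s0, NA_real_)
  mtr <- 100 * (1 - set$s_plus / s0)
  ihmtr <- 100 * ((set$s_plus + set$s_minus) -
                    (set$s_dual_pm + set$s_dual_mp)) / s0
  out <- list(mtr = quantitative_map(mtr, "MTR", valid = ok & is.finite(mtr)),
              ihmtr = quantitative_map(ihmtr, "ihMTR",
                                       valid = ok & is.finite(ihmtr)))
  if (mtrd) out$mtrd <- 100 * (1 - set$s_dual_pm / s0)
  out
}
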