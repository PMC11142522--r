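#' Single-voxel erosion of one ROI
#'
#' Extracts the mask of one label and erodes it by one voxel with the
#' 6-connected structuring element, reducing partial-volume contamination
#' at ROI boundaries. The result may be empty.
#'
#' @param labels 3D integer label volume.
#' @param roi_id Label value to extract (must be present in `labels`).
#' @return 3D logical mask.
#' @export
erode_roi <- function(labels, roi_id) {
  if (!any(labels == roi_id)) stop("label ", roi_id, " not present", call. = FALSE)
  erode6(labels == roi_id)
}

#' Weak Chauvenet outlier exclusion
#'
#' Single non-iterated pass: values deviating more than `k` sample
#' standard deviations from the mean are excluded. With Gaussian data and
#' k = 3 the expected exclusion fraction is about 0.27 percent.
#'
#' @param values Numeric vector (length at least 2).
#' @param k SD multiple (default 3).
#' @return List with `values` (retained), `n_excluded`, and `keep`
#'   (logical index into the input).
#' @export
chauvenet_filter <- function(values, k = 3) {
  stopifnot(length(values) >= 2)
  mu <- mean(values)
  s <- stats::sd(values)
  keep <- if (is.na(s) || s == 0) rep(TRUE, length(values))
          else abs(values - mu) <= k * s
  list(values = values[keep], n_excluded = sum(!keep), keep = keep)
}

#' Filtered ROI value extraction
#'
#' Values of a quantitative map over one eroded ROI after the study's
#' exclusion rules: voxels with zero or invalid map values are removed
#' first (fitting failures and masking produce zeros, not data), then the
#' weak Chauvenet criterion drops outliers beyond `k` SD. The reported
#' voxel count refers to the retained map values, not the label volume.
#'
#' @param map A [quantitative_map()] (or plain 3D array).
#' @param labels 3D integer label volume on the same grid.
#' @param roi_id Label to extract.
#' @param k Chauvenet SD multiple.
#' @return List with `values`, `n_voxels` (retained count), `n_excluded`
#'   (Chauvenet exclusions), and `empty` flag.
#' @export
roi_values <- function(map, labels, roi_id, k = 3) {
  dat <- if (inherits(map, "quantitative_map")) map$data else map
  stopifnot(identical(dim(dat), dim(labels)))
  mask <- erode_roi(labels, roi_id)
  v <- dat[mask]
  v <- v[is.finite(v) & v != 0]
  if (length(v) < 2) {
    return(list(values = v, n_voxels = length(v), n_excluded = 0L,
                empty = length(v) == 0))
  }
  cf <- chauvenet_filter(v, k = k)
  list(values = cf$values, n_voxels = length(cf$values),
       n_excluded = cf$n_excluded, empty = length(cf$values) == 0)
}

#' Per-subject ROI summaries for a set of maps
#'
#' Applies [roi_values()] to every (map, ROI) pair and returns one row per
#' pair with the subject's within-ROI mean, SD and retained voxel count.
#'
#' @param maps Named list of [quantitative_map()]s (names = map types).
#' @param labels 3D integer label volume.
#' @param roi_ids Integer labels to summarize (default: the 12 study ROIs).
#' @param subject,session Identifiers copied into the output.
#' @return data.frame with columns `subject`, `session`, `map`, `roi`,
#'   `n_voxels`, `mean`, `sd`.
#' @export
subject_roi_summary <- function(maps, labels, roi_ids = 1:12,
                                subject = 1L, session = 1L) {
  rois <- roi_labels()
  rows <- list()
  for (mt in names(maps)) {
    for (id in roi_ids) {
      rv <- roi_values(maps[[mt]], labels, id)
      rows[[length(rows) + 1]] <- data.frame(
        subject = subject, session = session, map = mt,
        roi = rois$name[match(id, rois$id)],
        n_voxels = rv$n_voxels,
        mean = if (rv$empty) NA_real_ else mean(rv$values),
        sd = if (length(rv$values) > 1) stats::sd(rv$values) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Cohort variability table
#'
#' Aggregates per-subject ROI summaries into the study's variability
#' table: per (map, ROI), the mean of per-subject means, their SD across
#' subjects (inter-subject variability), the mean of per-subject
#' within-ROI SDs (intra-ROI variability), coefficients of variation
#' (CV = 100 SD / mean, sign carried by the mean), and voxel-count
#' statistics.
#'
#' @param summaries data.frame as produced by rbind-ing
#'   [subject_roi_summary()] over at least two subjects.
#' @return data.frame with columns `map`, `roi`, `n_mean`, `n_sd`,
#'   `n_cv_pct`, `mean`, `sd_inter`, `cv_pct`, `sd_intra`.
#' @export
summarize_cohort <- function(summaries) {
  if (length(unique(summaries$subject)) < 2) {
    stop("at least two subjects are required", call. = FALSE)
  }
  sp <- split(summaries, list(summaries$map, summaries$roi), drop = TRUE)
  rows <- lapply(sp, function(g) {
    data.frame(map = g$map[1], roi = g$roi[1],
               n_mean = mean(g$n_voxels), n_sd = stats::sd(g$n_voxels),
               n_cv_pct = 100 * stats::sd(g$n_voxels) / mean(g$n_voxels),
               mean = mean(g$mean, na.rm = TRUE),
               sd_inter = stats::sd(g$mean, na.rm = TRUE),
               cv_pct = 100 * stats::sd(g$mean, na.rm = TRUE) /
                 mean(g$mean, na.rm = TRUE),
               sd_intra = mean(g$sd, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(match(out$map, MAP_TYPES), match(out$roi, roi_labels()$name)), ]
}

#' Mean intra-ROI to inter-subject variability ratio
#'
#' The headline summary of a variability table: the ratio
#' sd_intra / sd_inter per (map, ROI) cell, averaged either over all cells
#' (`by = "pooled"`) or per map first (`by = "map"`; the mean is identical
#' for equal group sizes, the spread differs).
#'
#' @param tab Variability table in the layout of [summarize_cohort()] /
#'   [roi_reference_table()].
#' @param by Averaging mode.
#' @return List with `mean` and `sd` of the ratios.
#' @export
variability_ratio <- function(tab, by = c("pooled", "map")) {
  by <- match.arg(by)
  r <- tab$sd_intra / tab$sd_inter
  if (by == "map") {
    m <- tapply(r, tab$map, mean)
    list(mean = mean(m), sd = stats::sd(as.vector(m)))
  } else {
    list(mean = mean(r), sd = stats::sd(r))
  }
}

#' Right-left hemispheric regression
#'
#' Ordinary least squares of left-hemisphere on right-hemisphere ROI means
#' pooled over subjects and ROIs, with Pearson's r and the two-sided
#' p-value from t = r sqrt((n-2)/(1-r^2)).
#'
#' @param left,right Paired numeric vectors (n >= 3).
#' @return List with `slope`, `intercept`, `r`, `p_value`, `n`.
#' @export
lr_regression <- function(left, right) {
  ok <- is.finite(left) & is.finite(right)
  left <- left[ok]; right <- right[ok]
  n <- length(left)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(right) == 0 || stats::sd(left) == 0) {
    stop("zero variance in hemispheric means", call. = FALSE)
  }
  fit <- stats::lm(left ~ right)
  r <- stats::cor(left, right)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  if (abs(r) == 1) p <- 0
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), r = r, p_value = p, n = n)
}

#' Hemispheric ROI means of one map
#'
#' Splits each bilateral ROI at the mid-sagittal plane (first axis) and
#' returns the filtered left and right means.
#'
#' @param map A [quantitative_map()] (or 3D array).
#' @param labels 3D integer label volume.
#' @param roi_id Label to extract.
#' @return List with `left` and `right` means (`NA` when empty).
#' @export
hemisphere_means <- function(map, labels, roi_id) {
  d <- dim(labels)
  half <- d[1] / 2
  xidx <- slice.index(labels, 1)
  lab_l <- labels; lab_l[xidx > half] <- 0L
  lab_r <- labels; lab_r[xidx <= half] <- 0L
  get_mean <- function(lab) {
    if (!any(lab == roi_id)) return(NA_real_)
    rv <- roi_values(map, lab, roi_id)
    if (rv$empty) NA_real_ else mean(rv$values)
  }
  list(left = get_mean(lab_l), right = get_mean(lab_r))
}

#' Bland-Altman scan-rescan agreement
#'
#' For paired session means, computes the difference d = s1 - s2 and mean
#' m = (s1 + s2)/2, the mean and sample SD of d, the 95 percent limits of
#' agreement (mean difference +/- 1.96 SD), and the linear regression of d
#' on m (slope, intercept, Pearson r, two-sided p on n - 2 df).
#'
#' @param s1,s2 Paired numeric vectors of session means (n >= 3).
#' @return List with `mean_diff`, `sd_diff`, `loa_upper`, `loa_lower`,
#'   `slope`, `intercept`, `r`, `p_value`, `n_pairs`.
#' @export
bland_altman <- function(s1, s2) {
  ok <- is.finite(s1) & is.finite(s2)
  s1 <- s1[ok]; s2 <- s2[ok]
  n <- length(s1)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  d <- s1 - s2
  m <- (s1 + s2) / 2
  md <- mean(d); sdd <- stats::sd(d)
  if (stats::sd(m) > 0 && sdd > 0) {
    fit <- stats::lm(d ~ m)
    r <- stats::cor(d, m)
    tt <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    slope <- unname(stats::coef(fit)[2]); icpt <- unname(stats::coef(fit)[1])
  } else {
    slope <- 0; icpt <- md; r <- NA_real_; p <- NA_real_
  }
  list(mean_diff = md, sd_diff = sdd,
       loa_upper = md + 1.96 * sdd, loa_lower = md - 1.96 * sdd,
       slope = slope, intercept = icpt, r = r, p_value = p, n_pairs = n)
}
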