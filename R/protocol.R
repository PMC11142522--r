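#' Acquisition protocol representation
#'
#' A `sequence_spec` holds the acquisition parameters of one pulse sequence
#' (TR, echo/inversion times, flip angles, b-values, duration, voxel size);
#' a `sequence_protocol` is an ordered list of such specs with unique names.
#' The packaged default (see [default_protocol()]) describes the eight-sequence
#' 3 T brain protocol used throughout the package, including the short
#' reversed-phase-encode diffusion segment, for a nominal 45:30 min session.
#'
#' @param name Sequence label (unique within a protocol).
#' @param kind One of `"anatomical"`, `"mese"`, `"megre"`, `"irepi"`,
#'   `"vfa"`, `"dwi"`, `"ihmt"`; drives validation and simulation.
#' @param tr_ms Repetition time in ms (positive).
#' @param te_ms Echo times in ms, strictly increasing.
#' @param ti_ms Optional inversion times in ms, strictly increasing.
#' @param flip_deg Excitation flip angles in degrees, each in (0, 180].
#' @param refocus_deg Optional refocusing flip angle in degrees in (0, 180].
#' @param bvalues_s_mm2 Optional diffusion b-values in s/mm^2 (non-negative).
#' @param n_directions Optional number of diffusion gradient directions.
#' @param duration_s Sequence duration in whole seconds.
#' @param voxel_mm Acquired voxel size, three positive reals in mm.
#' @param comments Free-text acquisition notes (acceleration, partial
#'   Fourier, ...); metadata only.
#' @return An object of class `sequence_spec`.
#' @export
sequence_spec <- function(name, kind = "anatomical", tr_ms, te_ms,
                          ti_ms = NULL, flip_deg, refocus_deg = NULL,
                          bvalues_s_mm2 = NULL, n_directions = NULL,
                          duration_s = 0L, voxel_mm = c(1, 1, 1),
                          comments = NULL) {
  kind <- match.arg(kind, c("anatomical", "mese", "megre", "irepi", "vfa",
                            "dwi", "ihmt"))
  stop_field <- function(cond, field, msg) {
    if (cond) stop(sprintf("sequence '%s', field '%s': %s", name, field, msg),
                   call. = FALSE)
  }
  stop_field(!is.character(name) || nchar(name) == 0, "name", "must be non-empty text")
  stop_field(!is.numeric(tr_ms) || length(tr_ms) != 1 || tr_ms <= 0,
             "tr_ms", "must be a positive scalar")
  stop_field(!is.numeric(te_ms) || length(te_ms) < 1 || any(te_ms <= 0),
             "te_ms", "must be positive")
  stop_field(length(te_ms) > 1 && any(diff(te_ms) <= 0),
             "te_ms", "must be strictly increasing")
  if (!is.null(ti_ms)) {
    stop_field(any(ti_ms <= 0) || (length(ti_ms) > 1 && any(diff(ti_ms) <= 0)),
               "ti_ms", "must be positive and strictly increasing")
  }
  stop_field(any(flip_deg <= 0 | flip_deg > 180), "flip_deg",
             "must lie in (0, 180]")
  if (!is.null(refocus_deg)) {
    stop_field(length(refocus_deg) != 1 || refocus_deg <= 0 || refocus_deg > 180,
               "refocus_deg", "must lie in (0, 180]")
  }
  if (!is.null(bvalues_s_mm2)) {
    stop_field(any(bvalues_s_mm2 < 0), "bvalues_s_mm2", "must be non-negative")
  }
  if (!is.null(n_directions)) {
    stop_field(n_directions < 1 || n_directions != round(n_directions),
               "n_directions", "must be a positive integer")
  }
  stop_field(duration_s < 0 || duration_s != round(duration_s),
             "duration_s", "must be a non-negative integer number of seconds")
  stop_field(length(voxel_mm) != 3 || any(voxel_mm <= 0), "voxel_mm",
             "must be three positive reals")
  structure(list(name = name, kind = kind, tr_ms = tr_ms, te_ms = te_ms,
                 ti_ms = ti_ms, flip_deg = flip_deg, refocus_deg = refocus_deg,
                 bvalues_s_mm2 = bvalues_s_mm2,
                 n_directions = if (is.null(n_directions)) NULL else as.integer(n_directions),
                 duration_s = as.integer(duration_s),
                 voxel_mm = as.numeric(voxel_mm), comments = comments),
            class = "sequence_spec")
}

#' @param sequences List of [sequence_spec()] objects.
#' @rdname sequence_spec
#' @export
sequence_protocol <- function(sequences = list()) {
  stopifnot(all(vapply(sequences, inherits, TRUE, "sequence_spec")))
  nm <- vapply(sequences, `[[`, "", "name")
  if (anyDuplicated(nm)) {
    stop("sequence names must be unique: ", paste(nm[duplicated(nm)], collapse = ", "))
  }
  structure(list(sequences = sequences), class = "sequence_protocol")
}

#' @export
print.sequence_protocol <- function(x, ...) {
  cat(sprintf("<sequence_protocol> %d sequences, %.1f min total\n",
              length(x$sequences), total_duration_min(x)))
  for (s in x$sequences) {
    cat(sprintf("  %-10s %-10s TR %g ms, %d TE(s), duration %s\n",
                s$name, s$kind, s$tr_ms, length(s$te_ms),
                format_mmss(s$duration_s)))
  }
  invisible(x)
}

#' Parse and format "mm:ss" durations
#'
#' Durations are stored internally as integer seconds and rendered as
#' `"mm:ss"` only at the file boundary; parse and format are exact inverses.
#'
#' @param x A `"mm:ss"` string (for [parse_mmss()]) or an integer number of
#'   seconds (for [format_mmss()]).
#' @return Integer seconds, or a `"mm:ss"` string.
#' @export
parse_mmss <- function(x) {
  m <- regmatches(x, regexec("^([0-9]+):([0-5][0-9])$", x))[[1]]
  if (length(m) != 3) stop("duration must be 'mm:ss', got: ", x, call. = FALSE)
  as.integer(m[2]) * 60L + as.integer(m[3])
}

#' @rdname parse_mmss
#' @export
format_mmss <- function(x) sprintf("%02d:%02d", x %/% 60L, x %% 60L)

#' Load, save and interrogate acquisition protocols
#'
#' Protocols are stored as one YAML file with a `sequences` list, one block
#' per sequence; durations appear as `"mm:ss"` strings in the file. The
#' packaged default reproduces the full eight-sequence brain protocol.
#'
#' @param path Path to a protocol YAML file.
#' @return [load_protocol()] returns a validated `sequence_protocol`.
#' @export
load_protocol <- function(path) {
  if (!file.exists(path)) stop("protocol file not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$sequences)) doc$sequences <- list()
  seqs <- lapply(doc$sequences, function(s) {
    required <- c("name", "tr_ms", "te_ms", "flip_deg", "duration")
    missing <- setdiff(required, names(s))
    if (length(missing) > 0) {
      stop("protocol sequence is missing field(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    sequence_spec(
      name = s$name, kind = if (is.null(s$kind)) "anatomical" else s$kind,
      tr_ms = s$tr_ms, te_ms = unlist(s$te_ms),
      ti_ms = if (is.null(s$ti_ms)) NULL else unlist(s$ti_ms),
      flip_deg = unlist(s$flip_deg), refocus_deg = s$refocus_deg,
      bvalues_s_mm2 = if (is.null(s$bvalues_s_mm2)) NULL else unlist(s$bvalues_s_mm2),
      n_directions = s$n_directions,
      duration_s = parse_mmss(s$duration),
      voxel_mm = if (is.null(s$voxel_mm)) c(1, 1, 1) else unlist(s$voxel_mm),
      comments = s$comments)
  })
  sequence_protocol(seqs)
}

#' @param protocol A `sequence_protocol`.
#' @rdname load_protocol
#' @export
save_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "sequence_protocol"))
  blocks <- lapply(protocol$sequences, function(s) {
    b <- list(name = s$name, kind = s$kind, tr_ms = s$tr_ms,
              te_ms = as.list(s$te_ms))
    if (!is.null(s$ti_ms)) b$ti_ms <- as.list(s$ti_ms)
    b$flip_deg <- as.list(s$flip_deg)
    if (!is.null(s$refocus_deg)) b$refocus_deg <- s$refocus_deg
    if (!is.null(s$bvalues_s_mm2)) b$bvalues_s_mm2 <- as.list(s$bvalues_s_mm2)
    if (!is.null(s$n_directions)) b$n_directions <- s$n_directions
    b$duration <- format_mmss(s$duration_s)
    b$voxel_mm <- as.list(s$voxel_mm)
    if (!is.null(s$comments)) b$comments <- s$comments
    b
  })
  yaml::write_yaml(list(sequences = blocks), path, precision = 12)
  invisible(path)
}

#' @rdname load_protocol
#' @export
default_protocol <- function() {
  load_protocol(system.file("extdata", "protocol_default.yaml",
                            package = "multiqmap", mustWork = TRUE))
}

#' @details [total_duration_min()] sums the per-sequence durations and
#'   reports minutes; it is additive over protocol concatenation.
#' @rdname load_protocol
#' @export
total_duration_min <- function(protocol) {
  stopifnot(inherits(protocol, "sequence_protocol"))
  sum(vapply(protocol$sequences, `[[`, 0L, "duration_s")) / 60
}
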