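#' The ESD surgical phase vocabulary
#'
#' The four workflow phases of endoscopic submucosal dissection, in canonical
#' order: Marking (electrocautery dots placed around the lesion), Injection
#' (submucosal fluid lift), Dissection (mucosal incision and submucosal
#' dissection, including knife hemostasis) and Idle (instrument exchange or
#' scope adjustment). The integer coding `Marking = 0, Injection = 1,
#' Dissection = 2, Idle = 3` is a fixed part of the public contract: the
#' Pearson inter-rater agreement is computed on these codes.
#'
#' @return Character vector of the four phase names in canonical order.
#' @export
#' @examples
#' esd_phases()
#' phase_code("Dissection")
esd_phases <- function() {
  c("Marking", "Injection", "Dissection", "Idle")
}

#' @rdname esd_phases
#' @param phase Character vector of phase names.
#' @return `phase_code()`: integer codes in 0..3.
#' @export
phase_code <- function(phase) {
  idx <- match(phase, esd_phases())
  if (anyNA(idx)) {
    bad <- unique(phase[is.na(idx)])
    stop("unknown phase label(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(esd_phases(), collapse = ", "), ")",
         call. = FALSE)
  }
  idx - 1L
}

#' @rdname esd_phases
#' @param code Integer vector of codes in 0..3.
#' @return `phase_from_code()`: character phase names.
#' @export
phase_from_code <- function(code) {
  if (any(!code %in% 0:3)) stop("phase codes must lie in 0..3", call. = FALSE)
  esd_phases()[code + 1L]
}

#' Construct a frame-wise phase annotation track
#'
#' An annotation track holds one phase label per frame of a case at a known
#' frame rate, plus case metadata. Frames are indexed 0-based; frame `t`
#' covers time `[t/fps, (t+1)/fps)` seconds.
#'
#' @param case_id Case identifier string.
#' @param fps Frames per second of the labelled sequence (positive).
#' @param labels Character vector of phase names, one per frame (may be empty).
#' @param metadata Optional named list; recognised keys are `date`,
#'   `surgeon_id`, `organ`, `lesion_size_cm` (positive when present) and
#'   `training_status` (one of `"independent"`, `"with help"`, `"take over"`).
#' @return An object of class `annotation_track`.
#' @export
annotation_track <- function(case_id, fps, labels, metadata = list()) {
  stopifnot(is.character(case_id), length(case_id) == 1L)
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0) {
    stop("fps must be a positive number", call. = FALSE)
  }
  labels <- as.character(labels)
  phase_code(labels)  # validates vocabulary
  if (!is.null(metadata$lesion_size_cm)) {
    if (!is.numeric(metadata$lesion_size_cm) || metadata$lesion_size_cm <= 0) {
      stop("lesion_size_cm must be > 0 when present", call. = FALSE)
    }
  }
  if (!is.null(metadata$training_status) &&
      !metadata$training_status %in% c("independent", "with help", "take over")) {
    stop("training_status must be one of: independent, with help, take over",
         call. = FALSE)
  }
  structure(
    list(case_id = case_id, fps = fps, labels = labels, metadata = metadata),
    class = "annotation_track"
  )
}

#' @export
print.annotation_track <- function(x, ...) {
  cat("<annotation_track> case", x$case_id, "-", length(x$labels),
      "frames @", x$fps, "fps\n")
  if (length(x$labels)) {
    tab <- table(factor(x$labels, levels = esd_phases()))
    cat(paste0("  ", names(tab), ": ", as.integer(tab), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' @export
length.annotation_track <- function(x) length(x$labels)

#' Read a phase annotation file
#'
#' Two CSV dialects are supported. Frame-wise: header `frame,phase`, one row
#' per frame, 0-based and contiguous. Segment: header `start,end,phase` with
#' half-open frame ranges `[start, end)` that must tile `0..T` without gaps or
#' overlaps; segments are expanded to frame-wise labels.
#'
#' @param path Path to the CSV file.
#' @param fps Frame rate the labels refer to.
#' @param case_id Case identifier; defaults to the file stem.
#' @param metadata Optional metadata list (see [annotation_track()]).
#' @return An [annotation_track()].
#' @export
read_annotation <- function(path, fps, case_id = NULL, metadata = list()) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  if (is.null(case_id)) case_id <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  labels <- if (all(c("frame", "phase") %in% names(df))) {
    .labels_from_frame_table(df)
  } else if (all(c("start", "end", "phase") %in% names(df))) {
    labels_from_segments(df)
  } else {
    stop("unrecognised annotation format: expected columns frame,phase or ",
         "start,end,phase in ", path, call. = FALSE)
  }
  annotation_track(case_id, fps, labels, metadata)
}

.labels_from_frame_table <- function(df) {
  if (nrow(df) == 0L) return(character(0))
  ord <- order(df$frame)
  df <- df[ord, , drop = FALSE]
  expected <- seq.int(0L, nrow(df) - 1L)
  if (!identical(as.integer(df$frame), expected)) {
    bad <- which(as.integer(df$frame) != expected)[1L]
    stop("frame indices must be 0-based and contiguous; problem at row ", bad,
         " (frame ", df$frame[bad], ")", call. = FALSE)
  }
  bad_phase <- which(!df$phase %in% esd_phases())
  if (length(bad_phase)) {
    stop("unknown phase '", df$phase[bad_phase[1L]], "' at row ",
         bad_phase[1L], call. = FALSE)
  }
  as.character(df$phase)
}

#' Expand phase segments to frame-wise labels
#'
#' Inverse of [segments_from_labels()]: a table of half-open `[start, end)`
#' frame ranges is expanded to one label per frame. Segments must start at 0,
#' be contiguous, and not overlap.
#'
#' @param segments Data frame with columns `start`, `end`, `phase`.
#' @return Character vector of per-frame phase labels.
#' @export
labels_from_segments <- function(segments) {
  if (nrow(segments) == 0L) return(character(0))
  segments <- segments[order(segments$start), , drop = FALSE]
  if (any(segments$start >= segments$end)) {
    stop("segments must satisfy start < end", call. = FALSE)
  }
  expected_start <- c(0L, as.integer(segments$end[-nrow(segments)]))
  if (!identical(as.integer(segments$start), expected_start)) {
    bad <- which(as.integer(segments$start) != expected_start)[1L]
    stop("gap or overlap in segment frame ranges at segment ", bad,
         " (start ", segments$start[bad], ", expected ", expected_start[bad],
         ")", call. = FALSE)
  }
  bad_phase <- which(!segments$phase %in% esd_phases())
  if (length(bad_phase)) {
    stop("unknown phase '", segments$phase[bad_phase[1L]], "' at segment ",
         bad_phase[1L], call. = FALSE)
  }
  rep(as.character(segments$phase), times = segments$end - segments$start)
}

#' Run-length view of an annotation track
#'
#' Encodes the per-frame labels as maximal constant segments, half-open
#' `[start, end)`, 0-based. Concatenating the segments reproduces the labels
#' exactly; adjacent segments always differ in phase.
#'
#' @param track An [annotation_track()] or a character vector of labels.
#' @return Data frame with columns `start`, `end`, `phase`.
#' @export
segments_from_labels <- function(track) {
  labels <- if (inherits(track, "annotation_track")) track$labels else as.character(track)
  if (length(labels) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      phase = character(0), stringsAsFactors = FALSE))
  }
  r <- rle(labels)
  end <- cumsum(r$lengths)
  data.frame(start = c(0L, end[-length(end)]), end = as.integer(end),
             phase = r$values, stringsAsFactors = FALSE)
}

#' Write an annotation track to CSV
#'
#' @param track An [annotation_track()].
#' @param path Output path.
#' @param format `"frame"` for one row per frame (`frame,phase`) or
#'   `"segment"` for run-length rows (`start,end,phase`).
#' @return `path`, invisibly.
#' @export
write_annotation <- function(track, path, format = c("frame", "segment")) {
  format <- match.arg(format)
  df <- if (format == "frame") {
    data.frame(frame = seq_along(track$labels) - 1L, phase = track$labels)
  } else {
    segments_from_labels(track)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Downsample an annotation track to a lower frame rate
#'
#' Keeps the first frame of each window of `fps / target_fps` frames (the
#' convention used when reducing clinical video to 1 fps for labelling). The
#' ratio must be a whole number.
#'
#' @param track An [annotation_track()].
#' @param target_fps Target frame rate; must divide `track$fps` exactly.
#' @return An [annotation_track()] at `target_fps`.
#' @export
downsample_track <- function(track, target_fps) {
  if (target_fps > track$fps) {
    stop("target_fps must not exceed the track fps", call. = FALSE)
  }
  ratio <- track$fps / target_fps
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop("track fps (", track$fps, ") is not an integer multiple of target_fps (",
         target_fps, ")", call. = FALSE)
  }
  ratio <- as.integer(round(ratio))
  keep <- seq.int(1L, length(track$labels), by = ratio)
  if (length(track$labels) == 0L) keep <- integer(0)
  annotation_track(track$case_id, target_fps, track$labels[keep], track$metadata)
}

#' Pearson inter-rater agreement between two annotation tracks
#'
#' The Pearson correlation coefficient of the two integer-coded label
#' sequences under the canonical coding (Marking = 0 .. Idle = 3). Used to
#' quantify agreement between two independent annotators of the same case.
#'
#' @param a,b [annotation_track()] objects (or label vectors) of equal length.
#' @return A number in \[-1, 1\].
#' @export
pearson_agreement <- function(a, b) {
  la <- if (inherits(a, "annotation_track")) a$labels else as.character(a)
  lb <- if (inherits(b, "annotation_track")) b$labels else as.character(b)
  if (length(la) != length(lb)) {
    stop("tracks differ in length (", length(la), " vs ", length(lb), ")",
         call. = FALSE)
  }
  if (length(la) < 2L) stop("need at least 2 frames", call. = FALSE)
  ca <- phase_code(la)
  cb <- phase_code(lb)
  if (stats::sd(ca) == 0 && stats::sd(cb) == 0) {
    stop("correlation undefined: both tracks are constant", call. = FALSE)
  }
  if (stats::sd(ca) == 0 || stats::sd(cb) == 0) {
    stop("correlation undefined: one track is constant", call. = FALSE)
  }
  stats::cor(ca, cb)
}

#' Read / write per-case metadata JSON
#'
#' The metadata file carries keys `case_id`, `date`, `surgeon_id`, `organ`,
#' `lesion_size_cm`, `training_status` and `fps`.
#'
#' @param path Path to a JSON file.
#' @return `read_case_metadata()`: a named list.
#' @export
read_case_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path, call. = FALSE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @rdname read_case_metadata
#' @param meta Named list of metadata.
#' @export
write_case_metadata <- function(meta, path) {
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
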