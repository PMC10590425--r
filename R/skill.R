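#' Phase transition statistics
#'
#' Counts every frame-to-frame phase change and accumulates the 4x4
#' from-phase to to-phase transition matrix (zero diagonal). The total equals
#' the number of run-length segments minus one.
#'
#' @param labels Phase label sequence (an [annotation_track()],
#'   [prediction_track()] or character vector).
#' @return List of class `transition_stats`: `total` and 4x4 integer
#'   `matrix`.
#' @export
count_transitions <- function(labels) {
  lab <- as_phase_labels(labels)
  n <- length(lab)
  m <- matrix(0L, 4L, 4L, dimnames = list(from = esd_phases(), to = esd_phases()))
  if (n >= 2L) {
    from <- lab[-n]
    to <- lab[-1L]
    chg <- from != to
    if (any(chg)) {
      tab <- table(factor(from[chg], levels = esd_phases()),
                   factor(to[chg], levels = esd_phases()))
      m[] <- as.integer(tab)
    }
  }
  structure(list(total = sum(m), matrix = m), class = "transition_stats")
}

#' Normalized Transition (NT) index curve
#'
#' The online skill score: the cumulative number of phase transitions up to
#' each frame, divided by the lesion size in cm (transitions/cm). A lower
#' curve indicates a smoother, more skilled operation. With
#' `per_minute = TRUE` the curve is additionally divided by elapsed minutes
#' (a transition-rate reading); the default is the cumulative-count form,
#' whose final value times the lesion size equals the total transition count
#' exactly.
#'
#' @param labels Phase label sequence (track, prediction or character).
#' @param fps Frame rate of the sequence.
#' @param lesion_size_cm Lesion size in cm (> 0).
#' @param per_minute Normalise additionally by elapsed minutes.
#' @return List of class `nt_curve`: `time_s`, `value`, `final` and the
#'   normalisation used.
#' @export
nt_index_curve <- function(labels, fps, lesion_size_cm, per_minute = FALSE) {
  if (!is.numeric(lesion_size_cm) || lesion_size_cm <= 0) {
    stop("lesion_size_cm must be > 0", call. = FALSE)
  }
  lab <- as_phase_labels(labels)
  n <- length(lab)
  cum <- if (n >= 2L) cumsum(c(0L, lab[-1L] != lab[-n])) else numeric(n)
  time_s <- (seq_len(n) - 1L) / fps
  value <- cum / lesion_size_cm
  if (per_minute) {
    minutes <- pmax(time_s / 60, 1 / (60 * fps))  # guard t = 0
    value <- value / minutes
  }
  structure(list(time_s = time_s, value = value,
                 final = if (n) value[n] else 0,
                 lesion_size_cm = lesion_size_cm, per_minute = per_minute),
            class = "nt_curve")
}

#' Per-phase durations and ratios
#'
#' @param labels Phase label sequence (track, prediction or character).
#' @param fps Frame rate.
#' @return Data frame with one row per phase: `phase`, `duration_s`,
#'   `ratio`; ratios sum to 1.
#' @export
phase_periods <- function(labels, fps) {
  lab <- as_phase_labels(labels)
  if (length(lab) == 0L) stop("empty label sequence", call. = FALSE)
  counts <- table(factor(lab, levels = esd_phases()))
  data.frame(phase = esd_phases(),
             duration_s = as.numeric(counts) / fps,
             ratio = as.numeric(counts) / length(lab))
}

#' Derived skill scores
#'
#' The three offline ratios reported alongside the NT-index: Idle period /
#' tumor size (s/cm), Idle period / Dissection period (dimensionless; marked
#' unavailable when no Dissection occurred) and procedure duration / tumor
#' size (s/cm).
#'
#' @param periods Output of [phase_periods()].
#' @param lesion_size_cm Lesion size in cm (> 0).
#' @param total_duration_s Total procedure duration in seconds; defaults to
#'   the sum of the phase durations.
#' @return Named list: `idle_per_tumor`, `idle_per_dissection` (`NA` when
#'   unavailable), `procedure_per_tumor`.
#' @export
derived_scores <- function(periods, lesion_size_cm,
                           total_duration_s = sum(periods$duration_s)) {
  if (lesion_size_cm <= 0) stop("lesion_size_cm must be > 0", call. = FALSE)
  idle <- periods$duration_s[periods$phase == "Idle"]
  diss <- periods$duration_s[periods$phase == "Dissection"]
  list(idle_per_tumor = idle / lesion_size_cm,
       idle_per_dissection = if (diss > 0) idle / diss else NA_real_,
       procedure_per_tumor = total_duration_s / lesion_size_cm)
}

#' Skill summary for one case
#'
#' @param labels Phase label sequence (track, prediction or character).
#' @param fps Frame rate.
#' @param lesion_size_cm Lesion size in cm, or `NULL` when unknown (the
#'   NT-index and per-tumor scores are then marked unavailable).
#' @param training_status Optional training status string.
#' @return List of class `skill_summary`: `periods`, `transitions`,
#'   `nt_curve` (or `NULL`), `nt_final`, `scores`, `training_status`.
#' @export
skill_summary <- function(labels, fps, lesion_size_cm = NULL,
                          training_status = NULL) {
  periods <- phase_periods(labels, fps)
  trans <- count_transitions(labels)
  if (!is.null(lesion_size_cm)) {
    nt <- nt_index_curve(labels, fps, lesion_size_cm)
    scores <- derived_scores(periods, lesion_size_cm)
  } else {
    nt <- NULL
    scores <- list(idle_per_tumor = NA_real_, idle_per_dissection = NA_real_,
                   procedure_per_tumor = NA_real_)
    idle <- periods$duration_s[periods$phase == "Idle"]
    diss <- periods$duration_s[periods$phase == "Dissection"]
    if (diss > 0) scores$idle_per_dissection <- idle / diss
  }
  structure(list(periods = periods, transitions = trans, nt_curve = nt,
                 nt_final = if (!is.null(nt)) nt$final else NA_real_,
                 scores = scores,
                 training_status = training_status %||% NA_character_),
            class = "skill_summary")
}

#' Generate the structured case summary report
#'
#' Assembles the automatic post-procedure report: basic case information, the
#' phase color bar (run-length segments of the predicted labels), the
#' duration pie data, the transition matrix, the NT-index curve and the
#' derived skill scores, plus the training status. The document serialises
#' losslessly to JSON and renders to a self-contained HTML page.
#'
#' @param meta Case metadata list (see [read_case_metadata()]); `date`,
#'   `case_id`, `surgeon_id`, `lesion_size_cm`, `training_status`, `fps` and
#'   optional `hospital` are used.
#' @param predictions A [prediction_track()] or [annotation_track()]
#'   providing the phase labels (the report records which source was used).
#' @param lesion_size_cm Overrides `meta$lesion_size_cm` when given.
#' @return Object of class `report_document`.
#' @export
generate_report <- function(meta, predictions,
                            lesion_size_cm = meta$lesion_size_cm) {
  labels <- as_phase_labels(predictions)
  if (length(labels) == 0L) stop("predictions are empty", call. = FALSE)
  fps <- meta$fps %||% (if (!is.null(predictions$fps)) predictions$fps else 1)
  source <- if (inherits(predictions, "prediction_track")) "model" else "annotation"
  if (!is.null(lesion_size_cm) && is.na(lesion_size_cm)) lesion_size_cm <- NULL
  summ <- skill_summary(labels, fps, lesion_size_cm,
                        training_status = meta$training_status)
  structure(list(
    basic_info = list(date = meta$date %||% NA_character_,
                      hospital = meta$hospital %||% NA_character_,
                      case_id = meta$case_id %||% NA_character_,
                      endoscopist = meta$surgeon_id %||% NA_character_,
                      organ = meta$organ %||% NA_character_,
                      lesion_size_cm = lesion_size_cm %||% NA_real_,
                      fps = fps, label_source = source),
    color_bar = segments_from_labels(labels),
    pie = summ$periods,
    transitions = list(total = summ$transitions$total,
                       matrix = summ$transitions$matrix),
    nt_curve = if (!is.null(summ$nt_curve)) {
      list(time_s = summ$nt_curve$time_s, value = summ$nt_curve$value,
           final = summ$nt_curve$final)
    },
    skill = list(nt_final = summ$nt_final,
                 idle_per_tumor = summ$scores$idle_per_tumor,
                 idle_per_dissection = summ$scores$idle_per_dissection,
                 procedure_per_tumor = summ$scores$procedure_per_tumor,
                 training_status = summ$training_status)),
    class = "report_document")
}

#' Serialise / parse a report document as JSON
#'
#' Round-trips losslessly: `report_from_json(report_to_json(x))` reproduces
#' every field (numbers at full precision).
#'
#' @param report A [generate_report()] document.
#' @param path Optional file path; when given the JSON is written there.
#' @return `report_to_json()`: JSON string (invisibly when `path` given).
#' @export
report_to_json <- function(report, path = NULL) {
  x <- unclass(report)
  x$transitions$matrix <- unname(x$transitions$matrix)
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = I(17), null = "null",
                           na = "null", dataframe = "columns")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' @rdname report_to_json
#' @param json JSON string or path to a JSON file.
#' @return `report_from_json()`: a `report_document`.
#' @export
report_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  for (f in c("date", "hospital", "case_id", "endoscopist", "organ",
              "label_source")) {
    x$basic_info[[f]] <- as.character(x$basic_info[[f]] %||% NA_character_)
  }
  x$basic_info$lesion_size_cm <- as.numeric(x$basic_info$lesion_size_cm %||% NA_real_)
  x$basic_info$fps <- as.numeric(x$basic_info$fps)
  x$basic_info <- x$basic_info[c("date", "hospital", "case_id", "endoscopist",
                                 "organ", "lesion_size_cm", "fps",
                                 "label_source")]
  x$skill$training_status <- as.character(x$skill$training_status %||% NA_character_)
  x$color_bar <- as.data.frame(x$color_bar)
  x$color_bar$start <- as.integer(x$color_bar$start)
  x$color_bar$end <- as.integer(x$color_bar$end)
  x$pie <- as.data.frame(x$pie)
  x$pie$duration_s <- as.numeric(x$pie$duration_s)
  x$pie$ratio <- as.numeric(x$pie$ratio)
  m <- matrix(as.integer(x$transitions$matrix), 4L, 4L,
              dimnames = list(from = esd_phases(), to = esd_phases()))
  x$transitions <- list(total = as.integer(x$transitions$total), matrix = m)
  if (!is.null(x$nt_curve)) x$nt_curve <- lapply(x$nt_curve, as.numeric)
  for (f in c("idle_per_tumor", "idle_per_dissection", "procedure_per_tumor",
              "nt_final")) {
    x$skill[[f]] <- as.numeric(x$skill[[f]] %||% NA_real_)
  }
  structure(x, class = "report_document")
}

#' Rank operators by final NT-index
#'
#' Ascending final NT-index = smoother operation = higher rank.
#'
#' @param reports Named list of `report_document`s (or `skill_summary`s).
#' @return Data frame ordered from most to least skilled.
#' @export
rank_by_nt_index <- function(reports) {
  nt <- vapply(reports, function(r) {
    if (inherits(r, "report_document")) r$skill$nt_final else r$nt_final
  }, numeric(1))
  out <- data.frame(id = names(reports) %||% as.character(seq_along(reports)),
                    nt_final = nt)
  out <- out[order(out$nt_final), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

phase_palette <- function() {
  c(Marking = "#d9aa3c", Injection = "#4682c8", Dissection = "#c34b4b",
    Idle = "#8c8c8c")
}

#' Render a report document to self-contained HTML
#'
#' Inline-SVG rendering of every section: basic information, phase color
#' bar, duration pie, transition matrix, NT-index curve and skill scores.
#'
#' @param report A [generate_report()] document.
#' @param path Output HTML path.
#' @return `path`, invisibly.
#' @export
render_report_html <- function(report, path) {
  pal <- phase_palette()
  bi <- report$basic_info
  n_frames <- max(report$color_bar$end)
  esc <- function(x) {
    x <- gsub("&", "&amp;", as.character(x), fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  fmt <- function(x, digits = 2) {
    if (is.null(x) || length(x) == 0 || is.na(x)) "n/a" else formatC(x, digits = digits, format = "f")
  }
  bar <- paste0(vapply(seq_len(nrow(report$color_bar)), function(i) {
    s <- report$color_bar[i, ]
    sprintf('<rect x="%.3f%%" width="%.3f%%" y="0" height="30" fill="%s"/>',
            100 * s$start / n_frames, 100 * (s$end - s$start) / n_frames,
            pal[[s$phase]])
  }, ""), collapse = "")
  # pie slices
  angles <- cumsum(c(0, report$pie$ratio)) * 2 * pi
  pie <- paste0(vapply(seq_len(nrow(report$pie)), function(i) {
    if (report$pie$ratio[i] <= 0) return("")
    a0 <- angles[i] - pi / 2
    a1 <- angles[i + 1] - pi / 2
    large <- as.integer((a1 - a0) > pi)
    if (report$pie$ratio[i] >= 1 - 1e-12) {
      return(sprintf('<circle cx="60" cy="60" r="55" fill="%s"/>',
                     pal[[report$pie$phase[i]]]))
    }
    sprintf('<path d="M60,60 L%.2f,%.2f A55,55 0 %d 1 %.2f,%.2f Z" fill="%s"/>',
            60 + 55 * cos(a0), 60 + 55 * sin(a0), large,
            60 + 55 * cos(a1), 60 + 55 * sin(a1), pal[[report$pie$phase[i]]])
  }, ""), collapse = "")
  tmat <- report$transitions$matrix
  trows <- paste0(vapply(seq_len(4L), function(i) {
    paste0("<tr><th>", esd_phases()[i], "</th>",
           paste0("<td>", tmat[i, ], "</td>", collapse = ""), "</tr>")
  }, ""), collapse = "")
  nt_svg <- if (!is.null(report$nt_curve) && length(report$nt_curve$time_s) > 1) {
    tmax <- max(report$nt_curve$time_s)
    vmax <- max(report$nt_curve$value, 1e-9)
    pts <- paste(sprintf("%.2f,%.2f", 10 + 380 * report$nt_curve$time_s / tmax,
                         110 - 100 * report$nt_curve$value / vmax),
                 collapse = " ")
    sprintf(paste0('<svg width="400" height="120" viewBox="0 0 400 120">',
                   '<polyline points="%s" fill="none" stroke="#c34b4b" stroke-width="2"/>',
                   '<line x1="10" y1="110" x2="390" y2="110" stroke="#333"/>',
                   '<line x1="10" y1="10" x2="10" y2="110" stroke="#333"/></svg>',
                   '<p>final NT-index: %s transitions/cm</p>'),
            pts, fmt(report$nt_curve$final))
  } else {
    "<p>NT-index unavailable (no lesion size recorded).</p>"
  }
  legend <- paste0(vapply(esd_phases(), function(ph) {
    sprintf('<span style="color:%s">&#9632;</span> %s ', pal[[ph]], ph)
  }, ""), collapse = "")
  html <- sprintf('<!DOCTYPE html>
<html><head><meta charset="utf-8"><title>ESD workflow summary %s</title>
<style>body{font-family:sans-serif;max-width:760px;margin:2em auto}
table{border-collapse:collapse}td,th{border:1px solid #999;padding:4px 8px;text-align:center}</style>
</head><body>
<h1>ESD workflow summary report</h1>
<section id="basic-info"><h2>Basic information</h2>
<table><tr><th>Date</th><td>%s</td></tr><tr><th>Hospital</th><td>%s</td></tr>
<tr><th>Case</th><td>%s</td></tr><tr><th>Endoscopist</th><td>%s</td></tr>
<tr><th>Organ</th><td>%s</td></tr><tr><th>Lesion size (cm)</th><td>%s</td></tr>
<tr><th>Training status</th><td>%s</td></tr><tr><th>Label source</th><td>%s</td></tr></table></section>
<section id="color-bar"><h2>Phase color bar</h2>
<svg width="100%%" height="30">%s</svg><p>%s</p></section>
<section id="duration-pie"><h2>Phase duration distribution</h2>
<svg width="120" height="120">%s</svg>
<p>%s</p></section>
<section id="transition-matrix"><h2>Phase transitions (total: %d)</h2>
<table><tr><th>from \\ to</th>%s</tr>%s</table></section>
<section id="nt-index"><h2>NT-index curve</h2>%s</section>
<section id="skill-scores"><h2>Skill scores</h2>
<table><tr><th>Idle period / tumor size (s/cm)</th><td>%s</td></tr>
<tr><th>Idle period / dissection period</th><td>%s</td></tr>
<tr><th>Procedure duration / tumor size (s/cm)</th><td>%s</td></tr></table></section>
</body></html>',
    esc(bi$case_id), esc(bi$date), esc(bi$hospital), esc(bi$case_id),
    esc(bi$endoscopist), esc(bi$organ), fmt(bi$lesion_size_cm, 1),
    esc(report$skill$training_status), esc(bi$label_source),
    bar, legend, pie,
    paste(sprintf("%s: %.1f s (%.1f%%)", report$pie$phase,
                  report$pie$duration_s, 100 * report$pie$ratio),
          collapse = "; "),
    report$transitions$total,
    paste0("<th>", esd_phases(), "</th>", collapse = ""), trows,
    nt_svg,
    fmt(report$skill$idle_per_tumor), fmt(report$skill$idle_per_dissection),
    fmt(report$skill$procedure_per_tumor))
  writeLines(html, path)
  invisible(path)
}
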