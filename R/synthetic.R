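#' Workflow grammar for synthetic ESD procedures
#'
#' A semi-Markov description of the ESD phase structure: the procedure starts
#' with Marking, then alternates Injection and Dissection interleaved with
#' Idle pauses (instrument exchanges). Each visit to a phase draws an explicit
#' dwell time from a per-phase Gamma distribution, which creates realistic
#' segment structure for the temporal model.
#'
#' @param initial_phase Phase the procedure starts in (default `"Marking"`).
#' @param transitions 4x4 nonnegative matrix of transition weights
#'   (rows = from, columns = to, canonical phase order), zero diagonal. Rows
#'   are renormalised at sampling time, so only ratios matter.
#' @param dwell_mean_s Named numeric vector of per-phase mean dwell times in
#'   seconds.
#' @param dwell_shape Gamma shape parameter shared by all phases (dispersion:
#'   larger is more regular).
#' @return An object of class `workflow_grammar`.
#' @export
workflow_grammar <- function(initial_phase = "Marking",
                             transitions = default_transitions(),
                             dwell_mean_s = c(Marking = 20, Injection = 10,
                                              Dissection = 60, Idle = 8),
                             dwell_shape = 4) {
  phases <- esd_phases()
  stopifnot(initial_phase %in% phases)
  transitions <- as.matrix(transitions)
  if (!all(dim(transitions) == c(4L, 4L))) stop("transitions must be 4x4", call. = FALSE)
  dimnames(transitions) <- list(phases, phases)
  if (any(transitions < 0)) stop("transition weights must be nonnegative", call. = FALSE)
  if (any(diag(transitions) != 0)) stop("self-transitions must have zero weight", call. = FALSE)
  dwell_mean_s <- dwell_mean_s[phases]
  if (any(is.na(dwell_mean_s)) || any(dwell_mean_s <= 0)) {
    stop("dwell_mean_s must give a positive mean for every phase", call. = FALSE)
  }
  if (dwell_shape <= 0) stop("dwell_shape must be positive", call. = FALSE)
  structure(list(initial_phase = initial_phase, transitions = transitions,
                 dwell_mean_s = dwell_mean_s, dwell_shape = dwell_shape),
            class = "workflow_grammar")
}

#' @rdname workflow_grammar
#' @export
default_transitions <- function() {
  phases <- esd_phases()
  w <- matrix(0, 4, 4, dimnames = list(phases, phases))
  w["Marking", c("Injection", "Idle")] <- c(0.5, 0.5)
  w["Injection", c("Dissection", "Idle")] <- c(0.8, 0.2)
  w["Dissection", c("Injection", "Idle")] <- c(0.3, 0.7)
  w["Idle", c("Injection", "Dissection")] <- c(0.35, 0.65)
  w
}

#' Skill profile of a synthetic operator
#'
#' The smoothness of an ESD operation shows up as the frequency of hesitation
#' and instrument exchanges, i.e. transitions into Idle. The profile scales
#' the grammar's transition weights into Idle (`idle_rate_multiplier`) and all
#' dwell means (`dwell_scale`); a novice therefore produces more phase
#' transitions per procedure than an expert on the same grammar.
#'
#' @param idle_rate_multiplier Positive multiplier on transition weights into
#'   Idle, or one of the preset names `"expert"` (1) / `"novice"` (3).
#' @param dwell_scale Positive multiplier on all dwell means.
#' @return An object of class `skill_profile`.
#' @export
skill_profile <- function(idle_rate_multiplier = 1, dwell_scale = 1) {
  if (is.character(idle_rate_multiplier)) {
    idle_rate_multiplier <- switch(match.arg(idle_rate_multiplier,
                                             c("expert", "novice")),
                                   expert = 1, novice = 3)
  }
  if (idle_rate_multiplier <= 0 || dwell_scale <= 0) {
    stop("skill profile parameters must be positive", call. = FALSE)
  }
  structure(list(idle_rate_multiplier = idle_rate_multiplier,
                 dwell_scale = dwell_scale),
            class = "skill_profile")
}

#' Sample a semi-Markov phase sequence
#'
#' Draws a phase-labelled track from a [workflow_grammar()]: start in the
#' initial phase, sample a Gamma dwell time, sample the next phase from the
#' outgoing transition weights (weights into Idle scaled by the skill
#' profile), and truncate at the requested duration. Deterministic given
#' `seed`.
#'
#' @param grammar A [workflow_grammar()].
#' @param duration_s Procedure duration in seconds (> 0).
#' @param skill A [skill_profile()].
#' @param fps Frame rate of the generated labels (default 1, the annotation
#'   rate).
#' @param seed Integer seed.
#' @param case_id Case identifier for the returned track.
#' @param metadata Metadata list passed to [annotation_track()].
#' @return An [annotation_track()] with `duration_s * fps` frames.
#' @export
sample_phase_sequence <- function(grammar, duration_s, skill = skill_profile(),
                                  fps = 1, seed = 1L, case_id = "synthetic",
                                  metadata = list()) {
  if (duration_s <= 0) stop("duration_s must be > 0", call. = FALSE)
  stopifnot(inherits(grammar, "workflow_grammar"), inherits(skill, "skill_profile"))
  w <- grammar$transitions
  w[, "Idle"] <- w[, "Idle"] * skill$idle_rate_multiplier
  deadlock <- rownames(w)[rowSums(w) == 0 & rownames(w) != "Idle"]
  if (length(deadlock)) {
    stop("grammar deadlock: no outgoing weight from phase(s) ",
         paste(deadlock, collapse = ", "), call. = FALSE)
  }
  if (sum(w["Idle", ]) == 0) {
    stop("grammar deadlock: no outgoing weight from Idle", call. = FALSE)
  }
  n_frames <- as.integer(round(duration_s * fps))
  dwell_mean <- grammar$dwell_mean_s * skill$dwell_scale
  shape <- grammar$dwell_shape
  labels <- withr::with_seed(seed, {
    out <- character(0)
    phase <- grammar$initial_phase
    while (length(out) < n_frames) {
      dwell_s <- stats::rgamma(1L, shape = shape,
                               scale = dwell_mean[[phase]] / shape)
      k <- max(1L, as.integer(round(dwell_s * fps)))
      out <- c(out, rep(phase, k))
      phase <- sample(esd_phases(), 1L, prob = w[phase, ])
    }
    out[seq_len(n_frames)]
  })
  annotation_track(case_id, fps, labels, metadata)
}

#' Appearance configuration for rendered synthetic video
#'
#' Controls the per-phase look of rendered frames: a distinct base colour per
#' phase, a sinusoidal texture, an optional moving bright ellipse emulating a
#' surgical tool, and i.i.d. Gaussian pixel noise. The defaults (64x64) keep
#' desk-scale training fast; clinical resolutions are supported but not
#' default.
#'
#' @param height,width Frame size in pixels.
#' @param base_colors 4x3 matrix of 8-bit RGB base colours, one row per phase
#'   in canonical order; rows must be pairwise distinct.
#' @param texture_amplitude Amplitude of the sinusoidal texture (8-bit units).
#' @param noise_sd Standard deviation of the Gaussian pixel noise.
#' @param tool_overlay Whether to draw the moving tool-like ellipse.
#' @return An object of class `appearance_config`.
#' @export
appearance_config <- function(height = 64L, width = 64L,
                              base_colors = default_base_colors(),
                              texture_amplitude = 12, noise_sd = 8,
                              tool_overlay = TRUE) {
  stopifnot(height >= 16L, width >= 16L)
  base_colors <- as.matrix(base_colors)
  if (!all(dim(base_colors) == c(4L, 3L))) stop("base_colors must be 4x3", call. = FALSE)
  if (anyDuplicated(base_colors) > 0) {
    stop("per-phase base colours must be pairwise distinct", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  structure(list(height = as.integer(height), width = as.integer(width),
                 base_colors = base_colors, texture_amplitude = texture_amplitude,
                 noise_sd = noise_sd, tool_overlay = isTRUE(tool_overlay)),
            class = "appearance_config")
}

#' @rdname appearance_config
#' @export
default_base_colors <- function() {
  matrix(c(205, 170, 70,    # Marking: cautery-dot yellow
           70, 130, 200,    # Injection: saline-lift blue
           195, 75, 75,     # Dissection: submucosal red
           95, 95, 95),     # Idle: desaturated grey
         nrow = 4, byrow = TRUE,
         dimnames = list(esd_phases(), c("R", "G", "B")))
}

#' A synthetic video stream
#'
#' @param frames Integer array of dimension `(T, H, W, 3)` with 8-bit values.
#' @param fps Frame rate.
#' @param case_id Case identifier.
#' @return An object of class `video_stream`.
#' @export
video_stream <- function(frames, fps, case_id = "synthetic") {
  stopifnot(length(dim(frames)) == 4L, dim(frames)[4L] == 3L)
  structure(list(frames = frames, fps = fps, case_id = case_id),
            class = "video_stream")
}

#' @export
print.video_stream <- function(x, ...) {
  d <- dim(x$frames)
  cat("<video_stream>", x$case_id, "-", d[1L], "frames of", d[2L], "x", d[3L],
      "@", x$fps, "fps\n")
  invisible(x)
}

#' @export
length.video_stream <- function(x) dim(x$frames)[1L]

#' Render a synthetic video for an annotation track
#'
#' One frame per label: the phase base colour, a phase-dependent sinusoidal
#' texture drifting over time, an optional bright moving ellipse emulating a
#' surgical tool, and Gaussian pixel noise, clipped to \[0, 255\]. A pure
#' function of `(track, appearance, seed)`.
#'
#' @param track An [annotation_track()].
#' @param appearance An [appearance_config()].
#' @param seed Integer seed for the pixel noise and tool path.
#' @return A [video_stream()] with one frame per track label.
#' @export
render_video <- function(track, appearance = appearance_config(), seed = 1L) {
  h <- appearance$height
  w <- appearance$width
  n <- length(track$labels)
  codes <- phase_code(track$labels)
  xg <- matrix(seq_len(w), h, w, byrow = TRUE) / w
  yg <- matrix(seq_len(h), h, w) / h
  # per-phase texture frequency (cycles per frame width)
  freq <- c(3, 5, 7, 2)
  frames <- withr::with_seed(seed, {
    out <- array(0L, dim = c(n, h, w, 3L))
    tool_cx <- 0.5 + 0.35 * sin(seq_len(n) / 17)
    tool_cy <- 0.5 + 0.35 * cos(seq_len(n) / 23)
    for (t in seq_len(n)) {
      k <- codes[t] + 1L
      tex <- appearance$texture_amplitude *
        sin(2 * pi * freq[k] * (xg + yg) + 0.25 * t)
      tool <- 0
      if (appearance$tool_overlay) {
        d2 <- ((xg - tool_cx[t]) / 0.12)^2 + ((yg - tool_cy[t]) / 0.05)^2
        tool <- 70 * (d2 < 1)
      }
      for (ch in 1:3) {
        px <- appearance$base_colors[k, ch] + tex + tool +
          stats::rnorm(h * w, sd = appearance$noise_sd)
        out[t, , , ch] <- as.integer(pmin(255, pmax(0, round(px))))
      }
    }
    out
  })
  video_stream(frames, track$fps, track$case_id)
}

#' Simulate a second annotator for a track
#'
#' Emulates inter-rater disagreement: every internal segment boundary is
#' shifted by a `round(Normal(0, boundary_jitter_s * fps))` draw (clipped so
#' no segment becomes empty), then each segment is relabelled to a uniformly
#' random *other* phase with probability `relabel_rate`.
#'
#' @param track An [annotation_track()].
#' @param boundary_jitter_s Boundary jitter standard deviation in seconds
#'   (>= 0).
#' @param relabel_rate Per-segment relabel probability in \[0, 1\].
#' @param seed Integer seed.
#' @return An [annotation_track()] of the same length and fps.
#' @export
simulate_rater <- function(track, boundary_jitter_s = 0, relabel_rate = 0,
                           seed = 1L) {
  stopifnot(boundary_jitter_s >= 0, relabel_rate >= 0, relabel_rate <= 1)
  seg <- segments_from_labels(track)
  n_seg <- nrow(seg)
  n <- length(track$labels)
  if (n_seg <= 1L && relabel_rate == 0) return(track)
  withr::with_seed(seed, {
    if (n_seg > 1L) {
      bounds <- seg$end[-n_seg]  # internal boundaries
      shifted <- bounds + as.integer(round(stats::rnorm(length(bounds),
                                                        sd = boundary_jitter_s * track$fps)))
      prev <- 0L
      for (i in seq_along(shifted)) {
        upper <- if (i < length(bounds)) bounds[i + 1L] - 1L else n - 1L
        lo <- prev + 1L
        shifted[i] <- if (lo > upper) bounds[i] else min(max(shifted[i], lo), upper)
        prev <- shifted[i]
      }
      seg$start <- c(0L, shifted)
      seg$end <- c(shifted, n)
    }
    relabel <- stats::runif(n_seg) < relabel_rate
    for (i in which(relabel)) {
      seg$phase[i] <- sample(setdiff(esd_phases(), seg$phase[i]), 1L)
    }
  })
  # boundary clipping cannot create empties, but merged identical neighbours
  # after relabelling are fine: labels_from_segments only checks contiguity
  annotation_track(track$case_id, track$fps, labels_from_segments(seg),
                   track$metadata)
}

#' Simulate a complete synthetic ESD case
#'
#' Bundles a sampled phase track, an (optional) rendered video and case
#' metadata into one object, as downstream training and reporting expect.
#'
#' @param case_id Case identifier.
#' @param seed Integer seed (drives both track sampling and rendering).
#' @param duration_s Procedure duration in seconds.
#' @param fps Frame rate (default 1, the annotation rate).
#' @param grammar A [workflow_grammar()].
#' @param skill A [skill_profile()].
#' @param appearance An [appearance_config()].
#' @param date Case date (`Date` or string).
#' @param surgeon_id,organ,training_status,lesion_size_cm Case metadata.
#' @param render Whether to render frames (skip for label-only analyses).
#' @return An object of class `esd_case`: list with `track`, `video` (or
#'   `NULL`) and `metadata`.
#' @export
simulate_case <- function(case_id = "case-001", seed = 1L, duration_s = 240,
                          fps = 1, grammar = workflow_grammar(),
                          skill = skill_profile(),
                          appearance = appearance_config(),
                          date = as.Date("2026-01-01"), surgeon_id = "S1",
                          organ = "stomach", training_status = NULL,
                          lesion_size_cm = 2.5, render = TRUE) {
  metadata <- list(date = as.character(date), surgeon_id = surgeon_id,
                   organ = organ, lesion_size_cm = lesion_size_cm,
                   fps = fps)
  if (!is.null(training_status)) metadata$training_status <- training_status
  metadata$case_id <- case_id
  track <- sample_phase_sequence(grammar, duration_s, skill, fps,
                                 seed = sub_seed(seed, "track"),
                                 case_id = case_id, metadata = metadata)
  video <- if (render) render_video(track, appearance, seed = sub_seed(seed, "video"))
  structure(list(track = track, video = video, metadata = metadata),
            class = "esd_case")
}

#' Simulate a date-ordered cohort of synthetic cases
#'
#' @param n_cases Number of cases.
#' @param seed Base seed; case `i` uses a sub-seed derived from it.
#' @param start_date Date of the first case; cases are one week apart.
#' @param ... Passed on to [simulate_case()] (e.g. `duration_s`, `skill`,
#'   `render`).
#' @return List of [simulate_case()] objects ordered by date.
#' @export
simulate_cohort <- function(n_cases, seed = 1L,
                            start_date = as.Date("2026-01-01"), ...) {
  lapply(seq_len(n_cases), function(i) {
    simulate_case(case_id = sprintf("case-%03d", i),
                  seed = sub_seed(seed, paste0("case", i)),
                  date = start_date + 7 * (i - 1), ...)
  })
}
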