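# PERCLOS scoring per unit cycle and the normal/fatigued verdict.

#' Unit-cycle configuration for the fatigue verdict
#'
#' A unit cycle is a fixed window of `f0` frames (default 150, about 6.5 s
#' at ~23 fps). Within each cycle the classifier evaluates four criteria,
#' any of which (inclusive comparison) marks the cycle fatigued:
#' eye PERCLOS >= `perclos_threshold`, mouth PERCLOS >= `perclos_threshold`,
#' longest consecutive closed-eye run >= `fe_threshold` frames, longest
#' consecutive yawning run >= `fm_threshold` frames. Individual criteria can
#' be switched off via `criteria`, e.g. to study one decision boundary in
#' isolation. `stride` controls window placement: the default `stride = f0`
#' tiles non-overlapping cycles; a smaller stride slides the window for
#' streaming use.
#'
#' @param f0 cycle length in frames (>= 1).
#' @param perclos_threshold PERCLOS decision threshold in (0, 1).
#' @param fe_threshold,fm_threshold consecutive-frame thresholds (positive).
#' @param stride window stride in frames, default `f0`.
#' @param criteria character subset of
#'   `c("perclos_eyes", "perclos_mouth", "fe", "fm")`; enabled criteria.
#' @return An object of class `"cycle_config"`.
#' @export
cycle_config <- function(f0 = 150L, perclos_threshold = 0.15,
                         fe_threshold = 20L, fm_threshold = 30L,
                         stride = f0,
                         criteria = c("perclos_eyes", "perclos_mouth",
                                      "fe", "fm")) {
  f0 <- as.integer(f0); stride <- as.integer(stride)
  if (is.na(f0) || f0 < 1L) stop_config("f0 must be >= 1 frame")
  if (!is.numeric(perclos_threshold) || perclos_threshold <= 0 ||
      perclos_threshold >= 1)
    stop_config("perclos_threshold must lie in (0, 1)")
  if (fe_threshold <= 0 || fm_threshold <= 0)
    stop_config("fe_threshold and fm_threshold must be positive")
  if (is.na(stride) || stride < 1L) stop_config("stride must be >= 1")
  criteria <- match.arg(criteria, several.ok = TRUE)
  structure(list(f0 = f0, perclos_threshold = perclos_threshold,
                 fe_threshold = as.numeric(fe_threshold),
                 fm_threshold = as.numeric(fm_threshold),
                 stride = stride, criteria = criteria),
            class = "cycle_config")
}

#' PERCLOS score of a window
#'
#' Fraction of a unit cycle spent in state: the sum of each episode's
#' overlap with the window `[f_start, f_end)`, in frames, divided by `f0`.
#' Episodes straddling the border contribute only their clipped overlap, so
#' the score is always in \[0, 1\].
#'
#' @param episodes data frame from [find_episodes()] (any one kind).
#' @param window numeric `c(f_start, f_end)`, half-open frame window with
#'   `f_end - f_start == f0`.
#' @param f0 cycle length in frames.
#' @return PERCLOS score in \[0, 1\].
#' @examples
#' eps <- data.frame(kind = "eye_closure", start = c(10L, 50L),
#'                   end = c(16L, 67L), duration = c(6L, 17L))
#' perclos_score(eps, c(0, 150), 150)  # 23/150
#' @export
perclos_score <- function(episodes, window, f0 = diff(window)) {
  if (!is.numeric(f0) || length(f0) != 1L || f0 <= 0)
    stop_config("f0 must be a positive number of frames")
  if (length(window) != 2L || window[2L] - window[1L] != f0)
    stop_config("window must satisfy f_end - f_start == f0")
  if (is.null(episodes) || nrow(episodes) == 0L) return(0)
  ov <- pmax(0, pmin(episodes$end, window[2L]) -
                pmax(episodes$start, window[1L]))
  sum(ov) / f0
}

#' Classify one cycle summary
#'
#' Applies the combined fatigue rule to precomputed cycle statistics: the
#' verdict is `"fatigued"` iff any enabled criterion holds (inclusive):
#' `p_eyes >= perclos_threshold`, `p_mouth >= perclos_threshold`,
#' `fe >= fe_threshold`, `fm >= fm_threshold`. `triggered` lists every
#' satisfied criterion, so the verdict is auditable.
#'
#' @param p_eyes,p_mouth PERCLOS scores in \[0, 1\].
#' @param fe,fm longest consecutive closed-eye / yawning runs, frames.
#' @param config a [cycle_config()].
#' @return List with `verdict` (`"normal"` or `"fatigued"`) and `triggered`
#'   (character vector of criteria that fired).
#' @export
classify_summary <- function(p_eyes, p_mouth, fe, fm,
                             config = cycle_config()) {
  vals <- c(p_eyes, p_mouth, fe, fm)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop_input("cycle statistics must be finite and non-negative")
  trig <- character()
  if ("perclos_eyes" %in% config$criteria &&
      p_eyes >= config$perclos_threshold) trig <- c(trig, "perclos_eyes")
  if ("perclos_mouth" %in% config$criteria &&
      p_mouth >= config$perclos_threshold) trig <- c(trig, "perclos_mouth")
  if ("fe" %in% config$criteria && fe >= config$fe_threshold)
    trig <- c(trig, "fe")
  if ("fm" %in% config$criteria && fm >= config$fm_threshold)
    trig <- c(trig, "fm")
  list(verdict = if (length(trig)) "fatigued" else "normal",
       triggered = trig)
}

#' Fatigue classification of a frame sequence
#'
#' The full detection pipeline: ratios (if raw frames are given) -> per-frame
#' states -> episodes -> per-cycle PERCLOS and consecutive-frame statistics
#' -> verdict per cycle and overall. Windows of `f0` frames are tiled at the
#' configured stride from the first frame index; a trailing partial window is
#' still evaluated (with `f0` as the PERCLOS divisor) and flagged `partial`.
#' Episodes straddling a window border contribute their clipped overlap to
#' PERCLOS but their full duration to F_e/F_m (a 25-frame closure is a
#' 25-frame closure regardless of the tiling). The overall verdict is
#' fatigued iff any complete cycle is fatigued; when the input is shorter
#' than one cycle the partial cycles decide.
#'
#' @param x list of [landmark_frame()] objects, or a ratio data frame from
#'   [compute_ratio_series()], or a state data frame from [frame_states()].
#' @param thresholds a [thresholds()] object.
#' @param config a [cycle_config()].
#' @param labels optional per-frame detector labels (see [frame_states()]).
#' @param map a [keypoint_map()], used when `x` is a frame list.
#' @return An object of class `"fatigue_report"`: list with `cycles` (one
#'   row per window: `f_start`, `f_end`, `p_eyes`, `p_mouth`, `fe`, `fm`,
#'   `triggered`, `verdict`, `partial`), `overall`, `states`, `episodes`,
#'   `thresholds`, `config`, and `ratios` when computed.
#' @examples
#' sim <- simulate_face(simulation_config(
#'   n_frames = 150, events = list(event_spec("closure", 60, 25))))
#' rep <- classify_sequence(sim$frames)
#' rep$overall
#' @export
classify_sequence <- function(x, thresholds = perclos::thresholds(),
                              config = cycle_config(), labels = NULL,
                              map = keypoint_map()) {
  ratios <- NULL
  if (is.data.frame(x) && all(c("eyes_closed", "yawning") %in% names(x))) {
    states <- x
  } else {
    if (is.data.frame(x)) ratios <- x
    else if (is.list(x) && length(x) &&
             inherits(x[[1L]], "landmark_frame"))
      ratios <- compute_ratio_series(x, map)
    else stop_input("x must be landmark frames, a ratio series or states")
    if (nrow(ratios) == 0L) stop_input("empty input sequence")
    states <- frame_states(ratios, thresholds, labels)
  }
  if (nrow(states) == 0L) stop_input("empty input sequence")

  eye_eps <- find_episodes(states, "eye_closure")
  yawn_eps <- find_episodes(states, "yawn")
  first <- min(states$frame_index); last <- max(states$frame_index)
  starts <- seq(first, last, by = config$stride)
  rows <- lapply(starts, function(s) {
    e <- s + config$f0
    win <- c(s, e)
    overlaps <- function(eps)
      eps[eps$end > s & eps$start < e, , drop = FALSE]
    oe <- overlaps(eye_eps); om <- overlaps(yawn_eps)
    p_eyes <- perclos_score(eye_eps, win, config$f0)
    p_mouth <- perclos_score(yawn_eps, win, config$f0)
    fe <- max_consecutive(oe); fm <- max_consecutive(om)
    cls <- classify_summary(p_eyes, p_mouth, fe, fm, config)
    data.frame(f_start = s, f_end = e, p_eyes = p_eyes, p_mouth = p_mouth,
               fe = fe, fm = fm,
               triggered = paste(cls$triggered, collapse = ","),
               verdict = cls$verdict, partial = e > last + 1L)
  })
  cycles <- do.call(rbind, rows)
  complete <- !cycles$partial
  overall <- if (any(complete)) {
    if (any(cycles$verdict[complete] == "fatigued")) "fatigued" else "normal"
  } else {
    if (any(cycles$verdict == "fatigued")) "fatigued" else "normal"
  }
  structure(list(cycles = cycles, overall = overall, ratios = ratios,
                 states = states,
                 episodes = rbind(eye_eps, yawn_eps),
                 thresholds = thresholds, config = config),
            class = "fatigue_report")
}

#' @export
print.fatigue_report <- function(x, ...) {
  cat(sprintf("Fatigue detection report: %d cycle(s), overall verdict: %s\n",
              nrow(x$cycles), toupper(x$overall)))
  print(x$cycles, row.names = FALSE)
  invisible(x)
}

#' @export
summary.fatigue_report <- function(object, ...) {
  cat("Fatigue detection report\n")
  cat(sprintf("  frames:      %d (indices %d..%d)\n", nrow(object$states),
              min(object$states$frame_index),
              max(object$states$frame_index)))
  cat(sprintf("  thresholds:  EAR < %g (closed), MAR > %g (yawn)\n",
              object$thresholds$ear_closed, object$thresholds$mar_yawn))
  cfg <- object$config
  cat(sprintf("  cycle:       F0 = %d, PERCLOS >= %g, Fe >= %g, Fm >= %g\n",
              cfg$f0, cfg$perclos_threshold, cfg$fe_threshold,
              cfg$fm_threshold))
  cat(sprintf("  criteria:    %s\n", paste(cfg$criteria, collapse = ", ")))
  cat(sprintf("  episodes:    %d eye closure(s), %d yawn(s)\n",
              sum(object$episodes$kind == "eye_closure"),
              sum(object$episodes$kind == "yawn")))
  cat(sprintf("  fatigued cycles: %d of %d\n",
              sum(object$cycles$verdict == "fatigued"), nrow(object$cycles)))
  cat(sprintf("  OVERALL: %s\n", toupper(object$overall)))
  invisible(object)
}

#' @export
as.data.frame.fatigue_report <- function(x, ...) x$cycles

#' Plot EAR/MAR traces with states and thresholds
#'
#' Two stacked panels: EAR with the closed-eye threshold and MAR with the
#' yawn threshold; frames in state are marked along the baseline. Requires
#' the report to have been built from frames or a ratio series.
#'
#' @param x a `"fatigue_report"`.
#' @param ... passed to [graphics::plot()].
#' @return The report, invisibly.
#' @export
plot.fatigue_report <- function(x, ...) {
  if (is.null(x$ratios))
    stop_input("report was built from states only; no ratio traces to plot")
  r <- x$ratios; s <- x$states
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(r$frame_index, r$ear, type = "l", xlab = "frame",
                 ylab = "EAR", main = "Eye aspect ratio", ...)
  graphics::abline(h = x$thresholds$ear_closed, lty = 2, col = "red")
  if (any(s$eyes_closed))
    graphics::points(s$frame_index[s$eyes_closed],
                     rep(min(r$ear, na.rm = TRUE), sum(s$eyes_closed)),
                     pch = "|", col = "red")
  graphics::plot(r$frame_index, r$mar, type = "l", xlab = "frame",
                 ylab = "MAR", main = "Mouth aspect ratio", ...)
  graphics::abline(h = x$thresholds$mar_yawn, lty = 2, col = "blue")
  if (any(s$yawning))
    graphics::points(s$frame_index[s$yawning],
                     rep(min(r$mar, na.rm = TRUE), sum(s$yawning)),
                     pch = "|", col = "blue")
  invisible(x)
}
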