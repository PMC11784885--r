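# Eye and mouth aspect ratios. Planar formulas: only x and y enter; any z
# coordinate is carried through untouched. All ratios are sums of absolute
# vertical separations over three times the corner width, so they are
# invariant under translation, uniform scaling and axis reflection.

sum_vgaps <- function(frame, pairs) {
  s <- 0
  for (p in pairs)
    s <- s + abs(frame_coord(frame, p[1L], "y") - frame_coord(frame, p[2L], "y"))
  s
}

#' Eye aspect ratio (EAR) of one frame
#'
#' EAR of one eye is the sum of the three eyelid vertical separations divided
#' by three times the eye-corner width; the frame's EAR is the mean of the
#' left and right eye values:
#' \deqn{EAR_{right} = \frac{|Y_{384}-Y_{381}| + |Y_{386}-Y_{374}| +
#'   |Y_{388}-Y_{390}|}{3\,|X_{362}-X_{263}|}}
#' (left eye analogous over its own indices), \eqn{EAR = (EAR_{left} +
#' EAR_{right})/2}. EAR approaches 0 as the lids close.
#'
#' A zero eye width makes the ratio undefined: the frame is flagged invalid
#' (all three values `NA` plus a `perclos_invalid_frame` warning) rather than
#' silently zeroed. A missing or non-finite required landmark raises a
#' structured input error naming the frame and index.
#'
#' @param frame a [landmark_frame()].
#' @param map a [keypoint_map()].
#' @return Named numeric vector `c(ear_left, ear_right, ear)`.
#' @seealso [compute_mar()], [compute_ratio_series()]
#' @examples
#' f <- neutral_mesh(simulation_config(n_frames = 1))
#' compute_ear(f)
#' @export
compute_ear <- function(frame, map = keypoint_map()) {
  wl <- abs(diff(frame_coord(frame, map$left_eye_width, "x")))
  wr <- abs(diff(frame_coord(frame, map$right_eye_width, "x")))
  if (wl == 0 || wr == 0) {
    warn_invalid_frame(sprintf(
      "frame %d: zero eye width, EAR undefined", frame$frame_index))
    return(c(ear_left = NA_real_, ear_right = NA_real_, ear = NA_real_))
  }
  el <- sum_vgaps(frame, map$left_eye_vertical) / (3 * wl)
  er <- sum_vgaps(frame, map$right_eye_vertical) / (3 * wr)
  c(ear_left = el, ear_right = er, ear = (el + er) / 2)
}

#' Mouth aspect ratio (MAR) of one frame
#'
#' MAR uses eight points on the outer lip contour (inner-contour points are
#' unreliable across speakers):
#' \deqn{MAR = \frac{|Y_{39}-Y_{181}| + |Y_{0}-Y_{17}| +
#'   |Y_{269}-Y_{405}|}{3\,|X_{61}-X_{291}|}}
#' A closed mouth typically sits in the 0.2--0.3 band; yawns push MAR well
#' above 1. Zero mouth width flags the frame invalid (`NA` +
#' `perclos_invalid_frame` warning); missing landmarks raise a structured
#' input error naming the frame and index.
#'
#' @inheritParams compute_ear
#' @return MAR as a single numeric value.
#' @export
compute_mar <- function(frame, map = keypoint_map()) {
  w <- abs(diff(frame_coord(frame, map$mouth_width, "x")))
  if (w == 0) {
    warn_invalid_frame(sprintf(
      "frame %d: zero mouth width, MAR undefined", frame$frame_index))
    return(NA_real_)
  }
  sum_vgaps(frame, map$mouth_vertical) / (3 * w)
}

#' Per-frame EAR/MAR series
#'
#' Applies [compute_ear()] and [compute_mar()] to an ordered frame sequence.
#' One row per input frame, in order; frames with degenerate (zero-width)
#' geometry yield `valid = FALSE` rows instead of aborting the run.
#'
#' @param frames list of [landmark_frame()] objects with strictly increasing
#'   `frame_index`.
#' @param map a [keypoint_map()].
#' @return Data frame with columns `frame_index`, `ear_left`, `ear_right`,
#'   `ear`, `mar`, `valid`.
#' @export
compute_ratio_series <- function(frames, map = keypoint_map()) {
  if (length(frames) == 0L)
    return(data.frame(frame_index = integer(), ear_left = numeric(),
                      ear_right = numeric(), ear = numeric(),
                      mar = numeric(), valid = logical()))
  fi <- vapply(frames, function(f) f$frame_index, integer(1))
  if (any(diff(fi) <= 0L))
    stop_input("frame_index must be strictly increasing (no duplicates)")
  n <- length(frames)
  out <- data.frame(frame_index = fi, ear_left = NA_real_,
                    ear_right = NA_real_, ear = NA_real_, mar = NA_real_,
                    valid = FALSE)
  for (k in seq_len(n)) {
    e <- withCallingHandlers(
      compute_ear(frames[[k]], map),
      perclos_invalid_frame = function(w) invokeRestart("muffleWarning"))
    m <- withCallingHandlers(
      compute_mar(frames[[k]], map),
      perclos_invalid_frame = function(w) invokeRestart("muffleWarning"))
    out$ear_left[k] <- e[["ear_left"]]
    out$ear_right[k] <- e[["ear_right"]]
    out$ear[k] <- e[["ear"]]
    out$mar[k] <- m
    out$valid[k] <- all(is.finite(c(e, m)))
  }
  out
}
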