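# Synthetic facial kinematics: landmark sequences with known blink, closure
# and yawn events plus per-frame ground truth, so the whole detection
# pipeline can be exercised without any video data.
#
# Template geometry uses a 640-unit face width so noise magnitudes read like
# pixels. Eye width 80, mouth width 160; eyelid/lip gaps are set directly
# from the target EAR/MAR (gap = ratio * corner width, identical across the
# three vertical probes).

.face_geom <- list(
  left_eye  = list(corners = c(160, 240), y = 300, xs = c(180, 200, 220)),
  right_eye = list(corners = c(400, 480), y = 300, xs = c(420, 440, 460)),
  mouth     = list(corners = c(240, 400), y = 480, xs = c(280, 320, 360))
)

#' One animation event for the simulator
#'
#' `blink` and `closure` drive the eyelids (a blink is just a short closure);
#' `yawn` drives the lips. `onset` and `duration` delimit the plateau: frames
#' `[onset, onset + duration)` sit at the event's extreme ratio. `intensity`
#' scales how far the ratio travels from baseline toward the extreme (1 =
#' fully closed / fully open).
#'
#' @param kind `"blink"`, `"closure"` or `"yawn"`.
#' @param onset first plateau frame (>= 0).
#' @param duration plateau length in frames (>= 1).
#' @param intensity in (0, 1].
#' @return An object of class `"event_spec"`.
#' @export
event_spec <- function(kind = c("blink", "closure", "yawn"), onset, duration,
                       intensity = 1) {
  kind <- match.arg(kind)
  onset <- as.integer(onset); duration <- as.integer(duration)
  if (is.na(onset) || onset < 0L) stop_config("onset must be >= 0")
  if (is.na(duration) || duration < 1L) stop_config("duration must be >= 1")
  if (!is.numeric(intensity) || intensity <= 0 || intensity > 1)
    stop_config("intensity must lie in (0, 1]")
  structure(list(kind = kind, onset = onset, duration = duration,
                 intensity = intensity), class = "event_spec")
}

#' Simulation configuration
#'
#' Defaults encode the behavioural regime the detector assumes: resting EAR
#' 0.10 dipping to 0.005 during closures (below the 0.02 closed-eye
#' threshold), resting MAR 0.25 (inside the 0.2--0.3 closed-mouth band)
#' plateauing at 1.1 during yawns (above the 0.65 yawn threshold), at 23 fps
#' (a ~6.5 s yawn is then ~150 frames, one unit cycle). `ramp` frames of
#' linear attack/release precede and follow each plateau; the ramps approach
#' the decision thresholds without crossing them, the final closing motion
#' happening within one frame, so a simulated event occupies exactly its
#' stated plateau frames in the ground truth.
#'
#' @param n_frames sequence length in frames (>= 1).
#' @param fps nominal frame rate in Hz (only used to size default events).
#' @param events list of [event_spec()] objects; same-kind events (eye
#'   events: blink/closure together; yawns separately) must not overlap.
#' @param noise_sd Gaussian noise sd in coordinate units (face width 640),
#'   added independently per coordinate after animation.
#' @param seed optional integer; same seed, same output, caller RNG state
#'   untouched.
#' @param baseline_ear,closed_ear open/closed resting EAR; must bracket the
#'   0.02 threshold (`closed_ear < 0.02 < baseline_ear`).
#' @param baseline_mar closed-mouth MAR, constrained to \[0.2, 0.3\].
#' @param yawn_mar yawn-plateau MAR, > 0.65.
#' @param ramp attack/release length in frames (>= 0).
#' @return An object of class `"simulation_config"`.
#' @export
simulation_config <- function(n_frames, fps = 23, events = list(),
                              noise_sd = 0, seed = NULL,
                              baseline_ear = 0.10, closed_ear = 0.005,
                              baseline_mar = 0.25, yawn_mar = 1.1,
                              ramp = 10L) {
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 1L) stop_config("n_frames must be >= 1")
  if (!is.numeric(fps) || fps <= 0) stop_config("fps must be positive")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop_config("noise_sd must be >= 0")
  if (!(closed_ear < 0.02 && 0.02 < baseline_ear))
    stop_config("need closed_ear < 0.02 < baseline_ear")
  if (baseline_mar < 0.2 || baseline_mar > 0.3)
    stop_config("baseline_mar must lie in the closed-mouth band [0.2, 0.3]")
  if (yawn_mar <= 0.65) stop_config("yawn_mar must exceed 0.65")
  ramp <- as.integer(ramp)
  if (is.na(ramp) || ramp < 0L) stop_config("ramp must be >= 0")
  if (!all(vapply(events, inherits, logical(1), "event_spec")))
    stop_config("events must be a list of event_spec objects")
  for (ev in events)
    if (ev$onset + ev$duration > n_frames)
      stop_config(sprintf("event (%s, onset %d, duration %d) exceeds n_frames",
                          ev$kind, ev$onset, ev$duration))
  check_overlap <- function(evs, what) {
    if (length(evs) < 2L) return(invisible())
    o <- order(vapply(evs, `[[`, integer(1), "onset"))
    evs <- evs[o]
    for (k in seq_along(evs)[-1L])
      if (evs[[k]]$onset < evs[[k - 1L]]$onset + evs[[k - 1L]]$duration)
        stop_config(sprintf("overlapping %s events", what))
  }
  check_overlap(Filter(function(e) e$kind != "yawn", events), "eye")
  check_overlap(Filter(function(e) e$kind == "yawn", events), "yawn")
  structure(list(n_frames = n_frames, fps = fps, events = events,
                 noise_sd = noise_sd, seed = seed,
                 baseline_ear = baseline_ear, closed_ear = closed_ear,
                 baseline_mar = baseline_mar, yawn_mar = yawn_mar,
                 ramp = ramp),
            class = "simulation_config")
}

#' A default yawn event sized to the frame rate
#'
#' Typical yawns last about 6.5 s, i.e. `round(6.5 * fps)` frames -- 150
#' frames at the default 23 fps, a full unit cycle.
#'
#' @param config a [simulation_config()].
#' @param onset first plateau frame, default 0.
#' @return An [event_spec()] of kind `"yawn"`.
#' @export
default_yawn <- function(config, onset = 0L) {
  if (!is.numeric(config$fps) || config$fps <= 0)
    stop_config("fps must be positive")
  event_spec("yawn", onset, round(6.5 * config$fps))
}

#' Neutral face template
#'
#' A canonical 468-point mesh whose computed EAR equals `baseline_ear` and
#' MAR equals `baseline_mar` by construction. Non-keypoint indices are
#' static filler placed on a face-sized ellipse.
#'
#' @param config a [simulation_config()].
#' @param frame_index frame number for the returned frame.
#' @return A [landmark_frame()].
#' @export
neutral_mesh <- function(config, frame_index = 0L) {
  mesh_at(config$baseline_ear, config$baseline_mar, frame_index)
}

# build the template mesh for given instantaneous EAR/MAR
mesh_at <- function(ear, mar, frame_index = 0L, map = keypoint_map()) {
  i <- 0:467
  pts <- cbind(x = 320 + 310 * cos(2 * pi * i / 468),
               y = 400 + 380 * sin(2 * pi * i / 468),
               z = 0)
  set_xy <- function(pts, idx, x, y) {
    pts[idx + 1L, "x"] <- x; pts[idx + 1L, "y"] <- y; pts
  }
  place_eye <- function(pts, geom, width_pair, vpairs, gap) {
    pts <- set_xy(pts, width_pair[1L], geom$corners[1L], geom$y)
    pts <- set_xy(pts, width_pair[2L], geom$corners[2L], geom$y)
    for (k in 1:3) {
      pts <- set_xy(pts, vpairs[[k]][1L], geom$xs[k], geom$y - gap / 2)
      pts <- set_xy(pts, vpairs[[k]][2L], geom$xs[k], geom$y + gap / 2)
    }
    pts
  }
  eye_w <- diff(.face_geom$left_eye$corners)
  mouth_w <- diff(.face_geom$mouth$corners)
  pts <- place_eye(pts, .face_geom$left_eye, map$left_eye_width,
                   map$left_eye_vertical, ear * eye_w)
  pts <- place_eye(pts, .face_geom$right_eye, map$right_eye_width,
                   map$right_eye_vertical, ear * eye_w)
  pts <- place_eye(pts, .face_geom$mouth, map$mouth_width,
                   map$mouth_vertical, mar * mouth_w)
  landmark_frame(pts, frame_index)
}

# per-frame ratio trace for one channel. `toward` gives the in-event
# direction (-1 eyes closing, +1 mouth opening). Ramps interpolate from the
# baseline toward the decision threshold (or the plateau level if it stops
# short of the threshold) over ramp + 1 steps, so ramp frames approach but
# never reach the threshold: sub-threshold frames are exactly the plateau.
animate_trace <- function(n, baseline, plateau_full, threshold, events, ramp,
                          toward) {
  tr <- rep(baseline, n)
  combine <- if (toward < 0) pmin else pmax
  clampi <- function(i) i[i >= 1L & i <= n]
  for (ev in events) {
    lev <- baseline + ev$intensity * (plateau_full - baseline)
    ramp_end <- if (toward < 0) max(threshold, lev) else min(threshold, lev)
    pl <- clampi(ev$onset:(ev$onset + ev$duration - 1L) + 1L)
    tr[pl] <- combine(tr[pl], lev)
    if (ramp > 0L) {
      for (j in seq_len(ramp)) {
        a <- ev$onset - ramp + j - 1L         # attack, 0-based frame index
        r <- ev$onset + ev$duration + j - 1L  # release
        val_a <- baseline + (j / (ramp + 1)) * (ramp_end - baseline)
        val_r <- baseline + ((ramp - j + 1) / (ramp + 1)) * (ramp_end - baseline)
        ia <- clampi(a + 1L); ir <- clampi(r + 1L)
        tr[ia] <- combine(tr[ia], val_a)
        tr[ir] <- combine(tr[ir], val_r)
      }
    }
  }
  tr
}

#' Simulate a landmark-frame sequence with ground truth
#'
#' Animates the neutral template through the configured blink/closure/yawn
#' events: eyelid gaps follow a linear attack / plateau / release EAR
#' profile, lip gaps the analogous MAR profile, then independent Gaussian
#' noise (sd `noise_sd`) is added to every coordinate. Ground truth marks a
#' frame closed/yawning iff its noiseless EAR/MAR crosses the default
#' decision thresholds (0.02 / 0.65, strict), which by construction is
#' exactly the event plateau.
#'
#' @param config a [simulation_config()].
#' @return An object of class `"face_simulation"`: list with `frames` (list
#'   of [landmark_frame()]), `truth` (data frame `frame_index`,
#'   `eyes_closed`, `yawning`), `events`, and the noiseless `ear`/`mar`
#'   traces.
#' @examples
#' sim <- simulate_face(simulation_config(
#'   n_frames = 150, events = list(event_spec("closure", 60, 25))))
#' sum(sim$truth$eyes_closed)  # 25
#' @export
simulate_face <- function(config) {
  if (!inherits(config, "simulation_config"))
    stop_config("config must come from simulation_config()")
  n <- config$n_frames
  thr <- thresholds()  # truth is defined against the default thresholds
  eye_events <- Filter(function(e) e$kind != "yawn", config$events)
  yawn_events <- Filter(function(e) e$kind == "yawn", config$events)
  ear_tr <- animate_trace(n, config$baseline_ear, config$closed_ear,
                          thr$ear_closed, eye_events, config$ramp, -1)
  mar_tr <- animate_trace(n, config$baseline_mar, config$yawn_mar,
                          thr$mar_yawn, yawn_events, config$ramp, +1)

  if (!is.null(config$seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old_seed, envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(config$seed))
  }

  frames <- vector("list", n)
  for (k in seq_len(n)) {
    f <- mesh_at(ear_tr[k], mar_tr[k], frame_index = k - 1L)
    if (config$noise_sd > 0)
      f$points <- f$points + stats::rnorm(length(f$points),
                                          sd = config$noise_sd)
    frames[[k]] <- f
  }
  truth <- data.frame(frame_index = 0:(n - 1L),
                      eyes_closed = ear_tr < thr$ear_closed,
                      yawning = mar_tr > thr$mar_yawn)
  structure(list(frames = frames, truth = truth, events = config$events,
                 ear = ear_tr, mar = mar_tr, config = config),
            class = "face_simulation")
}

#' @export
print.face_simulation <- function(x, ...) {
  cat(sprintf(
    "<face_simulation> %d frames, %d event(s), noise sd %g; closed frames %d, yawning frames %d\n",
    x$config$n_frames, length(x$events), x$config$noise_sd,
    sum(x$truth$eyes_closed), sum(x$truth$yawning)))
  invisible(x)
}
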