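# Facial-mesh data model: landmark frames and the fixed keypoint map used by
# the eye/mouth aspect-ratio formulas. Landmark indices are 0-based
# throughout, matching the published mesh numbering (index 0 is a lip point).

#' Keypoint map for eye and mouth aspect ratios
#'
#' The fixed landmark indices the aspect-ratio formulas read from a 468-point
#' facial mesh. Each "width" entry is a horizontal corner pair; each
#' "vertical" entry is a list of three (upper, lower) lid or lip pairs.
#' Defaults follow the standard attention-mesh numbering: right eye corners
#' 362/263 with lid pairs (384,381), (386,374), (388,390); left eye corners
#' 33/133 with lid pairs (161,163), (159,145), (157,154); mouth corners
#' 61/291 with outer-lip pairs (39,181), (0,17), (269,405).
#'
#' Indices are 0-based. The defaults are immutable in the sense that the
#' ratio formulas are defined for them, but any pair can be overridden, e.g.
#' to adapt to a different mesh topology.
#'
#' @param right_eye_width,left_eye_width integer pairs, eye-corner indices.
#' @param right_eye_vertical,left_eye_vertical lists of three integer pairs,
#'   (upper lid, lower lid) per vertical probe.
#' @param mouth_width integer pair, mouth-corner indices.
#' @param mouth_vertical list of three integer pairs on the outer lip contour.
#' @return An object of class `"keypoint_map"`.
#' @examples
#' km <- keypoint_map()
#' km$mouth_width
#' @export
keypoint_map <- function(right_eye_width = c(362L, 263L),
                         right_eye_vertical = list(c(384L, 381L),
                                                   c(386L, 374L),
                                                   c(388L, 390L)),
                         left_eye_width = c(33L, 133L),
                         left_eye_vertical = list(c(161L, 163L),
                                                  c(159L, 145L),
                                                  c(157L, 154L)),
                         mouth_width = c(61L, 291L),
                         mouth_vertical = list(c(39L, 181L),
                                               c(0L, 17L),
                                               c(269L, 405L))) {
  map <- list(
    right_eye_width = as.integer(right_eye_width),
    right_eye_vertical = lapply(right_eye_vertical, as.integer),
    left_eye_width = as.integer(left_eye_width),
    left_eye_vertical = lapply(left_eye_vertical, as.integer),
    mouth_width = as.integer(mouth_width),
    mouth_vertical = lapply(mouth_vertical, as.integer)
  )
  check_pair <- function(p, what) {
    if (length(p) != 2L || any(is.na(p)) || any(p < 0L))
      stop_input(sprintf("%s must be a pair of non-negative indices", what))
  }
  check_group <- function(width, vertical, what) {
    check_pair(width, paste(what, "width"))
    for (p in vertical) check_pair(p, paste(what, "vertical pair"))
    idx <- c(width, unlist(vertical))
    if (anyDuplicated(idx))
      stop_input(sprintf("duplicated landmark index in %s keypoints", what))
  }
  check_group(map$right_eye_width, map$right_eye_vertical, "right eye")
  check_group(map$left_eye_width, map$left_eye_vertical, "left eye")
  check_group(map$mouth_width, map$mouth_vertical, "mouth")
  structure(map, class = "keypoint_map")
}

# all 0-based indices a map touches
map_indices <- function(map) {
  sort(unique(c(map$right_eye_width, unlist(map$right_eye_vertical),
                map$left_eye_width, unlist(map$left_eye_vertical),
                map$mouth_width, unlist(map$mouth_vertical))))
}

#' Construct a single landmark frame
#'
#' One video frame's facial mesh: at least 468 indexed 2D/3D points in mesh
#' order (row `i + 1` of `points` holds landmark index `i`; indexing is
#' 0-based to match the published keypoint numbers). Coordinates must share
#' one length unit on both axes — pixels are recommended; per-axis normalized
#' coordinates distort the ratios on non-square images (see
#' [read_landmark_table()] for rescaling on read).
#'
#' @param points numeric matrix with >= 468 rows and columns `x`, `y` and
#'   optionally `z` (z is carried but ignored by the planar ratio formulas).
#' @param frame_index non-negative integer frame number.
#' @param timestamp optional time in seconds.
#' @return An object of class `"landmark_frame"`.
#' @export
landmark_frame <- function(points, frame_index = 0L, timestamp = NULL) {
  points <- as.matrix(points)
  if (ncol(points) == 2L) colnames(points) <- c("x", "y")
  else if (ncol(points) == 3L) colnames(points) <- c("x", "y", "z")
  else stop_input("points must have 2 or 3 columns (x, y[, z])")
  if (nrow(points) < 468L)
    stop_input(sprintf("a landmark frame needs >= 468 points, got %d",
                       nrow(points)))
  storage.mode(points) <- "double"
  frame_index <- as.integer(frame_index)
  if (is.na(frame_index) || frame_index < 0L)
    stop_input("frame_index must be a non-negative integer")
  structure(list(frame_index = frame_index, points = points,
                 timestamp = timestamp),
            class = "landmark_frame")
}

#' @export
print.landmark_frame <- function(x, ...) {
  cat(sprintf("<landmark_frame> frame %d: %d points (%s)\n",
              x$frame_index, nrow(x$points),
              paste(colnames(x$points), collapse = ",")))
  invisible(x)
}

# coordinate lookup by 0-based landmark index; errors name the frame and the
# missing index (structured input error)
frame_coord <- function(frame, idx, axis) {
  pts <- frame$points
  bad <- idx + 1L > nrow(pts)
  if (any(bad))
    stop_input(sprintf("frame %d: landmark index %d missing",
                       frame$frame_index, idx[bad][1L]))
  v <- pts[idx + 1L, axis]
  if (any(!is.finite(v)))
    stop_input(sprintf("frame %d: landmark index %d has non-finite %s",
                       frame$frame_index, idx[!is.finite(v)][1L], axis))
  unname(v)
}

# structured error/condition helpers shared across the package
stop_input <- function(msg, call = sys.call(-1)) {
  stop(structure(class = c("perclos_input_error", "error", "condition"),
                 list(message = msg, call = call)))
}

stop_config <- function(msg, call = sys.call(-1)) {
  stop(structure(class = c("perclos_config_error", "error", "condition"),
                 list(message = msg, call = call)))
}

warn_invalid_frame <- function(msg) {
  warning(structure(class = c("perclos_invalid_frame", "warning", "condition"),
                    list(message = msg, call = NULL)))
}
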