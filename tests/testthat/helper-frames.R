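# Independent frame construction for tests: places the aspect-ratio
# keypoints explicitly from corner/gap specifications, with all other mesh
# indices as inert filler. Deliberately does not reuse the package's
# template builder.

KM <- keypoint_map()

# spec: list(corners = c(x_left, x_right), y = centre line, gaps = c(g1, g2, g3))
build_face_frame <- function(left_eye = list(corners = c(100, 130), y = 300,
                                             gaps = c(6, 8, 6)),
                             right_eye = left_eye_mirror(left_eye),
                             mouth = list(corners = c(90, 130), y = 480,
                                          gaps = c(30, 36, 30)),
                             frame_index = 0L, n_points = 468L) {
  pts <- matrix(1, nrow = n_points, ncol = 2,
                dimnames = list(NULL, c("x", "y")))
  put <- function(pts, idx, x, y) { pts[idx + 1, 1] <- x; pts[idx + 1, 2] <- y; pts }
  place <- function(pts, spec, width_pair, vpairs) {
    pts <- put(pts, width_pair[1], spec$corners[1], spec$y)
    pts <- put(pts, width_pair[2], spec$corners[2], spec$y)
    xs <- seq(spec$corners[1], spec$corners[2], length.out = 5)[2:4]
    for (k in 1:3) {
      pts <- put(pts, vpairs[[k]][1], xs[k], spec$y - spec$gaps[k] / 2)
      pts <- put(pts, vpairs[[k]][2], xs[k], spec$y + spec$gaps[k] / 2)
    }
    pts
  }
  pts <- place(pts, left_eye, KM$left_eye_width, KM$left_eye_vertical)
  pts <- place(pts, right_eye, KM$right_eye_width, KM$right_eye_vertical)
  pts <- place(pts, mouth, KM$mouth_width, KM$mouth_vertical)
  landmark_frame(pts, frame_index)
}

left_eye_mirror <- function(spec) {
  # same widths and gaps, shifted to the other side of the face
  list(corners = spec$corners + 200, y = spec$y, gaps = spec$gaps)
}

# apply an affine map (x, y) -> s * (x, y) + shift to every point
transform_frame <- function(frame, s = 1, shift = c(0, 0)) {
  frame$points[, "x"] <- s * frame$points[, "x"] + shift[1]
  frame$points[, "y"] <- s * frame$points[, "y"] + shift[2]
  frame
}

# reflect all x about a vertical axis
mirror_frame <- function(frame, axis_x = 0) {
  frame$points[, "x"] <- 2 * axis_x - frame$points[, "x"]
  frame
}

# states data frame straight from boolean vectors (frame 0..n-1)
states_from_flags <- function(closed, yawn = rep(FALSE, length(closed))) {
  data.frame(frame_index = seq_along(closed) - 1L, eyes_closed = closed,
             yawning = yawn, valid = TRUE)
}
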