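# Delimited-text readers and writers for every format the pipeline touches,
# plus YAML run configuration. Two landmark layouts are supported:
#   long: header frame,index,x,y[,z] -- one row per landmark
#   wide: header frame_index,x_0,y_0[,z_0],x_1,... -- one row per frame
# Landmark indices are 0-based in both.

#' Write landmark frames as delimited text
#'
#' @param frames list of [landmark_frame()] objects.
#' @param path output file.
#' @param format `"long"` (frame,index,x,y\[,z\]) or `"wide"` (one row per
#'   frame, coordinate triples in index order).
#' @return `path`, invisibly.
#' @export
write_landmark_table <- function(frames, path, format = c("long", "wide")) {
  format <- match.arg(format)
  has_z <- ncol(frames[[1L]]$points) == 3L
  if (format == "long") {
    tabs <- lapply(frames, function(f) {
      d <- data.frame(frame = f$frame_index,
                      index = seq_len(nrow(f$points)) - 1L,
                      x = f$points[, "x"], y = f$points[, "y"])
      if (has_z) d$z <- f$points[, "z"]
      d
    })
    utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  } else {
    rows <- lapply(frames, function(f) {
      v <- as.vector(t(f$points))
      c(f$frame_index, v)
    })
    m <- do.call(rbind, rows)
    axes <- if (has_z) c("x", "y", "z") else c("x", "y")
    idx <- rep(seq_len(nrow(frames[[1L]]$points)) - 1L, each = length(axes))
    colnames(m) <- c("frame_index", paste0(axes, "_", idx))
    utils::write.csv(m, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read landmark frames from delimited text
#'
#' Auto-detects the long or wide layout from the header. Coordinates are
#' pixels by default; `coords = "normalized"` rescales per-axis normalized
#' output (as many mesh extractors emit) by the image dimensions, restoring
#' the isotropic units the aspect-ratio formulas require.
#'
#' @param path input file.
#' @param coords `"pixel"` or `"normalized"`.
#' @param image_dims numeric `c(width, height)`; required for
#'   `coords = "normalized"`.
#' @param map a [keypoint_map()]; every frame is validated to contain the
#'   map's indices (errors name the frame and the missing index).
#' @return List of [landmark_frame()] objects ordered by frame index.
#' @export
read_landmark_table <- function(path, coords = c("pixel", "normalized"),
                                image_dims = NULL, map = keypoint_map()) {
  coords <- match.arg(coords)
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  if (coords == "normalized" &&
      (length(image_dims) != 2L || any(image_dims <= 0)))
    stop_config("normalized coordinates need image_dims = c(width, height)")
  tab <- utils::read.csv(path)
  long <- "index" %in% names(tab)
  frames <- if (long) parse_long_table(tab) else parse_wide_table(tab)
  if (coords == "normalized")
    frames <- lapply(frames, function(f) {
      f$points[, "x"] <- f$points[, "x"] * image_dims[1L]
      f$points[, "y"] <- f$points[, "y"] * image_dims[2L]
      f
    })
  need <- map_indices(map)
  for (f in frames)
    for (i in need)
      if (i + 1L > nrow(f$points) || any(!is.finite(f$points[i + 1L, c("x", "y")])))
        stop_input(sprintf("frame %d: required landmark index %d missing",
                           f$frame_index, i))
  frames
}

parse_long_table <- function(tab) {
  req <- c("frame", "index", "x", "y")
  if (!all(req %in% names(tab)))
    stop_input("long landmark table needs columns frame,index,x,y[,z]")
  num_cols <- intersect(c("frame", "index", "x", "y", "z"), names(tab))
  for (cl in num_cols) {
    bad <- which(is.na(suppressWarnings(as.numeric(tab[[cl]]))))
    if (length(bad))
      stop_input(sprintf("malformed value in column %s at line %d",
                         cl, bad[1L] + 1L))  # +1 for header line
  }
  has_z <- "z" %in% names(tab)
  out <- lapply(split(tab, tab$frame), function(d) {
    d <- d[order(d$index), , drop = FALSE]
    n <- max(d$index) + 1L
    pts <- matrix(NA_real_, nrow = n, ncol = if (has_z) 3L else 2L,
                  dimnames = list(NULL, if (has_z) c("x", "y", "z")
                                  else c("x", "y")))
    pts[d$index + 1L, "x"] <- d$x
    pts[d$index + 1L, "y"] <- d$y
    if (has_z) pts[d$index + 1L, "z"] <- d$z
    landmark_frame(pts, d$frame[1L])
  })
  unname(out[order(vapply(out, function(f) f$frame_index, integer(1)))])
}

parse_wide_table <- function(tab) {
  if (names(tab)[1L] != "frame_index")
    stop_input("wide landmark table must start with a frame_index column")
  axes <- unique(sub("_\\d+$", "", names(tab)[-1L]))
  if (!identical(axes, c("x", "y")) && !identical(axes, c("x", "y", "z")))
    stop_input("wide landmark table needs x_i,y_i[,z_i] coordinate columns")
  na_rows <- which(!stats::complete.cases(tab))
  if (length(na_rows))
    stop_input(sprintf("malformed row at line %d", na_rows[1L] + 1L))
  lapply(seq_len(nrow(tab)), function(k) {
    v <- as.numeric(tab[k, -1L])
    pts <- matrix(v, ncol = length(axes), byrow = TRUE,
                  dimnames = list(NULL, axes))
    landmark_frame(pts, tab$frame_index[k])
  })
}

#' Write / read per-frame truth or state series
#'
#' Sidecar format shared by the simulator's ground truth and the detector's
#' state output: columns `frame_index`, `eyes_closed`, `yawning`.
#'
#' @param states data frame with those columns.
#' @param path file path.
#' @return `path` (write) or the data frame (read).
#' @export
write_states <- function(states, path) {
  utils::write.csv(
    states[, intersect(c("frame_index", "eyes_closed", "yawning"),
                       names(states))],
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_states
#' @export
read_states <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  tab <- utils::read.csv(path)
  tab$eyes_closed <- as.logical(tab$eyes_closed)
  tab$yawning <- as.logical(tab$yawning)
  tab
}

#' Write episodes as delimited rows
#'
#' @param episodes data frame from [find_episodes()].
#' @param path file path.
#' @export
write_episodes <- function(episodes, path) {
  utils::write.csv(episodes, path, row.names = FALSE)
  invisible(path)
}

#' Read detection / ground-truth box tables
#'
#' Delimited rows `class,x_min,y_min,x_max,y_max[,confidence]` (confidence
#' required for detections, absent for ground truth). Coordinates are
#' pixels, origin top-left.
#'
#' @param path file path.
#' @param detections if `TRUE`, require a `confidence` column.
#' @return Data frame.
#' @export
read_boxes <- function(path, detections = FALSE) {
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  tab <- utils::read.csv(path)
  req <- c("class", box_cols, if (detections) "confidence")
  if (!all(req %in% names(tab)))
    stop_input(sprintf("box table needs columns %s",
                       paste(req, collapse = ",")))
  tab
}

#' Write a verdict report
#'
#' `format = "csv"` writes the per-cycle rows; `format = "text"` writes a
#' human-readable report with a provenance block (full threshold and cycle
#' configuration, package version, frame count) so every verdict is
#' auditable.
#'
#' @param report a `"fatigue_report"` from [classify_sequence()].
#' @param path file path.
#' @param format `"text"` or `"csv"`.
#' @export
write_verdict_report <- function(report, path, format = c("text", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(report$cycles, path, row.names = FALSE)
    return(invisible(path))
  }
  cfg <- report$config; thr <- report$thresholds
  lines <- c(
    "# fatigue detection report",
    sprintf("# package: perclos %s",
            as.character(utils::packageVersion("perclos"))),
    sprintf("# frames: %d", nrow(report$states)),
    sprintf("# ear_closed: %g", thr$ear_closed),
    sprintf("# mar_yawn: %g", thr$mar_yawn),
    sprintf("# f0: %d", cfg$f0),
    sprintf("# perclos_threshold: %g", cfg$perclos_threshold),
    sprintf("# fe_threshold: %g", cfg$fe_threshold),
    sprintf("# fm_threshold: %g", cfg$fm_threshold),
    sprintf("# stride: %d", cfg$stride),
    sprintf("# criteria: %s", paste(cfg$criteria, collapse = ",")),
    paste(utils::capture.output(
      print(report$cycles, row.names = FALSE)), collapse = "\n"),
    sprintf("OVERALL: %s", report$overall))
  writeLines(lines, path)
  invisible(path)
}

#' Read a YAML run configuration
#'
#' Top-level keys `thresholds:` (`ear_closed`, `mar_yawn`) and `cycle:`
#' (`f0`, `perclos_threshold`, `fe_threshold`, `fm_threshold`, `stride`,
#' `criteria`) override the printed defaults; omitted keys keep them.
#'
#' @param path YAML file.
#' @return List with validated `thresholds` and `cycle` objects.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  y <- yaml::read_yaml(path)
  thr <- do.call(thresholds, as.list(y$thresholds))
  cyc <- do.call(cycle_config, as.list(y$cycle))
  list(thresholds = thr, cycle = cyc)
}
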