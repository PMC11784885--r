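# Per-frame state thresholding and run-length episode segmentation.

#' Decision thresholds for per-frame states
#'
#' `ear_closed` is the EAR below which the eyes count as closed (default
#' 0.02: closure drives EAR toward 0); `mar_yawn` is the MAR above which the
#' mouth counts as yawning (default 0.65: closed mouths rest near 0.2--0.3,
#' yawns plateau near 1.1). Comparisons are strict (`<` / `>`), so a frame
#' sitting exactly on a threshold is in the normal state.
#'
#' @param ear_closed positive EAR threshold.
#' @param mar_yawn positive MAR threshold.
#' @return An object of class `"perclos_thresholds"`.
#' @export
thresholds <- function(ear_closed = 0.02, mar_yawn = 0.65) {
  if (!is.numeric(ear_closed) || length(ear_closed) != 1L || ear_closed <= 0)
    stop_config("ear_closed must be a single positive number")
  if (!is.numeric(mar_yawn) || length(mar_yawn) != 1L || mar_yawn <= 0)
    stop_config("mar_yawn must be a single positive number")
  structure(list(ear_closed = ear_closed, mar_yawn = mar_yawn),
            class = "perclos_thresholds")
}

#' Per-frame closed-eye / yawning states
#'
#' Thresholds the ratio series into boolean states. With no detector labels:
#' `yawning` iff `mar > mar_yawn` and `eyes_closed` iff `ear < ear_closed`
#' (both strict). When per-frame detector class labels are supplied the
#' combined rule is applied literally: `yawning` iff `o_mouth AND mar >
#' mar_yawn`; `eyes_closed` iff `c_eyes OR ear < ear_closed`. Invalid ratio
#' rows are neither closed nor yawning under the default policy.
#'
#' @param ratios data frame from [compute_ratio_series()] (columns `ear`,
#'   `mar`, `valid`; `frame_index` optional for a single ad-hoc row).
#' @param thresholds a [thresholds()] object.
#' @param labels optional data frame of per-frame detector flags, with
#'   logical columns `o_mouth` and `c_eyes` aligned row-by-row with `ratios`.
#' @return Data frame with columns `frame_index`, `eyes_closed`, `yawning`,
#'   `valid`.
#' @export
frame_states <- function(ratios, thresholds = perclos::thresholds(),
                         labels = NULL) {
  if (!all(c("ear", "mar") %in% names(ratios)))
    stop_input("ratios must have columns ear and mar")
  valid <- if ("valid" %in% names(ratios)) ratios$valid else
    is.finite(ratios$ear) & is.finite(ratios$mar)
  fi <- if ("frame_index" %in% names(ratios)) ratios$frame_index else
    seq_len(nrow(ratios)) - 1L
  closed <- valid & !is.na(ratios$ear) & ratios$ear < thresholds$ear_closed
  yawn <- valid & !is.na(ratios$mar) & ratios$mar > thresholds$mar_yawn
  if (!is.null(labels)) {
    if (nrow(labels) != nrow(ratios))
      stop_input("labels must align row-by-row with ratios")
    if ("o_mouth" %in% names(labels))
      yawn <- yawn & as.logical(labels$o_mouth)
    if ("c_eyes" %in% names(labels))
      closed <- (valid & as.logical(labels$c_eyes)) | closed
  }
  data.frame(frame_index = fi, eyes_closed = closed & valid,
             yawning = yawn & valid, valid = valid)
}

#' Maximal episodes of one state
#'
#' Run-length encodes a boolean state series into maximal episodes, reported
#' half-open: `start` is the first frame in state, `end` the first frame
#' after it, so `duration = end - start` is the number of in-state frames.
#' With `gap_tolerance = g > 0`, runs separated by at most `g` out-of-state
#' frames merge into one episode spanning the gap (duration is the merged
#' span); the raw unmerged runs remain available for PERCLOS accounting via
#' `gap_tolerance = 0`.
#'
#' @param states data frame from [frame_states()], contiguous in
#'   `frame_index`.
#' @param kind `"eye_closure"` (uses `eyes_closed`) or `"yawn"` (`yawning`).
#' @param gap_tolerance non-negative integer merge gap in frames.
#' @return Data frame with columns `kind`, `start`, `end`, `duration`,
#'   sorted and disjoint.
#' @export
find_episodes <- function(states, kind = c("eye_closure", "yawn"),
                          gap_tolerance = 0L) {
  kind <- match.arg(kind)
  gap_tolerance <- as.integer(gap_tolerance)
  if (is.na(gap_tolerance) || gap_tolerance < 0L)
    stop_config("gap_tolerance must be a non-negative integer")
  fi <- states$frame_index
  if (length(fi) > 1L && any(diff(fi) != 1L))
    stop_input("frame_index must be contiguous for episode detection")
  flag <- if (kind == "eye_closure") states$eyes_closed else states$yawning
  empty <- data.frame(kind = character(), start = integer(),
                      end = integer(), duration = integer())
  if (length(flag) == 0L || !any(flag)) return(empty)
  r <- rle(as.logical(flag))
  ends_rel <- cumsum(r$lengths)
  starts_rel <- ends_rel - r$lengths + 1L
  keep <- r$values
  start <- fi[starts_rel[keep]]
  end <- fi[ends_rel[keep]] + 1L
  if (gap_tolerance > 0L && length(start) > 1L) {
    ms <- start[1L]; me <- end[1L]
    out_s <- integer(); out_e <- integer()
    for (k in seq_along(start)[-1L]) {
      if (start[k] - me <= gap_tolerance) {
        me <- end[k]
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        ms <- start[k]; me <- end[k]
      }
    }
    start <- c(out_s, ms); end <- c(out_e, me)
  }
  data.frame(kind = kind, start = as.integer(start), end = as.integer(end),
             duration = as.integer(end - start))
}

#' Longest consecutive run among episodes
#'
#' The maximum episode duration in frames -- the quantity F_e (eyes) or F_m
#' (mouth) for a window. Empty input gives 0.
#'
#' @param episodes data frame from [find_episodes()].
#' @return Integer frame count.
#' @export
max_consecutive <- function(episodes) {
  if (is.null(episodes) || nrow(episodes) == 0L) return(0L)
  if (any(episodes$duration < 1L) || any(episodes$end <= episodes$start))
    stop_input("malformed episodes: need end > start and duration >= 1")
  as.integer(max(episodes$duration))
}
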