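#' Facial regions of interest
#'
#' Three named rectangular pixel regions per frame: forehead, left cheek and
#' right cheek. Boxes use 0-based pixel coordinates and are half-open,
#' `[x0, x1) x [y0, y1)`, so areas are unambiguous. Each region is either one
#' static box (recycled over frames) or a list with one box per frame.
#'
#' @param forehead,left_cheek,right_cheek Either a numeric vector
#'   `c(x0, x1, y0, y1)` or a list of such vectors (one per frame).
#' @param source `"landmark_detector"` or `"fixed_coordinates"`.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(forehead, left_cheek, right_cheek,
                    source = c("fixed_coordinates", "landmark_detector")) {
  source <- match.arg(source)
  check_box <- function(b, nm) {
    if (!is.numeric(b) || length(b) != 4L)
      stop("roi_set: region '", nm, "' box must be c(x0, x1, y0, y1)", call. = FALSE)
    if (b[2] <= b[1] || b[4] <= b[3])
      stop("roi_set: region '", nm, "' is empty", call. = FALSE)
    b
  }
  norm <- function(r, nm) {
    if (is.list(r)) lapply(r, check_box, nm = nm) else check_box(r, nm)
  }
  structure(list(forehead = norm(forehead, "forehead"),
                 left_cheek = norm(left_cheek, "left_cheek"),
                 right_cheek = norm(right_cheek, "right_cheek"),
                 source = source),
            class = "roi_set")
}

region_names <- function() c("forehead", "left_cheek", "right_cheek")

# box for region `nm` at frame i (1-based), handling static vs per-frame
region_box <- function(rois, nm, i) {
  r <- rois[[nm]]
  if (is.list(r)) r[[i]] else r
}

# map named facial landmarks to the three ROI boxes.
# Landmarks (0-based pixel coords, y down): brow_left, brow_right, eye_left,
# eye_right, nose_left, nose_right, jaw_left, jaw_right, hairline.
# Forehead: spans the inter-brow width, sits directly above the brows with
# height 25% of the brow-to-hairline span. Cheeks: boxes bounded by the outer
# eye corner, nose wing and jaw landmarks, eroded 10% per side to avoid
# region edges.
landmarks_to_rois <- function(lm, height, width) {
  need <- c("brow_left", "brow_right", "eye_left", "eye_right",
            "nose_left", "nose_right", "jaw_left", "jaw_right", "hairline")
  miss <- setdiff(need, names(lm))
  if (length(miss))
    stop("landmarks_to_rois: missing landmark(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  gx <- function(nm) lm[[nm]][1]
  gy <- function(nm) lm[[nm]][2]
  clampx <- function(v) pmin(pmax(v, 0), width)
  clampy <- function(v) pmin(pmax(v, 0), height)

  brow_y <- min(gy("brow_left"), gy("brow_right"))
  span <- brow_y - gy("hairline")
  if (span <= 0) stop("landmarks_to_rois: hairline must lie above the brows", call. = FALSE)
  fh <- c(min(gx("brow_left"), gx("brow_right")),
          max(gx("brow_left"), gx("brow_right")),
          brow_y - 0.25 * span, brow_y)

  erode <- function(b, f = 0.10) {
    w <- b[2] - b[1]; h <- b[4] - b[3]
    c(b[1] + f * w, b[2] - f * w, b[3] + f * h, b[4] - f * h)
  }
  lc <- erode(c(min(gx("eye_left"), gx("jaw_left")), gx("nose_left"),
                gy("eye_left"), gy("jaw_left")))
  rc <- erode(c(gx("nose_right"), max(gx("eye_right"), gx("jaw_right")),
                gy("eye_right"), gy("jaw_right")))

  snap <- function(b) {
    b <- c(clampx(round(b[1:2])), clampy(round(b[3:4])))
    if (b[2] <= b[1] || b[4] <= b[3])
      stop("landmarks_to_rois: degenerate region after snapping", call. = FALSE)
    b
  }
  list(forehead = snap(fh), left_cheek = snap(lc), right_cheek = snap(rc))
}

#' Locate facial ROIs in a video
#'
#' Runs a pluggable landmark detector on every frame and maps the landmarks to
#' forehead / left-cheek / right-cheek boxes. Frames where detection fails
#' inherit the last valid regions, up to `max_hold_s` seconds of consecutive
#' failures; leading failures are back-filled from the first valid frame. If
#' no frame yields a detection, the `fallback` fixed-coordinate [roi_set()] is
#' used; with neither, a detection-failure error is raised.
#'
#' @param video A [video_sequence()].
#' @param detector `function(frame)` returning a named list of landmark points
#'   `c(x, y)` (see [landmarks_to_rois()] for the required names), or `NULL`
#'   on failure. When `detector` itself is `NULL`, only the fallback is used.
#' @param fallback Optional [roi_set()] with `source = "fixed_coordinates"`.
#' @param max_hold_s Maximum consecutive detector-failure span (seconds) to
#'   bridge by holding the last valid regions.
#' @return An [roi_set()] with per-frame boxes (or the static fallback).
#' @export
detect_rois <- function(video, detector = NULL, fallback = NULL, max_hold_s = 1) {
  stopifnot(inherits(video, "video_sequence"))
  per_frame <- vector("list", video$n_frames)
  if (!is.null(detector)) {
    for (i in seq_len(video$n_frames)) {
      lm <- tryCatch(detector(video$frames[[i]]), error = function(e) NULL)
      if (!is.null(lm))
        per_frame[[i]] <- landmarks_to_rois(lm, video$height, video$width)
    }
  }
  valid <- !vapply(per_frame, is.null, logical(1))
  if (!any(valid)) {
    if (!is.null(fallback)) {
      stopifnot(inherits(fallback, "roi_set"))
      return(fallback)
    }
    stop("detect_rois: no face found in any frame and no fallback provided",
         call. = FALSE)
  }
  max_hold <- max(1L, ceiling(max_hold_s * video$fps))
  first_valid <- which(valid)[1]
  for (i in seq_len(first_valid - 1L)) per_frame[[i]] <- per_frame[[first_valid]]
  run <- 0L
  for (i in seq.int(first_valid + 1L, length.out = video$n_frames - first_valid)) {
    if (is.null(per_frame[[i]])) {
      run <- run + 1L
      if (run > max_hold)
        stop("detect_rois: detection lost for more than ", max_hold_s,
             " s at frame ", i, call. = FALSE)
      per_frame[[i]] <- per_frame[[i - 1L]]
    } else run <- 0L
  }
  roi_set(forehead = lapply(per_frame, `[[`, "forehead"),
          left_cheek = lapply(per_frame, `[[`, "left_cheek"),
          right_cheek = lapply(per_frame, `[[`, "right_cheek"),
          source = "landmark_detector")
}

#' Reduce video frames to ROI-averaged RGB traces
#'
#' For each region and frame, spatially averages the R, G and B pixel values
#' over the region's box, yielding one [rgb_trace()] per region.
#'
#' @param video A [video_sequence()].
#' @param rois An [roi_set()] valid for `video`.
#' @return Named list of three [rgb_trace()] objects
#'   (`forehead`, `left_cheek`, `right_cheek`).
#' @export
extract_trace <- function(video, rois) {
  stopifnot(inherits(video, "video_sequence"), inherits(rois, "roi_set"))
  out <- list()
  for (nm in region_names()) {
    M <- matrix(0, nrow = video$n_frames, ncol = 3L)
    for (i in seq_len(video$n_frames)) {
      b <- region_box(rois, nm, i)
      if (b[1] < 0 || b[3] < 0 || b[2] > video$width || b[4] > video$height)
        stop("extract_trace: region '", nm, "' outside frame bounds at frame ",
             i, call. = FALSE)
      rows <- (b[3] + 1L):b[4]   # 0-based half-open [y0, y1) -> 1-based rows
      cols <- (b[1] + 1L):b[2]
      px <- video$frames[[i]][rows, cols, , drop = FALSE]
      M[i, ] <- apply(px, 3L, mean)
    }
    out[[nm]] <- rgb_trace(M[, 1], M[, 2], M[, 3], fps = video$fps,
                           roi_name = nm, recording_id = video$recording_id)
  }
  out
}

#' Fuse region traces into one trace
#'
#' Per-frame, channel-wise unweighted mean of the three region traces; the
#' result carries `roi_name = "fused"`. The operation is symmetric in region
#' order and idempotent on identical inputs.
#'
#' @param traces List of [rgb_trace()] objects sharing length and fps.
#' @return A fused [rgb_trace()].
#' @export
fuse_traces <- function(traces) {
  stopifnot(is.list(traces), length(traces) >= 1L)
  lens <- vapply(traces, function(tr) tr$n_frames, integer(1))
  fpss <- vapply(traces, function(tr) tr$fps, numeric(1))
  if (length(unique(lens)) != 1L)
    stop("fuse_traces: traces differ in length (alignment error)", call. = FALSE)
  if (length(unique(fpss)) != 1L)
    stop("fuse_traces: traces differ in fps (alignment error)", call. = FALSE)
  avg <- function(ch) Reduce(`+`, lapply(traces, `[[`, ch)) / length(traces)
  rgb_trace(avg("R"), avg("G"), avg("B"), fps = fpss[1], roi_name = "fused",
            recording_id = traces[[1]]$recording_id)
}
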