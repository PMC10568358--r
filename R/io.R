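#' ROI-averaged RGB trace
#'
#' Container for a per-frame, spatially averaged RGB intensity series -- the
#' canonical interchange form between video/ROI handling and the rPPG core.
#'
#' @param R,G,B Equal-length numeric vectors of non-negative mean pixel
#'   intensities, one value per frame (arbitrary intensity units, typically
#'   0-255).
#' @param fps Frame rate in Hz (> 0).
#' @param roi_name Name of the source region, or `"fused"` for a combined
#'   trace.
#' @param recording_id Optional recording identifier.
#' @return An object of class `rgb_trace`: a list with elements `R`, `G`, `B`,
#'   `fps`, `roi_name`, `recording_id` and `n_frames`.
#' @export
rgb_trace <- function(R, G, B, fps, roi_name = "fused", recording_id = NULL) {
  R <- as.numeric(R); G <- as.numeric(G); B <- as.numeric(B)
  n <- length(R)
  if (length(G) != n || length(B) != n)
    stop("rgb_trace: R, G, B must have equal length", call. = FALSE)
  if (n < 2L)
    stop("rgb_trace: need at least 2 frames", call. = FALSE)
  if (!all(is.finite(c(R, G, B))) || any(c(R, G, B) < 0))
    stop("rgb_trace: channel values must be finite and >= 0", call. = FALSE)
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    stop("rgb_trace: fps must be a single positive number", call. = FALSE)
  structure(
    list(R = R, G = G, B = B, fps = as.numeric(fps),
         roi_name = roi_name, recording_id = recording_id, n_frames = n),
    class = "rgb_trace"
  )
}

#' @export
print.rgb_trace <- function(x, ...) {
  cat(sprintf("<rgb_trace> %d frames @ %.6g fps (%.1f s), roi = %s\n",
              x$n_frames, x$fps, x$n_frames / x$fps, x$roi_name))
  invisible(x)
}

#' Ground-truth record from a contact sensor
#'
#' Reference data for one recording: a contact-PPG waveform and/or a reference
#' heart-rate series from a pulse oximeter. Either component may be absent --
#' a record can be usable for the HR benchmark but not the HRV benchmark.
#'
#' @param hr Numeric vector of reference heart-rate samples (bpm), or `NULL`.
#' @param ppg Numeric vector of contact-PPG samples (arbitrary units), or
#'   `NULL`.
#' @param fs Sampling frequency in Hz for the PPG (and HR) series.
#' @param recording_id Optional recording identifier.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(hr = NULL, ppg = NULL, fs, recording_id = NULL) {
  if (!is.null(hr)) hr <- as.numeric(hr)
  if (!is.null(ppg)) ppg <- as.numeric(ppg)
  if ((is.null(hr) || length(hr) == 0L) && (is.null(ppg) || length(ppg) == 0L))
    stop("ground_truth: empty record (neither hr nor ppg present)", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("ground_truth: fs must be a single positive number", call. = FALSE)
  structure(
    list(hr = hr, ppg = ppg, fs = as.numeric(fs), recording_id = recording_id),
    class = "ground_truth"
  )
}

#' Subject metadata
#'
#' @param subject_id Subject identifier.
#' @param fitzpatrick Fitzpatrick skin type, an integer in 1..6.
#' @param gender `"male"` or `"female"`.
#' @return An object of class `subject_meta`.
#' @export
subject_meta <- function(subject_id, fitzpatrick, gender) {
  fitzpatrick <- as.integer(fitzpatrick)
  if (!fitzpatrick %in% 1:6)
    stop("subject_meta: fitzpatrick must be in 1..6", call. = FALSE)
  gender <- match.arg(gender, c("male", "female"))
  structure(list(subject_id = as.character(subject_id),
                 fitzpatrick = fitzpatrick, gender = gender),
            class = "subject_meta")
}

# parse "# key=value" comment headers from the top of a CSV file
read_header_meta <- function(path, n = 10L) {
  lines <- readLines(path, n = n, warn = FALSE)
  lines <- lines[startsWith(trimws(lines), "#")]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("#\\s*([A-Za-z_]+)\\s*=\\s*([-0-9.eE]+)", ln))[[1]]
    if (length(m) == 3L) out[[m[2]]] <- as.numeric(m[3])
  }
  out
}

#' Read an RGB trace from CSV
#'
#' Expects a comma-separated file with header columns `frame,R,G,B` (one row
#' per frame) and the frame rate carried in a `# fps=<value>` comment line at
#' the top of the file. Row order is preserved exactly as on disk.
#'
#' @param path Path to the CSV file.
#' @param fps Optional frame-rate override; when `NULL` the `# fps=` header
#'   comment is required.
#' @param roi_name,recording_id Passed through to [rgb_trace()].
#' @return An [rgb_trace()] object.
#' @export
read_trace_csv <- function(path, fps = NULL, roi_name = "fused",
                           recording_id = NULL) {
  if (!file.exists(path)) stop("read_trace_csv: file not found: ", path, call. = FALSE)
  meta <- read_header_meta(path)
  fps <- fps %||% meta$fps
  if (is.null(fps))
    stop("read_trace_csv: no fps given and no '# fps=' header in ", path, call. = FALSE)
  df <- read.csv(path, comment.char = "#")
  need <- c("frame", "R", "G", "B")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_trace_csv: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (cn in need)
    if (!is.numeric(df[[cn]]))
      stop("read_trace_csv: non-numeric values in column '", cn, "'", call. = FALSE)
  rgb_trace(df$R, df$G, df$B, fps = fps, roi_name = roi_name,
            recording_id = recording_id %||% sub("\\.csv$", "", basename(path)))
}

#' Write an RGB trace to CSV
#'
#' Counterpart of [read_trace_csv()]: writes `frame,R,G,B` rows preceded by a
#' `# fps=<value>` comment so the file is self-contained.
#'
#' @param trace An [rgb_trace()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "rgb_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fps=%.10g", trace$fps), con)
  df <- data.frame(frame = seq_len(trace$n_frames) - 1L,
                   R = trace$R, G = trace$G, B = trace$B)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a ground-truth record from CSV
#'
#' Expects columns `t` plus `hr` and/or `ppg`, with the sampling frequency in
#' a `# fs=<value>` header comment (or via the `fs` argument). A column that is
#' entirely `NA` counts as absent.
#'
#' @param path Path to the CSV file.
#' @param fs Optional sampling-frequency override.
#' @param recording_id Optional identifier.
#' @return A [ground_truth()] object.
#' @export
read_ground_truth <- function(path, fs = NULL, recording_id = NULL) {
  if (!file.exists(path)) stop("read_ground_truth: file not found: ", path, call. = FALSE)
  meta <- read_header_meta(path)
  fs <- fs %||% meta$fs
  if (is.null(fs))
    stop("read_ground_truth: no fs given and no '# fs=' header in ", path, call. = FALSE)
  df <- tryCatch(read.csv(path, comment.char = "#"),
                 error = function(e) stop("read_ground_truth: parse error: ",
                                          conditionMessage(e), call. = FALSE))
  pick <- function(cn) {
    if (!cn %in% names(df)) return(NULL)
    v <- df[[cn]]
    v <- v[!is.na(v)]
    if (length(v) == 0L) NULL else as.numeric(v)
  }
  hr <- pick("hr"); ppg <- pick("ppg")
  if (is.null(hr) && is.null(ppg))
    stop("read_ground_truth: empty record (no hr or ppg column with data) in ",
         path, call. = FALSE)
  ground_truth(hr = hr, ppg = ppg, fs = fs,
               recording_id = recording_id %||% sub("\\.csv$", "", basename(path)))
}

#' Write a ground-truth record to CSV
#'
#' @param gt A [ground_truth()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  stopifnot(inherits(gt, "ground_truth"))
  n <- max(length(gt$hr), length(gt$ppg))
  pad <- function(v) if (is.null(v)) rep(NA_real_, n) else c(v, rep(NA_real_, n - length(v)))
  df <- data.frame(t = (seq_len(n) - 1L) / gt$fs, hr = pad(gt$hr), ppg = pad(gt$ppg))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g", gt$fs), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Video frame sequence
#'
#' An ordered stack of equally sized RGB frames with a frame rate. Frames are
#' numeric `H x W x 3` arrays on the 0-255 intensity scale.
#'
#' @param frames List of `H x W x 3` numeric arrays, values in `[0, 255]`.
#' @param fps Frame rate (Hz).
#' @param recording_id Optional identifier.
#' @return An object of class `video_sequence`.
#' @export
video_sequence <- function(frames, fps, recording_id = NULL) {
  if (!is.list(frames) || length(frames) == 0L)
    stop("video_sequence: empty input (no frames)", call. = FALSE)
  d <- dim(frames[[1]])
  if (length(d) != 3L || d[3] != 3L)
    stop("video_sequence: frames must be H x W x 3 arrays", call. = FALSE)
  ok <- vapply(frames, function(f) identical(dim(f), d), logical(1))
  if (!all(ok))
    stop("video_sequence: all frames must share dimensions", call. = FALSE)
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    stop("video_sequence: fps must be a single positive number", call. = FALSE)
  structure(list(frames = frames, fps = as.numeric(fps),
                 height = d[1], width = d[2], n_frames = length(frames),
                 recording_id = recording_id),
            class = "video_sequence")
}

#' @export
print.video_sequence <- function(x, ...) {
  cat(sprintf("<video_sequence> %d frames of %dx%d @ %.6g fps\n",
              x$n_frames, x$width, x$height, x$fps))
  invisible(x)
}

#' Read a video frame stack
#'
#' Reads a multi-page TIFF frame stack (one page per frame, RGB). The frame
#' rate comes from a `<path>.meta` sidecar (a line `fps=<value>`) written by
#' [write_video()], unless overridden with `fps`.
#'
#' @param path Path to the multi-page TIFF file.
#' @param fps Optional frame-rate override (takes precedence over the
#'   sidecar).
#' @param recording_id Optional identifier.
#' @return A [video_sequence()] object with frames on the 0-255 scale.
#' @export
read_video <- function(path, fps = NULL, recording_id = NULL) {
  if (!file.exists(path)) stop("read_video: file not found: ", path, call. = FALSE)
  if (is.null(fps)) {
    sidecar <- paste0(path, ".meta")
    if (file.exists(sidecar)) {
      ln <- grep("^fps=", readLines(sidecar, warn = FALSE), value = TRUE)
      if (length(ln)) fps <- as.numeric(sub("^fps=", "", ln[1]))
    }
  }
  if (is.null(fps) || !is.finite(fps))
    stop("read_video: no fps override and no usable sidecar for ", path, call. = FALSE)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop("read_video: decode error: ",
                                             conditionMessage(e), call. = FALSE))
  if (is.array(pages)) pages <- list(pages)
  if (length(pages) == 0L) stop("read_video: empty input (zero frames)", call. = FALSE)
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 2L) p <- array(rep(p, 3L), c(dim(p), 3L))
    p[, , 1:3, drop = FALSE] * 255
  })
  video_sequence(frames, fps = fps,
                 recording_id = recording_id %||% sub("\\.[^.]+$", "", basename(path)))
}

#' Write a video frame stack
#'
#' Writes frames as a multi-page TIFF plus an fps sidecar `<path>.meta`,
#' round-tripping with [read_video()].
#'
#' @param video A [video_sequence()] object.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_video <- function(video, path) {
  stopifnot(inherits(video, "video_sequence"))
  pages <- lapply(video$frames, function(f) pmin(pmax(f / 255, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  writeLines(sprintf("fps=%.10g", video$fps), paste0(path, ".meta"))
  invisible(path)
}

#' Write benchmark report files
#'
#' Serialises per-recording vitals and per-subgroup agreement statistics to a
#' report directory: `details.csv` (one row per recording) and `summary.csv`
#' (one row per subgroup x metric), plus any supplied ggplot figures as PNG.
#'
#' @param details Data frame of per-recording estimates (e.g. the records
#'   table from [cohort_vitals()]).
#' @param summary Data frame of per-subgroup agreement statistics (e.g. from
#'   [benchmark_run()]).
#' @param dir Output directory (created if needed).
#' @param plots Optional named list of ggplot objects; each is saved as
#'   `<name>.png`.
#' @return Character vector of written file paths, invisibly.
#' @export
write_report <- function(details, summary, dir, plots = NULL) {
  if (is.null(details) || nrow(details) == 0L)
    stop("write_report: empty results", call. = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  drop_lists <- function(df) df[, !vapply(df, is.list, logical(1)), drop = FALSE]
  paths <- character(0)
  p <- file.path(dir, "details.csv")
  write.csv(drop_lists(as.data.frame(details)), p, row.names = FALSE)
  paths <- c(paths, p)
  if (!is.null(summary) && nrow(summary) > 0L) {
    p <- file.path(dir, "summary.csv")
    write.csv(drop_lists(as.data.frame(summary)), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  for (nm in names(plots)) {
    p <- file.path(dir, paste0(nm, ".png"))
    ggplot2::ggsave(p, plots[[nm]], width = 6, height = 5, dpi = 120)
    paths <- c(paths, p)
  }
  invisible(paths)
}
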