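#' @title Landmark data model
#' @description The 33-point full-body landmark topology used by on-device
#'   pose detectors (BlazePose family). Coordinates are image pixels with the
#'   origin at the top-left corner: x increases rightward, y increases
#'   downward. The z coordinate is a relative depth indication only and is
#'   carried through I/O but never used in any kinematic computation.
#' @name pose-model
NULL

#' Names of the 33 body landmarks, in index order
#'
#' The fixed named index map used throughout the package. The exact index
#' order of the upstream detector is not standardised in print; this ordering
#' is the package's documented convention and all named accessors resolve
#' through it.
#'
#' @return Character vector of length 33.
#' @export
#' @examples
#' landmark_names()[c(24, 26, 28)]  # left hip, knee, ankle
landmark_names <- function() {
  c("nose",
    "left_eye_inner", "left_eye", "left_eye_outer",
    "right_eye_inner", "right_eye", "right_eye_outer",
    "left_ear", "right_ear",
    "mouth_left", "mouth_right",
    "left_shoulder", "right_shoulder",
    "left_elbow", "right_elbow",
    "left_wrist", "right_wrist",
    "left_pinky", "right_pinky",
    "left_index", "right_index",
    "left_thumb", "right_thumb",
    "left_hip", "right_hip",
    "left_knee", "right_knee",
    "left_ankle", "right_ankle",
    "left_heel", "right_heel",
    "left_foot_index", "right_foot_index")
}

N_LANDMARKS <- 33L

#' Construct a single landmark frame
#'
#' A frame is a 33 x 4 numeric matrix (columns x, y, z, conf; rows named by
#' [landmark_names()]) with a capture-time attribute `t_s` in seconds.
#'
#' @param pts Numeric 33 x 4 matrix, columns x (px), y (px), z (relative),
#'   conf (in \[0, 1\]). Row order must follow [landmark_names()].
#' @param t_s Capture time in seconds.
#' @return A `landmark_frame` object.
#' @export
landmark_frame <- function(pts, t_s = 0) {
  pts <- as.matrix(pts)
  if (!is.numeric(pts) || nrow(pts) != N_LANDMARKS || ncol(pts) != 4L) {
    stop("landmark contract violation: a frame must contain exactly 33 points ",
         "with 4 values (x, y, z, conf); got ", nrow(pts), " x ", ncol(pts),
         call. = FALSE)
  }
  dimnames(pts) <- list(landmark_names(), c("x", "y", "z", "conf"))
  if (!all(is.finite(pts[, "x"])) || !all(is.finite(pts[, "y"])))
    stop("validation error: non-finite landmark coordinates", call. = FALSE)
  if (any(pts[, "conf"] < 0 | pts[, "conf"] > 1 | !is.finite(pts[, "conf"])))
    stop("validation error: landmark confidence outside [0, 1]", call. = FALSE)
  if (!is.numeric(t_s) || length(t_s) != 1L || !is.finite(t_s))
    stop("validation error: t_s must be a finite number", call. = FALSE)
  structure(pts, t_s = as.numeric(t_s), class = c("landmark_frame", "matrix", "array"))
}

#' @export
print.landmark_frame <- function(x, ...) {
  cat(sprintf("<landmark_frame> t = %.4f s, 33 points, mean conf %.2f\n",
              attr(x, "t_s"), mean(x[, "conf"])))
  invisible(x)
}

frame_time <- function(frame) attr(frame, "t_s")

#' Look up a landmark point by name
#'
#' @param frame A `landmark_frame`.
#' @param name Landmark name (see [landmark_names()]).
#' @return Named numeric vector (x, y, z, conf).
#' @export
landmark_point <- function(frame, name) {
  if (!name %in% landmark_names())
    stop("unknown landmark name: ", name, call. = FALSE)
  frame[name, ]
}

#' Construct a time-ordered landmark sequence
#'
#' @param frames List of `landmark_frame` objects with non-decreasing
#'   timestamps.
#' @param fps_nominal Nominal capture rate in Hz (> 0). Timestamps are stored
#'   explicitly so dropped frames remain representable.
#' @return A `landmark_sequence` object.
#' @export
landmark_sequence <- function(frames, fps_nominal = 30) {
  stopifnot(is.list(frames))
  if (!all(vapply(frames, inherits, logical(1), "landmark_frame")))
    stop("all elements must be landmark_frame objects", call. = FALSE)
  if (!is.numeric(fps_nominal) || fps_nominal <= 0)
    stop("validation error: fps_nominal must be > 0", call. = FALSE)
  t <- vapply(frames, frame_time, numeric(1))
  if (length(t) > 1L && any(diff(t) < 0))
    stop("validation error: timestamps must be non-decreasing", call. = FALSE)
  structure(list(frames = frames, fps_nominal = as.numeric(fps_nominal)),
            class = "landmark_sequence")
}

#' @export
length.landmark_sequence <- function(x) length(x$frames)

#' @export
print.landmark_sequence <- function(x, ...) {
  n <- length(x$frames)
  if (n > 0L) {
    t <- vapply(x$frames, frame_time, numeric(1))
    cat(sprintf("<landmark_sequence> %d frames, %.2f-%.2f s, nominal %g fps\n",
                n, min(t), max(t), x$fps_nominal))
  } else {
    cat(sprintf("<landmark_sequence> 0 frames, nominal %g fps\n", x$fps_nominal))
  }
  invisible(x)
}

#' Timestamps of a landmark sequence
#'
#' @param seq A `landmark_sequence`.
#' @return Numeric vector of capture times in seconds.
#' @export
sequence_times <- function(seq) {
  vapply(seq$frames, frame_time, numeric(1))
}

#' Read a landmark sequence from file
#'
#' Two on-disk dialects are supported. JSONL: one frame per line,
#' `{"t": seconds, "pts": [[x, y, z, c] x 33]}` in the documented index
#' order. CSV: a `t` column followed by `<name>_x`, `<name>_y`, `<name>_z`,
#' `<name>_c` per landmark, one row per frame. Exactly one skeleton per
#' frame: any other point count is a contract violation.
#'
#' @param path File path.
#' @param format `"jsonl"` or `"csv"`; default guesses from the extension.
#' @param fps_nominal Nominal capture rate attached to the sequence (Hz).
#' @return A validated `landmark_sequence`.
#' @export
read_landmarks <- function(path, format = c("auto", "jsonl", "csv"),
                           fps_nominal = 30) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "csv") "csv" else "jsonl"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  frames <- if (format == "jsonl") read_landmarks_jsonl(path)
            else read_landmarks_csv(path)
  landmark_sequence(frames, fps_nominal = fps_nominal)
}

read_landmarks_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  frames <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyMatrix = TRUE),
                    error = function(e)
                      stop("parse error at line ", i, ": ", conditionMessage(e),
                           call. = FALSE))
    if (is.null(rec$t) || is.null(rec$pts))
      stop("parse error at line ", i, ": missing 't' or 'pts'", call. = FALSE)
    pts <- rec$pts
    if (is.list(pts)) pts <- do.call(rbind, pts)
    frames[[i]] <- tryCatch(landmark_frame(pts, t_s = rec$t),
                            error = function(e)
                              stop("line ", i, ": ", conditionMessage(e),
                                   call. = FALSE))
  }
  frames
}

landmark_csv_header <- function() {
  nm <- landmark_names()
  c("t", as.vector(t(outer(nm, c("x", "y", "z", "c"), paste, sep = "_"))))
}

read_landmarks_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  expected <- landmark_csv_header()
  if (!identical(names(df), expected))
    stop("contract violation: CSV columns do not match the 33-landmark ",
         "schema (expected ", length(expected), " columns, got ",
         ncol(df), ")", call. = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    row <- as.numeric(df[i, -1L])
    pts <- matrix(row, nrow = N_LANDMARKS, ncol = 4L, byrow = TRUE)
    tryCatch(landmark_frame(pts, t_s = df$t[[i]]),
             error = function(e)
               stop("row ", i, ": ", conditionMessage(e), call. = FALSE))
  })
}

#' Write a landmark sequence to file
#'
#' Counterpart of [read_landmarks()]; the written file re-reads to a
#' value-identical sequence (within float round-trip).
#'
#' @param seq A `landmark_sequence`.
#' @param path Output file path.
#' @param format `"jsonl"` or `"csv"`; default guesses from the extension.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(seq, path, format = c("auto", "jsonl", "csv")) {
  stopifnot(inherits(seq, "landmark_sequence"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "csv") "csv" else "jsonl"
  }
  if (format == "jsonl") {
    lines <- vapply(seq$frames, function(fr) {
      jsonlite::toJSON(list(t = frame_time(fr),
                            pts = unname(fr[, c("x", "y", "z", "conf")])),
                       auto_unbox = TRUE, digits = NA)
    }, character(1))
    ok <- tryCatch({writeLines(lines, path); TRUE},
                   error = function(e) FALSE)
    if (!ok) stop("I/O error: cannot write ", path, call. = FALSE)
  } else {
    mat <- t(vapply(seq$frames, function(fr)
      c(frame_time(fr), as.vector(t(fr))), numeric(1L + 4L * N_LANDMARKS)))
    if (length(seq$frames) == 0L) mat <- matrix(numeric(0), ncol = 1L + 4L * N_LANDMARKS)
    df <- as.data.frame(mat)
    names(df) <- landmark_csv_header()
    ok <- tryCatch({utils::write.csv(df, path, row.names = FALSE); TRUE},
                   error = function(e) FALSE)
    if (!ok) stop("I/O error: cannot write ", path, call. = FALSE)
  }
  invisible(path)
}

#' Confidence gate for a frame
#'
#' A frame is reliable for a computation when every joint the computation
#' uses has detection confidence at or above `min_conf` (inclusive
#' boundary). Frames failing the gate are treated as unreliable rather than
#' erroring.
#'
#' @param frame A `landmark_frame`.
#' @param required_joints Character vector of landmark names (non-empty).
#' @param min_conf Minimum confidence in \[0, 1\]; default 0.5.
#' @return Logical flag.
#' @export
frame_is_reliable <- function(frame, required_joints, min_conf = 0.5) {
  stopifnot(inherits(frame, "landmark_frame"))
  if (length(required_joints) == 0L)
    stop("required_joints must be non-empty", call. = FALSE)
  unknown <- setdiff(required_joints, landmark_names())
  if (length(unknown))
    stop("unknown landmark name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(min_conf) || min_conf < 0 || min_conf > 1)
    stop("min_conf must be in [0, 1]", call. = FALSE)
  all(frame[required_joints, "conf"] >= min_conf)
}
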