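# Reading NTU-style .skeleton text files and persisting datasets.

#' Parse an NTU-style .skeleton file
#'
#' Reads the plain-text skeleton dialect used by the Kinect-V2 NTU recordings:
#' a frame count on the first line, then per frame a body count followed by,
#' for each body, one header line (body id plus tracking fields), one
#' joint-count line, and one line per joint whose first three whitespace
#' separated fields are the x, y, z coordinates in meters. Remaining joint
#' columns (depth/color projections, orientation quaternion, tracking state)
#' are parsed but only the tracking state (last column, when present) is kept.
#'
#' Frames in which a body is absent are recorded as null (all-zero) frames of
#' that body's track, so every returned track spans the full recording.
#'
#' @param path path to a `.skeleton` text file.
#' @return A list of `body_track` objects, one per distinct body id, each with
#'   fields `body_id` (character), `coords` (`T x J x 3`), `flags` (`T x J`
#'   integer tracking states) and `null_frame` (logical length `T`).
#' @seealso [select_main_actor()] to reduce multi-body files to one
#'   [pose_sequence].
#' @examples
#' path <- system.file("extdata", "example_synthetic.skeleton",
#'                     package = "skelflow")
#' tracks <- read_ntu_skeleton(path)
#' length(tracks)
#' dim(tracks[[1]]$coords)
#' @export
read_ntu_skeleton <- function(path) {
  if (!file.exists(path)) stop("skeleton file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  pos <- 0L
  next_line <- function(what) {
    pos <<- pos + 1L
    if (pos > length(lines))
      stop(sprintf("parse error at line %d: truncated file, expected %s",
                   pos, what))
    lines[[pos]]
  }
  scalar_int <- function(what) {
    ln <- trimws(next_line(what))
    v <- suppressWarnings(as.integer(ln))
    if (length(v) != 1L || is.na(v))
      stop(sprintf("parse error at line %d: expected %s, got '%s'",
                   pos, what, ln))
    v
  }

  n_frames <- scalar_int("frame count")
  if (n_frames < 1L) stop("parse error at line 1: frame count must be >= 1")

  J <- NA_integer_
  # body_id -> list(coords = list per frame index, flags)
  frames_by_body <- list()
  order_seen <- character(0)

  for (t in seq_len(n_frames)) {
    n_bodies <- scalar_int(sprintf("body count of frame %d", t))
    if (n_bodies < 0L)
      stop(sprintf("parse error at line %d: negative body count", pos))
    for (b in seq_len(n_bodies)) {
      header <- strsplit(trimws(next_line("body header")), "\\s+")[[1]]
      if (length(header) < 1L || !nzchar(header[1]))
        stop(sprintf("parse error at line %d: empty body header", pos))
      body_id <- header[1]
      jc <- scalar_int("joint count")
      if (is.na(J)) {
        if (jc < 1L)
          stop(sprintf("format error at line %d: joint count must be >= 1", pos))
        J <- jc
      } else if (jc != J) {
        stop(sprintf(
          "format error at line %d: joint count %d differs from declared %d",
          pos, jc, J))
      }
      xyz <- matrix(0, nrow = J, ncol = 3)
      flg <- integer(J)
      for (j in seq_len(J)) {
        fields <- strsplit(trimws(next_line(sprintf("joint %d of frame %d", j, t))),
                           "\\s+")[[1]]
        vals <- suppressWarnings(as.numeric(fields))
        if (length(vals) < 3L || any(is.na(vals[1:3])))
          stop(sprintf("parse error at line %d: joint line needs >= 3 numeric fields",
                       pos))
        xyz[j, ] <- vals[1:3]
        # NTU joint rows end with an integer tracking state.
        flg[j] <- if (length(vals) > 3L && !is.na(vals[length(vals)]))
          as.integer(vals[length(vals)]) else 1L
      }
      if (is.null(frames_by_body[[body_id]])) {
        frames_by_body[[body_id]] <- list(coords = vector("list", n_frames),
                                          flags = vector("list", n_frames))
        order_seen <- c(order_seen, body_id)
      }
      frames_by_body[[body_id]]$coords[[t]] <- xyz
      frames_by_body[[body_id]]$flags[[t]] <- flg
    }
  }
  if (pos < length(lines) && any(nzchar(trimws(lines[(pos + 1L):length(lines)]))))
    stop(sprintf("parse error at line %d: trailing content after declared frames",
                 pos + 1L))
  if (length(order_seen) == 0L)
    stop("format error: file declares no bodies in any frame")

  lapply(order_seen, function(id) {
    rec <- frames_by_body[[id]]
    coords <- array(0, dim = c(n_frames, J, 3))
    flags <- matrix(0L, nrow = n_frames, ncol = J)
    null_frame <- rep(TRUE, n_frames)
    for (t in seq_len(n_frames)) {
      if (!is.null(rec$coords[[t]])) {
        coords[t, , ] <- rec$coords[[t]]
        flags[t, ] <- rec$flags[[t]]
        null_frame[t] <- all(rec$coords[[t]] == 0)
      }
    }
    structure(list(body_id = id, coords = coords, flags = flags,
                   null_frame = null_frame),
              class = "body_track")
  })
}

#' Select the main actor among parsed body tracks
#'
#' Multi-body recordings are reduced to a single [pose_sequence] by keeping
#' the track with the largest motion energy: the sum over joints and axes of
#' the temporal variance of coordinates, computed over non-null frames only.
#' Ties are broken by the lexicographically smallest body id, so the choice is
#' deterministic and invariant to track order.
#'
#' @param tracks list of `body_track` objects from [read_ntu_skeleton()].
#' @param seq_id identifier for the resulting sequence.
#' @return A [pose_sequence] (null frames retained as all-zero frames; see
#'   [pad_null_frames()]).
#' @export
select_main_actor <- function(tracks, seq_id = "") {
  if (length(tracks) < 1L) stop("need at least one body track")
  energies <- vapply(tracks, motion_energy, numeric(1))
  live <- vapply(tracks, function(tr) any(!tr$null_frame), logical(1))
  if (!any(live)) stop("empty sequence: all tracks consist of null frames only")
  ids <- vapply(tracks, function(tr) tr$body_id, character(1))
  # order: descending energy, then ascending body_id; drop fully-null tracks
  keep <- which(live)
  best <- keep[order(-energies[keep], ids[keep])][1]
  tr <- tracks[[best]]
  pose_sequence(tr$coords, seq_id = if (nzchar(seq_id)) seq_id else tr$body_id)
}

motion_energy <- function(track) {
  ok <- !track$null_frame
  if (sum(ok) < 2L) return(0)
  sub <- track$coords[ok, , , drop = FALSE]
  sum(apply(sub, c(2, 3), stats::var))
}

#' Save / load a dataset container
#'
#' Persists a [dataset_handle] losslessly: coordinates round-trip bit-exactly
#' and labels, split tag and metadata exactly. Sequences keep their individual
#' frame counts (ragged storage). The on-disk container is a single
#' serialized R object with a format marker and version, validated on load.
#'
#' @param data a [dataset_handle].
#' @param path file path to write / read.
#' @return `save_dataset()` returns `path` invisibly; `load_dataset()` returns
#'   the restored [dataset_handle].
#' @export
save_dataset <- function(data, path) {
  if (!inherits(data, "dataset_handle")) stop("data must be a dataset_handle")
  payload <- list(
    format = "skelflow-dataset",
    version = 1L,
    coords = lapply(data$sequences, function(s) s$coords),
    seq_ids = vapply(data$sequences, function(s) s$seq_id, character(1)),
    labels = data$labels,
    split_tag = data$split_tag,
    meta = data$meta
  )
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) {
  if (!file.exists(path)) stop("dataset file not found: ", path)
  payload <- tryCatch(readRDS(path),
                      error = function(e) stop("container error: unreadable dataset file: ",
                                               conditionMessage(e)))
  if (!is.list(payload) || !identical(payload$format, "skelflow-dataset"))
    stop("container error: not a skelflow dataset container")
  for (field in c("coords", "labels", "split_tag"))
    if (is.null(payload[[field]]))
      stop("container error: missing '", field, "' in dataset container")
  if (length(payload$coords) != length(payload$labels))
    stop("container error: coords/labels length mismatch")
  seqs <- mapply(function(co, id) {
    if (!is.array(co) || length(dim(co)) != 3L)
      stop("container error: sequence array has wrong shape")
    pose_sequence(co, seq_id = id)
  }, payload$coords, payload$seq_ids, SIMPLIFY = FALSE)
  dataset_handle(seqs, labels = payload$labels, split_tag = payload$split_tag,
                 meta = if (is.null(payload$meta)) list() else payload$meta)
}
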