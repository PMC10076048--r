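# Normalization recipe: null-frame padding, spine centering, axis alignment,
# temporal resampling. Joint indices are 1-based and default to the Kinect-V2
# 25-joint layout.

#' Normalization configuration
#'
#' Joint indices follow the Kinect-V2/NTU 25-joint convention, 1-based:
#' joint 1 is the spine base ("hip"), joint 2 the spine mid ("spine"),
#' joint 5 the left shoulder and joint 9 the right shoulder. All indices are
#' configurable for other skeleton layouts.
#'
#' @param spine_center_index joint moved to the origin in every frame.
#' @param hip_index,spine_index the bone made parallel to the z axis.
#' @param left_shoulder_index,right_shoulder_index the bone made parallel to
#'   the x axis (right-to-left direction).
#' @param max_frames fixed output length of [temporal_resample()].
#' @param rotation_reference `"first_valid_frame"` computes one rotation from
#'   the first non-null frame and applies it to all frames (preserving
#'   within-sequence orientation motion); `"per_frame"` re-estimates the
#'   rotation in every frame (removing it), kept for ablation.
#' @return An object of class `normalization_config`.
#' @export
normalization_config <- function(spine_center_index = 2L, hip_index = 1L,
                                 spine_index = 2L, left_shoulder_index = 5L,
                                 right_shoulder_index = 9L, max_frames = 50L,
                                 rotation_reference = c("first_valid_frame",
                                                        "per_frame")) {
  idx <- c(spine_center_index, hip_index, spine_index,
           left_shoulder_index, right_shoulder_index)
  if (any(idx < 1L)) stop("config error: joint indices must be >= 1")
  if (hip_index == spine_index)
    stop("config error: hip and spine indices must differ")
  if (left_shoulder_index == right_shoulder_index)
    stop("config error: shoulder indices must differ")
  if (max_frames < 1L) stop("config error: max_frames must be >= 1")
  structure(list(spine_center_index = as.integer(spine_center_index),
                 hip_index = as.integer(hip_index),
                 spine_index = as.integer(spine_index),
                 left_shoulder_index = as.integer(left_shoulder_index),
                 right_shoulder_index = as.integer(right_shoulder_index),
                 max_frames = as.integer(max_frames),
                 rotation_reference = match.arg(rotation_reference)),
            class = "normalization_config")
}

check_cfg_indices <- function(cfg, J) {
  idx <- c(cfg$spine_center_index, cfg$hip_index, cfg$spine_index,
           cfg$left_shoulder_index, cfg$right_shoulder_index)
  if (any(idx > J))
    stop(sprintf("config error: joint index out of range (J = %d)", J))
}

#' Replace null frames by their nearest preceding frame
#'
#' A null frame (all coordinates exactly zero, the sensor's missed-detection
#' convention) is replaced by the closest preceding non-null frame; leading
#' null frames are replaced by the first non-null frame. The frame count is
#' unchanged.
#'
#' @param seq a [pose_sequence].
#' @return A [pose_sequence] with no null frames.
#' @export
pad_null_frames <- function(seq) {
  nullf <- is_null_frame(seq$coords)
  if (all(nullf)) stop("empty sequence: all frames are null")
  if (!any(nullf)) return(seq)
  coords <- seq$coords
  first_ok <- which(!nullf)[1]
  last_ok <- first_ok
  for (t in seq_len(dim(coords)[1])) {
    if (nullf[t]) coords[t, , ] <- coords[last_ok, , ] else last_ok <- t
  }
  # leading nulls take the first non-null frame
  if (first_ok > 1L)
    for (t in seq_len(first_ok - 1L)) coords[t, , ] <- coords[first_ok, , ]
  pose_sequence(coords, label = seq$label, seq_id = seq$seq_id)
}

#' Move the spine-center joint to the origin in every frame
#'
#' @param seq a [pose_sequence].
#' @param cfg a [normalization_config].
#' @return A [pose_sequence] whose `spine_center_index` joint is exactly
#'   `(0, 0, 0)` in every frame.
#' @export
center_spine <- function(seq, cfg = normalization_config()) {
  check_cfg_indices(cfg, n_joints(seq))
  coords <- seq$coords
  TT <- dim(coords)[1]; J <- dim(coords)[2]
  ctr <- coords[, cfg$spine_center_index, , drop = FALSE] # T x 1 x 3
  coords <- coords - ctr[, rep(1L, J), , drop = FALSE]
  pose_sequence(coords, label = seq$label, seq_id = seq$seq_id)
}

# Orthonormal body basis from one frame: z' along hip->spine, x' along the
# right->left shoulder direction with its z' component removed, y' = z' x x'.
# Columns of the returned matrix are (x', y', z').
body_basis <- function(frame, cfg, frame_idx = 1L) {
  zv <- frame[cfg$spine_index, ] - frame[cfg$hip_index, ]
  nz <- sqrt(sum(zv^2))
  if (nz < 1e-12)
    stop(sprintf("degenerate reference bones in frame %d: hip and spine coincide",
                 frame_idx))
  zu <- zv / nz
  sh <- frame[cfg$left_shoulder_index, ] - frame[cfg$right_shoulder_index, ]
  xv <- sh - sum(sh * zu) * zu
  nx <- sqrt(sum(xv^2))
  if (nx < 1e-12)
    stop(sprintf("degenerate reference bones in frame %d: shoulder line is zero or collinear with the spine",
                 frame_idx))
  xu <- xv / nx
  yu <- c(zu[2] * xu[3] - zu[3] * xu[2],
          zu[3] * xu[1] - zu[1] * xu[3],
          zu[1] * xu[2] - zu[2] * xu[1])
  cbind(xu, yu, zu, deparse.level = 0)
}

#' Rotate a sequence into its body-centric axes
#'
#' Builds a rotation from a reference frame (by default the first non-null
#' frame) so that the hip-to-spine bone is parallel to the z axis and the
#' right-to-left shoulder line is parallel to the x axis, then expresses every
#' frame in that basis. With `rotation_reference = "per_frame"` the basis is
#' recomputed each frame instead.
#'
#' @param seq a [pose_sequence].
#' @param cfg a [normalization_config].
#' @return The rotated [pose_sequence].
#' @export
align_axes <- function(seq, cfg = normalization_config()) {
  check_cfg_indices(cfg, n_joints(seq))
  coords <- seq$coords
  TT <- dim(coords)[1]
  if (cfg$rotation_reference == "first_valid_frame") {
    nullf <- is_null_frame(coords)
    if (all(nullf)) stop("empty sequence: all frames are null")
    ref <- which(!nullf)[1]
    R <- body_basis(coords[ref, , ], cfg, ref)
    for (t in seq_len(TT)) coords[t, , ] <- coords[t, , ] %*% R
  } else {
    for (t in seq_len(TT)) {
      R <- body_basis(coords[t, , ], cfg, t)
      coords[t, , ] <- coords[t, , ] %*% R
    }
  }
  pose_sequence(coords, label = seq$label, seq_id = seq$seq_id)
}

#' Resample a sequence to a fixed frame count
#'
#' Sequences longer than `max_frames` are uniformly subsampled at
#' `round(linspace(1, T, max_frames))` (strictly increasing indices, keeping
#' the first and last frame); shorter sequences are padded by repeating the
#' last frame. The output always has exactly `max_frames` frames.
#'
#' @param seq a [pose_sequence].
#' @param max_frames target frame count (default 50).
#' @return A [pose_sequence] with `max_frames` frames.
#' @export
temporal_resample <- function(seq, max_frames = 50L) {
  max_frames <- as.integer(max_frames)
  if (is.na(max_frames) || max_frames < 1L)
    stop("config error: max_frames must be >= 1")
  TT <- n_frames(seq)
  if (TT > max_frames) {
    if (max_frames == 1L) idx <- 1L
    else idx <- as.integer(floor(seq(1, TT, length.out = max_frames) + 0.5))
    coords <- seq$coords[idx, , , drop = FALSE]
  } else {
    coords <- seq$coords[c(seq_len(TT), rep(TT, max_frames - TT)), , ,
                         drop = FALSE]
  }
  pose_sequence(coords, label = seq$label, seq_id = seq$seq_id)
}

#' Full normalization pipeline
#'
#' Composes the four stages in order: [pad_null_frames()], [center_spine()],
#' [align_axes()], [temporal_resample()]. The result is invariant to global
#' translation and (proper) rotation of the input, has the spine-center joint
#' at the origin in every frame, the reference-frame hip-to-spine bone along
#' z, and exactly `cfg$max_frames` frames. Applying it twice gives the same
#' result as applying it once.
#'
#' @param seq a [pose_sequence].
#' @param cfg a [normalization_config].
#' @return The normalized [pose_sequence].
#' @export
normalize_sequence <- function(seq, cfg = normalization_config()) {
  temporal_resample(align_axes(center_spine(pad_null_frames(seq), cfg), cfg),
                    cfg$max_frames)
}

#' Normalize every sequence of a dataset
#'
#' @param data a [dataset_handle].
#' @param cfg a [normalization_config].
#' @return A [dataset_handle] of normalized sequences (labels and metadata
#'   preserved; `meta$normalized` set).
#' @export
normalize_dataset <- function(data, cfg = normalization_config()) {
  seqs <- lapply(data$sequences, normalize_sequence, cfg = cfg)
  meta <- data$meta
  meta$normalized <- TRUE
  meta$max_frames <- cfg$max_frames
  dataset_handle(seqs, labels = data$labels, split_tag = data$split_tag,
                 meta = meta)
}
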