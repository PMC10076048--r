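#' Pose sequence container
#'
#' A pose sequence holds the ordered frames of one body's 3D joint
#' coordinates: an array of shape `T x J x 3` (frames x joints x axes, in
#' meters). It is the raw signal from which all supervision signals
#' (pose flows) are derived.
#'
#' @param coords numeric array of dimension `c(T, J, 3)`; all entries finite.
#' @param label optional nonnegative integer class label.
#' @param seq_id character identifier.
#' @return An object of class `pose_sequence` with fields `coords`, `label`,
#'   `seq_id`.
#' @export
pose_sequence <- function(coords, label = NULL, seq_id = "") {
  if (!is.array(coords) || length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop("coords must be a T x J x 3 array")
  if (dim(coords)[1] < 1L) stop("pose_sequence needs T >= 1 frames")
  if (dim(coords)[2] < 2L) stop("pose_sequence needs J >= 2 joints")
  if (!all(is.finite(coords))) stop("coords must be finite")
  if (!is.null(label)) {
    label <- as.integer(label)
    if (is.na(label) || label < 0L) stop("label must be a nonnegative integer")
  }
  structure(list(coords = coords, label = label, seq_id = as.character(seq_id)),
            class = "pose_sequence")
}

#' @export
print.pose_sequence <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<pose_sequence '%s': T=%d frames, J=%d joints%s>\n",
              x$seq_id, d[1], d[2],
              if (is.null(x$label)) "" else sprintf(", label=%d", x$label)))
  invisible(x)
}

n_frames <- function(seq) dim(seq$coords)[1]
n_joints <- function(seq) dim(seq$coords)[2]

#' Dataset of pose sequences
#'
#' Bundles a list of [pose_sequence] objects with integer labels and split
#' metadata. Sequences may have differing frame counts T (ragged storage);
#' [normalize_dataset()] unifies them to a fixed length.
#'
#' @param sequences list of [pose_sequence] objects.
#' @param labels integer vector, one nonnegative label per sequence. Defaults
#'   to the sequences' own `label` fields.
#' @param split_tag `"train"` or `"test"`.
#' @param meta free-form named list of metadata.
#' @return An object of class `dataset_handle`.
#' @export
dataset_handle <- function(sequences, labels = NULL, split_tag = "train",
                           meta = list()) {
  if (!is.list(sequences) || !all(vapply(sequences, inherits, TRUE, "pose_sequence")))
    stop("sequences must be a list of pose_sequence objects")
  if (is.null(labels)) {
    labels <- vapply(sequences, function(s) {
      if (is.null(s$label)) stop("labels not given and a sequence has no label")
      s$label
    }, integer(1))
  }
  labels <- as.integer(labels)
  if (length(labels) != length(sequences))
    stop("length(labels) must equal length(sequences)")
  if (any(is.na(labels)) || any(labels < 0L))
    stop("labels must be nonnegative integers")
  split_tag <- match.arg(split_tag, c("train", "test"))
  structure(list(sequences = sequences, labels = labels,
                 split_tag = split_tag, meta = meta),
            class = "dataset_handle")
}

#' @export
print.dataset_handle <- function(x, ...) {
  cat(sprintf("<dataset_handle [%s]: %d sequences, %d classes>\n",
              x$split_tag, length(x$sequences), length(unique(x$labels))))
  invisible(x)
}

#' @export
length.dataset_handle <- function(x) length(x$sequences)

# A frame is "null" when every coordinate is exactly zero: the sensor
# convention for a missed body detection.
is_null_frame <- function(coords) {
  apply(coords, 1, function(fr) all(fr == 0))
}
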