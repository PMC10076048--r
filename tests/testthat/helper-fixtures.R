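# Shared fixtures: tiny hand-built sequences, skeleton-file writers, and a
# finite-difference gradient helper.

# a minimal valid sequence: T frames, J joints, deterministic coordinates
toy_sequence <- function(T_frames = 4, J = 10, offset = 0) {
  coords <- array(0, dim = c(T_frames, J, 3))
  for (t in seq_len(T_frames))
    for (j in seq_len(J))
      coords[t, j, ] <- c(0.3 * sin(j) + 0.01 * t, 0.2 * cos(2 * j),
                          0.1 * j - 0.005 * t) + offset
  pose_sequence(coords, seq_id = "toy")
}

# random finite sequence under a local seed
random_sequence <- function(T_frames = 5, J = 6, seed = 1, scale = 0.5) {
  coords <- array(0, dim = c(T_frames, J, 3))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  coords[] <- rnorm(length(coords), sd = scale)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  pose_sequence(coords, seq_id = paste0("rnd", seed))
}

# 4-joint skeleton satisfying the default alignment indices is impossible
# (defaults need joint 9); a small config for toy skeletons instead:
toy_cfg <- function(max_frames = 50) {
  normalization_config(spine_center_index = 2, hip_index = 1, spine_index = 2,
                       left_shoulder_index = 3, right_shoulder_index = 4,
                       max_frames = max_frames)
}

# write an NTU-style .skeleton file from a list of per-frame body records.
# frames: list over t of list of bodies; each body = list(id, coords J x 3)
write_skeleton_file <- function(frames, path = tempfile(fileext = ".skeleton")) {
  lines <- c(as.character(length(frames)))
  for (fr in frames) {
    lines <- c(lines, as.character(length(fr)))
    for (body in fr) {
      lines <- c(lines, paste(c(body$id, rep("0", 9)), collapse = " "))
      J <- nrow(body$coords)
      lines <- c(lines, as.character(J))
      for (j in seq_len(J)) {
        lines <- c(lines, paste(c(sprintf("%.6f", body$coords[j, ]),
                                  rep("0", 8), "2"), collapse = " "))
      }
    }
  }
  writeLines(lines, path)
  path
}

body_coords <- function(J, base = 0) {
  matrix(seq_len(J * 3) * 0.01 + base, nrow = J, ncol = 3)
}

# central finite differences of f at x (vector/array), elementwise
numeric_gradient <- function(f, x, h = 1e-6) {
  g <- x * 0
  for (k in seq_along(x)) {
    xp <- x; xp[k] <- xp[k] + h
    xm <- x; xm[k] <- xm[k] - h
    g[k] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# rotation matrix about a unit axis by angle (right-handed)
rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

rotate_sequence <- function(seq, R) {
  coords <- seq$coords
  for (t in seq_len(dim(coords)[1])) coords[t, , ] <- coords[t, , ] %*% t(R)
  pose_sequence(coords, label = seq$label, seq_id = seq$seq_id)
}

translate_sequence <- function(seq, v) {
  coords <- seq$coords
  for (t in seq_len(dim(coords)[1]))
    coords[t, , ] <- sweep(coords[t, , ], 2, v, "+")
  pose_sequence(coords, label = seq$label, seq_id = seq$seq_id)
}

# small normalized synthetic dataset for network/training tests
small_norm_dataset <- function(n_per_class = 2, J = 25, T_frames = 50,
                               seed = 0) {
  spec <- synthetic_dataset_spec(per_class_train = n_per_class,
                                 per_class_test = n_per_class,
                                 T_frames = T_frames, J = J, seed = seed)
  ds <- generate_dataset(spec)
  list(train = normalize_dataset(ds$train),
       test = normalize_dataset(ds$test))
}
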