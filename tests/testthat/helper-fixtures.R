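# Shared fixtures and independent oracles used across test files.

# Brute-force all-pairs minimum distance between two coordinate sets:
# the independent oracle for the vectorized distance kernel.
brute_min_dist <- function(A, B) {
  best <- Inf
  for (i in seq_len(nrow(A)))
    for (j in seq_len(nrow(B)))
      best <- min(best, sqrt(sum((A[i, ] - B[j, ])^2)))
  best
}

# Brute-force contact count for one frame: double loop over residue pairs.
brute_contact_count <- function(traj, frame = 1, cutoff = 5,
                                residue_set = c("TYR", "PHE")) {
  res <- select_aromatics(traj, residue_set)
  n <- nrow(res)
  cnt <- 0L
  if (n < 2) return(0L)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- min_carbon_distance(traj, res[i, ], res[j, ], frame = frame)
    if (d <= cutoff) cnt <- cnt + 1L
  }
  cnt
}

# Apply a rigid rotation + translation to every frame of a trajectory.
rigid_transform <- function(traj, angles = c(0.3, 0.7, 1.1),
                            shift = c(5, -3, 2)) {
  cx <- cos(angles); sx <- sin(angles)
  Rx <- matrix(c(1, 0, 0, 0, cx[1], -sx[1], 0, sx[1], cx[1]), 3, byrow = TRUE)
  Ry <- matrix(c(cx[2], 0, sx[2], 0, 1, 0, -sx[2], 0, cx[2]), 3, byrow = TRUE)
  Rz <- matrix(c(cx[3], -sx[3], 0, sx[3], cx[3], 0, 0, 0, 1), 3, byrow = TRUE)
  R <- Rz %*% Ry %*% Rx
  for (f in seq_len(dim(traj$coords)[3]))
    traj$coords[, , f] <- sweep(traj$coords[, , f] %*% t(R), 2, shift, `+`)
  traj
}

# Stacked-ring fiber where adjacent subunits' rings sit exactly `rise`
# apart: the planted minimum C-C distance equals the rise.
stacked_fiber <- function(n_subunits = 4, rise = 4.5, n_frames = 1,
                          jitter_sd = 0, seed = 1, remove_ring_at = NULL,
                          two_residues = FALSE) {
  aro <- if (two_residues)
    list(TYR = c(0, 0, 0), PHE = c(6, 0, 2.25)) else list(TYR = c(0, 0, 0))
  gen_fiber(n_subunits = n_subunits, rise = rise, twist = 0,
            aromatics_per_subunit = aro, remove_ring_at = remove_ring_at,
            jitter_sd = jitter_sd, n_frames = n_frames, seed = seed)
}
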