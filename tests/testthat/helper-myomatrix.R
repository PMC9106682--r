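# Desk-scale generator configuration: same layout rules as the realistic
# defaults but with radius 80 nm / sarcomere 800 nm at 20 nm voxels so that
# a 64 x 64 cross-section hosts a 3 x 3 myofibril bundle and ~500 slices
# host 10 sarcomeres.
small_config <- function(grid_shape = c(480L, 64L, 64L),
                         n_myofibrils = 9L,
                         p_single = 0, p_multi = 0, seed = 1L, ...) {
  generator_config(grid_shape = grid_shape, voxel_size = c(20, 20, 20),
                   n_myofibrils = n_myofibrils,
                   myofibril_radius_mean = 80,
                   sarcomere_length = 800, srt_gap_thickness = 40,
                   p_single = p_single, p_multi = p_multi, seed = seed, ...)
}

# stamp a solid disk label into slices zs of a (nz, nr, nc) array
stamp_disk <- function(arr, zs, cr, cc, r, label) {
  nr <- dim(arr)[2]; nc <- dim(arr)[3]
  for (dr in -r:r) for (dc in -r:r) {
    if (dr^2 + dc^2 <= r^2) {
      pr <- cr + dr; pc <- cc + dc
      if (pr >= 1 && pr <= nr && pc >= 1 && pc <= nc) {
        arr[zs, pr, pc] <- label
      }
    }
  }
  arr
}

# Compare a detected event table to ground truth: equal counts and, after
# ordering, matching type, classification, branch_count and z within 1 slice.
events_match <- function(truth, detected, tol_z = 1L) {
  if (nrow(truth) != nrow(detected)) return(FALSE)
  if (nrow(truth) == 0L) return(TRUE)
  key <- function(df) df[order(df$z_position, df$type, df$branch_count), ]
  a <- key(truth); b <- key(detected)
  all(a$type == b$type) &&
    all(a$classification == b$classification) &&
    all(a$branch_count == b$branch_count) &&
    all(abs(a$z_position - b$z_position) <= tol_z)
}

expect_events_match <- function(truth, detected) {
  expect_true(events_match(truth, detected))
}
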