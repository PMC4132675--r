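# Shared fixtures, all generated in code.

# A full rectangular-box mask (every grid voxel is a member), built directly
# so geometry tests do not depend on the random region-growing path.
cube_mask <- function(n) {
  g <- as.matrix(expand.grid(x = seq_len(n), y = seq_len(n), z = seq_len(n)))
  structure(list(shape = rep(n, 3L), voxels = g, name = "cube",
                 hemisphere = NA_character_, voxel_size_mm = 1.5),
            class = "roi_mask")
}

# A small, fast synthetic subject: RefTC-only trial set by default.
small_subject <- function(n_per_exemplar = 20, roi_voxels = 48,
                          shape = c(8, 8, 8), amplitude = 1, noise_sd = 1,
                          ...) {
  seqn <- generate_test_session(n_ref_per_exemplar = n_per_exemplar,
                                n_rtc = 0, n_ntc = 0)
  simulate_roi_subject(sequence = seqn, roi_voxels = roi_voxels, shape = shape,
                       amplitude = amplitude, noise_sd = noise_sd, ...)
}

reftc3 <- c("RefTC-1", "RefTC-2", "RefTC-3")

# Fast config for small fixtures.
quick_config <- function(...) decoding_config(n_folds = 10, ...)
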