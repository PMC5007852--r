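# Shared fixtures, built once per test run.  The standard field is the
# 30-cell, SNR-8, 512x512 resting scene with a fixed seed.

.fixtures <- new.env()

std_scene <- function() {
  if (is.null(.fixtures$scene))
    .fixtures$scene <- render_scene(scene_preset("resting", n_cells = 30,
                                                 rng_seed = 1L))
  .fixtures$scene
}

std_seg <- function() {
  if (is.null(.fixtures$seg))
    .fixtures$seg <- segment_scene(std_scene()$stack)
  .fixtures$seg
}

# a digital disk mask
disk_mask <- function(r, side = 2 * r + 7) {
  ctr <- (side + 1) / 2
  micromorph:::stamp_disk(matrix(FALSE, side, side), ctr, ctr, r)
}
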