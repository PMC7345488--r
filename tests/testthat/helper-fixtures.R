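# Shared fixtures built in code. The default look-up table is built once
# per test run; phantoms are rendered on demand.

default_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- build_lookup_table(optics_config())
    tab
  }
})

uniform_phantom <- function(llt = 60, noise_sd = 0, seed = NULL, ...) {
  render_phantom(
    phantom_spec(llt_field = list(profile = "uniform", value = llt),
                 noise_sd = noise_sd, seed = seed, ...),
    default_table())
}

# A static blink cycle: n identical phantom frames at 0.05-s spacing.
static_cycle <- function(llt = 60, n = 41, noise_sd = 0, seed = NULL) {
  ph <- uniform_phantom(llt, noise_sd = noise_sd, seed = seed)
  frames <- lapply(seq_len(n) - 1L, function(k)
    tear_frame(k * 0.05, ph$image))
  blink_cycle(frames, duration_s = (n - 1) * 0.05 + 0.05)
}

# Tiny synthetic "gray ramp" cycle for frameio tests that don't need rings:
# each frame's first pixel encodes its index so frames are distinguishable.
index_cycle <- function(times_s) {
  frames <- lapply(seq_along(times_s), function(i) {
    img <- array(100L, c(4, 4, 3))
    img[1, 1, 1] <- i %% 256L
    img[2, 1, 1] <- i %/% 256L
    tear_frame(times_s[i], img)
  })
  blink_cycle(frames)
}

frame_index <- function(frame)
  frame$image[1, 1, 1] + 256L * frame$image[2, 1, 1]
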