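# Shared fixtures and independent oracles, built in code at test time.

# Naive two-pass Pearson correlation: the independent oracle against which
# the package's implementation is checked.
pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Small rendering scene used by multi-seed end-to-end properties.
small_scene <- function(...) {
  scene_config(n_interior = 120, n_edge = 4, n_mitotic = 3,
               field_size = 256, nuclei_per_field = 14, ...)
}

# Noise-free single-disk field: uniform density disk on constant background.
disk_field <- function(value = 7, background = 0, radius = 10, size = 64,
                       centers = list(c(32, 32)), channel = "Hoechst") {
  img <- matrix(background, size, size)
  for (cc in centers) {
    for (r in seq_len(size)) for (c in seq_len(size)) {
      if ((r - cc[1])^2 + (c - cc[2])^2 <= radius^2) img[r, c] <- value
    }
  }
  chans <- list(img)
  names(chans) <- channel
  field_image(chans, field_id = 1)
}

# Noise-free mark panel (sigma 0) for exact-value checks.
noiseless_marks <- function() {
  list(
    prop = mark_model("prop", "proportional", amplitude = 100, sigma = 0),
    rc = mark_model("rc", "replication_coupled", amplitude = 100, sigma = 0)
  )
}
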