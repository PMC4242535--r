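# Shared fixtures, built in code at test time.

# two triangular modes at gray 90 and 170 with a single interior zero at 130
two_triangle_hist <- function() {
  pmax(0, 40 - abs(0:255 - 90)) + pmax(0, 40 - abs(0:255 - 170))
}

two_spike_hist <- function(g1 = 50L, g2 = 200L, n1 = 1000L, n2 = 1000L) {
  h <- integer(256)
  h[g1 + 1L] <- n1
  h[g2 + 1L] <- n2
  h
}

# an image whose masked histogram equals the given counts (values laid out
# deterministically), useful for driving image-level entry points
image_from_hist <- function(counts, ncol = 64L) {
  vals <- rep(0:255, counts)
  n <- length(vals)
  nrow <- ceiling(n / ncol)
  pad <- nrow * ncol - n
  m <- matrix(c(vals, rep(vals[n], pad)), nrow, ncol)
  mask <- matrix(c(rep(TRUE, n), rep(FALSE, pad)), nrow, ncol)
  gray_image(m, mask)
}

rand_image <- function(seed, h = 40L, w = 40L) {
  set.seed(seed)
  gray_image(matrix(sample(0:255, h * w, replace = TRUE), h, w))
}

small_scene <- function(seed = 1L, width = 128L, height = 128L, ...) {
  simulate_scene(scene_params(width = width, height = height, seed = seed, ...))
}
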