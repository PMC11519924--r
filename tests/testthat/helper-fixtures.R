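# Shared fixture builders. Everything is generated in code; nothing is
# read from disk except what the tests themselves write to tempdirs.

# uniform dye box with optional Gaussian pixel noise
make_dye_box <- function(n = 40, color = c(0.7, 0.55, 0.4), noise = 0.01,
                         seed = 1) {
  set.seed(seed)
  arr <- array(0, c(n, n, 3))
  for (ch in 1:3) {
    arr[, , ch] <- pmin(pmax(color[ch] + stats::rnorm(n * n, 0, noise), 0), 1)
  }
  arr
}

full_box <- function(n) list(x0 = 0, y0 = 0, x1 = n, y1 = n)

# random 8-bit colors, optionally constrained so g is the minimum channel
random_colors <- function(n, g_min = FALSE, seed = 42) {
  set.seed(seed)
  r <- sample(0:255, n, replace = TRUE)
  g <- sample(0:255, n, replace = TRUE)
  b <- sample(0:255, n, replace = TRUE)
  if (g_min) {
    lo <- pmin(r, g, b)
    hi <- pmax(r, g, b)
    keep <- hi > 0
    data.frame(r = pmax(r, g)[keep], g = lo[keep], b = pmax(b, g)[keep])
  } else {
    data.frame(r = r, g = g, b = b)
  }
}

reference_chip <- function() {
  chip_scene(c(0, 5, 10, 20, 50, 100))
}

# sigmas scaled to the ~370 px fixture frame (defaults assume full
# phone resolution)
fixture_sigmas <- c(4, 13, 45)
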