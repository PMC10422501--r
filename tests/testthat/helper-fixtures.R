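# Shared fixtures and independent oracles for the test suite.

# Independent brute-force regional pooling oracle. Region ranges are
# restated here from the printed 1-based inclusive definitions and the
# pooled values are accumulated cell by cell, so this path shares no code
# with regionMean()/regionMax()/mmsp().
oracle_regions <- list(
  whole        = list(r = 1:7, c = 1:7),
  center       = list(r = 3:5, c = 3:5),
  top_left     = list(r = 1:4, c = 1:4),
  top_right    = list(r = 1:4, c = 4:7),
  bottom_left  = list(r = 4:7, c = 1:4),
  bottom_right = list(r = 4:7, c = 4:7)
)

oracle_region_mean <- function(stack, region, coefficient = NULL) {
  rg <- oracle_regions[[region]]
  acc <- rep(0, dim(stack)[3])
  n <- 0L
  for (i in rg$r) for (j in rg$c) {
    acc <- acc + stack[i, j, ]
    n <- n + 1L
  }
  if (is.null(coefficient)) coefficient <- 1 / n
  acc * coefficient
}

oracle_region_max <- function(stack, region) {
  rg <- oracle_regions[[region]]
  acc <- rep(-Inf, dim(stack)[3])
  for (i in rg$r) for (j in rg$c) acc <- pmax(acc, stack[i, j, ])
  acc
}

# coefficient convention: "true_mean" uses 1/|region|; "ninth" uses the
# printed 1/9 for every sub-region and 1/49 for the whole grid.
oracle_mmsp <- function(stack, mode = "true_mean") {
  region_names <- names(oracle_regions)
  coef_for <- function(region) {
    if (mode == "true_mean") NULL
    else if (region == "whole") 1 / 49 else 1 / 9
  }
  means <- unlist(lapply(region_names, function(r)
    oracle_region_mean(stack, r, coef_for(r))))
  maxes <- unlist(lapply(region_names, function(r) oracle_region_max(stack, r)))
  c(means, maxes)
}

random_stack <- function(seed, channels = 512) {
  set.seed(seed)
  array(rnorm(7 * 7 * channels), c(7, 7, channels))
}

random_rgb <- function(seed, h = 32, w = 32) {
  set.seed(seed)
  array(runif(h * w * 3), c(h, w, 3))
}

# A small manifest data.frame for protocol tests.
toy_records <- function(n_subjects = 3, n_classes = 2, reps = 2) {
  g <- expand.grid(rep = seq_len(reps), class = seq_len(n_classes),
                   subject = seq_len(n_subjects))
  data.frame(
    clip_id = sprintf("s%d_c%d_r%d", g$subject, g$class, g$rep),
    path = file.path(tempdir(), "none"),
    subject_id = sprintf("subj%d", g$subject),
    label = sprintf("act%d", g$class),
    native_fps = 30,
    stringsAsFactors = FALSE)
}

# Two well-separated Gaussian blobs in d dimensions; margin guaranteed by
# construction (centres at +/- mu with mu >> noise).
separable_blobs <- function(seed, n_per = 10, d = 8, mu = 4, sd = 0.5) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * d, mean = mu, sd = sd), n_per),
             matrix(rnorm(n_per * d, mean = -mu, sd = sd), n_per))
  list(x = x, y = rep(c("a", "b"), each = n_per))
}
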