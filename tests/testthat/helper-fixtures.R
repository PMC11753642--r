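# Shared fixtures, all generated in code.

# tiny 2x2 single-channel test image as a plain matrix
tiny_mat <- function() matrix(c(1, 3, 2, 4), nrow = 2) # [[1,2],[3,4]]

# small RGB labeled image with deterministic content
small_rgb <- function(h = 8, w = 8, label = "a") {
  px <- array(0, c(h, w, 3))
  px[, , 1] <- matrix(seq(0, 255, length.out = h * w), h, w)
  px[, , 2] <- 128
  px[, , 3] <- t(matrix(seq(0, 255, length.out = h * w), w, h))
  labeled_image(px, label, "fixture")
}

# two-class feature table where feature "sep" separates perfectly and the
# rest are pure noise
separable_table <- function(n_per_class = 20, d_noise = 4, seed = 42) {
  withr::with_seed(seed, {
    y <- rep(c("a", "b"), each = n_per_class)
    sep <- ifelse(y == "a", 0, 10) + stats::rnorm(2 * n_per_class, 0, 0.1)
    noise <- matrix(stats::rnorm(2 * n_per_class * d_noise), ncol = d_noise)
    colnames(noise) <- sprintf("noise_%d", seq_len(d_noise))
    df <- tibble::as_tibble(as.data.frame(noise))
    df$sep <- sep
    df$label <- y
    df
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
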