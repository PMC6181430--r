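# Small fixtures shared across test files; everything is built in code.

# 2 x 2 grid with a 2-channel separable bank: f depends only on level_A.
tiny_separable_model <- function(noise = 1) {
  g <- stimulus_grid(2, 2)
  tuning <- gaussian_tuning_bank(g, centers = c(0, 1), widths = c(1, 1),
                                 gains = c(1, 1), values_A = c(0, 1))
  encoding_model(g, tuning, noise_cov = noise)
}

# Decoded-trial tibble from explicit per-condition sample vectors
# (ordered A1B1, A1B2, A2B1, A2B2).
decoded_tbl <- function(x11, x12, x21, x22) {
  tibble::tibble(
    level_A = rep(c(1L, 1L, 2L, 2L),
                  times = c(length(x11), length(x12),
                            length(x21), length(x22))),
    level_B = rep(c(1L, 2L, 1L, 2L),
                  times = c(length(x11), length(x12),
                            length(x21), length(x22))),
    decoded_value = c(x11, x12, x21, x22)
  )
}

# Two well-separated 2-D point clouds along axis 1, labelled 1/2.
separable_clouds <- function(n = 20, gap = 10, seed = 42) {
  withr::with_seed(seed, {
    x <- rbind(cbind(rnorm(n), rnorm(n)),
               cbind(rnorm(n) + gap, rnorm(n)))
    list(x = x, y = rep(c(1L, 2L), each = n))
  })
}
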