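# Small in-code fixtures shared across test files.

fixture_spec <- function(format = "spiral", ...) {
  template_spec(format, image_size = 256L, turns = 3L, ...)
}

fixture_exam <- function(label = "PG", amp = NULL, seed = 101L,
                         format = "spiral", ...) {
  synthesize_exam(fixture_spec(format),
                  subject_spec(label, tremor_amplitude_px = amp, seed = seed),
                  ...)
}

iou <- function(a, b) sum(a & b) / sum(a | b)

# well-separated two-blob classification fixture
blob_data <- function(n_per_class = 50, sdev = 0.1, gap = 10, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(2 * n_per_class, 0, sdev), ncol = 2),
             matrix(rnorm(2 * n_per_class, gap, sdev), ncol = 2))
  list(x = x, y = rep(c("CG", "PG"), each = n_per_class))
}
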