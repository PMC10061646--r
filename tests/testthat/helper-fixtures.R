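# Shared fixtures built in code: small seeded feature tables and image
# sets reused across test files.

small_features <- function(n_per_class = 20, dim = 16, sep = 6, seed = 42) {
  generate_feature_table(synthetic_feature_spec(
    n_per_class = n_per_class, dim = dim, class_mean_separation = sep,
    noise_sd = 1, seed = seed))
}

small_images <- function(n_per_class = 6, size = 64, seed = 7) {
  generate_cell_images(synthetic_image_spec(
    n_per_class = n_per_class, image_size = size, seed = seed))
}

# Independent least-squares oracle: QR factorization (full-column-rank
# systems), a different algorithmic route than the SVD-based solver.
qr_lstsq <- function(A, B) {
  qr.coef(qr(A), B)
}

expect_frobenius_close <- function(X, Y, tol) {
  expect_lt(sqrt(sum((X - Y)^2)), tol)
}
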