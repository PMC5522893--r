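# Independent brute-force oracles shared across test files.

# Assemble the tangent-coordinate matrix and its sample covariance explicitly
# from an alignment, and eigendecompose it.
brute_force_pca <- function(alignment) {
  wide_x <- tidyr::pivot_wider(alignment$shapes[, c("subject_id", "point", "x")],
    names_from = "point", values_from = "x"
  )
  wide_y <- tidyr::pivot_wider(alignment$shapes[, c("subject_id", "point", "y")],
    names_from = "point", values_from = "y"
  )
  ids <- wide_x$subject_id
  k <- ncol(wide_x) - 1
  mu <- c(rbind(alignment$mean_shape$x, alignment$mean_shape$y))
  X <- matrix(0, length(ids), 2 * k)
  for (i in seq_along(ids)) {
    xy <- c(rbind(as.numeric(wide_x[i, -1]), as.numeric(wide_y[i, -1])))
    X[i, ] <- xy / sum(xy * mu) # tangent rescaling
  }
  centre <- colMeans(X)
  Xc <- sweep(X, 2, centre)
  S <- (t(Xc) %*% Xc) / (length(ids) - 1)
  eg <- eigen(S, symmetric = TRUE)
  scores <- Xc %*% eg$vectors
  list(values = eg$values, vectors = eg$vectors, centre = centre, scores = scores)
}

# Residuals from explicitly solved normal equations on intercept + dummies.
normal_equations_residuals <- function(v, f) {
  X <- cbind(1, outer(as.character(f), sort(unique(as.character(f)))[-1], `==`) * 1)
  beta <- solve(t(X) %*% X, t(X) %*% v)
  as.vector(v - X %*% beta)
}
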