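# Exact (non-approximated) t-SNE: suitable for the hundreds of molecules a
# chemical-space plot shows. Conditional distributions P are calibrated per
# point to the target perplexity by bisection on the Gaussian bandwidth;
# optimization is plain gradient descent with momentum and early
# exaggeration.

tsne_exact <- function(x, seed = 1L, perplexity = 30, max_iter = 500L,
                       eta = 200, momentum = c(0.5, 0.8), exaggerate = 4,
                       exaggerate_iter = 50L) {
  set.seed(seed)
  n <- nrow(x)
  d2 <- as.matrix(stats::dist(x))^2
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta_lo <- 0; beta_hi <- Inf; beta <- 1
    di <- d2[i, -i]
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { beta <- beta / 2; next }
      p <- w / sw
      h <- -sum(p[p > 0] * log(p[p > 0]))
      if (abs(h - target) < 1e-5) break
      if (h > target) { beta_lo <- beta; beta <- if (is.finite(beta_hi)) (beta + beta_hi) / 2 else beta * 2 }
      else { beta_hi <- beta; beta <- (beta + beta_lo) / 2 }
    }
    P[i, -i] <- w / sum(w)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  inc <- matrix(0, n, 2)
  Puse <- P * exaggerate
  for (it in seq_len(max_iter)) {
    if (it == exaggerate_iter + 1L) Puse <- P
    num <- 1 / (1 + as.matrix(stats::dist(y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Puse - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% y
    mom <- if (it <= 250) momentum[1] else momentum[2]
    inc <- mom * inc - eta * grad
    y <- y + inc
    y <- sweep(y, 2, colMeans(y))
  }
  y
}
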