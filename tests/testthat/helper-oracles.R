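# Independent oracles and fixture builders shared across tests.
# Each oracle is a direct, unoptimized restatement of the quantity it
# checks, kept deliberately separate from the package's implementation.

# Fisher distance by direct mean/variance arithmetic (population variance)
brute_fisher <- function(a, b) {
  m1 <- sum(a) / length(a)
  m2 <- sum(b) / length(b)
  v1 <- sum((a - m1)^2) / length(a)
  v2 <- sum((b - m2)^2) / length(b)
  abs(m1 - m2) / max(v1 + v2, 1e-12)
}

# coordinate descent for 1/(2n) * ||y - b0 - X b||^2 + lambda * sum|b|
cd_lasso <- function(X, y, lambda, iters = 2000L, tol = 1e-12) {
  n <- nrow(X); p <- ncol(X)
  b <- numeric(p)
  b0 <- mean(y)
  xsq <- colSums(X^2) / n
  r <- y - b0
  for (it in seq_len(iters)) {
    delta <- 0
    for (j in seq_len(p)) {
      if (xsq[j] == 0) next
      rho <- sum(X[, j] * r) / n + xsq[j] * b[j]
      bj <- sign(rho) * max(abs(rho) - lambda, 0) / xsq[j]
      if (bj != b[j]) {
        r <- r - X[, j] * (bj - b[j])
        delta <- max(delta, abs(bj - b[j]))
        b[j] <- bj
      }
    }
    b0_new <- b0 + mean(r)
    r <- r - (b0_new - b0)
    b0 <- b0_new
    if (delta < tol) break
  }
  list(b0 = b0, beta = b)
}

# minimum rotated-bounding-box area over a grid of angles (0.1 degree steps)
brute_min_rect_area <- function(P, step_deg = 0.1) {
  angles <- seq(0, 90, by = step_deg) * pi / 180
  areas <- vapply(angles, function(a) {
    Q <- P %*% rbind(c(cos(a), -sin(a)), c(sin(a), cos(a)))
    (max(Q[, 1]) - min(Q[, 1])) * (max(Q[, 2]) - min(Q[, 2]))
  }, numeric(1))
  min(areas)
}

# AUC by Mann-Whitney pair counting (ties count 1/2)
mw_auc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# small deterministic labeled expression set
tiny_em <- function(m = 20L, n_per_class = 10L, shift = 0.3, seed = 42L,
                    n_informative = 4L) {
  set.seed(seed)
  n <- 2L * n_per_class
  v <- matrix(runif(m * n, 0.3, 0.7), m, n,
              dimnames = list(sprintf("g%02d", 1:m), sprintf("s%02d", 1:n)))
  labels <- rep(c("CTL", "AD"), each = n_per_class)
  v[seq_len(n_informative), labels == "AD"] <-
    v[seq_len(n_informative), labels == "AD"] + shift
  expression_set(pmin(v, 1), stats::setNames(labels, colnames(v)),
                 normalized = TRUE)
}

# shared synthetic fixture for pipeline-level tests (small, fast)
pipeline_fixture_spec <- function(seed = 7L)
  synthetic_spec(n_genes = 300L, n_informative = 20L,
                 samples_per_class = c(CTL = 40L, AD = 40L),
                 effect_size = 0.2, noise_sd = 0.1, seed = seed)
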