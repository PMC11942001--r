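# Shared fixtures and independent oracles, all built in code.

# tiny raw-scale matrix with mixed feature classes
toy_matrix <- function() {
  vals <- matrix(c(0, 2, 4, 6,
                   1, 0, 0, 0,
                   3, 1, 0, 0,
                   5, 7, 9, 11), nrow = 4,
                 dimnames = list(paste0("s", 1:4),
                                 c("TF1", "miR1", "miR2", "gene1")))
  expression_matrix(vals, feature_class = c("TF", "MIRNA", "MIRNA", "GENE"),
                    scale = "raw")
}

# von Mises-Fisher sampler (Wood's rejection algorithm) — used only to
# construct test data, independent of the package's EM fitting code
rvmf <- function(n, mu, kappa) {
  d <- length(mu)
  mu <- mu / sqrt(sum(mu^2))
  b <- (-2 * kappa + sqrt(4 * kappa^2 + (d - 1)^2)) / (d - 1)
  x0 <- (1 - b) / (1 + b)
  cc <- kappa * x0 + (d - 1) * log(1 - x0^2)
  out <- matrix(0, n, d)
  for (i in seq_len(n)) {
    repeat {
      Z <- stats::rbeta(1, (d - 1) / 2, (d - 1) / 2)
      W <- (1 - (1 + b) * Z) / (1 - (1 - b) * Z)
      U <- stats::runif(1)
      if (kappa * W + (d - 1) * log(1 - x0 * W) - cc >= log(U)) break
    }
    v <- stats::rnorm(d)
    v <- v - sum(v * mu) * mu
    v <- v / sqrt(sum(v^2))
    out[i, ] <- W * mu + sqrt(1 - W^2) * v
  }
  out
}

# brute-force spherical 2-means (Lloyd from all distinct seed pairs on a
# subsample) — independent clustering oracle for two-bundle data
sphere_2means <- function(X, iters = 50) {
  n <- nrow(X)
  best <- NULL
  set.seed(99)
  for (rep in 1:10) {
    ctr <- X[sample.int(n, 2), , drop = FALSE]
    for (it in seq_len(iters)) {
      asg <- max.col(X %*% t(ctr))
      for (k in 1:2) {
        if (!any(asg == k)) next
        v <- colSums(X[asg == k, , drop = FALSE])
        ctr[k, ] <- v / sqrt(sum(v^2))
      }
    }
    obj <- sum(X * ctr[asg, ])
    if (is.null(best) || obj > best$obj) best <- list(asg = asg, obj = obj)
  }
  best$asg
}

# exact optimal-transport LP between uniform empirical measures, solved by
# the simplex method — independent oracle for wasserstein_1d
lp_wasserstein <- function(a, b) {
  n <- length(a); m <- length(b)
  cost <- as.vector(outer(a, b, function(x, y) abs(x - y)))
  A3 <- matrix(0, n + m, n * m)
  for (i in seq_len(n)) for (j in seq_len(m)) A3[i, (j - 1) * n + i] <- 1
  for (j in seq_len(m)) for (i in seq_len(n)) A3[n + j, (j - 1) * n + i] <- 1
  b3 <- c(rep(1 / n, n), rep(1 / m, m))
  # drop the redundant mass-balance equality for a full-rank system
  unname(boot::simplex(a = cost, A3 = A3[-(n + m), , drop = FALSE],
                       b3 = b3[-(n + m)], maxi = FALSE)$value)
}

# brute-force evaluation of the Auer-Gervini step function on a theta grid —
# independent oracle for select_dimension's closed-form hull computation
ag_step_lengths_grid <- function(lambda, n, theta_max = NULL, grid = 20000) {
  p <- length(lambda)
  lam <- pmax(lambda, 1e-12)
  h <- sapply(0:(p - 1), function(d) {
    resid <- mean(lam[(d + 1):p])
    -(n / 2) * (sum(log(lam[seq_len(d)])) + (p - d) * log(resid))
  })
  dims <- 0:(p - 1)
  if (is.null(theta_max)) theta_max <- max(diff(h)) * 1.5 + 1
  thetas <- seq(0, theta_max, length.out = grid)
  maps <- vapply(thetas, function(th) dims[which.max(h - th * dims)],
                 numeric(1))
  vapply(split(thetas, maps), function(v) diff(range(v)), numeric(1))
}

# standard small generator configuration used across module tests
small_config <- function(seed = 1, ...) {
  generator_config(n_samples = 200, n_tissues = 3,
                   cluster_sizes = rep(10, 3), n_genes = 80,
                   frac_unexplained = 0.2, frac_tissue_switch = 0.1,
                   gene_noise_sd = 0.5, tissue_separation = 3,
                   seed = seed, ...)
}
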