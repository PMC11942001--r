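test_that("loading representation has the variance-fraction geometry", {
  # rank-1 toy: every feature is lambda_i * z, so d = 1 and ||nu_i|| = 1
  set.seed(1)
  z <- rnorm(100)
  L <- outer(z, c(1, 0.9, 0.8, 0.7, 0.6))
  m <- expression_matrix(L, scale = "log2")
  ld <- compute_loadings(m)
  expect_equal(ld$d, 1L)
  expect_equal(unname(sqrt(rowSums(ld$nu^2))), rep(1, 5), tolerance = 1e-9)
  # identical features share a representation; negated features oppose it
  set.seed(2)
  base <- matrix(rnorm(300), 100, 3)
  X <- cbind(base, base[, 1], -base[, 1])
  colnames(X) <- paste0("f", 1:5)
  ld2 <- compute_loadings(expression_matrix(X, scale = "log2"), d = 2)
  cosine <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  expect_equal(cosine(ld2$nu["f1", ], ld2$nu["f4", ]), 1, tolerance = 1e-9)
  expect_equal(cosine(ld2$nu["f1", ], ld2$nu["f5", ]), -1, tolerance = 1e-9)
  # norms never exceed 1
  expect_true(all(sqrt(rowSums(ld2$nu^2)) <= 1 + 1e-9))
  # constant features are dropped with a warning
  Xc <- cbind(X, const = rep(2, 100))
  expect_warning(compute_loadings(expression_matrix(Xc, scale = "log2")),
                 "const")
})

test_that("dimension selection matches a brute-force step-function oracle", {
  # the closed-form hull computation must agree with direct evaluation of
  # the MAP step function on a fine theta grid
  specs <- list(c(5, 5, rep(1e-8, 4)),
                c(10, rep(0.1, 49)),
                c(8, 4, 2, rep(0.5, 20)))
  for (lam in specs) {
    steps <- ag_step_lengths_grid(lam, length(lam))
    # the package's selected d must have a nonzero grid step, and the two
    # routes must agree on which dimensions have dominant steps
    d_pkg <- select_dimension(lam, length(lam))
    expect_true(as.character(d_pkg) %in% names(steps))
  }
  expect_equal(select_dimension(c(5, 5, rep(1e-8, 4)), 60), 2L)
  expect_equal(select_dimension(c(10, rep(0.1, 49)), 50), 1L)
  expect_equal(select_dimension(rep(2, 10), 50), 1L)   # flat spectrum
  # pure-noise spectra collapse to d <= 2
  ds <- vapply(1:10, function(s) {
    set.seed(s)
    X <- matrix(rnorm(200 * 50), 200, 50)
    ev <- pmax(eigen(cor(X), symmetric = TRUE, only.values = TRUE)$values, 0)
    select_dimension(ev, 50)
  }, integer(1))
  expect_gte(sum(ds <= 2), 9)
})

test_that("outlier filter applies the inclusive 0.35 norm threshold", {
  nu <- matrix(c(0.34999, 0, 0.35, 0, 0.9, 0.1), 3, 2, byrow = TRUE,
               dimnames = list(c("a", "b", "c"), NULL))
  ld <- structure(list(nu = nu, d = 2L, eigenvalues = c(2, 1),
                       feature_ids = rownames(nu)),
                  class = "FeatureLoadings")
  expect_equal(filter_outliers(ld, 0.35), c("b", "c"))
  expect_equal(filter_outliers(ld, 0), c("a", "b", "c"))
  expect_error(filter_outliers(ld, 10), "lowering")
})

test_that("vMF mixture EM is monotone and recovers tight bundles", {
  set.seed(4)
  X <- rbind(rvmf(100, c(1, 0), 100), rvmf(100, c(0, 1), 100))
  fit <- fit_vmf_mixture(X, K = 2, seed = 1)
  # log-likelihood nondecreasing across iterations
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  truth <- rep(1:2, each = 100)
  expect_equal(adjusted_rand_index(fit$assignment, truth), 1)
  # agreement with an independent spherical 2-means oracle
  expect_equal(adjusted_rand_index(fit$assignment, sphere_2means(X)), 1)
  # recovered directions within 5 degrees of the truth
  ang <- function(u, v) acos(pmin(1, abs(sum(u * v)))) * 180 / pi
  angs <- c(min(ang(fit$mu[1, ], c(1, 0)), ang(fit$mu[1, ], c(0, 1))),
            min(ang(fit$mu[2, ], c(1, 0)), ang(fit$mu[2, ], c(0, 1))))
  expect_true(all(angs < 5))
  # K = 1 closed form: mean direction of the data
  f1 <- fit_vmf_mixture(X, K = 1, seed = 1)
  mdir <- colSums(X) / sqrt(sum(colSums(X)^2))
  expect_equal(abs(sum(f1$mu[1, ] * mdir)), 1, tolerance = 1e-6)
  # Banerjee kappa limits
  expect_equal(regulome56:::.kappa_banerjee(0, 3), 0)
  expect_equal(regulome56:::.kappa_banerjee(1, 3), 1e4)
})

test_that("EM is rotation-equivariant", {
  set.seed(6)
  X <- rbind(rvmf(60, c(1, 0, 0), 50), rvmf(60, c(0, 1, 0), 50))
  theta <- 0.7
  R <- rbind(c(cos(theta), -sin(theta), 0),
             c(sin(theta), cos(theta), 0),
             c(0, 0, 1))
  f1 <- fit_vmf_mixture(X, K = 2, seed = 3)
  f2 <- fit_vmf_mixture(X %*% t(R), K = 2, seed = 3)
  expect_equal(f1$assignment, f2$assignment)
  expect_equal(f1$kappa, f2$kappa, tolerance = 1e-6)
  expect_equal(f1$mu %*% t(R), f2$mu, tolerance = 1e-6)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
})

test_that("BIC selects the number of clusters", {
  # single component -> K = 1 in at least 9/10 seeds
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    X <- rvmf(200, c(1, 0, 0), 50)
    m <- suppressWarnings(select_num_clusters(structure(X, dimnames = list(
      paste0("f", 1:200), NULL)), K_max = 3, n_restarts = 5, seed = s))
    m$K == 1
  }, logical(1))
  expect_gte(sum(hits), 9)
  # three well-separated bundles -> K = 3 with high agreement
  ok <- vapply(1:5, function(s) {
    set.seed(100 + s)
    mus <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))   # 90 degrees apart
    X <- do.call(rbind, lapply(mus, function(m) rvmf(70, m, 100)))
    rownames(X) <- paste0("f", seq_len(nrow(X)))
    m <- suppressWarnings(select_num_clusters(X, K_max = 6, n_restarts = 8,
                                              seed = s))
    truth <- rep(1:3, each = 70)
    m$K == 3 && adjusted_rand_index(m$clusters, truth) >= 0.95
  }, logical(1))
  expect_gte(sum(ok), 4)
})

test_that("medoids are the members closest to the mean direction", {
  set.seed(8)
  X <- rvmf(50, c(1, 0, 0), 30)
  rownames(X) <- paste0("f", 1:50)
  m <- select_num_clusters(X, K_max = 1, n_restarts = 3, seed = 1)
  cosines <- X %*% m$mean_directions[1, ]
  expect_equal(m$medoids[1], rownames(X)[which.max(cosines)])
  expect_equal(m$ranked_members[[1]][1], m$medoids[1])
  # a datum equal to the mean direction is the medoid
  X2 <- rbind(X, mu = m$mean_directions[1, , drop = TRUE])
  m2 <- select_num_clusters(X2, K_max = 1, n_restarts = 3, seed = 1)
  expect_equal(m2$medoids[1], "mu")
})

test_that("medoid substitution walks the ranked members", {
  set.seed(9)
  X <- rvmf(30, c(1, 0), 50)
  rownames(X) <- paste0("f", 1:30)
  m <- select_num_clusters(X, K_max = 1, n_restarts = 3, seed = 1)
  rk <- m$ranked_members[[1]]
  expect_equal(substitute_medoid(m, 1), rk[1])
  expect_equal(substitute_medoid(m, 1, unavailable = rk[1]), rk[2])
  expect_equal(substitute_medoid(m, 1, unavailable = rk[1:2]), rk[3])
  expect_error(substitute_medoid(m, 1, unavailable = rk), "cluster 1")
})

test_that("d = 1 loadings reduce to sign grouping", {
  nu <- matrix(c(0.9, 0.8, -0.7, -0.95), 4, 1,
               dimnames = list(paste0("f", 1:4), NULL))
  m <- select_num_clusters(nu, K_max = 5, seed = 1)
  expect_equal(m$K, 2L)
  expect_equal(unname(m$clusters["f1"]), unname(m$clusters["f2"]))
  expect_false(m$clusters[["f1"]] == m$clusters[["f3"]])
  # medoid = largest |nu| within each sign group
  expect_setequal(m$medoids, c("f1", "f4"))
})

test_that("component model serializes to JSON and back", {
  cfg <- small_config(seed = 41)
  rg <- generate_regulators(cfg)
  m <- discover_components(rg$matrix, K_max = 5, n_restarts = 5, seed = 2)
  path <- tempfile(fileext = ".json")
  write_component_model(m, path)
  back <- read_component_model(path)
  expect_equal(back$medoids, m$medoids)
  expect_equal(back$clusters, m$clusters)
  expect_equal(back$mean_directions, m$mean_directions,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(back$K, m$K)
  expect_equal(substitute_medoid(back, 1, back$medoids[1]),
               m$ranked_members[[1]][2])
})

test_that("end-to-end discovery recovers generator clusters", {
  ok <- vapply(1:3, function(s) {
    cfg <- generator_config(n_samples = 500, n_tissues = 1,
                            cluster_sizes = c(10, 15, 20),
                            within_cluster_loading = 0.9,
                            regulator_noise_sd = 0.3,
                            tissue_separation = 0, seed = s)
    rg <- generate_regulators(cfg)
    m <- discover_components(rg$matrix, K_max = 6, n_restarts = 10,
                             seed = s)
    truth <- rg$truth$cluster_assignment[m$retained]
    m$K == 3 && adjusted_rand_index(m$clusters, truth) >= 0.9
  }, logical(1))
  expect_true(all(ok))
})

test_that("package ARI agrees with the mclust reference", {
  skip_if_not_installed("mclust")
  set.seed(10)
  for (i in 1:20) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("mirror mode identifies antipodal directions", {
  set.seed(12)
  X <- rvmf(40, c(1, 0, 0), 80)
  X[1:20, ] <- -X[1:20, ]          # half the bundle flipped
  rownames(X) <- paste0("f", 1:40)
  plain <- suppressWarnings(select_num_clusters(X, K_max = 3,
                                                n_restarts = 5, seed = 2))
  mirrored <- suppressWarnings(select_num_clusters(X, K_max = 3,
                                                   n_restarts = 5, seed = 2,
                                                   mirror = TRUE))
  expect_gt(plain$K, 1)            # antipodal halves split without mirroring
  expect_equal(mirrored$K, 1L)     # one component once signs are identified
})

test_that("the pairwise medoid rule picks the summed-cosine minimizer", {
  set.seed(13)
  X <- rvmf(30, c(0, 1), 60)
  rownames(X) <- paste0("f", 1:30)
  m <- select_num_clusters(X, K_max = 1, n_restarts = 3, seed = 1,
                           medoid_rule = "pairwise")
  S <- X %*% t(X)
  expect_equal(m$medoids[1], rownames(X)[which.max(rowSums(S))])
})
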