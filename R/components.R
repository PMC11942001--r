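# Regulatory-component discovery on the loading hypersphere.
#
# Pipeline: (1) represent each regulator by its loadings on the top-d
# principal components of the feature correlation structure, with d chosen
# by an Auer-Gervini-style Bayesian step-function criterion; (2) discard
# features whose loading vector is short (low communality); (3) cluster the
# directions of the surviving loading vectors with a von Mises-Fisher
# mixture, picking the number of clusters by BIC; (4) report each cluster's
# members ranked by closeness to the mean direction, the top one being the
# cluster medoid that stands in for the whole regulatory component.

#' Principal-component feature representations
#'
#' Standardizes every feature across samples and eigendecomposes the
#' feature-feature correlation matrix. Feature i is represented by
#' `nu_i[k] = v_k[i] * sqrt(lambda_k)` over the top-d components, so that
#' `||nu_i||^2` equals the fraction of feature i's (unit) variance captured
#' by those d components.
#'
#' @param regulators `ExpressionMatrix` (>= 3 samples, >= 3 features).
#' @param d optional fixed dimension; default selects it with
#'   [select_dimension()].
#' @param drop_constant drop zero-variance features with a warning
#'   (default) instead of failing.
#' @return A `FeatureLoadings` list: `nu` (features x d matrix),
#'   `d`, `eigenvalues` (full descending spectrum), `feature_ids`.
#' @export
compute_loadings <- function(regulators, d = NULL, drop_constant = TRUE) {
  stopifnot(inherits(regulators, "ExpressionMatrix"))
  X <- regulators$values
  if (nrow(X) < 3 || ncol(X) < 3)
    stop("need at least 3 samples and 3 features")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    if (!drop_constant)
      stop("constant feature(s): ",
           paste(regulators$feature_ids[sds == 0], collapse = ", "))
    warning("dropping constant feature(s): ",
            paste(regulators$feature_ids[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  ids <- colnames(X)
  Z <- scale(X)
  R <- stats::cor(X)
  eg <- eigen(R, symmetric = TRUE)
  lambda <- pmax(eg$values, 0)
  if (is.null(d)) d <- select_dimension(lambda, n_features = ncol(X))
  d <- max(1L, min(as.integer(d), length(lambda)))
  nu <- eg$vectors[, seq_len(d), drop = FALSE] %*%
    diag(sqrt(lambda[seq_len(d)]), d, d)
  rownames(nu) <- ids
  structure(list(nu = nu, d = d, eigenvalues = lambda, feature_ids = ids),
            class = "FeatureLoadings")
}

# Profile log-likelihood of "d real components + isotropic residual" for a
# descending spectrum; the workhorse of the Auer-Gervini criterion.
.ag_loglik <- function(lambda, n) {
  p <- length(lambda)
  lam <- pmax(lambda, 1e-12)
  sapply(0:(p - 1), function(d) {
    resid <- mean(lam[(d + 1):p])
    -(n / 2) * (sum(log(lam[seq_len(d)])) + (p - d) * log(resid))
  })
}

#' Bayesian selection of the number of significant components
#'
#' Auer-Gervini-style procedure: the maximum-a-posteriori dimension under a
#' prior penalty `theta * d` is a nonincreasing step function of theta, and
#' the theta-stability interval of each dimension (its "step") is obtained
#' in closed form from the upper concave hull of the profile
#' log-likelihood. The selected d is the largest dimension whose step is
#' judged significant; always at least 1.
#'
#' Criteria (pluggable): `"theta_doubling"` (default) calls a step
#' significant when it spans at least a twofold range of theta
#' (`theta_hi >= 2 * theta_lo`) — the dimension stays maximum-a-posteriori
#' across a doubling of the prior penalty, a scale-invariant robustness
#' requirement that smooth pure-noise spectra (whose steps all have
#' multiplicative width close to 1) cannot meet. `"twice_mean"` requires
#' the step length to be at least twice the mean finite step length;
#' `"longest_step"` takes the single longest finite step.
#'
#' @param eigenvalues nonincreasing, nonnegative spectrum.
#' @param n_features number of observations behind the spectrum (features,
#'   for a feature-by-sample decomposition).
#' @param criterion `"theta_doubling"` (default), `"twice_mean"` or
#'   `"longest_step"`.
#' @return Integer dimension d >= 1.
#' @export
select_dimension <- function(eigenvalues, n_features,
                             criterion = c("theta_doubling", "twice_mean",
                                           "longest_step")) {
  criterion <- match.arg(criterion)
  lambda <- as.numeric(eigenvalues)
  if (any(lambda < -1e-8)) stop("eigenvalues must be nonnegative")
  lambda <- pmax(lambda, 0)
  p <- length(lambda)
  if (p < 2) return(1L)
  if (max(lambda) - min(lambda) < 1e-12) return(1L)  # flat spectrum
  h <- .ag_loglik(lambda, n_features)   # h[d+1] = loglik of dimension d
  dims <- 0:(p - 1)
  # upper concave hull of (d, h): candidate MAP dimensions as theta varies
  hull <- 1L
  for (i in 2:length(dims)) {
    while (length(hull) >= 2) {
      a <- hull[length(hull) - 1]; b <- hull[length(hull)]
      s1 <- (h[b] - h[a]) / (dims[b] - dims[a])
      s2 <- (h[i] - h[b]) / (dims[i] - dims[b])
      if (s2 >= s1) hull <- hull[-length(hull)] else break
    }
    hull <- c(hull, i)
  }
  hd <- dims[hull]; hh <- h[hull]
  m <- length(hull)
  # MAP(theta) = argmax h(d) - theta*d; hull point j is optimal for theta in
  # (slope to the next hull point, slope to the previous one)
  slopes <- (diff(hh)) / (diff(hd))     # decreasing, MAP switches here
  theta_hi <- c(Inf, slopes)            # upper end for each hull point
  theta_lo <- c(slopes, 0)              # lower end (last point: theta -> 0)
  # step length per hull dimension, restricted to theta >= 0
  len <- pmax(pmin(theta_hi, Inf) - pmax(theta_lo, 0), 0)
  len[1] <- Inf                          # d = 0 holds for all large theta
  finite <- is.finite(len) & hd >= 1
  if (!any(finite)) return(1L)
  if (criterion == "longest_step")
    return(max(1L, as.integer(hd[finite][which.max(len[finite])])))
  if (criterion == "twice_mean") {
    thr <- 2 * mean(len[finite])
    sig <- finite & len >= thr
  } else {  # theta_doubling
    # the largest hull dimension holds as theta -> 0 (the unpenalized,
    # saturated end) and would pass any multiplicative test trivially;
    # near-degenerate spectrum tails produce vanishing steps whose ratios
    # are noise, so a doubling must also have non-trivial absolute length
    lo <- pmax(theta_lo, 0)
    # spike admissibility: a retained component's eigenvalue must stand
    # above the spectrum's mean (Kaiser-style), which screens out steps
    # generated by eigenvalue crowding at the noise floor
    admissible <- hd >= 1 & lambda[pmax(hd, 1)] > mean(lambda)
    sig <- finite & (theta_hi >= 2 * lo) & hd < max(hd) &
      len >= mean(len[finite]) & admissible
  }
  if (!any(sig)) return(1L)
  max(1L, as.integer(max(hd[sig])))
}

#' Discard features with short loading vectors
#'
#' A feature whose representation has `||nu_i|| < threshold` has little of
#' its variance captured by the shared components (weak communality) and is
#' treated as an outlier.
#'
#' @param loadings a `FeatureLoadings`.
#' @param threshold retention threshold on `||nu_i||_2` (default 0.35,
#'   inclusive: a norm exactly at the threshold is retained).
#' @return Character vector of retained feature ids.
#' @export
filter_outliers <- function(loadings, threshold = 0.35) {
  stopifnot(inherits(loadings, "FeatureLoadings"))
  norms <- sqrt(rowSums(loadings$nu^2))
  retained <- loadings$feature_ids[norms >= threshold]
  if (length(retained) == 0)
    stop("no features pass ||nu|| >= ", threshold,
         "; consider lowering the threshold")
  retained
}

# -- von Mises-Fisher mixture ------------------------------------------------

# log normalizing constant of the vMF density on S^{d-1}
.log_cvmf <- function(kappa, d) {
  nu <- d / 2 - 1
  if (kappa < 1e-8) {
    # uniform limit: inverse surface area of S^{d-1}
    return(lgamma(d / 2) - log(2) - (d / 2) * log(pi))
  }
  # log I_nu(kappa) via the exponentially scaled Bessel function
  bi <- besselI(kappa, nu, expon.scaled = TRUE)
  if (bi <= 0 || !is.finite(bi)) {
    # large-kappa asymptotic: I_nu(k) ~ e^k / sqrt(2 pi k)
    log_bessel <- kappa - 0.5 * log(2 * pi * kappa)
  } else {
    log_bessel <- log(bi) + kappa
  }
  nu * log(kappa) - (d / 2) * log(2 * pi) - log_bessel
}

# Banerjee et al. closed-form concentration estimate from the mean resultant
# length rbar.
.kappa_banerjee <- function(rbar, d, kappa_max = 1e4) {
  if (rbar >= 1 - 1e-12) return(kappa_max)
  if (rbar <= 0) return(0)
  min((rbar * d - rbar^3) / (1 - rbar^2), kappa_max)
}

# spherical k-means++ seeding: greedy probabilistic spread by cosine distance
.skmeans_pp <- function(X, K) {
  n <- nrow(X)
  centers <- matrix(0, K, ncol(X))
  i <- sample.int(n, 1)
  centers[1, ] <- X[i, ]
  if (K > 1) {
    d2 <- 1 - X %*% centers[1, ]          # cosine distance to nearest center
    for (k in 2:K) {
      w <- pmax(as.numeric(d2), 0)^2
      if (sum(w) <= 0) i <- sample.int(n, 1)
      else i <- sample.int(n, 1, prob = w)
      centers[k, ] <- X[i, ]
      d2 <- pmin(d2, 1 - X %*% centers[k, ])
    }
  }
  centers
}

#' Fit a K-component von Mises-Fisher mixture by EM
#'
#' E-step responsibilities are proportional to
#' `w_k c_d(kappa_k) exp(kappa_k mu_k' x)`; the M-step sets `mu_k` to the
#' normalized weighted resultant and `kappa_k` by the Banerjee closed-form
#' approximation. Degenerate clusters (resultant length ~ 1) have kappa
#' capped at `kappa_max`.
#'
#' @param directions matrix of unit vectors (rows) on the sphere, d >= 2.
#' @param K number of components.
#' @param seed integer seed for the k-means++ initialization.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param kappa_max concentration cap for degenerate clusters.
#' @return List: `mu` (K x d), `kappa`, `weights`, `assignment` (max
#'   responsibility), `responsibilities`, `loglik`, `loglik_trace`,
#'   `converged`.
#' @export
fit_vmf_mixture <- function(directions, K, seed = 1, max_iter = 500,
                            tol = 1e-7, kappa_max = 1e4) {
  X <- as.matrix(directions)
  n <- nrow(X); d <- ncol(X)
  if (d < 2) stop("vMF mixture requires dimension >= 2; use sign grouping for d = 1")
  if (K < 1) stop("K must be >= 1")
  if (n < K) stop("fewer points than components")
  nrm <- sqrt(rowSums(X^2))
  if (any(abs(nrm - 1) > 1e-6)) X <- X / nrm
  set.seed(seed)
  mu <- .skmeans_pp(X, K)
  mu <- mu / sqrt(rowSums(mu^2))
  kappa <- rep(10, K)
  w <- rep(1 / K, K)
  prev_ll <- -Inf; trace <- numeric(0); converged <- FALSE
  R_resp <- NULL
  for (it in seq_len(max_iter)) {
    # E-step in log space
    logdens <- X %*% t(mu) * rep(kappa, each = n)
    for (k in seq_len(K))
      logdens[, k] <- logdens[, k] + .log_cvmf(kappa[k], d) + log(w[k])
    mx <- apply(logdens, 1, max)
    lse <- mx + log(rowSums(exp(logdens - mx)))
    ll <- sum(lse)
    trace <- c(trace, ll)
    R_resp <- exp(logdens - lse)
    if (is.finite(prev_ll) &&
        abs(ll - prev_ll) <= tol * (abs(prev_ll) + 1e-12)) {
      converged <- TRUE
      break
    }
    prev_ll <- ll
    # M-step
    Nk <- colSums(R_resp)
    w <- Nk / n
    for (k in seq_len(K)) {
      res <- colSums(R_resp[, k] * X)
      rlen <- sqrt(sum(res^2))
      if (Nk[k] < 1e-10 || rlen < 1e-12) {
        # empty cluster: re-seed at the worst-fit point
        worst <- which.min(lse)
        mu[k, ] <- X[worst, ]
        kappa[k] <- 10
        next
      }
      mu[k, ] <- res / rlen
      rbar <- rlen / Nk[k]
      if (rbar >= 1 - 1e-12)
        warning("degenerate cluster ", k, ": kappa capped at ", kappa_max)
      kappa[k] <- .kappa_banerjee(rbar, d, kappa_max)
    }
  }
  list(mu = mu, kappa = kappa, weights = w,
       assignment = max.col(R_resp, ties.method = "first"),
       responsibilities = R_resp,
       loglik = trace[length(trace)], loglik_trace = trace,
       converged = converged)
}

# BIC for a K-component vMF mixture on S^{d-1}:
# K(d-1) direction parameters + K concentrations + (K-1) weights.
.vmf_bic <- function(loglik, K, d, n) {
  m <- K * (d - 1) + K + (K - 1)
  -2 * loglik + m * log(n)
}

#' Cluster loading directions, selecting K by BIC
#'
#' For each K in `1:K_max`, fits `n_restarts` seeded EM runs and keeps the
#' best log-likelihood; the K minimizing `BIC = -2 logL + m log(N)` (ties
#' toward smaller K) wins. Within each cluster, members are ranked by
#' descending cosine `mu_k' x`; the rank-1 member is the cluster medoid.
#' With d = 1 directions are just signs and clustering reduces to sign
#' grouping.
#'
#' @param loadings a `FeatureLoadings`, or a features x d matrix of
#'   (not necessarily normalized) loading vectors with rownames.
#' @param retained optional feature ids to cluster (default: all).
#' @param K_max largest number of clusters to consider.
#' @param n_restarts EM restarts per K.
#' @param seed integer seed.
#' @param mirror if `TRUE`, identify antipodal directions (x and -x are the
#'   same component) by flipping each direction into the hemisphere of its
#'   largest-magnitude coordinate before clustering; off by default.
#' @param medoid_rule `"centroid"` (default; medoid = member closest to the
#'   mean direction, which also defines the substitution ranking) or
#'   `"pairwise"` (medoid = member minimizing summed cosine distance to its
#'   cluster mates; ranking unchanged otherwise).
#' @return A `ComponentModel`: `retained`, `clusters` (named integer
#'   vector), `mean_directions`, `concentrations`, `weights`,
#'   `ranked_members` (list per cluster), `medoids`, `bic`, `bic_trace`,
#'   `K`, `d`, `loglik`.
#' @export
select_num_clusters <- function(loadings, retained = NULL, K_max = 10,
                                n_restarts = 20, seed = 1, mirror = FALSE,
                                medoid_rule = c("centroid", "pairwise")) {
  medoid_rule <- match.arg(medoid_rule)
  nu <- if (inherits(loadings, "FeatureLoadings")) loadings$nu
        else as.matrix(loadings)
  if (is.null(retained)) retained <- rownames(nu)
  nu <- nu[retained, , drop = FALSE]
  N <- nrow(nu); d <- ncol(nu)
  if (N < 1) stop("no retained features to cluster")
  if (d == 1) return(.sign_cluster_model(nu, retained))
  X <- nu / sqrt(rowSums(nu^2))
  if (mirror) {
    flip <- apply(X, 1, function(x) sign(x[which.max(abs(x))]))
    flip[flip == 0] <- 1
    X <- X * flip
  }
  best <- NULL; bic_trace <- stats::setNames(rep(NA_real_, K_max),
                                             paste0("K", seq_len(K_max)))
  for (K in seq_len(K_max)) {
    if (N < K) next
    best_k <- NULL
    for (r in seq_len(n_restarts)) {
      sub_seed <- (as.numeric(seed) %% 2000003) * 1000 + K * 37 + r
      fit <- fit_vmf_mixture(X, K, seed = as.integer(sub_seed %% 2147483647))
      if (is.null(best_k) || fit$loglik > best_k$loglik) best_k <- fit
    }
    bic <- .vmf_bic(best_k$loglik, K, d, N)
    bic_trace[K] <- bic
    if (is.null(best) || bic < best$bic - 1e-9) {   # ties -> smaller K
      best <- list(fit = best_k, K = K, bic = bic)
    }
  }
  fit <- best$fit; K <- best$K
  clusters <- stats::setNames(fit$assignment, retained)
  cosines <- X %*% t(fit$mu)
  ranked <- vector("list", K)
  for (k in seq_len(K)) {
    members <- which(fit$assignment == k)
    ord <- members[order(-cosines[members, k], members)]  # ties: input order
    ranked[[k]] <- retained[ord]
  }
  medoids <- vapply(ranked, `[`, character(1), 1)
  if (medoid_rule == "pairwise") {
    medoids <- vapply(seq_len(K), function(k) {
      members <- which(fit$assignment == k)
      S <- X[members, , drop = FALSE] %*% t(X[members, , drop = FALSE])
      retained[members[which.max(rowSums(S))]]   # min summed cosine distance
    }, character(1))
  }
  structure(list(retained = retained, clusters = clusters,
                 mean_directions = fit$mu, concentrations = fit$kappa,
                 weights = fit$weights, ranked_members = ranked,
                 medoids = medoids,
                 bic = best$bic, bic_trace = bic_trace,
                 K = K, d = d, loglik = fit$loglik),
            class = "ComponentModel")
}

# d = 1 degenerate case: directions are +/-1; group by sign, medoid = the
# member with the largest |nu| in each sign group.
.sign_cluster_model <- function(nu, retained) {
  sgn <- sign(nu[, 1])
  sgn[sgn == 0] <- 1
  levs <- sort(unique(sgn), decreasing = TRUE)
  clusters <- stats::setNames(match(sgn, levs), retained)
  K <- length(levs)
  ranked <- vector("list", K)
  for (k in seq_len(K)) {
    members <- which(clusters == k)
    ord <- members[order(-abs(nu[members, 1]), members)]
    ranked[[k]] <- retained[ord]
  }
  structure(list(retained = retained, clusters = clusters,
                 mean_directions = matrix(levs, K, 1),
                 concentrations = rep(Inf, K),
                 weights = as.numeric(table(clusters)) / length(retained),
                 ranked_members = ranked,
                 medoids = vapply(ranked, `[`, character(1), 1),
                 bic = NA_real_, bic_trace = NA_real_,
                 K = K, d = 1L, loglik = NA_real_),
            class = "ComponentModel")
}

#' @export
print.ComponentModel <- function(x, ...) {
  cat(sprintf("ComponentModel: %d clusters over %d features (d = %d)\n",
              x$K, length(x$retained), x$d))
  cat("  medoids:", paste(x$medoids, collapse = ", "), "\n")
  invisible(x)
}

#' Replace an unavailable medoid by the next-ranked cluster member
#'
#' Walks the cluster's members in order of closeness to the mean direction
#' and returns the first one not in `unavailable` — the substitution used
#' when a medoid is missing from a target dataset.
#'
#' @param model a `ComponentModel`.
#' @param k cluster index.
#' @param unavailable feature ids that cannot be used.
#' @return A feature id.
#' @export
substitute_medoid <- function(model, k, unavailable = character()) {
  stopifnot(inherits(model, "ComponentModel"))
  members <- model$ranked_members[[k]]
  if (length(members) == 0) stop("cluster ", k, " has no members")
  ok <- members[!(members %in% unavailable)]
  if (length(ok) == 0)
    stop("all members of cluster ", k, " are unavailable")
  ok[1]
}

#' Full regulatory-component discovery pipeline
#'
#' [compute_loadings()] (with Bayesian dimension selection), then
#' [filter_outliers()] at `threshold`, then [select_num_clusters()] on the
#' retained directions.
#'
#' @param regulators `ExpressionMatrix` of regulator expression.
#' @param threshold loading-norm retention threshold.
#' @param K_max,n_restarts,seed passed to [select_num_clusters()].
#' @param d optional fixed representation dimension.
#' @return A `ComponentModel` (with the `FeatureLoadings` attached as
#'   attribute `"loadings"`).
#' @export
discover_components <- function(regulators, threshold = 0.35, K_max = 10,
                                n_restarts = 20, seed = 1, d = NULL) {
  loadings <- compute_loadings(regulators, d = d)
  retained <- filter_outliers(loadings, threshold)
  model <- select_num_clusters(loadings, retained = retained, K_max = K_max,
                               n_restarts = n_restarts, seed = seed)
  attr(model, "loadings") <- loadings
  model
}

#' Serialize / deserialize a ComponentModel as JSON
#'
#' @param model a `ComponentModel`.
#' @param path output file.
#' @return `path` invisibly; `read_component_model` returns the model.
#' @export
write_component_model <- function(model, path) {
  stopifnot(inherits(model, "ComponentModel"))
  obj <- list(retained = model$retained,
              clusters = as.list(model$clusters),
              mean_directions = model$mean_directions,
              concentrations = model$concentrations,
              weights = model$weights,
              ranked_members = model$ranked_members,
              medoids = model$medoids,
              bic = model$bic, bic_trace = as.list(model$bic_trace),
              K = model$K, d = model$d, loglik = model$loglik)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_component_model
#' @export
read_component_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  # equal-size clusters simplify to a character matrix, one row per cluster
  ranked <- if (is.matrix(obj$ranked_members))
    lapply(asplit(obj$ranked_members, 1), as.character)
  else lapply(obj$ranked_members, unlist)
  structure(list(retained = obj$retained,
                 clusters = stats::setNames(as.integer(unlist(obj$clusters)),
                                            names(obj$clusters)),
                 mean_directions = as.matrix(obj$mean_directions),
                 concentrations = obj$concentrations,
                 weights = obj$weights,
                 ranked_members = ranked,
                 medoids = obj$medoids,
                 bic = obj$bic,
                 bic_trace = unlist(obj$bic_trace),
                 K = as.integer(obj$K), d = as.integer(obj$d),
                 loglik = obj$loglik),
            class = "ComponentModel")
}
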