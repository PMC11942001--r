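# Cross-dataset application of the Tissue-Aware model: pseudo-tissue
# construction (K-means over the regulator space) with cross-validated K,
# nearest-centroid assignment of target samples, feature matching across
# miRNA naming dialects (exact / arm-suffix base name / ranked-member
# substitution), and per-feature Wasserstein-1 shift diagnostics against a
# mismatched-pair null.

#' Cluster samples into pseudo-tissues
#'
#' K-means in the selected-regulator space with k-means++ seeding, keeping
#' the best of `n_init` restarts by total within-cluster sum of squares.
#' Pseudo-tissues stand in for tissue labels when labels do not transfer
#' across datasets.
#'
#' @param X `ExpressionMatrix` or samples x features matrix.
#' @param K number of clusters (1 <= K <= n).
#' @param seed integer seed.
#' @param n_init number of seeded restarts.
#' @return A `PseudoTissueMap`: `K`, `centroids` (K x p), `feature_ids`,
#'   `assignment`, `training_inertia`.
#' @export
fit_pseudo_tissues <- function(X, K, seed = 1, n_init = 10) {
  Xm <- .as_xy(X)
  n <- nrow(Xm)
  if (K < 1 || K > n) stop("K must lie in [1, n]")
  if (nrow(unique(Xm)) < K)
    stop("fewer than K distinct samples")
  set.seed(seed)
  if (K == 1) {
    centers <- matrix(colMeans(Xm), 1, ncol(Xm))
    assign <- rep(1L, n)
    inertia <- sum(sweep(Xm, 2, centers[1, ])^2)
  } else {
    best <- NULL
    for (r in seq_len(n_init)) {
      init <- .kmeanspp_centers(Xm, K)
      km <- suppressWarnings(
        stats::kmeans(Xm, centers = init, iter.max = 100))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    centers <- best$centers
    assign <- as.integer(best$cluster)
    inertia <- best$tot.withinss
  }
  colnames(centers) <- colnames(Xm)
  structure(list(K = as.integer(K), centroids = centers,
                 feature_ids = colnames(Xm), assignment = assign,
                 training_inertia = inertia),
            class = "PseudoTissueMap")
}

# k-means++ center selection (squared-Euclidean spreading)
.kmeanspp_centers <- function(X, K) {
  n <- nrow(X)
  centers <- matrix(0, K, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  if (K > 1) {
    d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
    for (k in 2:K) {
      if (sum(d2) <= 0) i <- sample.int(n, 1)
      else i <- sample.int(n, 1, prob = d2)
      centers[k, ] <- X[i, ]
      d2 <- pmin(d2, rowSums(sweep(X, 2, centers[k, ])^2))
    }
  }
  # kmeans() rejects duplicate centers; jitter exact duplicates minutely
  if (anyDuplicated(centers))
    centers <- centers + stats::rnorm(length(centers), sd = 1e-9)
  centers
}

#' Assign samples to the nearest pseudo-tissue centroid
#'
#' @param x a sample vector, or a samples x features matrix /
#'   `ExpressionMatrix` (columns aligned to `map$feature_ids` by name when
#'   named).
#' @param map a `PseudoTissueMap`.
#' @return Integer cluster index (vector for matrix input); ties go to the
#'   lowest index.
#' @export
assign_pseudo_tissue <- function(x, map) {
  stopifnot(inherits(map, "PseudoTissueMap"))
  Xm <- if (is.null(dim(x)) && !inherits(x, "ExpressionMatrix"))
    matrix(x, 1) else .as_xy(x)
  if (!is.null(colnames(Xm))) {
    missing_ids <- setdiff(map$feature_ids, colnames(Xm))
    if (length(missing_ids))
      stop("sample lacks features: ", paste(missing_ids, collapse = ", "))
    Xm <- Xm[, map$feature_ids, drop = FALSE]
  } else if (ncol(Xm) != length(map$feature_ids)) {
    stop("dimension mismatch: expected ", length(map$feature_ids),
         " features")
  }
  # squared distances via ||x||^2 - 2 x.c + ||c||^2; ties -> lowest index
  cross <- Xm %*% t(map$centroids)
  c2 <- rowSums(map$centroids^2)
  d2 <- sweep(-2 * cross, 2, c2, "+")
  apply(d2, 1, which.min)
}

#' Tune the number of pseudo-tissues by cross-validation
#'
#' For each K: in every fold, fit pseudo-tissues and a Tissue-Aware model
#' (pseudo-tissue labels standing in for tissues) on the training split,
#' assign held-out samples to their nearest centroid, predict, and
#' accumulate RMSE and correlation score. `K_best` minimizes the mean RMSE;
#' the correlation-score curve is reported as a concordance check.
#'
#' @param X regulators (`ExpressionMatrix` or matrix).
#' @param Y outcomes (same samples).
#' @param K_range candidate cluster counts.
#' @param folds number of CV folds (default 5).
#' @param seed integer seed (folds, clustering, score nulls).
#' @return A list: `K_best`, `rmse` (named per-K), `cor_score` (named
#'   per-K), `folds`.
#' @export
tune_num_pseudo_tissues <- function(X, Y, K_range = 2:20, folds = 5,
                                    seed = 1) {
  if (folds < 2) stop("folds must be >= 2")
  Xm <- .as_xy(X); Ym <- .as_xy(Y)
  n <- nrow(Xm)
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), n))
  rmse <- stats::setNames(rep(NA_real_, length(K_range)),
                          paste0("K", K_range))
  cscore <- rmse
  for (i in seq_along(K_range)) {
    K <- K_range[i]
    sse <- 0; m <- 0; cs <- numeric(folds); ok <- TRUE
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      if (sum(tr) < K) { ok <- FALSE; break }
      map <- fit_pseudo_tissues(Xm[tr, , drop = FALSE], K,
                                seed = seed + 31L * f)
      lab_tr <- paste0("PT", map$assignment)
      # guard: a singleton pseudo-tissue cannot host a stage-2 fit
      while (min(table(lab_tr)) < 2) {
        singles <- names(which(table(lab_tr) < 2))
        keepc <- setdiff(unique(lab_tr), singles)
        idx <- lab_tr %in% singles
        near <- assign_pseudo_tissue(Xm[tr, , drop = FALSE][idx, ,
                                                            drop = FALSE],
                                     map)
        lab_tr[idx] <- paste0("PT", near)
        if (all(paste0("PT", near) %in% singles)) break
      }
      fit <- fit_tissue_aware(Xm[tr, , drop = FALSE],
                              Ym[tr, , drop = FALSE], lab_tr)
      te <- !tr
      lab_te <- paste0("PT", assign_pseudo_tissue(Xm[te, , drop = FALSE],
                                                  map))
      lab_te[!(lab_te %in% fit$tissues)] <- fit$tissues[1]
      pred <- predict(fit, Xm[te, , drop = FALSE], tissue = lab_te)
      sse <- sse + sum((Ym[te, , drop = FALSE] - pred)^2)
      m <- m + sum(te) * ncol(Ym)
      cs[f] <- correlation_score(Ym[te, , drop = FALSE], pred,
                                 n_null_pairs = max(ncol(Ym), 100),
                                 seed = seed + f)$score
    }
    if (!ok) next
    rmse[i] <- sqrt(sse / m)
    cscore[i] <- mean(cs)
  }
  valid <- which(!is.na(rmse))
  list(K_best = K_range[valid[which.min(rmse[valid])]],
       rmse = rmse, cor_score = cscore, folds = folds)
}

# -- feature matching across naming dialects ---------------------------------

.strip_arm <- function(ids) sub("-[35]p$", "", ids, ignore.case = TRUE)

#' Match source regulators to a target dataset's feature ids
#'
#' For every source id: (1) exact id match; (2) strip a terminal mature-arm
#' suffix ("-3p"/"-5p", case-insensitive) and match the base name — the
#' directional-vs-aggregate miRNA dialect; (3) walk the source feature's
#' cluster members in medoid rank order, trying each exact-then-base, and
#' take the first hit as a substitute; (4) otherwise unmatched. When two
#' sources claim one target id the higher-priority match wins
#' (exact > base_name > substitute; then source order) with a warning.
#'
#' @param source_ids regulator ids used by the trained model.
#' @param target_ids feature ids available in the target dataset.
#' @param model optional `ComponentModel` supplying ranked cluster members
#'   for substitution.
#' @return A `FeatureMapping`: data.frame `pairs` (source_id, target_id,
#'   match_type) and character vector `unmatched`.
#' @export
match_features <- function(source_ids, target_ids, model = NULL) {
  target_base <- .strip_arm(target_ids)
  find_one <- function(id) {
    hit <- match(id, target_ids)
    if (!is.na(hit)) return(c(target_ids[hit], "exact"))
    base <- .strip_arm(id)
    hit <- match(tolower(base), tolower(target_ids))
    if (!is.na(hit)) return(c(target_ids[hit], "base_name"))
    c(NA_character_, NA_character_)
  }
  rows <- list(); unmatched <- character(0)
  for (id in source_ids) {
    r <- find_one(id)
    type <- r[2]
    if (is.na(r[1]) && !is.null(model)) {
      k <- model$clusters[[id]]
      if (!is.null(k) && !is.na(k)) {
        for (cand in model$ranked_members[[k]]) {
          if (cand == id) next
          rc <- find_one(cand)
          if (!is.na(rc[1])) { r <- rc; type <- "substitute"; break }
        }
      }
    }
    if (is.na(r[1])) unmatched <- c(unmatched, id)
    else rows[[length(rows) + 1]] <-
      data.frame(source_id = id, target_id = r[1], match_type = type,
                 stringsAsFactors = FALSE)
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source_id = character(0), target_id = character(0),
               match_type = character(0))
  # resolve target collisions by priority then source order
  if (nrow(pairs) && anyDuplicated(pairs$target_id)) {
    prio <- match(pairs$match_type, c("exact", "base_name", "substitute"))
    keep <- !duplicated(pairs$target_id[order(prio, seq_len(nrow(pairs)))])
    keep <- keep[order(order(prio, seq_len(nrow(pairs))))]
    dropped <- pairs$source_id[!keep]
    warning("target collision; dropped lower-priority match for: ",
            paste(dropped, collapse = ", "))
    unmatched <- c(unmatched, dropped)
    pairs <- pairs[keep, , drop = FALSE]
  }
  structure(list(pairs = pairs, unmatched = unmatched),
            class = "FeatureMapping")
}

#' One-dimensional Wasserstein-1 distance between empirical distributions
#'
#' The earth-mover distance `W1 = integral |F_a - F_b|` between the
#' empirical CDFs. Equal sample sizes reduce to the mean absolute
#' difference of sorted values; unequal sizes are integrated over the
#' merged breakpoints.
#'
#' @param a,b nonempty finite numeric vectors.
#' @return Nonnegative distance (same units as the data).
#' @export
wasserstein_1d <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) stop("empty input")
  if (!all(is.finite(a)) || !all(is.finite(b))) stop("non-finite input")
  if (length(a) == length(b))
    return(mean(abs(sort(a) - sort(b))))
  grid <- sort(unique(c(a, b)))
  if (length(grid) == 1) return(0)
  Fa <- stats::ecdf(a)(grid); Fb <- stats::ecdf(b)(grid)
  sum(abs(Fa[-length(grid)] - Fb[-length(grid)]) * diff(grid))
}

#' Per-feature covariate-shift report against a mismatched-pair null
#'
#' For every matched (source, target) feature pair, the Wasserstein-1
#' distance between the two expression distributions; the null comes from
#' mismatched ordered pairs (source_i, target_j), i != j — all of them when
#' at most `max_null`, else a seeded subsample. Each matched distance is
#' placed as a percentile within the null.
#'
#' @param source,target `ExpressionMatrix` objects (or matrices with
#'   column names).
#' @param mapping a `FeatureMapping` from [match_features()].
#' @param max_null null-pair budget (default 1e4).
#' @param seed integer seed for null subsampling.
#' @return A `ShiftReport` data.frame: source_id, target_id, match_type,
#'   distance, percentile; the null distances are attached as attribute
#'   `"null"`.
#' @export
shift_report <- function(source, target, mapping, max_null = 1e4, seed = 1) {
  stopifnot(inherits(mapping, "FeatureMapping"))
  Sm <- .as_xy(source); Tm <- .as_xy(target)
  pairs <- mapping$pairs
  if (nrow(pairs) < 2)
    stop("need at least 2 matched pairs to form a null")
  P <- nrow(pairs)
  matched <- vapply(seq_len(P), function(i) {
    wasserstein_1d(Sm[, pairs$source_id[i]], Tm[, pairs$target_id[i]])
  }, numeric(1))
  all_pairs <- expand.grid(i = seq_len(P), j = seq_len(P))
  all_pairs <- all_pairs[all_pairs$i != all_pairs$j, , drop = FALSE]
  if (nrow(all_pairs) > max_null) {
    set.seed(seed)
    all_pairs <- all_pairs[sample.int(nrow(all_pairs), max_null), ,
                           drop = FALSE]
  }
  null <- vapply(seq_len(nrow(all_pairs)), function(r) {
    wasserstein_1d(Sm[, pairs$source_id[all_pairs$i[r]]],
                   Tm[, pairs$target_id[all_pairs$j[r]]])
  }, numeric(1))
  pct <- vapply(matched, function(d) 100 * mean(null < d), numeric(1))
  out <- data.frame(pairs, distance = matched, percentile = pct,
                    stringsAsFactors = FALSE)
  attr(out, "null") <- null
  class(out) <- c("ShiftReport", "data.frame")
  out
}
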