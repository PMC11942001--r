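# Predictability evaluation: beta-mixture decomposition of the per-gene R^2
# distribution, poor/well tail labels, gene predictability categories, the
# correlation-score statistic used for landmark-gene comparisons, and the
# cross-validated tissue-classification harness.

# weighted MLE of Beta(a, b): Newton on the digamma score equations,
# initialized from (weighted) method of moments. lx/l1x are precomputed
# log(x) and log1p(-x).
.beta_wmle <- function(x, w, lx = log(x), l1x = log1p(-x),
                       max_iter = 100, tol = 1e-10) {
  w <- w / sum(w)
  m <- sum(w * x)
  v <- sum(w * (x - m)^2)
  v <- max(v, 1e-10)
  common <- max(m * (1 - m) / v - 1, 1e-3)
  a <- max(m * common, 1e-3); b <- max((1 - m) * common, 1e-3)
  t1 <- sum(w * lx); t2 <- sum(w * l1x)
  for (i in seq_len(max_iter)) {
    g1 <- digamma(a) - digamma(a + b) - t1
    g2 <- digamma(b) - digamma(a + b) - t2
    tg <- trigamma(a + b)
    J11 <- trigamma(a) - tg; J22 <- trigamma(b) - tg
    det <- J11 * J22 - tg^2
    if (!is.finite(det) || abs(det) < 1e-300) break
    da <- (J22 * g1 + tg * g2) / det
    db <- (tg * g1 + J11 * g2) / det
    step <- 1
    while ((a - step * da <= 0 || b - step * db <= 0) && step > 1e-8)
      step <- step / 2
    a_new <- a - step * da; b_new <- b - step * db
    if (abs(a_new - a) + abs(b_new - b) < tol * (a + b)) {
      a <- a_new; b <- b_new; break
    }
    a <- a_new; b <- b_new
  }
  c(a = a, b = b)
}

#' Fit a beta mixture to values in (0, 1), selecting k by BIC
#'
#' EM over `k_range` components: responsibilities from weighted beta
#' densities, M-step by weighted maximum likelihood (Newton on the digamma
#' equations) initialized from a quantile split. The component count
#' minimizing `BIC = -2 logL + (3k - 1) log(n)` is returned. Input values
#' are clipped to `[eps, 1 - eps]` first.
#'
#' @param values numeric vector (e.g. per-gene R^2), n >= 10.
#' @param k_range candidate component counts (default 1:4).
#' @param seed integer seed (initialization jitter).
#' @param eps clipping margin.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   tolerance.
#' @return A `BetaMixtureFit`: `k`, `shapes` (k x 2), `weights`, `loglik`,
#'   `bic`, `bic_trace`, `responsibilities`, `converged`, `degenerate`,
#'   `loglik_trace` (per-iteration log-likelihood of the selected k).
#' @export
fit_beta_mixture <- function(values, k_range = 1:4, seed = 1, eps = 1e-6,
                             max_iter = 1000, tol = 1e-8) {
  x <- pmin(pmax(as.numeric(values), eps), 1 - eps)
  n <- length(x)
  if (n < 10) stop("need at least 10 values")
  degenerate <- stats::sd(x) < 1e-12
  if (degenerate) {
    fit <- list(k = 1L, shapes = matrix(c(1, 1), 1, 2,
                                        dimnames = list(NULL, c("a", "b"))),
                weights = 1, loglik = NA_real_, bic = NA_real_,
                bic_trace = NA_real_,
                responsibilities = matrix(1, n, 1),
                converged = TRUE, degenerate = TRUE)
    class(fit) <- "BetaMixtureFit"
    return(fit)
  }
  set.seed(seed)
  best <- NULL
  lx <- log(x); l1x <- log1p(-x)
  bic_trace <- stats::setNames(rep(NA_real_, length(k_range)),
                               paste0("k", k_range))
  for (k in k_range) {
    # initialize from a quantile split: k groups of roughly equal size
    ord <- order(x + stats::rnorm(n, sd = 1e-9))
    grp <- if (k == 1) rep(1L, n) else
      cut(seq_len(n), breaks = k, labels = FALSE)[order(ord)]
    shapes <- t(vapply(seq_len(k), function(j) {
      .beta_wmle(x, as.numeric(grp == j) + 1e-6, lx, l1x)
    }, numeric(2)))
    w <- as.numeric(table(factor(grp, levels = seq_len(k)))) / n
    prev_ll <- -Inf; converged <- FALSE; R <- NULL; ll <- NA_real_
    ll_trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      logd <- vapply(seq_len(k), function(j) {
        (shapes[j, 1] - 1) * lx + (shapes[j, 2] - 1) * l1x -
          lbeta(shapes[j, 1], shapes[j, 2]) + log(w[j])
      }, numeric(n))
      logd <- matrix(logd, n, k)
      mx <- if (k == 1) logd[, 1] else
        as.numeric(do.call(pmax, lapply(seq_len(k), function(j) logd[, j])))
      lse <- mx + log(rowSums(exp(logd - mx)))
      ll <- sum(lse)
      ll_trace <- c(ll_trace, ll)
      R <- exp(logd - lse)
      if (is.finite(prev_ll) &&
          abs(ll - prev_ll) <= tol * (abs(prev_ll) + 1e-12)) {
        converged <- TRUE; break
      }
      prev_ll <- ll
      w <- colMeans(R)
      w <- pmax(w, 1e-8); w <- w / sum(w)
      for (j in seq_len(k)) shapes[j, ] <- .beta_wmle(x, R[, j], lx, l1x)
    }
    bic <- -2 * ll + (3 * k - 1) * log(n)
    bic_trace[paste0("k", k)] <- bic
    if (is.null(best) || bic < best$bic - 1e-9) {
      best <- list(k = as.integer(k), shapes = shapes, weights = w,
                   loglik = ll, bic = bic, responsibilities = R,
                   converged = converged, loglik_trace = ll_trace)
    }
  }
  best$bic_trace <- bic_trace
  best$degenerate <- FALSE
  colnames(best$shapes) <- c("a", "b")
  class(best) <- "BetaMixtureFit"
  best
}

#' @export
print.BetaMixtureFit <- function(x, ...) {
  cat(sprintf("BetaMixtureFit: k = %d, BIC = %.2f\n", x$k, x$bic))
  for (j in seq_len(x$k))
    cat(sprintf("  comp %d: Beta(%.3f, %.3f), w = %.3f, mean = %.3f\n",
                j, x$shapes[j, 1], x$shapes[j, 2], x$weights[j],
                x$shapes[j, 1] / sum(x$shapes[j, ])))
  invisible(x)
}

#' Label observations by the mixture tails
#'
#' The component with the largest mean `a/(a+b)` is the "well"-explained
#' tail and the smallest-mean component the "poor" tail; observations go to
#' the tail (or, for k > 2, to `"other"` middle components) with maximum
#' responsibility. Equal-mean ties go to the larger-weight component; an
#' observation with exactly tied responsibilities goes to the lower-mean
#' side. With k = 1 all observations take the single component's side of
#' its mean versus 0.5.
#'
#' @param fit a `BetaMixtureFit`.
#' @return Character vector (`"poor"`, `"well"`, `"other"`) per observation.
#' @export
label_tail_components <- function(fit) {
  stopifnot(inherits(fit, "BetaMixtureFit"))
  means <- fit$shapes[, 1] / rowSums(fit$shapes)
  n <- nrow(fit$responsibilities)
  if (fit$k == 1)
    return(rep(if (means[1] >= 0.5) "well" else "poor", n))
  ord <- order(means, fit$weights)   # equal means: smaller weight first
  poor_j <- ord[1]; well_j <- ord[fit$k]
  lab <- rep("other", fit$k)
  lab[poor_j] <- "poor"; lab[well_j] <- "well"
  R <- fit$responsibilities
  # exact responsibility ties resolve to the lower-mean component
  pick <- apply(R, 1, function(r) {
    top <- which(r >= max(r) - 1e-12)
    top[which.min(means[top])]
  })
  lab[pick]
}

#' Categorize genes by predictability under the two models
#'
#' Global-threshold categories: `poor_both` if R^2 < `low` under both
#' models, `well_both` if R^2 > `high` under both. Mixture-class switches:
#' `switch` if the gene is in the poor tail under the Tissue-Agnostic model
#' and the well tail under the Tissue-Aware model; `strong_switch`
#' additionally requires at least a `fold`-fold R^2 increase
#' (`strong_switch` is a subset of `switch`). Genes matching none are
#' `other`.
#'
#' @param r2_agnostic,r2_aware per-gene R^2 vectors (aligned).
#' @param class_agnostic,class_aware per-gene mixture tail labels
#'   (`"poor"`/`"well"`/`"other"`).
#' @param low,high global thresholds (defaults 0.3, 0.7).
#' @param fold fold-increase factor for `strong_switch` (default 4).
#' @return A data.frame: gene, r2_agnostic, r2_aware, class_agnostic,
#'   class_aware, switch, strong_switch, category.
#' @export
categorize_genes <- function(r2_agnostic, r2_aware, class_agnostic,
                             class_aware, low = 0.3, high = 0.7, fold = 4) {
  G <- length(r2_agnostic)
  stopifnot(length(r2_aware) == G, length(class_agnostic) == G,
            length(class_aware) == G)
  genes <- names(r2_agnostic)
  if (is.null(genes)) genes <- paste0("g", seq_len(G))
  sw <- class_agnostic == "poor" & class_aware == "well"
  strong <- sw & (r2_aware >= fold * r2_agnostic)
  category <- rep("other", G)
  category[r2_agnostic < low & r2_aware < low] <- "poor_both"
  category[r2_agnostic > high & r2_aware > high] <- "well_both"
  category[sw] <- "switch"
  category[strong] <- "strong_switch"
  data.frame(gene = genes, r2_agnostic = as.numeric(r2_agnostic),
             r2_aware = as.numeric(r2_aware),
             class_agnostic = class_agnostic, class_aware = class_aware,
             switch = sw, strong_switch = strong, category = category,
             stringsAsFactors = FALSE)
}

#' Correlation score: fraction of best-inferred genes
#'
#' A gene g is "best inferred" when the Pearson correlation between its
#' prediction and its observed profile, `R_gg = cor(yhat_g, y_g)`, exceeds
#' the `percentile`-th percentile of a null distribution built from
#' randomly mismatched pairs `cor(yhat_g1, y_g2)`, `g1 != g2`. The score is
#' the fraction of best-inferred genes. Genes with zero variance in either
#' matrix are excluded from both the matched set and the null.
#'
#' @param Y observed samples x genes matrix (or `ExpressionMatrix`).
#' @param Y_hat predictions, same shape.
#' @param n_null_pairs null draws (default: one per gene).
#' @param percentile null percentile defining significance (default 95).
#' @param seed integer seed for null-pair sampling.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A list: `score`, `best_inferred` (named logical), `matched`
#'   (R_gg), `null` (null correlations), `threshold`.
#' @export
correlation_score <- function(Y, Y_hat, n_null_pairs = NULL, percentile = 95,
                              seed = 1, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  Ym <- .as_xy(Y); Hm <- .as_xy(Y_hat)
  if (!all(dim(Ym) == dim(Hm))) stop("Y and Y_hat must have the same shape")
  G0 <- ncol(Ym)
  if (G0 < 2) stop("need at least 2 genes")
  ok <- apply(Ym, 2, stats::sd) > 0 & apply(Hm, 2, stats::sd) > 0
  if (!all(ok))
    message(sum(!ok), " zero-variance gene(s) excluded from the score")
  Ym <- Ym[, ok, drop = FALSE]; Hm <- Hm[, ok, drop = FALSE]
  G <- ncol(Ym)
  if (G < 2) stop("fewer than 2 non-degenerate genes")
  if (is.null(n_null_pairs)) n_null_pairs <- G
  if (n_null_pairs < 100)
    warning("n_null_pairs < 100: the null percentile will be unstable")
  if (method == "spearman") {
    Ym <- apply(Ym, 2, rank); Hm <- apply(Hm, 2, rank)
  }
  Ys <- scale(Ym); Hs <- scale(Hm)
  n <- nrow(Ys)
  matched <- colSums(Hs * Ys) / (n - 1)
  set.seed(seed)
  g1 <- sample.int(G, n_null_pairs, replace = TRUE)
  g2 <- sample.int(G - 1, n_null_pairs, replace = TRUE)
  g2 <- ifelse(g2 >= g1, g2 + 1L, g2)    # uniform over ordered pairs g1 != g2
  null <- colSums(Hs[, g1, drop = FALSE] * Ys[, g2, drop = FALSE]) / (n - 1)
  threshold <- stats::quantile(null, percentile / 100, names = FALSE)
  best <- matched > threshold
  names(best) <- colnames(Ym)
  list(score = mean(best), best_inferred = best,
       matched = stats::setNames(matched, colnames(Ym)),
       null = null, threshold = threshold)
}

#' Tissue classification from the regulator panel
#'
#' Stratified k-fold cross-validation of a multi-class support-vector
#' machine (library defaults) on the selected regulators; reports the mean
#' hold-out accuracy and the average confusion matrix in percent (rows =
#' true class, each row summing to 100).
#'
#' @param X `ExpressionMatrix` or samples x features matrix.
#' @param labels per-sample class labels (defaults to `X$tissue`).
#' @param folds number of CV folds (default 10); classes with fewer than
#'   `folds` samples trigger a stratified reduction with a warning.
#' @param seed integer seed for fold assignment.
#' @return A list: `accuracy` (percent), `confusion` (percent matrix),
#'   `fold_accuracy`.
#' @export
classify_tissues <- function(X, labels = NULL, folds = 10, seed = 1) {
  if (is.null(labels) && inherits(X, "ExpressionMatrix")) labels <- X$tissue
  Xm <- .as_xy(X)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 classes")
  min_class <- min(table(labels))
  if (min_class < folds) {
    folds <- max(2, min_class)
    warning("smallest class has ", min_class,
            " samples; reducing to ", folds, "-fold CV")
  }
  set.seed(seed)
  fold_id <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  L <- nlevels(labels)
  conf_sum <- matrix(0, L, L, dimnames = list(levels(labels),
                                              levels(labels)))
  acc <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f; te <- !tr
    fit <- e1071::svm(Xm[tr, , drop = FALSE], labels[tr])
    pred <- stats::predict(fit, Xm[te, , drop = FALSE])
    acc[f] <- mean(pred == labels[te])
    cm <- table(factor(labels[te], levels = levels(labels)),
                factor(pred, levels = levels(labels)))
    row_n <- rowSums(cm)
    pct <- sweep(cm, 1, pmax(row_n, 1), "/") * 100
    conf_sum <- conf_sum + pct
  }
  list(accuracy = 100 * mean(acc), confusion = conf_sum / folds,
       fold_accuracy = 100 * acc)
}
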