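# Seeded generators emulating the regulatory structure the analysis assumes:
# regulators organized into correlated clusters driven by latent factors,
# outcome genes linear in the cluster medoids with tissue-specific terms,
# a fraction of genes unexplained by regulators, and a shifted/renamed
# "target" dataset for transportability experiments.

# Deterministic per-stage sub-seeds so adding genes never perturbs the
# regulator draws (single user-facing seed, independent stage streams).
.stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + stage * 104729) %% 2147483647L)
}

#' Configuration for the synthetic regulome generator
#'
#' @param n_samples number of samples.
#' @param n_tissues number of tissue labels; tissue means of the latent
#'   cluster factors are separated by `tissue_separation`.
#' @param cluster_sizes integer vector, one entry per regulator cluster.
#' @param within_cluster_loading lower bound of the member loadings
#'   lambda_j on the cluster's latent factor, in (0, 1); loadings are drawn
#'   uniformly in `[within_cluster_loading, 0.99]`.
#' @param regulator_noise_sd sd of the member-specific noise.
#' @param n_genes number of outcome genes.
#' @param frac_unexplained fraction of genes generated as pure noise
#'   (no regulator signal), producing the left mode of a bimodal R^2
#'   distribution.
#' @param frac_tissue_switch fraction of genes whose medoid coefficients
#'   differ by tissue (predictable only with tissue information).
#' @param gene_noise_sd sd of the additive gene noise.
#' @param tissue_separation Euclidean norm of each tissue's mean offset in
#'   latent-factor space (0 = no tissue structure in the regulators).
#' @param frac_mirna_clusters fraction of clusters whose members are named
#'   and classed as miRNAs (with -5p/-3p arm suffixes); the rest are TFs.
#' @param seed integer seed controlling every draw.
#' @return A `GeneratorConfig` list.
#' @export
generator_config <- function(n_samples = 500, n_tissues = 3,
                             cluster_sizes = c(20, 20, 20, 20, 20),
                             within_cluster_loading = 0.9,
                             regulator_noise_sd = 0.3,
                             n_genes = 200, frac_unexplained = 0.2,
                             frac_tissue_switch = 0.1, gene_noise_sd = 0.5,
                             tissue_separation = 3, frac_mirna_clusters = 0.5,
                             seed = 1) {
  stopifnot(length(cluster_sizes) >= 1, all(cluster_sizes >= 1),
            within_cluster_loading > 0, within_cluster_loading < 1,
            regulator_noise_sd >= 0, gene_noise_sd >= 0,
            tissue_separation >= 0, n_tissues >= 1)
  if (frac_unexplained < 0 || frac_unexplained > 1 ||
      frac_tissue_switch < 0 || frac_tissue_switch > 1)
    stop("fractions must lie in [0, 1]")
  if (frac_unexplained + frac_tissue_switch > 1)
    stop("frac_unexplained + frac_tissue_switch must not exceed 1")
  structure(list(n_samples = as.integer(n_samples),
                 n_tissues = as.integer(n_tissues),
                 cluster_sizes = as.integer(cluster_sizes),
                 within_cluster_loading = within_cluster_loading,
                 regulator_noise_sd = regulator_noise_sd,
                 n_genes = as.integer(n_genes),
                 frac_unexplained = frac_unexplained,
                 frac_tissue_switch = frac_tissue_switch,
                 gene_noise_sd = gene_noise_sd,
                 tissue_separation = tissue_separation,
                 frac_mirna_clusters = frac_mirna_clusters,
                 seed = as.integer(seed)),
            class = "GeneratorConfig")
}

#' Generate clustered regulator expression with ground truth
#'
#' Each cluster c has a latent per-sample factor `z_c ~ N(m_t, 1)`, where the
#' tissue mean vectors `m_t` are random directions of norm
#' `tissue_separation` in latent space. Member j of cluster c is
#' `lambda_j * z_c + eps`, `lambda_j ~ U[within_cluster_loading, 0.99]`,
#' `eps ~ N(0, regulator_noise_sd^2)`. The ground-truth medoid of a cluster
#' is its largest-loading member.
#'
#' @param config a [generator_config()].
#' @return A list: `matrix` (`ExpressionMatrix` of regulators, with tissue
#'   labels) and `truth` (list with `cluster_assignment`, `true_medoids`,
#'   `latent`, `loadings`).
#' @export
generate_regulators <- function(config) {
  stopifnot(inherits(config, "GeneratorConfig"))
  set.seed(.stage_seed(config$seed, 1L))
  C <- length(config$cluster_sizes)
  n <- config$n_samples
  tissue <- sort(rep_len(seq_len(config$n_tissues), n))
  # tissue mean offsets in latent space: random unit directions scaled
  offsets <- matrix(0, config$n_tissues, C)
  if (config$n_tissues > 1 && config$tissue_separation > 0) {
    for (t in seq_len(config$n_tissues)) {
      u <- stats::rnorm(C)
      offsets[t, ] <- config$tissue_separation * u / sqrt(sum(u^2))
    }
  }
  latent <- matrix(stats::rnorm(n * C), n, C) + offsets[tissue, , drop = FALSE]
  n_mir_clusters <- round(config$frac_mirna_clusters * C)
  mir_clusters <- if (n_mir_clusters > 0) seq_len(C) > (C - n_mir_clusters)
    else rep(FALSE, C)
  cols <- vector("list", C)
  ids <- character(0); cls <- character(0)
  assignment <- integer(0); loadings <- numeric(0); medoids <- character(C)
  for (c in seq_len(C)) {
    m <- config$cluster_sizes[c]
    lam <- stats::runif(m, config$within_cluster_loading, 0.99)
    eps <- matrix(stats::rnorm(n * m, sd = config$regulator_noise_sd), n, m)
    cols[[c]] <- outer(latent[, c], lam) + eps
    id_c <- if (mir_clusters[c]) {
      sprintf("hsa-miR-c%d-%d-%s", c, seq_len(m),
              rep_len(c("5p", "3p"), m))
    } else sprintf("TF_c%d_%d", c, seq_len(m))
    ids <- c(ids, id_c)
    cls <- c(cls, rep(if (mir_clusters[c]) "MIRNA" else "TF", m))
    assignment <- c(assignment, rep(c, m))
    loadings <- c(loadings, lam)
    medoids[c] <- id_c[which.max(lam)]
  }
  vals <- do.call(cbind, cols)
  mat <- expression_matrix(vals, sample_ids = sprintf("S%04d", seq_len(n)),
                           feature_ids = ids, feature_class = cls,
                           tissue = paste0("tissue", tissue), scale = "log2")
  truth <- list(cluster_assignment = stats::setNames(assignment, ids),
                true_medoids = medoids,
                latent = latent,
                loadings = stats::setNames(loadings, ids))
  list(matrix = mat, truth = truth)
}

#' Generate outcome genes from the regulator medoids
#'
#' Genes fall into three categories. "explained": a global linear function of
#' the medoid expressions (a random subset of medoids carries nonzero
#' coefficients) plus a tissue-specific intercept and noise. "tissue_switch":
#' the medoid coefficients themselves differ by tissue, so the gene is only
#' predictable once tissue is modeled. "unexplained": independent Gaussian
#' noise, carrying no regulator signal.
#'
#' @param regulators `ExpressionMatrix` from [generate_regulators()] (must
#'   carry tissue labels).
#' @param truth ground truth from [generate_regulators()].
#' @param config the same [generator_config()].
#' @return A list: `matrix` (`ExpressionMatrix` of genes) and `truth` with
#'   `gene_category`, `global_intercept`, `tissue_intercepts`,
#'   `coefficients` (medoids x genes, global stage), and
#'   `tissue_coefficients` (per-tissue list, combined per-tissue slopes).
#' @export
generate_transcriptome <- function(regulators, truth, config) {
  stopifnot(inherits(regulators, "ExpressionMatrix"))
  if (is.null(regulators$tissue))
    stop("regulators must carry tissue labels")
  set.seed(.stage_seed(config$seed, 2L))
  X <- regulators$values[, truth$true_medoids, drop = FALSE]
  n <- nrow(X); K <- ncol(X); G <- config$n_genes
  tissues <- unique(regulators$tissue)
  Tn <- length(tissues)
  n_unex <- round(config$frac_unexplained * G)
  n_switch <- round(config$frac_tissue_switch * G)
  category <- rep("explained", G)
  if (n_unex > 0) category[seq_len(n_unex)] <- "unexplained"
  if (n_switch > 0) category[n_unex + seq_len(n_switch)] <- "tissue_switch"
  category <- sample(category)   # shuffle so categories interleave
  gene_ids <- sprintf("gene%05d", seq_len(G))
  a0 <- stats::rnorm(G)
  at <- matrix(stats::rnorm(Tn * G), Tn, G,
               dimnames = list(tissues, gene_ids))
  beta <- matrix(0, K, G, dimnames = list(truth$true_medoids, gene_ids))
  beta_t <- lapply(tissues, function(t) beta)
  names(beta_t) <- tissues
  Y <- matrix(stats::rnorm(n * G, sd = config$gene_noise_sd), n, G)
  tid <- match(regulators$tissue, tissues)
  draw_beta <- function() {
    active <- stats::runif(K) < 0.5
    if (!any(active)) active[sample.int(K, 1)] <- TRUE
    b <- numeric(K)
    b[active] <- stats::runif(sum(active), 0.5, 2) *
      sample(c(-1, 1), sum(active), replace = TRUE)
    b
  }
  for (g in seq_len(G)) {
    if (category[g] == "unexplained") {
      Y[, g] <- a0[g] + Y[, g]
      at[, g] <- 0
      next
    }
    if (category[g] == "explained") {
      b <- draw_beta()
      beta[, g] <- b
      for (t in seq_len(Tn)) beta_t[[t]][, g] <- b
      Y[, g] <- Y[, g] + a0[g] + at[tid, g] + drop(X %*% b)
    } else {  # tissue_switch: per-tissue slopes
      for (t in seq_len(Tn)) {
        b <- draw_beta()
        beta_t[[t]][, g] <- b
        rows <- which(tid == t)
        Y[rows, g] <- Y[rows, g] + a0[g] + at[t, g] +
          drop(X[rows, , drop = FALSE] %*% b)
      }
    }
  }
  mat <- expression_matrix(Y, sample_ids = regulators$sample_ids,
                           feature_ids = gene_ids,
                           feature_class = rep("GENE", G),
                           tissue = regulators$tissue, scale = "log2")
  list(matrix = mat,
       truth = list(gene_category = stats::setNames(category, gene_ids),
                    global_intercept = stats::setNames(a0, gene_ids),
                    tissue_intercepts = at,
                    coefficients = beta,
                    tissue_coefficients = beta_t))
}

#' Generate a covariate-shifted "target" dataset from a source matrix
#'
#' Emulates cross-dataset transfer artifacts: selected features undergo an
#' affine shift `x -> a*x + b` (technological/biological covariate shift),
#' some features are dropped (absent from the target platform), and ids can
#' be renamed (e.g. stripping the miRNA mature-arm suffix, as when
#' directional source measurements meet aggregate target counts).
#'
#' @param source an `ExpressionMatrix`.
#' @param shift_spec named list / data.frame mapping feature id to
#'   `c(a, b)` (scale, location), or NULL for none.
#' @param rename_rules named character vector `old_id = new_id`, or NULL.
#' @param drop_list character vector of feature ids to remove.
#' @return The transformed `ExpressionMatrix`.
#' @export
generate_shifted_target <- function(source, shift_spec = NULL,
                                    rename_rules = NULL,
                                    drop_list = character()) {
  stopifnot(inherits(source, "ExpressionMatrix"))
  out <- source
  if (!is.null(shift_spec) && length(shift_spec)) {
    bad <- setdiff(names(shift_spec), source$feature_ids)
    if (length(bad))
      stop("shift features absent from source: ", paste(bad, collapse = ", "))
    for (id in names(shift_spec)) {
      ab <- shift_spec[[id]]
      j <- match(id, out$feature_ids)
      out$values[, j] <- ab[1] * out$values[, j] + ab[2]
    }
  }
  if (length(drop_list)) {
    keep <- which(!(out$feature_ids %in% drop_list))
    out <- em_subset(out, features = keep)
  }
  if (!is.null(rename_rules) && length(rename_rules)) {
    idx <- match(names(rename_rules), out$feature_ids)
    new_ids <- out$feature_ids
    new_ids[idx[!is.na(idx)]] <- rename_rules[!is.na(idx)]
    if (anyDuplicated(new_ids))
      stop("rename collision: duplicate id '",
           new_ids[duplicated(new_ids)][1], "'")
    out$feature_ids <- new_ids
    colnames(out$values) <- new_ids
  }
  out
}
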