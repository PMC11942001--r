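test_that("pseudo-tissue fitting finds blob centers deterministically", {
  set.seed(1)
  X <- rbind(matrix(rnorm(50 * 3, 0), 50, 3),
             matrix(rnorm(50 * 3, 8), 50, 3))
  colnames(X) <- paste0("f", 1:3)
  m <- fit_pseudo_tissues(X, K = 2, seed = 4)
  ctr <- m$centroids[order(m$centroids[, 1]), ]
  expect_equal(unname(ctr[1, ]), rep(0, 3), tolerance = 0.5)
  expect_equal(unname(ctr[2, ]), rep(8, 3), tolerance = 0.5)
  m2 <- fit_pseudo_tissues(X, K = 2, seed = 4)
  expect_identical(m$centroids, m2$centroids)
  # K = 1 closed form
  m1 <- fit_pseudo_tissues(X, K = 1, seed = 1)
  expect_equal(unname(m1$centroids[1, ]), unname(colMeans(X)),
               tolerance = 1e-12)
  expect_error(fit_pseudo_tissues(X, K = 0), "K must")
  dup <- X[rep(1, 10), ]
  expect_error(fit_pseudo_tissues(dup, K = 3), "distinct")
})

test_that("nearest-centroid assignment handles ties and translation", {
  map <- structure(list(K = 3L,
                        centroids = rbind(c(0, 0), c(4, 0), c(2, 0)),
                        feature_ids = c("a", "b"),
                        assignment = integer(0),
                        training_inertia = 0),
                   class = "PseudoTissueMap")
  expect_equal(assign_pseudo_tissue(c(4, 0), map), 2)
  expect_equal(assign_pseudo_tissue(c(1, 0), map), 1)   # tie 1 vs 3 -> 1
  # translation invariance
  sh <- map; sh$centroids <- sh$centroids + 5
  expect_equal(assign_pseudo_tissue(c(1, 0) + 5, sh), 1)
  expect_error(assign_pseudo_tissue(c(1, 2, 3), map), "mismatch")
  # named matrix input aligns by feature id
  X <- matrix(c(0, 0.1, 0, 4.2), 2, 2, dimnames = list(NULL, c("b", "a")))
  expect_equal(assign_pseudo_tissue(X, map), c(1, 2))
})

test_that("pseudo-tissue count tuning recovers the tissue count", {
  cfg <- generator_config(n_samples = 240, n_tissues = 6,
                          cluster_sizes = rep(12, 4), n_genes = 80,
                          frac_unexplained = 0.1, frac_tissue_switch = 0.3,
                          gene_noise_sd = 0.4, tissue_separation = 6,
                          seed = 17)
  rg <- generate_regulators(cfg)
  gn <- generate_transcriptome(rg$matrix, rg$truth, cfg)
  X <- em_subset(rg$matrix, features = rg$truth$true_medoids)
  tuned <- tune_num_pseudo_tissues(X, gn$matrix, K_range = 2:9, folds = 5,
                                   seed = 17)
  expect_true(tuned$K_best %in% 5:7)
  expect_true(all(tuned$rmse >= 0, na.rm = TRUE))
  expect_equal(names(which.min(tuned$rmse)), paste0("K", tuned$K_best))
})

test_that("K = 1 pseudo-tissue CV equals the tissue-agnostic CV error", {
  set.seed(2)
  X <- matrix(rnorm(100 * 4), 100, 4, dimnames = list(NULL, paste0("x", 1:4)))
  Y <- matrix(rnorm(100 * 20), 100, 20, dimnames = list(NULL, paste0("g", 1:20)))
  tuned <- tune_num_pseudo_tissues(X, Y, K_range = 1, folds = 5, seed = 9)
  # manual agnostic CV with the same fold assignment
  set.seed(9)
  fold_id <- sample(rep_len(1:5, 100))
  sse <- 0
  for (f in 1:5) {
    tr <- fold_id != f
    fit <- fit_tissue_agnostic(X[tr, ], Y[tr, ])
    sse <- sse + sum((Y[!tr, ] - predict(fit, X[!tr, ]))^2)
  }
  expect_equal(unname(tuned$rmse[["K1"]]), sqrt(sse / (100 * 20)),
               tolerance = 1e-9)
})

test_that("feature matching applies exact > base-name > substitute priority", {
  # base-name dialect: directional source vs aggregate target
  fm <- match_features(c("hsa-miR-21a-5p", "TFX"),
                       c("hsa-miR-21a", "TFX"))
  expect_equal(fm$pairs$match_type[fm$pairs$source_id == "hsa-miR-21a-5p"],
               "base_name")
  expect_equal(fm$pairs$match_type[fm$pairs$source_id == "TFX"], "exact")
  # substitution walks the cluster's ranked members
  model <- structure(list(
    clusters = c("hsa-miR-664a-3p" = 1L, "hsa-miR-29c" = 1L,
                 "hsa-miR-1-5p" = 1L),
    ranked_members = list(c("hsa-miR-664a-3p", "hsa-miR-29c",
                            "hsa-miR-1-5p"))), class = "ComponentModel")
  fm2 <- match_features("hsa-miR-664a-3p",
                        c("hsa-miR-29c", "unrelated"), model = model)
  expect_equal(fm2$pairs$target_id, "hsa-miR-29c")
  expect_equal(fm2$pairs$match_type, "substitute")
  # unmatched when nothing applies
  fm3 <- match_features("hsa-miR-999-5p", "other")
  expect_equal(fm3$unmatched, "hsa-miR-999-5p")
  expect_equal(nrow(fm3$pairs), 0)
  # collision resolves to the higher-priority match with a warning
  expect_warning(
    fm4 <- match_features(c("mirA", "mirA-5p"), "mirA"),
    "collision")
  expect_equal(fm4$pairs$source_id, "mirA")
  expect_equal(fm4$pairs$match_type, "exact")
  expect_true("mirA-5p" %in% fm4$unmatched)
})

test_that("wasserstein_1d matches the transport LP and metric axioms", {
  skip_if_not_installed("boot")
  expect_equal(wasserstein_1d(c(0, 1), c(1, 2)), 1)
  expect_equal(wasserstein_1d(c(1, 5), c(1, 5)), 0)
  set.seed(3)
  a10 <- rnorm(10)
  expect_equal(wasserstein_1d(a10, a10 + 2.5), 2.5, tolerance = 1e-12)
  expect_equal(lp_wasserstein(a10, a10 + 2.5), 2.5, tolerance = 1e-9)
  # LP agreement on random unequal-size instances
  set.seed(4)
  for (i in 1:40) {
    a <- rnorm(sample(2:10, 1), sd = 2)
    b <- rnorm(sample(2:10, 1), mean = 1, sd = 3)
    expect_equal(wasserstein_1d(a, b), lp_wasserstein(a, b),
                 tolerance = 1e-9)
  }
  # symmetry and triangle inequality on random triples
  set.seed(5)
  for (i in 1:30) {
    a <- rnorm(6); b <- rnorm(6, 1); c <- rnorm(6, -1, 2)
    expect_equal(wasserstein_1d(a, b), wasserstein_1d(b, a),
                 tolerance = 1e-12)
    expect_lte(wasserstein_1d(a, c),
               wasserstein_1d(a, b) + wasserstein_1d(b, c) + 1e-12)
  }
  expect_error(wasserstein_1d(numeric(0), 1), "empty")
})

test_that("shift report separates shifted miRNAs from stable TFs", {
  cfg <- small_config(seed = 71)
  src <- generate_regulators(cfg)$matrix
  mir <- src$feature_ids[src$feature_class == "MIRNA"]
  tf <- src$feature_ids[src$feature_class == "TF"]
  shift <- setNames(rep(list(c(1, 2)), length(mir)), mir)
  tgt <- generate_shifted_target(src, shift_spec = shift)
  fm <- match_features(src$feature_ids, tgt$feature_ids)
  rep <- shift_report(src, tgt, fm, seed = 1)
  mir_d <- rep$distance[rep$source_id %in% mir]
  tf_d <- rep$distance[rep$source_id %in% tf]
  expect_true(all(mir_d >= 2 - 1e-9))
  expect_true(all(tf_d < 1e-9))
  expect_true(all(rep$distance >= 0))
  # identity mapping on an identical target: distances all zero
  fm_id <- match_features(src$feature_ids, src$feature_ids)
  rep0 <- shift_report(src, src, fm_id, seed = 1)
  expect_true(all(rep0$distance < 1e-12))
  expect_true(all(rep0$percentile <= 100))
  # two features -> exactly 2 mismatched ordered pairs in the null
  two <- em_subset(src, features = src$feature_ids[1:2])
  fm2 <- match_features(two$feature_ids, two$feature_ids)
  rep2 <- shift_report(two, two, fm2, seed = 1)
  expect_equal(length(attr(rep2, "null")), 2)
})

test_that("transport on a clean clone beats the miRNA-shifted target", {
  cfg <- generator_config(n_samples = 300, n_tissues = 4,
                          cluster_sizes = rep(12, 4), n_genes = 120,
                          frac_unexplained = 0.15, frac_tissue_switch = 0.3,
                          gene_noise_sd = 0.5, tissue_separation = 4,
                          seed = 23)
  rg <- generate_regulators(cfg)
  gn <- generate_transcriptome(rg$matrix, rg$truth, cfg)
  X <- em_subset(rg$matrix, features = rg$truth$true_medoids)
  map <- fit_pseudo_tissues(X, K = 5, seed = 23)
  fit <- fit_tissue_aware(X, gn$matrix, paste0("PT", map$assignment))
  score <- function(tgt) {
    lab <- paste0("PT", assign_pseudo_tissue(tgt, map))
    lab[!(lab %in% fit$tissues)] <- fit$tissues[1]
    correlation_score(gn$matrix, predict(fit, tgt, tissue = lab),
                      seed = 23)$score
  }
  mir <- X$feature_ids[X$feature_class == "MIRNA"]
  set.seed(123)
  shift <- setNames(lapply(mir, function(i)
    c(1, sample(c(-1, 1), 1) * runif(1, 3, 6))), mir)
  expect_gt(score(X), score(generate_shifted_target(X, shift_spec = shift)))
})
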