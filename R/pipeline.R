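# End-to-end orchestration of the synthetic analysis: simulate ->
# preprocess -> components -> fit -> evaluate -> transport, driven by a
# plain list (or YAML) configuration, with every stage output written as
# TSV/JSON and a manifest of seeds and content hashes.

.default_run_config <- function() {
  list(seed = 1,
       out_dir = "regulome56-run",
       stages = c("simulate", "components", "fit", "evaluate", "transport"),
       generator = list(),                 # overrides for generator_config()
       threshold = 0.35, K_max = 10, n_restarts = 20,
       beta_k_range = 1:4,
       low = 0.3, high = 0.7, fold = 4, percentile = 95,
       pseudo_K_range = 2:10, cv_folds = 5,
       mirna_shift = 2)
}

#' Run the full synthetic analysis pipeline
#'
#' Stages in dependency order: `simulate` (regulators + transcriptome +
#' shifted target), `components` (loading representation, outlier filter,
#' vMF clustering, medoids), `fit` (Tissue-Agnostic and Tissue-Aware models
#' on the medoid panel), `evaluate` (per-gene R^2, beta-mixture tails, gene
#' categories, correlation score), `transport` (feature matching, shift
#' report, pseudo-tissue prediction of the shifted target). All outputs are
#' plain TSV/JSON under `config$out_dir`, listed in `manifest.json` with
#' md5 content hashes; a rerun with the same config reproduces them.
#'
#' @param config list of options (see `.default_run_config` in the source)
#'   or the path to a YAML file of the same shape; omitted keys take
#'   defaults.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(.default_run_config(), config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  emit <- function(name, writer) {
    path <- file.path(cfg$out_dir, name)
    writer(path)
    outputs <<- c(outputs, path)
    path
  }
  res <- list()

  if (!("simulate" %in% cfg$stages))
    stop("stage 'simulate' is required: run the fit stage first")
  gen_cfg <- do.call(generator_config,
                     utils::modifyList(list(seed = cfg$seed), cfg$generator))
  regs <- generate_regulators(gen_cfg)
  genes <- generate_transcriptome(regs$matrix, regs$truth, gen_cfg)
  res$generator <- gen_cfg
  res$regulators <- regs
  res$genes <- genes
  emit("regulators.tsv", function(p) write_matrix(regs$matrix, p))
  emit("genes.tsv", function(p) write_matrix(genes$matrix, p))
  emit("tissues.tsv", function(p)
    utils::write.table(data.frame(sample_id = regs$matrix$sample_ids,
                                  tissue = regs$matrix$tissue),
                       p, sep = "\t", quote = FALSE, row.names = FALSE))
  emit("ground_truth_clusters.tsv", function(p)
    utils::write.table(data.frame(feature_id = names(regs$truth$cluster_assignment),
                                  cluster = regs$truth$cluster_assignment,
                                  loading = regs$truth$loadings),
                       p, sep = "\t", quote = FALSE, row.names = FALSE))

  if ("components" %in% cfg$stages) {
    model <- discover_components(regs$matrix, threshold = cfg$threshold,
                                 K_max = cfg$K_max,
                                 n_restarts = cfg$n_restarts,
                                 seed = cfg$seed)
    res$components <- model
    emit("components.json", function(p) write_component_model(model, p))
  }

  if ("fit" %in% cfg$stages) {
    if (is.null(res$components)) stop("run the components stage first")
    medoids <- res$components$medoids
    Xsel <- em_subset(regs$matrix, features = medoids)
    agnostic <- fit_tissue_agnostic(Xsel, genes$matrix)
    aware <- fit_tissue_aware(Xsel, genes$matrix)
    res$fit <- list(agnostic = agnostic, aware = aware, X = Xsel)
    r2a <- r_squared(genes$matrix, predict(agnostic, Xsel))
    r2w <- r_squared(genes$matrix, predict(aware, Xsel))
    res$r2 <- list(agnostic = r2a, aware = r2w)
    emit("r2.tsv", function(p)
      utils::write.table(data.frame(gene = names(r2a),
                                    r2_agnostic = as.numeric(r2a),
                                    r2_aware = as.numeric(r2w)),
                         p, sep = "\t", quote = FALSE, row.names = FALSE))
  }

  if ("evaluate" %in% cfg$stages) {
    if (is.null(res$fit)) stop("run the fit stage first")
    fa <- fit_beta_mixture(res$r2$agnostic, k_range = cfg$beta_k_range,
                           seed = cfg$seed)
    fw <- fit_beta_mixture(res$r2$aware, k_range = cfg$beta_k_range,
                           seed = cfg$seed)
    cat_df <- categorize_genes(res$r2$agnostic, res$r2$aware,
                               label_tail_components(fa),
                               label_tail_components(fw),
                               low = cfg$low, high = cfg$high,
                               fold = cfg$fold)
    sc <- correlation_score(genes$matrix,
                            predict(res$fit$aware, res$fit$X),
                            percentile = cfg$percentile, seed = cfg$seed)
    res$evaluate <- list(beta_agnostic = fa, beta_aware = fw,
                         categories = cat_df, cor_score = sc)
    emit("gene_categories.tsv", function(p)
      utils::write.table(cat_df, p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
    emit("evaluation.json", function(p)
      jsonlite::write_json(
        list(beta_k = c(agnostic = fa$k, aware = fw$k),
             mean_r2 = c(agnostic = mean(res$r2$agnostic),
                         aware = mean(res$r2$aware)),
             correlation_score = sc$score,
             category_counts = as.list(table(cat_df$category))),
        p, auto_unbox = TRUE, digits = NA))
  }

  if ("transport" %in% cfg$stages) {
    if (is.null(res$fit)) stop("run the fit stage first")
    Xsel <- res$fit$X
    mir <- Xsel$feature_ids[Xsel$feature_class == "MIRNA"]
    shift <- stats::setNames(rep(list(c(1, cfg$mirna_shift)), length(mir)),
                             mir)
    target <- generate_shifted_target(
      regs$matrix, shift_spec = shift,
      rename_rules = stats::setNames(.strip_arm(mir), mir))
    mapping <- match_features(Xsel$feature_ids, target$feature_ids,
                              model = res$components)
    rep_df <- shift_report(regs$matrix, target, mapping, seed = cfg$seed)
    map <- fit_pseudo_tissues(Xsel, K = min(cfg$K_max, nrow(Xsel$values)),
                              seed = cfg$seed)
    res$transport <- list(target = target, mapping = mapping,
                          shift = rep_df, pseudo = map)
    emit("feature_mapping.tsv", function(p)
      utils::write.table(mapping$pairs, p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
    emit("shift_report.tsv", function(p)
      utils::write.table(as.data.frame(rep_df), p, sep = "\t",
                         quote = FALSE, row.names = FALSE))
  }

  manifest <- list(
    config = cfg[setdiff(names(cfg), "stages")],
    stages = cfg$stages,
    seed = cfg$seed,
    outputs = lapply(outputs, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}
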