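# End-to-end orchestration: networks -> attribute features -> clustering
# features -> negatives -> training -> evaluation/prediction, under one
# configuration object and one master seed.

#' Pipeline configuration with published defaults
#'
#' Collects every tunable parameter. Defaults: attribute embedding dimensions
#' 300 (drugs) and 100 (diseases); clustering feature dimension k = 200 with
#' control parameters alpha = 0.2, beta = 0.1; tower layer dimensions
#' {128, 64} / {64, 32} for attribute channels and {128, 32} for clustering
#' channels; head {64, 32, 2}; 30 epochs at learning rate 0.001, batch size
#' 128, dropout 0.5, L2 strength 0.01, 5 sampled neighbors, mean aggregator;
#' 5-fold cross-validation with 5 repeats.
#'
#' @param ... Named overrides of any default.
#' @return A named list of class `drgcc_config`.
#' @export
drgcc_config <- function(...) {
  cfg <- list(
    d_drug = 300L, d_dis = 100L,
    k = 200L, alpha = 0.2, beta = 0.1,
    cmf_max_iter = 1000L, cmf_tol = 1e-6,
    epochs = 30L, lr = 0.001, batch_size = 128L, lambda = 0.01,
    dropout = 0.5, n_k = 5L, aggregator = "mean",
    head_dims = c(64L, 32L, 2L),
    folds = 5L, repeats = 5L,
    symptom_weighting = "tfidf",
    disease_sim_denominator = "product",
    mcode = list(edge_threshold = 0.2, degree_cutoff = 2,
                 node_score_cutoff = 0.2, k_core = 2, haircut = TRUE),
    walk = list(restart = 0.3, left_steps = 2, right_steps = 2)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) {
    abort(sprintf("unknown configuration keys: %s", paste(bad, collapse = ", ")))
  }
  for (nm in names(over)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]])) utils::modifyList(cfg[[nm]], over[[nm]]) else over[[nm]]
    message(sprintf("config override: %s", nm))
  }
  structure(cfg, class = c("drgcc_config", "list"))
}

#' Prepare all model inputs from a raw data bundle
#'
#' Executes the data-processing stages: reconstructs the two networks from
#' gene evidence, embeds fingerprints and symptom profiles into attribute
#' feature matrices (embedding dimensions are capped at what the table shape
#' supports), partitions both networks into clusters, scores unknown pairs by
#' the bi-random walk, and assembles the labeled pair set with as many
#' reliable negatives as there are positives.
#'
#' @param bundle A list with `Y`, `ddi`, `semantic`, `drug_gene`, `dis_gene`,
#'   `fingerprints`, `symptoms` (e.g. from [generate_fixture()] or
#'   [read_fixture()]).
#' @param config A [drgcc_config()].
#' @param seed Master seed for the stochastic stages.
#' @param cluster_assignments Optional list with `drug` and/or `disease`
#'   assignments (tibbles of `entity_id`, `cluster`) supplied in place of
#'   [cluster_network()].
#' @return A list of class `drgcc_inputs` with networks, feature matrices,
#'   cluster assignments, walk scores and the labeled `pairs` tibble.
#' @export
prepare_inputs <- function(bundle, config = drgcc_config(), seed = 1,
                           cluster_assignments = NULL) {
  drug_net <- reconstruct_ddi(bundle$ddi, bundle$drug_gene)
  dis_net <- reconstruct_disease_similarity(
    bundle$semantic, bundle$dis_gene,
    denominator = config$disease_sim_denominator
  )
  d_drug <- min(config$d_drug, dim(bundle$fingerprints))
  d_dis <- min(config$d_dis, dim(bundle$symptoms))
  if (d_drug < config$d_drug || d_dis < config$d_dis) {
    message(sprintf(
      "attribute dimensions capped at table shape: d_drug = %d, d_dis = %d",
      d_drug, d_dis
    ))
  }
  f_drug <- attribute_features(bundle$fingerprints, d_drug,
                               weighting = "tfidf")
  f_dis <- attribute_features(bundle$symptoms, d_dis,
                              weighting = config$symptom_weighting)
  mc <- config$mcode
  assign_drug <- cluster_assignments$drug %||% cluster_network(
    drug_net, edge_threshold = mc$edge_threshold,
    degree_cutoff = mc$degree_cutoff,
    node_score_cutoff = mc$node_score_cutoff,
    k_core = mc$k_core, haircut = mc$haircut
  )
  assign_dis <- cluster_assignments$disease %||% cluster_network(
    dis_net, edge_threshold = mc$edge_threshold,
    degree_cutoff = mc$degree_cutoff,
    node_score_cutoff = mc$node_score_cutoff,
    k_core = mc$k_core, haircut = mc$haircut
  )
  assign_drug <- as_cluster_assignment(assign_drug, rownames(drug_net))
  assign_dis <- as_cluster_assignment(assign_dis, rownames(dis_net))
  walk_scores <- birw_scores(bundle$Y, drug_net, dis_net,
                             left_steps = config$walk$left_steps,
                             right_steps = config$walk$right_steps,
                             restart = config$walk$restart)
  negatives <- select_negatives(walk_scores, bundle$Y,
                                seed = derive_seed(seed, "negatives"))
  pairs <- labeled_pairs(bundle$Y, negatives)
  structure(
    list(Y = bundle$Y, drug_net = drug_net, dis_net = dis_net,
         F_drug = f_drug, F_dis = f_dis,
         assign_drug = assign_drug, assign_dis = assign_dis,
         walk_scores = walk_scores, negatives = negatives, pairs = pairs),
    class = "drgcc_inputs"
  )
}

#' Run the full pipeline on a data bundle
#'
#' Prepares the inputs, optionally cross-validates, then fits the final model
#' on all labeled pairs and scores every drug-disease pair. A manifest with
#' the configuration hash and derived seeds makes reruns comparable.
#'
#' @param bundle Raw data bundle (see [prepare_inputs()]).
#' @param config A [drgcc_config()].
#' @param seed Master seed.
#' @param mode Feature mode (`"both"`, `"attribute"`, `"cluster"`).
#' @param evaluate Run cross-validation (`folds`/`repeats` from `config`)
#'   before the final fit.
#' @return List with `inputs`, `model`, `predictions` (all pairs, ranked),
#'   optional `eval`, and `manifest`.
#' @export
run_pipeline <- function(bundle, config = drgcc_config(), seed = 1,
                         mode = "both", evaluate = FALSE) {
  inputs <- prepare_inputs(bundle, config, seed = seed)
  ev <- NULL
  if (evaluate) {
    ev <- evaluate_cv(inputs, config, folds = config$folds,
                      repeats = config$repeats, seed = seed, mode = mode)
  }
  model <- fit_fold_model(inputs, config, inputs$pairs, mode,
                          seed = derive_seed(seed, "final"))
  preds <- predict(model)
  known <- tibble::tibble(
    drug_id = inputs$pairs$drug_id[inputs$pairs$label == 1],
    disease_id = inputs$pairs$disease_id[inputs$pairs$label == 1],
    known = TRUE
  )
  preds <- dplyr::arrange(
    dplyr::mutate(
      dplyr::left_join(preds, known, by = c("drug_id", "disease_id")),
      known = !is.na(.data$known)
    ),
    dplyr::desc(.data$probability)
  )
  manifest <- list(
    config_hash = rlang::hash(list(unclass(config), seed, mode)),
    seed = seed, mode = mode,
    n_drugs = length(model$drug_ids), n_diseases = length(model$dis_ids),
    n_positives = sum(inputs$pairs$label == 1),
    n_negatives = sum(inputs$pairs$label == 0)
  )
  list(inputs = inputs, model = model, predictions = preds, eval = ev,
       manifest = manifest)
}
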