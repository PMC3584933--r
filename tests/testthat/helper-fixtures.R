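# Small hand-built DAGs and random-world helpers shared across test files.

chain_dag <- function() {
  # root <- A <- B
  go_dag(parents = list("GO:0000001" = character(),
                        "GO:0000002" = "GO:0000001",
                        "GO:0000003" = "GO:0000002"),
         namespace = stats::setNames(rep("biological_process", 3),
                                     sprintf("GO:%07d", 1:3)))
}

diamond_dag <- function() {
  # root <- A, root <- B, A <- C, B <- C
  go_dag(parents = list("GO:0000001" = character(),
                        "GO:0000002" = "GO:0000001",
                        "GO:0000003" = "GO:0000001",
                        "GO:0000004" = c("GO:0000002", "GO:0000003")),
         namespace = stats::setNames(rep("biological_process", 4),
                                     sprintf("GO:%07d", 1:4)))
}

# random predictions + truth over a toy DAG, with deliberately discretized
# confidences so tie groups occur
random_eval_world <- function(seed, n_terms = 30, n_targets = 4) {
  dag <- make_toy_dag(n_terms, branching = 2, seed = seed)
  set.seed(seed + 10000L)
  targets <- sprintf("T%02d", seq_len(n_targets))
  preds <- list()
  truth <- list()
  conf_levels <- seq(0.05, 1, by = 0.05)
  for (tg in targets) {
    np <- sample(0:8, 1)
    if (np > 0) {
      terms <- sample(dag$terms, np)
      preds[[length(preds) + 1L]] <- prediction_frame(
        tg, terms, sample(conf_levels, np, replace = TRUE), 0L)
    }
    truth[[tg]] <- sample(dag$terms, sample(1:4, 1))
  }
  predictions <- if (length(preds) > 0) do.call(rbind, preds)
                 else empty_predictions()
  predictions <- do.call(rbind, lapply(
    split(predictions, predictions$target), finalize))
  list(dag = dag, predictions = predictions, truth = annotation_map(truth),
       targets = targets)
}

# random undirected graph as a domain_assignments object (each "protein"
# contributes one clique of 2-3 domains)
random_graph_world <- function(seed, n_nodes = 40, n_proteins = 30) {
  set.seed(seed)
  doms <- sprintf("PF%03d", seq_len(n_nodes))
  prots <- lapply(seq_len(n_proteins), function(i)
    sample(doms, sample(1:3, 1)))
  names(prots) <- sprintf("P%03d", seq_len(n_proteins))
  domain_assignments("spX", prots)
}
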