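# Shared synthetic fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

# A mid-size cohort with clear planted signal, reused by several files.
std_cohort <- function() {
  if (is.null(fixture_env$std)) {
    cfg <- synthetic_config(
      n_genes = 600, n_regions = 5,
      subjects_per_group = c(CON = 20, MCI = 20, AD = 20),
      deg_per_region = 40, shared_fraction = 0.5,
      effect_size_log2fc = 1, seed = 7
    )
    fixture_env$std <- generate_cohort(cfg)
  }
  fixture_env$std
}

std_degs <- function() {
  if (is.null(fixture_env$degs)) {
    fixture_env$degs <- degs_per_region(std_cohort()$expr, std_cohort()$samples)
  }
  fixture_env$degs
}

# A small trained model on the shared cohort (masked features, DEG-BRIN).
std_fit <- function() {
  if (is.null(fixture_env$fit)) {
    co <- std_cohort()
    degs <- std_degs()
    brin <- build_degbrin(degs)
    fixture_env$fit <- degbrin_gcn(
      co$expr, co$samples, brin, degs$universal,
      feature_mode = "masked", region_sets = degs$region_sets,
      hidden_dim = 8, dropout = 0.2, max_epochs = 15, patience = 5, seed = 2
    )
  }
  fixture_env$fit
}

# Tiny hand-checkable graphs.
path_graph_abc <- function() {
  W <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  W["a", "b"] <- W["b", "a"] <- 1
  W["b", "c"] <- W["c", "b"] <- 1
  weighted_graph(W)
}

star_graph_k13 <- function() {
  nodes <- c("center", "l1", "l2", "l3")
  W <- matrix(0, 4, 4, dimnames = list(nodes, nodes))
  W["center", c("l1", "l2", "l3")] <- 1
  W[c("l1", "l2", "l3"), "center"] <- 1
  weighted_graph(W)
}

# Minimal trained-model ingredients for the GCN tests.
tiny_gcn <- function(feature_mode = "broadcast", seed = 2) {
  n_nodes <- if (feature_mode == "nodal") 4L else 3L
  in_dim <- if (feature_mode == "nodal") 1L else 5L
  config <- gcn_config(n_nodes = n_nodes, in_dim = in_dim, hidden_dim = 4,
                       dropout = 0, feature_mode = feature_mode, seed = seed)
  params <- init_params(config)
  W <- matrix(0, n_nodes, n_nodes)
  W[1, 2] <- W[2, 1] <- 2
  if (n_nodes > 2) W[2, 3] <- W[3, 2] <- 1
  diag(W) <- seq_len(n_nodes)
  list(config = config, params = params,
       a_hat = normalize_adjacency(W))
}
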