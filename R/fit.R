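#' Fit the DEG-BRIN graph convolutional classifier
#'
#' High-level fitting interface: given a preprocessed expression matrix, the
#' sample table and a brain-region interaction graph, builds standardized
#' per-sample node features over the universal DEG list, splits the samples
#' into stratified train/validation/test partitions, rebalances the training
#' classes by random over-sampling, trains the two-layer GCN with early
#' stopping and evaluates it on the held-out test set.
#'
#' @param expr Numeric matrix, genes x samples (log2 scale).
#' @param samples data.frame with sample_id, group (and region, used for the
#'   masked feature mode).
#' @param graph A [weighted_graph()] whose nodes index the convolution; for
#'   the region model this is the DEG-BRIN (or a matched random graph), for
#'   the PPI variant a gene-level graph with self-loops.
#' @param genes Character vector of input genes (the universal list G). In
#'   nodal mode these must equal the graph nodes.
#' @param feature_mode Passed to [gcn_config()].
#' @param region_sets Named list of per-region gene sets; required for the
#'   masked mode.
#' @param hidden_dim,dropout,lr,weight_decay,max_epochs,patience,batch_size
#'   Training hyperparameters (defaults are the tuned configuration).
#' @param fractions Split fractions (train, val, test).
#' @param seed Integer seed controlling split, over-sampling, initialisation
#'   and shuffling.
#' @return Object of class \code{degbrin_gcn} with the trained parameters,
#'   training record, split assignment, test metrics and everything needed
#'   by [predict.degbrin_gcn()].
#' @export
degbrin_gcn <- function(expr, samples, graph, genes,
                        feature_mode = c("broadcast", "masked", "nodal"),
                        region_sets = NULL,
                        hidden_dim = 103, dropout = 0.458,
                        lr = 0.00703, weight_decay = 1.06e-5,
                        max_epochs = 200, patience = 20, batch_size = 32,
                        fractions = c(0.7, 0.1, 0.2), seed = 1L) {
  feature_mode <- match.arg(feature_mode)
  stopifnot(inherits(graph, "weighted_graph"))
  if (feature_mode == "nodal" && !identical(genes, graph$nodes)) {
    stop("nodal mode requires genes identical to the graph nodes",
         call. = FALSE)
  }
  missing_genes <- setdiff(genes, rownames(expr))
  if (length(missing_genes) > 0) {
    stop("genes absent from expression matrix: ",
         paste(utils::head(missing_genes, 3), collapse = ", "), call. = FALSE)
  }
  split <- stratified_split(samples, fractions,
                            seed = derive_seed(seed, "split"))
  part <- split$partition[match(samples$sample_id, split$sample_id)]
  train_meta <- samples[part == "train", , drop = FALSE]
  ros_ids <- random_oversample(
    train_meta$sample_id,
    train_meta$group,
    seed = derive_seed(seed, "ros")
  )
  train_meta <- train_meta[match(ros_ids, train_meta$sample_id), , drop = FALSE]

  tr <- build_items(expr, train_meta, genes)
  va <- build_items(expr, samples[part == "val", , drop = FALSE], genes,
                    scaling = tr$scaling)
  te <- build_items(expr, samples[part == "test", , drop = FALSE], genes,
                    scaling = tr$scaling)

  mask <- NULL
  in_dim <- length(genes)
  if (feature_mode == "masked") {
    if (is.null(region_sets)) {
      stop("feature_mode 'masked' requires region_sets", call. = FALSE)
    }
    mask <- region_mask(region_sets, genes, graph$nodes)
  }
  if (feature_mode == "nodal") in_dim <- 1L
  config <- gcn_config(
    n_nodes = length(graph$nodes), in_dim = in_dim,
    hidden_dim = hidden_dim, dropout = dropout,
    feature_mode = feature_mode, seed = derive_seed(seed, "init")
  )
  a_hat <- normalize_adjacency(graph)
  trained <- gcn_train(
    config, a_hat, tr$items, va$items, mask = mask,
    lr = lr, weight_decay = weight_decay, max_epochs = max_epochs,
    patience = patience, batch_size = batch_size,
    seed = derive_seed(seed, "train")
  )
  test_metrics <- gcn_evaluate(trained$params, a_hat, te$items, mask = mask)
  structure(
    list(
      params = trained$params, config = config, a_hat = a_hat,
      graph = graph, genes = genes, mask = mask,
      scaling = tr$scaling, split = split,
      record = trained$record, grad_samples = trained$grad_samples,
      train_items_cache = tr$items,
      best_epoch = trained$best_epoch,
      test_metrics = test_metrics,
      feature_mode = feature_mode, seed = seed,
      call = match.call()
    ),
    class = "degbrin_gcn"
  )
}

#' @export
print.degbrin_gcn <- function(x, ...) {
  cat("Interpretable two-layer GCN classifier (", x$feature_mode,
      " features)\n", sep = "")
  cat("  graph: ", length(x$graph$nodes), " nodes, ",
      nrow(x$graph$edges), " edges\n", sep = "")
  cat("  input genes: ", length(x$genes),
      ", hidden: ", x$config$hidden_dim, "\n", sep = "")
  cat("  best epoch: ", x$best_epoch,
      " (val loss ", signif(min(x$record$val_loss), 4), ")\n", sep = "")
  cat("  test accuracy: ", signif(x$test_metrics$accuracy, 4), "\n", sep = "")
  invisible(x)
}

#' @export
summary.degbrin_gcn <- function(object, ...) {
  cat("Call:\n  ")
  print(object$call)
  print(object)
  cat("\nPer-class test metrics:\n")
  print(object$test_metrics$per_class, row.names = FALSE, digits = 3)
  cat("\nTop 5 region importances (softplus gate):\n")
  imp <- importance_report(object)
  print(utils::head(imp$regions, 5), row.names = FALSE, digits = 3)
  invisible(object)
}

#' Importance gate values of a fitted model
#'
#' @param object A \code{degbrin_gcn} fit.
#' @param ... Unused.
#' @return Named list with \code{gene_gate} and \code{region_gate} softplus
#'   activations (the learned importances).
#' @export
coef.degbrin_gcn <- function(object, ...) {
  list(
    gene_gate = stats::setNames(softplus(object$params$gene_gate),
                                if (object$feature_mode == "nodal") "shared"
                                else object$genes),
    region_gate = stats::setNames(softplus(object$params$region_gate),
                                  object$graph$nodes)
  )
}

#' Predict diagnostic classes for new samples
#'
#' @param object A \code{degbrin_gcn} fit.
#' @param expr Expression matrix containing the model's genes.
#' @param samples data.frame with sample_id (group optional).
#' @param type \code{"class"} or \code{"prob"}.
#' @param ... Unused.
#' @return Character vector of classes, or a samples x classes probability
#'   matrix.
#' @export
predict.degbrin_gcn <- function(object, expr, samples, type = c("class", "prob"),
                                ...) {
  type <- match.arg(type)
  if (!"group" %in% names(samples)) samples$group <- GROUP_LEVELS[1]
  built <- build_items(expr, samples, object$genes, scaling = object$scaling)
  probs <- t(vapply(built$items, function(it) {
    gcn_forward(object$params, object$a_hat, it$x, mask = object$mask,
                training = FALSE)$probs
  }, numeric(object$config$n_classes)))
  dimnames(probs) <- list(samples$sample_id, GROUP_LEVELS)
  if (type == "prob") probs
  else GROUP_LEVELS[max.col(probs, ties.method = "first")]
}

#' Training-curve plot
#'
#' Training and validation loss per epoch, with the best (early-stopping)
#' epoch marked.
#'
#' @param x A \code{degbrin_gcn} fit.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.degbrin_gcn <- function(x, ...) {
  rec <- x$record
  graphics::matplot(rec$epoch, cbind(rec$train_loss, rec$val_loss),
                    type = "l", lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "cross-entropy loss", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"),
                   col = c("steelblue", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}

#' Compare the DEG-BRIN model with random-topology and PPI ablations
#'
#' Trains and evaluates, under identical splits and per-seed conditions:
#' the DEG-BRIN GCN; a Random-GCN whose graph matches the DEG-BRIN node and
#' edge counts but has uniformly random topology; and (when a PPI edge list
#' is supplied) a PPI-GCN whose nodes are the universal-list genes with
#' binary PPI adjacency plus unit self-loops and per-gene scalar features.
#'
#' @param expr,samples Expression matrix and sample table.
#' @param region_degs A \code{region_deg_sets} object.
#' @param ppi Optional PPI edge data.frame (gene_a, gene_b, score).
#' @param ppi_tau Confidence threshold for the PPI graph (default 0.4).
#' @param seeds Integer vector of training seeds (paired across models).
#' @param feature_mode Feature mode for the region models (default
#'   \code{"masked"}, which lets the graph topology matter; see the methods
#'   vignette).
#' @param ... Further arguments to [degbrin_gcn()] (hyperparameters).
#' @return List with \code{table} (Table-1-shaped data.frame: model, class,
#'   precision, recall, f1, accuracy_mean, accuracy_sd) and \code{fits}
#'   (per model, the fit of the first seed) and \code{accuracies} (model x
#'   seed matrix).
#' @export
compare_models <- function(expr, samples, region_degs, ppi = NULL,
                           ppi_tau = 0.4, seeds = 1:5,
                           feature_mode = "masked", ...) {
  stopifnot(inherits(region_degs, "region_deg_sets"))
  genes <- region_degs$universal
  if (length(genes) < 2) stop("universal DEG list too small to model",
                              call. = FALSE)
  brin <- build_degbrin(region_degs)
  rand <- random_graph_matched(
    length(brin$nodes), n_edges(brin),
    self_loop_weights = diag(brin$W), nodes = brin$nodes,
    seed = derive_seed(seeds[1], "random_graph")
  )
  models <- list(
    "DEG-BRIN-GCN" = list(graph = brin, mode = feature_mode,
                          genes = genes, rs = region_degs$region_sets),
    "Random-GCN" = list(graph = rand, mode = feature_mode,
                        genes = genes, rs = region_degs$region_sets)
  )
  if (!is.null(ppi)) {
    ppi_graph <- add_self_loops(threshold_ppi(ppi, ppi_tau, nodes = genes))
    models[["PPI-GCN"]] <- list(graph = ppi_graph, mode = "nodal",
                                genes = genes, rs = NULL)
  } else {
    warning("no PPI edge list supplied: comparing DEG-BRIN and Random only")
  }
  acc <- matrix(NA_real_, length(models), length(seeds),
                dimnames = list(names(models), paste0("seed", seeds)))
  fits <- list()
  rows <- list()
  for (mn in names(models)) {
    m <- models[[mn]]
    for (si in seq_along(seeds)) {
      fit <- degbrin_gcn(expr, samples, m$graph, m$genes,
                         feature_mode = m$mode, region_sets = m$rs,
                         seed = seeds[si], ...)
      acc[mn, si] <- fit$test_metrics$accuracy
      if (si == 1) fits[[mn]] <- fit
    }
    pc <- fits[[mn]]$test_metrics$per_class
    pc$model <- mn
    pc$accuracy_mean <- mean(acc[mn, ])
    pc$accuracy_sd <- stats::sd(acc[mn, ])
    rows[[mn]] <- pc
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab[, c("model", "class", "precision", "recall", "f1",
                       "accuracy_mean", "accuracy_sd")],
       fits = fits, accuracies = acc)
}
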