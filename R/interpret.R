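#' Region and gene importance report
#'
#' Importance is read directly off the trainable gates: the softplus
#' activation of the gene gate scores each input gene, and of the region
#' gate each graph node. The \code{"gate_gradient"} mode additionally
#' weights each score by the mean absolute input-gradient (saliency) of the
#' corresponding features over the training samples, combining learned
#' magnitude with sensitivity; entries masked out of a node contribute no
#' saliency.
#'
#' @param fit A \code{degbrin_gcn} fit (or a \code{gcn_params} object, in
#'   which case gene/region labels must be supplied).
#' @param mode \code{"gate"} (default) or \code{"gate_gradient"}.
#' @param gene_labels,region_labels Labels when \code{fit} is a raw
#'   parameter set.
#' @return List of class \code{importance_report}: \code{genes} and
#'   \code{regions}, each a data.frame (rank, label, score) sorted by
#'   descending score with lexicographic tie-break, plus \code{method}.
#' @export
importance_report <- function(fit, mode = c("gate", "gate_gradient"),
                              gene_labels = NULL, region_labels = NULL) {
  mode <- match.arg(mode)
  if (inherits(fit, "degbrin_gcn")) {
    params <- fit$params
    gene_labels <- if (fit$feature_mode == "nodal") fit$graph$nodes
      else fit$genes
    region_labels <- fit$graph$nodes
  } else {
    params <- fit
    if (is.null(gene_labels) || is.null(region_labels)) {
      stop("labels required when passing raw parameters", call. = FALSE)
    }
  }
  gene_score <- softplus(params$gene_gate)
  region_score <- softplus(params$region_gate)
  if (inherits(fit, "degbrin_gcn") && fit$feature_mode == "nodal") {
    ## nodal mode: the per-node (gene) information sits in the region gate
    gene_score <- region_score
  }
  if (mode == "gate_gradient") {
    if (!inherits(fit, "degbrin_gcn")) {
      stop("gate_gradient mode needs a full fit with gradient history",
           call. = FALSE)
    }
    gg <- gate_gradient_means(fit)
    gene_score <- gene_score * gg$gene
    region_score <- region_score * gg$region
  }
  if (max(gene_score) - min(gene_score) < 1e-12 &&
      max(region_score) - min(region_score) < 1e-12) {
    warning("all importance scores are uniform (untrained gates?)")
  }
  rank_tab <- function(labels, score) {
    ord <- order(-score, labels)
    data.frame(rank = seq_along(ord), label = labels[ord],
               score = as.numeric(score[ord]), stringsAsFactors = FALSE)
  }
  structure(
    list(genes = rank_tab(gene_labels, gene_score),
         regions = rank_tab(region_labels, region_score),
         method = mode),
    class = "importance_report"
  )
}

## Mean absolute input-gradient per gene and per node, recomputed over the
## training items at the best parameters: the saliency of each node-feature
## entry, averaged over samples. Masked-out entries contribute exactly zero,
## so nodes whose region DEG set carries no features score zero.
gate_gradient_means <- function(fit) {
  items <- fit$train_items_cache
  if (is.null(items)) {
    ## neutral weighting when the training items were not retained
    return(list(gene = 1, region = 1))
  }
  g_sum <- 0; r_sum <- 0
  for (it in items) {
    fwd <- gcn_forward(fit$params, fit$a_hat, it$x, mask = fit$mask,
                       training = FALSE, keep_cache = TRUE)
    bk <- gcn_backward(fit$params, fwd, it$label, input_grad = TRUE)
    dH0 <- attr(bk, "dH0")
    g_sum <- g_sum + colMeans(abs(dH0))
    r_sum <- r_sum + rowMeans(abs(dH0))
  }
  list(gene = g_sum / length(items), region = r_sum / length(items))
}

#' @export
print.importance_report <- function(x, ...) {
  cat("Importance report (method:", x$method, ")\n")
  cat("Top regions:\n")
  print(utils::head(x$regions, 5), row.names = FALSE, digits = 3)
  cat("Top genes:\n")
  print(utils::head(x$genes, 5), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Moments of the training gradient distribution
#'
#' Mean, standard deviation, range and Pearson (non-excess) kurtosis
#' m4/m2^2 of the pooled per-epoch gradient samples; a normal distribution
#' has kurtosis 3, heavier tails exceed 3 (leptokurtic).
#'
#' @param grad_samples Numeric vector (e.g. the \code{grad_samples} element
#'   of a fit), or a \code{degbrin_gcn} object.
#' @return List: mean, sd, min, max, kurtosis, n.
#' @export
gradient_stats <- function(grad_samples) {
  if (inherits(grad_samples, "degbrin_gcn")) {
    grad_samples <- grad_samples$grad_samples
  }
  g <- grad_samples[is.finite(grad_samples)]
  if (length(g) == 0) stop("empty gradient sample", call. = FALSE)
  m <- mean(g)
  m2 <- mean((g - m)^2)
  kurt <- if (m2 <= 0) {
    warning("constant gradient sample: kurtosis undefined")
    NA_real_
  } else {
    mean((g - m)^4) / m2^2
  }
  list(mean = m, sd = stats::sd(g), min = min(g), max = max(g),
       kurtosis = kurt, n = length(g))
}

#' Region-gene-pathway triad table
#'
#' For each of the \code{top_k} most important regions, reports the
#' globally top-ranked genes that belong to that region's DEG set and the
#' significantly enriched pathways (adjusted p < \code{alpha}) containing
#' at least one of those genes — the cross-scale summary linking spatial,
#' molecular and functional views of the model.
#'
#' @param importance An [importance_report()].
#' @param region_sets Named list of per-region DEG sets (or a
#'   \code{region_deg_sets} object).
#' @param enrichment Named list: per region, an enrichment data.frame from
#'   [enrich_hypergeom()].
#' @param collection The [gene_set_collection()] used for the enrichment
#'   (needed to test pathway membership of the top genes).
#' @param top_k Number of regions reported (default 5).
#' @param top_genes Size of the global top-gene list intersected with each
#'   region (default 20).
#' @param alpha Significance cutoff on adjusted p (default 0.05).
#' @return data.frame (region, genes, pathways, key_genes); list columns
#'   are collapsed to ";"-separated strings.
#' @export
triad_table <- function(importance, region_sets, enrichment, collection,
                        top_k = 5, top_genes = 20, alpha = 0.05) {
  stopifnot(inherits(importance, "importance_report"))
  if (inherits(region_sets, "region_deg_sets")) {
    region_sets <- region_sets$region_sets
  }
  top_regions <- utils::head(importance$regions$label, top_k)
  global_top <- utils::head(importance$genes$label, top_genes)
  rows <- lapply(top_regions, function(r) {
    genes_r <- intersect(global_top, region_sets[[r]])
    enr <- enrichment[[r]]
    paths <- character(0)
    keys <- genes_r
    if (!is.null(enr) && nrow(enr) > 0) {
      sig <- enr[enr$adj_p < alpha, , drop = FALSE]
      if (nrow(sig) > 0 && length(genes_r) > 0) {
        hit <- vapply(sig$term, function(tm) {
          length(intersect(collection$sets[[tm]], genes_r)) > 0
        }, logical(1))
        paths <- sig$term[hit]
        keys <- unique(c(genes_r,
                         intersect(unlist(collection$sets[paths]),
                                   region_sets[[r]])))
      }
    }
    data.frame(
      region = r,
      genes = paste(genes_r, collapse = ";"),
      pathways = paste(paths, collapse = ";"),
      key_genes = paste(utils::head(keys, 6), collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Overlap between top-ranked importance genes and hub genes
#'
#' @param importance An [importance_report()].
#' @param hubs Character vector of hub gene ids.
#' @param top_n Number of top importance genes considered (default 20).
#' @return Fraction of the top-n genes that are hubs.
#' @export
overlap_with_hubs <- function(importance, hubs, top_n = 20) {
  stopifnot(inherits(importance, "importance_report"))
  if (top_n > nrow(importance$genes)) {
    stop("'top_n' exceeds the number of scored genes", call. = FALSE)
  }
  top <- utils::head(importance$genes$label, top_n)
  length(intersect(top, hubs)) / top_n
}
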