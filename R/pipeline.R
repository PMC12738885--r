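#' Write an expression matrix as TSV
#'
#' First column \code{gene}, one column per sample.
#'
#' @param expr Numeric matrix with gene rownames and sample colnames.
#' @param path Output file.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read an expression TSV written by [write_expression_tsv()]
#'
#' @param path File path.
#' @return Numeric matrix, genes x samples.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read a sample metadata TSV
#'
#' Expects columns sample_id, subject_id, region, diagnosis and/or group;
#' when \code{group} is absent it is derived from \code{diagnosis} via
#' [consolidate_groups()].
#'
#' @param path File path.
#' @return data.frame.
#' @export
read_metadata_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!"group" %in% names(df)) {
    if (!"diagnosis" %in% names(df)) {
      stop("metadata needs a 'group' or 'diagnosis' column", call. = FALSE)
    }
    df$group <- consolidate_groups(df$diagnosis)
  }
  df
}

#' Validate pipeline input files
#'
#' Collects (rather than throws) structural problems: missing columns,
#' samples present in the metadata but absent from the matrix (and vice
#' versa), PPI scores outside [0, 1], PPI self-pairs.
#'
#' @param expr Expression matrix (or NULL).
#' @param samples Metadata data.frame (or NULL).
#' @param ppi PPI edge data.frame (or NULL).
#' @return Character vector of problems; empty when everything is clean.
#' @export
validate_inputs <- function(expr = NULL, samples = NULL, ppi = NULL) {
  problems <- character(0)
  if (!is.null(samples)) {
    need <- c("sample_id", "region", "group")
    miss <- setdiff(need, names(samples))
    if (length(miss) > 0) {
      problems <- c(problems,
                    paste("metadata missing column(s):",
                          paste(miss, collapse = ", ")))
    }
    if (!is.null(expr) && "sample_id" %in% names(samples)) {
      absent <- setdiff(samples$sample_id, colnames(expr))
      if (length(absent) > 0) {
        problems <- c(problems,
                      paste("metadata sample(s) absent from matrix:",
                            paste(utils::head(absent, 3), collapse = ", ")))
      }
      orphan <- setdiff(colnames(expr), samples$sample_id)
      if (length(orphan) > 0) {
        problems <- c(problems,
                      paste("matrix column(s) absent from metadata:",
                            paste(utils::head(orphan, 3), collapse = ", ")))
      }
    }
    if ("group" %in% names(samples)) {
      bad <- setdiff(unique(samples$group), GROUP_LEVELS)
      if (length(bad) > 0) {
        problems <- c(problems,
                      paste("unknown group label(s):",
                            paste(bad, collapse = ", ")))
      }
    }
  }
  if (!is.null(expr) && anyNA(expr)) {
    problems <- c(problems, "expression matrix contains missing values")
  }
  if (!is.null(ppi)) {
    need <- c("gene_a", "gene_b", "score")
    miss <- setdiff(need, names(ppi))
    if (length(miss) > 0) {
      problems <- c(problems, paste("PPI missing column(s):",
                                    paste(miss, collapse = ", ")))
    } else {
      if (any(ppi$score < 0 | ppi$score > 1)) {
        problems <- c(problems, "PPI score(s) outside [0, 1]")
      }
      if (any(ppi$gene_a == ppi$gene_b)) {
        problems <- c(problems, "PPI self-pair(s) present")
      }
    }
  }
  problems
}

#' Default pipeline configuration
#'
#' @param seed Global seed fanned out to every stage.
#' @param out_dir Output directory.
#' @param simdata Overrides for [synthetic_config()] fields.
#' @param dge Overrides: lfc_threshold, alpha, min_regions.
#' @param model Overrides: hidden_dim, dropout, feature_mode.
#' @param training Overrides: lr, weight_decay, max_epochs, patience,
#'   batch_size, seeds.
#' @return Nested configuration list.
#' @export
pipeline_config <- function(seed = 1L, out_dir = "degbrin_run",
                            simdata = list(), dge = list(), model = list(),
                            training = list()) {
  defaults <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    simdata = list(n_genes = 1000, n_regions = 6,
                   subjects_per_group = c(CON = 30, MCI = 30, AD = 30),
                   deg_per_region = 40, shared_fraction = 0.5,
                   effect_size_log2fc = 1.0,
                   prior_df_d0 = 4, prior_var_s0sq = 0.25),
    dge = list(lfc_threshold = 0.585, alpha = 0.05, min_regions = 2),
    model = list(hidden_dim = 32, dropout = 0.3, feature_mode = "masked"),
    training = list(lr = 0.00703, weight_decay = 1.06e-5, max_epochs = 60,
                    patience = 15, batch_size = 32)
  )
  defaults$simdata[names(simdata)] <- simdata
  defaults$dge[names(dge)] <- dge
  defaults$model[names(model)] <- model
  defaults$training[names(training)] <- training
  defaults
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys mirror [pipeline_config()] arguments.
#' @return Configuration list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simdata$subjects_per_group)) {
    y$simdata$subjects_per_group <- unlist(y$simdata$subjects_per_group)
  }
  pipeline_config(
    seed = y$seed %||% 1L,
    out_dir = y$out_dir %||% "degbrin_run",
    simdata = y$simdata %||% list(),
    dge = y$dge %||% list(),
    model = y$model %||% list(),
    training = y$training %||% list()
  )
}

#' Run the full pipeline on a synthetic cohort
#'
#' Executes simulate -> differential expression -> DEG-BRIN construction ->
#' GCN training -> evaluation -> interpretation, writing every artifact
#' under \code{config$out_dir} together with a manifest of content hashes.
#' Stages whose output files already exist are skipped unless
#' \code{force = TRUE}.
#'
#' @param config A [pipeline_config()].
#' @param force Logical; rerun stages whose outputs exist.
#' @return Invisibly, the manifest (data.frame artifact/path/md5).
#' @export
run_pipeline <- function(config, force = FALSE) {
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    expression = file.path(out, "expression.tsv"),
    metadata = file.path(out, "metadata.tsv"),
    ground_truth = file.path(out, "ground_truth.json"),
    deg_sets = file.path(out, "region_deg_sets.json"),
    degbrin = file.path(out, "degbrin_edges.tsv"),
    metrics = file.path(out, "test_metrics.json"),
    importance = file.path(out, "importance.tsv"),
    gradient_stats = file.path(out, "gradient_stats.json")
  )

  if (force || !file.exists(paths$expression)) {
    sim_args <- c(config$simdata, list(seed = derive_seed(config$seed, "sim")))
    cohort <- do.call(synthetic_config, sim_args)
    cohort <- generate_cohort(cohort)
    write_cohort(cohort, out)
  } else {
    message("simulate: outputs exist, skipping")
  }
  expr <- read_expression_tsv(paths$expression)
  samples <- read_metadata_tsv(paths$metadata)
  problems <- validate_inputs(expr, samples)
  if (length(problems) > 0) {
    stop("input validation failed:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }

  if (force || !file.exists(paths$deg_sets)) {
    expr_pp <- preprocess_expression(expr)
    degs <- degs_per_region(expr_pp, samples,
                            lfc_threshold = config$dge$lfc_threshold,
                            alpha = config$dge$alpha,
                            min_regions = config$dge$min_regions)
    jsonlite::write_json(
      list(region_sets = degs$region_sets, universal = degs$universal,
           frequency = as.list(degs$frequency)),
      paths$deg_sets, auto_unbox = FALSE, digits = NA
    )
    saved_degs <- degs
  } else {
    message("dge: outputs exist, skipping")
    expr_pp <- preprocess_expression(expr)
    saved_degs <- degs_per_region(expr_pp, samples,
                                  lfc_threshold = config$dge$lfc_threshold,
                                  alpha = config$dge$alpha,
                                  min_regions = config$dge$min_regions)
  }

  brin <- build_degbrin(saved_degs)
  write_graph_tsv(brin, paths$degbrin)

  if (force || !file.exists(paths$metrics)) {
    fit <- degbrin_gcn(
      expr_pp, samples, brin, saved_degs$universal,
      feature_mode = config$model$feature_mode,
      region_sets = saved_degs$region_sets,
      hidden_dim = config$model$hidden_dim,
      dropout = config$model$dropout,
      lr = config$training$lr,
      weight_decay = config$training$weight_decay,
      max_epochs = config$training$max_epochs,
      patience = config$training$patience,
      batch_size = config$training$batch_size,
      seed = derive_seed(config$seed, "fit")
    )
    jsonlite::write_json(
      list(accuracy = fit$test_metrics$accuracy,
           per_class = fit$test_metrics$per_class,
           best_epoch = fit$best_epoch),
      paths$metrics, auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
    imp <- importance_report(fit)
    utils::write.table(
      rbind(
        cbind(kind = "region", imp$regions),
        cbind(kind = "gene", imp$genes)
      ),
      paths$importance, sep = "\t", quote = FALSE, row.names = FALSE
    )
    gs <- gradient_stats(fit)
    jsonlite::write_json(gs, paths$gradient_stats, auto_unbox = TRUE,
                         digits = NA)
  } else {
    message("train/interpret: outputs exist, skipping")
  }

  manifest <- data.frame(
    artifact = names(paths),
    path = unlist(paths),
    md5 = unname(tools::md5sum(unlist(paths))),
    stringsAsFactors = FALSE, row.names = NULL
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(manifest)
}
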