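#' Configuration for a synthetic multi-region cohort
#'
#' Collects and validates all parameters of the cohort generator. The
#' generator emulates the structure of a postmortem multi-region microarray
#' study: every subject contributes one sample per anatomical region, raw
#' diagnoses are consolidated into CON/MCI/AD, and differential expression is
#' planted per region with a configurable cross-region shared pool.
#'
#' @param n_genes Number of genes simulated.
#' @param n_regions Number of brain regions (default 19; the first
#'   \code{n_regions} labels of [brain_regions()] are used, padded with
#'   generic labels beyond 19).
#' @param subjects_per_group Named integer vector with elements CON, MCI and
#'   AD giving the number of subjects per analytical group.
#' @param deg_per_region Number of genes planted as differentially expressed
#'   in each region.
#' @param shared_fraction Fraction of each region's planted genes drawn from
#'   a common cross-region pool (drives the co-occurrence network signal).
#' @param effect_size_log2fc Magnitude of planted group mean shifts on the
#'   log2 scale.
#' @param prior_df_d0 Prior degrees of freedom of the gene-variance
#'   distribution (scaled inverse-chi-square).
#' @param prior_var_s0sq Prior (typical) residual variance.
#' @param baseline_mean,baseline_sd Mean and spread of per-gene baseline
#'   log2 intensities.
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return An object of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_genes = 2000, n_regions = 19,
                             subjects_per_group = c(CON = 23, MCI = 42, AD = 34),
                             deg_per_region = 40, shared_fraction = 0.5,
                             effect_size_log2fc = 1.0,
                             prior_df_d0 = 4, prior_var_s0sq = 0.25,
                             baseline_mean = 7, baseline_sd = 1.5,
                             seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes")
  n_regions <- check_count(n_regions, "n_regions")
  deg_per_region <- check_count(deg_per_region, "deg_per_region", min = 0)
  check_fraction(shared_fraction, "shared_fraction")
  if (!is.numeric(effect_size_log2fc) || effect_size_log2fc <= 0) {
    stop("'effect_size_log2fc' must be a positive real", call. = FALSE)
  }
  if (!is.numeric(prior_df_d0) || prior_df_d0 <= 0) {
    stop("'prior_df_d0' must be positive", call. = FALSE)
  }
  if (!is.numeric(prior_var_s0sq) || prior_var_s0sq <= 0) {
    stop("'prior_var_s0sq' must be positive", call. = FALSE)
  }
  if (is.null(names(subjects_per_group)) ||
      !setequal(names(subjects_per_group), GROUP_LEVELS)) {
    stop("'subjects_per_group' must be named with CON, MCI and AD", call. = FALSE)
  }
  for (g in GROUP_LEVELS) {
    check_count(subjects_per_group[[g]], paste0("subjects_per_group[", g, "]"))
  }
  if (deg_per_region > n_genes) {
    stop("'deg_per_region' cannot exceed 'n_genes'", call. = FALSE)
  }
  structure(
    list(
      n_genes = n_genes, n_regions = n_regions,
      subjects_per_group = subjects_per_group[GROUP_LEVELS],
      deg_per_region = deg_per_region, shared_fraction = shared_fraction,
      effect_size_log2fc = effect_size_log2fc,
      prior_df_d0 = prior_df_d0, prior_var_s0sq = prior_var_s0sq,
      baseline_mean = baseline_mean, baseline_sd = baseline_sd,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

region_labels <- function(n) {
  base <- brain_regions()
  if (n <= length(base)) base[seq_len(n)]
  else c(base, sprintf("region_%02d", seq_len(n - length(base)) + length(base)))
}

## Effect patterns over (MCI, AD) shifts relative to CON. Each planted gene
## gets one pattern so that all three pairwise contrasts carry signal
## somewhere: "mci" perturbs MCI only, "ad" perturbs AD only, "both" moves
## MCI and AD together (progressive dysregulation shared by the two stages).
plant_pattern <- function(pattern, delta, sign) {
  shift <- switch(pattern,
    mci  = c(MCI = sign * delta, AD = 0),
    ad   = c(MCI = 0, AD = sign * delta),
    both = c(MCI = sign * delta, AD = sign * delta)
  )
  c(CON = 0, shift)[GROUP_LEVELS]
}

## Contrasts whose group-mean difference has magnitude >= delta under a
## pattern; these define the per-contrast ground truth.
pattern_contrasts <- function(pattern) {
  switch(pattern,
    mci  = c("MCI-CON", "MCI-AD"),
    ad   = c("AD-CON", "MCI-AD"),
    both = c("MCI-CON", "AD-CON")
  )
}

CONTRAST_NAMES <- c("MCI-CON", "AD-CON", "MCI-AD")

#' Generate a synthetic multi-region expression cohort
#'
#' Simulates log2-scale expression for every (subject, region) pair. Gene
#' baselines are Normal, per-gene residual variances are drawn from a scaled
#' inverse-chi-square prior (so the empirical-Bayes moderation model is the
#' generating model and its hyperparameters are recoverable), and planted
#' differentially expressed genes receive additive group-dependent mean
#' shifts of magnitude \code{effect_size_log2fc} in their region only.
#'
#' @param config A [synthetic_config()].
#' @return A list with components \code{expr} (genes x samples numeric
#'   matrix), \code{samples} (data.frame: sample_id, subject_id, region,
#'   diagnosis, group) and \code{truth} (list: planted_degs
#'   (region -> contrast -> genes), shared_pool (the sampling pool),
#'   cross_region (genes planted in at least two regions), gene_variances,
#'   group_labels).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    stop("'config' must be created by synthetic_config()", call. = FALSE)
  }
  set.seed(config$seed)
  genes <- sprintf("g%05d", seq_len(config$n_genes))
  regions <- region_labels(config$n_regions)

  n_sub <- config$subjects_per_group
  groups <- rep(GROUP_LEVELS, times = n_sub)
  subjects <- sprintf("s%04d", seq_along(groups))
  ## Raw diagnoses consistent with the consolidation map: MCI subjects are
  ## split between Possible and Probable AD.
  diagnosis <- character(length(groups))
  diagnosis[groups == "CON"] <- "Normal"
  diagnosis[groups == "AD"] <- "Definite AD"
  mci_idx <- which(groups == "MCI")
  if (length(mci_idx) > 0) {
    half <- ceiling(length(mci_idx) / 2)
    diagnosis[mci_idx] <- rep(c("Possible AD", "Probable AD"),
                              c(half, length(mci_idx) - half))
  }

  mu <- stats::rnorm(config$n_genes, config$baseline_mean, config$baseline_sd)
  ## scaled inverse-chi-square: sigma^2 = d0 * s0^2 / chi^2_{d0}
  sigma2 <- config$prior_df_d0 * config$prior_var_s0sq /
    stats::rchisq(config$n_genes, df = config$prior_df_d0)

  ## Planted DEG bookkeeping: shared pool + region-specific genes.
  n_shared <- round(config$shared_fraction * config$deg_per_region)
  pool <- character(0)
  if (config$deg_per_region > 0 && config$shared_fraction > 0) {
    pool_size <- max(2L, config$deg_per_region)
    pool <- sample(genes, pool_size)
  }
  planted <- vector("list", config$n_regions)
  names(planted) <- regions
  ## effects[[region]] is an n_genes x 3 matrix of group shifts
  effects <- lapply(regions, function(r) {
    matrix(0, config$n_genes, 3, dimnames = list(genes, GROUP_LEVELS))
  })
  names(effects) <- regions

  for (r in regions) {
    planted[[r]] <- stats::setNames(
      rep(list(character(0)), length(CONTRAST_NAMES)), CONTRAST_NAMES
    )
    if (config$deg_per_region == 0) next
    shared_here <- if (n_shared > 0) sample(pool, min(n_shared, length(pool)))
      else character(0)
    own <- sample(setdiff(genes, shared_here),
                  config$deg_per_region - length(shared_here))
    chosen <- c(shared_here, own)
    pat <- sample(c("mci", "ad", "both"), length(chosen), replace = TRUE)
    sgn <- sample(c(-1, 1), length(chosen), replace = TRUE)
    for (i in seq_along(chosen)) {
      effects[[r]][chosen[i], ] <- plant_pattern(
        pat[i], config$effect_size_log2fc, sgn[i]
      )
      for (ct in pattern_contrasts(pat[i])) {
        planted[[r]][[ct]] <- c(planted[[r]][[ct]], chosen[i])
      }
    }
    planted[[r]] <- lapply(planted[[r]], sort)
  }

  n_samples <- length(subjects) * length(regions)
  expr <- matrix(NA_real_, config$n_genes, n_samples,
                 dimnames = list(genes, NULL))
  sample_id <- character(n_samples)
  sub_col <- character(n_samples)
  reg_col <- character(n_samples)
  k <- 0
  for (j in seq_along(subjects)) {
    for (r in regions) {
      k <- k + 1
      sample_id[k] <- paste0(subjects[j], "_", r)
      sub_col[k] <- subjects[j]
      reg_col[k] <- r
      expr[, k] <- mu + effects[[r]][, groups[j]] +
        stats::rnorm(config$n_genes, 0, sqrt(sigma2))
    }
  }
  colnames(expr) <- sample_id
  samples <- data.frame(
    sample_id = sample_id,
    subject_id = sub_col,
    region = reg_col,
    diagnosis = rep(diagnosis, each = length(regions)),
    group = rep(groups, each = length(regions)),
    stringsAsFactors = FALSE
  )
  region_planted <- lapply(planted, function(p) sort(unique(unlist(p))))
  plant_freq <- table(unlist(region_planted))
  truth <- list(
    planted_degs = planted,
    shared_pool = sort(pool),
    ## genes actually planted in >= 2 regions: the realized cross-region
    ## signal that the universal list G is built to recover
    cross_region = sort(names(plant_freq)[plant_freq >= 2]),
    gene_variances = stats::setNames(sigma2, genes),
    group_labels = stats::setNames(samples$group, samples$sample_id)
  )
  list(expr = expr, samples = samples, truth = truth)
}

#' Generate a synthetic protein-protein interaction edge list
#'
#' Draws an Erdos-Renyi edge set over the supplied genes with combined
#' confidence scores uniform in \code{score_range}, as a stand-in for a
#' STRING-style interaction table.
#'
#' @param genes Character vector of gene ids.
#' @param edge_density Probability in (0, 1) that an unordered pair is an
#'   edge (1 is allowed and gives the complete graph).
#' @param score_range Length-2 numeric interval within [0, 1].
#' @param seed Integer seed.
#' @return data.frame with columns gene_a, gene_b, score.
#' @export
generate_ppi <- function(genes, edge_density = 0.05,
                         score_range = c(0.15, 1), seed = 1L) {
  if (length(genes) == 0) stop("'genes' must be nonempty", call. = FALSE)
  if (anyDuplicated(genes)) stop("'genes' must be unique", call. = FALSE)
  if (!is.numeric(edge_density) || edge_density <= 0 || edge_density > 1) {
    stop("'edge_density' must lie in (0, 1]", call. = FALSE)
  }
  stopifnot(length(score_range) == 2, score_range[1] <= score_range[2],
            score_range[1] >= 0, score_range[2] <= 1)
  set.seed(as.integer(seed))
  idx <- utils::combn(length(genes), 2)
  keep <- if (edge_density >= 1) rep(TRUE, ncol(idx))
    else stats::runif(ncol(idx)) < edge_density
  a <- idx[1, keep]; b <- idx[2, keep]
  data.frame(
    gene_a = genes[a], gene_b = genes[b],
    score = stats::runif(sum(keep), score_range[1], score_range[2]),
    stringsAsFactors = FALSE
  )
}

#' Write a simulated cohort to plain-text files
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written (expression TSV, metadata TSV,
#'   ground-truth JSON).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr_path <- file.path(dir, "expression.tsv")
  meta_path <- file.path(dir, "metadata.tsv")
  truth_path <- file.path(dir, "ground_truth.json")
  write_expression_tsv(cohort$expr, expr_path)
  utils::write.table(cohort$samples, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(
      planted_degs = cohort$truth$planted_degs,
      shared_pool = cohort$truth$shared_pool,
      cross_region = cohort$truth$cross_region,
      gene_variances = as.list(cohort$truth$gene_variances),
      group_labels = as.list(cohort$truth$group_labels)
    ),
    truth_path, auto_unbox = TRUE, digits = NA
  )
  invisible(c(expression = expr_path, metadata = meta_path,
              ground_truth = truth_path))
}
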