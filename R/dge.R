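#' Preprocess an expression matrix
#'
#' Applies the standard quality filters for a log2-scale expression matrix:
#' rows (genes) containing missing values are removed, duplicate gene ids are
#' collapsed by their mean expression profile, and genes sitting below the
#' detection threshold in more than \code{max_below_fraction} of samples are
#' discarded as technical noise.
#'
#' @param expr Numeric matrix, genes x samples, with gene ids as rownames.
#' @param detection_threshold Detection limit on the log2 scale. If
#'   \code{NULL} (default), the 20th percentile of all finite values is used.
#' @param max_below_fraction Maximum tolerated fraction of samples below the
#'   detection threshold (strict: a gene is dropped only when the fraction
#'   exceeds this value). Default 0.6.
#' @return Filtered numeric matrix.
#' @export
preprocess_expression <- function(expr, detection_threshold = NULL,
                                  max_below_fraction = 0.6) {
  if (!is.matrix(expr) || nrow(expr) == 0 || ncol(expr) == 0) {
    stop("'expr' must be a nonempty genes x samples matrix", call. = FALSE)
  }
  if (is.null(rownames(expr))) stop("'expr' must have gene ids as rownames",
                                    call. = FALSE)
  check_fraction(max_below_fraction, "max_below_fraction")

  keep <- stats::complete.cases(expr)
  expr <- expr[keep, , drop = FALSE]
  if (nrow(expr) == 0) stop("all genes removed: every row had missing values",
                            call. = FALSE)

  if (anyDuplicated(rownames(expr))) {
    ids <- rownames(expr)
    expr <- rowsum(expr, group = ids) / as.vector(table(ids)[unique(ids)])
    ## rowsum orders by sort(unique); restore first-appearance order
    expr <- expr[unique(ids), , drop = FALSE]
  }

  if (is.null(detection_threshold)) {
    detection_threshold <- stats::quantile(expr, 0.2, names = FALSE)
  }
  below <- rowMeans(expr < detection_threshold)
  expr <- expr[below <= max_below_fraction, , drop = FALSE]
  if (nrow(expr) == 0) {
    stop("all genes removed by the detection filter", call. = FALSE)
  }
  expr
}

#' Per-gene ordinary least squares for a group contrast
#'
#' Fits the gene-wise linear model y_g = X beta_g + eps_g by least squares
#' simultaneously for all genes and extracts, for a single contrast, the
#' estimated log2 fold change, the residual standard deviation, the residual
#' degrees of freedom and the unscaled coefficient variance factor
#' v = c' (X'X)^{-1} c.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param design Design matrix (samples x coefficients), full column rank.
#' @param contrast Numeric contrast vector of length ncol(design).
#' @return data.frame with columns gene, coef, s, df, v.
#' @export
fit_gene_lm <- function(expr, design, contrast) {
  stopifnot(is.matrix(expr), is.matrix(design),
            nrow(design) == ncol(expr), length(contrast) == ncol(design))
  qr_x <- qr(design)
  if (qr_x$rank < ncol(design)) {
    stop("'design' must have full column rank", call. = FALSE)
  }
  n <- nrow(design)
  df <- n - qr_x$rank
  if (df <= 0) {
    stop("no residual degrees of freedom: need more samples than coefficients",
         call. = FALSE)
  }
  xtx_inv <- chol2inv(qr.R(qr_x))
  coefs <- t(qr.coef(qr_x, t(expr)))          # genes x coefficients
  fitted <- coefs %*% t(design)
  rss <- rowSums((expr - fitted)^2)
  data.frame(
    gene = rownames(expr),
    coef = as.vector(coefs %*% contrast),
    s = sqrt(rss / df),
    df = df,
    v = as.numeric(t(contrast) %*% xtx_inv %*% contrast),
    stringsAsFactors = FALSE
  )
}

## Inverse of the trigamma function by Newton iteration on 1/x scale
## (monotone, globally convergent for y > 0).
trigamma_inverse <- function(y) {
  stopifnot(all(is.finite(y)), all(y > 0))
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2L)
    x <- x + dif
    if (max(abs(dif / x)) < 1e-10) break
  }
  x
}

#' Empirical-Bayes moderation of gene-wise variances
#'
#' Estimates the hyperparameters (d0, s0^2) of a scaled inverse-chi-square
#' prior on the gene residual variances by moment matching on the log
#' variances (mean and variance of log s_g^2 matched against the log
#' scaled-F distribution implied by the prior), then forms the moderated
#' variance s~_g^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g), the moderated
#' t-statistic t~_g = coef_g / (s~_g sqrt(v_g)) on d0 + d_g degrees of
#' freedom, two-sided p-values and Benjamini-Hochberg adjusted p-values.
#'
#' When the dispersion of the observed log variances does not exceed the
#' sampling dispersion, d0 is taken as infinite (capped at 1e6) and every
#' variance shrinks fully to s0^2. Non-finite moment estimates trigger a
#' no-moderation fallback (d0 = 0) with a warning.
#'
#' @param fit data.frame from [fit_gene_lm()].
#' @param d0 Optional fixed prior degrees of freedom (bypasses estimation;
#'   0 means no moderation).
#' @param s0sq Optional fixed prior variance (required when \code{d0 > 0} is
#'   supplied).
#' @return List with elements \code{d0}, \code{s0sq} and \code{table}
#'   (data.frame: gene, log2fc, s, df, s2_post, t, p, adj_p).
#' @export
moderate_fit <- function(fit, d0 = NULL, s0sq = NULL) {
  stopifnot(is.data.frame(fit), all(c("gene", "coef", "s", "df", "v") %in%
                                      names(fit)))
  ok <- fit$df > 0 & fit$s > 0
  if (is.null(d0)) {
    if (sum(ok) < 2) {
      stop("need at least 2 genes with positive residual variance", call. = FALSE)
    }
    est <- estimate_variance_prior(fit$s[ok]^2, fit$df[ok])
    d0 <- est$d0
    s0sq <- est$s0sq
    if (!is.finite(s0sq) || s0sq <= 0) {
      warning("non-finite prior moment estimates; falling back to d0 = 0")
      d0 <- 0
      s0sq <- stats::median(fit$s[ok]^2)
    }
  } else if (d0 > 0 && is.null(s0sq)) {
    stop("'s0sq' must be supplied with a fixed positive 'd0'", call. = FALSE)
  }

  s2 <- fit$s^2
  if (d0 == 0) {
    s2_post <- s2
    df_total <- fit$df
  } else {
    d0 <- min(d0, 1e6)  # cap representing an infinite prior
    s2_post <- (d0 * s0sq + fit$df * s2) / (d0 + fit$df)
    df_total <- d0 + fit$df
  }
  t_stat <- fit$coef / sqrt(s2_post * fit$v)
  p <- 2 * stats::pt(-abs(t_stat), df = df_total)
  tab <- data.frame(
    gene = fit$gene,
    log2fc = fit$coef,
    s = fit$s,
    df = fit$df,
    s2_post = s2_post,
    t = t_stat,
    p = p,
    adj_p = bh_adjust(p),
    stringsAsFactors = FALSE
  )
  list(d0 = d0, s0sq = s0sq, table = tab)
}

#' Moment-matching estimate of the variance prior
#'
#' Under the scaled inverse-chi-square prior, log s_g^2 follows a shifted
#' log-F distribution; matching its first two moments (via digamma and
#' trigamma identities) yields closed-form estimates of d0 and s0^2.
#'
#' @param s2 Gene residual variances (positive).
#' @param df Residual degrees of freedom (scalar or per-gene vector).
#' @return List with \code{d0} (possibly \code{1e6}, the cap representing
#'   infinity) and \code{s0sq}.
#' @export
estimate_variance_prior <- function(s2, df) {
  stopifnot(all(s2 > 0), all(df > 0))
  df <- rep_len(df, length(s2))
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  e_bar <- mean(e)
  e_var <- stats::var(e) - mean(trigamma(df / 2))
  if (!is.finite(e_var)) return(list(d0 = NaN, s0sq = NaN))
  if (e_var <= 0) {
    d0 <- 1e6
  } else {
    d0 <- min(2 * trigamma_inverse(e_var), 1e6)
  }
  s0sq <- exp(e_bar + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0sq = s0sq)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' order-preserving with the input vector.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes
#'
#' A gene is a DEG when |log2FC| strictly exceeds \code{lfc_threshold} and
#' its BH-adjusted p-value is strictly below \code{alpha}.
#'
#' @param mod Result of [moderate_fit()] (or its \code{table} component).
#' @param lfc_threshold Fold-change bound on the log2 scale; the default
#'   0.585 corresponds to a 1.5-fold change.
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @return data.frame of the called rows, ordered by adjusted p.
#' @export
call_degs <- function(mod, lfc_threshold = 0.585, alpha = 0.05) {
  tab <- if (is.data.frame(mod)) mod else mod$table
  hit <- abs(tab$log2fc) > lfc_threshold & tab$adj_p < alpha
  out <- tab[hit, , drop = FALSE]
  out[order(out$adj_p, out$gene), , drop = FALSE]
}

#' Per-region differential expression over the three group contrasts
#'
#' For every region, fits each available pairwise contrast (MCI-CON, AD-CON,
#' MCI-AD) on the samples of the two groups involved, moderates the
#' variances, calls DEGs, takes the per-region union over contrasts, and
#' assembles the cross-region universal list G of genes differentially
#' expressed in at least \code{min_regions} regions.
#'
#' @param expr Numeric matrix, genes x samples (log2 scale, preprocessed).
#' @param samples data.frame with columns sample_id, region, group.
#' @param lfc_threshold,alpha Thresholds passed to [call_degs()].
#' @param min_regions Minimum number of regions a gene must be called in to
#'   enter the universal list (default 2).
#' @return List of class \code{region_deg_sets}: \code{tables} (region ->
#'   contrast -> DEG data.frame), \code{region_sets} (region -> union gene
#'   set), \code{frequency} (named vector, regions per gene),
#'   \code{universal} (the list G), \code{min_regions}, \code{universe}.
#' @export
degs_per_region <- function(expr, samples, lfc_threshold = 0.585,
                            alpha = 0.05, min_regions = 2) {
  stopifnot(is.matrix(expr), is.data.frame(samples),
            all(c("sample_id", "region", "group") %in% names(samples)))
  if (!all(samples$sample_id %in% colnames(expr))) {
    stop("every metadata sample_id must be a column of 'expr'", call. = FALSE)
  }
  regions <- unique(samples$region)
  pairs <- list("MCI-CON" = c("MCI", "CON"),
                "AD-CON" = c("AD", "CON"),
                "MCI-AD" = c("MCI", "AD"))
  tables <- list()
  region_sets <- list()
  any_contrast <- FALSE
  for (r in regions) {
    meta_r <- samples[samples$region == r, , drop = FALSE]
    tabs <- list()
    for (ct in names(pairs)) {
      gr <- pairs[[ct]]
      meta_c <- meta_r[meta_r$group %in% gr, , drop = FALSE]
      counts <- table(factor(meta_c$group, levels = gr))
      if (any(counts < 2)) {
        warning(sprintf("region %s: contrast %s skipped (a group has < 2 samples)",
                        r, ct))
        next
      }
      y <- expr[, meta_c$sample_id, drop = FALSE]
      grp <- factor(meta_c$group, levels = rev(gr))  # baseline = second group
      design <- stats::model.matrix(~grp)
      fit <- fit_gene_lm(y, design, contrast = c(0, 1))
      mod <- moderate_fit(fit)
      degs <- call_degs(mod, lfc_threshold, alpha)
      degs$contrast <- if (nrow(degs)) ct else character(0)
      tabs[[ct]] <- degs
      any_contrast <- TRUE
    }
    tables[[r]] <- tabs
    region_sets[[r]] <- sort(unique(unlist(lapply(tabs, `[[`, "gene"))))
  }
  if (!any_contrast) {
    stop("no region had a contrast with enough samples", call. = FALSE)
  }
  freq_tab <- table(unlist(region_sets))
  frequency <- stats::setNames(as.integer(freq_tab), names(freq_tab))
  universal <- sort(names(frequency)[frequency >= min_regions])
  structure(
    list(
      tables = tables, region_sets = region_sets, frequency = frequency,
      universal = universal, min_regions = min_regions,
      universe = rownames(expr)
    ),
    class = "region_deg_sets"
  )
}

#' @export
print.region_deg_sets <- function(x, ...) {
  cat("Region DEG sets over", length(x$region_sets), "regions\n")
  sizes <- vapply(x$region_sets, length, integer(1))
  cat("  per-region DEG counts:", paste(sizes, collapse = " "), "\n")
  cat("  universal list G (>= ", x$min_regions, " regions): ",
      length(x$universal), " genes\n", sep = "")
  invisible(x)
}
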