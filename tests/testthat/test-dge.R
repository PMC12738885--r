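make_expr <- function(values, genes, samples) {
  matrix(values, nrow = length(genes), ncol = length(samples),
         dimnames = list(genes, samples), byrow = TRUE)
}

test_that("preprocessing applies the detection, missingness and duplicate rules", {
  # gene below threshold in 61% of samples is removed at the 0.6 bound
  m <- rbind(
    low = c(rep(0, 61), rep(10, 39)),
    borderline = c(rep(0, 60), rep(10, 40)),
    high = rep(10, 100)
  )
  colnames(m) <- sprintf("s%03d", 1:100)
  out <- preprocess_expression(m, detection_threshold = 5,
                               max_below_fraction = 0.6)
  expect_setequal(rownames(out), c("borderline", "high"))

  # nothing below threshold: identity
  clean <- make_expr(rnorm(20, 10), sprintf("g%d", 1:4), sprintf("s%d", 1:5))
  expect_equal(preprocess_expression(clean, detection_threshold = 0), clean)

  # duplicate ids collapse to the mean profile
  dup <- matrix(c(1, 3, 3, 5), 2, 2, byrow = TRUE,
                dimnames = list(c("gX", "gX"), c("s1", "s2")))
  out <- preprocess_expression(dup, detection_threshold = -Inf)
  expect_equal(unname(out["gX", ]), c(2, 4))

  # rows with missing values are dropped
  with_na <- clean
  with_na[2, 3] <- NA
  expect_equal(nrow(preprocess_expression(with_na, detection_threshold = 0)), 3)

  expect_error(preprocess_expression(clean, detection_threshold = 100),
               "all genes removed")
})

test_that("gene-wise least squares matches closed forms and a per-gene lm oracle", {
  # noiseless two-group shift
  y <- matrix(c(0, 0, 0, 1, 1, 1), 1, 6,
              dimnames = list("g1", sprintf("s%d", 1:6)))
  grp <- factor(rep(c("a", "b"), each = 3), levels = c("a", "b"))
  design <- model.matrix(~grp)
  fit <- fit_gene_lm(y, design, c(0, 1))
  expect_equal(fit$coef, 1)
  expect_equal(fit$s, 0)
  expect_equal(fit$df, 4)
  # balanced two-group contrast: v = 2/n per group
  expect_equal(fit$v, 2 / 3)

  # random matrix against per-gene lm()
  set.seed(42)
  n <- 10
  y <- matrix(rnorm(50 * 2 * n), 50, 2 * n,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:(2 * n))))
  grp <- factor(rep(c("a", "b"), each = n), levels = c("a", "b"))
  design <- model.matrix(~grp)
  fit <- fit_gene_lm(y, design, c(0, 1))
  for (i in c(1, 17, 50)) {
    lm_fit <- lm(y[i, ] ~ grp)
    expect_equal(fit$coef[i], unname(coef(lm_fit)[2]), tolerance = 1e-10)
    expect_equal(fit$s[i], summary(lm_fit)$sigma, tolerance = 1e-10)
    expect_equal(fit$df[i], lm_fit$df.residual)
  }

  expect_error(fit_gene_lm(y, cbind(design, design[, 2]), c(0, 1, 0)),
               "full column rank")
})

test_that("moderation reduces to the ordinary t at d0 = 0 and caps at the common-variance limit", {
  set.seed(1)
  fit <- data.frame(gene = sprintf("g%d", 1:20), coef = rnorm(20),
                    s = sqrt(rchisq(20, 5) / 5), df = 5, v = 0.2)
  plain <- moderate_fit(fit, d0 = 0)
  expect_equal(plain$table$t, fit$coef / (fit$s * sqrt(fit$v)),
               tolerance = 1e-12)

  # identical observed variances: the dispersion of log s^2 cannot exceed
  # its pure sampling component, so d0 hits the infinity cap and every
  # posterior variance shrinks fully to the prior value s0^2 (which carries
  # the chi-square sampling-bias correction exp(log(d/2) - digamma(d/2)))
  same <- fit
  same$s <- 0.7
  capped <- moderate_fit(same)
  expect_gte(capped$d0, 1e6)
  s0_expected <- 0.49 * exp(log(5 / 2) - digamma(5 / 2))
  expect_equal(capped$s0sq, s0_expected, tolerance = 1e-4)
  expect_equal(capped$table$s2_post, rep(capped$s0sq, 20), tolerance = 1e-4)
})

test_that("moderated variances interpolate monotonically between s^2 and s0^2", {
  set.seed(8)
  fit <- data.frame(gene = sprintf("g%d", 1:200), coef = rnorm(200),
                    s = sqrt(0.25 * 4 / rchisq(200, 4) * rchisq(200, 10) / 10),
                    df = 10, v = 0.2)
  mod <- moderate_fit(fit)
  lo <- pmin(fit$s^2, mod$s0sq)
  hi <- pmax(fit$s^2, mod$s0sq)
  expect_true(all(mod$table$s2_post >= lo - 1e-12))
  expect_true(all(mod$table$s2_post <= hi + 1e-12))
  # |t~| between the ordinary t at s and the t at s0
  t_s <- abs(fit$coef / (fit$s * sqrt(fit$v)))
  t_s0 <- abs(fit$coef / (sqrt(mod$s0sq * fit$v)))
  t_mod <- abs(mod$table$t)
  expect_true(all(t_mod >= pmin(t_s, t_s0) - 1e-9))
  expect_true(all(t_mod <= pmax(t_s, t_s0) + 1e-9))
})

test_that("variance-prior hyperparameters are recovered within 20%", {
  d0_true <- 4
  s0sq_true <- 0.25
  df <- 38
  set.seed(123)
  est <- replicate(10, {
    sigma2 <- d0_true * s0sq_true / rchisq(2000, d0_true)
    s2 <- sigma2 * rchisq(2000, df) / df
    unlist(estimate_variance_prior(s2, df))
  })
  expect_lt(abs(median(est["d0", ]) - d0_true) / d0_true, 0.2)
  expect_lt(abs(median(est["s0sq", ]) - s0sq_true) / s0sq_true, 0.2)
})

test_that("BH adjustment matches hand computation and preserves order structure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(11)
  p <- runif(40)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  perm <- sample(40)
  expect_equal(bh_adjust(p[perm]), adj[perm])
})

test_that("DEG calling applies both thresholds with strict inequalities", {
  tab <- data.frame(
    gene = c("called", "boundary", "big_fc_weak_p", "weak"),
    log2fc = c(0.60, 0.585, 2.0, 0.1),
    s = 1, df = 10, s2_post = 1,
    t = c(5, 5, 2, 1),
    p = c(0.001, 0.001, 0.04, 0.5),
    adj_p = c(0.01, 0.01, 0.06, 0.9)
  )
  expect_identical(call_degs(tab)$gene, "called")
})

test_that("per-region DEG sets form unions, frequencies and the universal list", {
  co <- std_cohort()
  degs <- std_degs()
  # per-region set is the union of its contrast tables
  r <- names(degs$tables)[1]
  union_genes <- sort(unique(unlist(lapply(degs$tables[[r]], `[[`, "gene"))))
  expect_identical(degs$region_sets[[r]], union_genes)
  # universal list: only genes called in >= 2 regions
  expect_true(all(degs$frequency[degs$universal] >= 2))
  singles <- names(degs$frequency)[degs$frequency == 1]
  expect_length(intersect(singles, degs$universal), 0)
  # planted cross-region genes are recovered
  expect_gte(mean(co$truth$cross_region %in% degs$universal), 0.8)
})

test_that("moderated pipeline matches limma on a shared fixture", {
  skip_if_not_installed("limma")
  set.seed(99)
  n <- 8
  y <- matrix(rnorm(200 * 2 * n, sd = rep(sqrt(0.2 * 4 / rchisq(200, 4)), 2 * n)),
              200, 2 * n, dimnames = list(sprintf("g%03d", 1:200),
                                          sprintf("s%02d", 1:(2 * n))))
  grp <- factor(rep(c("a", "b"), each = n), levels = c("a", "b"))
  design <- model.matrix(~grp)
  fit <- fit_gene_lm(y, design, c(0, 1))
  mod <- moderate_fit(fit)

  lfit <- limma::eBayes(limma::lmFit(y, design))
  expect_equal(mod$d0, lfit$df.prior, tolerance = 1e-6)
  expect_equal(mod$s0sq, lfit$s2.prior, tolerance = 1e-6)
  expect_equal(mod$table$t, lfit$t[, 2], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(mod$table$p, lfit$p.value[, 2], tolerance = 1e-8,
               ignore_attr = TRUE)
})
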