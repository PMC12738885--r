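test_that("largest-remainder apportionment reproduces the canonical splits", {
  expect_equal(largest_remainder(1053, c(0.7, 0.1, 0.2)), c(737L, 105L, 211L))
  expect_equal(largest_remainder(10, c(0.7, 0.1, 0.2)), c(7L, 1L, 2L))
  expect_equal(sum(largest_remainder(997, c(0.55, 0.25, 0.2))), 997L)
})

test_that("stratified splitting balances classes and matches global totals", {
  # class sizes mirroring a 1,053-sample three-group cohort
  sizes <- c(CON = 242, MCI = 449, AD = 362)
  samples <- data.frame(
    sample_id = sprintf("s%04d", 1:1053),
    group = rep(names(sizes), times = sizes)
  )
  split <- stratified_split(samples, c(0.7, 0.1, 0.2), seed = 4)
  tot <- table(split$partition)[c("train", "val", "test")]
  expect_equal(unname(as.integer(tot)), c(737L, 105L, 211L))
  # partitions disjoint and exhaustive
  expect_setequal(split$sample_id, samples$sample_id)
  expect_equal(anyDuplicated(split$sample_id), 0L)
  # per-class counts within one sample of exact proportions
  for (cl in names(sizes)) {
    cnt <- table(factor(split$partition[split$group == cl],
                        levels = c("train", "val", "test")))
    exact <- sizes[cl] * c(0.7, 0.1, 0.2)
    expect_true(all(abs(as.integer(cnt) - exact) <= 1))
  }
  # determinism
  split2 <- stratified_split(samples, c(0.7, 0.1, 0.2), seed = 4)
  expect_identical(split, split2)
  split3 <- stratified_split(samples, c(0.7, 0.1, 0.2), seed = 5)
  expect_false(identical(split$partition, split3$partition))
})

test_that("a class too small to split lands wholly in train with a warning", {
  samples <- data.frame(
    sample_id = sprintf("s%02d", 1:22),
    group = c(rep("CON", 10), rep("MCI", 10), rep("AD", 2))
  )
  expect_warning(split <- stratified_split(samples, seed = 1), "AD")
  expect_true(all(split$partition[split$group == "AD"] == "train"))
})

test_that("random over-sampling equalises counts and keeps the originals", {
  ids <- sprintf("s%02d", 1:20)
  labels <- rep(c("CON", "MCI", "AD"), times = c(10, 6, 4))
  out <- random_oversample(ids, labels, seed = 2)
  out_labels <- labels[match(out, ids)]
  expect_equal(length(out), 30L)
  expect_true(all(table(out_labels) == 10))
  # originals retained; extras drawn from the observed pool (multiset superset)
  expect_true(all(ids %in% out))
  expect_true(all(out %in% ids))

  balanced <- random_oversample(ids[1:9], rep(c("a", "b", "c"), each = 3),
                                seed = 1)
  expect_setequal(balanced, ids[1:9])
  expect_length(balanced, 9L)
})

test_that("training fits a separable problem and respects early stopping", {
  # two well-separated classes on a 2-node graph
  set.seed(6)
  make_item <- function(label) {
    centre <- if (label == 1) c(2, -2) else c(-2, 2)
    list(x = centre + rnorm(2, 0, 0.3), label = label, id = "x")
  }
  items <- lapply(rep(1:2, each = 20), make_item)
  val <- lapply(rep(1:2, each = 5), make_item)
  cfg <- gcn_config(n_nodes = 2, in_dim = 2, hidden_dim = 4, n_classes = 2,
                    dropout = 0, seed = 3)
  W <- matrix(c(2, 1, 1, 2), 2, 2)
  fit <- gcn_train(cfg, normalize_adjacency(W), items, val, lr = 0.05,
                   max_epochs = 200, patience = 20, seed = 9)
  ev <- gcn_evaluate(fit$params, normalize_adjacency(W), items)
  expect_equal(ev$accuracy, 1.0)

  # patience = 0 stops at the first non-improving epoch (an aggressive
  # learning rate forces oscillation early)
  fit0 <- gcn_train(cfg, normalize_adjacency(W), items, val, lr = 1.0,
                    max_epochs = 200, patience = 0, seed = 9)
  vl <- fit0$record$val_loss
  running_best <- cummin(vl)
  first_flat <- which(vl[-1] >= running_best[-length(vl)] - 1e-9)[1] + 1L
  expect_false(is.na(first_flat))
  expect_equal(nrow(fit0$record), first_flat)

  # identical seeds give identical records
  fit2 <- gcn_train(cfg, normalize_adjacency(W), items, val, lr = 0.05,
                    max_epochs = 200, patience = 20, seed = 9)
  expect_identical(fit$record, fit2$record)
  # early stopping never returns a worse-than-best epoch
  expect_equal(min(fit$record$val_loss),
               fit$record$val_loss[fit$best_epoch])
})

test_that("metrics reports match hand-computed confusion counts", {
  perfect <- metrics_report(c(1, 2, 3, 1), c(1, 2, 3, 1))
  expect_equal(perfect$accuracy, 1)
  expect_true(all(perfect$per_class$f1[perfect$per_class$support > 0] == 1))

  # TP=8, FP=2, FN=2 for class 1
  truth <- c(rep(1, 10), rep(2, 10))
  pred <- c(rep(1, 8), 2, 2, 1, 1, rep(2, 8))
  rep1 <- metrics_report(pred, truth, class_names = c("A", "B", "C"))
  expect_equal(rep1$per_class$precision[1], 0.8)
  expect_equal(rep1$per_class$recall[1], 0.8)
  expect_equal(rep1$per_class$f1[1], 0.8)

  # class never predicted: precision 0 with warning
  expect_warning(
    rep2 <- metrics_report(c(1, 1, 1), c(1, 1, 2), class_names = c("A", "B")),
    "never predicted"
  )
  expect_equal(rep2$per_class$precision[2], 0)
  expect_equal(rep2$per_class$f1[2], 0)
})

test_that("the fitted model object supports the standard S3 verbs", {
  co <- std_cohort()
  degs <- std_degs()
  fit <- std_fit()
  expect_s3_class(fit, "degbrin_gcn")
  expect_output(print(fit), "test accuracy")
  expect_output(summary(fit), "Per-class")
  gates <- coef(fit)
  expect_length(gates$gene_gate, length(degs$universal))
  expect_length(gates$region_gate, 5)
  expect_true(all(gates$gene_gate > 0))

  # ROS never touches validation or test partitions
  expect_equal(anyDuplicated(fit$split$sample_id), 0L)
  expect_setequal(fit$split$sample_id, co$samples$sample_id)

  preds <- predict(fit, co$expr, co$samples)
  expect_true(all(preds %in% c("CON", "MCI", "AD")))
  probs <- predict(fit, co$expr, co$samples, type = "prob")
  expect_equal(unname(rowSums(probs)), rep(1, nrow(probs)), tolerance = 1e-9)

  path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(path)
  expect_silent(plot(fit))
  grDevices::dev.off()
})

test_that("densely planted cohorts are classified far above chance", {
  cfg <- synthetic_config(
    n_genes = 600, n_regions = 5,
    subjects_per_group = c(CON = 30, MCI = 30, AD = 30),
    deg_per_region = 40, shared_fraction = 0.5,
    effect_size_log2fc = 1.0, seed = 11
  )
  co <- generate_cohort(cfg)
  degs <- degs_per_region(co$expr, co$samples)
  brin <- build_degbrin(degs)
  fit <- degbrin_gcn(co$expr, co$samples, brin, degs$universal,
                     feature_mode = "masked", region_sets = degs$region_sets,
                     hidden_dim = 16, dropout = 0.3, max_epochs = 40,
                     patience = 10, seed = 1)
  expect_gt(fit$test_metrics$accuracy, 0.8)
})

test_that("hyperparameter search logs every trial and returns the argmax", {
  objective <- function(hidden_dim, lr, weight_decay, dropout) {
    -abs(log10(lr) + 3.5) - abs(dropout - 0.5)
  }
  res <- hyperparameter_search(objective, n_trials = 12, seed = 3)
  expect_equal(nrow(res$trials), 12L)
  expect_false(anyNA(res$trials$score))
  expect_true(all(res$best$score >= res$trials$score))
  expect_true(all(res$trials$hidden_dim >= 64 & res$trials$hidden_dim <= 256))
  expect_true(all(res$trials$lr >= 1e-4 & res$trials$lr <= 1e-3))
  expect_true(all(res$trials$dropout >= 0.3 & res$trials$dropout <= 0.7))

  single <- hyperparameter_search(objective, n_trials = 1, seed = 5)
  expect_equal(nrow(single$trials), 1L)
  expect_equal(single$best$trial, 1)
})
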