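#' Largest-remainder apportionment
#'
#' Allocates \code{total} units over fractions that sum to 1: floor the
#' exact shares, then distribute the remaining units to the largest
#' fractional remainders (ties to the earlier fraction).
#'
#' @param total Integer total.
#' @param fractions Numeric vector summing to 1.
#' @return Integer vector summing to \code{total}.
#' @export
largest_remainder <- function(total, fractions) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9, total >= 0)
  exact <- total * fractions
  base <- floor(exact)
  short <- total - sum(base)
  if (short > 0) {
    rem <- exact - base
    add <- order(rem, decreasing = TRUE)[seq_len(short)]
    base[add] <- base[add] + 1
  }
  as.integer(base)
}

#' Stratified train/validation/test split
#'
#' Shuffles within each class and allocates by largest-remainder rounding of
#' class_size x fraction, then reconciles the per-partition totals to the
#' largest-remainder allocation of the overall totals by moving single
#' samples between partitions within classes whose rounding went the
#' opposite way (so every class stays within one sample of its exact
#' proportions). Classes smaller than 3 go entirely to train with a warning.
#'
#' @param samples data.frame with columns sample_id and group (class label).
#' @param fractions Numeric length-3 vector (train, val, test), summing to 1.
#' @param seed Integer seed.
#' @return data.frame (sample_id, group, partition) with partition in
#'   \{train, val, test\}.
#' @export
stratified_split <- function(samples, fractions = c(0.7, 0.1, 0.2),
                             seed = 1L) {
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "group") %in% names(samples)),
            length(fractions) == 3, abs(sum(fractions) - 1) < 1e-9)
  set.seed(as.integer(seed))
  parts <- c("train", "val", "test")
  classes <- unique(samples$group)
  small <- classes[table(factor(samples$group, levels = classes))[classes] < 3]
  alloc <- matrix(0L, length(classes), 3,
                  dimnames = list(classes, parts))
  for (cl in classes) {
    n_cl <- sum(samples$group == cl)
    if (cl %in% small) {
      warning(sprintf("class %s has < 3 samples; assigning all to train", cl))
      alloc[cl, ] <- c(n_cl, 0L, 0L)
    } else {
      alloc[cl, ] <- largest_remainder(n_cl, fractions)
    }
  }
  ## reconcile totals to the global largest-remainder allocation
  target <- largest_remainder(nrow(samples) - sum(alloc[small, , drop = FALSE]),
                              fractions)
  big <- setdiff(classes, small)
  exact <- outer(table(factor(samples$group, levels = big))[big], fractions)
  for (iter in 1:100) {
    tot <- colSums(alloc[big, , drop = FALSE])
    over <- which(tot > target)
    under <- which(tot < target)
    if (length(over) == 0) break
    o <- over[1]; u <- under[1]
    ## move one sample of the class whose rounding most favoured o over u
    score <- (alloc[big, o] - exact[, o]) - (alloc[big, u] - exact[, u])
    movable <- big[alloc[big, o] > 0]
    cl <- movable[which.max(score[match(movable, big)])]
    alloc[cl, o] <- alloc[cl, o] - 1L
    alloc[cl, u] <- alloc[cl, u] + 1L
  }
  out <- samples[, c("sample_id", "group")]
  out$partition <- NA_character_
  for (cl in classes) {
    idx <- which(samples$group == cl)
    idx <- idx[sample.int(length(idx))]
    out$partition[idx] <- rep(parts, times = alloc[cl, ])
  }
  out
}

#' Random over-sampling of the training set
#'
#' Duplicates minority-class training samples (with replacement) until every
#' class matches the majority class count. All original samples are kept;
#' validation and test sets are never touched.
#'
#' @param train_ids Character vector of training sample ids.
#' @param labels Named vector (or vector aligned with train_ids) of class
#'   labels.
#' @param seed Integer seed.
#' @return Character vector of (possibly duplicated) sample ids.
#' @export
random_oversample <- function(train_ids, labels, seed = 1L) {
  stopifnot(length(train_ids) == length(labels), length(train_ids) > 0)
  counts <- table(labels)
  if (any(counts == 0)) stop("every class must appear in train", call. = FALSE)
  set.seed(as.integer(seed))
  target <- max(counts)
  extra <- unlist(lapply(names(counts), function(cl) {
    pool <- train_ids[labels == cl]
    need <- target - length(pool)
    if (need > 0) sample(pool, need, replace = TRUE) else character(0)
  }))
  c(train_ids, extra)
}

## Assemble per-sample graph batch items: standardized features over the
## universal gene list (z-scored with training-set statistics).
## Returns list(items = list of (x, label, id), scaling = list(center, scale)).
build_items <- function(expr, samples, genes, scaling = NULL) {
  stopifnot(all(genes %in% rownames(expr)))
  X <- expr[genes, samples$sample_id, drop = FALSE]
  if (is.null(scaling)) {
    scaling <- list(center = rowMeans(X),
                    scale = pmax(apply(X, 1, stats::sd), 1e-8))
  }
  Xs <- (X - scaling$center) / scaling$scale
  items <- lapply(seq_len(ncol(Xs)), function(j) {
    list(x = Xs[, j],
         label = match(samples$group[j], GROUP_LEVELS),
         id = samples$sample_id[j])
  })
  list(items = items, scaling = scaling)
}

## Node x gene mask from region DEG sets restricted to the universal list.
region_mask <- function(region_sets, genes, regions) {
  M <- matrix(0, length(regions), length(genes),
              dimnames = list(regions, genes))
  for (r in regions) {
    hit <- intersect(region_sets[[r]], genes)
    M[r, hit] <- 1
  }
  M
}

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0)
}

adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    m_hat <- state$m[[nm]] / (1 - beta1^state$t)
    v_hat <- state$v[[nm]] / (1 - beta2^state$t)
    ## decoupled weight decay: never applied to gates or biases
    decay <- if (nm %in% c("theta1", "theta2", "w_c")) weight_decay else 0
    params[[nm]] <- params[[nm]] - lr * (m_hat / (sqrt(v_hat) + eps) +
                                           decay * params[[nm]])
  }
  list(params = params, state = state)
}

eval_items <- function(params, a_hat, items, mask = NULL) {
  losses <- numeric(length(items))
  pred <- integer(length(items))
  truth <- integer(length(items))
  for (i in seq_along(items)) {
    it <- items[[i]]
    fwd <- gcn_forward(params, a_hat, it$x, mask = mask, training = FALSE)
    losses[i] <- cross_entropy(fwd$probs, it$label)
    pred[i] <- which.max(fwd$probs)
    truth[i] <- it$label
  }
  list(loss = mean(losses), accuracy = mean(pred == truth),
       pred = pred, truth = truth)
}

#' Train the GCN classifier
#'
#' Adaptive-moment gradient descent with decoupled weight decay over
#' shuffled mini-batches, early stopping on validation loss with the stated
#' patience, returning the parameters of the best validation epoch. A small
#' sample of gradient values is recorded each epoch for downstream
#' gradient-distribution analysis.
#'
#' @param config A [gcn_config()].
#' @param a_hat Normalised adjacency matrix.
#' @param train_items,val_items Lists of batch items (elements with
#'   \code{x}, \code{label}).
#' @param mask Optional node mask (masked mode).
#' @param lr Learning rate (default 0.00703, the tuned value).
#' @param weight_decay Decoupled weight-decay coefficient (default
#'   1.06e-5, the tuned value).
#' @param max_epochs Maximum epochs (default 200).
#' @param patience Early-stopping patience in epochs (default 20).
#' @param batch_size Mini-batch size (default 32).
#' @param seed Integer seed for shuffling and dropout.
#' @param grad_sample_size Gradient values sampled per epoch (default 200).
#' @return List with \code{params} (best), \code{record} (data.frame of
#'   per-epoch train loss, val loss, val accuracy), \code{grad_samples}
#'   (numeric vector pooled over epochs), \code{best_epoch}.
#' @export
gcn_train <- function(config, a_hat, train_items, val_items, mask = NULL,
                      lr = 0.00703, weight_decay = 1.06e-5,
                      max_epochs = 200, patience = 20, batch_size = 32,
                      seed = 1L, grad_sample_size = 200) {
  stopifnot(length(train_items) > 0, length(val_items) > 0)
  params <- init_params(config)
  state <- adam_state(params)
  set.seed(as.integer(seed))
  best <- list(loss = Inf, params = params, epoch = 0)
  wait <- 0
  rec <- list()
  grad_samples <- list()
  for (epoch in seq_len(max_epochs)) {
    idx <- sample.int(length(train_items))
    batch_losses <- numeric(0)
    epoch_grads <- NULL
    for (start in seq(1, length(idx), by = batch_size)) {
      bidx <- idx[start:min(start + batch_size - 1, length(idx))]
      acc <- NULL
      bl <- 0
      for (i in bidx) {
        it <- train_items[[i]]
        lg <- gcn_loss_grad(params, a_hat, it$x, it$label, mask = mask,
                            training = TRUE)
        if (!is.finite(lg$loss)) {
          stop(sprintf("non-finite training loss at epoch %d (sample %s)",
                       epoch, it$id %||% i), call. = FALSE)
        }
        bl <- bl + lg$loss
        acc <- if (is.null(acc)) lg$grads
          else mapply(`+`, acc, lg$grads, SIMPLIFY = FALSE)
      }
      grads <- lapply(acc, `/`, length(bidx))
      if (is.null(epoch_grads)) epoch_grads <- grads
      step <- adam_step(params, grads, state, lr, weight_decay)
      params <- step$params
      state <- step$state
      batch_losses <- c(batch_losses, bl / length(bidx))
    }
    gvec <- flatten_params(unclass(epoch_grads))
    take <- sample.int(length(gvec), min(grad_sample_size, length(gvec)))
    grad_samples[[epoch]] <- gvec[take]
    ev <- eval_items(params, a_hat, val_items, mask = mask)
    rec[[epoch]] <- data.frame(epoch = epoch,
                               train_loss = mean(batch_losses),
                               val_loss = ev$loss,
                               val_accuracy = ev$accuracy)
    if (ev$loss < best$loss - 1e-9) {
      best <- list(loss = ev$loss, params = params, epoch = epoch)
      wait <- 0
    } else {
      wait <- wait + 1
      if (wait > patience) break
    }
  }
  list(params = best$params,
       record = do.call(rbind, rec),
       grad_samples = unlist(grad_samples),
       best_epoch = best$epoch)
}

#' Classification metrics report
#'
#' Per-class precision, recall and F1 plus overall accuracy from predicted
#' and true class indices. A class never predicted has precision 0 by
#' convention (with a warning); F1 is 0 when precision and recall are both 0.
#'
#' @param pred Integer predicted class indices.
#' @param truth Integer true class indices.
#' @param class_names Character labels (default CON/MCI/AD ordering).
#' @return List with \code{per_class} data.frame (class, precision, recall,
#'   f1, support) and \code{accuracy}.
#' @export
metrics_report <- function(pred, truth, class_names = GROUP_LEVELS) {
  stopifnot(length(pred) == length(truth), length(truth) > 0)
  k <- length(class_names)
  cm <- table(factor(truth, levels = seq_len(k)),
              factor(pred, levels = seq_len(k)))
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  never <- (tp + fp) == 0
  if (any(never & (tp + fn) > 0)) {
    warning("class never predicted: ",
            paste(class_names[never], collapse = ", "),
            "; precision set to 0")
  }
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  list(
    per_class = data.frame(
      class = class_names,
      precision = as.numeric(precision),
      recall = as.numeric(recall),
      f1 = as.numeric(f1),
      support = as.numeric(rowSums(cm)),
      stringsAsFactors = FALSE
    ),
    accuracy = sum(tp) / length(truth)
  )
}

#' Evaluate trained parameters on a test set
#'
#' @param params Trained \code{gcn_params}.
#' @param a_hat Normalised adjacency.
#' @param test_items List of batch items.
#' @param mask Optional node mask.
#' @return A [metrics_report()] augmented with \code{loss}.
#' @export
gcn_evaluate <- function(params, a_hat, test_items, mask = NULL) {
  ev <- eval_items(params, a_hat, test_items, mask = mask)
  rep <- metrics_report(ev$pred, ev$truth)
  rep$loss <- ev$loss
  rep
}

#' Seeded random hyperparameter search
#'
#' Uniform sampling over hidden dimension and dropout, log-uniform over
#' learning rate and weight decay, maximising validation accuracy.
#'
#' @param objective Function(hidden_dim, lr, weight_decay, dropout) ->
#'   validation accuracy.
#' @param n_trials Number of trials (default 30).
#' @param hidden_range,lr_range,wd_range,dropout_range Search bounds.
#' @param seed Integer seed.
#' @return List with \code{best} (row of the log) and \code{trials}
#'   (data.frame of every sampled configuration and its score).
#' @export
hyperparameter_search <- function(objective, n_trials = 30,
                                  hidden_range = c(64, 256),
                                  lr_range = c(1e-4, 1e-3),
                                  wd_range = c(1e-6, 1e-3),
                                  dropout_range = c(0.3, 0.7),
                                  seed = 1L) {
  check_count(n_trials, "n_trials")
  set.seed(as.integer(seed))
  trials <- data.frame(
    trial = seq_len(n_trials),
    hidden_dim = round(stats::runif(n_trials, hidden_range[1],
                                    hidden_range[2])),
    lr = exp(stats::runif(n_trials, log(lr_range[1]), log(lr_range[2]))),
    weight_decay = exp(stats::runif(n_trials, log(wd_range[1]),
                                    log(wd_range[2]))),
    dropout = stats::runif(n_trials, dropout_range[1], dropout_range[2])
  )
  trials$score <- NA_real_
  for (i in seq_len(n_trials)) {
    trials$score[i] <- objective(trials$hidden_dim[i], trials$lr[i],
                                 trials$weight_decay[i], trials$dropout[i])
  }
  list(best = trials[which.max(trials$score), , drop = FALSE],
       trials = trials)
}
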