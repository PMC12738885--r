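#' Configuration of the interpretable two-layer GCN
#'
#' @param n_nodes Number of graph nodes (brain regions, or genes for the
#'   PPI variant).
#' @param in_dim Input feature dimension per node (the universal DEG list
#'   size for the region model; 1 for the nodal variant).
#' @param hidden_dim Hidden dimension of both convolution layers
#'   (default 103, the tuned value; 256 is the untuned architecture width).
#' @param n_classes Number of diagnostic classes (default 3: CON/MCI/AD).
#' @param dropout Dropout probability applied after the first convolution
#'   during training (default 0.458, the tuned value).
#' @param feature_mode One of \code{"broadcast"} (every node receives the
#'   sample's full feature vector), \code{"masked"} (broadcast, then entries
#'   for genes absent from a node's region DEG set are zeroed) or
#'   \code{"nodal"} (one node per gene, scalar feature; requires
#'   \code{in_dim = 1}).
#' @param seed Integer seed for parameter initialisation.
#' @return Object of class \code{gcn_config}.
#' @export
gcn_config <- function(n_nodes, in_dim, hidden_dim = 103, n_classes = 3,
                       dropout = 0.458, feature_mode = "broadcast",
                       seed = 1L) {
  n_nodes <- check_count(n_nodes, "n_nodes")
  in_dim <- check_count(in_dim, "in_dim")
  hidden_dim <- check_count(hidden_dim, "hidden_dim")
  n_classes <- check_count(n_classes, "n_classes", min = 2)
  check_fraction(dropout, "dropout", open_upper = TRUE)
  feature_mode <- match.arg(feature_mode, c("broadcast", "masked", "nodal"))
  if (feature_mode == "nodal" && in_dim != 1) {
    stop("feature_mode 'nodal' requires in_dim = 1", call. = FALSE)
  }
  structure(
    list(n_nodes = n_nodes, in_dim = in_dim, hidden_dim = hidden_dim,
         n_classes = n_classes, dropout = dropout,
         feature_mode = feature_mode, seed = as.integer(seed)),
    class = "gcn_config"
  )
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Initialise GCN parameters
#'
#' Glorot-uniform convolution and classifier weights, zero biases, unit
#' layer-norm scale, and gene/region importance gates initialised so their
#' softplus activation is exactly 1 (neutral gating).
#'
#' @param config A [gcn_config()].
#' @return Named list of parameter arrays (class \code{gcn_params}):
#'   \code{theta1}, \code{theta2}, \code{ln_scale}, \code{ln_shift},
#'   \code{w_c}, \code{b_c}, \code{gene_gate}, \code{region_gate}.
#' @export
init_params <- function(config) {
  stopifnot(inherits(config, "gcn_config"))
  set.seed(config$seed)
  gate0 <- softplus_inv(1)   # log(e - 1): softplus(gate0) == 1
  structure(
    list(
      theta1 = glorot(config$in_dim, config$hidden_dim),
      theta2 = glorot(config$hidden_dim, config$hidden_dim),
      ln_scale = rep(1, config$hidden_dim),
      ln_shift = rep(0, config$hidden_dim),
      w_c = glorot(config$hidden_dim, config$n_classes),  # stored transposed
      b_c = rep(0, config$n_classes),
      gene_gate = rep(gate0, config$in_dim),
      region_gate = rep(gate0, config$n_nodes)
    ),
    class = "gcn_params", config = config
  )
}

elu <- function(x) ifelse(x > 0, x, expm1(x))
elu_grad <- function(x) ifelse(x > 0, 1, exp(x))

LN_EPS <- 1e-5

## Build the node-feature matrix H0 for one sample.
##  broadcast: every node row is softplus(gene_gate) * x
##  masked:    additionally multiplied by a node x feature binary mask
##  nodal:     one node per gene; column vector softplus(gate) * x
build_h0 <- function(params, x, config, mask = NULL) {
  g <- softplus(params$gene_gate)
  if (config$feature_mode == "nodal") {
    matrix(g * x, ncol = 1)
  } else {
    gx <- g * x
    H0 <- matrix(gx, nrow = config$n_nodes, ncol = config$in_dim,
                 byrow = TRUE)
    if (config$feature_mode == "masked") {
      if (is.null(mask)) stop("feature_mode 'masked' requires a mask",
                              call. = FALSE)
      H0 <- H0 * mask
    }
    H0
  }
}

#' Forward pass of the GCN classifier
#'
#' Computes, for one sample, the class probability vector through: gated
#' input features, two graph convolutions H' = ELU(A_hat H Theta) with
#' dropout after the first during training, per-node layer normalisation
#' over the hidden axis, region-gate scaling of the node embeddings, global
#' mean pooling and a softmax head.
#'
#' @param params A \code{gcn_params} object.
#' @param a_hat Normalised adjacency matrix (n_nodes x n_nodes).
#' @param x Numeric feature vector (length \code{in_dim}, or \code{n_nodes}
#'   in nodal mode).
#' @param mask Optional n_nodes x in_dim binary mask (masked mode).
#' @param training Logical; enables dropout.
#' @param keep_cache Logical; retain intermediates for backprop.
#' @return List with \code{probs} (length n_classes, sums to 1) and, when
#'   \code{keep_cache}, a \code{cache} of intermediates.
#' @export
gcn_forward <- function(params, a_hat, x, mask = NULL, training = FALSE,
                        keep_cache = FALSE) {
  config <- attr(params, "config")
  if (any(!is.finite(x))) stop("non-finite input features", call. = FALSE)
  H0 <- build_h0(params, x, config, mask)
  AH0 <- a_hat %*% H0
  Z1 <- AH0 %*% params$theta1
  H1 <- elu(Z1)
  if (training && config$dropout > 0) {
    drop_mask <- matrix(
      stats::rbinom(length(H1), 1, 1 - config$dropout) / (1 - config$dropout),
      nrow(H1), ncol(H1)
    )
  } else {
    drop_mask <- NULL
  }
  H1d <- if (is.null(drop_mask)) H1 else H1 * drop_mask
  AH1 <- a_hat %*% H1d
  Z2 <- AH1 %*% params$theta2
  H2 <- elu(Z2)
  ## per-node layer normalisation over the hidden axis
  mu <- rowMeans(H2)
  cen <- H2 - mu
  varr <- rowMeans(cen^2)
  inv_sd <- 1 / sqrt(varr + LN_EPS)
  Hn <- cen * inv_sd
  L <- sweep(Hn, 2, params$ln_scale, `*`)
  L <- sweep(L, 2, params$ln_shift, `+`)
  r <- softplus(params$region_gate)
  Lr <- L * r
  z <- colMeans(Lr)
  logits <- as.vector(t(params$w_c) %*% z + params$b_c)
  probs <- softmax(logits)
  out <- list(probs = probs)
  if (keep_cache) {
    out$cache <- list(H0 = H0, AH0 = AH0, Z1 = Z1, H1 = H1,
                      drop_mask = drop_mask, H1d = H1d, AH1 = AH1, Z2 = Z2,
                      Hn = Hn, inv_sd = inv_sd, r = r, L = L, z = z,
                      x = x, mask = mask, a_hat = a_hat)
  }
  out
}

softmax <- function(logits) {
  e <- exp(logits - max(logits))
  e / sum(e)
}

#' Cross-entropy loss
#'
#' Negative log probability of the true class, with the probability floored
#' at 1e-12.
#'
#' @param probs Probability vector (sums to 1).
#' @param label Integer class index (1-based).
#' @return Nonnegative scalar.
#' @export
cross_entropy <- function(probs, label) {
  -log(max(probs[label], 1e-12))
}

## Backward pass: gradients of the cross-entropy loss for one sample with
## respect to every parameter block. Mirrors gcn_forward step by step.
## With input_grad = TRUE the gradient with respect to the node-feature
## matrix H0 is attached as an attribute (used for saliency-style
## importance weighting).
gcn_backward <- function(params, fwd, label, input_grad = FALSE) {
  config <- attr(params, "config")
  cache <- fwd$cache
  n <- config$n_nodes
  dlogits <- fwd$probs
  dlogits[label] <- dlogits[label] - 1
  dw_c <- outer(cache$z, dlogits)          # hidden x classes
  db_c <- dlogits
  dz <- as.vector(params$w_c %*% dlogits)
  dLr <- matrix(dz / n, n, config$hidden_dim, byrow = TRUE)
  dr <- rowSums(dLr * cache$L)
  dL <- dLr * cache$r
  ## layer-norm affine
  dHn <- sweep(dL, 2, params$ln_scale, `*`)
  dln_scale <- colSums(dL * cache$Hn)
  dln_shift <- colSums(dL)
  ## layer-norm core (per row, population variance)
  row_mean_dHn <- rowMeans(dHn)
  row_mean_dHnHn <- rowMeans(dHn * cache$Hn)
  dH2 <- cache$inv_sd * (dHn - row_mean_dHn - cache$Hn * row_mean_dHnHn)
  dZ2 <- dH2 * elu_grad(cache$Z2)
  dtheta2 <- crossprod(cache$AH1, dZ2)
  dH1d <- cache$a_hat %*% (dZ2 %*% t(params$theta2))  # a_hat symmetric
  dH1 <- if (is.null(cache$drop_mask)) dH1d else dH1d * cache$drop_mask
  dZ1 <- dH1 * elu_grad(cache$Z1)
  dtheta1 <- crossprod(cache$AH0, dZ1)
  dH0 <- cache$a_hat %*% (dZ1 %*% t(params$theta1))
  if (config$feature_mode == "masked") dH0 <- dH0 * cache$mask
  if (config$feature_mode == "nodal") {
    ## scalar gate shared by every node's feature
    dgene_gate <- sum(as.vector(dH0) * cache$x) * sigmoid(params$gene_gate)
  } else {
    dgene_gate <- colSums(dH0) * cache$x * sigmoid(params$gene_gate)
  }
  dregion_gate <- dr * sigmoid(params$region_gate)
  out <- list(theta1 = dtheta1, theta2 = dtheta2,
              ln_scale = dln_scale, ln_shift = dln_shift,
              w_c = dw_c, b_c = db_c,
              gene_gate = dgene_gate, region_gate = dregion_gate)
  if (input_grad) attr(out, "dH0") <- dH0
  out
}

#' Loss and gradient for one sample
#'
#' @param params A \code{gcn_params}.
#' @param a_hat Normalised adjacency.
#' @param x Feature vector.
#' @param label Integer class index (1-based).
#' @param mask Optional node mask (masked mode).
#' @param training Logical; enables dropout.
#' @return List with \code{loss}, \code{probs} and \code{grads} (named list
#'   matching the parameter blocks).
#' @export
gcn_loss_grad <- function(params, a_hat, x, label, mask = NULL,
                          training = FALSE) {
  fwd <- gcn_forward(params, a_hat, x, mask = mask, training = training,
                     keep_cache = TRUE)
  list(
    loss = cross_entropy(fwd$probs, label),
    probs = fwd$probs,
    grads = gcn_backward(params, fwd, label)
  )
}

## Flatten / unflatten parameters (finite-difference checks, gradient
## sampling for the training record).
flatten_params <- function(p) unlist(p, use.names = FALSE)

unflatten_params <- function(template, v) {
  out <- template
  pos <- 1
  for (nm in names(template)) {
    len <- length(template[[nm]])
    block <- v[pos:(pos + len - 1)]
    if (is.matrix(template[[nm]])) {
      out[[nm]] <- matrix(block, nrow(template[[nm]]), ncol(template[[nm]]))
    } else {
      out[[nm]] <- block
    }
    pos <- pos + len
  }
  attributes(out) <- attributes(template)
  out
}
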