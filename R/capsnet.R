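# The micro-capsule network.
#
# Architecture (binary case, 342-point windows expanded to 19 x 18):
#   input (19,18,1)
#     -> Con-1: 8 filters, 4x4, same padding, ReLU        -> (19,18,8)
#     -> Con-2: two stacked 4x4 valid convolutions, ReLU  -> (13,12,8)
#     -> primary capsules: reshape into 4-D vectors + squash -> (312,4)
#     -> per-pair prediction u_hat[i,j] = u[i] %*% W[i,j] -> (312,K,16)
#     -> dynamic routing-by-agreement (r iterations)      -> (K,16)
#     -> capsule lengths = class presence probabilities   -> (K)
# trained with the margin loss on capsule lengths. There is no
# reconstruction decoder: the model is deliberately minimal for
# small-sample EEG classification.
#
# All tensors are plain R arrays with the batch as the first dimension;
# convolutions run as im2col matrix products. Forward and backward passes
# are implemented here in full (including the Adam updates in train.R):
# the capsule machinery is the heart of the package, not an off-the-shelf
# layer stack.

#' Model configuration for the micro-capsule network
#'
#' @param input_hw integer `c(h, w)` of the expanded segment matrix.
#' @param n_classes number of label capsules K (>= 2).
#' @param routing_iters dynamic-routing iterations r (default 3, the
#'   routing-by-agreement convention).
#' @param conv_filters filters in each convolutional layer (default 8).
#' @param conv_kernel square kernel size (default 4; Con-1 same-padded,
#'   the Con-2 stage is two stacked valid convolutions).
#' @param primary_dim primary capsule dimension (default 4).
#' @param label_dim label capsule dimension (default 16).
#' @param m_plus,m_minus,lambda margin-loss parameters (0.9, 0.1, 0.5).
#' @param loss_threshold optional early-stop threshold on training loss
#'   (disabled when `NULL`).
#' @return an object of class `capsnet_config`.
#' @export
capsnet_config <- function(input_hw, n_classes, routing_iters = 3L,
                           conv_filters = 8L, conv_kernel = 4L,
                           primary_dim = 4L, label_dim = 16L,
                           m_plus = 0.9, m_minus = 0.1, lambda = 0.5,
                           loss_threshold = NULL) {
  h <- as.integer(input_hw[1L]); w <- as.integer(input_hw[2L])
  k <- as.integer(conv_kernel)
  shrink <- 2L * (k - 1L)
  if (h - shrink < 1L || w - shrink < 1L)
    stopf("input %dx%d is smaller than the receptive field of two valid %dx%d convolutions",
          h, w, k, k)
  if (n_classes < 2L) stopf("need at least 2 classes")
  if (routing_iters < 1L) stopf("routing_iters must be >= 1")
  if (!(0 <= m_minus && m_minus < m_plus && m_plus <= 1))
    stopf("margin boundaries must satisfy 0 <= m_minus < m_plus <= 1")
  if (lambda <= 0) stopf("lambda must be > 0")
  hp <- h - shrink; wp <- w - shrink
  if ((hp * wp * conv_filters) %% primary_dim != 0L)
    stopf("feature map %dx%dx%d is not divisible into %d-D capsules",
          hp, wp, conv_filters, primary_dim)
  structure(list(
    input_hw = c(h, w), n_classes = as.integer(n_classes),
    routing_iters = as.integer(routing_iters),
    conv_filters = as.integer(conv_filters), conv_kernel = k,
    primary_dim = as.integer(primary_dim), label_dim = as.integer(label_dim),
    feat_hw = c(hp, wp),
    n_primary = as.integer(hp * wp * conv_filters / primary_dim),
    m_plus = m_plus, m_minus = m_minus, lambda = lambda,
    loss_threshold = loss_threshold), class = "capsnet_config")
}

#' @export
print.capsnet_config <- function(x, ...) {
  cat(sprintf(
    "<capsnet_config> input (%d,%d,1) -> conv (%d,%d,%d) -> %d primary capsules (dim %d) -> %d label capsules (dim %d), r = %d\n",
    x$input_hw[1], x$input_hw[2], x$feat_hw[1], x$feat_hw[2], x$conv_filters,
    x$n_primary, x$primary_dim, x$n_classes, x$label_dim, x$routing_iters))
  invisible(x)
}

## ---- im2col convolution machinery -------------------------------------

# Precompute the gather index matrix (n_positions x k*k*cin) mapping output
# positions (column-major over oh, ow) to linear indices of the padded input
# array (hp, wp, cin).
im2col_index <- function(h, w, cin, k, pad = c(0L, 0L, 0L, 0L)) {
  hp <- h + pad[1L] + pad[2L]; wp <- w + pad[3L] + pad[4L]
  oh <- hp - k + 1L; ow <- wp - k + 1L
  pos_r <- rep(seq_len(oh), times = ow)
  pos_c <- rep(seq_len(ow), each = oh)
  off <- expand.grid(di = 0:(k - 1L), dj = 0:(k - 1L), ch = seq_len(cin))
  idx <- matrix(0L, oh * ow, nrow(off))
  for (e in seq_len(nrow(off))) {
    r <- pos_r + off$di[e]; cc <- pos_c + off$dj[e]
    idx[, e] <- r + (cc - 1L) * hp + (off$ch[e] - 1L) * hp * wp
  }
  list(idx = idx, oh = oh, ow = ow, hp = hp, wp = wp, cin = cin,
       pad = pad, h = h, w = w)
}

pad_input <- function(x, ix) {
  # x: (B, h, w, cin) -> zero-padded (B, hp, wp, cin)
  if (all(ix$pad == 0L)) return(x)
  B <- dim(x)[1L]
  out <- array(0, c(B, ix$hp, ix$wp, ix$cin))
  out[, ix$pad[1L] + seq_len(ix$h), ix$pad[3L] + seq_len(ix$w), ] <- x
  out
}

conv_forward <- function(x, km, bias, ix) {
  B <- dim(x)[1L]
  xp <- pad_input(x, ix)
  xm <- matrix(xp, B, ix$hp * ix$wp * ix$cin)
  cols <- matrix(xm[, as.vector(ix$idx)], B * nrow(ix$idx), ncol(ix$idx))
  z <- sweep(cols %*% km, 2L, bias, "+")
  list(z = array(z, c(B, ix$oh, ix$ow, ncol(km))), cols = cols)
}

conv_backward <- function(gz, cols, km, ix, need_input_grad = TRUE) {
  # gz: (B, oh, ow, F) gradient wrt pre-activation
  B <- dim(gz)[1L]
  npos <- nrow(ix$idx); E <- ncol(ix$idx)
  gm <- matrix(gz, B * npos, dim(gz)[4L])
  g_km <- crossprod(cols, gm)
  g_b <- colSums(gm)
  gx <- NULL
  if (need_input_grad) {
    gc <- gm %*% t(km)                       # (B*npos, E)
    gc <- array(gc, c(B, npos, E))
    gpad <- matrix(0, B, ix$hp * ix$wp * ix$cin)
    for (e in seq_len(E)) {
      cols_e <- ix$idx[, e]
      gpad[, cols_e] <- gpad[, cols_e] + matrix(gc[, , e], B, npos)
    }
    gpad <- array(gpad, c(B, ix$hp, ix$wp, ix$cin))
    gx <- gpad[, ix$pad[1L] + seq_len(ix$h), ix$pad[3L] + seq_len(ix$w), ,
               drop = FALSE]
  }
  list(g_km = g_km, g_b = g_b, g_x = gx)
}

## ---- squash ------------------------------------------------------------

#' Squash activation (length-compressing nonlinearity)
#'
#' Maps a vector s to `(||s||^2 / (1 + ||s||^2)) * s / ||s||`: direction is
#' preserved and the output length lies strictly below 1, so a capsule's
#' length can be read as a probability of presence. The zero vector maps to
#' itself (the formulation `s * ||s|| / (1 + ||s||^2)` is singularity-free;
#' norms are floored at 1e-8 in the backward pass only).
#'
#' @param s numeric vector, or a matrix whose rows are vectors.
#' @return the squashed vector/matrix.
#' @export
squash <- function(s) {
  if (!all(is.finite(s))) stopf("squash: non-finite input")
  if (is.matrix(s)) return(squash_rows(s))
  n2 <- sum(s^2)
  s * (sqrt(n2) / (1 + n2))
}

squash_rows <- function(S) {
  n2 <- rowSums(S^2)
  S * (sqrt(n2) / (1 + n2))
}

squash_rows_backward <- function(S, g_out) {
  n2 <- rowSums(S^2)
  n <- sqrt(n2)
  g <- n / (1 + n2)
  gp <- (1 - n2) / (1 + n2)^2
  dotp <- rowSums(S * g_out)
  g_out * g + S * (gp * dotp / pmax(n, 1e-8))
}

## ---- model construction ------------------------------------------------

rtrunc_norm <- function(n, sd, lim = 2) {
  # truncated normal on [-lim*sd, lim*sd] via inverse-CDF sampling
  qnorm(runif(n, pnorm(-lim), pnorm(lim))) * sd
}

#' Initialise a micro-capsule network
#'
#' Convolution kernels use fan-in (He) initialisation, biases start at zero,
#' and the routing weight array W uses a truncated normal (sd 0.05).
#'
#' @param cfg a [capsnet_config].
#' @param seed integer seed for the weight draw.
#' @return an object of class `capsnet_model`.
#' @export
init_capsnet <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "capsnet_config"))
  set.seed(derive_seed(seed, "init"))
  k <- cfg$conv_kernel; f <- cfg$conv_filters
  h <- cfg$input_hw[1L]; w <- cfg$input_hw[2L]
  # TF-style same padding for an even kernel: floor((k-1)/2) before,
  # ceil((k-1)/2) after
  pb <- (k - 1L) %/% 2L; pa <- k - 1L - pb
  ix1 <- im2col_index(h, w, 1L, k, pad = c(pb, pa, pb, pa))
  ix2a <- im2col_index(h, w, f, k)
  ix2b <- im2col_index(ix2a$oh, ix2a$ow, f, k)
  he <- function(fan_in, n) rnorm(n, sd = sqrt(2 / fan_in))
  P <- cfg$primary_dim; D <- cfg$label_dim; K <- cfg$n_classes
  model <- list(
    cfg = cfg,
    km1 = matrix(he(k * k, k * k * f), k * k, f), b1 = numeric(f),
    km2a = matrix(he(k * k * f, k * k * f * f), k * k * f, f), b2a = numeric(f),
    km2b = matrix(he(k * k * f, k * k * f * f), k * k * f, f), b2b = numeric(f),
    # W[, (j-1)*D + d, i] holds the (P x D) prediction map from primary
    # capsule i to label capsule j
    W = array(rtrunc_norm(P * K * D * cfg$n_primary, 0.05),
              c(P, K * D, cfg$n_primary)),
    ix1 = ix1, ix2a = ix2a, ix2b = ix2b)
  class(model) <- "capsnet_model"
  model
}

#' @export
print.capsnet_model <- function(x, ...) {
  print(x$cfg)
  cat(sprintf("  trainable parameters: %d\n", count_params(x)))
  invisible(x)
}

#' Count trainable parameters
#' @param model a `capsnet_model`.
#' @return integer parameter count.
#' @export
count_params <- function(model) {
  sum(vapply(model[c("km1", "b1", "km2a", "b2a", "km2b", "b2b", "W")],
             length, integer(1)))
}

param_names <- c("km1", "b1", "km2a", "b2a", "km2b", "b2b", "W")

## ---- forward pass ------------------------------------------------------

as_batch <- function(x, cfg) {
  # accept (h, w) matrix, (B, h, w) array, or (B, h, w, 1)
  if (is.matrix(x)) x <- array(x, c(1L, dim(x)))
  if (length(dim(x)) == 4L) x <- array(x, dim(x)[1:3])
  if (length(dim(x)) != 3L || any(dim(x)[2:3] != cfg$input_hw))
    stopf("input shape (%s) does not match configured (%d,%d)",
          paste(dim(x), collapse = ","), cfg$input_hw[1L], cfg$input_hw[2L])
  x
}

#' Convolutional feature extraction stage
#'
#' Con-1 (same-padded, ReLU) followed by the Con-2 stage (two stacked valid
#' convolutions, ReLU), shrinking each spatial dimension by
#' `2 * (kernel - 1)` overall: (19,18,1) -> (19,18,8) -> (13,12,8) in the
#' canonical configuration.
#'
#' @param model a `capsnet_model`.
#' @param x input batch: (h,w) matrix or (B,h,w) array.
#' @return feature array (B, h', w', filters).
#' @export
feature_extract <- function(model, x) {
  feature_extract_cached(model, as_batch(x, model$cfg))$f2b
}

feature_extract_cached <- function(model, x) {
  B <- dim(x)[1L]
  x4 <- array(x, c(dim(x), 1L))
  c1 <- conv_forward(x4, model$km1, model$b1, model$ix1)
  f1 <- pmax(c1$z, 0)
  c2a <- conv_forward(f1, model$km2a, model$b2a, model$ix2a)
  f2a <- pmax(c2a$z, 0)
  c2b <- conv_forward(f2a, model$km2b, model$b2b, model$ix2b)
  f2b <- pmax(c2b$z, 0)
  list(x4 = x4, z1 = c1$z, cols1 = c1$cols, f1 = f1,
       z2a = c2a$z, cols2a = c2a$cols, f2a = f2a,
       z2b = c2b$z, cols2b = c2b$cols, f2b = f2b, B = B)
}

#' Form primary capsules from a convolutional feature map
#'
#' The feature map is read out channel-fastest, then along columns, then
#' rows, grouped into `dim`-dimensional vectors, and squashed. No weights
#' are involved: 13*12*8 features become exactly 312 four-dimensional
#' capsules.
#'
#' @param features array (B, h', w', filters) from [feature_extract()].
#' @param dim capsule dimension (default 4).
#' @return array (B, n_capsules, dim) of squashed capsule vectors.
#' @export
to_primary_capsules <- function(features, dim = 4L) {
  d <- base::dim(features)
  if (length(d) == 3L) { features <- array(features, c(1L, d)); d <- base::dim(features) }
  N <- prod(d[2:4])
  if (N %% dim != 0L)
    stopf("feature map of %d values is not divisible into %d-D capsules", N, dim)
  pc <- primary_capsules_cached(features, as.integer(dim))
  pc$u
}

primary_capsules_cached <- function(features, P) {
  d <- base::dim(features)
  B <- d[1L]; I <- prod(d[2:4]) %/% P
  flat <- matrix(aperm(features, c(1L, 4L, 3L, 2L)), B, prod(d[2:4]))
  # flat columns run channel-fastest, then w', then h'; consecutive groups
  # of P columns form one capsule. Rows of S are (b, i) pairs, b fastest.
  arr <- array(flat, c(B, P, I))
  S <- matrix(aperm(arr, c(1L, 3L, 2L)), B * I, P)
  u_mat <- squash_rows(S)
  list(u = array(u_mat, c(B, I, P)), S = S, B = B, I = I, P = P)
}

# u: (B, I, P) -> u_hat: (B, I, K*D), u_hat[b,i,] = u[b,i,] %*% W[,,i].
# Vectorized over the primary-capsule axis: one broadcast product per input
# dimension p instead of a loop over the (up to 312) capsules.
predict_uhat <- function(model, u) {
  B <- dim(u)[1L]; I <- dim(u)[2L]; P <- dim(u)[3L]
  JD <- dim(model$W)[2L]
  u_hat <- array(0, c(B, I, JD))
  for (p in seq_len(P)) {
    up <- matrix(u[, , p], B, I)
    Wp <- rep(as.vector(t(model$W[p, , ])), each = B)  # (B,I,JD) layout
    u_hat <- u_hat + array(up, c(B, I, JD)) * array(Wp, c(B, I, JD))
  }
  u_hat
}

#' Dynamic routing-by-agreement
#'
#' Routing logits b start at zero. Each iteration: coupling coefficients
#' c[i,] are the softmax of b[i,] over the K label capsules (each primary
#' capsule distributes one unit of vote); the label pre-activation s_j is
#' the coupling-weighted sum of predictions u_hat[i,j]; v_j = squash(s_j);
#' and b[i,j] is incremented by the agreement dot product u_hat[i,j] . v_j
#' (skipped after the final iteration).
#'
#' @param u_hat prediction array: (n_primary, K, dim) for one sample or
#'   (B, n_primary, K, dim) for a batch.
#' @param r number of routing iterations (>= 1).
#' @return for one sample: `list(v, b, c, s)` with `v` (K x dim) the label
#'   capsules; for a batch the same with a leading batch dimension on each.
#' @export
dynamic_routing <- function(u_hat, r = 3L) {
  if (r < 1L) stopf("routing needs r >= 1 iterations")
  d <- dim(u_hat)
  single <- length(d) == 3L
  if (single) { u_hat <- array(u_hat, c(1L, d)); d <- dim(u_hat) }
  if (length(d) != 4L) stopf("u_hat must be (n_primary, K, dim) or (B, n_primary, K, dim)")
  B <- d[1L]; I <- d[2L]; K <- d[3L]; D <- d[4L]
  # routing_core works on (B, I, K*D) with the dim index fastest inside
  # each label-capsule block
  uh_blocks <- array(aperm(u_hat, c(1L, 2L, 4L, 3L)), c(B, I, K * D))
  rs <- routing_core(uh_blocks, K, D, as.integer(r))
  v <- array(rs$s_post, c(B, K, D))
  out <- list(v = v, b = rs$b, c = rs$c, s = rs$s)
  if (single) {
    out$v <- array(out$v, c(K, D)); out$s <- array(out$s, c(K, D))
    out$b <- matrix(out$b, I, K); out$c <- matrix(out$c, I, K)
  }
  out
}

# Batched routing. u_hat: (B, I, K*D) with label-capsule blocks of width D.
routing_core <- function(u_hat, K, D, r) {
  B <- dim(u_hat)[1L]; I <- dim(u_hat)[2L]
  b_log <- array(0, c(B, I, K))
  cpl <- NULL; s <- NULL; v <- NULL
  for (t in seq_len(r)) {
    mx <- b_log[, , 1L, drop = FALSE]
    if (K > 1L) for (j in 2:K) mx <- pmax(mx, b_log[, , j, drop = FALSE])
    e <- exp(b_log - array(mx, c(B, I, K)))
    cpl <- e / array(rowSums(matrix(e, B * I, K)), c(B, I, K))
    s <- array(0, c(B, K, D))
    v <- array(0, c(B, K, D))
    # sum over primary capsules as a matrix product with a block indicator
    sum_i <- kronecker(diag(D), matrix(1, I, 1))   # (I*D, D)
    for (j in seq_len(K)) {
      Uj <- u_hat[, , (j - 1L) * D + seq_len(D), drop = FALSE]
      cj <- cpl[, , j, drop = FALSE]
      prod_ <- Uj * array(cj, c(B, I, D))
      sj <- matrix(prod_, B, I * D) %*% sum_i        # (B, D)
      s[, j, ] <- sj
      v[, j, ] <- squash_rows(sj)
    }
    if (t < r) {
      for (j in seq_len(K)) {
        Uj <- u_hat[, , (j - 1L) * D + seq_len(D), drop = FALSE]
        vj <- matrix(v[, j, ], B, D)
        vex <- aperm(array(vj, c(B, D, I)), c(1L, 3L, 2L))
        agree <- matrix(rowSums(matrix(Uj * vex, B * I, D)), B, I)
        b_log[, , j] <- matrix(b_log[, , j], B, I) + agree
      }
    }
  }
  list(b = b_log, c = cpl, s = s, s_post = v)
}

#' Class presence probabilities from label capsules
#'
#' The Euclidean length of each label capsule is the probability that the
#' corresponding class is present; the predicted class is the longest
#' capsule, ties broken by the lowest class index.
#'
#' @param v label capsules: (K, dim) matrix or (B, K, dim) array.
#' @return numeric vector of K lengths (or a B x K matrix).
#' @export
class_probabilities <- function(v) {
  if (is.matrix(v)) return(sqrt(rowSums(v^2)))
  d <- dim(v)
  if (length(d) != 3L) stopf("v must be (K, dim) or (B, K, dim)")
  out <- matrix(0, d[1L], d[2L])
  for (j in seq_len(d[2L]))
    out[, j] <- sqrt(rowSums(matrix(v[, j, ], d[1L], d[3L])^2))
  out
}

#' Predicted class indices from a probability matrix
#' @param probs B x K matrix of capsule lengths.
#' @return integer vector of 0-based class predictions.
#' @export
predict_classes <- function(probs) {
  max.col(probs, ties.method = "first") - 1L
}

#' Margin loss on capsule lengths
#'
#' Per class k: `L_k = p_k * max(0, m+ - ||v_k||)^2 +
#' lambda * (1 - p_k) * max(0, ||v_k|| - m-)^2` with `p_k = 1` for the true
#' class and 0 otherwise. The sample loss sums over classes; the batch loss
#' is the mean over samples (optionally weighted per true class).
#'
#' @param lengths B x K matrix (or length-K vector) of capsule lengths.
#' @param labels integer vector of 0-based true classes.
#' @param m_plus,m_minus,lambda margin parameters (defaults 0.9, 0.1, 0.5).
#' @param class_weights optional length-K per-class loss multipliers.
#' @return `list(per_sample, batch)`.
#' @export
margin_loss <- function(lengths, labels, m_plus = 0.9, m_minus = 0.1,
                        lambda = 0.5, class_weights = NULL) {
  if (is.vector(lengths)) lengths <- matrix(lengths, nrow = 1L)
  if (any(lengths < -1e-6) || any(lengths > 1 + 1e-6))
    stopf("capsule lengths must lie in [0, 1]")
  B <- nrow(lengths); K <- ncol(lengths)
  labels <- as.integer(labels)
  if (length(labels) != B || any(labels < 0L) || any(labels >= K))
    stopf("labels must be 0..%d, one per sample", K - 1L)
  Pk <- matrix(0, B, K); Pk[cbind(seq_len(B), labels + 1L)] <- 1
  Lk <- Pk * pmax(0, m_plus - lengths)^2 +
    lambda * (1 - Pk) * pmax(0, lengths - m_minus)^2
  per_sample <- rowSums(Lk)
  wts <- if (is.null(class_weights)) rep(1, B) else class_weights[labels + 1L]
  list(per_sample = per_sample, batch = mean(per_sample * wts))
}

#' Full forward pass of the micro-capsule network
#'
#' Composes feature extraction, primary-capsule formation, per-pair
#' prediction, dynamic routing, and capsule lengths; when labels are given
#' the margin loss is evaluated too.
#'
#' @param model a `capsnet_model`.
#' @param x input batch: (h,w) matrix or (B,h,w) array.
#' @param labels optional 0-based class labels for the loss.
#' @param class_weights optional per-class loss multipliers.
#' @param keep_cache retain intermediates for [capsnet_backward()]?
#' @return list with `probs` (B x K capsule lengths), `pred` (0-based class
#'   predictions), `v` (B, K, dim) label capsules, `routing`
#'   (final coupling coefficients), `loss` (when labels given), and
#'   `cache` (when requested).
#' @export
capsnet_forward <- function(model, x, labels = NULL, class_weights = NULL,
                            keep_cache = FALSE) {
  cfg <- model$cfg
  x <- as_batch(x, cfg)
  fc <- feature_extract_cached(model, x)
  pc <- primary_capsules_cached(fc$f2b, cfg$primary_dim)
  u_hat <- predict_uhat(model, pc$u)
  rs <- routing_core(u_hat, cfg$n_classes, cfg$label_dim, cfg$routing_iters)
  B <- pc$B; K <- cfg$n_classes; D <- cfg$label_dim
  lengths <- matrix(0, B, K)
  for (j in seq_len(K))
    lengths[, j] <- sqrt(rowSums(matrix(rs$s_post[, j, ], B, D)^2))
  out <- list(probs = lengths, pred = predict_classes(lengths),
              v = rs$s_post, routing = rs$c)
  if (!is.null(labels)) {
    ml <- margin_loss(lengths, labels, cfg$m_plus, cfg$m_minus, cfg$lambda,
                      class_weights)
    out$loss <- ml$batch
    out$per_sample_loss <- ml$per_sample
  }
  if (keep_cache)
    out$cache <- list(fc = fc, pc = pc, u_hat = u_hat, rs = rs,
                      lengths = lengths, labels = labels,
                      class_weights = class_weights)
  out
}

## ---- backward pass -----------------------------------------------------

# Gradient of the batch-mean margin loss wrt all trainable weights. The
# converged coupling coefficients are treated as constants (the gradient
# flows through the final weighted sum and squash, not through the
# softmax/agreement recursion); with r = 1 this is exact.
capsnet_backward <- function(model, fwd) {
  cfg <- model$cfg
  ca <- fwd$cache
  B <- ca$pc$B; I <- ca$pc$I; P <- ca$pc$P
  K <- cfg$n_classes; D <- cfg$label_dim
  lengths <- ca$lengths; labels <- as.integer(ca$labels)

  wts <- if (is.null(ca$class_weights)) rep(1, B) else ca$class_weights[labels + 1L]
  Pk <- matrix(0, B, K); Pk[cbind(seq_len(B), labels + 1L)] <- 1
  g_len <- (Pk * (-2) * pmax(0, cfg$m_plus - lengths) +
              cfg$lambda * (1 - Pk) * 2 * pmax(0, lengths - cfg$m_minus)) *
    (wts / B)

  g_uhat <- array(0, c(B, I, K * D))
  for (j in seq_len(K)) {
    vj <- matrix(ca$rs$s_post[, j, ], B, D)
    sj <- matrix(ca$rs$s[, j, ], B, D)
    lj <- pmax(lengths[, j], 1e-8)
    g_v <- vj * (g_len[, j] / lj)
    g_s <- squash_rows_backward(sj, g_v)
    cj <- ca$rs$c[, , j, drop = FALSE]
    gex <- aperm(array(g_s, c(B, D, I)), c(1L, 3L, 2L))
    g_uhat[, , (j - 1L) * D + seq_len(D)] <-
      array(cj, c(B, I, D)) * gex
  }

  # g_W[p,jd,i] = sum_b u[b,i,p] g_uhat[b,i,jd];
  # g_u[b,i,p] = sum_jd g_uhat[b,i,jd] W[p,jd,i] -- vectorized per p
  JD <- K * D
  g_W <- array(0, dim(model$W))
  g_u <- array(0, c(B, I, P))
  for (p in seq_len(P)) {
    up <- matrix(ca$pc$u[, , p], B, I)
    M <- array(up, c(B, I, JD)) * g_uhat
    g_W[p, , ] <- t(matrix(colSums(matrix(M, B, I * JD)), I, JD))
    Wp <- rep(as.vector(t(model$W[p, , ])), each = B)
    g_u[, , p] <- matrix(rowSums(matrix(g_uhat * array(Wp, c(B, I, JD)),
                                        B * I, JD)), B, I)
  }

  # rows of pc$S are (b, i) pairs with b fastest, matching matrix(g_u, ...)
  g_S <- squash_rows_backward(ca$pc$S, matrix(g_u, B * I, P))

  # back through the reshape: (B*I, P) -> flat (B, N) channel-fastest ->
  # feature map (B, h', w', F)
  hp <- cfg$feat_hw[1L]; wp <- cfg$feat_hw[2L]; Fc <- cfg$conv_filters
  g_flat <- matrix(aperm(array(g_S, c(B, I, P)), c(1L, 3L, 2L)), B, I * P)
  g_f2b <- aperm(array(g_flat, c(B, Fc, wp, hp)), c(1L, 4L, 3L, 2L))

  g_z2b <- g_f2b * (ca$fc$z2b > 0)
  bw2b <- conv_backward(g_z2b, ca$fc$cols2b, model$km2b, model$ix2b)
  g_z2a <- bw2b$g_x * (ca$fc$z2a > 0)
  bw2a <- conv_backward(g_z2a, ca$fc$cols2a, model$km2a, model$ix2a)
  g_z1 <- bw2a$g_x * (ca$fc$z1 > 0)
  bw1 <- conv_backward(g_z1, ca$fc$cols1, model$km1, model$ix1,
                       need_input_grad = FALSE)

  list(km1 = bw1$g_km, b1 = bw1$g_b,
       km2a = bw2a$g_km, b2a = bw2a$g_b,
       km2b = bw2b$g_km, b2b = bw2b$g_b,
       W = g_W)
}

## ---- checkpoints -------------------------------------------------------

#' Save a model (weights + configuration) as a single JSON checkpoint
#' @param model a `capsnet_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  payload <- list(
    cfg = unclass(model$cfg),
    weights = lapply(model[param_names], function(wt) {
      list(dim = if (is.null(dim(wt))) length(wt) else dim(wt),
           values = as.vector(wt))
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a JSON checkpoint, verifying weight shapes against its configuration
#' @param path checkpoint path.
#' @return a `capsnet_model`.
#' @export
load_checkpoint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cf <- payload$cfg
  cfg <- capsnet_config(
    input_hw = cf$input_hw, n_classes = cf$n_classes,
    routing_iters = cf$routing_iters, conv_filters = cf$conv_filters,
    conv_kernel = cf$conv_kernel, primary_dim = cf$primary_dim,
    label_dim = cf$label_dim, m_plus = cf$m_plus, m_minus = cf$m_minus,
    lambda = cf$lambda, loss_threshold = cf$loss_threshold)
  model <- init_capsnet(cfg, seed = 0L)
  for (nm in param_names) {
    wt <- payload$weights[[nm]]
    want <- if (is.null(dim(model[[nm]]))) length(model[[nm]]) else dim(model[[nm]])
    if (!identical(as.integer(wt$dim), as.integer(want)))
      stopf("checkpoint %s: weight %s has shape (%s), expected (%s)",
            path, nm, paste(wt$dim, collapse = ","),
            paste(want, collapse = ","))
    arr <- wt$values
    if (length(wt$dim) > 1L) arr <- array(arr, wt$dim)
    if (is.matrix(model[[nm]])) arr <- matrix(arr, wt$dim[1L], wt$dim[2L])
    model[[nm]] <- arr
  }
  model
}
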