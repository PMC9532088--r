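# Dense-block network engine: explicit forward and backward passes over
# (H, W, C, N) arrays. Convolution and 2x2 average pooling run through the
# compiled im2col kernels in src/; batch norm, ReLU, global average pooling
# and the softmax head are vectorized R. The execution plan is fixed by the
# arch_config: stem conv (+ stem pooling), dense blocks of BN-ReLU-conv3x3
# layers with concatenation, transitions of BN-ReLU-conv1x1-avgpool with
# optional Log-Gabor channel concatenation, then BN-ReLU-GAP-softmax.

tensor_cat <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

to_cmat <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
}

from_cmat <- function(m, d) {
  aperm(array(m, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

bn_forward <- function(x, gamma, beta, state, training,
                       eps = 1e-5, momentum = 0.1) {
  xm <- to_cmat(x)
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    v[v < 0] <- 0
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v
  } else {
    mu <- state$mean
    v <- state$var
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, istd, "*")
  ym <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(y = from_cmat(ym, dim(x)), state = state,
       cache = list(xhat = xhat, istd = istd, gamma = gamma, d = dim(x),
                    training = training))
}

bn_backward <- function(dy, cache) {
  dym <- to_cmat(dy)
  xhat <- cache$xhat
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2, cache$gamma, "*")
  if (cache$training) {
    m <- nrow(dym)
    C <- ncol(dym)
    mean_dxhat <- matrix(colMeans(dxhat), m, C, byrow = TRUE)
    mean_dxhat_xhat <- matrix(colMeans(dxhat * xhat), m, C, byrow = TRUE)
    dxm <- sweep(dxhat - mean_dxhat - xhat * mean_dxhat_xhat, 2,
                 cache$istd, "*")
  } else {
    dxm <- sweep(dxhat, 2, cache$istd, "*")
  }
  list(dx = from_cmat(dxm, cache$d), dgamma = dgamma, dbeta = dbeta)
}

conv_init <- function(kh, cin, cout) {
  matrix(stats::rnorm(kh * kh * cin * cout, 0, sqrt(2 / (kh * kh * cin))),
         nrow = kh * kh * cin, ncol = cout)
}

# Execution plan: ordered channel bookkeeping shared by init/forward/backward.
nn_plan <- function(config) {
  k_fuse <- fusion_channels(config)
  nb <- length(config$block_sizes)
  plan <- list(
    stem_pools = as.integer(round(log2(config$stem_downsample))),
    k_fuse = k_fuse, nb = nb,
    fuse_first = k_fuse > 0 && config$fusion_site == "block_input",
    block_in = integer(nb), trans_in = integer(nb - 1)
  )
  ch <- config$stem_channels
  if (plan$fuse_first) ch <- ch + k_fuse
  for (b in seq_len(nb)) {
    plan$block_in[b] <- ch
    ch <- ch + config$block_sizes[b] * config$growth_rate
    if (b < nb) {
      plan$trans_in[b] <- ch
      ch <- floor(ch * config$compression)
      if (k_fuse > 0) ch <- ch + k_fuse
    }
  }
  plan$final_channels <- ch
  plan
}

#' Initialize network weights
#'
#' He-normal convolution weights, unit-gamma/zero-beta batch norm, and a
#' zero-bias softmax head, drawn from the given seed so initialization is
#' reproducible.
#'
#' @param spec A [build_backbone()] result.
#' @param seed Integer seed.
#' @return A list with `params` (named list of weight arrays) and `bn_state`
#'   (named list of running mean/var per batch-norm layer).
#' @export
init_network <- function(spec, seed = 1) {
  config <- spec$config
  plan <- nn_plan(config)
  params <- list()
  bn_state <- list()
  withr::with_seed(as.integer(seed), {
    params$stem.w <- conv_init(3, config$in_channels, config$stem_channels)
    params$stem.b <- numeric(config$stem_channels)
    for (b in seq_len(plan$nb)) {
      cin <- plan$block_in[b]
      for (l in seq_len(config$block_sizes[b])) {
        p <- sprintf("b%d.l%d", b, l)
        params[[paste0(p, ".bn.gamma")]] <- rep(1, cin)
        params[[paste0(p, ".bn.beta")]] <- numeric(cin)
        bn_state[[p]] <- list(mean = numeric(cin), var = rep(1, cin))
        params[[paste0(p, ".conv.w")]] <- conv_init(3, cin, config$growth_rate)
        params[[paste0(p, ".conv.b")]] <- numeric(config$growth_rate)
        cin <- cin + config$growth_rate
      }
      if (b < plan$nb) {
        p <- sprintf("t%d", b)
        cin <- plan$trans_in[b]
        cout <- floor(cin * config$compression)
        params[[paste0(p, ".bn.gamma")]] <- rep(1, cin)
        params[[paste0(p, ".bn.beta")]] <- numeric(cin)
        bn_state[[p]] <- list(mean = numeric(cin), var = rep(1, cin))
        params[[paste0(p, ".conv.w")]] <- conv_init(1, cin, cout)
        params[[paste0(p, ".conv.b")]] <- numeric(cout)
      }
    }
    cf <- plan$final_channels
    params$final.bn.gamma <- rep(1, cf)
    params$final.bn.beta <- numeric(cf)
    bn_state$final <- list(mean = numeric(cf), var = rep(1, cf))
    params$head.w <- matrix(stats::rnorm(config$num_classes * cf, 0,
                                         sqrt(1 / cf)),
                            nrow = config$num_classes, ncol = cf)
    params$head.b <- numeric(config$num_classes)
  })
  list(params = params, bn_state = bn_state)
}

# One BN-ReLU-conv step. Returns output, caches (post-ReLU activation doubles
# as the conv input and the ReLU mask source).
bnrc_forward <- function(x, params, bn_state, prefix, k, training) {
  bn <- bn_forward(x, params[[paste0(prefix, ".bn.gamma")]],
                   params[[paste0(prefix, ".bn.beta")]],
                   bn_state[[prefix]], training)
  a <- bn$y
  a[a < 0] <- 0
  y <- cpp_conv2d_forward(a, params[[paste0(prefix, ".conv.w")]],
                          params[[paste0(prefix, ".conv.b")]], k, k)
  list(y = y, state = bn$state,
       cache = list(bn = bn$cache, a = a, k = k))
}

bnrc_backward <- function(dy, params, prefix, cache, grads) {
  cb <- cpp_conv2d_backward(cache$a, params[[paste0(prefix, ".conv.w")]],
                            dy, cache$k, cache$k)
  grads[[paste0(prefix, ".conv.w")]] <- cb$dw
  grads[[paste0(prefix, ".conv.b")]] <- cb$db
  da <- cb$dx
  da[cache$a <= 0] <- 0
  bb <- bn_backward(da, cache$bn)
  grads[[paste0(prefix, ".bn.gamma")]] <- bb$dgamma
  grads[[paste0(prefix, ".bn.beta")]] <- bb$dbeta
  list(dx = bb$dx, grads = grads)
}

#' Forward pass of the network
#'
#' @param params,bn_state From [init_network()] (or a trained fit).
#' @param spec A [build_backbone()] result.
#' @param x Input batch, array of dim (H, W, in_channels, N).
#' @param gmaps For fusion: list of standardized Log-Gabor map arrays, one
#'   per fusion site, each of dim (H_site, W_site, K, N); `NULL` otherwise.
#' @param training Batch-norm mode; `TRUE` also builds the backward cache.
#' @return List with `logits` (classes x N), `probs`, updated `bn_state`,
#'   and `cache` (when `training`).
#' @export
network_forward <- function(params, bn_state, spec, x, gmaps = NULL,
                            training = FALSE) {
  config <- spec$config
  plan <- nn_plan(config)
  keep_cache <- training
  cache <- list(blocks = vector("list", plan$nb),
                trans = vector("list", plan$nb - 1))
  if (plan$k_fuse > 0 && is.null(gmaps)) {
    stop("fusion is enabled but no Log-Gabor maps were supplied",
         call. = FALSE)
  }
  X <- cpp_conv2d_forward(x, params$stem.w, params$stem.b, 3L, 3L)
  cache$stem_x <- if (keep_cache) x
  cache$stem_pool_dims <- list()
  if (plan$stem_pools > 0) {
    for (i in seq_len(plan$stem_pools)) {
      cache$stem_pool_dims[[i]] <- dim(X)
      X <- cpp_avgpool2_forward(X)
    }
  }
  site <- 0L
  if (plan$fuse_first) {
    site <- site + 1L
    X <- tensor_cat(X, gmaps[[site]])
  }
  for (b in seq_len(plan$nb)) {
    nl <- config$block_sizes[b]
    bcache <- vector("list", nl)
    for (l in seq_len(nl)) {
      p <- sprintf("b%d.l%d", b, l)
      st <- bnrc_forward(X, params, bn_state, p, 3L, training)
      bn_state[[p]] <- st$state
      if (keep_cache) bcache[[l]] <- st$cache
      X <- tensor_cat(X, st$y)
    }
    cache$blocks[[b]] <- bcache
    if (b < plan$nb) {
      p <- sprintf("t%d", b)
      st <- bnrc_forward(X, params, bn_state, p, 1L, training)
      bn_state[[p]] <- st$state
      tc <- st$cache
      tc$pool_dim <- dim(st$y)
      X <- cpp_avgpool2_forward(st$y)
      if (plan$k_fuse > 0) {
        site <- site + 1L
        tc$pre_fuse_channels <- dim(X)[3]
        X <- tensor_cat(X, gmaps[[site]])
      }
      if (keep_cache) cache$trans[[b]] <- tc
    }
  }
  bn <- bn_forward(X, params$final.bn.gamma, params$final.bn.beta,
                   bn_state$final, training)
  bn_state$final <- bn$state
  A <- bn$y
  A[A < 0] <- 0
  d <- dim(A)
  feat <- matrix(colMeans(matrix(A, nrow = d[1] * d[2])), nrow = d[3])
  logits <- params$head.w %*% feat + params$head.b
  probs <- softmax_probs(logits)
  if (keep_cache) {
    cache$final_bn <- bn$cache
    cache$final_a <- A
    cache$feat <- feat
  }
  list(logits = logits, probs = probs, bn_state = bn_state,
       cache = if (keep_cache) cache)
}

softmax_probs <- function(logits) {
  shifted <- sweep(logits, 2, apply(logits, 2, max))
  e <- exp(shifted)
  sweep(e, 2, colSums(e), "/")
}

#' Backward pass: parameter gradients of the mean cross-entropy loss
#'
#' @param params Network parameters.
#' @param spec The `network_spec` used in the forward pass.
#' @param fwd Result of [network_forward()] with `training = TRUE`.
#' @param y_true Integer class labels (1-based) for the batch.
#' @return A named list of gradients matching `params`.
#' @export
network_backward <- function(params, spec, fwd, y_true) {
  config <- spec$config
  plan <- nn_plan(config)
  cache <- fwd$cache
  n <- length(y_true)
  dlogits <- fwd$probs
  dlogits[cbind(y_true, seq_len(n))] <-
    dlogits[cbind(y_true, seq_len(n))] - 1
  dlogits <- dlogits / n
  grads <- list()
  grads$head.w <- dlogits %*% t(cache$feat)
  grads$head.b <- rowSums(dlogits)
  dfeat <- t(params$head.w) %*% dlogits
  d <- dim(cache$final_a)
  dA <- array(rep(dfeat, each = d[1] * d[2]) / (d[1] * d[2]), dim = d)
  dA[cache$final_a <= 0] <- 0
  bb <- bn_backward(dA, cache$final_bn)
  grads$final.bn.gamma <- bb$dgamma
  grads$final.bn.beta <- bb$dbeta
  dX <- bb$dx
  for (b in rev(seq_len(plan$nb))) {
    nl <- config$block_sizes[b]
    cin_last <- plan$block_in[b] + (nl - 1) * config$growth_rate
    for (l in rev(seq_len(nl))) {
      cin <- plan$block_in[b] + (l - 1) * config$growth_rate
      d_new <- dX[, , cin + seq_len(config$growth_rate), , drop = FALSE]
      dX <- dX[, , seq_len(cin), , drop = FALSE]
      p <- sprintf("b%d.l%d", b, l)
      res <- bnrc_backward(d_new, params, p, cache$blocks[[b]][[l]], grads)
      grads <- res$grads
      dX <- dX + res$dx
    }
    if (b > 1) {
      tb <- b - 1
      tc <- cache$trans[[tb]]
      if (plan$k_fuse > 0) {
        dX <- dX[, , seq_len(tc$pre_fuse_channels), , drop = FALSE]
      }
      dX <- cpp_avgpool2_backward(dX, tc$pool_dim[1], tc$pool_dim[2])
      p <- sprintf("t%d", tb)
      res <- bnrc_backward(dX, params, p, tc, grads)
      grads <- res$grads
      dX <- res$dx
    }
  }
  if (plan$fuse_first) {
    dX <- dX[, , seq_len(config$stem_channels), , drop = FALSE]
  }
  if (plan$stem_pools > 0) {
    for (i in rev(seq_along(cache$stem_pool_dims))) {
      dm <- cache$stem_pool_dims[[i]]
      dX <- cpp_avgpool2_backward(dX, dm[1], dm[2])
    }
  }
  cb <- cpp_conv2d_backward(cache$stem_x, params$stem.w, dX, 3L, 3L)
  grads$stem.w <- cb$dw
  grads$stem.b <- cb$db
  grads
}

#' Mean cross-entropy loss and accuracy of a batch of probabilities
#' @param probs classes x N probability matrix.
#' @param y_true Integer labels (1-based).
#' @return List with `loss` and `acc`.
#' @export
xent_loss <- function(probs, y_true) {
  n <- length(y_true)
  p <- pmax(probs[cbind(y_true, seq_len(n))], 1e-12)
  pred <- apply(probs, 2, which.max)
  list(loss = -mean(log(p)), acc = mean(pred == y_true))
}
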