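# Deep ConvNet engine for the two fusion classifiers.
#
# Activations flow as arrays [time, batch, channels]; convolutions are
# im2col gathers followed by BLAS matrix multiplies, so training runs at
# practical speed in plain R. All convolutions are valid-padded with
# stride 1 along time; all max-pools have size 2, stride 2, flooring odd
# lengths.

SENSOR_SETS <- list(
  "eeg" = list(eeg = 1:6),
  "eeg+spr" = list(eeg = 1:6, spr = 7L),
  "eeg+ecg" = list(eeg = 1:6, ecg = 8L),
  "eeg+spr+ecg" = list(eeg = 1:6, spr = 7L, ecg = 8L)
)

#' Model specification for the fusion classifiers
#'
#' Captures architecture kind, sensor configuration and training
#' hyperparameters. Defaults follow the protocol: dropout 0.38 and dense
#' L2 penalty 1.3 for the data-level network with at most 200 epochs and
#' early-stopping patience 50; dropout 0.5, L2 0.7, 50 epochs and patience
#' 20 for the feature-level network; Adam at learning rate 1e-3 with batch
#' size 128 for both.
#'
#' @param arch `"data_fusion"` (one network over the concatenated 2D input
#'   array) or `"feature_fusion"` (one branch per sensor, features
#'   concatenated before two dense layers).
#' @param sensors sensor configuration: `"eeg"`, `"eeg+spr"`, `"eeg+ecg"`
#'   or `"eeg+spr+ecg"`.
#' @param window_samples samples per segment (600 for 3 s at 200 Sa/s).
#' @param dropout dropout fraction; arch-dependent default.
#' @param l2_penalty L2 penalty on dense-layer weight matrices;
#'   arch-dependent default.
#' @param dense_hidden hidden dense width of the feature-level head.
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param max_epochs,patience training budget and early-stopping patience;
#'   arch-dependent defaults.
#' @param val_fraction fraction of the training segments carved out
#'   (stratified, seeded) to monitor early stopping.
#' @param seed integer seed for weight initialization, the validation
#'   split, shuffling and dropout.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(arch = c("data_fusion", "feature_fusion"),
                       sensors = c("eeg+spr+ecg", "eeg", "eeg+spr", "eeg+ecg"),
                       window_samples = 600L,
                       dropout = NULL, l2_penalty = NULL,
                       dense_hidden = 500L,
                       learning_rate = 1e-3, batch_size = 128L,
                       max_epochs = NULL, patience = NULL,
                       val_fraction = 0.1, seed = 1L) {
  arch <- match.arg(arch)
  sensors <- match.arg(sensors)
  data_level <- arch == "data_fusion"
  spec <- list(
    arch = arch, sensors = sensors,
    window_samples = as.integer(window_samples),
    dropout = if (is.null(dropout)) (if (data_level) 0.38 else 0.5) else dropout,
    l2_penalty = if (is.null(l2_penalty)) (if (data_level) 1.3 else 0.7) else l2_penalty,
    dense_hidden = as.integer(dense_hidden),
    n_classes = 2L,
    learning_rate = learning_rate,
    batch_size = as.integer(batch_size),
    max_epochs = if (is.null(max_epochs)) (if (data_level) 200L else 50L)
                 else as.integer(max_epochs),
    patience = if (is.null(patience)) (if (data_level) 50L else 20L)
               else as.integer(patience),
    val_fraction = val_fraction,
    seed = as.integer(seed))
  structure(spec, class = "model_spec")
}

#' Time-length chain of the four-block ConvNet
#'
#' Valid kernel-5 convolutions shrink the time axis by 4; max-pools halve
#' it with floor. For a 600-sample input the chain is
#' 600, 596, 298, 294, 147, 143, 71, 67, 33.
#'
#' @param window_samples input length in samples.
#' @return integer vector of the nine time lengths (input, then after each
#'   conv and pool); errors if any stage becomes too short.
#' @export
deep4_time_chain <- function(window_samples) {
  t <- as.integer(window_samples)
  chain <- t
  for (blk in 1:4) {
    if (t < 5L)
      stop(sprintf("architecture error: input of %d samples too short for four conv/pool blocks",
                   window_samples))
    t <- t - 4L
    chain <- c(chain, t)
    t <- t %/% 2L
    if (t < 1L)
      stop(sprintf("architecture error: input of %d samples too short for four conv/pool blocks",
                   window_samples))
    chain <- c(chain, t)
  }
  chain
}

#' Minimal input length accepted by the architecture
#'
#' @return smallest number of samples for which [deep4_time_chain()] is
#'   valid.
#' @export
deep4_min_input <- function() {
  t <- 5L
  while (inherits(try(deep4_time_chain(t), silent = TRUE), "try-error"))
    t <- t + 1L
  t
}

glorot <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

op_tconv <- function(k, c_out) {
  list(type = "tconv", k = k,
       W = glorot(k, k * c_out, c(k, c_out)), b = numeric(c_out))
}
op_sconv <- function(e, f_in, f_out) {
  list(type = "sconv", e = e,
       W = glorot(e * f_in, f_out, c(e * f_in, f_out)), b = numeric(f_out))
}
op_conv <- function(k, c_in, c_out) {
  list(type = "conv", k = k,
       W = glorot(k * c_in, k * c_out, c(k * c_in, c_out)),
       b = numeric(c_out))
}
op_bn <- function(c) {
  list(type = "bn", gamma = rep(1, c), beta = numeric(c),
       run_mean = numeric(c), run_var = rep(1, c))
}
op_dense <- function(f_in, f_out, l2 = 0, activation = "linear") {
  list(type = "dense", l2 = l2, activation = activation,
       W = glorot(f_in, f_out, c(f_in, f_out)), b = numeric(f_out))
}

# one BD-Deep4 branch: block 1 (temporal conv, optional spatial conv over
# all electrode rows) then three conv blocks of 50/100/200 filters
make_branch <- function(channels, spatial, dropout, window_samples) {
  e <- length(channels)
  ops <- list(op_tconv(5L, 25L))
  if (spatial) ops <- c(ops, list(op_sconv(e, 25L, 25L)))
  ops <- c(ops, list(op_bn(25L), list(type = "elu"), list(type = "pool"),
                     list(type = "drop", p = dropout)))
  widths <- c(25L, 50L, 100L, 200L)
  for (i in 2:4) {
    ops <- c(ops, list(op_conv(5L, widths[i - 1], widths[i]), op_bn(widths[i]),
                       list(type = "elu"), list(type = "pool"),
                       list(type = "drop", p = dropout)))
  }
  chain <- deep4_time_chain(window_samples)
  list(channels = channels, spatial = spatial, ops = ops,
       flat_dim = chain[length(chain)] * 200L)
}

#' Build the data-level fusion network
#'
#' A single four-block deep ConvNet over the synchronized 2D input array
#' (600 samples x NChannels rows): temporal convolution (25 kernels of
#' length 5), spatial convolution spanning all input rows, batch
#' normalization with trainable scale and shift, ELU, max-pool and dropout;
#' three further conv blocks of 50/100/200 filters; then a flatten and a
#' 2-unit softmax dense layer carrying the L2 penalty.
#'
#' @param spec a [model_spec] with `arch = "data_fusion"`.
#' @return an object of class `bd_net`.
#' @export
build_data_fusion <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$arch != "data_fusion")
    stop("spec$arch must be 'data_fusion'")
  set.seed(spec$seed)
  channels <- sort(unique(unlist(SENSOR_SETS[[spec$sensors]])))
  branch <- make_branch(channels, spatial = TRUE, dropout = spec$dropout,
                        window_samples = spec$window_samples)
  head <- list(op_dense(branch$flat_dim, spec$n_classes,
                        l2 = spec$l2_penalty, activation = "softmax"))
  structure(list(spec = spec, branches = list(branch), head = head),
            class = "bd_net")
}

#' Build the feature-level fusion network (ConvNet-Fus)
#'
#' One BD-Deep4 branch per sensor group: the EEG branch has both the
#' temporal and the spatial convolution in block 1; single-channel SPR and
#' ECG branches have the temporal convolution only. Each branch flattens to
#' 6,600 features (600-sample input); branch outputs are concatenated and
#' fed through a 500-unit ReLU dense layer and a 2-unit softmax layer,
#' both carrying the L2 penalty.
#'
#' @param spec a [model_spec] with `arch = "feature_fusion"`.
#' @return an object of class `bd_net`.
#' @export
build_feature_fusion <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$arch != "feature_fusion")
    stop("spec$arch must be 'feature_fusion'")
  set.seed(spec$seed)
  groups <- SENSOR_SETS[[spec$sensors]]
  if (!length(groups)) stop("architecture error: empty branch list")
  branches <- lapply(names(groups), function(g) {
    make_branch(groups[[g]], spatial = g == "eeg", dropout = spec$dropout,
                window_samples = spec$window_samples)
  })
  flat_total <- sum(vapply(branches, `[[`, 1L, "flat_dim"))
  head <- list(op_dense(flat_total, spec$dense_hidden,
                        l2 = spec$l2_penalty, activation = "relu"),
               op_dense(spec$dense_hidden, spec$n_classes,
                        l2 = spec$l2_penalty, activation = "softmax"))
  structure(list(spec = spec, branches = branches, head = head),
            class = "bd_net")
}

#' Build a network from a model specification
#'
#' @param spec a [model_spec].
#' @return a `bd_net`.
#' @export
build_network <- function(spec) {
  if (spec$arch == "data_fusion") build_data_fusion(spec)
  else build_feature_fusion(spec)
}

#' Count trainable parameters
#'
#' Sums weights, biases and batch-norm scale/shift pairs over all layers;
#' batch-norm running statistics are not trainable and are excluded.
#'
#' @param net a `bd_net`.
#' @return integer parameter count.
#' @export
count_trainable_parameters <- function(net) {
  stopifnot(inherits(net, "bd_net"))
  cnt <- 0L
  for (op in all_ops(net)) {
    for (f in c("W", "b", "gamma", "beta"))
      if (!is.null(op[[f]])) cnt <- cnt + length(op[[f]])
  }
  cnt
}

all_ops <- function(net) {
  c(unlist(lapply(net$branches, `[[`, "ops"), recursive = FALSE), net$head)
}

#' @export
print.bd_net <- function(x, ...) {
  cat(sprintf("<bd_net> %s, sensors %s, input %d samples\n",
              x$spec$arch, x$spec$sensors, x$spec$window_samples))
  cat(sprintf("  %d branch(es), %s trainable parameters\n",
              length(x$branches),
              format(count_trainable_parameters(x), big.mark = ",")))
  invisible(x)
}

## ---- forward / backward primitives ------------------------------------

## ---- branch and head passes -------------------------------------------

branch_fwd <- function(br, x, train) {
  d <- dim(x)                       # [T, B, E]
  bsz <- d[2]; e <- d[3]
  caches <- vector("list", length(br$ops))
  ops <- br$ops
  cur <- x
  i <- 1L
  # block 1: the temporal and spatial convolutions compose linearly, so
  # spatial branches evaluate them as one im2col gemm with the effective
  # kernel W1 o W2 (the parameter tensors stay separate for counting and
  # optimization); the huge per-electrode temporal intermediate is never
  # materialized
  if (br$spatial) {
    op1 <- ops[[1L]]; op2 <- ops[[2L]]
    eff <- fused_block1_weights(op1, op2, op1$k, e)
    cur <- cpp_conv1d_fwd(x, d, eff$W, eff$b, op1$k)
    caches[[1L]] <- list(x = x, dimx = d, k = op1$k, e = e)
    i <- 3L
  } else {
    op1 <- ops[[1L]]
    dim(cur) <- c(d[1], bsz * e, 1L)
    x1 <- cur
    cur <- cpp_conv1d_fwd(x1, dim(x1), op1$W, op1$b, op1$k)
    caches[[1L]] <- list(x = x1, dimx = dim(x1))
    dim(cur) <- c(dim(cur)[1], bsz, 25L)
    i <- 2L
  }
  while (i <= length(ops)) {
    op <- ops[[i]]
    if (op$type == "conv") {
      dimx <- dim(cur)
      y <- cpp_conv1d_fwd(cur, dimx, op$W, op$b, op$k)
      caches[[i]] <- list(x = cur, dimx = dimx)
      cur <- y
    } else if (op$type == "bn") {
      d3 <- dim(cur)
      bf <- cpp_bn_fwd(cur, d3[1] * d3[2], d3[3], op$gamma, op$beta,
                       train, op$run_mean, op$run_var, 1e-5)
      if (train) {
        # cumulative average early so inference statistics are usable
        # after very few updates, exponential (0.9) once warmed up
        step <- (op$bn_steps %||% 0L) + 1L
        mom <- min(0.9, 1 - 1 / step)
        op$run_mean <- mom * op$run_mean + (1 - mom) * bf$mu
        op$run_var <- mom * op$run_var + (1 - mom) * bf$var
        op$bn_steps <- step
        ops[[i]] <- op
      }
      caches[[i]] <- list(x = cur, mu = bf$mu, isd = bf$isd, d = d3)
      cur <- bf$y
      dim(cur) <- d3
    } else if (op$type == "elu") {
      d3 <- dim(cur)
      cur <- cpp_elu_fwd(cur)
      dim(cur) <- d3
      caches[[i]] <- list(y = cur)
    } else if (op$type == "pool") {
      dimx <- dim(cur)
      pf <- cpp_pool_fwd(cur, dimx)
      caches[[i]] <- list(first = pf$first, dimx = dimx)
      cur <- pf$y
    } else if (op$type == "drop") {
      if (train && op$p > 0) {
        d3 <- dim(cur)
        dr <- cpp_dropout(cur, op$p)
        caches[[i]] <- dr$mask
        cur <- dr$y
        dim(cur) <- d3
      } else caches[i] <- list(NULL)
    }
    i <- i + 1L
  }
  dflat <- dim(cur)                    # [T, B, C] -> B x (T*C)
  flat <- aperm(cur, c(2, 1, 3))
  dim(flat) <- c(bsz, dflat[1] * dflat[3])
  br$ops <- ops
  list(y = flat, caches = caches, dflat = dflat, br = br)
}

branch_bwd <- function(br, fwd, dflat_y) {
  dflat <- fwd$dflat
  bsz <- dflat[2]
  dcur <- array(dflat_y, c(bsz, dflat[1], dflat[3]))
  dcur <- aperm(dcur, c(2, 1, 3))
  grads <- vector("list", length(br$ops))
  first <- if (br$spatial) 2L else 1L    # ops consumed by the entry block
  for (i in seq.int(length(br$ops), first + 1L)) {
    op <- br$ops[[i]]
    cache <- fwd$caches[[i]]
    if (op$type == "drop") {
      if (!is.null(cache)) dcur <- dcur * cache
    } else if (op$type == "pool") {
      dcur <- cpp_pool_bwd(dcur, cache$first, cache$dimx)
    } else if (op$type == "elu") {
      d3 <- dim(dcur)
      dcur <- cpp_elu_bwd(dcur, cache$y)
      dim(dcur) <- d3
    } else if (op$type == "bn") {
      bb <- cpp_bn_bwd(cache$x, dcur, cache$d[1] * cache$d[2], cache$d[3],
                       op$gamma, cache$mu, cache$isd)
      grads[[i]] <- list(dgamma = bb$dgamma, dbeta = bb$dbeta)
      dcur <- bb$dx
      dim(dcur) <- cache$d
    } else if (op$type == "conv") {
      cb <- cpp_conv1d_bwd(cache$x, cache$dimx, dcur, op$W, op$k, TRUE)
      grads[[i]] <- list(dW = cb$dW, db = cb$db)
      dcur <- cb$dx
    }
  }
  # entry block; input gradients are never needed, only parameter ones
  if (br$spatial) {
    cache <- fwd$caches[[1L]]
    op1 <- br$ops[[1L]]; op2 <- br$ops[[2L]]
    eff <- fused_block1_weights(op1, op2, cache$k, cache$e)
    cb <- cpp_conv1d_bwd(cache$x, cache$dimx, dcur, eff$W, cache$k, FALSE)
    g <- fused_block1_unmix(cb$dW, cb$db, op1, op2, cache$k, cache$e)
    grads[[1L]] <- g$g1
    grads[[2L]] <- g$g2
  } else {
    cache <- fwd$caches[[1L]]
    op1 <- br$ops[[1L]]
    cb <- cpp_conv1d_bwd(cache$x, cache$dimx, dcur, op1$W, op1$k, FALSE)
    grads[[1L]] <- list(dW = cb$dW, db = cb$db)
  }
  list(grads = grads)
}

# effective first-block kernel: Weff[(j,e), f2] = sum_f W1[j,f] W2[(e,f), f2]
# and bias beff[f2] = b2[f2] + sum_{e,f} W2[(e,f), f2] b1[f]
fused_block1_weights <- function(op1, op2, k, e) {
  w2a <- array(op2$W, c(e, 25L, 25L))                    # (e, f, f2)
  tmp <- op1$W %*% matrix(aperm(w2a, c(2, 1, 3)), 25L)   # k x (e, f2)
  weff <- array(tmp, c(k, e, 25L))
  dim(weff) <- c(k * e, 25L)
  beff <- op2$b +
    as.vector(crossprod(matrix(op2$W, e * 25L, 25L), rep(op1$b, each = e)))
  list(W = weff, b = beff)
}

# chain rule from the effective-kernel gradient back to the two parameter
# tensors of block 1
fused_block1_unmix <- function(dweff, dbeff, op1, op2, k, e) {
  w2a <- array(op2$W, c(e, 25L, 25L))
  dweffm <- matrix(dweff, k, e * 25L)                    # k x (e, f2)
  # dW1[j,f] = sum_{e,f2} dWeff[j,(e,f2)] W2[e,f,f2]
  w2b <- matrix(aperm(w2a, c(1, 3, 2)), e * 25L, 25L)    # (e,f2) x f
  dw1 <- dweffm %*% w2b
  # dW2[(e,f),f2] = sum_j dWeff[j,(e,f2)] W1[j,f]
  tmp <- crossprod(op1$W, dweffm)                        # f x (e, f2)
  dw2 <- aperm(array(tmp, c(25L, e, 25L)), c(2, 1, 3))   # (e, f, f2)
  dim(dw2) <- c(e * 25L, 25L)
  # b1 reaches the output only through beff
  s <- apply(w2a, c(2, 3), sum)                          # f x f2
  db1 <- as.vector(s %*% dbeff)
  list(g1 = list(dW = dw1, db = db1), g2 = list(dW = dw2, db = dbeff))
}

dense_fwd <- function(x, op) {
  y <- x %*% op$W
  y <- y + rep(op$b, each = nrow(y))
  act <- switch(op$activation,
                linear = y,
                relu = pmax(y, 0),
                softmax = {
                  e <- exp(y - apply(y, 1, max))
                  e / rowSums(e)
                })
  list(y = act, x = x, z = y)
}

dense_bwd <- function(dy, cache, op) {
  if (op$activation == "relu") dy <- dy * (cache$z > 0)
  dw <- crossprod(cache$x, dy) + 2 * op$l2 * op$W
  db <- colSums(dy)
  dx <- tcrossprod(dy, op$W)
  list(dW = dw, db = db, dx = dx)
}

# full forward; returns probabilities and (when training) every cache
net_fwd <- function(net, x, train = FALSE) {
  feats <- list(); bfwd <- list()
  for (bi in seq_along(net$branches)) {
    br <- net$branches[[bi]]
    xb <- x[, , br$channels, drop = FALSE]
    f <- branch_fwd(br, xb, train)
    net$branches[[bi]] <- f$br
    feats[[bi]] <- f$y
    bfwd[[bi]] <- f
  }
  h <- do.call(cbind, feats)
  hcache <- vector("list", length(net$head))
  for (i in seq_along(net$head)) {
    df <- dense_fwd(h, net$head[[i]])
    hcache[[i]] <- df
    h <- df$y
  }
  list(p = h, bfwd = bfwd, hcache = hcache, net = net)
}

# categorical cross-entropy + L2 loss and full gradient for one minibatch
net_loss_grad <- function(net, x, y01, train = TRUE) {
  fw <- net_fwd(net, x, train = train)
  net <- fw$net
  p <- fw$p
  bsz <- nrow(p)
  yk <- y01 + 1L
  loss <- -mean(log(pmax(p[cbind(seq_len(bsz), yk)], 1e-12)))
  for (op in net$head) loss <- loss + op$l2 * sum(op$W^2)
  onehot <- matrix(0, bsz, ncol(p))
  onehot[cbind(seq_len(bsz), yk)] <- 1
  dz <- (p - onehot) / bsz
  hgrads <- vector("list", length(net$head))
  for (i in rev(seq_along(net$head))) {
    db <- dense_bwd(dz, fw$hcache[[i]], net$head[[i]])
    hgrads[[i]] <- db[c("dW", "db")]
    dz <- db$dx
  }
  bgrads <- vector("list", length(net$branches))
  off <- 0L
  for (bi in seq_along(net$branches)) {
    w <- net$branches[[bi]]$flat_dim
    dfb <- dz[, off + seq_len(w), drop = FALSE]
    off <- off + w
    bgrads[[bi]] <- branch_bwd(net$branches[[bi]], fw$bfwd[[bi]], dfb)$grads
  }
  list(loss = loss, net = net, hgrads = hgrads, bgrads = bgrads)
}

## ---- Adam -------------------------------------------------------------

adam_init_op <- function(op) {
  for (f in c("W", "b", "gamma", "beta")) {
    if (!is.null(op[[f]])) {
      op[[paste0("m_", f)]] <- op[[f]] * 0
      op[[paste0("v_", f)]] <- op[[f]] * 0
    }
  }
  op
}

adam_step_op <- function(op, g, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  if (is.null(g)) return(op)
  map <- c(W = "dW", b = "db", gamma = "dgamma", beta = "dbeta")
  # bias correction folded into the step size to avoid large temporaries;
  # the update runs in place (snapshots are deep-copied, see net_deep_copy)
  alpha <- lr * sqrt(1 - b2^t) / (1 - b1^t)
  eps_t <- eps * sqrt(1 - b2^t)
  for (f in names(map)) {
    gr <- g[[map[[f]]]]
    if (is.null(gr) || is.null(op[[f]])) next
    cpp_adam(op[[f]], op[[paste0("m_", f)]], op[[paste0("v_", f)]], gr,
             alpha, b1, b2, eps_t)
  }
  op
}

# force-duplicate every numeric tensor so the copy is safe against the
# in-place Adam update
net_deep_copy <- function(net) {
  dup <- function(op) {
    for (f in names(op)) if (is.double(op[[f]])) op[[f]] <- op[[f]] + 0
    op
  }
  for (bi in seq_along(net$branches))
    net$branches[[bi]]$ops <- lapply(net$branches[[bi]]$ops, dup)
  net$head <- lapply(net$head, dup)
  net
}

adam_init <- function(net) {
  for (bi in seq_along(net$branches))
    net$branches[[bi]]$ops <- lapply(net$branches[[bi]]$ops, adam_init_op)
  net$head <- lapply(net$head, adam_init_op)
  net
}

adam_step <- function(net, grads, lr, t) {
  for (bi in seq_along(net$branches)) {
    ops <- net$branches[[bi]]$ops
    for (i in seq_along(ops))
      ops[[i]] <- adam_step_op(ops[[i]], grads$bgrads[[bi]][[i]], lr, t)
    net$branches[[bi]]$ops <- ops
  }
  for (i in seq_along(net$head))
    net$head[[i]] <- adam_step_op(net$head[[i]], grads$hgrads[[i]], lr, t)
  net
}

## ---- training and inference -------------------------------------------

# x: [win, N, 8] standardized array; y01: 0/1 labels
net_train_loop <- function(net, x, y01, spec, xval = NULL, yval = NULL,
                           verbose = FALSE) {
  n <- dim(x)[2]
  net <- adam_init(net)
  best <- list(loss = Inf, net = net, epoch = 0L)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  t_step <- 0L
  wait <- 0L
  for (epoch in seq_len(spec$max_epochs)) {
    ord <- sample.int(n)
    tot <- 0; nb <- 0
    for (s0 in seq(1L, n, by = spec$batch_size)) {
      idx <- ord[s0:min(n, s0 + spec$batch_size - 1L)]
      res <- net_loss_grad(net, x[, idx, , drop = FALSE], y01[idx],
                           train = TRUE)
      net <- res$net
      t_step <- t_step + 1L
      net <- adam_step(net, res, spec$learning_rate, t_step)
      tot <- tot + res$loss; nb <- nb + 1
    }
    vl <- if (!is.null(xval) && dim(xval)[2] > 0) {
      net_eval_loss(net, xval, yval, spec$batch_size)
    } else tot / nb
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = tot / nb,
                                         val_loss = vl))
    if (verbose)
      message(sprintf("epoch %d: train %.4f, monitored %.4f", epoch,
                      tot / nb, vl))
    if (vl < best$loss - 1e-6) {
      best <- list(loss = vl, net = net_deep_copy(net), epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= spec$patience) break
    }
  }
  list(net = best$net, history = history, best_epoch = best$epoch)
}

net_eval_loss <- function(net, x, y01, batch_size) {
  n <- dim(x)[2]
  tot <- 0
  for (s0 in seq(1L, n, by = batch_size)) {
    idx <- s0:min(n, s0 + batch_size - 1L)
    fw <- net_fwd(net, x[, idx, , drop = FALSE], train = FALSE)
    yk <- y01[idx] + 1L
    tot <- tot - sum(log(pmax(fw$p[cbind(seq_along(idx), yk)], 1e-12)))
  }
  tot / n + sum(vapply(net$head, function(op) op$l2 * sum(op$W^2), 1))
}

net_predict_prob <- function(net, x, batch_size = 128L) {
  n <- dim(x)[2]
  out <- matrix(0, n, 2)
  for (s0 in seq(1L, n, by = batch_size)) {
    idx <- s0:min(n, s0 + batch_size - 1L)
    fw <- net_fwd(net, x[, idx, , drop = FALSE], train = FALSE)
    out[idx, ] <- fw$p
  }
  out
}
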