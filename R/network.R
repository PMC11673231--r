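#' Hyperparameter bundle for the survival network
#'
#' Mirrors the tuning box used for the model family: number and width of
#' hidden layers, Adam learning rate, decoupled weight decay, dropout,
#' activation, time-discretization and interpolation schemes, the composite
#' loss weights `alpha` (likelihood weight) and `beta` (ranking temperature),
#' plus optimization settings that live outside the search box (epochs,
#' batch size, early-stopping patience, seed).
#'
#' @param n_layers hidden layers, 1..8.
#' @param width hidden units per layer, 8..2048.
#' @param learning_rate Adam step size, 1e-5..0.1.
#' @param weight_decay decoupled weight decay, 0..0.9.
#' @param dropout dropout rate, 0..0.6.
#' @param activation one of `"relu"`, `"selu"`, `"tanh"`, `"sigmoid"`
#'   (`"linear"` is accepted for diagnostics but never sampled in tuning).
#' @param discretization `"km_quantiles"` or `"equidistant"`.
#' @param interpolation `"CDI"` or `"CHI"`.
#' @param alpha composite-loss likelihood weight in `[0, 1]`.
#' @param beta ranking-loss temperature in `[0.1, 100]`.
#' @param m number of time intervals (>= 2).
#' @param epochs maximum optimization epochs.
#' @param batch_size minibatch size; `Inf` = full batch.
#' @param patience early-stopping patience (epochs without validation
#'   improvement) when a validation set is supplied to the trainer.
#' @param seed integer seed governing initialization, dropout and batching.
#' @return list of class `hyperparams`.
#' @export
hyperparams <- function(n_layers = 1L, width = 64L, learning_rate = 2e-3,
                        weight_decay = 0.05, dropout = 0.3,
                        activation = "relu",
                        discretization = "km_quantiles",
                        interpolation = "CDI",
                        alpha = 0.25, beta = 0.48, m = 10L,
                        epochs = 300L, batch_size = Inf, patience = 16L,
                        seed = 1L) {
  assert_number(n_layers, "n_layers", 1, 8)
  assert_number(width, "width", 8, 2048)
  assert_number(learning_rate, "learning_rate", 1e-5, 0.1)
  assert_number(weight_decay, "weight_decay", 0, 0.9)
  assert_number(dropout, "dropout", 0, 0.6)
  assert_number(alpha, "alpha", 0, 1)
  assert_number(beta, "beta", 0.1, 100)
  assert_number(m, "m", 2, Inf)
  if (!activation %in% c("relu", "selu", "tanh", "sigmoid", "linear"))
    stopf("unknown activation '%s'", activation)
  if (!discretization %in% c("km_quantiles", "equidistant"))
    stopf("unknown discretization '%s'", discretization)
  if (!interpolation %in% c("CDI", "CHI"))
    stopf("unknown interpolation '%s'", interpolation)
  structure(list(
    n_layers = as.integer(n_layers), width = as.integer(width),
    learning_rate = learning_rate, weight_decay = weight_decay,
    dropout = dropout, activation = activation,
    discretization = discretization, interpolation = interpolation,
    alpha = alpha, beta = beta, m = as.integer(m),
    epochs = as.integer(epochs), batch_size = batch_size,
    patience = as.integer(patience), seed = as.integer(seed)),
    class = "hyperparams")
}

activation_fns <- function(name) {
  sl <- 1.0507009873554805
  sa <- 1.6732632423543772
  switch(name,
    relu = list(f = function(x) pmax(x, 0),
                df = function(pre, post) (pre > 0) * 1),
    selu = list(f = function(x) sl * ifelse(x > 0, x, sa * (exp(x) - 1)),
                df = function(pre, post) sl * ifelse(pre > 0, 1, sa * exp(pre))),
    tanh = list(f = tanh,
                df = function(pre, post) 1 - post^2),
    sigmoid = list(f = function(x) 1 / (1 + exp(-x)),
                   df = function(pre, post) post * (1 - post)),
    linear = list(f = identity,
                  df = function(pre, post) matrix(1, nrow(pre), ncol(pre))),
    stopf("unknown activation '%s'", name))
}

#' Build an untrained feed-forward survival network
#'
#' A fully connected trunk of `n_layers` hidden layers feeding a linear head
#' of width `out_width` that emits the raw outputs `psi`. For the N-MTLR
#' family the reverse cumulative sum producing the interval logits `phi` is
#' a fixed, parameter-free transform applied after the head (the head layer
#' carries no trainable parameters for it). Weights are Glorot-uniform
#' initialized under `hp$seed`.
#'
#' @param p number of input genes.
#' @param hp a [hyperparams] bundle.
#' @param out_width head width: `hp$m` for discrete-time losses (default),
#'   1 for the Cox head.
#' @return list of class `survnet` with `layers` (W, b per layer),
#'   `activation`, `sizes`, `cumsum_head`.
#' @export
build_network <- function(p, hp, out_width = hp$m) {
  if (p < 1L) stopf("p must be >= 1")
  activation_fns(hp$activation)  # validates the name
  sizes <- c(p, rep(hp$width, hp$n_layers), out_width)
  layers <- with_seed(hp$seed, lapply(seq_len(length(sizes) - 1L), function(l) {
    fan_in <- sizes[l]; fan_out <- sizes[l + 1L]
    lim <- sqrt(6 / (fan_in + fan_out))
    list(W = matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out),
         b = numeric(fan_out))
  }))
  structure(list(layers = layers, activation = hp$activation, sizes = sizes,
                 cumsum_head = TRUE, out_width = out_width),
            class = "survnet")
}

n_params <- function(net) {
  sum(vapply(net$layers, function(l) length(l$W) + length(l$b), 0))
}

# Forward pass. Returns psi plus per-layer caches for backprop/attribution.
# Dropout (inverted) is applied to hidden activations when training = TRUE;
# masks are drawn from the current RNG stream.
forward_pass <- function(net, X, dropout = 0, training = FALSE) {
  act <- activation_fns(net$activation)
  L <- length(net$layers)
  H <- X
  pre <- vector("list", L - 1L)
  post <- vector("list", L - 1L)
  masks <- vector("list", L - 1L)
  for (l in seq_len(L - 1L)) {
    Z <- H %*% net$layers[[l]]$W
    Z <- Z + rep(net$layers[[l]]$b, each = nrow(Z))
    pre[[l]] <- Z
    A <- act$f(Z)
    if (training && dropout > 0) {
      mk <- matrix(rbinom(length(A), 1L, 1 - dropout), nrow(A), ncol(A)) /
        (1 - dropout)
      A <- A * mk
      masks[[l]] <- mk
    }
    post[[l]] <- A
    H <- A
  }
  psi <- H %*% net$layers[[L]]$W
  psi <- psi + rep(net$layers[[L]]$b, each = nrow(psi))
  list(psi = psi, pre = pre, post = post, masks = masks, input = X)
}

# Backward pass: gradient of the loss wrt all weights given dpsi.
backward_pass <- function(net, cache, dpsi) {
  act <- activation_fns(net$activation)
  L <- length(net$layers)
  grads <- vector("list", L)
  H_last <- if (L > 1L) cache$post[[L - 1L]] else cache$input
  grads[[L]] <- list(W = crossprod(H_last, dpsi), b = colSums(dpsi))
  dH <- dpsi %*% t(net$layers[[L]]$W)
  for (l in rev(seq_len(L - 1L))) {
    if (!is.null(cache$masks[[l]])) dH <- dH * cache$masks[[l]]
    post_raw <- act$f(cache$pre[[l]])  # pre-dropout activation
    dZ <- dH * act$df(cache$pre[[l]], post_raw)
    H_in <- if (l > 1L) cache$post[[l - 1L]] else cache$input
    grads[[l]] <- list(W = crossprod(H_in, dZ), b = colSums(dZ))
    if (l > 1L) dH <- dZ %*% t(net$layers[[l]]$W)
  }
  grads
}

#' Train a survival network on a cohort
#'
#' Standardizes the cohort's expression (train statistics only), fits the
#' time grid on the training outcomes, builds the network and optimizes the
#' requested loss with Adam (decoupled weight decay on the weights, dropout
#' on hidden activations). With a fixed seed the loss trace is
#' bit-reproducible on CPU. Supplying a validation cohort enables early
#' stopping with `hp$patience` (the best-validation weights are restored).
#'
#' @param cohort a [survival_cohort] with expression on the log scale.
#' @param hp a [hyperparams] bundle.
#' @param loss_name one of `"nmtlr_rank"`, `"nmtlr"`, `"deephit"`, `"pmf"`,
#'   `"cox"`.
#' @param validation optional [survival_cohort] for early stopping.
#' @param grid optional pre-fitted [make_grid]; by default fitted on
#'   `cohort` (training data only).
#' @param std optional pre-computed standardization statistics
#'   (`list(center, scale)`); by default computed on `cohort`.
#' @return object of class `survnet_fit`: the network, hyperparameters,
#'   time grid, standardization statistics, gene list and training trace.
#' @export
train_survnet <- function(cohort, hp = hyperparams(),
                          loss_name = c("nmtlr_rank", "nmtlr", "deephit",
                                        "pmf", "cox"),
                          validation = NULL, grid = NULL, std = NULL) {
  loss_name <- match.arg(loss_name)
  if (is.null(std)) std <- standardize(cohort$X)
  X <- apply_standardization(cohort$X, std$center, std$scale)
  discrete <- loss_name != "cox"
  if (is.null(grid))
    grid <- make_grid(cohort$time, cohort$event, m = hp$m,
                      scheme = hp$discretization)
  k_idx <- if (discrete) assign_interval(cohort$time, grid) else NULL
  out_width <- if (discrete) grid$m else 1L
  net <- build_network(ncol(X), hp, out_width = out_width)
  net$cumsum_head <- loss_name %in% c("nmtlr_rank", "nmtlr")

  val_data <- NULL
  if (!is.null(validation)) {
    Xv <- apply_standardization(validation$X, std$center, std$scale)
    kv <- if (discrete) assign_interval(validation$time, grid) else NULL
    val_data <- list(X = Xv, k = kv, time = validation$time,
                     event = validation$event)
  }

  n <- nrow(X)
  bs <- if (!is.finite(hp$batch_size)) n else min(hp$batch_size, n)
  lr <- hp$learning_rate
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  state <- lapply(net$layers, function(l)
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0))
  trace <- numeric(0)
  best <- list(val = Inf, layers = net$layers, epoch = 0L)
  t_step <- 0L

  run <- with_seed(hp$seed, {
    for (epoch in seq_len(hp$epochs)) {
      idx <- if (bs < n) sample.int(n) else seq_len(n)
      batches <- split(idx, ceiling(seq_along(idx) / bs))
      ep_loss <- 0
      for (bi in batches) {
        cache <- forward_pass(net, X[bi, , drop = FALSE],
                              dropout = hp$dropout, training = TRUE)
        lg <- loss_grad_for(loss_name, cache$psi, k_idx[bi],
                            cohort$event[bi], cohort$time[bi],
                            hp$alpha, hp$beta)
        if (!is.finite(lg$loss))
          stopf(paste0("loss became non-finite at epoch %d; ",
                       "try a smaller learning rate"), epoch)
        grads <- backward_pass(net, cache, lg$grad)
        t_step <- t_step + 1L
        for (l in seq_along(net$layers)) {
          st <- state[[l]]
          st$mW <- b1 * st$mW + (1 - b1) * grads[[l]]$W
          st$vW <- b2 * st$vW + (1 - b2) * grads[[l]]$W^2
          st$mb <- b1 * st$mb + (1 - b1) * grads[[l]]$b
          st$vb <- b2 * st$vb + (1 - b2) * grads[[l]]$b^2
          mWh <- st$mW / (1 - b1^t_step); vWh <- st$vW / (1 - b2^t_step)
          mbh <- st$mb / (1 - b1^t_step); vbh <- st$vb / (1 - b2^t_step)
          net$layers[[l]]$W <- net$layers[[l]]$W -
            lr * (mWh / (sqrt(vWh) + eps) + hp$weight_decay * net$layers[[l]]$W)
          net$layers[[l]]$b <- net$layers[[l]]$b - lr * mbh / (sqrt(vbh) + eps)
          state[[l]] <- st
        }
        ep_loss <- ep_loss + lg$loss * length(bi)
      }
      trace <- c(trace, ep_loss / n)
      if (!is.null(val_data)) {
        vpsi <- forward_pass(net, val_data$X)$psi
        vl <- loss_grad_for(loss_name, vpsi, val_data$k, val_data$event,
                            val_data$time, hp$alpha, hp$beta)$loss
        if (vl < best$val - 1e-10) {
          best <- list(val = vl, layers = net$layers, epoch = epoch)
        } else if (epoch - best$epoch >= hp$patience) {
          break
        }
      }
    }
    if (!is.null(val_data) && is.finite(best$val)) net$layers <- best$layers
    list(net = net, trace = trace)
  })

  structure(list(net = run$net, hp = hp, loss_name = loss_name, grid = grid,
                 center = std$center, scale = std$scale,
                 genes = cohort$genes, trace = run$trace,
                 cohort_label = cohort$cohort_label),
            class = "survnet_fit")
}

#' @export
print.survnet_fit <- function(x, ...) {
  cat(sprintf("<survnet_fit> %s loss, %d genes -> %s, %d epochs (final loss %.4f)\n",
              x$loss_name, length(x$genes),
              paste(x$net$sizes[-1L], collapse = "-"),
              length(x$trace), tail(x$trace, 1L)))
  invisible(x)
}

#' Predict from a fitted survival network
#'
#' @param object a [train_survnet] fit.
#' @param newdata a [survival_cohort] or raw expression matrix with the
#'   fit's genes (log scale; standardization is applied internally).
#' @param type `"survival"` (default; at `times` if given, else at the grid
#'   cuts), `"pmf"`, `"psi"`, or `"risk"` (Cox head).
#' @param times optional evaluation times for `type = "survival"`,
#'   interpolated with the fit's interpolation scheme.
#' @param ... unused.
#' @export
predict.survnet_fit <- function(object, newdata, type = c("survival", "pmf",
                                                          "psi", "risk"),
                                times = NULL, ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "survival_cohort")) newdata$X else as.matrix(newdata)
  if (ncol(X) != length(object$genes))
    stopf("newdata has %d genes, model expects %d", ncol(X), length(object$genes))
  Xs <- apply_standardization(X, object$center, object$scale)
  psi <- forward_pass(object$net, Xs)$psi
  if (object$loss_name == "cox") {
    if (type %in% c("survival", "pmf"))
      stopf("a Cox-head model predicts risk scores, not discrete survival")
    return(drop(psi))
  }
  if (type == "psi") return(psi)
  phi <- if (object$net$cumsum_head) reverse_cumsum(psi) else psi
  pred <- pmf_from_phi(phi)
  if (type == "pmf") return(pred$pmf)
  if (is.null(times)) return(pred$S_at_cuts)
  interpolate_survival(pred$S_at_cuts, object$grid, times,
                       scheme = object$hp$interpolation)
}

#' Train one network on a target cohort plus auxiliary cohorts
#'
#' Multi-cohort combined training: the gene lists are inner-joined (in the
#' target's gene order), the cohorts are concatenated, and a single network
#' is trained on the pooled samples. Evaluation should always be on held-out
#' target-cohort subjects. With `standardization = "pooled"` (default) one
#' set of statistics is computed on the pooled training matrix; with
#' `"per_cohort"` each cohort is standardized by its own statistics before
#' concatenation (the target's statistics are stored for later application).
#'
#' @param target target [survival_cohort].
#' @param auxiliaries list of auxiliary [survival_cohort]s (possibly empty,
#'   in which case the result is identical to [train_survnet] on the target).
#' @inheritParams train_survnet
#' @param standardization `"pooled"` or `"per_cohort"`.
#' @export
combined_train <- function(target, auxiliaries = list(), hp = hyperparams(),
                           loss_name = "nmtlr_rank",
                           standardization = c("pooled", "per_cohort"),
                           validation = NULL) {
  standardization <- match.arg(standardization)
  if (!length(auxiliaries))
    return(train_survnet(target, hp, loss_name, validation = validation))
  shared <- Reduce(intersect, c(list(target$genes),
                                lapply(auxiliaries, `[[`, "genes")))
  shared <- target$genes[target$genes %in% shared]  # keep target order
  if (!length(shared)) stopf("empty gene intersection across cohorts")
  message(sprintf("combined training on %d shared genes across %d cohorts",
                  length(shared), length(auxiliaries) + 1L))
  take <- function(co, idx) survival_cohort(
    co$X[, shared, drop = FALSE], co$time, co$event,
    sprintf("c%d:%s", idx, co$subject_ids), shared, co$cohort_label)
  cohorts <- c(list(take(target, 0L)),
               Map(take, auxiliaries, seq_along(auxiliaries)))
  if (standardization == "per_cohort") {
    target_std <- standardize(cohorts[[1L]]$X)
    Xs <- lapply(cohorts, function(co) standardize(co$X)$X)
    merged <- survival_cohort(
      do.call(rbind, Xs),
      unlist(lapply(cohorts, `[[`, "time")),
      unlist(lapply(cohorts, `[[`, "event")),
      unlist(lapply(cohorts, `[[`, "subject_ids")),
      shared, target$cohort_label)
    # data already standardized per cohort; identity transform at fit time,
    # target statistics stored for transfer to new target samples
    fit <- train_survnet(merged, hp, loss_name, validation = validation,
                         std = list(center = setNames(rep(0, length(shared)), shared),
                                    scale = setNames(rep(1, length(shared)), shared)))
    fit$center <- target_std$center
    fit$scale <- target_std$scale
    return(fit)
  }
  merged <- survival_cohort(
    do.call(rbind, lapply(cohorts, `[[`, "X")),
    unlist(lapply(cohorts, `[[`, "time")),
    unlist(lapply(cohorts, `[[`, "event")),
    unlist(lapply(cohorts, `[[`, "subject_ids")),
    shared, target$cohort_label)
  train_survnet(merged, hp, loss_name, validation = validation)
}
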