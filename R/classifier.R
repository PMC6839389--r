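# Shallow pattern-recognition network for sonogram classification.
#
# Feed-forward network (tanh hidden layers, softmax output) trained by
# scaled conjugate gradient (SCG) backpropagation on a cross-entropy loss.
# SCG is a batch second-order-informed conjugate gradient method (Moller,
# 1993) that sizes each step from a one-dimensional quadratic model whose
# curvature is estimated by a finite-difference Hessian-vector product,
# regularized Levenberg-Marquardt style; there is no user learning rate.

#' Construct a labeled dataset
#'
#' @param features Numeric matrix, one feature vector per row.
#' @param labels Factor/character vector of per-row class labels, or a
#'   one-hot target matrix (each row all zeros except a single 1).
#' @param class_names Optional class name vector; defaults to the sorted
#'   unique labels (or `class1..classK` for one-hot input).
#' @return An object of class `labeled_dataset` with fields `features`,
#'   `targets` (one-hot), `labels` (integer class index), `class_names`.
#' @export
labeled_dataset <- function(features, labels, class_names = NULL) {
  features <- as.matrix(features)
  if (any(!is.finite(features))) {
    sono_stop("sonodct_numeric_error", "features contain non-finite values")
  }
  if (is.matrix(labels)) {
    ok <- apply(labels, 1L, function(r) sum(r == 1) == 1L && sum(r != 0) == 1L)
    if (!all(ok)) {
      sono_stop("sonodct_input_error",
                "one-hot targets must have exactly one 1 per row and zeros elsewhere")
    }
    targets <- labels
    idx <- apply(labels, 1L, which.max)
    if (is.null(class_names)) class_names <- paste0("class", seq_len(ncol(labels)))
  } else {
    labels <- as.character(labels)
    if (is.null(class_names)) class_names <- sort(unique(labels))
    idx <- match(labels, class_names)
    if (anyNA(idx)) {
      sono_stop("sonodct_input_error",
                sprintf("labels not in class_names: %s",
                        paste(unique(labels[is.na(idx)]), collapse = ", ")))
    }
    targets <- matrix(0, nrow(features), length(class_names))
    targets[cbind(seq_along(idx), idx)] <- 1
  }
  if (nrow(targets) != nrow(features)) {
    sono_stop("sonodct_dimension_error", "features and labels disagree in sample count")
  }
  colnames(targets) <- class_names
  structure(list(features = features, targets = targets,
                 labels = idx, class_names = class_names),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d samples x %d features, classes: %s\n",
              nrow(x$features), ncol(x$features),
              paste(sprintf("%s (%d)", x$class_names, tabulate(x$labels, length(x$class_names))),
                    collapse = ", ")))
  invisible(x)
}

#' Initialize a feed-forward network
#'
#' Weights are drawn uniformly on `[-1/sqrt(fan_in), 1/sqrt(fan_in)]`, biases
#' start at zero. Hidden layers use tanh; the output layer is a softmax, so
#' predicted posteriors always lie on the probability simplex.
#'
#' @param layer_sizes Integer vector `(input_dim, hidden..., n_classes)`.
#' @param seed Integer seed controlling the draw.
#' @return An object of class `sono_net` (untrained).
#' @export
init_network <- function(layer_sizes, seed = 1L) {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2L || any(layer_sizes < 1L)) {
    sono_stop("sonodct_config_error", "layer_sizes needs >= 2 entries, all >= 1")
  }
  L <- length(layer_sizes) - 1L
  weights <- vector("list", L)
  biases <- vector("list", L)
  with_seed(seed, {
    for (l in seq_len(L)) {
      fan_in <- layer_sizes[l]
      a <- 1 / sqrt(fan_in)
      weights[[l]] <- matrix(stats::runif(layer_sizes[l + 1L] * fan_in, -a, a),
                             layer_sizes[l + 1L], fan_in)
      biases[[l]] <- numeric(layer_sizes[l + 1L])
    }
  })
  structure(list(layer_sizes = layer_sizes, weights = weights, biases = biases,
                 hidden_activation = "tanh", output = "softmax",
                 feature_stats = NULL, class_names = NULL, training_meta = NULL),
            class = "sono_net")
}

#' @export
print.sono_net <- function(x, ...) {
  cat(sprintf("<sono_net> topology %s, %s hidden units, softmax output%s\n",
              paste(x$layer_sizes, collapse = "-"), x$hidden_activation,
              if (is.null(x$training_meta)) " (untrained)" else
                sprintf(", trained %d epochs, final loss %.4g",
                        x$training_meta$epochs, x$training_meta$final_train_loss)))
  invisible(x)
}

# ---- internal: flat parameter vector <-> weight list ----

.net_pack <- function(weights, biases) {
  unlist(c(lapply(weights, as.vector), biases), use.names = FALSE)
}

.net_unpack <- function(w, layer_sizes) {
  L <- length(layer_sizes) - 1L
  weights <- vector("list", L)
  biases <- vector("list", L)
  pos <- 0L
  for (l in seq_len(L)) {
    n <- layer_sizes[l + 1L] * layer_sizes[l]
    weights[[l]] <- matrix(w[pos + seq_len(n)], layer_sizes[l + 1L], layer_sizes[l])
    pos <- pos + n
  }
  for (l in seq_len(L)) {
    n <- layer_sizes[l + 1L]
    biases[[l]] <- w[pos + seq_len(n)]
    pos <- pos + n
  }
  list(weights = weights, biases = biases)
}

# forward pass; X has samples in rows. Returns activations per layer and
# softmax posteriors (log-sum-exp stabilized).
.net_forward <- function(X, weights, biases) {
  L <- length(weights)
  acts <- vector("list", L + 1L)
  acts[[1L]] <- X
  A <- X
  for (l in seq_len(L - 1L)) {
    A <- tanh(sweep(A %*% t(weights[[l]]), 2L, biases[[l]], "+"))
    acts[[l + 1L]] <- A
  }
  Z <- sweep(A %*% t(weights[[L]]), 2L, biases[[L]], "+")
  Z <- Z - apply(Z, 1L, max)
  P <- exp(Z)
  P <- P / rowSums(P)
  acts[[L + 1L]] <- P
  list(acts = acts, posterior = P)
}

.net_loss <- function(P, targets) {
  -sum(targets * log(pmax(P, 1e-300))) / nrow(targets)
}

# Regularized performance function and its gradient w.r.t. the packed
# parameter vector: perf = (1 - r) * cross-entropy + (r / 2) * sum of
# squared weights (biases unpenalized). r = 0 recovers pure cross-entropy;
# r > 0 shrinks weights, the standard guard against memorizing small
# samples with wide feature vectors.
.net_loss_grad <- function(w, layer_sizes, X, targets, reg = 0) {
  par <- .net_unpack(w, layer_sizes)
  fw <- .net_forward(X, par$weights, par$biases)
  L <- length(par$weights)
  n <- nrow(X)
  ce <- .net_loss(fw$posterior, targets)
  gw <- vector("list", L)
  gb <- vector("list", L)
  delta <- (fw$posterior - targets) * ((1 - reg) / n)  # softmax + cross-entropy
  for (l in L:1) {
    gw[[l]] <- t(delta) %*% fw$acts[[l]]
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% par$weights[[l]]) * (1 - fw$acts[[l]]^2)
    }
  }
  loss <- (1 - reg) * ce
  if (reg > 0) {
    ssw <- sum(vapply(par$weights, function(W) sum(W^2), numeric(1)))
    loss <- loss + reg * ssw / 2
    for (l in seq_len(L)) {
      gw[[l]] <- gw[[l]] + reg * par$weights[[l]]
    }
  }
  list(loss = loss, grad = .net_pack(gw, gb), ce = ce)
}

# ---- scaled conjugate gradient (Moller 1993) ----
#
# fn(w) must return list(loss, grad). Runs until the gradient norm drops
# below grad_tol, max_iter weight updates, or callback() returns TRUE
# (early stopping). Accepted steps never increase the loss.
.scg_optimize <- function(w, fn, max_iter = 500L, grad_tol = 1e-6,
                          callback = NULL) {
  sigma0 <- 5e-5
  lambda <- 5e-7
  lambda_bar <- 0
  eg <- fn(w)
  if (!is.finite(eg$loss)) {
    sono_stop("sonodct_divergence_error", "initial loss is non-finite")
  }
  E <- eg$loss
  r <- -eg$grad
  p <- r
  success <- TRUE
  nparam <- length(w)
  k <- 0L
  losses <- numeric(0)
  delta <- 0
  mu <- 0
  while (k < max_iter) {
    p2 <- sum(p * p)
    pnorm <- sqrt(p2)
    if (pnorm < .Machine$double.eps || sqrt(sum(r * r)) < grad_tol) break
    if (success) {
      sigma <- sigma0 / pnorm
      eg2 <- fn(w + sigma * p)
      s <- (eg2$grad - (-r)) / sigma   # -r is the current gradient
      delta <- sum(p * s)
    }
    # Levenberg-Marquardt regularization of the curvature estimate
    delta <- delta + (lambda - lambda_bar) * p2
    if (delta <= 0) {   # make the Hessian model positive definite
      lambda_bar <- 2 * (lambda - delta / p2)
      delta <- -delta + lambda * p2
      lambda <- lambda_bar
    }
    mu <- sum(p * r)
    alpha <- mu / delta
    eg_new <- fn(w + alpha * p)
    if (!is.finite(eg_new$loss)) {
      sono_stop("sonodct_divergence_error",
                sprintf("loss became non-finite at epoch %d", k + 1L))
    }
    Delta <- 2 * delta * (E - eg_new$loss) / mu^2   # comparison parameter
    if (is.finite(Delta) && Delta >= 0) {
      # accept: loss is non-increasing by construction
      w <- w + alpha * p
      E_prev <- E
      E <- eg_new$loss
      r_new <- -eg_new$grad
      lambda_bar <- 0
      success <- TRUE
      k <- k + 1L
      losses[k] <- E
      if (k %% nparam == 0L) {
        p <- r_new                      # restart in steepest descent
      } else {
        beta <- (sum(r_new * r_new) - sum(r_new * r)) / mu
        p <- r_new + beta * p
      }
      r <- r_new
      if (Delta >= 0.75) lambda <- lambda / 4
      if (!is.null(callback) && isTRUE(callback(w, E, k))) break
      if (abs(E_prev - E) < 1e-14 && sqrt(sum(r * r)) < 1e-8) break
    } else {
      lambda_bar <- lambda
      success <- FALSE
    }
    if (Delta < 0.25) lambda <- lambda + delta * (1 - Delta) / p2
    if (lambda > 1e20) break            # model hopelessly ill-conditioned
  }
  list(w = w, loss = E, epochs = k, loss_curve = losses)
}

# plain batch gradient descent with momentum; fallback optimizer kept behind
# the config switch for cross-checking SCG
.gd_optimize <- function(w, fn, max_iter = 500L, grad_tol = 1e-6,
                         lr = 0.05, momentum = 0.9, callback = NULL) {
  v <- numeric(length(w))
  losses <- numeric(0)
  E <- fn(w)$loss
  for (k in seq_len(max_iter)) {
    eg <- fn(w)
    if (!is.finite(eg$loss)) {
      sono_stop("sonodct_divergence_error",
                sprintf("loss became non-finite at epoch %d", k))
    }
    if (sqrt(sum(eg$grad^2)) < grad_tol) break
    v <- momentum * v - lr * eg$grad
    w <- w + v
    E <- fn(w)$loss
    losses[k] <- E
    if (!is.null(callback) && isTRUE(callback(w, E, k))) break
  }
  list(w = w, loss = E, epochs = length(losses), loss_curve = losses)
}

# stratified index split; fractions sum to <= 1, remainder goes to train
.stratified_split <- function(labels, val_fraction, test_fraction) {
  train <- integer(0); val <- integer(0); test <- integer(0)
  for (cl in sort(unique(labels))) {
    idx <- sample(which(labels == cl))
    n <- length(idx)
    n_val <- floor(n * val_fraction)
    n_test <- floor(n * test_fraction)
    val <- c(val, idx[seq_len(n_val)])
    test <- c(test, idx[n_val + seq_len(n_test)])
    train <- c(train, idx[setdiff(seq_len(n), seq_len(n_val + n_test))])
  }
  list(train = sort(train), val = sort(val), test = sort(test))
}

#' Train the pattern-recognition network
#'
#' Features are z-scored with training-set statistics, the data are split
#' into stratified train/validation/test subsets, and the network is trained
#' by scaled conjugate gradient backpropagation on the cross-entropy loss.
#' Training stops on a validation-loss plateau (patience), a vanishing
#' gradient, or `max_epochs`; the weights with the best validation loss are
#' kept. Fully deterministic given `seed`.
#'
#' @param data A [labeled_dataset()].
#' @param config List of options: `hidden` (default `c(10, 10)`),
#'   `max_epochs` (500), `val_fraction` (0.15), `test_fraction` (0.15),
#'   `patience` (30 accepted steps without validation improvement),
#'   `grad_tol` (1e-6), `optimizer` (`"scg"`, default, or `"gd"`), and
#'   `regularization` (default 0.1): the performance function is
#'   `(1 - r) * cross-entropy + r * mean squared weights`, which keeps the
#'   wide spectral feature vectors (hundreds of inputs) from being memorized
#'   when samples are few. Validation loss and reported losses are always
#'   the plain cross-entropy.
#' @param seed Integer seed for the split and weight initialization.
#' @return A trained `sono_net` with `feature_stats`, `class_names`, and
#'   `training_meta` (loss curve, split indices, epochs, seed).
#' @export
train <- function(data, config = list(), seed = 1L) {
  stopifnot(inherits(data, "labeled_dataset"))
  cfg <- utils::modifyList(
    list(hidden = c(10L, 10L), max_epochs = 500L, val_fraction = 0.15,
         test_fraction = 0.15, patience = 30L, grad_tol = 1e-6,
         optimizer = "scg", regularization = 0.1),
    config
  )
  k <- ncol(data$targets)
  counts <- tabulate(data$labels, k)
  if (any(counts == 0L)) {
    sono_stop("sonodct_training_error",
              sprintf("class absent from training data: %s",
                      paste(data$class_names[counts == 0L], collapse = ", ")))
  }
  if (nrow(data$features) < k) {
    sono_stop("sonodct_training_error", "need at least as many samples as classes")
  }

  with_seed(seed, {
    split <- .stratified_split(data$labels, cfg$val_fraction, cfg$test_fraction)
    use_val <- length(split$val) >= 2L
    stats <- feature_stats(data$features[split$train, , drop = FALSE])
    X <- normalize_features(data$features, stats)
    Xtr <- X[split$train, , drop = FALSE]
    Ttr <- data$targets[split$train, , drop = FALSE]
    Xval <- X[split$val, , drop = FALSE]
    Tval <- data$targets[split$val, , drop = FALSE]

    layer_sizes <- c(ncol(X), cfg$hidden, k)
    net <- init_network(layer_sizes, seed = seed)
    w0 <- .net_pack(net$weights, net$biases)

    fn <- function(w) .net_loss_grad(w, layer_sizes, Xtr, Ttr,
                                     reg = cfg$regularization)
    best <- list(w = w0, val = Inf, epoch = 0L)
    stall <- 0L
    val_curve <- numeric(0)
    callback <- NULL
    if (use_val) {
      callback <- function(w, E, epoch) {
        par <- .net_unpack(w, layer_sizes)
        vl <- .net_loss(.net_forward(Xval, par$weights, par$biases)$posterior, Tval)
        val_curve[epoch] <<- vl
        if (vl < best$val - 1e-10) {
          best <<- list(w = w, val = vl, epoch = epoch)
          stall <<- 0L
        } else {
          stall <<- stall + 1L
        }
        stall >= cfg$patience
      }
    }
    opt <- if (identical(cfg$optimizer, "scg")) {
      .scg_optimize(w0, fn, max_iter = cfg$max_epochs, grad_tol = cfg$grad_tol,
                    callback = callback)
    } else {
      .gd_optimize(w0, fn, max_iter = cfg$max_epochs, grad_tol = cfg$grad_tol,
                   callback = callback)
    }
    w_final <- if (use_val && is.finite(best$val)) best$w else opt$w
    par <- .net_unpack(w_final, layer_sizes)
    net$weights <- par$weights
    net$biases <- par$biases
    net$feature_stats <- stats
    net$class_names <- data$class_names
    net$training_meta <- list(
      seed = seed, epochs = opt$epochs, optimizer = cfg$optimizer,
      loss_curve = opt$loss_curve, val_curve = val_curve,
      final_train_loss = fn(w_final)$ce,
      best_val_loss = if (use_val) best$val else NA_real_,
      split = split, config = cfg
    )
    net
  })
}

#' Predict class posteriors
#'
#' Applies the model's stored feature normalization and forward pass. Output
#' rows lie on the probability simplex; the predicted class is the argmax.
#'
#' @param object A trained `sono_net`.
#' @param newdata A [feature_vector()], numeric vector, or matrix with one
#'   feature vector per row.
#' @param ... Unused.
#' @return Numeric matrix of posteriors (rows = samples, columns = classes).
#' @export
predict.sono_net <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_vector")) newdata <- newdata$values
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1L)
  if (ncol(newdata) != object$layer_sizes[1L]) {
    sono_stop("sonodct_dimension_error",
              sprintf("feature length %d does not match model input dim %d",
                      ncol(newdata), object$layer_sizes[1L]))
  }
  if (!is.null(object$feature_stats)) {
    newdata <- normalize_features(newdata, object$feature_stats)
  }
  P <- .net_forward(newdata, object$weights, object$biases)$posterior
  if (!is.null(object$class_names)) colnames(P) <- object$class_names
  P
}

#' Save a trained model to a JSON file
#'
#' The schema records layer sizes, weights and biases, activation names,
#' feature normalization statistics, class names, and training metadata, so
#' a saved model fully reproduces [predict.sono_net()].
#'
#' @param model A `sono_net`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "sono_net"))
  obj <- list(
    format = "sonodct_model", version = 1L,
    layer_sizes = model$layer_sizes,
    weights = lapply(model$weights, function(w) unclass(w)),
    biases = model$biases,
    hidden_activation = model$hidden_activation,
    output = model$output,
    feature_stats = model$feature_stats,
    class_names = model$class_names,
    training_meta = model$training_meta[c("seed", "epochs", "optimizer",
                                          "final_train_loss", "best_val_loss")]
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path Path to the JSON model file.
#' @return A `sono_net`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "sonodct_model")) {
    sono_stop("sonodct_format_error", sprintf("%s is not a sonodct model file", path))
  }
  layer_sizes <- as.integer(obj$layer_sizes)
  weights <- lapply(obj$weights, function(w) {
    m <- as.matrix(w)
    storage.mode(m) <- "double"
    m
  })
  biases <- lapply(obj$biases, as.numeric)
  stats <- NULL
  if (!is.null(obj$feature_stats)) {
    stats <- list(location = as.numeric(obj$feature_stats$location),
                  scale = as.numeric(obj$feature_stats$scale))
  }
  structure(list(layer_sizes = layer_sizes, weights = weights, biases = biases,
                 hidden_activation = obj$hidden_activation, output = obj$output,
                 feature_stats = stats, class_names = obj$class_names,
                 training_meta = obj$training_meta),
            class = "sono_net")
}
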