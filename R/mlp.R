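#' Initialise a sigmoid multilayer perceptron
#'
#' Fully-connected network with logistic-sigmoid activations on every layer.
#' The default geometry is 8 inputs (one per sEMG channel) and two layers of
#' nine neurons each -- a hidden layer of 9 and an output layer of 9, one
#' output unit per gesture class. Weights are drawn from U(-0.5, 0.5),
#' biases start at zero; both are reproducible from `seed`.
#'
#' @param sizes integer vector of layer sizes, input first
#'   (default `c(8, 9, 9)`).
#' @param seed RNG seed for the weight draw.
#' @return An object of class `mlp_model` with `sizes`, lists `W` (weight
#'   matrices, out x in) and `b` (bias vectors), and `seed`.
#' @export
init_mlp <- function(sizes = c(8, 9, 9), seed = 1) {
  sizes <- as.integer(sizes)
  if (length(sizes) < 2 || any(sizes < 1))
    stop("sizes must name at least two layers, all >= 1")
  W <- vector("list", length(sizes) - 1)
  b <- vector("list", length(sizes) - 1)
  with_seed(seed, {
    for (l in seq_along(W)) {
      W[[l]] <- matrix(stats::runif(sizes[l + 1] * sizes[l], -0.5, 0.5),
                       nrow = sizes[l + 1], ncol = sizes[l])
      b[[l]] <- rep(0, sizes[l + 1])
    }
  })
  structure(list(sizes = sizes, W = W, b = b, seed = seed,
                 scaling = NULL),
            class = "mlp_model")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Forward pass
#'
#' Affine transform plus logistic sigmoid at every layer; outputs therefore
#' lie strictly inside (0, 1).
#'
#' @param model an `mlp_model`.
#' @param features numeric vector (one sample) or matrix with one sample
#'   per row; width must equal the input size.
#' @return Output activations: a vector for a single sample, otherwise a
#'   matrix (samples x outputs).
#' @export
mlp_forward <- function(model, features) {
  stopifnot(inherits(model, "mlp_model"))
  single <- is.null(dim(features))
  X <- if (single) matrix(features, nrow = 1) else as.matrix(features)
  if (ncol(X) != model$sizes[1])
    stop("feature width (", ncol(X), ") does not match input size (",
         model$sizes[1], ")")
  A <- X
  for (l in seq_along(model$W))
    A <- sigmoid(A %*% t(model$W[[l]]) +
                   matrix(model$b[[l]], nrow(A), length(model$b[[l]]),
                          byrow = TRUE))
  if (single) drop(A) else A
}

# Forward pass keeping per-layer activations (for backprop).
mlp_forward_full <- function(model, X) {
  acts <- vector("list", length(model$W) + 1)
  acts[[1]] <- X
  for (l in seq_along(model$W))
    acts[[l + 1]] <- sigmoid(acts[[l]] %*% t(model$W[[l]]) +
                               matrix(model$b[[l]], nrow(X),
                                      length(model$b[[l]]), byrow = TRUE))
  acts
}

# Mean-squared-error gradient via backpropagation. Returns list(W=, b=)
# of gradients of L = mean over samples and output units of (o - t)^2.
mlp_gradients <- function(model, X, Tg) {
  n <- nrow(X)
  K <- ncol(Tg)
  acts <- mlp_forward_full(model, X)
  L <- length(model$W)
  gW <- vector("list", L); gb <- vector("list", L)
  O <- acts[[L + 1]]
  delta <- (2 / (n * K)) * (O - Tg) * O * (1 - O)
  for (l in L:1) {
    gW[[l]] <- unname(t(delta) %*% acts[[l]])
    gb[[l]] <- unname(colSums(delta))
    if (l > 1) {
      A <- acts[[l]]
      delta <- (delta %*% model$W[[l]]) * A * (1 - A)
    }
  }
  list(W = gW, b = gb)
}

mlp_loss <- function(model, X, Tg) {
  O <- mlp_forward(model, X)
  if (is.null(dim(O))) O <- matrix(O, nrow = 1)
  mean((O - Tg)^2)
}

one_hot <- function(labels, n_classes) {
  Tg <- matrix(0, length(labels), n_classes)
  Tg[cbind(seq_along(labels), labels)] <- 1
  Tg
}

#' Train the classifier by backpropagation with early stopping
#'
#' Gradient descent on the mean squared error against one-hot targets,
#' sweeping the training set once per epoch. The default `"online"` method
#' applies one update per sample in data order -- the regime in which a
#' learning rate of 0.01 converges within the 1000-4000-epoch budget;
#' `"batch"` applies a single mean-gradient step per epoch (useful for
#' exact gradient analysis, but far slower to converge at the same rate).
#' After every epoch the test-set error is evaluated; training stops when
#' it has not improved for `patience` consecutive epochs (or at
#' `max_epochs`), and the returned model is the snapshot with the minimal
#' test error seen.
#'
#' @param model an `mlp_model` from [init_mlp()].
#' @param train_set,test_set `feature_matrix` objects with integer labels
#'   in `1..n_outputs`.
#' @param lr learning rate, default 0.01.
#' @param max_epochs epoch cap, default 4000.
#' @param patience early-stopping patience in epochs, default 50.
#' @param method `"online"` (per-sample updates, default) or `"batch"`
#'   (one full-sweep gradient step per epoch).
#' @return A list: `model` (best snapshot) and `history` (data.frame with
#'   `epoch`, `train_error`, `test_error`, plus attributes `stopped_epoch`
#'   and `best_epoch`).
#' @export
train_mlp <- function(model, train_set, test_set, lr = 0.01,
                      max_epochs = 4000, patience = 50,
                      method = c("online", "batch")) {
  method <- match.arg(method)
  stopifnot(inherits(model, "mlp_model"))
  if (nrow(train_set) == 0 || nrow(test_set) == 0)
    stop("train and test sets must be non-empty")
  Xtr <- unname(feature_values(train_set)); ytr <- train_set$label
  Xte <- unname(feature_values(test_set));  yte <- test_set$label
  if (anyNA(ytr) || anyNA(yte)) stop("labelled feature matrices required")
  K <- model$sizes[length(model$sizes)]
  if (max(ytr, yte) > K || min(ytr, yte) < 1)
    stop("labels must lie in 1..", K)
  missing_cls <- setdiff(unique(yte), unique(ytr))
  if (length(missing_cls) > 0)
    warning("classes present in test but absent in train: ",
            paste(missing_cls, collapse = ", "))
  Ttr <- one_hot(ytr, K); Tte <- one_hot(yte, K)

  if (method == "online") {
    if (length(model$sizes) != 3)
      stop("online training supports one hidden layer (sizes of length 3)")
    res <- mlp_train_online_cpp(Xtr, Ttr, Xte, Tte,
                                model$W[[1]], model$b[[1]],
                                model$W[[2]], model$b[[2]],
                                lr, as.integer(max_epochs),
                                as.integer(patience))
    model$W <- list(res$W1, res$W2)
    model$b <- list(res$b1, res$b2)
    history <- data.frame(epoch = seq_along(res$train_error),
                          train_error = res$train_error,
                          test_error = res$test_error)
    attr(history, "stopped_epoch") <- res$stopped_epoch
    attr(history, "best_epoch") <- res$best_epoch
    return(list(model = model, history = history))
  }

  hist_tr <- numeric(max_epochs); hist_te <- numeric(max_epochs)
  best <- list(err = Inf, W = model$W, b = model$b, epoch = 0L)
  wait <- 0L; epoch <- 0L
  while (epoch < max_epochs) {
    epoch <- epoch + 1L
    g <- mlp_gradients(model, Xtr, Ttr)
    for (l in seq_along(model$W)) {
      model$W[[l]] <- model$W[[l]] - lr * g$W[[l]]
      model$b[[l]] <- model$b[[l]] - lr * g$b[[l]]
    }
    hist_tr[epoch] <- mlp_loss(model, Xtr, Ttr)
    hist_te[epoch] <- mlp_loss(model, Xte, Tte)
    if (!is.finite(hist_tr[epoch]))
      stop("training aborted: loss became non-finite at epoch ", epoch)
    if (hist_te[epoch] < best$err) {
      best <- list(err = hist_te[epoch], W = model$W, b = model$b,
                   epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  model$W <- best$W; model$b <- best$b
  history <- data.frame(epoch = seq_len(epoch),
                        train_error = hist_tr[seq_len(epoch)],
                        test_error = hist_te[seq_len(epoch)])
  attr(history, "stopped_epoch") <- epoch
  attr(history, "best_epoch") <- best$epoch
  list(model = model, history = history)
}

# R-level single-sweep of per-sample updates; used as the independent
# cross-check of the C++ online trainer on tiny problems.
mlp_online_sweep_r <- function(model, X, Tg, lr) {
  for (s in seq_len(nrow(X))) {
    g <- mlp_gradients(model, X[s, , drop = FALSE], Tg[s, , drop = FALSE])
    for (l in seq_along(model$W)) {
      model$W[[l]] <- model$W[[l]] - lr * g$W[[l]]
      model$b[[l]] <- model$b[[l]] - lr * g$b[[l]]
    }
  }
  model
}

#' Classify feature vectors
#'
#' The class is the output unit with the maximal activation; exact ties
#' break toward the lowest index.
#'
#' @param model an `mlp_model`.
#' @param features vector or matrix as in [mlp_forward()].
#' @return Integer class index (vector when `features` is a matrix).
#' @export
classify_mlp <- function(model, features) {
  O <- mlp_forward(model, features)
  if (is.null(dim(O))) return(which.max(O))
  apply(O, 1, which.max)
}

#' Serialize / restore a trained model
#'
#' JSON file holding layer sizes, weights, biases, seed, feature-scaling
#' ranges and any training metadata.
#'
#' @param model an `mlp_model`.
#' @param file path to a JSON file.
#' @param metadata optional named list stored verbatim.
#' @return `write_mlp` returns `file` invisibly; `read_mlp` the restored
#'   `mlp_model` (metadata in attribute `metadata`).
#' @export
write_mlp <- function(model, file, metadata = NULL) {
  payload <- list(sizes = model$sizes, seed = model$seed,
                  W = lapply(model$W, unname),
                  b = lapply(model$b, unname),
                  scaling = if (is.null(model$scaling)) NULL else
                    lapply(unclass(model$scaling), unname),
                  metadata = metadata)
  jsonlite::write_json(payload, file, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(file)
}

#' @rdname write_mlp
#' @export
read_mlp <- function(file) {
  p <- jsonlite::read_json(file, simplifyVector = TRUE)
  sizes <- as.integer(p$sizes)
  W <- if (is.list(p$W)) lapply(p$W, as.matrix) else
    lapply(seq_len(dim(p$W)[1]), function(i) as.matrix(p$W[i, , ]))
  model <- structure(list(sizes = sizes, W = W,
                          b = if (is.list(p$b)) lapply(p$b, as.numeric) else
                            lapply(seq_len(nrow(p$b)), function(i)
                              as.numeric(p$b[i, ])),
                          seed = p$seed,
                          scaling = if (is.null(p$scaling)) NULL else
                            structure(lapply(p$scaling, as.numeric),
                                      class = "feature_scaling")),
                     class = "mlp_model")
  attr(model, "metadata") <- p$metadata
  model
}
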