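# Sigmoid MLP: initialisation, forward pass, gradient correctness, training
# with early stopping, and the argmax readout.

test_that("initialisation is seeded, shaped by the layer sizes", {
  m1 <- init_mlp(c(8, 9, 9), seed = 3)
  m2 <- init_mlp(c(8, 9, 9), seed = 3)
  m3 <- init_mlp(c(8, 9, 9), seed = 4)
  expect_identical(m1$W, m2$W)
  expect_false(identical(m1$W, m3$W))
  expect_identical(dim(m1$W[[1]]), c(9L, 8L))
  expect_identical(dim(m1$W[[2]]), c(9L, 9L))
  expect_true(all(abs(unlist(m1$W)) <= 0.5))
  expect_true(all(unlist(m1$b) == 0))
  expect_error(init_mlp(c(8, 0, 9)), "sizes")
})

test_that("the forward pass is a bounded sigmoid map", {
  m <- init_mlp(c(4, 3, 2), seed = 1)
  zero <- m
  zero$W <- lapply(zero$W, function(w) w * 0)
  expect_equal(mlp_forward(zero, c(1, -2, 3, 100)), c(0.5, 0.5))
  out <- mlp_forward(m, matrix(rnorm(40), ncol = 4))
  expect_true(all(out > 0 & out < 1))
  expect_identical(mlp_forward(m, c(1, 2, 3, 4)), mlp_forward(m, c(1, 2, 3, 4)))
  expect_error(mlp_forward(m, c(1, 2)), "input size")
})

test_that("backprop gradients match central finite differences", {
  withr::with_seed(12, {
    m <- init_mlp(c(3, 3, 3), seed = 12)
    X <- matrix(rnorm(15), ncol = 3)
    Tg <- spikemg:::one_hot(sample(1:3, 5, replace = TRUE), 3)
    g <- spikemg:::mlp_gradients(m, X, Tg)
    eps <- 1e-6
    for (l in 1:2) {
      for (idx in seq_len(length(m$W[[l]]))) {
        mp <- m; mp$W[[l]][idx] <- mp$W[[l]][idx] + eps
        mm <- m; mm$W[[l]][idx] <- mm$W[[l]][idx] - eps
        fd <- (spikemg:::mlp_loss(mp, X, Tg) -
                 spikemg:::mlp_loss(mm, X, Tg)) / (2 * eps)
        expect_equal(g$W[[l]][idx], fd, tolerance = 1e-5)
      }
      for (idx in seq_along(m$b[[l]])) {
        mp <- m; mp$b[[l]][idx] <- mp$b[[l]][idx] + eps
        mm <- m; mm$b[[l]][idx] <- mm$b[[l]][idx] - eps
        fd <- (spikemg:::mlp_loss(mp, X, Tg) -
                 spikemg:::mlp_loss(mm, X, Tg)) / (2 * eps)
        expect_equal(g$b[[l]][idx], fd, tolerance = 1e-5)
      }
    }
  })
})

test_that("the compiled online sweep equals the R per-sample reference", {
  withr::with_seed(31, {
    X <- matrix(runif(160), ncol = 8)
    y <- sample(1:9, 20, replace = TRUE)
    fm <- make_feature_matrix(seq_len(20) * 50, X, y)
    m <- init_mlp(c(8, 9, 9), seed = 2)
    fit <- train_mlp(m, fm, fm, max_epochs = 1, patience = 10,
                     method = "online")
    ref <- spikemg:::mlp_online_sweep_r(m, feature_values(fm),
                                        spikemg:::one_hot(y, 9), 0.01)
    expect_equal(fit$model$W, ref$W, tolerance = 1e-14)
    expect_equal(fit$model$b, ref$b, tolerance = 1e-14)
  })
})

test_that("zero learning rate leaves the weights untouched", {
  withr::with_seed(5, {
    X <- matrix(runif(80), ncol = 8)
    fm <- make_feature_matrix(seq_len(10) * 50, X,
                              sample(1:9, 10, replace = TRUE))
    m <- init_mlp(c(8, 9, 9), seed = 5)
    for (method in c("online", "batch")) {
      fit <- train_mlp(m, fm, fm, lr = 0, max_epochs = 30, patience = 100,
                       method = method)
      expect_identical(fit$model$W, m$W)
      expect_true(all(abs(diff(fit$history$test_error)) < 1e-15))
    }
  })
})

test_that("separable 9-class features are learned to >= 99% accuracy", {
  # well-separated Gaussian clusters in 8-D, one per gesture class
  withr::with_seed(77, {
    centers <- matrix(runif(9 * 8), 9, 8)
    centers <- 0.1 + 0.8 * centers
    draw <- function(n_per) {
      X <- do.call(rbind, lapply(1:9, function(k)
        matrix(rep(centers[k, ], n_per), ncol = 8, byrow = TRUE) +
          matrix(rnorm(n_per * 8, sd = 0.02), ncol = 8)))
      make_feature_matrix(seq_len(9 * n_per) * 50, X, rep(1:9, each = n_per))
    }
    train <- draw(40)
    test <- draw(20)
    m <- init_mlp(c(8, 9, 9), seed = 7)
    fit <- train_mlp(m, train, test, max_epochs = 4000, patience = 50)
    pred <- classify_mlp(fit$model, feature_values(test))
    expect_gte(mean(pred == test$label), 0.99)
    expect_lte(attr(fit$history, "stopped_epoch"), 4000)
  })
})

test_that("early stopping restores the best test-error snapshot", {
  withr::with_seed(14, {
    X <- matrix(runif(400), ncol = 8)
    y <- sample(1:5, 50, replace = TRUE)
    tr <- make_feature_matrix(seq_len(50) * 50, X, y)
    Xe <- matrix(runif(160), ncol = 8)
    te <- make_feature_matrix(seq_len(20) * 50, Xe,
                              sample(1:5, 20, replace = TRUE))
    m <- init_mlp(c(8, 9, 5), seed = 9)
    fit <- train_mlp(m, tr, te, max_epochs = 300, patience = 20)
    best <- attr(fit$history, "best_epoch")
    expect_identical(min(fit$history$test_error),
                     fit$history$test_error[best])
    returned_err <- spikemg:::mlp_loss(fit$model, feature_values(te),
                                       spikemg:::one_hot(te$label, 5))
    expect_equal(returned_err, min(fit$history$test_error),
                 tolerance = 1e-12)
    expect_lte(best, attr(fit$history, "stopped_epoch"))
  })
})

test_that("training is deterministic and flags unseen test classes", {
  withr::with_seed(15, {
    X <- matrix(runif(160), ncol = 8)
    tr <- make_feature_matrix(seq_len(20) * 50, X, rep(1:2, 10))
    te <- make_feature_matrix(seq_len(20) * 50, X, rep(c(1L, 3L), 10))
    m <- init_mlp(c(8, 9, 3), seed = 2)
    expect_warning(train_mlp(m, tr, te, max_epochs = 2), "absent in train")
    f1 <- suppressWarnings(train_mlp(m, tr, te, max_epochs = 20))
    f2 <- suppressWarnings(train_mlp(m, tr, te, max_epochs = 20))
    expect_identical(f1$model$W, f2$model$W)
  })
})

test_that("classification is an argmax with lowest-index tie-break", {
  m <- init_mlp(c(2, 3, 5), seed = 1)
  out <- mlp_forward(m, c(0.3, 0.8))
  expect_identical(classify_mlp(m, c(0.3, 0.8)), which.max(out))
  # all-zero weights tie every output at 0.5: the lowest index wins
  zero <- m
  zero$W <- lapply(zero$W, function(w) w * 0)
  expect_identical(classify_mlp(zero, c(0.3, 0.8)), 1L)
  # invariance under a strictly increasing transform of the outputs
  expect_identical(which.max(out), which.max(qlogis(out)))
})

test_that("model serialization round-trips through JSON", {
  withr::with_seed(3, {
    m <- init_mlp(c(8, 9, 9), seed = 11)
    m$scaling <- list(min = rep(0.1, 8), range = rep(2, 8))
    f <- withr::local_tempfile(fileext = ".json")
    write_mlp(m, f, metadata = list(extractor = "rms"))
    m2 <- read_mlp(f)
    expect_equal(m2$W, m$W)
    expect_equal(m2$b, m$b)
    expect_equal(m2$scaling$min, m$scaling$min)
    expect_identical(attr(m2, "metadata")$extractor, "rms")
    x <- runif(8)
    expect_equal(mlp_forward(m2, x), mlp_forward(m, x))
  })
})
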