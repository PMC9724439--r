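test_that("pair prediction is a symmetric product-head sigmoid", {
  set.seed(71)
  head <- list(W = matrix(rnorm(5 * 7), 5, 7), b = matrix(rnorm(7), 1))
  e1 <- rnorm(5); e2 <- rnorm(5)

  # zero embedding: output is sigmoid(bias), independent of the partner
  expect_equal(predict_pair(rep(0, 5), e2, head),
               as.vector(1 / (1 + exp(-head$b))))
  expect_equal(predict_pair(rep(0, 5), e1, head),
               predict_pair(rep(0, 5), e2, head))

  expect_equal(predict_pair(e1, e2, head), predict_pair(e2, e1, head))

  # explicit loop: product, affine map, sigmoid
  ref <- sapply(1:7, function(k) {
    1 / (1 + exp(-(sum(e1 * e2 * head$W[, k]) + head$b[1, k])))
  })
  expect_equal(predict_pair(e1, e2, head), ref)

  expect_error(predict_pair(e1, rnorm(4), head), "widths")
})

test_that("the multi-task BCE sums classes and averages pairs", {
  y <- matrix(rep(1, 7), 1)
  expect_equal(bce_loss(y, matrix(0.5, 1, 7)), 7 * log(2), tolerance = 1e-6)

  # near-exact prediction gives near-zero loss
  yy <- matrix(rbinom(14, 1, 0.5), 2)
  expect_lt(bce_loss(yy, pmin(pmax(yy, 1e-9), 1 - 1e-9)), 1e-5)

  # moving one coordinate from 0.5 toward its label strictly decreases loss
  y1 <- matrix(c(1, rep(0, 6)), 1)
  p <- matrix(0.5, 1, 7)
  losses <- sapply(c(0.5, 0.7, 0.9, 0.99), function(v) {
    p[1, 1] <- v; bce_loss(y1, p)
  })
  expect_true(all(diff(losses) < 0))

  expect_error(bce_loss(y1, matrix(0.5, 2, 7)), "shapes")
})

test_that("micro-F1 pools confusion counts across the seven classes", {
  y <- matrix(rbinom(70, 1, 0.4), 10)
  expect_equal(micro_f1(y, y)$micro_f1, 1)

  # hand case: TP = (2, 1), FP = (1, 0), FN = (0, 1) pooled over two classes
  y_true <- cbind(c(1, 1, 0, 0), c(1, 1, 0, 0))
  y_pred <- cbind(c(1, 1, 1, 0), c(1, 0, 0, 0))
  r <- micro_f1(y_true, y_pred)
  expect_equal(r$precision_m, 3 / 4)
  expect_equal(r$recall_m, 3 / 4)
  expect_equal(r$micro_f1, 0.75)

  expect_equal(micro_f1(y, y * 0)$micro_f1, 0)
  expect_error(micro_f1(y, y + 1), "binary")

  # independent per-element confusion-count oracle
  set.seed(72)
  for (i in 1:25) {
    yt <- matrix(rbinom(7 * 12, 1, runif(1, 0.2, 0.8)), 12)
    yp <- matrix(rbinom(7 * 12, 1, runif(1, 0.2, 0.8)), 12)
    tp <- fp <- fn <- 0
    for (r_ in 1:12) for (c_ in 1:7) {
      if (yt[r_, c_] == 1 && yp[r_, c_] == 1) tp <- tp + 1
      if (yt[r_, c_] == 0 && yp[r_, c_] == 1) fp <- fp + 1
      if (yt[r_, c_] == 1 && yp[r_, c_] == 0) fn <- fn + 1
    }
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    pre <- if (tp + fp > 0) tp / (tp + fp) else 0
    ref <- if (rec + pre > 0) 2 * rec * pre / (rec + pre) else 0
    expect_equal(micro_f1(yt, yp)$micro_f1, ref)
  }
})

test_that("training reduces the loss and is reproducible per seed", {
  cfg <- tiny_model_cfg()
  ds <- tiny_dataset(n = 12, p = 0.4, seed = 73, cfg = cfg)
  split <- split_random(ppihop:::graph_edges(ds$graph),
                        partition_spec("random", 0.2, seed = 1))
  m <- ppihop_model(cfg, ds, seed = 1)
  tc <- train_config(learning_rate = 0.02, batch_size = Inf, max_epochs = 8,
                     plateau_patience = 8, early_stop_patience = 8, seed = 2)
  fit <- ppihop_train(m, ds, split, tc)
  expect_lt(tail(fit$history$loss, 1), fit$history$loss[1])
  expect_equal(nrow(fit$history), 8L)
  expect_true(all(c("epoch", "lr", "loss", "micro_f1") %in% names(fit$history)))

  fit2 <- ppihop_train(ppihop_model(cfg, ds, seed = 1), ds, split, tc)
  expect_identical(fit$history$loss, fit2$history$loss)
  expect_identical(fit$final$micro_f1, fit2$final$micro_f1)
})

test_that("early stopping halts a non-improving run within patience + 1", {
  cfg <- tiny_model_cfg()
  ds <- tiny_dataset(n = 10, p = 0.4, seed = 74, cfg = cfg)
  split <- split_random(ppihop:::graph_edges(ds$graph),
                        partition_spec("random", 0.2, seed = 1))
  m <- ppihop_model(cfg, ds, seed = 1)
  # a vanishing learning rate freezes the model: the loss never improves
  tc <- train_config(learning_rate = 1e-15, batch_size = Inf, max_epochs = 60,
                     plateau_patience = 20, early_stop_patience = 20, seed = 1)
  fit <- ppihop_train(m, ds, split, tc)
  expect_lte(nrow(fit$history), 21L)
})

test_that("training rejects overlapping or empty splits", {
  cfg <- tiny_model_cfg()
  ds <- tiny_dataset(n = 10, p = 0.4, seed = 75, cfg = cfg)
  e <- ppihop:::graph_edges(ds$graph)
  m <- ppihop_model(cfg, ds, seed = 1)
  bad <- structure(list(train = e, test = e[1, , drop = FALSE], root = NULL,
                        scheme = "random", seed = 1), class = "ppi_partition")
  expect_error(ppihop_train(m, ds, bad, train_config(max_epochs = 1,
                                                     plateau_patience = 1,
                                                     early_stop_patience = 1)),
               "overlap")
  empty <- structure(list(train = e[0, ], test = e, root = NULL,
                          scheme = "random", seed = 1), class = "ppi_partition")
  expect_error(ppihop_train(m, ds, empty, train_config()), "empty")
})
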