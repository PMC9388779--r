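test_that("architecture validation and parameter arithmetic hold", {
  arch <- cnn_architecture()
  m <- build_cnn(arch, seed = 1)
  # forward pass returns 2 logits on the desk-scale default
  expect_length(cnn_forward(m, array(0, c(24, 28, 24)))$logits, 2)
  # a freshly built model has zero biases: the all-zero input rides the
  # bias path to exactly zero logits
  expect_identical(cnn_forward(m, array(0, c(24, 28, 24)))$logits, c(0, 0))
  # shape underflow names the offending block
  expect_error(cnn_architecture(input_dims = c(8, 8, 8),
                                n_filters = c(4, 8, 16, 32)),
               "block 4")
  expect_error(cnn_architecture(dropout_rate = 1), "dropout")
  # doubling block-1 filters adds the analytic parameter increment
  a1 <- cnn_architecture(input_dims = c(8, 8, 8), n_filters = c(4, 8),
                         fc_units = 8)
  a2 <- cnn_architecture(input_dims = c(8, 8, 8), n_filters = c(8, 8),
                         fc_units = 8)
  m1 <- build_cnn(a1, seed = 1); m2 <- build_cnn(a2, seed = 1)
  delta <- (27 * 1 * 4 + 4) +       # block 1: extra filters + biases
    27 * 4 * 8                      # block 2: extra input channels
  expect_equal(m2$n_parameters - m1$n_parameters, delta)
})

test_that("backpropagation matches finite-difference gradients", {
  arch <- cnn_architecture(input_dims = c(6, 6, 6), n_filters = c(3, 4),
                           fc_units = 5, dropout_rate = 0)
  m <- build_cnn(arch, seed = 2)
  set.seed(1)
  xs <- lapply(1:3, function(i) array(rnorm(216), c(6, 6, 6)))
  ys <- c(0L, 1L, 1L)
  lg <- cnn_loss_grad(m, xs, ys, training = FALSE)
  eps <- 1e-5
  check <- function(get, set, analytic) {
    p <- get(m$params)
    for (i in sample(length(p), min(8, length(p)))) {
      m2 <- m
      p1 <- p; p1[i] <- p[i] + eps; m2$params <- set(m$params, p1)
      up <- cnn_eval_loss(m2, xs, ys)
      p2 <- p; p2[i] <- p[i] - eps; m2$params <- set(m$params, p2)
      dn <- cnn_eval_loss(m2, xs, ys)
      expect_equal(analytic[i], (up - dn) / (2 * eps), tolerance = 1e-4)
    }
  }
  set.seed(3)
  check(function(p) p$conv[[1]]$W,
        function(p, v) { p$conv[[1]]$W <- v; p }, lg$grads$conv[[1]]$W)
  check(function(p) p$conv[[2]]$W,
        function(p, v) { p$conv[[2]]$W <- v; p }, lg$grads$conv[[2]]$W)
  check(function(p) p$fc1$W,
        function(p, v) { p$fc1$W <- v; p }, lg$grads$fc1$W)
  check(function(p) p$fc2$b,
        function(p, v) { p$fc2$b <- v; p }, lg$grads$fc2$b)
})

test_that("training reduces the loss on separable blob volumes", {
  arch <- cnn_architecture(input_dims = c(8, 8, 8), n_filters = c(4, 8),
                           fc_units = 8, dropout_rate = 0.2)
  cfg0 <- train_config(learning_rate = 0.01, max_epochs = 10,
                       patience_epochs = 5)
  decreased <- vapply(1:10, function(s) {
    d <- blob_dataset(12, seed0 = 1000 * s)
    m <- build_cnn(arch, seed = s)
    out <- train_with_revert(
      m, d$xs, d$ys,
      train_config(learning_rate = 0.01, max_epochs = 10,
                   patience_epochs = 5, seed = s))
    tail(out$history$train_loss, 1) < out$history$train_loss[1]
  }, TRUE)
  expect_gte(sum(decreased), 9)
})

test_that("revert-style early stopping restores the right checkpoint", {
  arch <- cnn_architecture(input_dims = c(8, 8, 8), n_filters = c(4),
                           fc_units = 4, dropout_rate = 0)
  m <- build_cnn(arch, seed = 1)
  d <- blob_dataset(8)
  # scripted: improving through epoch 12, flat afterwards
  err_seq <- c(seq(1, 0.5, length.out = 12), rep(0.5, 100))
  out <- train_with_revert(
    m, d$xs, d$ys,
    train_config(learning_rate = 0.01, max_epochs = 60,
                 patience_epochs = 10, seed = 1),
    eval_fn = function(model, epoch) err_seq[epoch])
  expect_true(out$reverted)
  expect_equal(out$revert_to, 13)               # first non-improving epoch
  expect_equal(max(out$history$epoch), 22)      # 13 + patience - 1
  # returned model equals the epoch-13 checkpoint (checksum match)
  v <- unlist(out$model$params, use.names = FALSE)
  h <- out$history
  expect_equal(c(sum(v), sum(v^2)),
               c(h$checksum_sum[13], h$checksum_sumsq[13]),
               tolerance = 1e-12)
  # strictly decreasing validation error never triggers a revert
  out2 <- train_with_revert(
    m, d$xs, d$ys,
    train_config(learning_rate = 0.01, max_epochs = 15,
                 patience_epochs = 10, seed = 1),
    eval_fn = function(model, epoch) 1 / epoch)
  expect_false(out2$reverted)
  expect_equal(max(out2$history$epoch), 15)
  expect_error(train_config(max_epochs = 50, patience_epochs = 50),
               "patience")
})

test_that("CGI labelling follows the rule with a strict > 3 boundary", {
  pre <- make_pretrain_cohort(seed = 3, with_volumes = FALSE)
  lab <- assign_cgi_labels(pre$records)
  expect_equal(nrow(lab), 441)
  expect_equal(sum(lab$label == 0), 248)
  expect_equal(sum(lab$label == 1), 193)
  expect_identical(attr(lab, "n_excluded"), 0L)
  # boundary: SZ with CGI 3 is excluded; HC with CGI 0 is label 0
  rec <- data.frame(group = c("HC", "SZ", "SZ", "FDR_SZ", "OCD"),
                    cgi = c(0, 3, 4, 0, 6))
  expect_message(lab2 <- assign_cgi_labels(rec), "1 record")
  expect_equal(nrow(lab2), 4)
  expect_identical(attr(lab2, "n_excluded"), 1L)
  expect_equal(lab2$label[lab2$group == "HC"], 0L)
  expect_true(all(lab2$label[lab2$group %in% c("SZ", "OCD")] == 1L))
})

test_that("stratified oversampling balances classes without touching the majority", {
  pre <- make_pretrain_cohort(seed = 3, with_volumes = FALSE)
  lab <- assign_cgi_labels(pre$records)
  bal <- oversample_balance(lab, seed = 3)
  expect_equal(nrow(bal), 496)
  expect_equal(sum(bal$label == 0), sum(bal$label == 1))
  # majority rows are exactly the original majority rows
  expect_equal(bal[bal$label == 0, names(lab)],
               lab[lab$label == 0, names(lab)], ignore_attr = TRUE)
  # every minority duplicate is one of the original minority records
  expect_true(all(bal$record_id[bal$label == 1] %in%
                    lab$record_id[lab$label == 1]))
  # already balanced input is returned unchanged
  even <- lab[c(which(lab$label == 0)[1:5], which(lab$label == 1)[1:5]), ]
  expect_identical(oversample_balance(even, seed = 1), even)
  # 3/1 duplicates the single minority record up to 3
  small <- data.frame(label = c(0, 0, 0, 1), sex = c(1, 0, 1, 0),
                      age = c(30, 40, 35, 28))
  bal2 <- suppressMessages(oversample_balance(small, seed = 2))
  expect_equal(nrow(bal2), 6)
  expect_equal(sum(bal2$label == 1), 3)
  expect_true(all(bal2$age[bal2$label == 1] == 28))
})

test_that("transfer fine-tuning freezes exactly the requested layers", {
  arch <- cnn_architecture(input_dims = c(8, 8, 8), n_filters = c(4, 8),
                           fc_units = 8, dropout_rate = 0)
  src <- blob_dataset(16, seed0 = 300)
  pre <- train_with_revert(build_cnn(arch, seed = 4), src$xs, src$ys,
                           train_config(learning_rate = 0.01,
                                        max_epochs = 8, patience_epochs = 5,
                                        seed = 4))
  tgt <- blob_dataset(10, seed0 = 700)
  ft <- transfer_finetune(pre$model, tgt$xs, tgt$ys, n_frozen_layers = 2,
                          config = train_config(learning_rate = 0.01,
                                                max_epochs = 6,
                                                patience_epochs = 5,
                                                seed = 5))
  # frozen conv parameters are bit-identical
  expect_identical(ft$model$params$conv, pre$model$params$conv)
  # decision layers did change
  expect_false(identical(ft$model$params$fc1$W, pre$model$params$fc1$W))
  # with nothing frozen, at least one conv parameter moves
  ft0 <- transfer_finetune(pre$model, tgt$xs, tgt$ys, n_frozen_layers = 0,
                           config = train_config(learning_rate = 0.01,
                                                 max_epochs = 3,
                                                 patience_epochs = 2,
                                                 seed = 5))
  expect_false(identical(ft0$model$params$conv, pre$model$params$conv))
  expect_error(transfer_finetune(pre$model, tgt$xs, tgt$ys,
                                 n_frozen_layers = 5), "exceeds")
})

test_that("pre-trained initialization reaches a target loss no later than random", {
  arch <- cnn_architecture(input_dims = c(8, 8, 8), n_filters = c(4, 8),
                           fc_units = 8, dropout_rate = 0)
  src <- blob_dataset(20, seed0 = 40)
  pre <- train_with_revert(build_cnn(arch, seed = 9), src$xs, src$ys,
                           train_config(learning_rate = 0.01,
                                        max_epochs = 25,
                                        patience_epochs = 20, seed = 9))
  epochs_to_hit <- function(history) {
    hit <- which(history$val_error < 0.45)
    if (length(hit)) hit[1] else nrow(history) + 1
  }
  res <- vapply(1:5, function(s) {
    tgt <- blob_dataset(10, seed0 = 5000 + s)
    val <- blob_dataset(10, seed0 = 9000 + s)
    cfg <- train_config(learning_rate = 0.01, max_epochs = 15,
                        patience_epochs = 14, seed = s)
    ft <- transfer_finetune(pre$model, tgt$xs, tgt$ys, n_frozen_layers = 2,
                            config = cfg, val_xs = val$xs, val_ys = val$ys)
    rnd <- train_with_revert(build_cnn(arch, seed = s), tgt$xs, tgt$ys,
                             cfg, val_xs = val$xs, val_ys = val$ys)
    c(pre = epochs_to_hit(ft$history), rand = epochs_to_hit(rnd$history))
  }, c(pre = 0, rand = 0))
  expect_lte(median(res["pre", ]), median(res["rand", ]))
})
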