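# --- exact backpropagation reference ----------------------------------------

test_that("a linear single layer reproduces the closed-form update", {
  set.seed(1)
  ann <- layered_ann(c(3, 2), act = "linear")
  x <- rnorm(3); tgt <- rnorm(2)
  upd <- bp_reference_update(ann, x, tgt)
  expect_equal(upd$dW[[1]], tcrossprod(tgt - drop(ann$W[[1]] %*% x), x))
  # zero mismatch: no update anywhere
  upd0 <- bp_reference_update(ann, x, drop(ann$W[[1]] %*% x))
  expect_true(all(abs(unlist(upd0$dW)) < 1e-14))
})

test_that("backpropagated gradients match central finite differences", {
  set.seed(2)
  ann <- layered_ann(c(4, 3, 2), act = "tanh", gains = 0.7)
  x <- runif(4, -1, 1); tgt <- runif(2, -0.5, 0.5)
  upd <- bp_reference_update(ann, x, tgt)
  loss <- function(a) {
    out <- ann_forward(a, x)$r[[length(a$W) + 1]]
    0.5 * sum((tgt - out)^2)
  }
  h <- 1e-6
  for (l in seq_along(ann$W)) {
    for (idx in seq_len(length(ann$W[[l]]))) {
      ap <- ann; ap$W[[l]][idx] <- ap$W[[l]][idx] + h
      am <- ann; am$W[[l]][idx] <- am$W[[l]][idx] - h
      num <- -(loss(ap) - loss(am)) / (2 * h)       # dW is the neg. gradient
      expect_equal(upd$dW[[l]][idx], num, tolerance = 1e-6)
    }
  }
})

test_that("batched and single forward passes agree", {
  set.seed(3)
  ann <- layered_ann(c(5, 4, 2), act = "tanh")
  X <- matrix(runif(20, -1, 1), 4, 5)
  batch <- ann_forward_batch(ann, X)
  for (i in 1:4)
    expect_equal(batch[i, ], ann_forward(ann, X[i, ])$r[[3]])
})

test_that("gradient descent with frozen lower layers trains only the chosen blocks", {
  set.seed(4)
  task <- generate_teacher_student(3)
  ann <- layered_ann(2^(3:0), act = "tanh")
  W0 <- ann$W
  tr <- ann_train(ann, task$train[1:20], epochs = 2, lr = 0.05,
                  trainable = 2:3)
  expect_identical(tr$ann$W[[1]], W0[[1]])
  expect_false(identical(tr$ann$W[[2]], W0[[2]]))
  expect_false(identical(tr$ann$W[[3]], W0[[3]]))
})

test_that("a fully trained layered network reduces the distillation loss 10-fold", {
  finals <- sapply(1:5, function(s) {
    set.seed(s)
    task <- generate_teacher_student(1)
    ann <- layered_ann(c(2, 1), act = "tanh")
    init <- evaluate_outputs(ann_forward_batch(ann, task$test$inputs),
                             task$test$targets, "mse_loss")
    tr <- ann_train(ann, task$train, epochs = 150, lr = 0.05,
                    eval_data = task$test, eval_every = 150)
    init / tail(tr$record$value, 1)
  })
  expect_gte(median(finals), 10)
})

# --- recurrent baseline ------------------------------------------------------

test_that("unrolled recurrent gradients match finite differences", {
  set.seed(5)
  rnn <- rnn_baseline(tau = 5)
  x <- c(0, 1, 1, 0, -1, -1, 0, 1, 0, -1)        # 10-step toy sequence
  g <- rnn_bptt_grad(rnn, x, target = 0.7)
  loss <- function(r) 0.5 * (0.7 - rnn_forward(r, x)$out)^2
  h <- 1e-6
  for (nm in c("W1", "W2")) {
    for (idx in seq_len(length(rnn[[nm]]))) {
      rp <- rnn; rp[[nm]][idx] <- rp[[nm]][idx] + h
      rm <- rnn; rm[[nm]][idx] <- rm[[nm]][idx] - h
      num <- -(loss(rp) - loss(rm)) / (2 * h)
      expect_equal(g[[paste0("d", nm)]][idx], num, tolerance = 1e-5)
    }
  }
})

test_that("an untrained recurrent readout sits at chance on balanced trials", {
  set.seed(6)
  te <- generate_dms(50, split = "test")
  accs <- sapply(1:10, function(s) {
    set.seed(s + 100)
    rnn_accuracy(rnn_baseline(), te)
  })
  # binomial-style bound around p = 0.5 for a sign readout
  expect_true(all(accs >= 0.2 & accs <= 0.8))
  expect_lt(abs(mean(accs) - 0.5), 0.15)
})

test_that("the recurrent baseline memorises the four noiseless conditions", {
  # fixed delay, one trial per condition: a capacity check
  set.seed(12)
  ds <- generate_dms(4)
  rnn <- rnn_baseline()
  res <- train_rnn_bptt(rnn, ds, epochs = 300, lr = 0.002, eval_data = ds)
  expect_equal(max(res$record$value), 1)
})

# --- metrics -----------------------------------------------------------------

test_that("alignment angles report identical, orthogonal and opposed updates", {
  A <- matrix(1:6, 2, 3)
  expect_equal(alignment_angle(list(A), list(A)), 0)
  expect_equal(alignment_angle(list(A), list(-A)), 180)
  B <- matrix(c(1, 0), 1, 2); C <- matrix(c(0, 1), 1, 2)
  expect_equal(alignment_angle(list(B), list(C)), 90)
  # zero-norm blocks are excluded from the median
  expect_equal(alignment_angle(list(A, A * 0), list(A, A)), 0)
  expect_true(is.na(alignment_angle(list(A * 0), list(A))))
})

test_that("evaluation metrics cover perfect, constant and sign decisions", {
  Y <- matrix(c(1, -1, 1, -1), 4, 1)
  expect_equal(evaluate_outputs(Y, Y, "mse_loss"), 0)
  expect_equal(evaluate_outputs(Y, Y, "accuracy"), 1)
  # constant-zero predictor: loss equals the mean squared target norm
  Z <- matrix(0, 4, 1)
  expect_equal(evaluate_outputs(Z, Y, "mse_loss"), mean(Y^2))
  # argmax decision for one-hot targets
  P <- rbind(c(0.2, 0.7), c(0.9, 0.3))
  T1 <- rbind(c(0, 1), c(1, 0))
  expect_equal(evaluate_outputs(P, T1, "accuracy"), 1)
  expect_error(evaluate_outputs(Y[0, , drop = FALSE], Y[0, , drop = FALSE]),
               "empty")
})
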