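test_that("lagged inputs pad the trial start with the first sample", {
  m <- matrix(rep(2, 19 * 10), 19, 10)
  v <- build_lagged_input(m, 5)
  expect_equal(v, rep(2, 95))

  # t = 1: five copies of sample 1
  ramp <- matrix(rep(0:10, each = 19), 19, 11)
  expect_equal(build_lagged_input(ramp, 1), rep(0, 95))
  # ramp s(t) = t-1: taps [10, 9, 8, 7, 6] per channel at t = 11
  expect_equal(build_lagged_input(ramp, 11),
               rep(c(10, 9, 8, 7, 6), each = 19))
  expect_error(build_lagged_input(ramp, 0), class = "bcisim_index_error")
  expect_error(build_lagged_input(ramp, 12), class = "bcisim_index_error")

  # matrix version row t equals the single-step version
  L <- lagged_input_matrix(ramp)
  for (t in c(1, 3, 11)) {
    expect_equal(L[t, ], build_lagged_input(ramp, t))
  }
})

test_that("forward pass is the documented composition with non-negative output", {
  cfg <- tiny_config()
  net <- init_emulator(cfg, c(A = 2), seed = 1)
  # zero all weights; output biases b -> output max(0, b)
  net$encoder <- lapply(net$encoder, function(m) m * 0)
  net$readouts$A <- lapply(net$readouts$A, function(m) m * 0)
  net$readouts$A$bo <- c(-1, 3)
  x <- runif(cfg$input_dim)
  expect_equal(forward(net, x), c(0, 3))
  # pure function: same input, same output
  expect_identical(forward(net, x), forward(net, x))

  # hand-computed single-hidden-unit composition
  cfg1 <- emulator_config(n_lags = 0, n_sensors = 1, encoder_widths = c(1, 1, 1),
                          readout_hidden_width = 1)
  net1 <- init_emulator(cfg1, c(S = 1), seed = 2)
  net1$encoder <- list(W1 = matrix(0.7), b1 = 0.1, W2 = matrix(1.3), b2 = -0.2,
                       W3 = matrix(0.9), b3 = 0.05)
  net1$readouts$S <- list(Wh = matrix(1.1), bh = 0.3, Wo = matrix(2.5),
                          bo = -0.4)
  x0 <- 0.6
  h <- tanh(1.1 * tanh(0.9 * tanh(1.3 * tanh(0.7 * x0 + 0.1) - 0.2) + 0.05) + 0.3)
  expect_equal(forward(net1, x0), max(0, 2.5 * h - 0.4), tolerance = 1e-12)

  expect_error(set_active_session(net, "nope"),
               class = "bcisim_missing_readout")
})

test_that("MAE loss is the elementwise mean absolute error", {
  a <- matrix(runif(12), 3, 4)
  expect_equal(mae_loss(a, a), 0)
  expect_equal(mae_loss(a + 2, a), 2)
  b <- matrix(runif(12), 3, 4)
  expect_equal(mae_loss(a, b), mean(abs(a - b)))
  expect_error(mae_loss(a, matrix(0, 4, 3)), class = "bcisim_shape_mismatch")
})

test_that("train/validation split is stratified, disjoint and seeded", {
  pairs <- tibble::tibble(condition = rep(1:8, each = 20),
                          id = 1:160)
  sp <- split_train_validation(pairs, fraction = 0.85, seed = 3)
  expect_equal(nrow(sp$train), 8 * 17)
  expect_equal(nrow(sp$validation), 8 * 3)
  expect_true(all(table(sp$train$condition) == 17))
  expect_equal(sort(c(sp$train$id, sp$validation$id)), 1:160)
  sp2 <- split_train_validation(pairs, fraction = 0.85, seed = 3)
  expect_identical(sp$train$id, sp2$train$id)
  expect_error(split_train_validation(pairs, fraction = 1.2),
               class = "bcisim_invalid_parameter")
})

test_that("session training converges, isolates readouts and is seeded", {
  # an already-converged net (zero gradient at entry) returns immediately
  cfg <- tiny_config()
  net <- init_emulator(cfg, c(A = 2, B = 3), seed = 1)
  net$encoder <- lapply(net$encoder, function(m) m * 0)
  net$readouts$A <- lapply(net$readouts$A, function(m) m * 0)
  net$readouts$A$bo <- c(4, 6)
  net$readouts$A$initialized <- TRUE
  X <- matrix(runif(20 * cfg$input_dim), 20)
  Y <- matrix(rep(c(4, 6), each = 20), 20)   # output exactly matches
  res <- train_session(net, X, Y, n_trials = 2,
                       control = emulator_control(warm_start_bias = FALSE))
  expect_equal(res$iterations, 0L)
  expect_equal(res$mae, 0)

  # training session A never touches session B's readout
  set.seed(5)
  net <- init_emulator(cfg, c(A = 2, B = 3), seed = 1)
  before_B <- net$readouts$B
  Y2 <- matrix(runif(40, 0, 10), 20, 2)
  res <- train_session(net, X, Y2, n_trials = 2,
                       control = emulator_control(steps_per_visit = 50))
  expect_identical(res$net$readouts$B, before_B)
  expect_gt(res$iterations, 0)

  # fixed seed reproducibility through the schedule
  pairs <- tibble::tibble(
    session_id = "A", condition = rep(1:2, each = 4),
    X = replicate(8, matrix(runif(5 * cfg$input_dim), 5), simplify = FALSE),
    Y = replicate(8, matrix(runif(10, 0, 5), 5, 2), simplify = FALSE))
  ctl <- emulator_control(steps_per_visit = 30, max_rounds = 2)
  n1 <- train_emulator(pairs, cfg, seed = 7, control = ctl)
  n2 <- train_emulator(pairs, cfg, seed = 7, control = ctl)
  expect_identical(n1$encoder, n2$encoder)
  expect_identical(n1$readouts, n2$readouts)
})

test_that("the emulator learns a learnable kinematics-to-rates map", {
  # rates are a ReLU-affine function of the kinematics: training must beat
  # the mean-rate predictor by a wide margin
  set.seed(8)
  cfg <- tiny_config()
  A <- matrix(rnorm(2 * cfg$input_dim, sd = 2), 2)
  b <- c(3, 5)
  make_X <- function(n) matrix(runif(n * cfg$input_dim), n)
  Xtr <- make_X(400); Xva <- make_X(100)
  Ytr <- t(pmax(A %*% t(Xtr) + b, 0)); Yva <- t(pmax(A %*% t(Xva) + b, 0))
  pairs <- tibble::tibble(
    session_id = "A", condition = rep(1:4, each = 4),
    X = lapply(split(seq_len(400), rep(1:16, each = 25)),
               function(i) Xtr[i, ]),
    Y = lapply(split(seq_len(400), rep(1:16, each = 25)),
               function(i) Ytr[i, ]))
  ctl <- emulator_control(steps_per_visit = 2500, max_rounds = 4, lr = 1e-2,
                          batch_size = 128, lr_decay = 0.7)
  net <- train_emulator(pairs, cfg, seed = 8, control = ctl)
  net <- set_active_session(net, "A")
  val_mae <- mae_loss(forward(net, Xva), Yva)
  expect_lt(val_mae, 0.10 * baseline_mae(Ytr, Yva))
})

test_that("the round schedule updates every session and returns the best round", {
  cfg <- tiny_config()
  set.seed(10)
  pairs <- tibble::tibble(
    session_id = rep(c("A", "B", "C"), each = 4),
    condition = rep(1:2, 6),
    X = replicate(12, matrix(runif(5 * cfg$input_dim), 5), simplify = FALSE),
    Y = replicate(12, matrix(runif(10, 0, 5), 5, 2), simplify = FALSE))
  counts <- vapply(split(pairs$Y, pairs$session_id),
                   function(y) ncol(y[[1]]), integer(1))
  net0 <- init_emulator(cfg, counts, seed = 3)
  before <- net0$readouts
  net <- train_schedule(net0, pairs, seed = 3,
                        control = emulator_control(steps_per_visit = 20,
                                                   max_rounds = 2))
  for (s in c("A", "B", "C")) {
    expect_false(identical(net$readouts[[s]]$Wo, before[[s]]$Wo))
  }
  expect_equal(nrow(net$train_log), 2)
  expect_equal(min(net$train_log$mae), net$train_log$mae[net$best_round])
})

test_that("emulated trials are valid neural trials", {
  cfg <- tiny_config()
  net <- init_emulator(cfg, c(A = 4), seed = 2)
  # constant rest input -> constant rate output
  kin <- matrix(0.4, cfg$n_sensors, 30)
  out <- emulate_trial(net, kin)
  expect_equal(dim(out), c(4L, 30L))
  expect_true(all(abs(out - out[, 1]) < 1e-12))
  # arbitrary input -> finite, non-negative, same length
  kin2 <- matrix(runif(cfg$n_sensors * 25), cfg$n_sensors, 25)
  out2 <- emulate_trial(net, kin2)
  expect_equal(ncol(out2), 25L)
  expect_true(all(is.finite(out2) & out2 >= 0))
})

test_that("reduced emulators exclude the withheld class but still respond to it", {
  cfg <- tiny_config()
  set.seed(12)
  pairs <- tibble::tibble(
    session_id = "A", condition = rep(1:8, each = 2),
    X = replicate(16, matrix(runif(5 * cfg$input_dim), 5), simplify = FALSE),
    Y = replicate(16, matrix(runif(10, 0, 5), 5, 2), simplify = FALSE))
  net <- train_emulator(pairs, cfg, seed = 2,
                        control = emulator_control(steps_per_visit = 10,
                                                   max_rounds = 1),
                        withhold_condition = 3)
  expect_equal(net$withheld_condition, 3)
  out <- forward(net, pairs$X[[5]])  # condition-3 inputs
  expect_true(all(is.finite(out) & out >= 0))
  expect_error(train_emulator(pairs, cfg, withhold_condition = 99),
               class = "bcisim_invalid_parameter")
})
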