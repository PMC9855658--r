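test_that("movement error and variation match hand-computed offsets", {
  start <- c(0, 0); target <- c(10, 0)
  # straight on-axis path
  straight <- cbind(seq(0, 10, length.out = 11), 0)
  expect_equal(movement_error(straight, start, target), 0)
  expect_equal(movement_variation(straight, start, target), 0)
  # constant 2 cm parallel offset
  offset <- cbind(seq(0, 10, length.out = 11), 2)
  expect_equal(movement_error(offset, start, target), 2)
  expect_equal(movement_variation(offset, start, target), 0)
  # offsets {0, 3, 0}: ME = 1, MV = sqrt(3)
  three <- cbind(c(0, 5, 10), c(0, 3, 0))
  expect_equal(movement_error(three, start, target), 1)
  expect_equal(movement_variation(three, start, target), sqrt(3),
               tolerance = 1e-12)
  # offsets {-1, +1}: two-point sample SD = sqrt(2)
  two <- cbind(c(3, 7), c(-1, 1))
  expect_equal(movement_variation(two, start, target), sqrt(2),
               tolerance = 1e-12)
  # signed for MV, absolute for ME
  sym <- cbind(c(0, 2.5, 5, 7.5, 10), c(0, 2, 0, -2, 0))
  expect_equal(movement_error(sym, start, target), 0.8)
  expect_lt(abs(mean(c(0, 2, 0, -2, 0))), 1e-12)
  expect_error(movement_error(straight, c(1, 1), c(1, 1)),
               class = "bcisim_geometry_error")
})

test_that("direction changes count component sign flips with a dead band", {
  start <- c(0, 0); target <- c(10, 0)
  mono <- cbind(seq(0, 10, length.out = 21), 0)
  dc <- direction_changes(mono, start, target)
  expect_equal(dc$MDC, 0L)
  expect_equal(dc$ODC, 0L)
  # overshoot past the target and come back, then out again: two parallel
  # flips (out -> back = 1, back -> out = 1)
  over <- cbind(c(0, 6, 12, 9, 11), 0)
  expect_equal(direction_changes(over, start, target)$ODC, 2L)
  expect_equal(direction_changes(over, start, target)$MDC, 0L)
  # sinusoidal weave whose perpendicular velocity crosses zero 3 times
  x <- seq(0, 10, length.out = 41)
  weave <- cbind(x, sin(2 * pi * x / 5))     # 2 periods: y' has 4 zeros...
  x3 <- seq(0, 7.5, length.out = 31)
  weave3 <- cbind(x3, sin(2 * pi * x3 / 5))  # 1.5 periods: 3 sign flips
  expect_equal(direction_changes(weave3, start, target)$MDC, 3L)
  # dead-band: tiny perpendicular jitter carries the previous sign
  jitter <- cbind(seq(0, 10, length.out = 11),
                  rep(c(0, 1e-9), length.out = 11))
  expect_equal(direction_changes(jitter, start, target, deadband = 1e-6)$MDC,
               0L)
})

test_that("distance ratio matches closed-form paths", {
  straight <- cbind(seq(0, 10, length.out = 11), 0)
  expect_equal(distance_ratio(straight), 1)
  # L-shaped path with legs 3 and 4: (3 + 4) / 5
  ell <- rbind(c(0, 0), c(3, 0), c(3, 4))
  expect_equal(distance_ratio(ell), 7 / 5)
  # dense semicircular arc: pi/2 to high precision
  th <- seq(0, pi, length.out = 1e5 + 1)
  semi <- cbind(5 * cos(th), 5 * sin(th))
  expect_equal(distance_ratio(semi), pi / 2, tolerance = 1e-8)
  expect_warning(dr <- distance_ratio(rbind(c(0, 0), c(1, 1), c(0, 0))))
  expect_true(is.na(dr))
})

test_that("error rate and movement time follow the protocol rules", {
  trials <- tibble::tibble(
    outcome = c(rep("hit", 68), rep("miss", 8), rep("hit", 4)),
    movement_time = c(runif(68, 1, 5), rep(NA, 8), runif(4, 6.6, 6.9)))
  # 8 misses + 4 late hits out of 80
  expect_equal(error_rate(trials, 6.5), 12 / 80)
  expect_equal(error_rate(trials[trials$movement_time < 2 & !is.na(trials$movement_time), , drop = FALSE][1:3, ]), 0)
  allmiss <- tibble::tibble(outcome = rep("miss", 5),
                            movement_time = rep(NA_real_, 5))
  expect_equal(error_rate(allmiss), 1)
  expect_equal(movement_time(2.5, "hit"), 2.5)
  expect_true(is.na(movement_time(2.5, "miss")))
})

test_that("all seven measures are invariant to rigid workspace motions", {
  set.seed(61)
  for (i in 1:5) {
    n <- 60
    traj <- cbind(cumsum(rnorm(n, 0.2)), cumsum(rnorm(n, 0.05)))
    start <- c(0, 0); target <- c(8, 3)
    th <- runif(1, 0, 2 * pi); shift <- rnorm(2, sd = 5)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    tr2 <- t(R %*% t(traj)) + matrix(shift, n, 2, byrow = TRUE)
    s2 <- as.numeric(R %*% start + shift); g2 <- as.numeric(R %*% target + shift)
    expect_equal(movement_error(traj, start, target),
                 movement_error(tr2, s2, g2), tolerance = 1e-9)
    expect_equal(movement_variation(traj, start, target),
                 movement_variation(tr2, s2, g2), tolerance = 1e-9)
    d1 <- direction_changes(traj, start, target)
    d2 <- direction_changes(tr2, s2, g2)
    expect_equal(d1$MDC, d2$MDC)
    expect_equal(d1$ODC, d2$ODC)
    expect_equal(distance_ratio(traj), distance_ratio(tr2), tolerance = 1e-9)
    # DR >= 1 and ME bounded by the largest offset
    expect_gte(distance_ratio(traj), 1)
    offs <- abs((traj[, 1] - start[1]) * (-(target - start)[2]) +
                  (traj[, 2] - start[2]) * (target - start)[1]) /
      sqrt(sum((target - start)^2))
    expect_lte(movement_error(traj, start, target), max(offs) + 1e-12)
  }
})

test_that("metric correlations behave like Pearson correlation", {
  set.seed(62)
  n <- 1000
  su <- tibble::tibble(MV = rnorm(n), ME = NA, MT = rnorm(n),
                       MDC = rnorm(n), ODC = rnorm(n))
  su$ME <- 2 * su$MV + rnorm(n, sd = 0.5)   # affine + noise
  mc <- metric_correlations(su)
  r_mv_me <- mc$r[mc$metric_a == "MV" & mc$metric_b == "ME"]
  # direct formula oracle
  oracle <- sum((su$MV - mean(su$MV)) * (su$ME - mean(su$ME))) /
    sqrt(sum((su$MV - mean(su$MV))^2) * sum((su$ME - mean(su$ME))^2))
  expect_equal(r_mv_me, oracle, tolerance = 1e-12)
  # independent metrics: |r| small
  r_ind <- mc$r[mc$metric_a == "MT" & mc$metric_b == "MDC"]
  expect_lt(abs(r_ind), 0.1)
  # a metric against a copy of itself: r = 1
  su2 <- su; su2$ODC <- su2$MV
  mc2 <- metric_correlations(su2)
  expect_equal(mc2$r[mc2$metric_a == "MV" & mc2$metric_b == "ODC"], 1)
  # constant column flagged
  su3 <- su; su3$MDC <- 1
  expect_warning(metric_correlations(su3[c("MV", "MDC")],
                                     metrics = c("MV", "MDC")),
                 "constant")
  mc3 <- suppressWarnings(metric_correlations(su3))
  expect_true(any(is.na(mc3$r)))
})

test_that("learning correction removes visit effects and isolates sessions", {
  # identical subjects: all corrected scores zero
  su <- tidyr::expand_grid(visit = 1:4, session_id = c("A", "B"))
  su$score <- 10
  res <- learning_corrected_session_effect(su)
  expect_equal(res$sd_across_sessions, 0)
  expect_true(all(res$per_session$mean_corrected == 0))

  # hand-built 2x2 table: visits {1: A=10, B=14}, {2: A=20, B=22}
  su2 <- tibble::tibble(visit = c(1, 1, 2, 2),
                        session_id = c("A", "B", "A", "B"),
                        score = c(10, 14, 20, 22))
  res2 <- learning_corrected_session_effect(su2)
  # visit means 12 and 21 -> corrected A: (-2, -1) mean -1.5; B: (2, 1) 1.5
  expect_equal(sort(res2$per_session$mean_corrected), c(-1.5, 1.5))
  expect_equal(res2$sd_across_sessions, sd(c(-1.5, 1.5)))

  # additive visit effect with no session effect: spread shrinks with n
  set.seed(63)
  big <- tidyr::expand_grid(visit = 1:4,
                            session_id = sprintf("S%02d", 1:6),
                            rep = 1:30)
  big$score <- 2 * big$visit + rnorm(nrow(big), sd = 1)
  res3 <- learning_corrected_session_effect(big[c("visit", "session_id",
                                                  "score")])
  expect_lt(res3$sd_across_sessions, 0.15)
  expect_error(learning_corrected_session_effect(su2[su2$visit == 1, ]),
               class = "bcisim_invalid_parameter")
})
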