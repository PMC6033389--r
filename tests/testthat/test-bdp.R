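test_that("transition probabilities implement the resting and transient rules", {
  s <- 0.0133; b <- 0.0262; dt <- 1e-7
  # extinction is absorbing: zero state gives zero probabilities
  expect_equal(unname(transition_probabilities(0, 5, dt, s, b, "transient",
                                               "primary")), c(0, 0))
  # resting: equal birth and death, x * dt * beta / sigma^2
  pr <- transition_probabilities(50, 0, dt, s, b, "resting", "secondary")
  expect_equal(unname(pr), rep(50 * dt * b / s^2, 2))
  # transient secondary: births blocked
  ps <- transition_probabilities(50, 1000, dt, s, b, "transient", "secondary")
  expect_equal(unname(ps[1]), 0)
  expect_equal(unname(ps[2]), 50 * dt * (1000 * dt + b) / s^2)
  # transient primary: birth and death balance exactly at i * dt = beta
  i_eq <- b / dt
  pp <- transition_probabilities(50, i_eq, dt, s, b, "transient", "primary")
  expect_equal(unname(pp[1]), unname(pp[2]))
  expect_error(transition_probabilities(1e12, 0, 1, s, b, "resting",
                                        "primary"), ">= 1")
})

test_that("simulated trajectories respect the chain's structural contracts", {
  traj <- bdp_simulate(0.0133, 0.0262, n0 = 40, dt = 1e-6, t_rest = 0.002,
                       t_end = 0.004, seed = 1, record_every = 1L)
  expect_true(all(traj$xp >= 0 & traj$xs >= 0))
  expect_true(all(abs(diff(traj$xp)) <= 1))
  expect_true(all(abs(diff(traj$xs)) <= 1))
  expect_equal(traj$xn, traj$xp - traj$xs)
  expect_equal(traj$time[1], -0.002)
  expect_equal(traj$xp[1], 40)
  expect_equal(traj$xs[1], 40)
  # same seed, same trajectory; different seed differs
  t2 <- bdp_simulate(0.0133, 0.0262, n0 = 40, dt = 1e-6, t_rest = 0.002,
                     t_end = 0.004, seed = 1, record_every = 1L)
  expect_identical(traj$xp, t2$xp)
  t3 <- bdp_simulate(0.0133, 0.0262, n0 = 40, dt = 1e-6, t_rest = 0.002,
                     t_end = 0.004, seed = 2, record_every = 1L)
  expect_false(identical(traj$xp, t3$xp))
  # degenerate beta = 0: all rates vanish, trajectories stay constant
  t0 <- bdp_simulate(0.01, 0, n0 = 25, dt = 1e-6, t_rest = 0.001,
                     t_end = 0.001, seed = 3)
  expect_true(all(t0$xp == 25))
  # an oversized step trips the probability guard
  expect_error(bdp_simulate(0.0133, 0.0262, n0 = 5000, dt = 1e-5,
                            t_rest = 0, t_end = 0.01, seed = 1),
               "decrease dt")
})

test_that("the resting process fluctuates around its initial size", {
  # equal birth and death rates make X a martingale: the time-averaged
  # trial mean stays within Monte-Carlo error of N0
  set.seed(42)
  n0 <- 50; trials <- 200
  means <- vapply(seq_len(trials), function(k) {
    traj <- bdp_simulate(0.0133, 0.0262, n0 = n0, dt = 1e-6,
                         t_rest = 0.01, t_end = 1e-6)
    mean(traj$xp[traj$time < 0])
  }, numeric(1))
  se <- sd(means) / sqrt(trials)
  expect_lt(abs(mean(means) - n0), 3 * se + 1e-9)
})

test_that("expected trajectories integrate the rate rules in closed form", {
  s <- 0.0133; b <- 0.0262
  expect_equal(expected_trajectory(s, b, 0, "primary"), 1)
  expect_equal(expected_trajectory(s, b, 0, "secondary"), 1)
  # primary peak at t = beta with value exp(beta^2 / (2 sigma^2))
  tg <- seq(0, 0.07, length.out = 701)
  ep <- expected_trajectory(s, b, tg, "primary")
  expect_equal(tg[which.max(ep)], b, tolerance = 1e-4)
  expect_equal(max(ep), exp(b^2 / (2 * s^2)), tolerance = 1e-6)
  expect_equal(exp(b^2 / (2 * s^2)), 6.96, tolerance = 1e-3)
  # numerical integration of the net rate reproduces the closed form
  for (pop in c("primary", "secondary")) {
    sgn <- if (pop == "primary") -1 else 1
    rho <- vapply(tg, function(tt)
      integrate(function(x) (x + sgn * b) / s^2, 0, tt,
                rel.tol = 1e-10)$value, numeric(1))
    expect_equal(expected_trajectory(s, b, tg, pop), exp(-rho),
                 tolerance = 1e-8)
  }
})

test_that("normalized net trajectories are comparable with psi*", {
  s <- 0.0133; b <- 0.0262
  traj <- bdp_simulate(s, b, n0 = 100, dt = 2e-7, t_rest = 0.001,
                       t_end = 0.05, seed = 11)
  nn <- normalized_net(traj)
  expect_equal(nn$xn_star, traj$xn / 100)
  # psi* equals psi / psi_P(0) on the transient side
  pos <- nn$time >= 0
  psi0 <- exp(-b^2 / (2 * s^2)) / (s * sqrt(2 * pi))
  expect_equal(nn$psi_star[pos],
               hwf_eval(nn$time[pos], s, b) / psi0, tolerance = 1e-10)
  expect_true(all(is.na(nn$psi_star[!pos])))
  # the populations start equal, so Xn* is near 0 just after the switch
  expect_lt(abs(nn$xn_star[which(pos)[1]]), 0.2)
})

test_that("residual analysis is deterministic under seed and exact in the limit", {
  s <- 0.0133; b <- 0.0262
  r1 <- residual_analysis(s, b, n0_values = c(10, 30), trials = 3L,
                          checkpoints = 25L, t_rest = 0.001, t_end = 0.03,
                          seed = 5)
  r2 <- residual_analysis(s, b, n0_values = c(10, 30), trials = 3L,
                          checkpoints = 25L, t_rest = 0.001, t_end = 0.03,
                          seed = 5)
  expect_identical(r1$mean_abs_residual, r2$mean_abs_residual)
  expect_true(all(r1$mean_abs_residual > 0))
  # deterministic surrogate: replacing the simulation with the expected
  # trajectory gives residual 0 by definition
  tk <- seq(0.03 / 25, 0.03, length.out = 25)
  psik <- expected_trajectory(s, b, tk, "primary") -
          expected_trajectory(s, b, tk, "secondary")
  expect_equal(mean(abs(psik - psik)), 0)
})
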