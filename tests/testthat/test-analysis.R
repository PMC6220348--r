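ray_traj <- function(angle, radii) {
  data.frame(x_cm = radii * cos(angle * pi / 180),
             y_cm = radii * sin(angle * pi / 180))
}

test_that("shooting angle interpolates the circle crossing", {
  # collinear samples: exact
  expect_equal(shooting_angle(ray_traj(30, 1:6)), 30, tolerance = 1e-12)
  expect_equal(shooting_angle(ray_traj(-135, 1:6)), -135, tolerance = 1e-12)

  # randomized two-point cases against an independent root-finding oracle:
  # the crossing radius |p1 + s (p2 - p1)| = R solved by uniroot
  set.seed(44)
  for (i in 1:100) {
    th1 <- runif(1, -180, 180); th2 <- th1 + runif(1, -25, 25)
    r1 <- runif(1, 3, 5.2); r2 <- runif(1, 5.4, 7)
    p1 <- r1 * c(cos(th1 * pi / 180), sin(th1 * pi / 180))
    p2 <- r2 * c(cos(th2 * pi / 180), sin(th2 * pi / 180))
    traj <- data.frame(x_cm = c(p1[1], p2[1]), y_cm = c(p1[2], p2[2]))
    # pad an inner sample so the two closest points are p1, p2
    traj <- rbind(c(p1[1] / 10, p1[2] / 10), traj)
    names(traj) <- c("x_cm", "y_cm")
    radius_at <- function(s) sqrt(sum((p1 + s * (p2 - p1))^2)) - 5.3
    s_star <- stats::uniroot(radius_at, c(0, 1), tol = 1e-14)$root
    pt <- p1 + s_star * (p2 - p1)
    oracle <- wrap_angle(atan2(pt[2], pt[1]) * 180 / pi)
    expect_equal(shooting_angle(traj), oracle, tolerance = 1e-9)
  }

  # documented two-sample case: (4.9 cm at 10 deg) then (5.7 cm at 20 deg)
  p1 <- 4.9 * c(cos(10 * pi / 180), sin(10 * pi / 180))
  p2 <- 5.7 * c(cos(20 * pi / 180), sin(20 * pi / 180))
  traj <- data.frame(x_cm = c(p1[1] / 2, p1[1], p2[1]),
                     y_cm = c(p1[2] / 2, p1[2], p2[2]))
  radius_at <- function(s) sqrt(sum((p1 + s * (p2 - p1))^2)) - 5.3
  s_star <- stats::uniroot(radius_at, c(0, 1), tol = 1e-14)$root
  pt <- p1 + s_star * (p2 - p1)
  expect_equal(shooting_angle(traj),
               wrap_angle(atan2(pt[2], pt[1]) * 180 / pi), tolerance = 1e-9)

  expect_error(shooting_angle(ray_traj(12, c(1, 2, 3)), id = 7),
               "no-crossing.*trial 7")
})

test_that("angular error is the wrapped signed difference", {
  expect_equal(angular_error(90, 90), 0)
  expect_equal(angular_error(0, -45), -45)
  expect_equal(angular_error(170, -170), 20)
  expect_equal(angular_error(-170, 170), -20)
  expect_equal(angular_error(0, 180), 180)  # boundary maps to +180
  # randomized check against the mod-360 wrapping oracle
  set.seed(5)
  for (i in 1:200) {
    tg <- runif(1, -720, 720); sh <- runif(1, -720, 720)
    d <- (sh - tg) %% 360
    if (d > 180) d <- d - 360
    expect_equal(angular_error(tg, sh), d, tolerance = 1e-12)
  }
})

fake_table <- function(adapt_err, washout_err, participant = "P1",
                       condition = 1L) {
  n1 <- length(adapt_err); n2 <- length(washout_err)
  tibble::tibble(
    participant = participant, condition = condition,
    block = c(rep("adaptation", n1), rep("washout", n2)),
    trial = seq_len(n1 + n2) - 1L,
    error = c(adapt_err, washout_err))
}

test_that("block windows follow the middle/last/first-10 formulas", {
  # L = 198: middle window is within-block trials 95..104
  tab <- fake_table(seq_len(198), seq_len(80) + 1000)
  s <- block_summary(tab)
  expect_equal(s$adapt_mid10, mean(95:104))
  expect_equal(s$adapt_last10, mean(189:198))
  expect_equal(s$washout_first10, mean(1001:1010))

  # constant error series: all summaries equal the constant
  s2 <- block_summary(fake_table(rep(-20, 50), rep(-20, 20)))
  expect_equal(unlist(s2[c("adapt_mid10", "adapt_last10", "washout_first10")]),
               c(adapt_mid10 = -20, adapt_last10 = -20, washout_first10 = -20))

  # L = 10: the middle window is the whole block
  s3 <- block_summary(fake_table(seq_len(10), rep(0, 10)))
  expect_equal(s3$adapt_mid10, mean(1:10))

  expect_error(block_summary(fake_table(seq_len(9), rep(0, 10))),
               "exceeds block length")
  expect_error(block_summary(fake_table(seq_len(20), numeric(0))), "washout")
})

test_that("exponential fit recovers noiseless parameters exactly", {
  t <- 0:79
  for (A in c(-45, 5, 25, 45)) {
    for (tau in c(2, 10, 30, 60)) {
      fit <- fit_exponential(A * exp(-t / tau))
      expect_equal(fit$A, A, tolerance = 1e-6)
      expect_equal(fit$tau, tau, tolerance = 1e-6)
      expect_gt(fit$r2, 1 - 1e-10)
    }
  }
  z <- fit_exponential(numeric(20))
  expect_equal(z$A, 0)
  expect_false(z$tau_defined)
  expect_true(is.na(z$tau))
  expect_error(fit_exponential(c(1, 2)), "length >= 3")
})

test_that("fitted washout time constant matches the model's decay rate", {
  # noise-free washout of the state-space model decays as (a-b)^t
  params <- model_params(a = 0.98, b = 0.18, sigma_u = 0, sigma_p = 0)
  out <- simulate_phase(data.frame(p = numeric(60), S = numeric(60)),
                        params, p_hat0 = 30)
  fit <- fit_exponential(out$c_obs)
  expect_equal(fit$tau, -1 / log(0.98 - 0.18), tolerance = 1e-4)
  expect_equal(fit$A, -30, tolerance = 1e-4)
})

test_that("profiled fit agrees with an independent nonlinear LS fitter", {
  set.seed(61)
  t <- 0:79
  y <- 20 * exp(-t / 15) + rnorm(80, 0, 1.5)
  fit <- fit_exponential(y)
  nls_fit <- minpack.lm::nlsLM(y ~ A * exp(-t / tau),
                               start = list(A = y[1], tau = 20),
                               control = minpack.lm::nls.lm.control(maxiter = 200))
  ref <- coef(nls_fit)
  expect_equal(fit$A, unname(ref["A"]), tolerance = 1e-4)
  expect_equal(fit$tau, unname(ref["tau"]), tolerance = 1e-4)
})

test_that("participant bootstrap is seeded and degenerates correctly", {
  t <- 0:19
  base <- -12 * exp(-t / 8)
  tabs <- lapply(1:3, function(i) {
    fake_table(rep(0, 12), base, participant = paste0("P", i))
  })
  tab <- dplyr::bind_rows(tabs)
  bt <- bootstrap_fit(tab, "washout", n_resamples = 200, seed = 4)
  # identical participants: resampling cannot move the estimates
  expect_lt(diff(range(bt$samples$A)), 1e-9)
  expect_lt(diff(range(bt$samples$tau)), 1e-9)
  expect_equal(bt$point[["A"]], -12, tolerance = 1e-6)
  expect_equal(bt$point[["tau"]], 8, tolerance = 1e-6)
  ci_A <- bt$ci[bt$ci$param == "A", ]
  expect_lte(ci_A$lower, ci_A$upper)

  bt2 <- bootstrap_fit(tab, "washout", n_resamples = 200, seed = 4)
  expect_identical(bt$samples, bt2$samples)

  expect_error(bootstrap_fit(tabs[[1]], "washout", 10, 1), "at least 2")
})

test_that("bootstrap on a heterogeneous cohort yields ordered, covering CIs", {
  set.seed(71)
  t <- 0:39
  tabs <- lapply(1:8, function(i) {
    amp <- -15 + rnorm(1, 0, 3)
    fake_table(rep(0, 12), amp * exp(-t / 10) + rnorm(40, 0, 1),
               participant = paste0("P", i))
  })
  bt <- bootstrap_fit(dplyr::bind_rows(tabs), "washout",
                      n_resamples = 500, seed = 6)
  # with real between-participant variance, the seed drives the resampling
  expect_false(identical(
    bt$samples,
    bootstrap_fit(dplyr::bind_rows(tabs), "washout",
                  n_resamples = 500, seed = 7)$samples))
  ci <- bt$ci
  expect_true(all(ci$lower <= ci$upper))
  expect_gt(ci$upper[ci$param == "tau"], 0)
  # point estimates fall inside their own percentile intervals
  for (p in c("A", "tau")) {
    expect_gte(bt$point[[p]], ci$lower[ci$param == p] - 1e-9)
    expect_lte(bt$point[[p]], ci$upper[ci$param == p] + 1e-9)
  }
})

make_summaries <- function(values_by_cond, window = "adapt_last10") {
  rows <- lapply(seq_along(values_by_cond), function(cond) {
    v <- values_by_cond[[cond]]
    tibble::tibble(participant = paste0("C", cond, "_", seq_along(v)),
                   condition = cond, adapt_mid10 = v, adapt_last10 = v,
                   washout_first10 = v)
  })
  dplyr::bind_rows(rows)
}

test_that("one-way ANOVA and Tukey behave at the contract level", {
  # four identical groups: no between-condition variance
  s0 <- make_summaries(rep(list(c(-3, -1, 0, 2, 4)), 4))
  res0 <- condition_anova(s0, "adapt_last10")
  expect_lt(res0$F, 1e-20)
  expect_gt(res0$p, 0.999)

  # two groups offset by 30 degrees with tiny noise
  set.seed(13)
  g1 <- rnorm(8, 0, 0.5); g2 <- rnorm(8, -30, 0.5)
  s1 <- make_summaries(list(g1, g2))
  res1 <- condition_anova(s1, "adapt_last10")
  expect_lt(res1$p, 1e-3)
  expect_lt(res1$tukey$p_adj[1], 1e-3)

  # permutation oracle on the same data agrees the effect is real
  obs_F <- res1$F
  y <- c(g1, g2); grp <- rep(1:2, each = 8)
  perm_F <- replicate(999, {
    yp <- sample(y)
    summary(stats::aov(yp ~ factor(grp)))[[1]][["F value"]][1]
  })
  expect_lt((1 + sum(perm_F >= obs_F)) / 1000, 0.01)

  expect_error(condition_anova(make_summaries(list(g1))), "2 conditions")
  expect_error(condition_anova(make_summaries(list(g1, -5))),
               "2 participants")
})

test_that("adaptation-washout correlation handles exact and null cases", {
  x <- c(-25, -18, -12, -6, -1)
  s <- tibble::tibble(participant = paste0("P", 1:5), condition = 2,
                      adapt_mid10 = x, adapt_last10 = x,
                      washout_first10 = 0.5 * x + 3)
  res <- adaptation_washout_correlation(s)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_equal(res$n, 5L)

  set.seed(17)
  big <- tibble::tibble(participant = paste0("P", 1:200), condition = 1,
                        adapt_mid10 = rnorm(200), adapt_last10 = rnorm(200),
                        washout_first10 = rnorm(200))
  expect_lt(abs(adaptation_washout_correlation(big)$r), 0.2)

  few <- s[1:2, ]
  expect_error(adaptation_washout_correlation(few), "fewer than 3")
})

test_that("mean error series averages participants per within-block trial", {
  t <- 0:9
  tab <- dplyr::bind_rows(
    fake_table(rep(0, 12), t * 1.0, participant = "P1"),
    fake_table(rep(0, 12), t * 3.0, participant = "P2"))
  ser <- mean_error_series(tab, "washout")
  expect_equal(ser$t, t)
  expect_equal(ser$mean_error, t * 2.0)
})
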