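test_that("p_off estimation follows the geometric MLE", {
  expect_equal(estimate_poff(rep(10L, 20)), 0.1)
  # recovery on synthetic geometric residence times
  set.seed(30)
  frames <- 1L + rgeom(1e4, 0.02)
  p_hat <- estimate_poff(frames)
  se <- 0.02 / sqrt(1e4)   # asymptotic SE of the geometric MLE ~ p/sqrt(n)
  expect_lt(abs(p_hat - 0.02), 4 * se)
  # infinitely long trajectories -> p_off -> 0
  expect_lt(estimate_poff(rep(1e9L, 20)), 1e-8)
  expect_error(estimate_poff(rep(5L, 5)), "at least 10")
  # the exponential variant agrees to first order
  expect_equal(estimate_poff(frames, method = "exponential"), p_hat,
               tolerance = 0.02)
})

test_that("transition counting is exact and conservative", {
  mk <- function(states, censored = FALSE) {
    tibble::tibble(traj_id = 1L, frame = seq_along(states) - 1L,
                   x_um = 0, y_um = 0, donor_intensity = 0,
                   acceptor_intensity = 0, fret_state = states,
                   starts_at_movie_start = FALSE,
                   ends_at_movie_end = censored)
  }
  c1 <- count_transitions(mk(c("low", "low", "high")))
  expect_equal(c1$N_LL, 1L)
  expect_equal(c1$N_LH, 1L)
  expect_equal(c1$N_HL, 0L)
  expect_equal(c1$N_HH, 0L)
  expect_equal(c1$N_off, 1L)

  c2 <- count_transitions(mk(c("high", "high", "high"), censored = TRUE))
  expect_equal(c2$N_HH, 2L)
  expect_equal(c2$N_off, 0L)

  # conservation: total steps = length - 1 for any sequence
  set.seed(31)
  for (rep in 1:10) {
    states <- sample(c("high", "low"), 15, replace = TRUE)
    cc <- count_transitions(mk(states))
    expect_equal(cc$N_LL + cc$N_LH + cc$N_HL + cc$N_HH, 14L)
  }
  expect_error(count_transitions(mk(c("low", NA, "high"))), "unassigned")
})

test_that("log-likelihood matches the hand-derived value and identities", {
  counts <- tibble::tibble(traj_id = 1L, N_LH = 1L, N_LL = 1L,
                           N_HL = 0L, N_HH = 0L, N_off = 1L)
  # (B(2,2)/B(1,1)) * 0.1 * 0.9^2 = (1/6) * 0.0081... = 0.0135
  ll <- beta_markov_loglik(c(1, 1, 1, 1), counts, p_off = 0.1)
  expect_equal(ll, log((1 / 6) * 0.1 * 0.81), tolerance = 1e-12)
  expect_equal(ll, -4.30507, tolerance = 1e-5)

  # empty corpus: empty product
  expect_equal(beta_markov_loglik(c(1, 1, 1, 1), counts[0, ], 0.1), 0)

  # an all-zero-count trajectory with N_off = 1 adds exactly ln(p_off)
  extra <- dplyr::add_row(counts, traj_id = 2L, N_LH = 0L, N_LL = 0L,
                          N_HL = 0L, N_HH = 0L, N_off = 1L)
  expect_equal(beta_markov_loglik(c(1, 1, 1, 1), extra, 0.1),
               ll + log(0.1), tolerance = 1e-12)
})

test_that("log-likelihood equals a numerical-integration brute force", {
  set.seed(32)
  shapes <- c(2, 50, 2, 25)
  for (rep in 1:5) {
    counts <- tibble::tibble(
      traj_id = 1:5,
      N_LH = rpois(5, 1), N_LL = rpois(5, 6),
      N_HL = rpois(5, 1), N_HH = rpois(5, 4),
      N_off = rbinom(5, 1, 0.8)
    )
    expect_equal(
      beta_markov_loglik(shapes, counts, 0.02),
      loglik_quadrature(shapes, counts, 0.02),
      tolerance = 1e-6
    )
  }
})

test_that("mean rates follow the digamma closed form and its limits", {
  m <- beta_markov_model(1, 1, 1, 1, p_off = 0.02, dt = 0.05)
  r <- mean_rates(m)
  expect_equal(unname(r$rate), c(20, 20))  # psi(2) - psi(1) = 1; 1 / 0.05
  # small-p limit: b -> infinity with a fixed gives r -> a / (b dt)
  m2 <- beta_markov_model(2, 2e5, 2, 2e5, dt = 0.05)
  expect_equal(unname(mean_rates(m2)$rate[2]), 2 / (2e5 * 0.05),
               tolerance = 1e-3)
  # identity r * dt = E[-ln(1 - p)] by Monte-Carlo integration
  set.seed(33)
  p <- rbeta(2e5, 3, 40)
  mc <- mean(-log1p(-p))
  m3 <- beta_markov_model(1, 1, 3, 40, dt = 0.05)
  expect_lt(abs(unname(kd_bar(m3)) * 0.05 - mc),
            4 * sd(-log1p(-p)) / sqrt(2e5))
})

test_that("rate density integrates to 1 and matches the mean rate", {
  m <- beta_markov_model(2, 30, 2.5, 20, dt = 0.05)
  for (w in c("HL", "LH")) {
    dens <- rate_density(m, w, rate = NULL)
    a <- if (w == "HL") m$aHL else m$aLH
    b <- if (w == "HL") m$bHL else m$bLH
    f <- function(r) {
      p <- -expm1(-r * m$dt)
      dbeta(p, a, b) * m$dt * exp(-r * m$dt)
    }
    total <- integrate(f, 0, Inf, rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-6)
    mean_r <- integrate(function(r) r * f(r), 0, Inf, rel.tol = 1e-10)$value
    want <- unname(mean_rates(m)$rate[ifelse(w == "LH", 1, 2)])
    expect_equal(mean_r, want, tolerance = 1e-6)
    expect_true(all(dens$density >= 0))
  }
  # point-mass limit concentrates at -ln(1 - p0) / dt
  m4 <- beta_markov_model(5e4, 45e4, 5e4, 45e4, dt = 0.05)  # p0 = 0.1
  dd <- rate_density(m4, "HL")
  mode_r <- dd$rate[which.max(dd$density)]
  expect_equal(mode_r, -log(0.9) / 0.05, tolerance = 0.05)
})

test_that("MLE recovers generator rates on synthetic corpora", {
  tr <- fret_truth(aLH = 2, bLH = 50, aHL = 2, bHL = 25, p_off = 0.02)
  d <- simulate_fret_trajectories(tr, 3000, seed = 34)
  d$fret_state <- d$true_state
  counts <- count_transitions(d)
  fit <- fit_beta_markov(counts, p_off = 0.02, dt = 0.05)
  r <- mean_rates(fit)
  truth_hl <- (digamma(27) - digamma(25)) / 0.05
  truth_lh <- (digamma(52) - digamma(50)) / 0.05
  expect_lt(abs(r$rate[r$transition == "HL"] - truth_hl),
            3 * r$se[r$transition == "HL"])
  expect_lt(abs(r$rate[r$transition == "LH"] - truth_lh),
            3 * r$se[r$transition == "LH"])
  # permuting trajectory order leaves the likelihood optimum unchanged
  set.seed(35)
  ll1 <- beta_markov_loglik(c(fit$aLH, fit$bLH, fit$aHL, fit$bHL),
                            counts, 0.02)
  ll2 <- beta_markov_loglik(c(fit$aLH, fit$bLH, fit$aHL, fit$bHL),
                            counts[sample(nrow(counts)), ], 0.02)
  expect_equal(ll1, ll2)
})

test_that("homogeneous data concentrate the fitted beta", {
  # all trajectories share one p: the fitted beta should concentrate
  # around it with the mean transition probability correct
  tr <- fret_truth(aLH = 5000, bLH = 45000, aHL = 5000, bHL = 45000,
                   p_off = 0.02)
  d <- simulate_fret_trajectories(tr, 1500, seed = 36)
  d$fret_state <- d$true_state
  fit <- fit_beta_markov(count_transitions(d), p_off = 0.02, dt = 0.05)
  mean_p_hl <- fit$aHL / (fit$aHL + fit$bHL)
  expect_lt(abs(mean_p_hl - 0.1), 0.015)
  expect_gt(fit$aHL + fit$bHL, 50)     # concentrated
})

test_that("dwell bookkeeping includes censored dwells and conserves frames", {
  mk <- function(states) {
    tibble::tibble(traj_id = 1L, frame = seq_along(states) - 1L,
                   fret_state = states)
  }
  dw <- dwell_times(mk(c("high", "high", "low", "high")))
  expect_equal(dw$frames[dw$state == "high"], c(2L, 1L))
  expect_equal(dw$frames[dw$state == "low"], 1L)
  expect_equal(sum(dw$frames), 4L)     # conservation

  dw2 <- dwell_times(mk(rep("high", 10)))
  expect_equal(dw2$frames, 10L)

  cc <- dwell_ccdf(dw, dt = 0.05)
  expect_equal(cc$ccdf[cc$state == "high" & cc$tau == 0.05], 1)
})

test_that("model simulation reproduces dwell distributions of held-out data", {
  tr <- fret_truth(aLH = 2, bLH = 40, aHL = 2, bHL = 20, p_off = 0.05)
  train <- simulate_fret_trajectories(tr, 1500, seed = 37)
  train$fret_state <- train$true_state
  res_frames <- train |> dplyr::count(traj_id) |> dplyr::pull(n)
  fit <- fit_beta_markov(count_transitions(train),
                         p_off = estimate_poff(res_frames), dt = 0.05)

  # p_HL point mass at 1 -> all high dwells are one frame
  m1 <- beta_markov_model(1e6, 1e-3, 1e6, 1e-3, p_off = 0.1, dt = 0.05)
  sim1 <- simulate_beta_markov(m1, residence_frames = rep(20L, 10), n = 50,
                               seed = 38)
  hi <- sim1$dwells |>
    dplyr::filter(state == "high") |>
    dplyr::pull(frames)
  expect_true(all(hi == 1L))

  # held-out comparison: simulated dwell CCDF tracks the empirical one
  heldout <- simulate_fret_trajectories(tr, 1500, seed = 39)
  heldout$fret_state <- heldout$true_state
  emp <- dwell_ccdf(dwell_times(heldout), dt = 0.05)
  sim <- simulate_beta_markov(fit, res_frames, n = 3000, seed = 40)
  for (st in c("high", "low")) {
    e <- emp[emp$state == st & emp$tau <= 0.5, ]
    s <- sim$ccdf[sim$ccdf$state == st, ]
    s_at <- approx(s$tau, s$ccdf, xout = e$tau, rule = 2)$y
    expect_lt(max(abs(s_at - e$ccdf)), 0.06)
  }

  # fixed seed reproducibility
  sim_b <- simulate_beta_markov(fit, res_frames, n = 3000, seed = 40)
  expect_identical(sim$ccdf, sim_b$ccdf)
})
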