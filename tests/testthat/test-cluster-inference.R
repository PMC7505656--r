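test_that("trajectory diffusion coefficient follows its definition", {
  # every squared displacement = 0.01 um^2 at dt = 0.05 -> D_T = 0.05
  d <- tibble::tibble(traj_id = 1L, frame = 0:9,
                      x_um = 0.1 * (0:9), y_um = 0)
  out <- trajectory_diffusion(d, dt = 0.05)
  expect_equal(out$D_T, 0.05)
  expect_false(out$immobile)

  # stationary trajectory -> 0, flagged
  d0 <- tibble::tibble(traj_id = 1L, frame = 0:9, x_um = 1, y_um = 1)
  out0 <- trajectory_diffusion(d0, dt = 0.05)
  expect_equal(out0$D_T, 0)
  expect_true(out0$immobile)

  # Brownian ensemble recovery
  tr <- fret_truth(cluster_size_law = function(n) rep(1, n), fL = 0.5)
  sim <- simulate_friction_trajectories(tr, 300, n_frames = 100, seed = 50)
  est <- trajectory_diffusion(sim$trajectories, dt = 0.05)
  se <- sd(est$D_T) / sqrt(nrow(est))
  expect_lt(abs(mean(est$D_T) - 2), 3 * se)
})

test_that("friction inversion and cluster size arithmetic", {
  rec <- friction_records(tibble::tibble(traj_id = 1L, D_T = 2), fL = 0.5)
  expect_equal(rec$f, 0.5)
  expect_equal(rec$N, 1)                     # monomer
  rec2 <- friction_records(tibble::tibble(traj_id = 1L, D_T = 1 / 14.5),
                           fL = 0.5)
  expect_equal(rec2$N, 29)
  # time-unit rescaling consistency: D in um^2/min with fL in min/um^2
  rec3 <- friction_records(tibble::tibble(traj_id = 1L, D_T = 2 * 60),
                           fL = 0.5 / 60)
  expect_equal(rec3$N, 1)
  # immobile records are excluded
  expect_message(
    out <- friction_records(tibble::tibble(traj_id = 1:2, D_T = c(0, 1))),
    "excluded")
  expect_equal(nrow(out), 1L)
})

test_that("size distributions are normalized and match their law", {
  d1 <- cluster_size_distribution(rep(1, 50))
  expect_equal(nrow(d1), 1L)
  expect_equal(d1$prob, 1)

  set.seed(51)
  N <- 1 + rexp(2e4, 1 / 29)
  dist <- cluster_size_distribution(N, binning = "linear", bin_width = 5)
  expect_equal(sum(dist$prob), 1)
  # chi-square of the histogram against the generating density
  lo <- dist$bin_center - 2.5
  hi <- dist$bin_center + 2.5
  p_theo <- pexp(pmax(hi - 1, 0), 1 / 29) - pexp(pmax(lo - 1, 0), 1 / 29)
  keep <- dist$count >= 5
  chi <- suppressWarnings(
    chisq.test(dist$count[keep], p = p_theo[keep], rescale.p = TRUE))
  expect_gt(chi$p.value, 0.001)
})

test_that("characteristic-size fit is exact on exact exponential input", {
  for (N0 in c(29, 34)) {
    N <- seq(2, 120, by = 4)
    dist <- tibble::tibble(bin_center = N, prob = 0.2 * exp(-N / N0))
    fit <- suppressWarnings(fit_characteristic_size(dist))
    expect_equal(fit$N0, N0, tolerance = 1e-8)
    expect_equal(fit$A, 0.2, tolerance = 1e-8)
  }
  # smallest-bin removal: corrupting only the smallest bin changes nothing
  N <- seq(2, 120, by = 4)
  dist <- tibble::tibble(bin_center = N, prob = 0.2 * exp(-N / 29))
  dist$prob[1] <- 0.9
  fit <- suppressWarnings(fit_characteristic_size(dist))
  expect_equal(fit$N0, 29, tolerance = 1e-8)
  # a non-decaying distribution is flagged
  flat <- tibble::tibble(bin_center = N, prob = seq_along(N))
  w <- capture_warnings(f2 <- fit_characteristic_size(flat))
  expect_true(any(grepl("does not decay", w)))
  expect_false(f2$reliable)
})

test_that("generative recovery of the characteristic size", {
  tr <- fret_truth(fL = 0.5,
                   cluster_size_law = function(n) 1 + rexp(n, 1 / 29))
  sim <- simulate_friction_trajectories(tr, 4000, n_frames = 150, seed = 52)
  rec <- friction_records(trajectory_diffusion(sim$trajectories, dt = 0.05),
                          fL = 0.5)
  dist <- cluster_size_distribution(rec$N, binning = "linear", bin_width = 6)
  fit <- fit_characteristic_size(dist)
  expect_true(fit$reliable)
  expect_lt(abs(fit$N0 - 29), 3 * fit$se + 2)
})

test_that("ensemble-time-averaged MSD matches the brute-force double loop", {
  set.seed(53)
  d <- purrr::map_dfr(1:5, function(i) {
    n <- sample(7:12, 1)
    tibble::tibble(traj_id = i, frame = seq_len(n) - 1L,
                   x_um = cumsum(rnorm(n, 0, 0.1)),
                   y_um = cumsum(rnorm(n, 0, 0.1)))
  })
  mine <- eta_msd(d, dt = 0.06, max_frames = 6)
  oracle <- eta_msd_bruteforce(d, dt = 0.06, max_frames = 6)
  expect_equal(mine$lag, oracle$lag)
  expect_equal(mine$msd, oracle$msd, tolerance = 1e-12)

  # immobile trajectories give identically zero MSD
  d0 <- tibble::tibble(traj_id = 1L, frame = 0:9, x_um = 2, y_um = 3)
  expect_true(all(eta_msd(d0, dt = 0.06)$msd == 0))

  # short trajectories are excluded
  expect_error(eta_msd(d[d$frame < 5, ], dt = 0.06), "longer than")
})

test_that("Brownian MSD fit recovers the diffusion coefficient", {
  # exact line: msd = (0.4, 0.8) at lag = (0.1, 0.2) -> D_TA = 1
  msd <- tibble::tibble(lag = c(0.1, 0.2), msd = c(0.4, 0.8))
  expect_equal(fit_brownian_msd(msd)$D_TA, 1)
  # linearity: doubling the MSD doubles D_TA
  expect_equal(fit_brownian_msd(dplyr::mutate(msd, msd = 2 * msd))$D_TA, 2)

  # recovery on a synthetic Brownian ensemble at dt = 0.06
  tr <- fret_truth(cluster_size_law = function(n) rep(1, n), fL = 0.5)
  sim <- simulate_friction_trajectories(tr, 500, n_frames = 10, dt = 0.06,
                                        seed = 54)
  curve <- eta_msd(sim$trajectories, dt = 0.06, max_frames = 6)
  fit <- fit_brownian_msd(curve)
  expect_lt(abs(fit$D_TA - 2), 3 * fit$se + 0.05)
  expect_equal(curve$msd[curve$lag == 0.06], 4 * 2 * 0.06, tolerance = 0.1)
})

test_that("surface coverage arithmetic and bounds", {
  cov <- surface_coverage(n_D = 100, n_A = 20, n_D_AC = 10,
                          A_D = 1000, R_D = 0.001)
  expect_equal(cov$theta, 110)
  expect_equal(surface_coverage(50, 30, 80, 1000, 0.01)$theta, 0)
  expect_equal(surface_coverage(1111, 0, 0, 1, 1)$fractional,
               1111 * 9e-6)
  expect_error(surface_coverage(10, 5, 50, 1000, 0.01), "contamination")
  expect_error(surface_coverage(10, 5, 1, 1000, 0))
})
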