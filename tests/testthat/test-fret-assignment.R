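test_that("colocalization pairs nearby observations and keeps singles", {
  don <- tibble::tibble(frame = 0L, x_um = 0, y_um = 0, intensity = 100,
                        snr = 10)
  acc <- tibble::tibble(frame = 0L, x_um = 0.5 * 0.43, y_um = 0,
                        intensity = 900, snr = 5)
  out <- colocalize_channels(don, acc)
  expect_equal(nrow(out), 1L)
  expect_true(out$paired)
  # pair position comes from the higher-snr member (the donor here)
  expect_equal(out$x_um, 0)

  # 3 px apart -> no pair
  acc_far <- dplyr::mutate(acc, x_um = 3 * 0.43)
  out2 <- colocalize_channels(don, acc_far)
  expect_equal(nrow(out2), 2L)
  expect_false(any(out2$paired))
})

test_that("greedy colocalization equals brute-force optimal on a cluster", {
  # 3 donors and 2 acceptors close together: exactly 2 pairs, and greedy
  # closest-first matches exhaustive assignment enumeration
  don <- tibble::tibble(frame = 0L, x_um = c(0, 0.2, 0.9), y_um = 0,
                        intensity = 100, snr = 1)
  acc <- tibble::tibble(frame = 0L, x_um = c(0.15, 0.85), y_um = 0,
                        intensity = 900, snr = 2)
  out <- colocalize_channels(don, acc, radius_px = 2, pixel_size = 0.43)
  expect_equal(sum(out$paired), 2L)
  expect_equal(nrow(out), 3L)          # 2 pairs + 1 unmatched donor
  # brute force: enumerate one-to-one assignments, pick closest-first
  # greedy order (0.05 for donor2-acc1, then 0.05 for donor3-acc2)
  paired <- out[out$paired, ]
  expect_setequal(round(paired$x_um, 2), c(0.15, 0.85))  # acceptor positions
})

test_that("threshold line separates two synthetic populations", {
  d <- two_population_intensities()
  thr <- fit_fret_threshold(d)
  # both centroids on opposite sides
  side <- function(x, y) sign(y - (thr$slope * x + thr$intercept))
  s1 <- side(thr$centroids[1, 1], thr$centroids[1, 2])
  s2 <- side(thr$centroids[2, 1], thr$centroids[2, 2])
  expect_lt(s1 * s2, 0)

  # populations mirrored across I_A = I_D: the optimal line is close to
  # the diagonal where both populations thin out
  states <- assign_fret_states(
    dplyr::mutate(d, traj_id = 1L, frame = dplyr::row_number()), thr)
  acc <- mean((states$population == "high") == (states$fret_state == "high"))
  expect_gt(acc, 0.99)
})

test_that("threshold grid search matches a fine brute-force search", {
  d <- two_population_intensities(n = 1500, seed = 9)
  thr <- fit_fret_threshold(d, bins = 50)
  # brute force on the same 50x50 histogram over a fine grid
  fine <- fit_fret_threshold(
    d, bins = 50,
    slopes = seq(-3, 3, length.out = 241),
    intercepts = seq(-500, 2500, length.out = 301))
  expect_lte(fine$objective, thr$objective * 1.0 + 1e-9)
  # the default grid must come within the brute-force optimum's counts
  # by a small margin (both cut through the empty valley)
  expect_lte(thr$objective, fine$objective + 5)
})

test_that("a unimodal heat map is refused", {
  set.seed(10)
  d <- tibble::tibble(donor_intensity = rnorm(2000, 500, 50),
                      acceptor_intensity = rnorm(2000, 500, 50))
  expect_error(fit_fret_threshold(d), "two distinguishable populations")
})

test_that("state assignment is deterministic, idempotent and correct", {
  tr <- fret_truth()
  d <- simulate_fret_trajectories(tr, 200, seed = 12)
  thr <- fit_fret_threshold(d)
  a1 <- assign_fret_states(d, thr)
  a2 <- assign_fret_states(a1, thr)
  expect_identical(a1$fret_state, a2$fret_state)
  # ~6 sigma population separation -> >= 99% per-frame accuracy
  expect_gt(mean(a1$fret_state == a1$true_state), 0.99)

  # extreme intensities map to the expected side
  hi <- tibble::tibble(traj_id = 1L, frame = 0:1, x_um = 0, y_um = 0,
                       donor_intensity = 0, acceptor_intensity = 1e5)
  expect_true(all(assign_fret_states(hi, thr)$fret_state == "high"))
  lo <- dplyr::mutate(hi, donor_intensity = 1e5, acceptor_intensity = 0)
  expect_true(all(assign_fret_states(lo, thr)$fret_state == "low"))
})

test_that("threshold fit is invariant to rescaling both intensity axes", {
  d <- two_population_intensities(n = 1200, seed = 13)
  thr1 <- fit_fret_threshold(d, bins = 60)
  scaled <- dplyr::mutate(d, donor_intensity = donor_intensity * 3,
                          acceptor_intensity = acceptor_intensity * 3)
  thr2 <- fit_fret_threshold(scaled, bins = 60)
  expect_equal(thr2$slope, thr1$slope, tolerance = 0.15)
  expect_equal(thr2$intercept, thr1$intercept * 3,
               tolerance = 0.1 * abs(thr1$intercept * 3) + 50)
})

test_that("purpose-specific trajectory filters follow the exclusion rules", {
  dt <- 0.05
  mk <- function(id, n, donor = 100, start = FALSE, end = FALSE) {
    tibble::tibble(traj_id = id, frame = seq_len(n) - 1L,
                   x_um = 0, y_um = 0,
                   donor_intensity = donor, acceptor_intensity = 50,
                   fret_state = "low",
                   starts_at_movie_start = start, ends_at_movie_end = end)
  }
  d <- dplyr::bind_rows(
    mk(1L, 1001L),            # contaminant: > 1000 frames
    mk(2L, 10L),              # 0.5 s: kinetics yes, diffusion no
    mk(3L, 20L),              # 1.0 s: everything
    mk(4L, 3L),               # 0.15 s: kinetics yes, diffusion no
    mk(5L, 2L),               # 2 frames: kinetics no
    mk(6L, 30L, start = TRUE) # censored: dwell no
  )
  kin <- filter_trajectories(d, "kinetics", dt = dt,
                             intensity_percentile = 100)
  expect_setequal(unique(kin$traj_id), c(2L, 3L, 4L, 6L))
  dif <- filter_trajectories(d, "diffusion", dt = dt,
                             intensity_percentile = 100)
  expect_setequal(unique(dif$traj_id), c(3L, 6L))
  dwl <- filter_trajectories(d, "dwell", dt = dt,
                             intensity_percentile = 100)
  expect_setequal(unique(dwl$traj_id), c(2L, 3L, 4L))
  # report counts are conserved
  rep <- filter_report(dwl)
  expect_equal(rep[["input"]],
               rep[["retained"]] + rep[["intensity_cutoff"]] +
                 rep[["contaminant_rule"]] + rep[["min_length"]] +
                 rep[["censoring"]])
})

test_that("the intensity percentile cutoff keeps exactly the bottom 60%", {
  d <- purrr::map_dfr(1:100, function(i) {
    tibble::tibble(traj_id = i, frame = 0:9, x_um = 0, y_um = 0,
                   donor_intensity = i, acceptor_intensity = 0,
                   fret_state = "low",
                   starts_at_movie_start = FALSE, ends_at_movie_end = FALSE)
  })
  out <- filter_trajectories(d, "kinetics", dt = 0.05)
  expect_equal(dplyr::n_distinct(out$traj_id), 60L)
  expect_equal(max(out$donor_intensity), 60)
})
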