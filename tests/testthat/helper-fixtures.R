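# shared fixture builders; everything is generated in code at test time

# minimal hand-built trajectory table
toy_trajectories <- function() {
  tibble::tibble(
    traj_id = c(1L, 1L, 1L, 2L, 2L),
    frame = c(0L, 1L, 2L, 5L, 6L),
    x_um = c(0, 0.1, 0.2, 3, 3.1),
    y_um = c(0, 0, 0, 1, 1),
    donor_intensity = c(100, 110, 90, 500, 520),
    acceptor_intensity = c(900, 950, 880, 40, 60),
    fret_state = c("high", "high", "low", "low", "low"),
    starts_at_movie_start = FALSE,
    ends_at_movie_end = c(FALSE, FALSE, FALSE, TRUE, TRUE)
  )
}

# two well-separated intensity populations (acceptor-rich and donor-rich)
two_population_intensities <- function(n = 2000, sep = 1000, sd = 60,
                                       seed = 42) {
  set.seed(seed)
  high <- tibble::tibble(donor_intensity = rnorm(n, 100, sd),
                         acceptor_intensity = rnorm(n, sep, sd))
  low <- tibble::tibble(donor_intensity = rnorm(n, sep, sd),
                        acceptor_intensity = rnorm(n, 100, sd))
  dplyr::bind_rows(high = high, low = low, .id = "population")
}

# brute-force greedy nearest-neighbour linking oracle on a tiny instance:
# enumerates pairs by distance, links closest-first within the radius
link_bruteforce <- function(locs, radius) {
  locs <- dplyr::arrange(locs, .data$frame)
  locs$traj_id <- NA_integer_
  next_id <- 1L
  frames <- sort(unique(locs$frame))
  for (fi in seq_along(frames)) {
    cur <- which(locs$frame == frames[fi])
    prev <- if (fi > 1L && frames[fi] - frames[fi - 1L] == 1L) {
      which(locs$frame == frames[fi - 1L])
    } else integer(0)
    if (length(prev) > 0L) {
      pairs <- expand.grid(p = prev, c = cur)
      pairs$d <- sqrt((locs$x_um[pairs$p] - locs$x_um[pairs$c])^2 +
                      (locs$y_um[pairs$p] - locs$y_um[pairs$c])^2)
      pairs <- pairs[order(pairs$d, pairs$p, pairs$c), ]
      used_p <- used_c <- integer(0)
      for (k in seq_len(nrow(pairs))) {
        if (pairs$d[k] > radius) break
        if (pairs$p[k] %in% used_p || pairs$c[k] %in% used_c) next
        locs$traj_id[pairs$c[k]] <- locs$traj_id[pairs$p[k]]
        used_p <- c(used_p, pairs$p[k])
        used_c <- c(used_c, pairs$c[k])
      }
    }
    new <- cur[is.na(locs$traj_id[cur])]
    if (length(new) > 0L) {
      locs$traj_id[new] <- seq.int(next_id, length.out = length(new))
      next_id <- next_id + length(new)
    }
  }
  locs
}

# numerical-integration oracle for the beta-Markov likelihood of one
# trajectory: marginalize the transition probabilities over their beta
# densities by quadrature instead of using the beta-function identity
loglik_quadrature <- function(shapes, counts, p_off) {
  aLH <- shapes[1]; bLH <- shapes[2]; aHL <- shapes[3]; bHL <- shapes[4]
  per_traj <- vapply(seq_len(nrow(counts)), function(k) {
    row <- counts[k, ]
    f_lh <- function(p) {
      p^row$N_LH * (1 - p)^row$N_LL * stats::dbeta(p, aLH, bLH)
    }
    f_hl <- function(p) {
      p^row$N_HL * (1 - p)^row$N_HH * stats::dbeta(p, aHL, bHL)
    }
    i_lh <- stats::integrate(f_lh, 0, 1, rel.tol = 1e-12)$value
    i_hl <- stats::integrate(f_hl, 0, 1, rel.tol = 1e-12)$value
    n_steps <- row$N_LL + row$N_LH + row$N_HL + row$N_HH
    log(i_lh) + log(i_hl) + row$N_off * log(p_off) +
      n_steps * log(1 - p_off)
  }, 0)
  sum(per_traj)
}

# brute-force ensemble-time-averaged MSD (direct double loop)
eta_msd_bruteforce <- function(data, dt, max_frames = 6L,
                               min_avg_frames = 3L) {
  ids <- unique(data$traj_id)
  kept <- list()
  for (id in ids) {
    tr <- data[data$traj_id == id, ]
    tr <- tr[order(tr$frame), ]
    if (nrow(tr) <= max_frames) next
    kept[[length(kept) + 1L]] <- tr[seq_len(max_frames), ]
  }
  lags <- integer(0)
  for (m in seq_len(max_frames)) {
    if (max_frames - m > min_avg_frames) lags <- c(lags, m)
  }
  msd <- vapply(lags, function(m) {
    per <- vapply(kept, function(tr) {
      Tn <- nrow(tr)
      acc <- 0
      cnt <- 0
      for (s in 1:(Tn - m)) {
        acc <- acc + (tr$x_um[s + m] - tr$x_um[s])^2 +
          (tr$y_um[s + m] - tr$y_um[s])^2
        cnt <- cnt + 1
      }
      acc / cnt
    }, 0)
    mean(per)
  }, 0)
  tibble::tibble(lag = lags * dt, msd = msd)
}
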