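#' Ground truth for synthetic FRET trajectory generation
#'
#' Bundles the generative quantities the analysis pipeline assumes: beta
#' shape parameters for the per-trajectory high/low transition
#' probabilities, a per-frame termination probability, state-dependent
#' diffusion coefficients (optionally mixtures), the lipid friction factor,
#' a cluster-size law, and the two-channel intensity model.
#'
#' Defaults are the study conditions used throughout the package: the
#' high-FRET state diffuses at 0.44 um^2/s, the low-FRET state at
#' 0.569 um^2/s, the lipid friction factor is 0.5 s/um^2 (i.e. a lipid
#' diffuses at 2 um^2/s), the acquisition interval is 50 ms, and the
#' intensity model is acceptor-dominant in the high-FRET state and
#' donor-dominant in the low-FRET state.
#'
#' @param aLH,bLH Beta shapes for the low-to-high transition probability.
#' @param aHL,bHL Beta shapes for the high-to-low transition probability.
#' @param p_off Per-frame termination (photobleaching/desorption)
#'   probability, in `[0, 1)`.
#' @param D_high,D_low State diffusion coefficients in um^2/s. Each may be
#'   a single value or a two-column object coercible to a tibble with
#'   columns `fraction` and `D` (a diffusivity mixture).
#' @param fL Lipid friction factor in s/um^2 (per kBT).
#' @param cluster_size_law Function `n -> N` drawing `n` cluster sizes
#'   (>= 1). Default: exponential with characteristic size 29, shifted to
#'   a minimum of 1 (monomer).
#' @param intensity_mean,intensity_sd Named lists with entries `high` and
#'   `low`, each a length-2 numeric `c(donor, acceptor)`, giving the
#'   Gaussian intensity model per state.
#' @param p_start_censor,p_end_censor Probability a trajectory is flagged
#'   as observed in the first / last movie frame (exercises the
#'   censoring-exclusion filters).
#' @return A list of class `fret_truth`.
#' @export
fret_truth <- function(aLH = 2, bLH = 50,
                       aHL = 2, bHL = 25,
                       p_off = 0.02,
                       D_high = 0.44, D_low = 0.569,
                       fL = 0.5,
                       cluster_size_law = function(n) 1 + stats::rexp(n, rate = 1 / 29),
                       intensity_mean = list(high = c(100, 1000), low = c(1000, 100)),
                       intensity_sd = list(high = c(60, 150), low = c(150, 60)),
                       p_start_censor = 0.02, p_end_censor = 0.02) {
  stopifnot(aLH > 0, bLH > 0, aHL > 0, bHL > 0,
            p_off >= 0, p_off < 1, fL > 0,
            p_start_censor >= 0, p_start_censor <= 1,
            p_end_censor >= 0, p_end_censor <= 1)
  as_mixture <- function(D) {
    if (is.numeric(D) && length(D) == 1L) {
      D <- tibble::tibble(fraction = 1, D = D)
    } else {
      D <- tibble::as_tibble(D)
    }
    stopifnot(all(c("fraction", "D") %in% names(D)),
              all(D$D > 0), all(D$fraction >= 0),
              abs(sum(D$fraction) - 1) < 1e-8)
    D
  }
  structure(
    list(aLH = aLH, bLH = bLH, aHL = aHL, bHL = bHL, p_off = p_off,
         D_high = as_mixture(D_high), D_low = as_mixture(D_low),
         fL = fL, cluster_size_law = cluster_size_law,
         intensity_mean = intensity_mean, intensity_sd = intensity_sd,
         p_start_censor = p_start_censor, p_end_censor = p_end_censor),
    class = "fret_truth"
  )
}

#' @export
print.fret_truth <- function(x, ...) {
  cat("<fret_truth>\n")
  cat(sprintf("  p(L->H) ~ Beta(%.3g, %.3g)   p(H->L) ~ Beta(%.3g, %.3g)\n",
              x$aLH, x$bLH, x$aHL, x$bHL))
  cat(sprintf("  p_off = %.4g per frame; fL = %.3g s/um^2\n", x$p_off, x$fL))
  cat(sprintf("  D_high mixture: %s um^2/s; D_low mixture: %s um^2/s\n",
              paste(signif(x$D_high$D, 3), collapse = "/"),
              paste(signif(x$D_low$D, 3), collapse = "/")))
  invisible(x)
}

.draw_mixture_D <- function(mixture, n) {
  idx <- sample.int(nrow(mixture), n, replace = TRUE, prob = mixture$fraction)
  mixture$D[idx]
}

#' Simulate two-channel FRET trajectories
#'
#' Generates a ground-truth-labeled trajectory table. Each trajectory draws
#' its own transition probabilities `(pLH, pHL)` from the beta
#' distributions, then evolves frame by frame: survive with probability
#' `1 - p_off`, switch state with the drawn probability, take a 2D Brownian
#' step with the current state's diffusion coefficient, and emit donor and
#' acceptor intensities from the state's Gaussian intensity model
#' (truncated at zero).
#'
#' @param truth A [fret_truth()] object.
#' @param n_traj Number of trajectories.
#' @param dt Acquisition interval in seconds.
#' @param max_frames Hard cap on trajectory length (default 5000), so
#'   `p_off = 0` cannot produce infinite trajectories.
#' @param seed Optional integer seed for reproducibility.
#' @return A trajectory table with extra columns `true_state` (the
#'   generating state) and attributes `truth` (the input), `params`
#'   (tibble of per-trajectory `pLH`, `pHL`) and `dt`.
#' @export
simulate_fret_trajectories <- function(truth, n_traj, dt = 0.05,
                                       max_frames = 5000L, seed = NULL) {
  stopifnot(inherits(truth, "fret_truth"), n_traj > 0, dt > 0, max_frames >= 2)
  if (!is.null(seed)) set.seed(seed)
  pLH <- stats::rbeta(n_traj, truth$aLH, truth$bLH)
  pHL <- stats::rbeta(n_traj, truth$aHL, truth$bHL)
  # geometric trajectory lengths (mean 1/p_off frames), floored at 2 so
  # every trajectory has a displacement, capped at max_frames
  n_frames <- if (truth$p_off > 0) {
    pmin(pmax(2L, 1L + stats::rgeom(n_traj, truth$p_off)), max_frames)
  } else {
    rep(as.integer(max_frames), n_traj)
  }
  starts <- stats::runif(n_traj) < truth$p_start_censor
  ends <- stats::runif(n_traj) < truth$p_end_censor

  sim_one <- function(k) {
    nf <- n_frames[k]
    state <- integer(nf)            # 1 = low, 2 = high
    state[1L] <- sample(1:2, 1L)
    if (nf > 1L) {
      u <- stats::runif(nf - 1L)
      for (i in 2L:nf) {
        p_switch <- if (state[i - 1L] == 1L) pLH[k] else pHL[k]
        state[i] <- if (u[i - 1L] < p_switch) 3L - state[i - 1L] else state[i - 1L]
      }
    }
    lab <- c("low", "high")[state]
    D <- ifelse(state == 1L,
                .draw_mixture_D(truth$D_low, nf),
                .draw_mixture_D(truth$D_high, nf))
    # step i -> i+1 uses the state at the originating frame i
    sd_step <- sqrt(2 * D[-nf] * dt)
    x <- cumsum(c(stats::runif(1, 0, 50), stats::rnorm(nf - 1L, 0, sd_step)))
    y <- cumsum(c(stats::runif(1, 0, 50), stats::rnorm(nf - 1L, 0, sd_step)))
    mu_d <- vapply(lab, function(s) truth$intensity_mean[[s]][1], 0)
    mu_a <- vapply(lab, function(s) truth$intensity_mean[[s]][2], 0)
    sd_d <- vapply(lab, function(s) truth$intensity_sd[[s]][1], 0)
    sd_a <- vapply(lab, function(s) truth$intensity_sd[[s]][2], 0)
    tibble::tibble(
      traj_id = k,
      frame = seq_len(nf) - 1L,
      x_um = x, y_um = y,
      donor_intensity = pmax(0, stats::rnorm(nf, mu_d, sd_d)),
      acceptor_intensity = pmax(0, stats::rnorm(nf, mu_a, sd_a)),
      fret_state = NA_character_,
      true_state = lab,
      starts_at_movie_start = starts[k],
      ends_at_movie_end = ends[k]
    )
  }
  data <- dplyr::bind_rows(lapply(seq_len(n_traj), sim_one))
  attr(data, "truth") <- truth
  attr(data, "params") <- tibble::tibble(traj_id = seq_len(n_traj),
                                         pLH = pLH, pHL = pHL,
                                         n_frames = n_frames)
  attr(data, "dt") <- dt
  data
}

#' Simulate squared frame-to-frame displacements from a diffusivity mixture
#'
#' Draws squared displacements distributed as the mixture of exponentials
#' with means `4 * D * dt` — the closed-form sampling counterpart of the
#' Gaussian-mixture model fitted by [fit_ccsdd()].
#'
#' @param mixture Tibble (or coercible) with columns `fraction` and `D`
#'   (um^2/s); fractions must sum to 1.
#' @param n Number of displacements.
#' @param dt Frame interval in seconds.
#' @param seed Optional integer seed.
#' @return Tibble with column `r2` (um^2).
#' @export
simulate_displacements <- function(mixture, n, dt = 0.05, seed = NULL) {
  mixture <- tibble::as_tibble(mixture)
  stopifnot(all(c("fraction", "D") %in% names(mixture)),
            all(mixture$D >= 0), abs(sum(mixture$fraction) - 1) < 1e-8,
            n > 0, dt > 0)
  if (any(mixture$D < 0)) stop("negative diffusion coefficient")
  if (!is.null(seed)) set.seed(seed)
  D <- .draw_mixture_D(mixture, n)
  tibble::tibble(r2 = stats::rexp(n, rate = 1) * 4 * D * dt)
}

#' Simulate mobility-encoded cluster-size data
#'
#' Draws a cluster size `N` per trajectory from the truth's cluster-size
#' law, sets the trajectory friction factor `f = N * fL` (additive,
#' free-draining), synthesizes a Brownian trajectory with `D = 1/f`, and
#' returns both the trajectory table and the generating truth, so the
#' downstream friction-factor inversion can be validated end to end.
#'
#' @param truth A [fret_truth()] object (uses `fL` and `cluster_size_law`).
#' @param n_traj Number of trajectories.
#' @param n_frames Frames per trajectory (default 100).
#' @param dt Frame interval in seconds.
#' @param seed Optional integer seed.
#' @return List with `trajectories` (trajectory table) and `truth` (tibble
#'   of `traj_id`, `N`, `f`, `D`).
#' @export
simulate_friction_trajectories <- function(truth, n_traj, n_frames = 100L,
                                           dt = 0.05, seed = NULL) {
  stopifnot(inherits(truth, "fret_truth"), n_traj > 0, n_frames >= 2, dt > 0)
  if (!is.null(seed)) set.seed(seed)
  N <- truth$cluster_size_law(n_traj)
  stopifnot(all(N > 0))
  f <- N * truth$fL
  D <- 1 / f
  sim_one <- function(k) {
    sd_step <- sqrt(2 * D[k] * dt)
    tibble::tibble(
      traj_id = k,
      frame = seq_len(n_frames) - 1L,
      x_um = cumsum(c(0, stats::rnorm(n_frames - 1L, 0, sd_step))),
      y_um = cumsum(c(0, stats::rnorm(n_frames - 1L, 0, sd_step))),
      donor_intensity = 0, acceptor_intensity = 0,
      fret_state = NA_character_,
      starts_at_movie_start = FALSE, ends_at_movie_end = FALSE
    )
  }
  list(
    trajectories = dplyr::bind_rows(lapply(seq_len(n_traj), sim_one)),
    truth = tibble::tibble(traj_id = seq_len(n_traj), N = N, f = f, D = D)
  )
}
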