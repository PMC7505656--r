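#' Estimate the per-frame termination probability
#'
#' The off-state (photobleaching, desorption, diffusion out of the field)
#' is estimated independently of the transition kinetics by fitting the
#' surface residence times to an exponential/geometric distribution.
#' `method = "geometric"` (default) is the discrete-time maximum-likelihood
#' estimate `p_off = 1 / mean(frames)`; `method = "exponential"` fits the
#' residence times in seconds to an exponential with mean `tau` and
#' returns the discrete-time equivalent `p_off = 1 - exp(-dt / tau)`. The
#' two agree to first order for small `p_off`.
#'
#' @param residence_frames Integer vector of uncensored surface residence
#'   times in frames (at least 10 required).
#' @param dt Frame interval in seconds (used by the exponential method).
#' @param method `"geometric"` or `"exponential"`.
#' @return `p_off`, the per-frame termination probability.
#' @export
estimate_poff <- function(residence_frames, dt = 0.05,
                          method = c("geometric", "exponential")) {
  method <- match.arg(method)
  residence_frames <- residence_frames[!is.na(residence_frames)]
  if (length(residence_frames) < 10L) {
    stop("need at least 10 uncensored residence times", call. = FALSE)
  }
  stopifnot(all(residence_frames >= 1))
  m <- mean(residence_frames)
  if (method == "geometric") 1 / m else 1 - exp(-1 / m)
}

#' Count FRET-state transitions per trajectory
#'
#' Tallies, for each trajectory, the number of low-to-high (`N_LH`),
#' low-to-low (`N_LL`), high-to-low (`N_HL`) and high-to-high (`N_HH`)
#' frame-to-frame steps, plus the terminal off transition `N_off` (1 if
#' the trajectory genuinely ended, 0 if it was censored by the end of the
#' movie).
#'
#' @param data A trajectory table with `fret_state` fully assigned
#'   (`"high"`/`"low"`); unassigned states are an error.
#' @return Tibble of class `state_counts` with one row per trajectory:
#'   `traj_id`, `N_LH`, `N_LL`, `N_HL`, `N_HH`, `N_off`.
#' @export
count_transitions <- function(data) {
  data <- validate_trajectories(data)
  if (any(is.na(data$fret_state))) {
    stop("unassigned fret_state present; run assign_fret_states() first",
         call. = FALSE)
  }
  data <- dplyr::arrange(data, .data$traj_id, .data$frame)
  cur <- data$fret_state
  nxt <- dplyr::lead(cur)
  same <- data$traj_id == dplyr::lead(data$traj_id)
  same[is.na(same)] <- FALSE
  step <- dplyr::case_when(
    !same ~ NA_character_,
    cur == "low" & nxt == "high" ~ "N_LH",
    cur == "low" & nxt == "low" ~ "N_LL",
    cur == "high" & nxt == "low" ~ "N_HL",
    cur == "high" & nxt == "high" ~ "N_HH"
  )
  counts <- tibble::tibble(traj_id = data$traj_id, step = step) |>
    dplyr::filter(!is.na(.data$step)) |>
    dplyr::count(.data$traj_id, .data$step) |>
    tidyr::pivot_wider(names_from = "step", values_from = "n",
                       values_fill = 0L)
  for (col in c("N_LH", "N_LL", "N_HL", "N_HH")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  ends <- data |>
    dplyr::group_by(.data$traj_id) |>
    dplyr::summarise(N_off = as.integer(!any(.data$ends_at_movie_end)),
                     .groups = "drop")
  out <- counts |>
    dplyr::right_join(ends, by = "traj_id") |>
    dplyr::mutate(dplyr::across(dplyr::starts_with("N_"),
                                ~ tidyr::replace_na(.x, 0L))) |>
    dplyr::select("traj_id", "N_LH", "N_LL", "N_HL", "N_HH", "N_off") |>
    dplyr::arrange(.data$traj_id)
  class(out) <- c("state_counts", class(out))
  out
}

#' Log-likelihood of the beta-Markov transition model
#'
#' The three-state (high/low/off) Markov model with beta-distributed
#' high/low transition probabilities has, for trajectory `k` with counts
#' `N_LH, N_LL, N_HL, N_HH, N_off`, the marginal likelihood contribution
#'
#' `B(aLH + N_LH, bLH + N_LL) / B(aLH, bLH) * B(aHL + N_HL, bHL + N_HH) /
#'  B(aHL, bHL) * p_off^N_off * (1 - p_off)^(N_LL + N_LH + N_HL + N_HH)`
#'
#' obtained by integrating the per-trajectory transition probabilities over
#' their beta priors. The sum of the log contributions is computed entirely
#' in log space via `lbeta()`.
#'
#' @param shapes Numeric length 4: `c(aLH, bLH, aHL, bHL)`, all positive.
#' @param counts A [count_transitions()] table.
#' @param p_off Per-frame termination probability, in `[0, 1)`.
#' @return The log-likelihood (0 for an empty corpus).
#' @export
beta_markov_loglik <- function(shapes, counts, p_off) {
  stopifnot(length(shapes) == 4L, all(shapes > 0), p_off >= 0, p_off < 1)
  if (nrow(counts) == 0L) return(0)
  aLH <- shapes[1L]; bLH <- shapes[2L]; aHL <- shapes[3L]; bHL <- shapes[4L]
  n_steps <- counts$N_LL + counts$N_LH + counts$N_HL + counts$N_HH
  lp_off <- if (any(counts$N_off > 0)) {
    if (p_off == 0) return(-Inf)
    counts$N_off * log(p_off)
  } else 0
  ll <- lbeta(aLH + counts$N_LH, bLH + counts$N_LL) - lbeta(aLH, bLH) +
    lbeta(aHL + counts$N_HL, bHL + counts$N_HH) - lbeta(aHL, bHL) +
    lp_off + n_steps * log1p(-p_off)
  out <- sum(ll)
  if (!is.finite(out)) {
    bad <- counts$traj_id[!is.finite(ll)]
    stop("non-finite log-likelihood contribution for trajectory id(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  out
}

#' Maximum-likelihood fit of the beta-Markov model
#'
#' Maximizes [beta_markov_loglik()] over the four beta shape parameters
#' with `p_off` held fixed (the two-stage procedure: `p_off` comes from
#' [estimate_poff()] on the residence times). Positivity is enforced by
#' optimizing in log-shape space; 8 random restarts around moment-based
#' starting values guard against local optima; the covariance is the
#' inverse of the observed Fisher information (numerical Hessian of the
#' negative log-likelihood) at the optimum.
#'
#' @param counts A [count_transitions()] table. The corpus must contain at
#'   least one low-state and one high-state visit.
#' @param p_off Fixed per-frame termination probability.
#' @param dt Frame interval in seconds.
#' @param n_starts Number of random restarts (default 8).
#' @param reltol Convergence tolerance on the log-likelihood (default 1e-8).
#' @return Object of class `beta_markov_fit` with fields `aLH`, `bLH`,
#'   `aHL`, `bHL`, `p_off`, `dt`, `loglik`, `vcov_log` (4x4 covariance of
#'   the log-shape estimates), `n_traj`, `degenerate` (TRUE when a shape
#'   hit the search boundary).
#' @export
fit_beta_markov <- function(counts, p_off, dt = 0.05, n_starts = 8L,
                            reltol = 1e-8) {
  stopifnot(nrow(counts) >= 1L)
  has_low <- sum(counts$N_LL + counts$N_LH) > 0
  has_high <- sum(counts$N_HH + counts$N_HL) > 0
  if (!has_low || !has_high) {
    stop("corpus must contain at least one low-state and one high-state visit",
         call. = FALSE)
  }
  nll <- function(theta) -beta_markov_loglik(exp(theta), counts, p_off)

  # moment starts: mean transition fractions across the corpus
  p_lh <- (sum(counts$N_LH) + 0.5) / (sum(counts$N_LH + counts$N_LL) + 1)
  p_hl <- (sum(counts$N_HL) + 0.5) / (sum(counts$N_HL + counts$N_HH) + 1)
  base <- log(c(10 * p_lh, 10 * (1 - p_lh), 10 * p_hl, 10 * (1 - p_hl)))
  best <- NULL
  for (s in seq_len(n_starts)) {
    th0 <- base + if (s == 1L) 0 else stats::rnorm(4L, 0, 1.5)
    res <- tryCatch(
      stats::optim(th0, nll, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = reltol)),
      error = function(e) NULL
    )
    if (!is.null(res)) {
      res <- tryCatch(
        stats::optim(res$par, nll, method = "BFGS",
                     control = list(maxit = 500, reltol = reltol)),
        error = function(e) res
      )
    }
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) stop("beta-Markov optimization failed from all starts",
                          call. = FALSE)
  hess <- stats::optimHess(best$par, nll)
  vcov_log <- tryCatch(solve(hess), error = function(e) {
    matrix(NA_real_, 4L, 4L)
  })
  shapes <- exp(best$par)
  degenerate <- any(shapes < 1e-4 | shapes > 1e6)
  if (degenerate) {
    warning("boundary solution: a beta shape parameter is at the edge of ",
            "the search range; the fit is weakly identified")
  }
  structure(
    list(aLH = shapes[1L], bLH = shapes[2L], aHL = shapes[3L],
         bHL = shapes[4L], p_off = p_off, dt = dt,
         loglik = -best$value, vcov_log = vcov_log,
         n_traj = nrow(counts), degenerate = degenerate,
         convergence = best$convergence),
    class = "beta_markov_fit"
  )
}

#' Construct a beta-Markov model without fitting
#'
#' Useful for simulation and for evaluating rate densities at known
#' parameters.
#'
#' @param aLH,bLH,aHL,bHL Positive beta shape parameters.
#' @param p_off Per-frame termination probability.
#' @param dt Frame interval in seconds.
#' @return A `beta_markov_fit` object (without likelihood or covariance).
#' @export
beta_markov_model <- function(aLH, bLH, aHL, bHL, p_off = 0.02, dt = 0.05) {
  stopifnot(aLH > 0, bLH > 0, aHL > 0, bHL > 0, p_off >= 0, p_off < 1, dt > 0)
  structure(
    list(aLH = aLH, bLH = bLH, aHL = aHL, bHL = bHL, p_off = p_off, dt = dt,
         loglik = NA_real_, vcov_log = matrix(NA_real_, 4L, 4L),
         n_traj = NA_integer_, degenerate = FALSE, convergence = NA_integer_),
    class = "beta_markov_fit"
  )
}

#' Mean transition rates and the average dissociation rate constant
#'
#' Under the beta-Markov model the mean transition rate is the expectation
#' of `-ln(1 - p) / dt` over the beta distribution of `p`, which has the
#' closed form `r = (digamma(a + b) - digamma(b)) / dt`. The high-to-low
#' rate is the average dissociation rate constant (k-bar-d), since
#' dissociation is unimolecular. Standard errors are delta-method
#' propagations of the MLE covariance — the square root of the Cramer-Rao
#' lower bound.
#'
#' @param model A `beta_markov_fit` object.
#' @return Tibble of class `rate_estimates` with columns `transition`
#'   (`"LH"`, `"HL"`), `rate` (s^-1) and `se` (s^-1; `NA` when no
#'   covariance is available). The `"HL"` row is k-bar-d.
#' @export
mean_rates <- function(model) {
  stopifnot(inherits(model, "beta_markov_fit"))
  dt <- model$dt
  rate_one <- function(a, b, V) {
    r <- (digamma(a + b) - digamma(b)) / dt
    se <- NA_real_
    if (!anyNA(V)) {
      # gradient w.r.t. (log a, log b)
      g <- c(a * trigamma(a + b),
             b * (trigamma(a + b) - trigamma(b))) / dt
      se <- sqrt(drop(t(g) %*% V %*% g))
    }
    c(rate = r, se = se)
  }
  V_LH <- model$vcov_log[1:2, 1:2, drop = FALSE]
  V_HL <- model$vcov_log[3:4, 3:4, drop = FALSE]
  lh <- rate_one(model$aLH, model$bLH, V_LH)
  hl <- rate_one(model$aHL, model$bHL, V_HL)
  out <- tibble::tibble(
    transition = c("LH", "HL"),
    rate = unname(c(lh["rate"], hl["rate"])),
    se = unname(c(lh["se"], hl["se"]))
  )
  class(out) <- c("rate_estimates", class(out))
  out
}

#' Average dissociation rate constant
#'
#' @param model A `beta_markov_fit` object.
#' @return k-bar-d in s^-1 (the mean high-to-low transition rate).
#' @export
kd_bar <- function(model) {
  rates <- mean_rates(model)
  rates$rate[rates$transition == "HL"]
}

#' Probability density of a transition rate
#'
#' Change of variables from `p ~ Beta(a, b)` to the rate
#' `r = -ln(1 - p) / dt`: `f_R(r) = f_Beta(1 - exp(-r dt)) * dt *
#' exp(-r dt)`. The density integrates to 1.
#'
#' @param model A `beta_markov_fit` object.
#' @param which `"HL"` (dissociation, default) or `"LH"`.
#' @param rate Optional rate grid in s^-1; a sensible grid is built from
#'   the distribution's quantiles when omitted.
#' @return Tibble with columns `rate` (s^-1) and `density`.
#' @export
rate_density <- function(model, which = c("HL", "LH"), rate = NULL) {
  which <- match.arg(which)
  a <- if (which == "HL") model$aHL else model$aLH
  b <- if (which == "HL") model$bHL else model$bLH
  dt <- model$dt
  if (is.null(rate)) {
    pq <- stats::qbeta(c(1e-5, 1 - 1e-5), a, b)
    rq <- -log1p(-pq) / dt
    rate <- seq(rq[1L], rq[2L], length.out = 512L)
  }
  p <- -expm1(-rate * dt)          # 1 - exp(-r dt)
  dens <- stats::dbeta(p, a, b) * dt * exp(-rate * dt)
  tibble::tibble(rate = rate, density = dens)
}

#' Dwell times per state
#'
#' The apparent dwell time is the number of consecutive frames a
#' trajectory spends in a given state (times `dt` for seconds). All dwell
#' times are included — not only those bounded by transitions — so
#' censored dwells at trajectory ends count too. The sum of the dwell
#' frames equals the total number of frames.
#'
#' @param data A trajectory table with `fret_state` assigned.
#' @return Tibble with columns `traj_id`, `state`, `frames`.
#' @export
dwell_times <- function(data) {
  if (any(is.na(data$fret_state))) {
    stop("unassigned fret_state present", call. = FALSE)
  }
  data <- dplyr::arrange(data, .data$traj_id, .data$frame)
  data |>
    dplyr::group_by(.data$traj_id) |>
    dplyr::reframe({
      r <- rle(.data$fret_state)
      tibble::tibble(state = r$values, frames = r$lengths)
    })
}

#' Complementary cumulative dwell-time distribution
#'
#' @param dwells Output of [dwell_times()] (or a tibble with `state`,
#'   `frames`).
#' @param dt Frame interval in seconds.
#' @return Tibble with columns `state`, `tau` (s) and `ccdf`
#'   (`P(dwell >= tau)`, equal to 1 at `tau = dt`).
#' @export
dwell_ccdf <- function(dwells, dt = 0.05) {
  dwells |>
    dplyr::group_by(.data$state) |>
    dplyr::reframe({
      f <- sort(.data$frames)
      u <- sort(unique(f))
      tibble::tibble(
        tau = u * dt,
        ccdf = vapply(u, function(k) mean(f >= k), 0)
      )
    })
}

#' Simulate the fitted model against an empirical residence-time sampler
#'
#' Per trajectory: draw `(pLH, pHL)` once from the fitted beta
#' distributions, simulate the two-state chain, truncate at a residence
#' time sampled (with replacement) from the supplied empirical residence
#' times, and return the dwell-time complementary cumulative distributions
#' of the simulated corpus — the model-consistency check against held-out
#' data.
#'
#' @param model A `beta_markov_fit` object.
#' @param residence_frames Integer vector of empirical residence times
#'   (frames) to sample trajectory lengths from.
#' @param n Number of simulated trajectories.
#' @param seed Optional integer seed.
#' @return List with `trajectories` (tibble `traj_id`, `frame`,
#'   `fret_state`), `dwells`, and `ccdf` (per-state dwell CCDF).
#' @export
simulate_beta_markov <- function(model, residence_frames, n, seed = NULL) {
  stopifnot(inherits(model, "beta_markov_fit"), length(residence_frames) > 0,
            n > 0)
  if (!is.null(seed)) set.seed(seed)
  lens <- sample(residence_frames, n, replace = TRUE)
  pLH <- stats::rbeta(n, model$aLH, model$bLH)
  pHL <- stats::rbeta(n, model$aHL, model$bHL)
  sim_one <- function(k) {
    nf <- max(1L, lens[k])
    st <- integer(nf)
    st[1L] <- sample(1:2, 1L)
    if (nf > 1L) {
      u <- stats::runif(nf - 1L)
      for (i in 2L:nf) {
        p <- if (st[i - 1L] == 1L) pLH[k] else pHL[k]
        st[i] <- if (u[i - 1L] < p) 3L - st[i - 1L] else st[i - 1L]
      }
    }
    tibble::tibble(traj_id = k, frame = seq_len(nf) - 1L,
                   fret_state = c("low", "high")[st])
  }
  traj <- dplyr::bind_rows(lapply(seq_len(n), sim_one))
  dw <- dwell_times(traj)
  list(trajectories = traj, dwells = dw, ccdf = dwell_ccdf(dw, model$dt))
}

#' @export
print.beta_markov_fit <- function(x, ...) {
  cat("<beta_markov_fit>\n")
  cat(sprintf("  p(L->H) ~ Beta(%.4g, %.4g); p(H->L) ~ Beta(%.4g, %.4g)\n",
              x$aLH, x$bLH, x$aHL, x$bHL))
  cat(sprintf("  p_off = %.4g, dt = %.3g s, n_traj = %s, logLik = %.4f\n",
              x$p_off, x$dt, x$n_traj, x$loglik))
  r <- mean_rates(x)
  cat(sprintf("  r_LH = %.4g s^-1; kd_bar = r_HL = %.4g s^-1\n",
              r$rate[1L], r$rate[2L]))
  invisible(x)
}

#' @export
tidy.beta_markov_fit <- function(x, ...) {
  r <- mean_rates(x)
  tibble::tibble(
    term = c("aLH", "bLH", "aHL", "bHL", "p_off", "r_LH", "r_HL"),
    estimate = c(x$aLH, x$bLH, x$aHL, x$bHL, x$p_off, r$rate),
    std.error = c(rep(NA_real_, 5L), r$se)
  )
}

#' @export
glance.beta_markov_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, n_traj = x$n_traj, kd_bar = kd_bar(x),
                 p_off = x$p_off, degenerate = x$degenerate)
}
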