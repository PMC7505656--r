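#' Squared frame-to-frame displacements, split by FRET state
#'
#' Helper shared by the diffusion functions: extracts consecutive-frame
#' squared Euclidean displacements from a trajectory table. A displacement
#' belongs to the state of its originating frame.
#'
#' @param data A trajectory table.
#' @param state `"all"`, `"high"` or `"low"`.
#' @return Numeric vector of squared displacements (um^2).
#' @export
squared_displacements <- function(data, state = c("all", "high", "low")) {
  state <- match.arg(state)
  data <- dplyr::arrange(data, .data$traj_id, .data$frame)
  same <- data$traj_id == dplyr::lead(data$traj_id)
  same[is.na(same)] <- FALSE
  r2 <- (dplyr::lead(data$x_um) - data$x_um)^2 +
        (dplyr::lead(data$y_um) - data$y_um)^2
  keep <- same
  if (state != "all") {
    if (all(is.na(data$fret_state))) {
      stop("fret_state is unassigned; run assign_fret_states() first",
           call. = FALSE)
    }
    keep <- keep & !is.na(data$fret_state) & data$fret_state == state
  }
  out <- r2[keep]
  if (length(out) == 0L) {
    stop("no displacements available for state '", state, "'", call. = FALSE)
  }
  out
}

#' Complementary cumulative squared displacement distribution (CCSDD)
#'
#' Computes the empirical complementary CDF `P(R^2 >= r^2)` of the
#' consecutive-frame squared displacements, optionally restricted to the
#' displacements originating in one FRET state. The distribution is
#' evaluated at every observed displacement (no binning), with the point
#' `r^2 = 0, P = 1` prepended.
#'
#' @param data A trajectory table with `fret_state` assigned when
#'   `state != "all"`.
#' @param state `"all"`, `"high"` or `"low"`.
#' @param dt Frame interval in seconds (stored for downstream fitting).
#' @return A tibble of class `ccsdd` with columns `r2` (um^2, increasing)
#'   and `prob` (non-increasing, `prob[1] = 1`), and attributes `n`,
#'   `state`, `dt`.
#' @export
compute_ccsdd <- function(data, state = c("all", "high", "low"), dt = 0.05) {
  state <- match.arg(state)
  stopifnot(dt > 0)
  r2 <- squared_displacements(data, state)
  ccsdd_from_r2(r2, state = state, dt = dt)
}

#' Build a CCSDD directly from squared displacements
#'
#' @param r2 Numeric vector of squared displacements (um^2).
#' @param state Label stored with the distribution.
#' @param dt Frame interval in seconds.
#' @return A `ccsdd` tibble; see [compute_ccsdd()].
#' @export
ccsdd_from_r2 <- function(r2, state = "all", dt = 0.05) {
  stopifnot(length(r2) > 0L, all(r2 >= 0), dt > 0)
  n <- length(r2)
  u <- sort(unique(r2))
  cnt <- tabulate(match(r2, u), nbins = length(u))
  prob <- rev(cumsum(rev(cnt))) / n   # P(R^2 >= u)
  if (u[1L] > 0) {
    u <- c(0, u)
    prob <- c(1, prob)
  }
  out <- tibble::tibble(r2 = u, prob = prob)
  class(out) <- c("ccsdd", class(out))
  attr(out, "n") <- n
  attr(out, "state") <- state
  attr(out, "dt") <- dt
  attr(out, "displacements") <- r2
  out
}

.softmax <- function(z) {
  e <- exp(c(z, 0) - max(c(z, 0)))
  e / sum(e)
}

.ccsdd_objective <- function(theta, r2, p_emp, M, dt) {
  z <- theta[seq_len(M - 1L)]
  logD <- theta[M:(2L * M - 1L)]
  cfrac <- if (M == 1L) 1 else .softmax(z)
  D <- exp(logD)
  E <- exp(-outer(r2, 4 * dt * D, "/"))
  m <- drop(E %*% cfrac)
  res <- m - p_emp
  sse <- sum(res^2)
  g_c <- 2 * drop(crossprod(E, res))                # dSSE/dc_i
  grad_z <- if (M == 1L) numeric(0) else {
    (cfrac * (g_c - sum(cfrac * g_c)))[seq_len(M - 1L)]
  }
  grad_logD <- vapply(seq_len(M), function(i) {
    2 * sum(res * cfrac[i] * E[, i] * r2 / (4 * dt * D[i]))
  }, 0)
  list(value = sse, gradient = c(grad_z, grad_logD))
}

#' Fit a Gaussian mixture model to a CCSDD
#'
#' Nonlinear least squares of
#' `P(R^2 >= r^2) = sum_i c_i exp(-r^2 / (4 dt D_i))` with `c_i >= 0`,
#' `sum c_i = 1` (enforced exactly through a softmax parameterization, so
#' the model equals 1 at `r^2 = 0`) and `D_i > 0` (log parameterization).
#' Multi-start BFGS with analytic gradients; components with
#' `c_i < 1e-3` are pruned and the model refit, so the reported number of
#' terms is the effective one. Diffusion coefficients are returned sorted
#' ascending.
#'
#' @param ccsdd A [compute_ccsdd()] object.
#' @param M Number of mixture terms (default 3).
#' @param n_starts Number of random starts (default 10).
#' @param init Optional warm-start list with elements `c` and `D` (used as
#'   the first start).
#' @param prune_tol Fraction below which a component is pruned (default
#'   1e-3).
#' @return Object of class `ccsdd_fit`: `c`, `D`, `M` (requested),
#'   `M_effective`, `dshort`, `sse`, `n`, `state`, `dt`, `convergence`.
#' @export
fit_ccsdd <- function(ccsdd, M = 3L, n_starts = 10L, init = NULL,
                      prune_tol = 1e-3) {
  stopifnot(inherits(ccsdd, "ccsdd"), M >= 1L, n_starts >= 1L)
  dt <- attr(ccsdd, "dt")
  r2 <- ccsdd$r2
  p_emp <- ccsdd$prob
  D_hat <- max(mean(attr(ccsdd, "displacements") %||% r2) / (4 * dt), 1e-8)
  # identifiability box: a component with 4*dt*D beyond the largest observed
  # displacement is a pure offset (D unidentified upward); one far below the
  # smallest positive displacement is a spike at zero
  r2_pos <- r2[r2 > 0]
  D_max <- max(r2) / (4 * dt)
  D_min <- min(r2_pos) / (4 * dt) / 100
  lo_hi <- function(M) list(
    lower = c(rep(-Inf, M - 1L), rep(log(D_min), M)),
    upper = c(rep(Inf, M - 1L), rep(log(D_max), M))
  )

  fit_M <- function(M, starts) {
    best <- NULL
    bounds <- lo_hi(M)
    for (th0 in starts) {
      cache <- new.env(parent = emptyenv())
      eval_at <- function(th) {
        if (!identical(cache$th, th)) {
          cache$th <- th
          cache$res <- .ccsdd_objective(th, r2, p_emp, M, dt)
        }
        cache$res
      }
      fn <- function(th) eval_at(th)$value
      gr <- function(th) eval_at(th)$gradient
      th0 <- pmin(pmax(th0, bounds$lower + 1e-6), bounds$upper - 1e-6)
      res <- tryCatch(
        stats::optim(th0, fn, gr, method = "L-BFGS-B",
                     lower = bounds$lower, upper = bounds$upper,
                     control = list(maxit = 500, factr = 1e4)),
        error = function(e) NULL
      )
      if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
    }
    if (is.null(best)) {
      stop("CCSDD mixture fit failed to converge from any start (M = ", M,
           ", n = ", attr(ccsdd, "n"), ")", call. = FALSE)
    }
    best
  }

  make_starts <- function(M) {
    starts <- list()
    if (!is.null(init) && length(init$D) == M) {
      cf <- init$c / sum(init$c)
      z0 <- log(pmax(cf, 1e-8))
      starts[[1L]] <- c((z0 - z0[M])[seq_len(M - 1L)], log(init$D))
    }
    # spread starts over decades around the moment estimate
    while (length(starts) < n_starts) {
      logD0 <- sort(log(D_hat) + stats::runif(M, -2.5, 1.5))
      z0 <- stats::rnorm(max(M - 1L, 0L), 0, 0.5)
      starts[[length(starts) + 1L]] <- c(z0, logD0)
    }
    starts
  }

  unpack <- function(best, M) {
    th <- best$par
    cfrac <- if (M == 1L) 1 else .softmax(th[seq_len(M - 1L)])
    D <- exp(th[M:(2L * M - 1L)])
    o <- order(D)
    list(c = cfrac[o], D = D[o], sse = best$value,
         convergence = best$convergence)
  }

  best <- fit_M(M, make_starts(M))
  sol <- unpack(best, M)
  # prune negligible components and refit at the effective order
  while (length(sol$D) > 1L && any(sol$c < prune_tol)) {
    keep <- sol$c >= prune_tol
    Meff <- sum(keep)
    cf <- sol$c[keep] / sum(sol$c[keep])
    init <- list(c = cf, D = sol$D[keep])
    z0 <- log(pmax(cf, 1e-8))
    st <- list(c((z0 - z0[Meff])[seq_len(Meff - 1L)], log(init$D)))
    sol <- unpack(fit_M(Meff, st), Meff)
  }
  structure(
    list(c = sol$c, D = sol$D, M = M, M_effective = length(sol$D),
         dshort = sum(sol$c * sol$D), sse = sol$sse,
         n = attr(ccsdd, "n"), state = attr(ccsdd, "state"), dt = dt,
         convergence = sol$convergence),
    class = "ccsdd_fit"
  )
}

#' Average short-time diffusion coefficient
#'
#' The mixture-weighted mean `sum(c_i * D_i)` of a CCSDD fit: the average
#' diffusion coefficient on the shortest experimentally accessible time
#' scale. Invariant to the ordering of mixture components.
#'
#' @param fit A [fit_ccsdd()] object.
#' @return D-bar-short in um^2/s.
#' @export
dshort <- function(fit) {
  stopifnot(inherits(fit, "ccsdd_fit"))
  sum(fit$c * fit$D)
}

#' @export
print.ccsdd_fit <- function(x, ...) {
  cat("<ccsdd_fit> state:", x$state, " n:", x$n, "\n")
  for (i in seq_along(x$D)) {
    cat(sprintf("  c%d = %.4f  D%d = %.4g um^2/s\n", i, x$c[i], i, x$D[i]))
  }
  cat(sprintf("  dshort = %.4g um^2/s (M requested %d, effective %d)\n",
              x$dshort, x$M, x$M_effective))
  invisible(x)
}

#' @export
tidy.ccsdd_fit <- function(x, ...) {
  tibble::tibble(component = seq_along(x$D), fraction = x$c, D = x$D)
}

#' @export
glance.ccsdd_fit <- function(x, ...) {
  tibble::tibble(dshort = x$dshort, M = x$M, M_effective = x$M_effective,
                 sse = x$sse, n = x$n, state = x$state)
}

#' Bootstrap standard error of the average short-time diffusion coefficient
#'
#' Resamples displacements with replacement, recomputes the CCSDD, refits
#' the mixture (warm-started at the full-data fit) and recomputes
#' D-bar-short for each replicate; the standard deviation across
#' replicates is the reported error. Replicate fit failures are tolerated
#' up to 20%.
#'
#' @param data A trajectory table (or a numeric vector of squared
#'   displacements).
#' @param state `"all"`, `"high"` or `"low"`.
#' @param dt Frame interval in seconds.
#' @param M Mixture order (default 3).
#' @param n_boot Number of bootstrap replicates (default 100).
#' @param seed Optional integer seed.
#' @return The bootstrap standard error, with attributes `replicates`
#'   (the replicate dshort values) and `estimate` (the full-data dshort).
#' @export
bootstrap_dshort <- function(data, state = "all", dt = 0.05, M = 3L,
                             n_boot = 100L, seed = NULL) {
  stopifnot(n_boot >= 2L)
  if (!is.null(seed)) set.seed(seed)
  r2 <- if (is.numeric(data)) data else squared_displacements(data, state)
  full <- fit_ccsdd(ccsdd_from_r2(r2, state, dt), M = M)
  reps <- vapply(seq_len(n_boot), function(b) {
    rb <- sample(r2, length(r2), replace = TRUE)
    tryCatch(
      fit_ccsdd(ccsdd_from_r2(rb, state, dt), M = M, n_starts = 2L,
                init = list(c = full$c, D = full$D))$dshort,
      error = function(e) NA_real_
    )
  }, 0)
  if (mean(is.na(reps)) > 0.2) {
    stop("more than 20% of bootstrap replicates failed to fit", call. = FALSE)
  }
  se <- stats::sd(reps, na.rm = TRUE)
  attr(se, "replicates") <- reps
  attr(se, "estimate") <- full$dshort
  se
}

#' Plot a CCSDD, optionally with its mixture fit
#'
#' @param object A `ccsdd` tibble.
#' @param fit Optional [fit_ccsdd()] object to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ccsdd <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$r2, y = .data$prob)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = expression(r^2 ~ (mu * m^2)),
      y = expression(P(R^2 >= r^2)),
      title = paste0("CCSDD (", attr(object, "state"), " state, n = ",
                     attr(object, "n"), ")")
    )
  if (!is.null(fit)) {
    dt <- fit$dt
    grid <- tibble::tibble(r2 = seq(0, max(object$r2), length.out = 200))
    grid$prob <- drop(exp(-outer(grid$r2, 4 * dt * fit$D, "/")) %*% fit$c)
    p <- p + ggplot2::geom_line(data = grid, color = "red")
  }
  p
}
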