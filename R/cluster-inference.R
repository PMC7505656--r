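#' Effective per-trajectory diffusion coefficient
#'
#' `D_T = mean(consecutive-frame squared displacement) / (4 dt)` for each
#' trajectory — the short-time mobility of the tracked object. Immobile
#' trajectories (all displacements zero) get `D_T = 0` and are flagged so
#' the friction inversion can exclude them.
#'
#' @param data A trajectory table.
#' @param dt Frame interval in seconds.
#' @return Tibble with columns `traj_id`, `D_T` (um^2/s), `n_disp`,
#'   `immobile`.
#' @export
trajectory_diffusion <- function(data, dt = 0.05) {
  stopifnot(dt > 0)
  data <- dplyr::arrange(data, .data$traj_id, .data$frame)
  data |>
    dplyr::group_by(.data$traj_id) |>
    dplyr::summarise(
      D_T = mean(diff(.data$x_um)^2 + diff(.data$y_um)^2) / (4 * dt),
      n_disp = dplyr::n() - 1L,
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_disp >= 1L) |>
    dplyr::mutate(immobile = .data$D_T == 0)
}

#' Friction factors and inferred cluster sizes from mobility
#'
#' Inverts mobility to cluster size through the Einstein relation and the
#' additive (free-draining) friction model: the trajectory friction factor
#' per kBT is `f = 1 / D_T` (s/um^2) and, with each protein contributing
#' one lipid friction factor `fL`, the apparent cluster size is
#' `N = f / fL`. `N` is real-valued; it is binned only when building a
#' distribution.
#'
#' @param diffusion Output of [trajectory_diffusion()] (or any tibble with
#'   `traj_id` and `D_T`).
#' @param fL Lipid friction factor in s/um^2 (default 0.5, i.e. a lipid
#'   diffuses at 2 um^2/s).
#' @return Tibble with columns `traj_id`, `D_T`, `f` (s/um^2), `N`.
#'   Trajectories with `D_T <= 0` are dropped with a message.
#' @export
friction_records <- function(diffusion, fL = 0.5) {
  stopifnot(fL > 0)
  bad <- diffusion$D_T <= 0 | !is.finite(diffusion$D_T)
  if (any(bad)) {
    message(sum(bad), " immobile/invalid trajectory(ies) excluded from ",
            "friction inversion")
  }
  diffusion |>
    dplyr::filter(.data$D_T > 0, is.finite(.data$D_T)) |>
    dplyr::mutate(f = 1 / .data$D_T, N = .data$f / fL) |>
    dplyr::select("traj_id", "D_T", "f", "N")
}

#' Cluster-size probability distribution
#'
#' Normalized histogram of the inferred (or simulated) cluster sizes.
#' Default binning is logarithmic with 16 bins per decade; linear binning
#' with unit width is available for integer-valued sizes (as produced by
#' the kinetic Monte Carlo simulator).
#'
#' @param N Numeric vector of cluster sizes (> 0), or a
#'   [friction_records()] tibble.
#' @param binning `"log"` (default) or `"linear"`.
#' @param bins_per_decade Bins per decade for logarithmic binning
#'   (default 16).
#' @param bin_width Bin width for linear binning (default 1).
#' @return Tibble of class `cluster_size_distribution` with columns
#'   `bin_center`, `prob` (sums to 1) and `count`; attribute `n_traj`.
#' @export
cluster_size_distribution <- function(N, binning = c("log", "linear"),
                                      bins_per_decade = 16L, bin_width = 1) {
  binning <- match.arg(binning)
  if (is.data.frame(N)) N <- N$N
  N <- N[is.finite(N) & N > 0]
  stopifnot(length(N) >= 1L)
  if (binning == "log") {
    lo <- floor(log10(min(N)) * bins_per_decade)
    hi <- ceiling(log10(max(N)) * bins_per_decade + 1e-9)
    breaks <- 10^(seq(lo, max(hi, lo + 1L)) / bins_per_decade)
    idx <- findInterval(N, breaks, rightmost.closed = TRUE)
    centers <- sqrt(breaks[-length(breaks)] * breaks[-1L])
  } else {
    lo <- floor(min(N) / bin_width) * bin_width
    hi <- ceiling(max(N) / bin_width) * bin_width
    breaks <- seq(lo, max(hi, lo + bin_width), by = bin_width)
    idx <- findInterval(N, breaks, rightmost.closed = TRUE)
    centers <- (breaks[-length(breaks)] + breaks[-1L]) / 2
  }
  cnt <- tabulate(idx, nbins = length(centers))
  out <- tibble::tibble(bin_center = centers, count = cnt,
                        prob = cnt / sum(cnt))
  out <- out[out$count > 0, , drop = FALSE]
  class(out) <- c("cluster_size_distribution", class(out))
  attr(out, "n_traj") <- length(N)
  attr(out, "binning") <- binning
  out
}

#' Characteristic cluster size from a single-exponential fit
#'
#' Least-squares fit of `A * exp(-N / N0)` to the (bin center, probability)
#' pairs; `N0` is the characteristic cluster size. Following the analysis
#' protocol, the bin at the smallest cluster size is removed before
#' fitting (monomer-dominated and sensitive to the tracking floor). The
#' fit is exact on exact exponential input.
#'
#' @param dist A [cluster_size_distribution()] tibble (or any tibble with
#'   `bin_center` and `prob`).
#' @param drop_smallest Remove the smallest-size bin before fitting
#'   (default TRUE).
#' @return List of class `cluster_size_fit`: `N0`, `A`, `se` (SE of `N0`
#'   from the fit covariance), `n_bins`, `reliable` (FALSE when the
#'   distribution does not decay).
#' @export
fit_characteristic_size <- function(dist, drop_smallest = TRUE) {
  d <- tibble::as_tibble(dist)[, c("bin_center", "prob")]
  d <- d[d$prob > 0, , drop = FALSE]
  d <- d[order(d$bin_center), , drop = FALSE]
  if (drop_smallest && nrow(d) > 1L) d <- d[-1L, , drop = FALSE]
  if (nrow(d) < 3L) {
    stop("need at least 3 bins after removing the smallest-size bin",
         call. = FALSE)
  }
  # log-linear start, then nonlinear least squares on the stated model
  lf <- stats::lm(log(prob) ~ bin_center, data = d)
  slope <- stats::coef(lf)[2L]
  reliable <- is.finite(slope) && slope < 0
  if (!reliable) {
    warning("cluster-size distribution does not decay; N0 is unreliable")
  }
  N0_0 <- if (reliable) -1 / slope else max(d$bin_center)
  A_0 <- exp(stats::coef(lf)[1L])
  fit <- tryCatch(
    stats::nls(prob ~ A * exp(-bin_center / N0), data = d,
               start = list(A = A_0, N0 = N0_0),
               control = stats::nls.control(maxiter = 200, warnOnly = TRUE)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    est <- c(A = unname(A_0), N0 = unname(N0_0))
    se <- NA_real_
  } else {
    est <- stats::coef(fit)
    se <- tryCatch(sqrt(diag(stats::vcov(fit)))["N0"],
                   error = function(e) NA_real_)
    if (!is.finite(est["N0"]) || est["N0"] <= 0) {
      # fall back to the log-linear estimate when nls degenerates
      est <- c(A = unname(A_0), N0 = unname(N0_0))
      se <- NA_real_
    }
  }
  structure(
    list(N0 = unname(est["N0"]), A = unname(est["A"]), se = unname(se),
         n_bins = nrow(d), reliable = reliable),
    class = "cluster_size_fit"
  )
}

#' @export
print.cluster_size_fit <- function(x, ...) {
  cat(sprintf("<cluster_size_fit> N0 = %.4g +/- %.3g (A = %.4g, %d bins%s)\n",
              x$N0, x$se, x$A, x$n_bins,
              if (x$reliable) "" else ", UNRELIABLE"))
  invisible(x)
}

#' @export
tidy.cluster_size_fit <- function(x, ...) {
  tibble::tibble(term = c("N0", "A"), estimate = c(x$N0, x$A),
                 std.error = c(x$se, NA_real_))
}

#' Ensemble-time-averaged mean squared displacement
#'
#' Time-averages the squared displacement of each trajectory at each lag
#' and then averages over trajectories. Trajectories shorter than
#' `max_frames` are excluded and longer ones are truncated at
#' `max_frames`; the MSD is evaluated only for lags leaving more than
#' `min_avg_frames` averaging terms.
#'
#' @param data A trajectory table.
#' @param dt Frame interval in seconds (0.06 s for the lipid-tracer
#'   dataset dialect).
#' @param max_frames Truncation length in frames (default 6).
#' @param min_avg_frames Minimum `T - tau/dt` (default 3 frames).
#' @return Tibble of class `msd_curve` with columns `lag` (s), `msd`
#'   (um^2), `n_traj`.
#' @export
eta_msd <- function(data, dt = 0.06, max_frames = 6L, min_avg_frames = 3L) {
  stopifnot(dt > 0, max_frames >= 2L)
  data <- dplyr::arrange(data, .data$traj_id, .data$frame)
  keep <- data |>
    dplyr::count(.data$traj_id) |>
    dplyr::filter(.data$n > max_frames)
  if (nrow(keep) == 0L) {
    stop("no trajectories longer than ", max_frames, " frames", call. = FALSE)
  }
  trunc <- data |>
    dplyr::filter(.data$traj_id %in% keep$traj_id) |>
    dplyr::group_by(.data$traj_id) |>
    dplyr::slice_head(n = max_frames) |>
    dplyr::ungroup()
  lags <- seq_len(max_frames - min_avg_frames - 1L)
  lags <- lags[max_frames - lags > min_avg_frames]
  if (length(lags) == 0L) stop("no admissible lag times", call. = FALSE)
  per_traj <- trunc |>
    dplyr::group_by(.data$traj_id) |>
    dplyr::reframe({
      x <- .data$x_um; y <- .data$y_um
      Tn <- length(x)
      tibble::tibble(
        lag_frames = lags,
        ta_msd = vapply(lags, function(m) {
          mean((x[(1 + m):Tn] - x[1:(Tn - m)])^2 +
               (y[(1 + m):Tn] - y[1:(Tn - m)])^2)
        }, 0)
      )
    })
  out <- per_traj |>
    dplyr::group_by(.data$lag_frames) |>
    dplyr::summarise(msd = mean(.data$ta_msd), n_traj = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(lag = .data$lag_frames * dt) |>
    dplyr::select("lag", "msd", "n_traj")
  class(out) <- c("msd_curve", class(out))
  attr(out, "dt") <- dt
  out
}

#' Fit the Brownian diffusion model to an MSD curve
#'
#' Least squares of `msd = 4 * D_TA * lag` through the origin.
#'
#' @param msd A [eta_msd()] tibble (or any tibble with `lag` and `msd`).
#' @return List with `D_TA` (um^2/s), `se`, and `flagged` (TRUE for a
#'   non-positive slope).
#' @export
fit_brownian_msd <- function(msd) {
  stopifnot(nrow(msd) >= 2L || (nrow(msd) >= 1L && msd$lag[1L] > 0))
  fit <- stats::lm(msd ~ 0 + lag, data = msd)
  slope <- unname(stats::coef(fit)[1L])
  # vcov warns on an exactly collinear (perfect) fit; the SE is then 0
  se <- unname(suppressWarnings(sqrt(diag(stats::vcov(fit)))[1L]))
  flagged <- slope <= 0
  if (flagged) warning("non-positive MSD slope; D_TA flagged")
  list(D_TA = slope / 4, se = se / 4, flagged = flagged)
}

#' Surface coverage estimate
#'
#' `theta = (n_D + n_A - n_D_AC) / (R_D * A_D)` in proteins per um^2,
#' where `n_D` and `n_A` count fluorescent objects in the donor and
#' acceptor channels, `n_D_AC` is the apparent donor-channel count of an
#' acceptor-only control (contamination and acceptor bleed-through),
#' `A_D` is the imaged donor-channel area and `R_D` the ratio of
#' donor-labeled to total protein. Counts should be restricted upstream to
#' objects tracked for three frames or more within the first ten movie
#' frames. The fractional areal coverage multiplies by the ectodomain
#' cross-section, 9 nm^2 = 9e-6 um^2.
#'
#' @param n_D,n_A,n_D_AC Object counts (see above).
#' @param A_D Donor-channel area in um^2.
#' @param R_D Donor-labeled fraction of total protein, in (0, 1].
#' @return Tibble with columns `theta` (proteins/um^2) and `fractional`.
#' @export
surface_coverage <- function(n_D, n_A, n_D_AC, A_D, R_D) {
  stopifnot(R_D > 0, R_D <= 1, A_D > 0)
  num <- n_D + n_A - n_D_AC
  if (num < 0) {
    stop("contamination exceeds signal: n_D + n_A - n_D_AC < 0", call. = FALSE)
  }
  theta <- num / (R_D * A_D)
  tibble::tibble(theta = theta, fractional = theta * 9e-6)
}

#' Plot a cluster-size distribution with its exponential fit
#'
#' @param object A [cluster_size_distribution()] tibble.
#' @param fit Optional [fit_characteristic_size()] result to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cluster_size_distribution <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$bin_center, y = .data$prob)) +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "cluster size N (proteins)", y = "probability")
  if (!is.null(fit)) {
    grid <- tibble::tibble(
      bin_center = seq(min(object$bin_center), max(object$bin_center),
                       length.out = 200))
    grid$prob <- fit$A * exp(-grid$bin_center / fit$N0)
    p <- p + ggplot2::geom_line(data = grid, color = "red")
  }
  p
}
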