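#' Colocalize donor- and acceptor-channel localizations
#'
#' Pairs localizations observed in the two emission channels of the same
#' frame. Pairs are matched one-to-one, closest first, and only within
#' `radius_px` pixels; the pair position is taken from the member with the
#' larger signal-to-noise ratio. Unmatched localizations are kept as
#' single-channel observations with zero intensity in the missing channel.
#'
#' @param donor,acceptor Tibbles with columns `frame`, `x_um`, `y_um`,
#'   `intensity` and optionally `snr` (defaults to `intensity` when
#'   absent).
#' @param radius_px Colocalization radius in pixels (default 2).
#' @param pixel_size Pixel size in micrometres (default 0.43).
#' @return Tibble with columns `frame`, `x_um`, `y_um`, `donor_intensity`,
#'   `acceptor_intensity`, `paired`.
#' @export
colocalize_channels <- function(donor, acceptor, radius_px = 2,
                                pixel_size = 0.43) {
  stopifnot(radius_px > 0, pixel_size > 0)
  radius <- radius_px * pixel_size
  prep <- function(d) {
    d <- tibble::as_tibble(d)
    stopifnot(all(c("frame", "x_um", "y_um", "intensity") %in% names(d)))
    if (!"snr" %in% names(d)) d$snr <- d$intensity
    d
  }
  donor <- prep(donor)
  acceptor <- prep(acceptor)
  frames <- sort(unique(c(donor$frame, acceptor$frame)))
  out <- lapply(frames, function(fr) {
    dd <- donor[donor$frame == fr, , drop = FALSE]
    aa <- acceptor[acceptor$frame == fr, , drop = FALSE]
    pair_d <- rep(NA_integer_, nrow(dd))
    if (nrow(dd) > 0L && nrow(aa) > 0L) {
      dist <- sqrt(outer(dd$x_um, aa$x_um, "-")^2 +
                   outer(dd$y_um, aa$y_um, "-")^2)
      repeat {
        m <- which.min(dist)
        if (length(m) == 0L || !is.finite(dist[m]) || dist[m] > radius) break
        i <- (m - 1L) %% nrow(dist) + 1L
        j <- (m - 1L) %/% nrow(dist) + 1L
        pair_d[i] <- j
        dist[i, ] <- Inf
        dist[, j] <- Inf
      }
    }
    rows <- list()
    if (nrow(dd) > 0L) {
      for (i in seq_len(nrow(dd))) {
        j <- pair_d[i]
        if (is.na(j)) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            frame = fr, x_um = dd$x_um[i], y_um = dd$y_um[i],
            donor_intensity = dd$intensity[i], acceptor_intensity = 0,
            paired = FALSE)
        } else {
          use_d <- dd$snr[i] >= aa$snr[j]
          rows[[length(rows) + 1L]] <- tibble::tibble(
            frame = fr,
            x_um = if (use_d) dd$x_um[i] else aa$x_um[j],
            y_um = if (use_d) dd$y_um[i] else aa$y_um[j],
            donor_intensity = dd$intensity[i],
            acceptor_intensity = aa$intensity[j],
            paired = TRUE)
        }
      }
    }
    unmatched_a <- setdiff(seq_len(nrow(aa)), pair_d[!is.na(pair_d)])
    for (j in unmatched_a) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        frame = fr, x_um = aa$x_um[j], y_um = aa$y_um[j],
        donor_intensity = 0, acceptor_intensity = aa$intensity[j],
        paired = FALSE)
    }
    dplyr::bind_rows(rows)
  })
  dplyr::bind_rows(out)
}

#' Fit the linear FRET threshold on the intensity heat map
#'
#' Builds a 2D histogram (heat map) of donor versus acceptor intensity and
#' grid-searches the line `I_A = slope * I_D + intercept` that minimizes
#' the integrated heat-map counts along the dividing line, subject to the
#' two population centroids lying on opposite sides. The two populations
#' are located by 2-means clustering; a heat map without two
#' distinguishable populations raises an error rather than silently
#' returning a degenerate threshold.
#'
#' @param data Tibble with columns `donor_intensity`, `acceptor_intensity`
#'   (a trajectory table works directly).
#' @param bins Number of histogram bins per axis (default 100), spanning
#'   the 1st-99th percentile of each intensity axis.
#' @param slopes,intercepts Optional numeric grids to search; defaults are
#'   built from the data scale (61 slopes covering angles -80..80 degrees
#'   in the normalized intensity plane, 81 intercepts across the
#'   histogram's acceptor range).
#' @param min_separation Minimum distance between the two population
#'   centroids, in pooled within-cluster standard deviations, below which
#'   the map is declared unimodal (default 2).
#' @return Object of class `fret_threshold`: list with `slope`,
#'   `intercept`, `high_side` (+1 if the acceptor-rich population
#'   satisfies `I_A > slope * I_D + intercept`), the population centroids
#'   and the objective value.
#' @export
fit_fret_threshold <- function(data, bins = 100L, slopes = NULL,
                               intercepts = NULL, min_separation = 2) {
  id <- data$donor_intensity
  ia <- data$acceptor_intensity
  stopifnot(length(id) >= 10L)
  # locate the two populations
  km <- stats::kmeans(cbind(id, ia), centers = 2L, nstart = 5L)
  cen <- km$centers
  pooled_sd <- sqrt(km$tot.withinss / (length(id) - 2L) / 2)
  sep <- sqrt(sum((cen[1L, ] - cen[2L, ])^2))
  if (!is.finite(pooled_sd) || pooled_sd == 0) pooled_sd <- 1e-12
  if (sep / pooled_sd < min_separation) {
    stop("intensity heat map does not show two distinguishable populations ",
         "(separation ", signif(sep / pooled_sd, 3),
         " pooled SDs); cannot fit a FRET threshold", call. = FALSE)
  }
  # heat map over the 1st-99th percentile window
  xr <- stats::quantile(id, c(0.01, 0.99), names = FALSE)
  yr <- stats::quantile(ia, c(0.01, 0.99), names = FALSE)
  if (diff(xr) <= 0) xr <- range(id) + c(-0.5, 0.5)
  if (diff(yr) <= 0) yr <- range(ia) + c(-0.5, 0.5)
  xb <- seq(xr[1], xr[2], length.out = bins + 1L)
  yb <- seq(yr[1], yr[2], length.out = bins + 1L)
  ix <- findInterval(id, xb, rightmost.closed = TRUE)
  iy <- findInterval(ia, yb, rightmost.closed = TRUE)
  keep <- ix >= 1L & ix <= bins & iy >= 1L & iy <= bins
  H <- matrix(0, bins, bins)
  if (any(keep)) {
    tab <- table(factor(ix[keep], levels = 1:bins),
                 factor(iy[keep], levels = 1:bins))
    H <- matrix(as.numeric(tab), bins, bins)
  }
  scale_y_x <- diff(yr) / diff(xr)   # slope scale between the two axes
  if (is.null(slopes)) {
    angles <- seq(-80, 80, length.out = 61) * pi / 180
    slopes <- sort(unique(c(tan(angles) * scale_y_x, -scale_y_x, scale_y_x, 0, 1, -1)))
  }
  if (is.null(intercepts)) {
    intercepts <- seq(yr[1] - abs(max(slopes)) * diff(xr), yr[2] + abs(max(slopes)) * diff(xr),
                      length.out = 161)
  }
  obj <- line_heatmap_integral(H, xb, yb, slopes, intercepts)
  # centroids must lie on opposite sides
  s1 <- outer(slopes * cen[1L, 1L], intercepts, "+") # value of line at centroid 1
  s2 <- outer(slopes * cen[2L, 1L], intercepts, "+")
  side1 <- sign(cen[1L, 2L] - s1)
  side2 <- sign(cen[2L, 2L] - s2)
  ok <- side1 * side2 < 0
  if (!any(ok)) {
    stop("no candidate threshold separates the two populations; ",
         "widen the slope/intercept grids", call. = FALSE)
  }
  obj[!ok] <- Inf
  best <- which.min(obj)
  bi <- (best - 1L) %% length(slopes) + 1L
  bj <- (best - 1L) %/% length(slopes) + 1L
  slope <- slopes[bi]
  intercept <- intercepts[bj]
  acceptor_rich <- which.max(cen[, 2L] - cen[, 1L])
  high_side <- sign(cen[acceptor_rich, 2L] -
                      (slope * cen[acceptor_rich, 1L] + intercept))
  structure(
    list(slope = slope, intercept = intercept, high_side = as.integer(high_side),
         centroids = cen, objective = obj[best],
         bins = bins, xrange = xr, yrange = yr),
    class = "fret_threshold"
  )
}

# integrated heat-map counts along each candidate line: for every slope x
# intercept pair, sum the counts of all bins the line crosses (column-wise
# traversal of the y-interval the segment covers in each x column)
line_heatmap_integral <- function(H, xb, yb, slopes, intercepts) {
  bins <- nrow(H)
  obj <- matrix(0, length(slopes), length(intercepts))
  ymin <- yb[1L]
  dy <- yb[2L] - yb[1L]
  for (si in seq_along(slopes)) {
    s <- slopes[si]
    y_lo_col <- pmin(s * xb[-length(xb)], s * xb[-1L])
    y_hi_col <- pmax(s * xb[-length(xb)], s * xb[-1L])
    for (ii in seq_along(intercepts)) {
      b <- intercepts[ii]
      j_lo <- floor((y_lo_col + b - ymin) / dy) + 1L
      j_hi <- floor((y_hi_col + b - ymin) / dy) + 1L
      tot <- 0
      for (col in seq_len(bins)) {
        jl <- max(1L, j_lo[col])
        jh <- min(bins, j_hi[col])
        if (jl <= jh) tot <- tot + sum(H[col, jl:jh])
      }
      obj[si, ii] <- tot
    }
  }
  obj
}

#' @export
print.fret_threshold <- function(x, ...) {
  cat("<fret_threshold>\n")
  cat(sprintf("  I_A = %.4g * I_D + %.4g; high-FRET side: %s\n",
              x$slope, x$intercept,
              if (x$high_side > 0) "above" else "below"))
  invisible(x)
}

#' Assign per-frame FRET states from a threshold line
#'
#' Each observation is classified by which side of the threshold line its
#' `(I_D, I_A)` point falls on; the acceptor-rich side is the high-FRET
#' state. Deterministic and idempotent.
#'
#' @param data A trajectory table.
#' @param threshold A [fit_fret_threshold()] object.
#' @return `data` with `fret_state` filled with `"high"`/`"low"`.
#' @export
assign_fret_states <- function(data, threshold) {
  stopifnot(inherits(threshold, "fret_threshold"))
  side <- sign(data$acceptor_intensity -
                 (threshold$slope * data$donor_intensity + threshold$intercept))
  side[side == 0] <- -threshold$high_side  # on-line points default to low
  data$fret_state <- ifelse(side == threshold$high_side, "high", "low")
  data
}

#' Filter trajectories for a specific analysis purpose
#'
#' Applies the trajectory exclusion rules appropriate for each analysis:
#'
#' * `"diffusion"` — median donor intensity at or below the 60th
#'   percentile of per-trajectory medians, total surface residence time of
#'   at least `min_residence_s` (default 0.71 s), and at most
#'   `max_frames` (1000) frames (longer trajectories are assumed
#'   contaminants);
#' * `"kinetics"` — median-intensity cutoff, length strictly greater than
#'   2 frames (0.1 s at 50 ms), and the 1000-frame contaminant rule;
#' * `"dwell"` — the kinetics rules plus exclusion of trajectories
#'   observed in the first or last movie frame (censoring rule for dwell
#'   and residence-time analyses).
#'
#' Rules are applied in the order intensity cutoff, contaminant rule,
#' length/residence minimum, censoring exclusion, and the removal counts
#' per rule are recorded so that removed + retained equals the input
#' count.
#'
#' @param data A trajectory table.
#' @param purpose One of `"diffusion"`, `"kinetics"`, `"dwell"`.
#' @param dt Acquisition interval in seconds.
#' @param intensity_percentile Median-donor-intensity percentile cutoff
#'   (default 60).
#' @param min_residence_s Minimum surface residence time for diffusion
#'   analysis (default 0.71 s).
#' @param max_frames Contaminant rule threshold (default 1000 frames).
#' @return The filtered trajectory table, with a `filter_report` attribute
#'   (see [filter_report()]).
#' @export
filter_trajectories <- function(data,
                                purpose = c("diffusion", "kinetics", "dwell"),
                                dt = 0.05,
                                intensity_percentile = 60,
                                min_residence_s = 0.71,
                                max_frames = 1000L) {
  purpose <- match.arg(purpose)
  stopifnot(dt > 0)
  data <- validate_trajectories(data)
  per_traj <- data |>
    dplyr::group_by(.data$traj_id) |>
    dplyr::summarise(
      n_frames = dplyr::n(),
      median_donor = stats::median(.data$donor_intensity),
      starts = any(.data$starts_at_movie_start),
      ends = any(.data$ends_at_movie_end),
      .groups = "drop"
    )
  n_in <- nrow(per_traj)
  report <- c(input = n_in, intensity_cutoff = 0L, contaminant_rule = 0L,
              min_length = 0L, censoring = 0L, retained = 0L)
  cutoff <- stats::quantile(per_traj$median_donor, intensity_percentile / 100,
                            names = FALSE)
  keep <- per_traj$median_donor <= cutoff
  report["intensity_cutoff"] <- sum(!keep)
  alive <- per_traj[keep, , drop = FALSE]

  long <- alive$n_frames > max_frames
  report["contaminant_rule"] <- sum(long)
  alive <- alive[!long, , drop = FALSE]

  short <- if (purpose == "diffusion") {
    alive$n_frames * dt < min_residence_s
  } else {
    alive$n_frames <= 2L
  }
  report["min_length"] <- sum(short)
  alive <- alive[!short, , drop = FALSE]

  if (purpose == "dwell") {
    cens <- alive$starts | alive$ends
    report["censoring"] <- sum(cens)
    alive <- alive[!cens, , drop = FALSE]
  }
  report["retained"] <- nrow(alive)
  out <- data[data$traj_id %in% alive$traj_id, , drop = FALSE]
  if (nrow(out) == 0L) {
    warning("no trajectories survive the ", purpose, " filters")
  }
  attr(out, "filter_report") <- report
  attr(out, "dt") <- dt
  out
}

#' Retrieve the filter report of a filtered trajectory table
#'
#' @param data Output of [filter_trajectories()].
#' @return Named integer vector: input count, removals per rule, retained.
#' @export
filter_report <- function(data) {
  rep <- attr(data, "filter_report")
  if (is.null(rep)) stop("no filter report attached; run filter_trajectories()")
  rep
}
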