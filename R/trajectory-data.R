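#' Trajectory tables
#'
#' All analysis functions in cadcluster operate on a "trajectory table": a
#' tibble with one row per (trajectory, frame) observation and the columns
#'
#' * `traj_id` — integer trajectory identifier,
#' * `frame` — integer frame index (consecutive within a trajectory),
#' * `x_um`, `y_um` — position in micrometres,
#' * `donor_intensity`, `acceptor_intensity` — fluorescence intensities
#'   (arbitrary units),
#' * `fret_state` — `"high"`, `"low"` or `NA` (unassigned),
#' * `starts_at_movie_start`, `ends_at_movie_end` — logical censoring flags
#'   (optional; assumed `FALSE` when absent).
#'
#' The acquisition interval `dt` (seconds, default 0.05) and the pixel size
#' (micrometres, default 0.43) are carried as attributes `dt` and
#' `pixel_size` when read from disk, and accepted as explicit arguments by
#' every function that needs them.
#'
#' @name trajectory-table
NULL

.traj_required_cols <- c("traj_id", "frame", "x_um", "y_um",
                         "donor_intensity", "acceptor_intensity")

.traj_all_cols <- c(.traj_required_cols, "fret_state",
                    "starts_at_movie_start", "ends_at_movie_end")

#' Validate a trajectory table
#'
#' Checks the column contract and the per-trajectory invariants: frames
#' strictly increasing and consecutive (gapless linking), at least two
#' frames per trajectory, one position per frame.
#'
#' @param data A trajectory table (see [trajectory-table]).
#' @param min_length Minimum trajectory length in frames (default 2).
#' @return `data`, invisibly, with missing optional columns filled in.
#' @export
validate_trajectories <- function(data, min_length = 2L) {
  missing <- setdiff(.traj_required_cols, names(data))
  if (length(missing) > 0L) {
    stop("trajectory table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"fret_state" %in% names(data)) data$fret_state <- NA_character_
  if (!"starts_at_movie_start" %in% names(data)) data$starts_at_movie_start <- FALSE
  if (!"ends_at_movie_end" %in% names(data)) data$ends_at_movie_end <- FALSE
  bad_state <- !is.na(data$fret_state) & !data$fret_state %in% c("high", "low")
  if (any(bad_state)) {
    stop("fret_state must be 'high', 'low' or NA", call. = FALSE)
  }
  if (nrow(data) > 0L) {
    chk <- data |>
      dplyr::group_by(.data$traj_id) |>
      dplyr::summarise(
        n = dplyr::n(),
        gapless = all(diff(.data$frame) == 1L),
        .groups = "drop"
      )
    if (any(!chk$gapless)) {
      stop("non-consecutive frames within trajectory id(s): ",
           paste(utils::head(chk$traj_id[!chk$gapless], 5L), collapse = ", "),
           call. = FALSE)
    }
    if (any(chk$n < min_length)) {
      stop("trajectories shorter than ", min_length, " frames: ",
           paste(utils::head(chk$traj_id[chk$n < min_length], 5L),
                 collapse = ", "), call. = FALSE)
    }
  }
  invisible(tibble::as_tibble(data))
}

#' Read a trajectory table from CSV
#'
#' Reads the comma-separated trajectory format (one row per trajectory and
#' frame; see [trajectory-table] for columns), sorts by trajectory id and
#' frame, and validates the per-trajectory invariants.
#'
#' @param path Path to a CSV file.
#' @param dt Acquisition interval in seconds, attached as attribute.
#' @param pixel_size Pixel size in micrometres, attached as attribute.
#' @param min_length Minimum trajectory length accepted (default 2 frames).
#' @return A validated trajectory tibble with attributes `dt`, `pixel_size`.
#' @export
read_trajectories <- function(path, dt = 0.05, pixel_size = 0.43,
                              min_length = 2L) {
  stopifnot(dt > 0, pixel_size > 0)
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(.traj_required_cols, names(data))
  if (length(missing) > 0L) {
    stop("file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  data <- data |>
    dplyr::mutate(
      traj_id = as.integer(.data$traj_id),
      frame = as.integer(.data$frame)
    ) |>
    dplyr::arrange(.data$traj_id, .data$frame)
  if ("fret_state" %in% names(data)) {
    data$fret_state <- dplyr::na_if(as.character(data$fret_state), "")
  }
  if ("starts_at_movie_start" %in% names(data)) {
    data$starts_at_movie_start <- as.logical(data$starts_at_movie_start)
  }
  if ("ends_at_movie_end" %in% names(data)) {
    data$ends_at_movie_end <- as.logical(data$ends_at_movie_end)
  }
  if (nrow(data) > 0L) {
    nondec <- data |>
      dplyr::group_by(.data$traj_id) |>
      dplyr::summarise(mono = !is.unsorted(.data$frame, strictly = TRUE),
                       .groups = "drop")
    if (any(!nondec$mono)) {
      stop("non-monotone frames within trajectory id(s): ",
           paste(utils::head(nondec$traj_id[!nondec$mono], 5L),
                 collapse = ", "), call. = FALSE)
    }
  }
  data <- validate_trajectories(data, min_length = min_length)
  attr(data, "dt") <- dt
  attr(data, "pixel_size") <- pixel_size
  data
}

#' Write a trajectory table to CSV
#'
#' Lossless counterpart of [read_trajectories()]: a file written here and
#' read back yields an identical table.
#'
#' @param data A trajectory table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(data, path) {
  data <- validate_trajectories(data, min_length = 1L)
  readr::write_csv(data[, .traj_all_cols], path, progress = FALSE)
  invisible(path)
}

#' Link per-frame localizations into trajectories
#'
#' Greedy nearest-neighbour frame-to-frame linking: localizations in
#' consecutive frames are paired closest-first, links longer than `radius`
#' are forbidden, and unlinked localizations start new trajectories. Ties
#' are broken by smallest distance, then lowest localization index. Gaps
#' are never bridged: a missed frame terminates the trajectory.
#'
#' @param localizations Tibble with columns `frame`, `x_um`, `y_um` and
#'   optionally `donor_intensity`, `acceptor_intensity`.
#' @param radius Maximum frame-to-frame displacement in micrometres
#'   (default 1.29, i.e. 3 pixels at 0.43 um/px).
#' @return The input tibble with a `traj_id` column, sorted by trajectory
#'   and frame. Single-frame trajectories are retained (filter afterwards
#'   with [validate_trajectories()] or length rules as needed).
#' @export
link_localizations <- function(localizations, radius = 1.29) {
  stopifnot(radius > 0)
  locs <- tibble::as_tibble(localizations)
  stopifnot(all(c("frame", "x_um", "y_um") %in% names(locs)))
  if (nrow(locs) == 0L) {
    locs$traj_id <- integer(0)
    return(locs)
  }
  locs$.row <- seq_len(nrow(locs))
  locs <- dplyr::arrange(locs, .data$frame, .data$.row)
  locs$traj_id <- NA_integer_
  next_id <- 1L
  frames <- sort(unique(locs$frame))
  idx_by_frame <- split(seq_len(nrow(locs)), factor(locs$frame, levels = frames))
  # seed first frame
  first <- idx_by_frame[[1L]]
  locs$traj_id[first] <- seq.int(next_id, length.out = length(first))
  next_id <- next_id + length(first)
  if (length(frames) > 1L) {
    for (fi in 2L:length(frames)) {
      cur <- idx_by_frame[[fi]]
      prev <- if (frames[fi] - frames[fi - 1L] == 1L) idx_by_frame[[fi - 1L]] else integer(0)
      if (length(prev) > 0L && length(cur) > 0L) {
        d <- sqrt(outer(locs$x_um[prev], locs$x_um[cur], "-")^2 +
                  outer(locs$y_um[prev], locs$y_um[cur], "-")^2)
        # greedy closest-first assignment
        repeat {
          m <- which.min(d)
          if (length(m) == 0L || !is.finite(d[m]) || d[m] > radius) break
          i <- (m - 1L) %% nrow(d) + 1L
          j <- (m - 1L) %/% nrow(d) + 1L
          locs$traj_id[cur[j]] <- locs$traj_id[prev[i]]
          d[i, ] <- Inf
          d[, j] <- Inf
        }
      }
      new <- cur[is.na(locs$traj_id[cur])]
      if (length(new) > 0L) {
        locs$traj_id[new] <- seq.int(next_id, length.out = length(new))
        next_id <- next_id + length(new)
      }
    }
  }
  locs |>
    dplyr::select(-".row") |>
    dplyr::relocate("traj_id") |>
    dplyr::arrange(.data$traj_id, .data$frame)
}
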