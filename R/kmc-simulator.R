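#' Configuration for the clustering kinetic Monte Carlo simulator
#'
#' Sets up an off-lattice, domain-based diffusion-reaction simulation of
#' membrane-tethered ectodomains on a periodic 2D square membrane patch.
#' Each molecule is a rigid rod of five 1.5 nm domains whose position is
#' the EC1 (N-terminal) domain centre; a cis-donor and a cis-acceptor site
#' sit on opposing sides of the EC1 surface. Two bond types exist:
#'
#' * specific — donor site of one molecule to acceptor site of another,
#'   within `cutoff_sp` (1.2 nm) and with relative in-plane orientation
#'   within `angle_sp` (30 deg) of the native-dimer alignment; at most one
#'   outgoing and one incoming specific bond per molecule, mandating
#'   linear oligomers;
#' * nonspecific — any EC1-EC1 pair within `cutoff_ns` (3.2 nm),
#'   unpolarized and without valence limit.
#'
#' Per step, every connected cluster takes a rigid Brownian move
#' (translation variance `4 D_trans dt` split over x/y; rotation RMS
#' `D_rot * dt` about the cluster centroid), then each eligible pair forms
#' a bond with probability `on * dt` and each existing bond breaks with
#' probability `off * dt` (all probabilities are validated to be <= 1).
#'
#' The reference time step is 0.01 ns; the default here is 10 ns, a
#' reduced-scale setting at which all bond probabilities remain valid and
#' every on/off ratio is unchanged — equilibrium cluster statistics depend
#' on the ratios, not the absolute rates.
#'
#' @param n_molecules Number of molecules (default 200).
#' @param box_nm Box side in nm (default 400; 200 molecules on 400 nm give
#'   1250 molecules/um^2).
#' @param dt Time step in seconds (default 1e-8).
#' @param D_trans Monomer translational diffusion coefficient, um^2/s
#'   (default 10).
#' @param D_rot Rotational step amplitude, degrees per ns (default 1).
#' @param on_ns,off_ns Nonspecific association/dissociation rates, s^-1
#'   (defaults 2e5 and 1e3, the calibrated mutant values).
#' @param on_sp,off_sp Specific association/dissociation rates, s^-1
#'   (default 0 and 0 = mutant mode; wild-type calibration is 1e8, 1e2).
#' @param cutoff_ns Nonspecific EC1-EC1 distance cutoff, nm (default 3.2).
#' @param cutoff_sp Specific donor-acceptor distance cutoff, nm (default
#'   1.2).
#' @param angle_sp Specific orientation cutoff, degrees (default 30).
#' @param site_radius Domain radius, nm (default 1.5; the donor and
#'   acceptor sites sit on the EC1 surface).
#' @param n_domains Number of collinear rigid domains per molecule
#'   (default 5; the rod extends opposite the orientation vector from the
#'   EC1 centre).
#' @param t_end Maximum simulated time, s.
#' @param n_samples Target number of recorded samples along the run.
#' @param plateau_window Samples per plateau-detection window (default 40).
#' @param plateau_tol Relative change of the windowed mean cluster size
#'   below which the run is declared equilibrated (default 0.02).
#' @param min_run_time Simulated time before plateau detection may stop
#'   the run, s (default `t_end / 4`).
#' @param rxn_every Reaction sub-sampling interval in steps (default 1):
#'   association and dissociation are evaluated every `rxn_every` steps
#'   with probabilities `rate * dt * rxn_every` (validated <= 1), while
#'   diffusion proceeds every step. Values > 1 trade reaction-time
#'   granularity for speed at identical rates and ratios.
#' @param cluster_d_inverse_n If TRUE clusters diffuse at `D_trans / N`
#'   (sensitivity mode); default FALSE (clusters move with the monomer
#'   coefficient).
#' @param intercluster_only Bonds form only between molecules of distinct
#'   clusters (default TRUE): association is a binding event between a
#'   molecule or cluster and another molecule or cluster, so cluster
#'   connectivity is a tree and fragmentation scales with cluster size.
#'   FALSE also allows intra-cluster bond formation (multivalent
#'   stabilization; at the calibrated rates this drives gelation).
#' @param internal_moves Treat bonds as flexible tethers: besides the
#'   collective rigid move, each bonded molecule attempts an individual
#'   Brownian move each step, rejected if it violates excluded volume or
#'   any incident bond's geometric criterion (anneals cluster geometry).
#'   Default FALSE: clusters are rigid ("move together").
#' @param hard_core Enforce excluded volume among all rod domains: moves
#'   bringing two discs of different molecules within one disc diameter
#'   are rejected, as are overlapping initial placements. Default FALSE:
#'   overlap is rejected at placement only (soft model).
#' @return A list of class `kmc_config`.
#' @export
kmc_config <- function(n_molecules = 200L, box_nm = 400, dt = 1e-8,
                       D_trans = 10, D_rot = 1,
                       on_ns = 2e5, off_ns = 1e3,
                       on_sp = 0, off_sp = 0,
                       cutoff_ns = 3.2, cutoff_sp = 1.2, angle_sp = 30,
                       site_radius = 1.5, n_domains = 5L,
                       t_end = 0.05, n_samples = 400L,
                       plateau_window = 40L, plateau_tol = 0.02,
                       min_run_time = t_end / 4, rxn_every = 1L,
                       cluster_d_inverse_n = FALSE,
                       intercluster_only = TRUE,
                       internal_moves = FALSE,
                       hard_core = FALSE) {
  stopifnot(n_molecules >= 1, box_nm > 0, dt > 0, D_trans >= 0, D_rot >= 0,
            on_ns >= 0, off_ns >= 0, on_sp >= 0, off_sp >= 0,
            cutoff_ns > 0, cutoff_sp > 0, angle_sp > 0, t_end > dt)
  probs <- c(on_ns, off_ns, on_sp, off_sp) * dt * rxn_every
  if (any(probs > 1)) {
    stop("rate * dt * rxn_every exceeds 1 for at least one reaction; ",
         "reduce dt or rxn_every", call. = FALSE)
  }
  structure(
    list(n_molecules = as.integer(n_molecules), box_nm = box_nm, dt = dt,
         D_trans = D_trans, D_rot = D_rot,
         on_ns = on_ns, off_ns = off_ns, on_sp = on_sp, off_sp = off_sp,
         cutoff_ns = cutoff_ns, cutoff_sp = cutoff_sp, angle_sp = angle_sp,
         site_radius = site_radius, n_domains = as.integer(n_domains),
         t_end = t_end,
         n_samples = as.integer(n_samples),
         plateau_window = as.integer(plateau_window),
         plateau_tol = plateau_tol, min_run_time = min_run_time,
         rxn_every = as.integer(rxn_every),
         cluster_d_inverse_n = cluster_d_inverse_n,
         intercluster_only = intercluster_only,
         internal_moves = internal_moves, hard_core = hard_core),
    class = "kmc_config"
  )
}

#' Surface density implied by a simulation box
#'
#' @param n_molecules Molecule count.
#' @param box_nm Box side in nm.
#' @return Density in molecules per um^2.
#' @export
kmc_density <- function(n_molecules, box_nm) {
  n_molecules * 1e6 / box_nm^2
}

#' @export
print.kmc_config <- function(x, ...) {
  cat("<kmc_config>\n")
  cat(sprintf("  %d molecules on a %g nm box (%.4g /um^2), dt = %g s\n",
              x$n_molecules, x$box_nm,
              kmc_density(x$n_molecules, x$box_nm), x$dt))
  cat(sprintf("  nonspecific on/off = %g / %g s^-1 (ratio %g)\n",
              x$on_ns, x$off_ns,
              if (x$off_ns > 0) x$on_ns / x$off_ns else NA))
  if (x$on_sp > 0) {
    cat(sprintf("  specific    on/off = %g / %g s^-1 (ratio %g)\n",
                x$on_sp, x$off_sp,
                if (x$off_sp > 0) x$on_sp / x$off_sp else NA))
  } else cat("  specific interactions disabled (mutant mode)\n")
  invisible(x)
}

#' Run the clustering kinetic Monte Carlo simulation
#'
#' Iterates diffusion, association and dissociation until `t_end` or until
#' the windowed mean cluster size plateaus. Replicas run with independent
#' seeds derived from `seed`.
#'
#' @param config A [kmc_config()] object.
#' @param replicas Number of independent replicas (default 1).
#' @param seed Optional integer seed.
#' @return Object of class `kmc_ensemble`: list with `config` and
#'   `replicas`, each replica holding `trace` (tibble `time`,
#'   `mean_size`), `samples` (list of integer vectors: component sizes at
#'   each recorded sample), `membership` (n x samples integer matrix of
#'   each molecule's cluster size), `final` (tibble of molecule poses,
#'   unwrapped squared displacements since t = 0 in nm^2, and
#'   specific-bond partners), `bonds_ns` (tibble), `equilibrated`,
#'   `sample_dt`.
#' @export
kmc_run <- function(config, replicas = 1L, seed = NULL) {
  stopifnot(inherits(config, "kmc_config"), replicas >= 1L)
  if (!is.null(seed)) set.seed(seed)
  total_steps <- ceiling(config$t_end / config$dt)
  sample_every <- max(1L, floor(total_steps / config$n_samples))
  reps <- lapply(seq_len(replicas), function(r) {
    raw <- .kmc_run_cpp(
      n = config$n_molecules, box = config$box_nm, dt = config$dt,
      D_trans_um2s = config$D_trans, D_rot_deg_ns = config$D_rot,
      on_ns = config$on_ns, off_ns = config$off_ns,
      on_sp = config$on_sp, off_sp = config$off_sp,
      cutoff_ns = config$cutoff_ns, cutoff_sp = config$cutoff_sp,
      angle_sp_deg = config$angle_sp, site_radius = config$site_radius,
      n_dom = config$n_domains,
      t_end = config$t_end, sample_every = sample_every,
      plateau_window = config$plateau_window,
      plateau_tol = config$plateau_tol,
      cluster_d_inverse_n = config$cluster_d_inverse_n,
      hard_core = config$hard_core,
      internal_moves = config$internal_moves,
      intercluster_only = config$intercluster_only,
      rxn_every = config$rxn_every,
      min_run_time = config$min_run_time
    )
    if (!raw$equilibrated) {
      warning("replica ", r, " did not reach the plateau criterion by t_end",
              call. = FALSE)
    }
    ends <- cumsum(raw$sizes_len)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    samples <- Map(function(s, e) raw$sizes_flat[s:e], starts, ends)
    list(
      trace = tibble::tibble(time = raw$time, mean_size = raw$mean_size),
      samples = samples,
      membership = raw$compsize_mol,
      final = tibble::tibble(
        id = seq_len(config$n_molecules),
        x_nm = raw$x, y_nm = raw$y, orientation_deg = raw$orientation,
        disp2_nm2 = raw$disp2,
        spec_partner = ifelse(raw$spec_out == 0L, NA_integer_, raw$spec_out)
      ),
      bonds_ns = tibble::tibble(i = raw$ns_i, j = raw$ns_j),
      equilibrated = raw$equilibrated,
      invariant_violations = raw$invariant_violations,
      n_steps = raw$n_steps,
      sample_dt = raw$sample_dt
    )
  })
  structure(list(config = config, replicas = reps), class = "kmc_ensemble")
}

#' @export
print.kmc_ensemble <- function(x, ...) {
  cat("<kmc_ensemble>", length(x$replicas), "replica(s)\n")
  fin <- vapply(x$replicas, function(r) utils::tail(r$trace$mean_size, 1L), 0)
  eq <- vapply(x$replicas, function(r) r$equilibrated, TRUE)
  cat(sprintf("  final mean cluster size: %s\n",
              paste(signif(fin, 3), collapse = ", ")))
  cat(sprintf("  equilibrated: %d / %d\n", sum(eq), length(eq)))
  invisible(x)
}

#' Pooled cluster sizes from an ensemble's analysis window
#'
#' Collects connected-component sizes over the final `window` fraction of
#' each replica's recorded samples, pooled across replicas.
#'
#' @param ensemble A [kmc_run()] result.
#' @param window Fraction of each run's tail to pool (default 0.25).
#' @return Integer vector of cluster sizes.
#' @export
kmc_cluster_sizes <- function(ensemble, window = 0.25) {
  stopifnot(inherits(ensemble, "kmc_ensemble"), window > 0, window <= 1)
  unlist(lapply(ensemble$replicas, function(r) {
    ns <- length(r$samples)
    from <- max(1L, ns - ceiling(window * ns) + 1L)
    unlist(r$samples[from:ns])
  }))
}

#' Cluster-size distribution and characteristic size of an ensemble
#'
#' Bins the pooled cluster sizes of the analysis window and fits the
#' single-exponential `A exp(-N / N0)` after removing the smallest-size
#' bin (see [fit_characteristic_size()]).
#'
#' @param ensemble A [kmc_run()] result.
#' @param window Tail fraction to pool (default 0.25).
#' @param bin_width Linear bin width in molecules (default 4).
#' @return List with `distribution` (a [cluster_size_distribution()]) and
#'   `fit` (a [fit_characteristic_size()] result).
#' @export
kmc_cluster_statistics <- function(ensemble, window = 0.25, bin_width = 4) {
  sizes <- kmc_cluster_sizes(ensemble, window)
  dist <- cluster_size_distribution(sizes, binning = "linear",
                                    bin_width = bin_width)
  list(distribution = dist, fit = fit_characteristic_size(dist))
}

#' Association-time distribution of an ensemble
#'
#' Per molecule, the contiguous intervals during which it belongs to a
#' cluster of size >= 2, measured on the stroboscopically sampled
#' membership record (experiment-like sampling at the trace interval).
#' Intervals still open at the end of a run are included (censored, like
#' experimental trajectories cut by the movie end).
#'
#' @param ensemble A [kmc_run()] result.
#' @return Tibble of class `association_times` with columns `replica`,
#'   `molecule`, `duration` (s), `censored`; attribute `sample_dt`.
#' @export
association_times <- function(ensemble) {
  stopifnot(inherits(ensemble, "kmc_ensemble"))
  out <- purrr::imap_dfr(ensemble$replicas, function(r, idx) {
    sdt <- r$sample_dt
    mem <- r$membership >= 2L
    n <- nrow(mem)
    purrr::map_dfr(seq_len(n), function(i) {
      v <- mem[i, ]
      runs <- rle(v)
      if (!any(runs$values)) return(NULL)
      ends_at <- cumsum(runs$lengths)
      assoc <- which(runs$values)
      tibble::tibble(
        replica = idx, molecule = i,
        duration = runs$lengths[assoc] * sdt,
        censored = ends_at[assoc] == length(v)
      )
    })
  })
  class(out) <- c("association_times", class(out))
  attr(out, "sample_dt") <- ensemble$replicas[[1L]]$sample_dt
  out
}

#' Complementary cumulative association-time distribution
#'
#' @param assoc An [association_times()] tibble.
#' @return Tibble with columns `duration` (s) and `ccdf`.
#' @export
association_ccdf <- function(assoc) {
  if (nrow(assoc) == 0L) {
    return(tibble::tibble(duration = numeric(0), ccdf = numeric(0)))
  }
  d <- sort(assoc$duration)
  u <- unique(d)
  tibble::tibble(
    duration = u,
    ccdf = vapply(u, function(t) mean(d >= t), 0)
  )
}

#' Plot the mean-cluster-size traces of an ensemble
#'
#' @param object A [kmc_run()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kmc_ensemble <- function(object, ...) {
  tr <- purrr::imap_dfr(object$replicas, function(r, idx) {
    dplyr::mutate(r$trace, replica = factor(idx))
  })
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$time, y = .data$mean_size,
                                   color = .data$replica)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "mean cluster size (molecules)")
}
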