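#' Selectivity-filter site geometry
#'
#' Ordered K+ binding-site geometry along the pore (z) axis: the cavity
#' below the filter, the filter sites Scav, S4, S3, S2, S1, S0 (inner to
#' outer), and the extracellular side. Interior sites occupy contiguous
#' half-open z intervals; the entry plane is the lower boundary of Scav and
#' the exit plane the upper boundary of S0. The default spacing of 0.31 nm
#' is the canonical carbonyl-plane separation of adjacent sites.
#'
#' @param centers named numeric vector of interior-site z centers (nm),
#'   strictly increasing, names `Scav`, `S4` .. `S0`; the default places
#'   Scav at 0 with 0.31 nm spacing.
#' @return an object of class `sf_geometry`: list with `sites` (all 8
#'   labels, cavity first), `centers` (z of all 8, cavity/ext placed one
#'   spacing beyond the planes), `boundaries` (7 interval boundaries of the
#'   6 interior sites), `entry_plane`, `exit_plane`.
#' @export
sf_geometry <- function(centers = NULL) {
  if (is.null(centers)) {
    centers <- seq(0, by = 0.31, length.out = 6L)
    names(centers) <- c("Scav", "S4", "S3", "S2", "S1", "S0")
  }
  if (length(centers) != 6L || is.null(names(centers)) ||
      !identical(names(centers), c("Scav", "S4", "S3", "S2", "S1", "S0")))
    stop("centers must be named Scav, S4, S3, S2, S1, S0", call. = FALSE)
  if (any(diff(centers) <= 0))
    stop("site centers must be strictly increasing in z", call. = FALSE)
  mid <- (centers[-1] + centers[-6]) / 2
  lo <- centers[[1]] - (mid[[1]] - centers[[1]])
  hi <- centers[[6]] + (centers[[6]] - mid[[5]])
  boundaries <- unname(c(lo, mid, hi))
  spacing <- mean(diff(centers))
  all_centers <- c(cavity = lo - spacing / 2, centers,
                   ext = hi + spacing / 2)
  structure(list(sites = c("cavity", names(centers), "ext"),
                 centers = unname(all_centers),
                 boundaries = boundaries,
                 entry_plane = boundaries[1L],
                 exit_plane = boundaries[7L]),
            class = "sf_geometry")
}

#' @export
print.sf_geometry <- function(x, ...) {
  cat("<sf_geometry> sites (z, nm):\n")
  print(stats::setNames(round(x$centers, 3), x$sites))
  cat(sprintf("  entry plane %.3f nm, exit plane %.3f nm\n",
              x$entry_plane, x$exit_plane))
  invisible(x)
}

#' Assign binding-site labels to trajectory frames
#'
#' Each frame is labeled by the half-open interval [lo, hi) containing its
#' z; frames below the entry plane are `cavity`, at or above the exit plane
#' `ext`.
#'
#' @param traj an `ion_trajectory` data.frame (columns `ion`, `time`, `z`)
#'   or any data.frame with a `z` column.
#' @param geom an [sf_geometry()].
#' @return `traj` with a `site` character column.
#' @export
assign_sites <- function(traj, geom) {
  stopifnot(inherits(geom, "sf_geometry"), "z" %in% names(traj))
  idx <- findInterval(traj$z, geom$boundaries) # 0 below, 7 above
  traj$site <- geom$sites[idx + 1L]
  traj
}

#' Count full ion traversals of the selectivity filter
#'
#' Three-zone state machine per ion (below the entry plane / inside the
#' filter / above the exit plane): an outward permeation event is recorded
#' when an ion that last entered the filter from below exits above; inward
#' is the mirror image. Partial entries that retreat count nothing; an ion
#' can produce many events. A z jump larger than `Lz/2` between consecutive
#' frames is treated as a periodic-boundary wrap and resets that ion's
#' state to unknown, preventing phantom crossings.
#'
#' @param traj an `ion_trajectory` data.frame (`ion`, `time`, `z`).
#' @param geom an [sf_geometry()].
#' @param Lz box length along z (nm) for wrap detection, or `NULL` to
#'   disable.
#' @return list with `n_outward`, `n_inward`, and `events` (data.frame:
#'   `ion`, `time`, `direction`).
#' @export
count_crossings <- function(traj, geom, Lz = NULL) {
  stopifnot(inherits(geom, "sf_geometry"),
            all(c("ion", "time", "z") %in% names(traj)))
  if (any(!is.finite(traj$z))) {
    bad <- which(!is.finite(traj$z))[1L]
    stop(sprintf("non-finite z for ion %s at frame %d",
                 traj$ion[bad], bad), call. = FALSE)
  }
  ev_ion <- integer(); ev_time <- numeric(); ev_dir <- character()
  for (id in unique(traj$ion)) {
    s <- traj[traj$ion == id, ]
    s <- s[order(s$time), ]
    zone <- ifelse(s$z < geom$entry_plane, 1L,
                   ifelse(s$z < geom$exit_plane, 2L, 3L))
    if (!is.null(Lz)) {
      wrap <- c(FALSE, abs(diff(s$z)) > Lz / 2)
      zone[wrap] <- NA_integer_ # unknown until the ion re-enters a zone
    }
    mem <- NA_integer_ # boundary zone from which the filter was last entered
    prev <- NA_integer_
    for (i in seq_along(zone)) {
      cur <- zone[i]
      if (is.na(cur)) { mem <- NA_integer_; prev <- NA_integer_; next }
      if (!is.na(prev) && cur != prev) {
        if (cur == 3L && ((prev == 2L && identical(mem, 1L)) || prev == 1L)) {
          ev_ion <- c(ev_ion, id); ev_time <- c(ev_time, s$time[i])
          ev_dir <- c(ev_dir, "outward")
        } else if (cur == 1L &&
                   ((prev == 2L && identical(mem, 3L)) || prev == 3L)) {
          ev_ion <- c(ev_ion, id); ev_time <- c(ev_time, s$time[i])
          ev_dir <- c(ev_dir, "inward")
        }
      }
      if (cur %in% c(1L, 3L)) mem <- cur
      prev <- cur
    }
  }
  list(n_outward = sum(ev_dir == "outward"),
       n_inward = sum(ev_dir == "inward"),
       events = data.frame(ion = ev_ion, time = ev_time,
                           direction = ev_dir))
}

#' Ionic current from permeation counts
#'
#' \eqn{I = (n_{out} - n_{in}) e_0 / t}; with t in ns the result is in pA.
#'
#' @param n_outward,n_inward full-traversal counts.
#' @param duration trajectory duration, ns.
#' @return current in pA.
#' @export
current_from_counts <- function(n_outward, n_inward, duration) {
  stop_if_not_scalar_pos(duration, "duration")
  (n_outward - n_inward) * .e0_coulomb / (duration * 1e-9) * 1e12
}

#' Per-site potassium occupancy
#'
#' For each interior binding site, the fraction of frames in which at least
#' one ion occupies the site (presence probability); the mean ion count per
#' frame is reported alongside.
#'
#' @param traj a labeled `ion_trajectory` (columns `time`, `site`); run
#'   [assign_sites()] first if needed.
#' @param geom an [sf_geometry()].
#' @return data.frame with columns `site`, `presence`, `mean_count`.
#' @export
site_occupancy <- function(traj, geom) {
  stopifnot("site" %in% names(traj))
  interior <- geom$sites[-c(1L, length(geom$sites))]
  times <- unique(traj$time)
  nf <- length(times)
  out <- lapply(interior, function(s) {
    sub <- traj[traj$site == s, ]
    per_frame <- table(factor(sub$time, levels = times))
    data.frame(site = s,
               presence = sum(per_frame >= 1L) / nf,
               mean_count = sum(per_frame) / nf)
  })
  do.call(rbind, out)
}

#' Free-energy profile from ion density along the pore axis
#'
#' The negative logarithm of the binned ion density, anchored so the global
#' minimum over occupied bins is zero:
#' \eqn{G(z) = -\ln[\rho(z)/\rho_{max}]} in kT units. Minima mark stable
#' binding sites, maxima the barriers between them. Empty bins are masked,
#' never assigned an artificial value.
#'
#' @param z ion z samples, nm.
#' @param bins number of bins.
#' @param range z range (nm); defaults to the geometry's full site span.
#' @param geom an [sf_geometry()] supplying the default range.
#' @param temperature optional temperature (K); when given, a `G_kJ_mol`
#'   column converts kT to kJ/mol.
#' @return data.frame of class `fe_profile`: `z` (bin centers), `G` (kT),
#'   `count`, `masked`.
#' @export
free_energy_profile <- function(z, bins = 80, range = NULL, geom = NULL,
                                temperature = NULL) {
  if (!length(z)) stop("need at least one sample", call. = FALSE)
  if (is.null(range)) {
    g <- geom %||% sf_geometry()
    range <- c(g$centers[1L], g$centers[length(g$centers)])
  }
  edges <- seq(range[1L], range[2L], length.out = bins + 1L)
  idx <- findInterval(z, edges, rightmost.closed = TRUE)
  idx <- idx[idx >= 1L & idx <= bins]
  if (!length(idx)) stop("all bins empty in range", call. = FALSE)
  counts <- tabulate(idx, nbins = bins)
  G <- rep(NA_real_, bins)
  occ <- counts > 0
  G[occ] <- -log(counts[occ] / max(counts))
  out <- data.frame(z = (edges[-1] + edges[-length(edges)]) / 2,
                    G = G, count = counts, masked = !occ)
  if (!is.null(temperature))
    out$G_kJ_mol <- out$G * .R_gas * temperature / 1000
  class(out) <- c("fe_profile", "data.frame")
  out
}

#' Membrane voltage from an applied electric field
#'
#' \eqn{V = E L_z}: the voltage generated across a periodic simulation box
#' of length Lz by a uniform field E.
#'
#' @param E electric field, V/nm.
#' @param Lz box length along z, nm.
#' @return voltage in mV.
#' @export
voltage_from_field <- function(E, Lz) {
  stop_if_not_scalar_pos(Lz, "Lz")
  E * Lz * 1000
}

#' Binned mean response with bootstrap confidence intervals
#'
#' Per-bin mean of `y` over `x`, with 95% percentile-bootstrap confidence
#' intervals. When `replica` ids are supplied whole replicas are resampled
#' (respecting within-replica correlation); otherwise points are resampled.
#'
#' @param x,y equal-length numeric vectors.
#' @param bin_edges bin boundaries for `x` (half-open, last bin closed).
#' @param n_bootstrap bootstrap resamples (>= 100).
#' @param seed RNG seed.
#' @param replica optional replica id per point.
#' @param conf confidence level.
#' @return data.frame: `bin_lo`, `bin_hi`, `mean`, `ci_lo`, `ci_hi`, `n`,
#'   `degenerate` (single contributing point or replica); empty bins have
#'   `n = 0` and NA statistics.
#' @export
binned_response <- function(x, y, bin_edges, n_bootstrap = 1000, seed,
                            replica = NULL, conf = 0.95) {
  stopifnot(length(x) == length(y))
  if (n_bootstrap < 100) stop("n_bootstrap must be >= 100", call. = FALSE)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  nb <- length(bin_edges) - 1L
  idx <- findInterval(x, bin_edges, rightmost.closed = TRUE)
  alpha <- (1 - conf) / 2
  with_seed(seed, {
    rows <- lapply(seq_len(nb), function(b) {
      sel <- which(idx == b)
      if (!length(sel))
        return(data.frame(bin_lo = bin_edges[b], bin_hi = bin_edges[b + 1L],
                          mean = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                          n = 0L, degenerate = NA))
      yy <- y[sel]
      if (is.null(replica)) {
        units <- as.list(yy)
      } else {
        units <- split(yy, replica[sel])
      }
      m <- mean(yy)
      if (length(units) < 2L) {
        return(data.frame(bin_lo = bin_edges[b], bin_hi = bin_edges[b + 1L],
                          mean = m, ci_lo = m, ci_hi = m,
                          n = length(sel), degenerate = TRUE))
      }
      boots <- vapply(seq_len(n_bootstrap), function(i) {
        pick <- sample.int(length(units), replace = TRUE)
        mean(unlist(units[pick]))
      }, numeric(1L))
      ci <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE)
      data.frame(bin_lo = bin_edges[b], bin_hi = bin_edges[b + 1L],
                 mean = m, ci_lo = ci[1L], ci_hi = ci[2L],
                 n = length(sel), degenerate = FALSE)
    })
    do.call(rbind, rows)
  })
}
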