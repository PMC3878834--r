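#' Lattice sites whose centres lie inside the seeding disc
#'
#' Site membership is boundary-inclusive: a site belongs to the disc iff its
#' centre lies within `radius_um` of the lattice centre.
#'
#' @param radius_um Disc radius, micrometres.
#' @param delta Lattice spacing, micrometres.
#' @param lattice_dim Lattice sites per side.
#' @return Integer matrix with columns `x`, `y` of 0-based site coordinates.
#' @export
disc_sites <- function(radius_um = 3250, delta = 18, lattice_dim = 867L) {
  ctr <- (lattice_dim - 1) / 2
  r_sites <- floor(radius_um / delta) # 3.25 mm / 18 um -> 180 sites
  span <- seq.int(max(0, floor(ctr - r_sites)),
                  min(lattice_dim - 1, ceiling(ctr + r_sites)))
  g <- expand.grid(x = span, y = span)
  keep <- (g$x - ctr)^2 + (g$y - ctr)^2 <= r_sites^2
  as.matrix(g[keep, , drop = FALSE])
}

#' Initialise a colony by uniform random seeding of a disc
#'
#' Places `n_cells` agents on distinct lattice sites chosen uniformly at
#' random (without replacement) among the sites inside the seeding disc,
#' mimicking the even seeding of cells inside the assay barrier.
#'
#' @param params A [lattice_params()] object.
#' @param n_cells Number of agents to place.
#' @param radius_um Seeding disc radius, micrometres.
#' @return A `colony_state` object: list with `agents` (0-based integer
#'   coordinate matrix), `dim`, `delta`, and elapsed time `t` (hours).
#' @export
initialise_colony <- function(params, n_cells, radius_um = 3250) {
  sites <- disc_sites(radius_um, params$delta, params$lattice_dim)
  if (n_cells > nrow(sites)) {
    stop("over capacity: ", n_cells, " cells requested but only ",
         nrow(sites), " lattice sites lie inside the disc")
  }
  idx <- if (n_cells > 0) sample.int(nrow(sites), n_cells) else integer(0)
  new_colony_state(sites[idx, , drop = FALSE], params$lattice_dim,
                   params$delta, t = 0)
}

new_colony_state <- function(agents, dim, delta, t) {
  storage.mode(agents) <- "integer"
  dimnames(agents) <- list(NULL, c("x", "y"))
  structure(list(agents = agents, dim = as.integer(dim), delta = delta,
                 t = t),
            class = "colony_state")
}

#' @export
print.colony_state <- function(x, ...) {
  cat(sprintf("<colony_state> %d agents on %d x %d lattice at t = %g h\n",
              nrow(x$agents), x$dim, x$dim, x$t))
  invisible(x)
}

#' Occupancy grid of a colony state
#'
#' @param state A `colony_state`.
#' @return A `dim x dim` 0/1 integer matrix (row = y + 1, column = x + 1).
#' @export
occupancy_grid <- function(state) {
  m <- matrix(0L, state$dim, state$dim)
  m[cbind(state$agents[, "y"] + 1L, state$agents[, "x"] + 1L)] <- 1L
  m
}

#' Advance a colony by time steps of the exclusion process
#'
#' Runs `n_steps` random-sequential-update steps (each a motility sweep then
#' a proliferation sweep) and returns snapshots at the requested step
#' indices. Randomness comes from R's global generator, so `set.seed()`
#' makes runs reproducible.
#'
#' @param state A `colony_state`.
#' @param params A [lattice_params()] object.
#' @param n_steps Number of steps to run.
#' @param record_steps Sorted integer step indices (0 = initial state) at
#'   which to record snapshots; defaults to the final step only.
#' @param periodic Wrap the lattice boundary instead of treating off-lattice
#'   sites as occupied. Used for spatially uniform growth experiments.
#' @return List of `colony_state` snapshots, one per recorded step.
#' @export
step_colony <- function(state, params, n_steps = 1L,
                        record_steps = n_steps, periodic = FALSE) {
  record_steps <- as.integer(record_steps)
  stopifnot(!is.unsorted(record_steps), all(record_steps >= 0),
            all(record_steps <= n_steps))
  snaps <- simulate_core(state$dim, state$agents, params$p_m, params$q,
                         params$p_p, as.integer(n_steps), record_steps,
                         periodic)
  lapply(seq_along(snaps), function(i) {
    new_colony_state(snaps[[i]], state$dim, state$delta,
                     t = state$t + record_steps[i] * params$tau)
  })
}

#' Simulate a colony and record snapshots at chosen times
#'
#' @param params A [lattice_params()] object; the run lasts
#'   `params$duration` hours (`params$b` steps).
#' @param init Initial `colony_state`, e.g. from [initialise_colony()].
#' @param record_times Times (hours) at which to record snapshots; each must
#'   be a multiple of the step duration `params$tau` within the run.
#' @param periodic Wrap the lattice boundary.
#' @return Named list of `colony_state` snapshots, names like `"t24"`.
#' @export
simulate_colony <- function(params, init, record_times = params$duration,
                            periodic = FALSE) {
  steps <- record_times / params$tau
  if (any(abs(steps - round(steps)) > 1e-8)) {
    stop("each record time must be a multiple of the step duration tau")
  }
  steps <- as.integer(round(steps))
  if (any(steps < 0) || any(steps > params$b)) {
    stop("record times must lie within [0, duration]")
  }
  ord <- order(steps)
  snaps <- step_colony(init, params, n_steps = params$b,
                       record_steps = steps[ord], periodic = periodic)
  out <- vector("list", length(snaps))
  out[ord] <- snaps
  names(out) <- paste0("t", record_times)
  out
}

#' Simulate replicate circular barrier assays
#'
#' Runs the full assay geometry (867 x 867 lattice, 18 micrometre spacing,
#' 3.25 mm seeding disc by default) for several independently seeded
#' replicates and returns the agent point patterns at the recorded times.
#'
#' @param D Cell diffusivity, square micrometres per hour.
#' @param q Adhesion strength in `[0, 1]`.
#' @param lambda Proliferation rate, per hour.
#' @param n_cells Cells seeded inside the barrier (e.g. 20000 or 30000).
#' @param replicates Number of replicate assays.
#' @param record_times Observation times, hours.
#' @param seed Base seed; replicate `r` uses `seed + r`.
#' @param radius_um Seeding disc radius, micrometres.
#' @param delta,lattice_dim,duration Lattice geometry and run length.
#' @return A tibble with columns `replicate`, `t`, `n`, and a list-column
#'   `pattern` of point-pattern tibbles (see [pattern_from_state()]).
#' @export
simulate_barrier_assay <- function(D, q, lambda, n_cells,
                                   replicates = 3, record_times = c(0, 24, 48),
                                   seed = 1, radius_um = 3250, delta = 18,
                                   lattice_dim = 867L, duration = 48) {
  params <- lattice_params(D, q, lambda, delta = delta, duration = duration,
                           lattice_dim = lattice_dim)
  rows <- purrr::map(seq_len(replicates), function(r) {
    set.seed(seed + r)
    init <- initialise_colony(params, n_cells, radius_um)
    snaps <- simulate_colony(params, init, record_times)
    tibble::tibble(
      replicate = r,
      t = record_times,
      n = vapply(snaps, function(s) nrow(s$agents), integer(1)),
      pattern = purrr::map(snaps, pattern_from_state)
    )
  })
  dplyr::bind_rows(rows)
}
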