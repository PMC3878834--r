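# Brute-force all-pairs oracle for the isolated-cell statistic: a point is
# isolated iff no other point lies within r (boundary inclusive).
brute_force_isolated_pct <- function(pattern, r = 18) {
  n <- nrow(pattern)
  if (n == 1) return(100)
  d <- as.matrix(dist(cbind(pattern$x_um, pattern$y_um)))
  diag(d) <- Inf
  100 * mean(apply(d, 1, min) > r)
}

# A point-pattern tibble from raw coordinates, micrometres.
make_pattern <- function(x, y, delta = 18) {
  p <- tibble::tibble(x_um = x, y_um = y)
  attr(p, "delta") <- delta
  p
}

# Scaled-down barrier assay used for behavioural tests: a 220-site lattice
# with a 1440 um seeding disc holding ~4000 cells at the standard seeding
# occupancy (about 20%).
small_assay_params <- function(D, q, lambda = 0, tau = NULL) {
  lattice_params(D, q, lambda, lattice_dim = 220L, tau = tau)
}

small_assay_init <- function(params, n_cells = 4000, seed = 1) {
  set.seed(seed)
  initialise_colony(params, n_cells, radius_um = 1440)
}
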