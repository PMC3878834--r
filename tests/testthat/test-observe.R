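test_that("states map to point patterns centred on the lattice origin", {
  p <- lattice_params(81, 0, 0, lattice_dim = 101L)
  ctr <- 50L
  st <- colonycal:::new_colony_state(
    cbind(x = c(ctr, ctr + 1L), y = c(ctr, ctr)), 101L, 18, 0)
  pat <- pattern_from_state(st)
  expect_equal(pat$x_um, c(0, 18))
  expect_equal(pat$y_um, c(0, 0))
  empty <- colonycal:::new_colony_state(
    matrix(integer(0), 0, 2, dimnames = list(NULL, c("x", "y"))),
    101L, 18, 0)
  expect_identical(nrow(pattern_from_state(empty)), 0L)
  # rasterising inverts the mapping
  mask <- pattern_to_mask(pat)
  expect_identical(sum(mask$mask), 2L)
})

test_that("edge detection recovers analytic disc areas", {
  disc <- generate_mask_fixture(3250, hole_fraction = 0, pixel_um = 18)
  a <- detect_leading_edge(disc)
  expect_lt(abs(a - attr(disc, "true_area")) / attr(disc, "true_area"),
            0.01)
  # hole filling restores a disc with 5% of interior pixels deleted
  holey <- generate_mask_fixture(3250, hole_fraction = 0.05, pixel_um = 18,
                                 seed = 4)
  a2 <- detect_leading_edge(holey)
  expect_lt(abs(a2 - attr(holey, "true_area")) / attr(holey, "true_area"),
            0.01)
  # a single pixel with zero closing radius is one pixel area
  one <- binary_mask(matrix(c(0, 0, 0, 0, 1, 0, 0, 0, 0), 3), 18)
  expect_equal(detect_leading_edge(one, closing_radius = 0), 324)
  expect_error(detect_leading_edge(binary_mask(matrix(0, 4, 4), 18)),
               "empty colony")
})

test_that("equivalent radius inverts the circle area", {
  expect_equal(equivalent_radius(pi), 1)
  expect_equal(equivalent_radius(pi * 3250^2), 3250)
  expect_equal(equivalent_radius(0), 0)
  areas <- seq(0, 1e6, length.out = 11)
  expect_true(all(diff(equivalent_radius(areas)) > 0)) # monotone
  expect_error(equivalent_radius(-1), "non-negative")
})

test_that("transect profiles bin counts into 98 sections", {
  empty <- make_pattern(numeric(0), numeric(0))
  prof <- transect_density_profile(empty)
  expect_identical(nrow(prof), 98L)
  expect_true(all(prof$density == 0))
  # 13 cells dropped into section 50 only
  x0 <- -7840 + 49 * 160
  pat <- make_pattern(x0 + seq(5, 155, length.out = 13), rep(0, 13))
  prof <- transect_density_profile(pat)
  expect_equal(prof$density[50], 13 / 41600 * 324)
  expect_equal(sum(prof$density > 0), 1L)
  # cells outside the strip are ignored
  pat2 <- make_pattern(c(0, 0), c(0, 500))
  expect_equal(sum(transect_density_profile(pat2)$density > 0), 1L)
  # a fully occupied lattice approaches the carrying capacity; individual
  # sections carry the 18 um discretisation error of the 160 x 260 bins
  g <- expand.grid(x = seq(-7900, 7900, by = 18), y = seq(-198, 198, by = 18))
  full <- make_pattern(g$x, g$y)
  prof <- transect_density_profile(full)
  expect_lt(abs(mean(prof$density) - 1), 0.05)
  expect_true(all(abs(prof$density - 1) < 0.12))
})

test_that("half-profile averaging folds replicates about the centre", {
  flat <- transect_density_profile(make_pattern(numeric(0), numeric(0)))
  flat$density <- rep(0.5, 98)
  half <- average_half_profiles(list(flat))
  expect_identical(nrow(half), 49L)
  expect_true(all(half$density == 0.5))
  # left half zeros, right half ones -> 0.5 everywhere
  lr <- flat
  lr$density <- rep(c(0, 1), each = 49)
  expect_true(all(average_half_profiles(list(lr))$density == 0.5))
  # a symmetric profile folds onto either half
  sym <- flat
  sym$density <- c(rev(seq_len(49)), seq_len(49)) / 49
  expect_equal(average_half_profiles(list(sym))$density, seq_len(49) / 49)
  # replicates average pointwise (here 2 profiles -> 4 halves)
  expect_equal(average_half_profiles(list(lr, flat))$density, rep(0.5, 49))
})

test_that("isolation uses an inclusive 18 um contact radius", {
  expect_equal(isolated_fraction(make_pattern(0, 0)), 100)
  expect_equal(isolated_fraction(make_pattern(c(0, 10), c(0, 0))), 0)
  # diagonal lattice neighbours (18*sqrt(2) um) are isolated, von Neumann
  # neighbours (exactly 18 um) are contacts
  expect_equal(isolated_fraction(make_pattern(c(0, 18), c(0, 18))), 100)
  expect_equal(isolated_fraction(make_pattern(c(0, 18), c(0, 0))), 0)
  expect_error(isolated_fraction(make_pattern(numeric(0), numeric(0))),
               "empty")
})

test_that("isolation agrees with the all-pairs brute force oracle", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(2:200, 1)
    pat <- make_pattern(runif(n, -500, 500), runif(n, -500, 500))
    expect_equal(isolated_fraction(pat), brute_force_isolated_pct(pat))
  }
})

test_that("on-lattice isolation is equivalent to having no neighbours", {
  p <- small_assay_params(243, 0.5)
  st <- small_assay_init(p, 1500, seed = 11)
  s <- simulate_colony(p, st, record_times = 24)[[1]]
  occ <- occupancy_grid(s)
  padded <- matrix(0L, s$dim + 2, s$dim + 2)
  padded[2:(s$dim + 1), 2:(s$dim + 1)] <- occ
  a <- vapply(seq_len(nrow(s$agents)), function(i) {
    x <- s$agents[i, "x"] + 2L
    y <- s$agents[i, "y"] + 2L
    padded[y, x - 1L] + padded[y, x + 1L] + padded[y - 1L, x] +
      padded[y + 1L, x]
  }, integer(1))
  expect_equal(isolated_fraction(pattern_from_state(s)), 100 * mean(a == 0))
})

test_that("clustering regions tile the colony centre and summarise", {
  # one cell pair and 7 isolated of 20 in each of the six regions
  centres_x <- c(-500, 0, 500)
  centres_y <- c(-1000, 1000)
  xs <- ys <- numeric(0)
  for (cy in centres_y) {
    for (cx in centres_x) {
      # 13 cells chained 10 um apart (none isolated) ...
      chain <- cbind(-200 + (0:12) * 10, rep(-800, 13))
      # ... plus 7 cells spaced ~66 um apart (all isolated)
      iso <- cbind(seq(-200, 200, length.out = 7), rep(500, 7))
      pts <- rbind(chain, iso)
      xs <- c(xs, cx + pts[, 1])
      ys <- c(ys, cy + pts[, 2])
    }
  }
  summ <- clustering_regions(make_pattern(xs, ys))
  expect_identical(nrow(summ), 6L)
  expect_true(all(summ$total == 20))
  expect_true(all(summ$pct_isolated == 35))
  expect_equal(attr(summ, "mean_pct"), 35)
  # empty regions are excluded with a warning
  expect_warning(clustering_regions(make_pattern(0, 0)), "zero cells")
})

test_that("subregion densities convert counts by the carrying capacity", {
  empty <- subregion_density(make_pattern(numeric(0), numeric(0)))
  expect_identical(nrow(empty), 4L)
  expect_true(all(empty$density == 0))
  # 49 cells in the box centred at (500, 500)
  pts <- expand.grid(x = 500 + seq(-90, 90, by = 30),
                     y = 500 + seq(-90, 90, by = 30))
  sr <- subregion_density(make_pattern(pts$x, pts$y))
  expect_equal(sr$count[sr$box == 4], 49)
  expect_equal(sr$density[sr$box == 4], 49 / 52900 * 324)
  expect_true(all(sr$count[sr$box != 4] == 0))
})

test_that("stronger adhesion lowers the 48 h isolated fraction", {
  iso <- vapply(c(0, 0.3, 0.6, 0.9), function(q) {
    p <- small_assay_params(243, q)
    vals <- vapply(1:20, function(r) {
      set.seed(700 + r)
      st <- initialise_colony(p, 4000, 1440)
      s <- simulate_colony(p, st, record_times = 48)[[1]]
      pat <- pattern_from_state(s)
      core <- pat[abs(pat$x_um) < 500 & abs(pat$y_um) < 500, ]
      isolated_fraction(core)
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(iso) < 0))
})
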