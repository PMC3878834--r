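#' Convert a colony state to a point pattern in micrometres
#'
#' Each agent becomes one point at its site centre, with the origin at the
#' lattice centre, so an agent one site to the right of centre maps to
#' `(delta, 0)`.
#'
#' @param state A `colony_state`.
#' @return A tibble with columns `x_um`, `y_um` and attributes `delta`,
#'   `lattice_dim`, `t`.
#' @export
pattern_from_state <- function(state) {
  ctr <- (state$dim - 1) / 2
  out <- tibble::tibble(
    x_um = (state$agents[, "x"] - ctr) * state$delta,
    y_um = (state$agents[, "y"] - ctr) * state$delta
  )
  attr(out, "delta") <- state$delta
  attr(out, "lattice_dim") <- state$dim
  attr(out, "t") <- state$t
  out
}

pattern_delta <- function(pattern, delta = NULL) {
  delta %||% attr(pattern, "delta") %||% 18
}

#' Rasterise a point pattern to a binary mask
#'
#' @param pattern A point-pattern tibble with `x_um`, `y_um`.
#' @param pixel_um Pixel size, micrometres (defaults to the pattern's
#'   lattice spacing).
#' @param dim Mask side length in pixels (defaults to the pattern's lattice
#'   dimension).
#' @return A `binary_mask` object: list with a 0/1 `mask` matrix and
#'   `pixel_um`.
#' @export
pattern_to_mask <- function(pattern, pixel_um = NULL, dim = NULL) {
  pixel_um <- pixel_um %||% pattern_delta(pattern)
  dim <- dim %||% attr(pattern, "lattice_dim") %||%
    (2L * as.integer(ceiling(max(abs(c(pattern$x_um, pattern$y_um, 0))) /
                               pixel_um)) + 1L)
  ctr <- (dim - 1) / 2
  px <- as.integer(round(pattern$x_um / pixel_um + ctr)) + 1L
  py <- as.integer(round(pattern$y_um / pixel_um + ctr)) + 1L
  keep <- px >= 1 & px <= dim & py >= 1 & py <= dim
  m <- matrix(0L, dim, dim)
  m[cbind(py[keep], px[keep])] <- 1L
  binary_mask(m, pixel_um)
}

#' Construct a binary mask object
#'
#' @param mask 0/1 matrix (rows = y, columns = x).
#' @param pixel_um Pixel size, micrometres; must be positive.
#' @return A `binary_mask` object.
#' @export
binary_mask <- function(mask, pixel_um) {
  stopifnot(is.matrix(mask), pixel_um > 0)
  structure(list(mask = mask != 0, pixel_um = pixel_um),
            class = "binary_mask")
}

#' Area enclosed by the detected leading edge of a colony mask
#'
#' Applies the standard edge-detection recipe used for both pseudo-
#' experimental and simulated colonies: morphological closing with a disc
#' structuring element, hole filling, and selection of the largest connected
#' component. The enclosed area is the component's pixel count times the
#' pixel area.
#'
#' @param mask A `binary_mask`.
#' @param closing_radius Disc radius of the closing element, micrometres
#'   (default three lattice spacings).
#' @return Enclosed area, square micrometres.
#' @export
detect_leading_edge <- function(mask, closing_radius = 54) {
  stopifnot(inherits(mask, "binary_mask"))
  m <- mask$mask
  if (!any(m)) stop("empty colony: the mask contains no foreground pixels")
  img <- EBImage::Image(t(m) * 1) # EBImage is column-major x,y
  r_px <- as.integer(round(closing_radius / mask$pixel_um))
  if (r_px > 0) {
    brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
    img <- EBImage::closing(img, brush)
  }
  img <- EBImage::fillHull(img)
  lab <- EBImage::bwlabel(img)
  counts <- tabulate(as.integer(EBImage::imageData(lab)))
  max(counts) * mask$pixel_um^2
}

#' Equivalent radius of an enclosed area
#'
#' The radius of the circle with the same area, `R = sqrt(A / pi)`.
#'
#' @param area Enclosed area, square micrometres (non-negative).
#' @return Radius in micrometres.
#' @export
equivalent_radius <- function(area) {
  if (any(area < 0)) stop("`area` must be non-negative")
  sqrt(area / pi)
}

#' Leading-edge area and equivalent radius of a point pattern
#'
#' Convenience wrapper: rasterise, detect the leading edge, and convert the
#' enclosed area to an equivalent radius.
#'
#' @inheritParams pattern_to_mask
#' @inheritParams detect_leading_edge
#' @return One-row tibble with `area` (square micrometres) and `radius`
#'   (micrometres).
#' @export
measure_radius <- function(pattern, pixel_um = NULL, dim = NULL,
                           closing_radius = 54) {
  area <- detect_leading_edge(pattern_to_mask(pattern, pixel_um, dim),
                              closing_radius)
  tibble::tibble(area = area, radius = equivalent_radius(area))
}

#' Cell density profile along a transect through the colony centre
#'
#' A strip through the colony centre is divided into `n_sections` sections
#' along the transect axis (by default 98 sections of length 160 and width
#' 260 micrometres). Each section's cell count is converted to a
#' non-dimensional density by dividing by the section area and the carrying
#' capacity `K = 1 / delta^2`.
#'
#' @param pattern Point-pattern tibble with `x_um`, `y_um`.
#' @param delta Lattice spacing used for the carrying capacity, micrometres.
#' @param orientation `"horizontal"` (bins along x) or `"vertical"`.
#' @param n_sections Number of sections.
#' @param section_length Section length along the transect axis,
#'   micrometres.
#' @param section_width Strip width, micrometres.
#' @return Tibble with `section` (1-based from the negative axis end),
#'   `r_um` (section-centre coordinate) and `density`.
#' @export
transect_density_profile <- function(pattern, delta = NULL,
                                     orientation = c("horizontal",
                                                     "vertical"),
                                     n_sections = 98L,
                                     section_length = 160,
                                     section_width = 260) {
  orientation <- match.arg(orientation)
  delta <- pattern_delta(pattern, delta)
  along <- if (orientation == "horizontal") pattern$x_um else pattern$y_um
  across <- if (orientation == "horizontal") pattern$y_um else pattern$x_um
  half <- n_sections * section_length / 2
  in_strip <- abs(across) <= section_width / 2
  idx <- floor((along[in_strip] + half) / section_length) + 1
  idx <- idx[idx >= 1 & idx <= n_sections]
  counts <- tabulate(idx, nbins = n_sections)
  tibble::tibble(
    section = seq_len(n_sections),
    r_um = -half + (seq_len(n_sections) - 0.5) * section_length,
    density = counts / (section_length * section_width) * delta^2
  )
}

#' Average replicate density profiles into one mean half-profile
#'
#' Each full profile is split at its centre into two half-profiles running
#' from the colony centre (`r = 0`) to the leading edge (the left half is
#' reversed), and all halves from all replicates are averaged pointwise, so
#' three replicate transects contribute six half-profiles.
#'
#' @param profiles Either a list of profile tibbles from
#'   [transect_density_profile()] or a single tibble with a `replicate`
#'   column alongside `section` and `density`.
#' @return Tibble with `section` (1 = colony centre), `r_um`, and the mean
#'   `density`.
#' @export
average_half_profiles <- function(profiles) {
  if (is.data.frame(profiles)) {
    profiles <- split(profiles, profiles$replicate)
  }
  stopifnot(length(profiles) >= 1)
  halves <- purrr::map(profiles, function(p) {
    p <- p[order(p$section), ]
    n <- nrow(p)
    stopifnot(n %% 2 == 0)
    h <- n / 2
    cbind(rev(p$density[seq_len(h)]), p$density[(h + 1):n])
  })
  h <- nrow(halves[[1]])
  mean_density <- rowMeans(do.call(cbind, halves))
  sec_len <- if (h > 0) {
    p1 <- profiles[[1]]
    diff(sort(p1$r_um))[1]
  } else 0
  tibble::tibble(section = seq_len(h),
                 r_um = (seq_len(h) - 0.5) * sec_len,
                 density = mean_density)
}

#' Percentage of isolated cells in a point pattern
#'
#' A cell is isolated iff no other cell centroid lies within the exclusion
#' radius (boundary inclusive, so lattice nearest neighbours at exactly one
#' spacing are contacts while diagonal neighbours are not).
#'
#' @param pattern Point-pattern tibble with `x_um`, `y_um`; must contain at
#'   least one point.
#' @param exclusion_radius Contact radius, micrometres.
#' @return Percentage of isolated cells, in `[0, 100]`.
#' @export
isolated_fraction <- function(pattern, exclusion_radius = 18) {
  if (nrow(pattern) == 0) {
    stop("the isolated fraction is undefined for an empty pattern")
  }
  flags <- isolated_flags_core(pattern$x_um, pattern$y_um, exclusion_radius)
  100 * mean(flags)
}

#' Clustering summary over six central regions
#'
#' Tiles a 3 (across) by 2 (down) grid of `region_w` by `region_h`
#' rectangles symmetrically about the colony centre and reports the
#' isolated-cell percentage in each, plus the across-region mean and
#' standard deviation. Regions containing no cells are dropped from the
#' summary with a warning.
#'
#' @inheritParams isolated_fraction
#' @param region_w,region_h Region width and height, micrometres.
#' @return Tibble with one row per region: `region`, `total`, `isolated`,
#'   `pct_isolated`; attributes `mean_pct` and `sd_pct` carry the summary.
#' @export
clustering_regions <- function(pattern, exclusion_radius = 18,
                               region_w = 500, region_h = 2000) {
  xb <- c(-1.5, -0.5, 0.5, 1.5) * region_w
  yb <- c(-1, 0, 1) * region_h
  rows <- list()
  k <- 0
  for (iy in 1:2) {
    for (ix in 1:3) {
      k <- k + 1
      sel <- pattern$x_um > xb[ix] & pattern$x_um <= xb[ix + 1] &
        pattern$y_um > yb[iy] & pattern$y_um <= yb[iy + 1]
      sub <- pattern[sel, , drop = FALSE]
      pct <- if (nrow(sub) > 0) {
        isolated_fraction(sub, exclusion_radius)
      } else {
        NA_real_
      }
      rows[[k]] <- tibble::tibble(
        region = k, total = nrow(sub),
        isolated = if (nrow(sub) > 0) round(pct * nrow(sub) / 100) else 0L,
        pct_isolated = pct
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (anyNA(out$pct_isolated)) {
    warning("regions with zero cells were excluded from the clustering mean")
  }
  attr(out, "mean_pct") <- mean(out$pct_isolated, na.rm = TRUE)
  attr(out, "sd_pct") <- sd(out$pct_isolated, na.rm = TRUE)
  out
}

#' Non-dimensional cell density in four central subregions
#'
#' Counts cells in four square boxes (230 micrometres a side by default)
#' whose centres sit at `(+-offset, +-offset)` from the colony centre, and
#' converts each count to a non-dimensional density via the carrying
#' capacity `K = 1 / delta^2`.
#'
#' @inheritParams transect_density_profile
#' @param box_size Box side length, micrometres.
#' @param offset Distance of each box centre from the colony centre along
#'   both axes, micrometres.
#' @return Tibble with `box`, `count`, `density`; attributes `mean_density`
#'   and `sd_density`.
#' @export
subregion_density <- function(pattern, delta = NULL, box_size = 230,
                              offset = 500) {
  delta <- pattern_delta(pattern, delta)
  centres <- expand.grid(cx = c(-offset, offset), cy = c(-offset, offset))
  rows <- purrr::map(seq_len(nrow(centres)), function(i) {
    cx <- centres$cx[i]
    cy <- centres$cy[i]
    sel <- abs(pattern$x_um - cx) <= box_size / 2 &
      abs(pattern$y_um - cy) <= box_size / 2
    n <- sum(sel)
    tibble::tibble(box = i, count = n,
                   density = n / box_size^2 * delta^2)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "mean_density") <- mean(out$density)
  attr(out, "sd_density") <- sd(out$density)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
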