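#' Mapped point communities
#'
#' A point community is a tibble of mapped individuals — columns `x`, `y`
#' (planar coordinates) and `species` — carrying its rectangular study region
#' as the `region` attribute, `c(xmin, xmax, ymin, ymax)`. This mirrors
#' stem-mapped forest-plot censuses, where every individual's location and
#' species are recorded.
#'
#' @param x Data frame with columns `x`, `y`, `species`.
#' @param region Numeric length-4 vector `c(xmin, xmax, ymin, ymax)`;
#'   defaults to the points' bounding box.
#' @return A tibble of class `point_community` with a `region` attribute.
#' @export
as_point_community <- function(x, region = NULL) {
  x <- as_tibble(x)
  if (!all(c("x", "y", "species") %in% names(x))) {
    abort("point community needs columns `x`, `y`, `species`")
  }
  if (nrow(x) < 1L) abort("point community must contain at least one individual")
  if (is.null(region)) region <- c(range(x$x), range(x$y))
  region <- as.numeric(region)
  if (length(region) != 4L || region[1] >= region[2] || region[3] >= region[4]) {
    abort("region must be c(xmin, xmax, ymin, ymax) with positive extent")
  }
  inside <- x$x >= region[1] & x$x <= region[2] & x$y >= region[3] & x$y <= region[4]
  if (!all(inside)) abort("all individuals must lie inside the region")
  x$species <- as.character(x$species)
  structure(x, region = region, class = c("point_community", class(x)))
}

#' Region of a point community
#' @param x A `point_community`.
#' @return `c(xmin, xmax, ymin, ymax)`.
#' @export
community_region <- function(x) attr(x, "region")

#' Read a mapped community from a delimited file
#'
#' @param path CSV/TSV file with columns `x`, `y`, `species`.
#' @inheritParams as_point_community
#' @return A `point_community`.
#' @export
load_point_community <- function(path, region = NULL) {
  as_point_community(
    readr::read_delim(path, delim = guess_delim(path), show_col_types = FALSE),
    region = region)
}

#' Census abundances of a point community
#'
#' Relative abundances computed from every mapped individual — the ground
#' truth a transect-based estimate is compared against.
#'
#' @param community A `point_community`.
#' @return An abundance tibble (columns `species`, `p`).
#' @export
census_abundances <- function(community) {
  tab <- table(community$species)
  as_abundances(tibble(species = names(tab), p = as.numeric(tab)))
}

# largest-remainder allocation of `total` individuals to probabilities p
allocate_counts <- function(p, total) {
  raw <- p * total
  n <- floor(raw)
  short <- total - sum(n)
  if (short > 0) {
    extra <- order(raw - n, decreasing = TRUE)[seq_len(short)]
    n[extra] <- n[extra] + 1
  }
  as.integer(n)
}

#' Completely spatially random (CSR) community
#'
#' Independent control condition: species labels are drawn iid from the
#' abundance vector and positions are uniform over the region, so nearby
#' individuals carry no information about each other's species. Transect
#' sampling through a CSR community is effectively independent sampling and
#' the estimated non-independence parameter should be near zero.
#'
#' @param abundances Abundance table (columns `species`, `p`).
#' @param total Number of individuals to place.
#' @param region `c(xmin, xmax, ymin, ymax)`.
#' @param seed Optional integer seed.
#' @return A `point_community` with exactly `total` individuals.
#' @export
csr_community <- function(abundances, total, region, seed = NULL) {
  a <- as_abundances(abundances)
  if (total < 1) abort("need at least one individual")
  if (!is.null(seed)) set.seed(seed)
  lab <- sample(a$species, total, replace = TRUE, prob = a$p)
  as_point_community(
    tibble(x = runif(total, region[1], region[2]),
           y = runif(total, region[3], region[4]),
           species = lab),
    region = region)
}

#' Clustered (Thomas-type) community
#'
#' Emulates spatially aggregated species distributions: for each species,
#' `parents` cluster centres are placed uniformly in the region and the
#' species' individuals are scattered around uniformly chosen centres with
#' isotropic Gaussian offsets of standard deviation `cluster_sd`. Offspring
#' falling outside the region are resampled (not clipped), keeping density
#' uniform near edges. Per-species totals follow the abundance vector via
#' largest-remainder rounding, so the community size is exact. Small
#' `cluster_sd` and few parents give strong conspecific aggregation; as
#' `cluster_sd` grows the pattern approaches complete spatial randomness.
#'
#' @param abundances Abundance table (columns `species`, `p`).
#' @param total Number of individuals to place.
#' @param region `c(xmin, xmax, ymin, ymax)`.
#' @param parents Cluster centres per species (>= 1).
#' @param cluster_sd Gaussian dispersal scale, in region length units (> 0).
#' @param seed Optional integer seed.
#' @return A `point_community` with exactly `total` individuals.
#' @export
thomas_community <- function(abundances, total, region, parents = 1,
                             cluster_sd = 5, seed = NULL) {
  a <- as_abundances(abundances)
  if (total < 1) abort("need at least one individual")
  if (parents < 1) abort("need at least one parent per species")
  if (cluster_sd <= 0) abort("cluster_sd must be positive")
  if (!is.null(seed)) set.seed(seed)
  n_per <- allocate_counts(a$p, total)
  pieces <- lapply(seq_len(nrow(a)), function(i) {
    n <- n_per[i]
    if (n == 0L) return(NULL)
    px <- runif(parents, region[1], region[2])
    py <- runif(parents, region[3], region[4])
    parent <- sample.int(parents, n, replace = TRUE)
    x <- px[parent] + rnorm(n, sd = cluster_sd)
    y <- py[parent] + rnorm(n, sd = cluster_sd)
    bad <- which(x < region[1] | x > region[2] | y < region[3] | y > region[4])
    while (length(bad) > 0L) {
      x[bad] <- px[parent[bad]] + rnorm(length(bad), sd = cluster_sd)
      y[bad] <- py[parent[bad]] + rnorm(length(bad), sd = cluster_sd)
      bad <- bad[x[bad] < region[1] | x[bad] > region[2] |
                   y[bad] < region[3] | y[bad] > region[4]]
    }
    tibble(x = x, y = y, species = a$species[i])
  })
  as_point_community(dplyr::bind_rows(pieces), region = region)
}

# length along a ray from `start` at `angle` until it leaves the rectangle
ray_exit_length <- function(start, angle, region) {
  dx <- cos(angle); dy <- sin(angle)
  tx <- if (abs(dx) < 1e-12) Inf else
    if (dx > 0) (region[2] - start[1]) / dx else (region[1] - start[1]) / dx
  ty <- if (abs(dy) < 1e-12) Inf else
    if (dy > 0) (region[4] - start[2]) / dy else (region[3] - start[2]) / dy
  max(min(tx, ty), 0)
}

# uniform angle whose ray has positive length inside the region
inward_angle <- function(start, region, max_tries = 1000L) {
  for (k in seq_len(max_tries)) {
    ang <- runif(1, 0, 2 * pi)
    if (ray_exit_length(start, ang, region) > 1e-9) return(ang)
  }
  abort("could not find an inward direction (degenerate region?)")
}

#' Place a random line transect on a region
#'
#' The transect's reference (start) point is placed uniformly on the region's
#' boundary (the field convention — surveys usually begin at the edge of the
#' study area) or uniformly inside it; the direction is uniform over angles
#' pointing into the region, and the centreline runs until it exits the
#' region.
#'
#' @param region `c(xmin, xmax, ymin, ymax)`.
#' @param width Band width, in region length units (> 0).
#' @param edge_start Start on the boundary (default) or anywhere inside.
#' @param seed Optional integer seed.
#' @return A list of class `transect` with `start`, `angle`, `width`,
#'   `length`.
#' @export
place_transect <- function(region, width = 1, edge_start = TRUE, seed = NULL) {
  if (region[1] >= region[2] || region[3] >= region[4]) abort("degenerate region")
  if (width <= 0) abort("width must be positive")
  if (!is.null(seed)) set.seed(seed)
  w <- region[2] - region[1]; h <- region[4] - region[3]
  if (edge_start) {
    u <- runif(1, 0, 2 * (w + h))  # position along the perimeter
    start <- if (u < w) c(region[1] + u, region[3])
      else if (u < w + h) c(region[2], region[3] + (u - w))
      else if (u < 2 * w + h) c(region[2] - (u - w - h), region[4])
      else c(region[1], region[4] - (u - 2 * w - h))
  } else {
    start <- c(runif(1, region[1], region[2]), runif(1, region[3], region[4]))
  }
  ang <- inward_angle(start, region)
  structure(list(start = start, angle = ang, width = width,
                 length = ray_exit_length(start, ang, region)),
            class = "transect")
}

#' Individuals inside a transect band
#'
#' Returns the community records whose perpendicular distance to the
#' transect's centreline is at most half the band width and whose projection
#' onto the centreline falls within the transect's length. Both boundaries
#' are closed (points exactly on the band edge are surveyed).
#'
#' @param community A `point_community`.
#' @param transect A `transect` from [place_transect()].
#' @return The subset of community rows inside the band.
#' @export
individuals_in_band <- function(community, transect) {
  u <- c(cos(transect$angle), sin(transect$angle))
  rx <- community$x - transect$start[1]
  ry <- community$y - transect$start[2]
  along <- rx * u[1] + ry * u[2]
  perp <- abs(rx * u[2] - ry * u[1])
  community[along >= 0 & along <= transect$length & perp <= transect$width / 2, ]
}

#' Order surveyed individuals by distance from a reference point
#'
#' Sorts records by increasing Euclidean distance from the reference point —
#' the sequence a surveyor walking the transect and always measuring the
#' nearest unmeasured individual would record. Exact distance ties are broken
#' uniformly at random.
#'
#' @param records Data frame with columns `x`, `y` (a band subset).
#' @param reference Numeric `c(x, y)` reference point.
#' @param seed Optional integer seed for the tie-break.
#' @return `records` reordered by distance.
#' @export
order_by_distance <- function(records, reference, seed = NULL) {
  if (nrow(records) < 1L) abort("no individuals to order")
  if (!is.null(seed)) set.seed(seed)
  dist <- sqrt((records$x - reference[1])^2 + (records$y - reference[2])^2)
  records[order(dist, runif(nrow(records))), ]
}

#' Sequential line-transect sample from a mapped community
#'
#' Implements the full survey protocol: place a transect starting on the
#' region's edge, survey every individual in its band in order of distance
#' from the start (random tie-break, no individual surveyed twice), and —
#' if the target sample size is not yet reached — chain a new transect from
#' the previous transect's endpoint in a fresh inward direction, excluding
#' previously surveyed individuals. The recorded sequence is truncated at
#' exactly `m` individuals.
#'
#' @param community A `point_community` with at least `m` individuals.
#' @param m Required sample size.
#' @param width Band width in region length units.
#' @param seed Optional integer seed (the whole replicate is reproducible).
#' @param max_empty Abort after this many consecutive transects that add no
#'   new individuals (guards against degenerate geometries).
#' @return Character vector of `m` species labels in survey order.
#' @export
#' @examples
#' com <- csr_community(make_abundances(5, "uniform"), 2000,
#'                      region = c(0, 100, 0, 100), seed = 1)
#' seq <- transect_sample(com, m = 50, width = 2, seed = 2)
#' estimate_pi(seq)
transect_sample <- function(community, m, width = 1, seed = NULL,
                            max_empty = 100L) {
  stopifnot(inherits(community, "point_community"))
  if (m < 1) abort("`m` must be at least 1")
  if (m > nrow(community)) abort("`m` exceeds the community's census size")
  if (!is.null(seed)) set.seed(seed)
  region <- community_region(community)
  remaining <- community
  labels <- character(0)
  tr <- place_transect(region, width = width, edge_start = TRUE)
  empties <- 0L
  while (length(labels) < m) {
    band <- individuals_in_band(remaining, tr)
    if (nrow(band) > 0L) {
      ordered <- order_by_distance(band, tr$start)
      labels <- c(labels, ordered$species)
      remaining <- dplyr::anti_join(remaining, ordered[, c("x", "y", "species")],
                                    by = c("x", "y", "species"))
      empties <- 0L
    } else {
      empties <- empties + 1L
      if (empties > max_empty) {
        abort("too many consecutive empty transects; increase width or density")
      }
    }
    if (length(labels) >= m) break
    endpoint <- tr$start + tr$length * c(cos(tr$angle), sin(tr$angle))
    # clamp numerical drift so the chained start stays in the region
    endpoint <- pmin(pmax(endpoint, region[c(1, 3)]), region[c(2, 4)])
    ang <- inward_angle(endpoint, region)
    tr <- structure(list(start = endpoint, angle = ang, width = width,
                         length = ray_exit_length(endpoint, ang, region)),
                    class = "transect")
  }
  labels[seq_len(m)]
}
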