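#' Parent-vessel specification
#'
#' Describes the straight parent-artery segment carrying the main flow. The
#' cross-section convention throughout the package is a 2D channel: `diameter`
#' is the channel height and `length` the streamwise extent.
#'
#' @param diameter Vessel diameter (mm). The sizing study uses 3.0, 3.5, 4.0
#'   and 4.5 mm.
#' @param length Vessel length (mm). Defaults to 10 x diameter, and is never
#'   allowed below 30 mm so that entrance and exit effects stay away from the
#'   aneurysm neck.
#' @return An object of class `parent_vessel`.
#' @export
parent_vessel <- function(diameter, length = NULL) {
  stopifnot(is.numeric(diameter), length(diameter) == 1L, is.finite(diameter))
  if (diameter <= 0) stop("parent vessel diameter must be positive", call. = FALSE)
  if (is.null(length)) length <- max(10 * diameter, 30)
  if (length < 30) stop("parent vessel length must be at least 30 mm", call. = FALSE)
  structure(list(diameter = diameter, length = length), class = "parent_vessel")
}

#' Analytic area of the aneurysm sac cross-section
#'
#' The sac is a circle of radius `sac_radius` whose chord of length
#' `neck_width` lies on the parent-channel wall; the sac region is the part of
#' the disk on the far side of the wall, i.e. the major circular segment.
#'
#' @param sac_radius Sac radius (mm).
#' @param neck_width Neck chord length (mm).
#' @return Area in mm^2.
#' @export
sac_segment_area <- function(sac_radius, neck_width) {
  theta <- 2 * asin(neck_width / (2 * sac_radius))  # central angle of the chord
  minor <- sac_radius^2 * (theta - sin(theta)) / 2
  pi * sac_radius^2 - minor
}

#' Build an idealized sidewall saccular aneurysm model
#'
#' The sac is a circle of the given radius attached to the upper wall of a
#' straight 2D channel; the chord where the circle meets the wall line is the
#' aneurysm neck. Neck width is held constant when the parent diameter changes,
#' so stented scenarios at different vessel sizes share an identical neck.
#'
#' @param parent_diameter Parent-artery diameter (mm).
#' @param sac_radius Sac radius (mm), default 5.0 (a large aneurysm).
#' @param neck_width Neck chord length (mm), default 4.0 (wide-necked).
#' @param neck_center_x Streamwise position of the neck center (mm); defaults
#'   to mid-vessel.
#' @param vessel_length Parent-vessel length (mm); defaults per
#'   [parent_vessel()].
#' @return An object of class `aneurysm_spec` with fields `parent`,
#'   `sac_radius`, `neck_width`, `neck_center_x` and the derived
#'   `sac_center_height`, the height of the sac center above the wall,
#'   `sqrt(sac_radius^2 - (neck_width/2)^2)`.
#' @examples
#' spec <- build_sidewall_model(4.0, 5.0, 4.0)
#' spec$sac_center_height  # sqrt(25 - 4) = 4.583
#' @export
build_sidewall_model <- function(parent_diameter, sac_radius = 5.0, neck_width = 4.0,
                                 neck_center_x = NULL, vessel_length = NULL) {
  stopifnot(is.numeric(parent_diameter), is.numeric(sac_radius), is.numeric(neck_width))
  if (parent_diameter <= 0 || sac_radius <= 0 || neck_width <= 0)
    stop("all geometric arguments must be positive", call. = FALSE)
  if (neck_width >= 2 * sac_radius)
    stop(sprintf("infeasible neck: neck_width (%.3g mm) must be < 2*sac_radius (%.3g mm)",
                 neck_width, 2 * sac_radius), call. = FALSE)
  hc <- sqrt(sac_radius^2 - (neck_width / 2)^2)
  # the sac dips below the wall line by (sac_radius - hc); it must not reach
  # the opposite channel wall
  if (sac_radius - hc >= parent_diameter)
    stop(sprintf("sac intersects the opposite vessel wall: sac dips %.3g mm below the neck line but the vessel is only %.3g mm deep",
                 sac_radius - hc, parent_diameter), call. = FALSE)
  parent <- parent_vessel(parent_diameter, vessel_length)
  if (is.null(neck_center_x)) neck_center_x <- parent$length / 2
  if (neck_center_x - neck_width / 2 <= 2 || neck_center_x + neck_width / 2 >= parent$length - 2)
    stop("neck must lie well inside the vessel (>= 2 mm from inlet/outlet)", call. = FALSE)
  structure(list(
    parent = parent,
    sac_radius = sac_radius,
    neck_width = neck_width,
    neck_center_x = neck_center_x,
    sac_center_height = hc
  ), class = "aneurysm_spec")
}

#' @export
print.aneurysm_spec <- function(x, ...) {
  cat(sprintf("Sidewall aneurysm model\n  parent vessel: %.2f mm x %.1f mm\n  sac radius: %.2f mm (center %.3f mm above wall)\n  neck width: %.2f mm at x = %.2f mm\n  sac area (analytic): %.2f mm^2\n",
              x$parent$diameter, x$parent$length, x$sac_radius, x$sac_center_height,
              x$neck_width, x$neck_center_x,
              sac_segment_area(x$sac_radius, x$neck_width)))
  invisible(x)
}

# Flood fill over the fluid mask; returns TRUE if all fluid cells are reachable
# from the seed (fluid region simply connected in the sense needed by the
# solver: one connected component).
fluid_connected <- function(fluid, seed) {
  nx <- nrow(fluid); ny <- ncol(fluid)
  visited <- matrix(FALSE, nx, ny)
  frontier <- matrix(seed, ncol = 2)
  visited[frontier] <- TRUE
  while (nrow(frontier) > 0) {
    nb <- rbind(
      cbind(frontier[, 1] + 1L, frontier[, 2]),
      cbind(frontier[, 1] - 1L, frontier[, 2]),
      cbind(frontier[, 1], frontier[, 2] + 1L),
      cbind(frontier[, 1], frontier[, 2] - 1L)
    )
    ok <- nb[, 1] >= 1L & nb[, 1] <= nx & nb[, 2] >= 1L & nb[, 2] <= ny
    nb <- nb[ok, , drop = FALSE]
    keep <- fluid[nb] & !visited[nb]
    nb <- unique(nb[keep, , drop = FALSE])
    if (nrow(nb) == 0) break
    visited[nb] <- TRUE
    frontier <- nb
  }
  all(visited[fluid])
}

# Enumerate wall faces of the sac region: faces between a sac fluid cell and a
# solid cell. side is the direction of the solid neighbour seen from the fluid
# cell (N = +y, S = -y, E = +x, W = -x).
sac_wall_faces <- function(lab) {
  nx <- nrow(lab); ny <- ncol(lab)
  solid_at <- function(di, dj) {
    m <- matrix(TRUE, nx, ny)  # out-of-range counts as solid
    ii <- seq_len(nx) + di; jj <- seq_len(ny) + dj
    iok <- ii >= 1L & ii <= nx; jok <- jj >= 1L & jj <= ny
    m[iok, jok] <- lab[ii[iok], jj[jok]] == 0L
    m
  }
  res <- list()
  sides <- list(N = c(0L, 1L), S = c(0L, -1L), E = c(1L, 0L), W = c(-1L, 0L))
  sac <- lab == 2L
  for (s in names(sides)) {
    d <- sides[[s]]
    hit <- which(sac & solid_at(d[1], d[2]), arr.ind = TRUE)
    if (nrow(hit) > 0)
      res[[s]] <- data.frame(i = hit[, 1], j = hit[, 2], side = s,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Rasterize an aneurysm model onto a uniform Cartesian grid
#'
#' Produces the labeled staggered-grid domain the flow solver operates on.
#' Cells are labeled solid (0), channel fluid (1) or sac fluid (2). The channel
#' wall is snapped to the nearest grid line and the neck center to the nearest
#' cell edge, so the neck/sac rasterization is identical for every parent
#' diameter at a fixed spacing.
#'
#' @param spec An [build_sidewall_model()] result, or `NULL` for a plain
#'   channel (see [channel_domain()]).
#' @param h Grid spacing (mm); must satisfy `h <= parent diameter / 10` and
#'   resolve the neck with at least 8 faces.
#' @param plane_offset Distance (mm) of the proximal/distal measurement planes
#'   outside the neck ends (default 1.0).
#' @return An object of class `grid_domain`. Lengths are stored in mm.
#' @export
rasterize <- function(spec, h, plane_offset = 1.0) {
  stopifnot(inherits(spec, "aneurysm_spec"), is.numeric(h), h > 0)
  D <- spec$parent$diameter
  if (h > D / 10 + 1e-12)
    stop(sprintf("grid spacing h = %.3g mm too coarse: must be <= parent diameter / 10 = %.3g mm",
                 h, D / 10), call. = FALSE)
  if (floor(spec$neck_width / h) < 8)
    stop(sprintf("grid spacing h = %.3g mm cannot resolve the %.3g mm neck with >= 8 faces",
                 h, spec$neck_width), call. = FALSE)

  n_chan <- as.integer(round(D / h))
  wall_y <- n_chan * h
  xc <- round(spec$neck_center_x / h) * h          # snap neck center to a grid line
  cyc <- wall_y + spec$sac_center_height           # sac center
  R <- spec$sac_radius
  nx <- as.integer(round(spec$parent$length / h))
  ny <- as.integer(ceiling((wall_y + spec$sac_center_height + R) / h)) + 1L

  cx <- (seq_len(nx) - 0.5) * h
  cy <- (seq_len(ny) - 0.5) * h
  lab <- matrix(0L, nx, ny)
  lab[, seq_len(n_chan)] <- 1L
  in_sac <- outer(cx, cy, function(x, y) (x - xc)^2 + (y - cyc)^2 < R^2)
  lab[in_sac & col(lab) > n_chan] <- 2L

  # neck faces: v-faces on the wall line with fluid on both sides
  j_neck <- n_chan + 1L            # v-face row index (face below cell row j_neck)
  neck_cols <- which(lab[, n_chan] == 1L & lab[, j_neck] == 2L)
  if (length(neck_cols) < 8)
    stop("rasterized neck has fewer than 8 faces; refine the grid", call. = FALSE)

  sac_cells <- which(lab == 2L)
  sac_area <- length(sac_cells) * h^2
  analytic <- sac_segment_area(R, spec$neck_width)
  theta <- 2 * asin(spec$neck_width / (2 * R))
  perim <- R * (2 * pi - theta) + spec$neck_width
  if (abs(sac_area - analytic) > 2 * h * perim)
    stop(sprintf("rasterized sac area %.3f mm^2 deviates from analytic %.3f mm^2 by more than 2*h*perimeter",
                 sac_area, analytic), call. = FALSE)

  if (!fluid_connected(lab > 0L, c(1L, 1L)))
    stop("rasterized fluid region is not simply connected", call. = FALSE)

  neck_x0 <- (min(neck_cols) - 1L) * h
  neck_x1 <- max(neck_cols) * h
  x_p <- neck_x0 - plane_offset
  x_d <- neck_x1 + plane_offset
  # snap planes to u-face columns (u-face i sits at x = (i-1)*h)
  i_p <- as.integer(round(x_p / h)) + 1L
  i_d <- as.integer(round(x_d / h)) + 1L

  structure(list(
    h = h, nx = nx, ny = ny, lab = lab,
    n_chan = n_chan, wall_y = wall_y, effective_diameter = wall_y,
    spec = spec,
    neck_cols = neck_cols, j_neck = j_neck,
    neck_x = c(neck_x0, neck_x1),
    x_p = (i_p - 1L) * h, x_d = (i_d - 1L) * h, i_p = i_p, i_d = i_d,
    sac_area = sac_area, sac_area_analytic = analytic,
    sac_walls = sac_wall_faces(lab)
  ), class = "grid_domain")
}

#' Plain-channel domain for solver validation
#'
#' A straight 2D channel without a sac, used for Poiseuille and Womersley
#' closed-form validation cases.
#'
#' @param height Channel height (mm).
#' @param length Channel length (mm).
#' @param h Grid spacing (mm); must divide the height to machine precision so
#'   that the walls fall on grid lines.
#' @return A `grid_domain` with an empty neck.
#' @export
channel_domain <- function(height, length, h) {
  n_chan <- as.integer(round(height / h))
  if (abs(n_chan * h - height) > 1e-9)
    stop("h must divide the channel height", call. = FALSE)
  nx <- as.integer(round(length / h))
  lab <- matrix(1L, nx, n_chan)
  structure(list(
    h = h, nx = nx, ny = n_chan, lab = lab,
    n_chan = n_chan, wall_y = height, effective_diameter = height,
    spec = NULL,
    neck_cols = integer(0), j_neck = n_chan + 1L,
    neck_x = c(NA_real_, NA_real_),
    x_p = NA_real_, x_d = NA_real_, i_p = NA_integer_, i_d = NA_integer_,
    sac_area = 0, sac_area_analytic = 0,
    sac_walls = NULL
  ), class = "grid_domain")
}

#' @export
print.grid_domain <- function(x, ...) {
  cat(sprintf("Grid domain: %d x %d cells at h = %.3g mm\n  channel: %d rows (%.2f mm); fluid cells: %d\n",
              x$nx, x$ny, x$h, x$n_chan, x$wall_y, sum(x$lab > 0L)))
  if (length(x$neck_cols) > 0)
    cat(sprintf("  neck: %d faces over [%.2f, %.2f] mm; sac area %.2f mm^2 (analytic %.2f)\n",
                length(x$neck_cols), x$neck_x[1], x$neck_x[2], x$sac_area, x$sac_area_analytic))
  invisible(x)
}

#' Export the label mask as a legacy-VTK structured-points file
#'
#' Writes an ASCII STRUCTURED_POINTS dataset with the cell labels (0 solid,
#' 1 channel, 2 sac) for inspection in ParaView or similar tools.
#'
#' @param domain A `grid_domain`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_domain_vtk <- function(domain, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# vtk DataFile Version 3.0",
    "fdhemo domain labels",
    "ASCII",
    "DATASET STRUCTURED_POINTS",
    sprintf("DIMENSIONS %d %d 1", domain$nx, domain$ny),
    "ORIGIN 0 0 0",
    sprintf("SPACING %g %g %g", domain$h, domain$h, domain$h),
    sprintf("POINT_DATA %d", domain$nx * domain$ny),
    "SCALARS label int 1",
    "LOOKUP_TABLE default"
  ), con)
  writeLines(paste(as.vector(domain$lab), collapse = " "), con)
  invisible(path)
}
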