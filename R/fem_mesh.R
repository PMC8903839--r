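#' Culture-well geometry
#'
#' Axisymmetric geometry of one bioreactor culture well: a cylindrical
#' hydrogel sample (default radius 4 mm, thickness 2.2 mm) sitting at the
#' bottom center of a cylindrical well filled with culture medium (default
#' ~2 ml). The well height is derived from the medium volume and well
#' radius; consistency is enforced to 5 %.
#'
#' @param sample_radius Sample radius, m (default 4e-3).
#' @param sample_thickness Sample thickness, m (default 2.2e-3).
#' @param medium_volume Culture-medium volume, m^3 (default 2e-6, i.e. 2 ml).
#' @param well_radius Well radius, m (default 8e-3).
#' @return An object of class `"well_geometry"` with derived `well_height`.
#' @export
well_geometry <- function(sample_radius = 4e-3, sample_thickness = 2.2e-3,
                          medium_volume = 2e-6, well_radius = 8e-3) {
  for (nm in c("sample_radius", "sample_thickness", "medium_volume",
               "well_radius")) {
    stop_if_not_scalar(get(nm), nm, positive = TRUE)
  }
  if (well_radius <= sample_radius) {
    stop("'well_radius' must exceed 'sample_radius'", call. = FALSE)
  }
  v_sample <- pi * sample_radius^2 * sample_thickness
  well_height <- (medium_volume + v_sample) / (pi * well_radius^2)
  if (well_height <= sample_thickness) {
    stop("medium volume too small: derived well height does not cover the sample",
         call. = FALSE)
  }
  v_med_check <- pi * well_radius^2 * well_height - v_sample
  if (abs(v_med_check - medium_volume) > 0.05 * medium_volume) {
    stop("internal geometry inconsistency (> 5% on medium volume)", call. = FALSE)
  }
  structure(list(sample_radius = sample_radius,
                 sample_thickness = sample_thickness,
                 medium_volume = medium_volume,
                 well_radius = well_radius,
                 well_height = well_height),
            class = "well_geometry")
}

#' @export
print.well_geometry <- function(x, ...) {
  cat(sprintf(paste0("Culture well: sample r = %g mm, t = %g mm; ",
                     "well r = %g mm, h = %.3g mm; medium %.3g ml\n"),
              x$sample_radius * 1e3, x$sample_thickness * 1e3,
              x$well_radius * 1e3, x$well_height * 1e3,
              x$medium_volume * 1e6))
  invisible(x)
}

#' Cyclic compression loading protocol
#'
#' Displacement-controlled cyclic compression of the sample: a static
#' pre-strain plus a cyclic amplitude at a given frequency (the reference
#' protocol is 10 % pre-strain, 10 % amplitude at 1 Hz).
#'
#' @param pre_strain Static compressive pre-strain fraction, `>= 0`.
#' @param amplitude Cyclic strain amplitude fraction, `> 0`.
#' @param frequency Loading frequency, Hz, `> 0`.
#' @param duration Stimulation duration, s (default 90 min).
#' @return An object of class `"loading_protocol"`.
#' @export
loading_protocol <- function(pre_strain = 0.10, amplitude = 0.10,
                             frequency = 1, duration = 5400) {
  stop_if_not_scalar(pre_strain, "pre_strain", nonneg = TRUE)
  stop_if_not_scalar(amplitude, "amplitude")
  stop_if_not_scalar(frequency, "frequency", positive = TRUE)
  stop_if_not_scalar(duration, "duration", positive = TRUE)
  if (pre_strain + amplitude >= 0.5) {
    stop("pre_strain + peak amplitude must stay below 0.5", call. = FALSE)
  }
  structure(list(pre_strain = pre_strain, amplitude = amplitude,
                 frequency = frequency, duration = duration),
            class = "loading_protocol")
}

#' Thermal boundary condition of the well
#'
#' Either `isothermal` (all outer well boundaries held at
#' `wall_temperature`, the realistic incubator-controlled case) or
#' `adiabatic` (no heat exchange, the idealized worst case).
#'
#' @param kind `"isothermal"` or `"adiabatic"`.
#' @param wall_temperature Wall temperature, degC (required for
#'   isothermal).
#' @return An object of class `"thermal_bc"`.
#' @export
thermal_bc <- function(kind = c("isothermal", "adiabatic"),
                       wall_temperature = NULL) {
  kind <- match.arg(kind)
  if (kind == "isothermal") {
    if (is.null(wall_temperature)) {
      stop("isothermal boundary requires 'wall_temperature'", call. = FALSE)
    }
    stop_if_not_scalar(wall_temperature, "wall_temperature")
  }
  structure(list(kind = kind, wall_temperature = wall_temperature),
            class = "thermal_bc")
}

# grid lines covering [0, a] then (a, b] with spacing ~h, both breakpoints exact
grid_lines <- function(a, b, h) {
  n1 <- max(2L, round(a / h) + 1L)
  g <- seq(0, a, length.out = n1)
  if (!is.null(b) && b > a) {
    n2 <- max(2L, round((b - a) / h) + 1L)
    g <- c(g, seq(a, b, length.out = n2)[-1])
  }
  g
}

#' Build an axisymmetric triangular mesh of the culture well
#'
#' Structured grid over the meridian rectangle `[0, R_w] x [0, H]` with
#' grid lines snapped to the sample boundary (`r = sample_radius`,
#' `z = sample_thickness`), each cell split into two triangles. Elements
#' are tagged `"sample"` or `"medium"` by centroid; boundary edges are
#' tagged `axis`, `base`, `wall`, `top`, and sample-medium `interface`
#' edges are recorded. With `include_medium = FALSE` only the sample
#' rectangle is meshed (tags `axis`, `base`, `piston` for the top face,
#' `side` for the lateral face) — the configuration used by the
#' poro-viscoelastic stage and by column benchmarks.
#'
#' @param geometry A [well_geometry()].
#' @param target_h Target element size, m, `> 0`.
#' @param include_medium Mesh the medium subdomain too? (default TRUE)
#' @return An object of class `"ct_mesh"`: list with `nodes` (n x 2 matrix
#'   of r, z), `tri` (nt x 3), `domain` (per element), `edges` (boundary
#'   and interface edge table), `geometry`, `h`.
#' @export
build_mesh <- function(geometry, target_h, include_medium = TRUE) {
  stopifnot(inherits(geometry, "well_geometry"))
  stop_if_not_scalar(target_h, "target_h", positive = TRUE)
  Rs <- geometry$sample_radius; ts <- geometry$sample_thickness
  Rw <- geometry$well_radius;   H  <- geometry$well_height

  r_lines <- grid_lines(Rs, if (include_medium) Rw else NULL, target_h)
  z_lines <- grid_lines(ts, if (include_medium) H else NULL, target_h)
  nr <- length(r_lines); nz <- length(z_lines)
  nodes <- cbind(r = rep(r_lines, times = nz),
                 z = rep(z_lines, each = nr))
  idx <- function(i, j) (j - 1L) * nr + i

  ii <- rep(seq_len(nr - 1L), times = nz - 1L)
  jj <- rep(seq_len(nz - 1L), each = nr - 1L)
  n00 <- idx(ii, jj); n10 <- idx(ii + 1L, jj)
  n01 <- idx(ii, jj + 1L); n11 <- idx(ii + 1L, jj + 1L)
  tri <- rbind(cbind(n00, n10, n11), cbind(n00, n11, n01))

  cent_r <- (nodes[tri[, 1], 1] + nodes[tri[, 2], 1] + nodes[tri[, 3], 1]) / 3
  cent_z <- (nodes[tri[, 1], 2] + nodes[tri[, 2], 2] + nodes[tri[, 3], 2]) / 3
  domain <- ifelse(cent_r < Rs + 1e-12 & cent_z < ts + 1e-12,
                   "sample", "medium")
  if (!include_medium) domain[] <- "sample"

  tol <- 1e-9 * max(Rw, H)
  r_max <- if (include_medium) Rw else Rs
  z_max <- if (include_medium) H else ts
  on_axis <- abs(nodes[, 1]) < tol
  on_base <- abs(nodes[, 2]) < tol
  on_wall <- abs(nodes[, 1] - r_max) < tol
  on_top  <- abs(nodes[, 2] - z_max) < tol

  edge_between <- function(mask) {
    # horizontal or vertical grid edges whose both endpoints satisfy mask
    ids <- which(mask)
    e <- NULL
    for (d in c(1L, nr)) {  # neighbor offsets along r (1) and z (nr)
      cand <- ids[(ids + d) %in% ids]
      if (length(cand)) e <- rbind(e, cbind(cand, cand + d))
    }
    e
  }
  edges <- NULL
  add_edges <- function(edges, mask, tag) {
    e <- edge_between(mask)
    if (is.null(e)) return(edges)
    rbind(edges, data.frame(n1 = e[, 1], n2 = e[, 2], tag = tag))
  }
  edges <- add_edges(edges, on_axis, "axis")
  edges <- add_edges(edges, on_base, "base")
  if (include_medium) {
    edges <- add_edges(edges, on_wall, "wall")
    edges <- add_edges(edges, on_top, "top")
    iface <- (abs(nodes[, 1] - Rs) < tol & nodes[, 2] <= ts + tol) |
             (abs(nodes[, 2] - ts) < tol & nodes[, 1] <= Rs + tol)
    e <- edge_between(iface)
    if (!is.null(e)) {
      keep <- !((abs(nodes[e[, 1], 1] - Rs) < tol & abs(nodes[e[, 2], 2] - ts) < tol &
                   nodes[e[, 2], 1] > Rs + tol) |
                  FALSE)
      # restrict to edges lying on the interface lines themselves
      on_rline <- abs(nodes[e[, 1], 1] - Rs) < tol & abs(nodes[e[, 2], 1] - Rs) < tol &
        nodes[e[, 1], 2] <= ts + tol & nodes[e[, 2], 2] <= ts + tol
      on_zline <- abs(nodes[e[, 1], 2] - ts) < tol & abs(nodes[e[, 2], 2] - ts) < tol &
        nodes[e[, 1], 1] <= Rs + tol & nodes[e[, 2], 1] <= Rs + tol
      e <- e[on_rline | on_zline, , drop = FALSE]
      if (nrow(e)) edges <- rbind(edges,
                                  data.frame(n1 = e[, 1], n2 = e[, 2],
                                             tag = "interface"))
    }
  } else {
    edges <- add_edges(edges, on_wall, "side")
    edges <- add_edges(edges, on_top, "piston")
  }

  structure(list(nodes = nodes, tri = tri, domain = domain, edges = edges,
                 geometry = geometry, h = target_h,
                 include_medium = include_medium),
            class = "ct_mesh")
}

#' @export
print.ct_mesh <- function(x, ...) {
  cat(sprintf("Axisymmetric mesh: %d nodes, %d triangles (%d sample / %d medium), h ~ %g mm\n",
              nrow(x$nodes), nrow(x$tri), sum(x$domain == "sample"),
              sum(x$domain == "medium"), x$h * 1e3))
  invisible(x)
}

#' Nodes lying on a tagged boundary
#'
#' @param mesh A `"ct_mesh"`.
#' @param tag Boundary tag (`"axis"`, `"base"`, `"wall"`, `"top"`,
#'   `"interface"`, `"side"`, `"piston"`).
#' @return Sorted vector of node indices.
#' @export
boundary_nodes <- function(mesh, tag) {
  e <- mesh$edges[mesh$edges$tag %in% tag, , drop = FALSE]
  sort(unique(c(e$n1, e$n2)))
}

#' Extract the sample subdomain as a stand-alone mesh
#'
#' Renumbers nodes of the `"sample"` elements of a full well mesh into a
#' sample-only mesh with tags `axis`, `base`, `piston` (sample top) and
#' `side` (lateral face). Attribute `"parent_nodes"` maps new node indices
#' back to the parent mesh.
#'
#' @param mesh A full-well `"ct_mesh"`.
#' @return A sample-only `"ct_mesh"`.
#' @export
sample_submesh <- function(mesh) {
  stopifnot(inherits(mesh, "ct_mesh"))
  keep_el <- mesh$domain == "sample"
  tri_old <- mesh$tri[keep_el, , drop = FALSE]
  old_nodes <- sort(unique(as.vector(tri_old)))
  remap <- integer(nrow(mesh$nodes)); remap[old_nodes] <- seq_along(old_nodes)
  nodes <- mesh$nodes[old_nodes, , drop = FALSE]
  tri <- matrix(remap[tri_old], ncol = 3)
  geo <- mesh$geometry
  tol <- 1e-9 * max(geo$well_radius, geo$well_height)
  on_axis <- abs(nodes[, 1]) < tol
  on_base <- abs(nodes[, 2]) < tol
  on_side <- abs(nodes[, 1] - geo$sample_radius) < tol
  on_top  <- abs(nodes[, 2] - geo$sample_thickness) < tol
  mk <- function(mask, tag) {
    ids <- which(mask)
    if (length(ids) < 2) return(NULL)
    # order along the boundary line and connect consecutive nodes
    ord <- ids[order(nodes[ids, 1], nodes[ids, 2])]
    data.frame(n1 = ord[-length(ord)], n2 = ord[-1], tag = tag)
  }
  edges <- rbind(mk(on_axis, "axis"), mk(on_base, "base"),
                 mk(on_side, "side"), mk(on_top, "piston"))
  structure(list(nodes = nodes, tri = tri,
                 domain = rep("sample", nrow(tri)), edges = edges,
                 geometry = geo, h = mesh$h, include_medium = FALSE,
                 parent_nodes = old_nodes),
            class = "ct_mesh")
}

# per-element geometry: area, constant shape-function gradients, centroid r
tri_geometry <- function(mesh) {
  p1 <- mesh$nodes[mesh$tri[, 1], , drop = FALSE]
  p2 <- mesh$nodes[mesh$tri[, 2], , drop = FALSE]
  p3 <- mesh$nodes[mesh$tri[, 3], , drop = FALSE]
  d <- (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
       (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])
  area <- d / 2                     # signed; positive for CCW
  if (any(area <= 0)) stop("mesh contains degenerate or inverted elements")
  # gradients of P1 shape functions: grad N_a = (b_a, c_a)
  b1 <- (p2[, 2] - p3[, 2]) / d; c1 <- (p3[, 1] - p2[, 1]) / d
  b2 <- (p3[, 2] - p1[, 2]) / d; c2 <- (p1[, 1] - p3[, 1]) / d
  b3 <- (p1[, 2] - p2[, 2]) / d; c3 <- (p2[, 1] - p1[, 1]) / d
  list(area = area,
       b = cbind(b1, b2, b3), c = cbind(c1, c2, c3),
       r_cent = (p1[, 1] + p2[, 1] + p3[, 1]) / 3,
       p1 = p1, p2 = p2, p3 = p3)
}
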