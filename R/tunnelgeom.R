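#' Tunnel detection parameters
#'
#' Defaults mirror the standard CAVER-style parameterisation: a 0.7 Angstrom
#' probe and weighting coefficient 2 for the path cost, with essentially
#' unlimited tunnels per frame (99999).
#'
#' @param probe_radius minimum admissible clearance along a tunnel (Angstrom)
#' @param weighting_coefficient exponent `wc` of the path cost
#'   `cost = sum(seg_len / r_seg^wc)`; throughput is `exp(-cost)`
#' @param shell_radius gap beyond the outermost atom at which bulk solvent
#'   begins; nodes radially past it are tunnel exits (Angstrom)
#' @param shell_depth extra margin of bulk sampled beyond the exit surface
#'   (Angstrom)
#' @param grid_spacing lattice spacing of the void grid (Angstrom)
#' @param max_tunnels_per_frame cap on tunnels extracted per frame
#' @param block_radius_cap cap on the tube radius blocked around an accepted
#'   tunnel before searching for the next one (Angstrom)
#' @param refine logical; refine path nodes by local clearance maximisation
#'   (sub-grid bottleneck accuracy)
#' @return A list of class `detect_params`.
#' @export
detect_params <- function(probe_radius = 0.7, weighting_coefficient = 2,
                          shell_radius = 3, shell_depth = 2,
                          grid_spacing = 0.5, max_tunnels_per_frame = 99999L,
                          block_radius_cap = 2.5, refine = TRUE) {
  stopifnot(probe_radius > 0, weighting_coefficient >= 0, grid_spacing > 0,
            shell_radius >= 0, shell_depth >= 0, max_tunnels_per_frame >= 1)
  structure(list(probe_radius = probe_radius,
                 weighting_coefficient = weighting_coefficient,
                 shell_radius = shell_radius, shell_depth = shell_depth,
                 grid_spacing = grid_spacing,
                 max_tunnels_per_frame = as.integer(max_tunnels_per_frame),
                 block_radius_cap = block_radius_cap, refine = refine),
            class = "detect_params")
}

.check_nondegenerate <- function(coords) {
  if (nrow(coords) < 4L)
    stop("need at least 4 atoms for tunnel detection", call. = FALSE)
  sv <- svd(scale(coords, scale = FALSE), nu = 0, nv = 0)$d
  if (sv[3] < 1e-6)
    stop("degenerate geometry: atoms are coplanar within tolerance",
         call. = FALSE)
  invisible(NULL)
}

#' Build the void-space graph of one frame
#'
#' Diagnostic view of the lattice the detector searches: nodes are grid points
#' with their exact clearance (distance to the nearest atom surface), flagged
#' admissible (clearance >= probe) and exterior (radially beyond the outermost
#' atom plus `shell_radius`). Edges connect 26-neighbouring admissible nodes.
#'
#' @param coords `n_atoms x 3` coordinate matrix
#' @param vdw per-atom vdW radii
#' @param params a [detect_params()] object
#' @return List with `nodes` (m x 3 matrix of admissible-node positions),
#'   `clearance`, `exterior` (logical), plus grid metadata `spacing`,
#'   `r_exterior` and `centroid`.
#' @export
build_void_graph <- function(coords, vdw, params = detect_params()) {
  .check_nondegenerate(coords)
  cen <- colMeans(coords)
  rmax <- sqrt(max(rowSums(sweep(coords, 2, cen)^2)))
  reach <- rmax + params$shell_radius + params$shell_depth
  s <- params$grid_spacing
  ax <- lapply(1:3, function(d) seq(cen[d] - reach, cen[d] + reach, by = s))
  pts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  colnames(pts) <- c("x", "y", "z")
  cl <- .clearance_at_cpp(coords, vdw, pts)
  keep <- cl >= params$probe_radius
  radial <- sqrt(rowSums(sweep(pts[keep, , drop = FALSE], 2, cen)^2))
  list(nodes = pts[keep, , drop = FALSE], clearance = cl[keep],
       exterior = radial > rmax + params$shell_radius,
       spacing = s, r_exterior = rmax + params$shell_radius, centroid = cen)
}

#' Clearance at arbitrary points
#'
#' Distance from each query point to the nearest atom surface (distance to the
#' nearest atom centre minus that atom's vdW radius). Negative inside an atom.
#'
#' @param coords `n_atoms x 3` coordinate matrix
#' @param vdw per-atom vdW radii
#' @param points `m x 3` query points
#' @return Numeric vector of clearances (Angstrom).
#' @export
clearance_at <- function(coords, vdw, points) {
  .clearance_at_cpp(as.matrix(coords), as.numeric(vdw),
                    matrix(as.numeric(points), ncol = 3L))
}

#' Detect tunnels in one frame
#'
#' Finds maximal-clearance pathways from the starting point to the exterior:
#' each tunnel is the minimum-cost path (edge cost `len / r_mean^wc`) over
#' void-grid nodes with clearance >= probe, extracted greedily best-throughput
#' first; after each accepted tunnel the nodes inside its void tube are
#' blocked, so each distinct exit yields one tunnel. Returns an empty list
#' (not an error) when no admissible path exists.
#'
#' @param coords `n_atoms x 3` coordinate matrix of the frame
#' @param vdw per-atom vdW radii
#' @param start length-3 starting point (Angstrom), typically from
#'   [compute_start_point()]
#' @param params a [detect_params()] object
#' @param frame_number global frame number attached to the returned tunnels
#' @return List of `tunnel` objects (see [new_tunnel()]), ordered by
#'   decreasing throughput.
#' @export
detect_tunnels <- function(coords, vdw, start, params = detect_params(),
                           frame_number = 1L) {
  coords <- as.matrix(coords)
  .check_nondegenerate(coords)
  profs <- .detect_frame_cpp(coords, as.numeric(vdw), as.numeric(start),
                             params$probe_radius,
                             params$weighting_coefficient,
                             params$grid_spacing, params$shell_radius,
                             params$shell_depth, params$max_tunnels_per_frame,
                             params$block_radius_cap, params$refine)
  lapply(profs, function(p)
    new_tunnel(nodes = p[, 1:3, drop = FALSE], radii = p[, 4],
               frame_number = frame_number,
               weighting_coefficient = params$weighting_coefficient))
}

#' Construct a tunnel from its centreline profile
#'
#' Derived quantities are computed from the profile: bottleneck = minimum
#' radius, length = polyline length, cost per [tunnel_cost()], and
#' throughput = exp(-cost).
#'
#' @param nodes `m x 3` ordered centreline nodes (start to exit, Angstrom)
#' @param radii per-node clearance radii (Angstrom, positive)
#' @param frame_number global frame number
#' @param weighting_coefficient cost exponent
#' @return Object of class `tunnel`.
#' @export
new_tunnel <- function(nodes, radii, frame_number,
                       weighting_coefficient = 2) {
  nodes <- as.matrix(nodes)
  stopifnot(nrow(nodes) == length(radii), nrow(nodes) >= 2L)
  if (any(radii <= 0)) stop("tunnel radii must be positive", call. = FALSE)
  bl <- bottleneck_and_length(list(nodes = nodes, radii = radii))
  cost <- tunnel_cost(list(nodes = nodes, radii = radii),
                      weighting_coefficient)
  structure(list(frame_number = as.integer(frame_number), nodes = nodes,
                 radii = as.numeric(radii), bottleneck = bl[["bottleneck"]],
                 length = bl[["length"]], cost = cost,
                 throughput = exp(-cost)),
            class = "tunnel")
}

#' @export
print.tunnel <- function(x, ...) {
  cat(sprintf(
    "tunnel: frame %d, %d nodes, bottleneck %.3f A, length %.2f A, throughput %.4g\n",
    x$frame_number, nrow(x$nodes), x$bottleneck, x$length, x$throughput))
  invisible(x)
}

#' Radius-weighted path cost of a tunnel profile
#'
#' `cost = sum over segments of seg_len / r_seg^wc`, where `r_seg` is the mean
#' of the segment's endpoint radii; throughput is `exp(-cost)`. With `wc = 0`
#' the cost reduces to the geometric length.
#'
#' @param profile list with `nodes` (m x 3) and `radii` (length m), or a
#'   `tunnel`
#' @param weighting_coefficient non-negative exponent `wc`
#' @return Non-negative scalar cost.
#' @export
#' @examples
#' p <- list(nodes = cbind(0:3, 0, 0), radii = rep(1, 4))
#' tunnel_cost(p, 2)  # 3: throughput exp(-3)
tunnel_cost <- function(profile, weighting_coefficient = 2) {
  r <- profile$radii
  if (any(r <= 0)) stop("tunnel radii must be positive", call. = FALSE)
  seg <- sqrt(rowSums((profile$nodes[-1, , drop = FALSE] -
                       profile$nodes[-nrow(profile$nodes), , drop = FALSE])^2))
  rseg <- (r[-1] + r[-length(r)]) / 2
  sum(seg / rseg^weighting_coefficient)
}

#' Bottleneck and length of a tunnel profile
#'
#' @param profile list with `nodes` (m x 3) and `radii`
#' @return Named numeric vector `c(bottleneck =, length =)` in Angstrom:
#'   minimum radius and polyline length.
#' @export
bottleneck_and_length <- function(profile) {
  seg <- sqrt(rowSums((profile$nodes[-1, , drop = FALSE] -
                       profile$nodes[-nrow(profile$nodes), , drop = FALSE])^2))
  c(bottleneck = min(profile$radii), length = sum(seg))
}

#' Cumulative arc length along a profile
#' @param nodes `m x 3` node matrix
#' @return Numeric vector of length m starting at 0, non-decreasing.
#' @export
cumulative_length <- function(nodes) {
  seg <- sqrt(rowSums((nodes[-1, , drop = FALSE] -
                       nodes[-nrow(nodes), , drop = FALSE])^2))
  c(0, cumsum(seg))
}
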