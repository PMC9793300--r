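#' Specify one designed channel of a synthetic shell
#'
#' A channel is a cylindrical corridor through the shell wall along `axis`
#' (from the cavity centre outward). Its designed bottleneck radius may be
#' gated over frames: constant, square-wave (open/closed), or sinusoidal
#' (breathing). Gating is deterministic; ground truth is exact by
#' construction.
#'
#' @param axis length-3 direction of the channel (normalised internally)
#' @param base_radius fully-open bottleneck radius (Angstrom)
#' @param gating list describing the per-frame radius: `list(type =
#'   "constant")`, `list(type = "square", period =, open_fraction =)` (open
#'   for the first `round(open_fraction * period)` frames of each period at
#'   `base_radius`, otherwise `closed_radius`), or `list(type = "sine",
#'   amplitude =, period =)` (radius `base_radius + amplitude *
#'   sin(2*pi*(t-1)/period)`, floored at 0.05)
#' @param closed_radius radius in closed square-wave frames (Angstrom; keep it
#'   below the probe radius)
#' @param open_threshold probe radius defining "open" in the ground truth
#' @return List of class `channel_spec`.
#' @export
channel_spec <- function(axis, base_radius, gating = list(type = "constant"),
                         closed_radius = 0.25, open_threshold = 0.7) {
  axis <- as.numeric(axis) / sqrt(sum(as.numeric(axis)^2))
  stopifnot(base_radius > 0, closed_radius >= 0,
            gating$type %in% c("constant", "square", "sine"))
  structure(list(axis = axis, base_radius = base_radius, gating = gating,
                 closed_radius = closed_radius,
                 open_threshold = open_threshold),
            class = "channel_spec")
}

#' Designed bottleneck radius of a channel over frames
#' @param channel a [channel_spec()]
#' @param t integer frame numbers (1-based)
#' @return Numeric vector of designed radii (Angstrom).
#' @export
designed_radius <- function(channel, t) {
  g <- channel$gating
  switch(g$type,
    constant = rep(channel$base_radius, length(t)),
    square = {
      open <- ((t - 1L) %% g$period) < round(g$open_fraction * g$period)
      ifelse(open, channel$base_radius, channel$closed_radius)
    },
    sine = pmax(0.05, channel$base_radius +
                  g$amplitude * sin(2 * pi * (t - 1) / g$period)))
}

#' Default three-channel layout of the synthetic benchmark
#'
#' Channel 1 (+x, 1.5 Angstrom) is always open; channel 2 (+y, 1.2 Angstrom)
#' breathes with a 40-frame square wave open half the time; channel 3
#' (+z, 1.0 Angstrom) is open only in the first 10% of the trajectory. The
#' three presences (1.0, 0.5, 0.1) span persistent, intermittent and rare
#' transient tunnels.
#'
#' @param n_frames trajectory length (sets the 10% window of channel 3)
#' @return List of three [channel_spec()] objects.
#' @export
default_channels <- function(n_frames) {
  list(channel_spec(c(1, 0, 0), 1.5),
       channel_spec(c(0, 1, 0), 1.2,
                    list(type = "square", period = 40L, open_fraction = 0.5)),
       channel_spec(c(0, 0, 1), 1.0,
                    list(type = "square", period = as.integer(n_frames),
                         open_fraction = 0.1)))
}

#' Specify a synthetic pseudo-protein shell
#'
#' A spherical shell of pseudo-atoms (Fibonacci-sphere placement, sealed to
#' the probe everywhere except at the designed channels) enclosing an empty
#' cavity, with four low-mobility "site" atoms near the centre whose centroid
#' serves as the tunnel-search starting point. Each channel is a cleared
#' corridor lined by collar atoms; its per-frame bottleneck is imposed by a
#' gate ring whose atoms move radially with the designed radius. Gaussian
#' positional jitter emulates thermal motion; all randomness flows from one
#' seed.
#'
#' @param n_frames number of frames
#' @param channels list of [channel_spec()] objects
#' @param shell_radius radius of the atom shell (Angstrom)
#' @param spacing target spacing of shell atoms (must stay below twice the
#'   vdW radius so the wall is sealed)
#' @param atom_vdw vdW radius of every pseudo-atom (1.7, carbon, so radii
#'   survive a PDB round trip)
#' @param jitter standard deviation of the positional jitter (Angstrom)
#' @param seed integer seed fixing all randomness
#' @return List of class `shell_spec`.
#' @export
shell_spec <- function(n_frames = 2000L, channels = default_channels(n_frames),
                       shell_radius = 11, spacing = 1.2, atom_vdw = 1.7,
                       jitter = 0.05, seed = 1L) {
  stopifnot(n_frames >= 1, spacing < 2 * atom_vdw, shell_radius > 5,
            jitter >= 0)
  for (ch in channels) {
    if (ch$base_radius - min(designed_radius(ch, seq_len(n_frames))) > 3)
      stop("gate travel above 3 Angstrom would unseal the channel wall",
           call. = FALSE)
  }
  # channels must not overlap: cap-to-cap great-circle separation
  if (length(channels) > 1L) {
    for (i in seq_along(channels)[-1]) for (j in seq_len(i - 1L)) {
      u <- channels[[i]]$axis; v <- channels[[j]]$axis
      sep <- shell_radius * acos(pmin(1, pmax(-1, sum(u * v))))
      cap_i <- channels[[i]]$base_radius + atom_vdw + 1.0
      cap_j <- channels[[j]]$base_radius + atom_vdw + 1.0
      if (sep < cap_i + cap_j + spacing)
        stop("channels ", j, " and ", i, " overlap within one atom spacing",
             call. = FALSE)
    }
  }
  structure(list(n_frames = as.integer(n_frames), channels = channels,
                 shell_radius = shell_radius, spacing = spacing,
                 atom_vdw = atom_vdw, jitter = jitter,
                 seed = as.integer(seed)),
            class = "shell_spec")
}

# Fibonacci sphere: n near-uniform points on the unit sphere (deterministic)
.fib_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (sqrt(5) + 1) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# distance from points to the ray {s*u : s > 0}; Inf where s <= 0
.ray_dist <- function(pts, u) {
  s <- pts %*% u
  d <- sqrt(pmax(0, rowSums(pts^2) - s^2))
  d[s <= 0] <- Inf
  d
}

.axis_basis <- function(u) {
  a <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- c(u[2] * a[3] - u[3] * a[2], u[3] * a[1] - u[1] * a[3],
          u[1] * a[2] - u[2] * a[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

# ring of m atoms around axis u at axial station s and radial distance rho
.ring <- function(u, basis, s, rho, m, phase = 0) {
  th <- 2 * pi * (seq_len(m) - 1L) / m + phase
  outer(rep(s, m), u) + rho * (cos(th) %o% basis$e1 + sin(th) %o% basis$e2)
}

#' Build a synthetic multi-frame ensemble from a shell specification
#'
#' Deterministic given the spec (byte-identical across calls). The returned
#' ensemble carries the designed vdW radius on every atom; the four site
#' atoms have residue name `SIT`, atom name `CA` and residue numbers
#' 9001-9004, so [default_start_selectors()] addresses them.
#'
#' @param spec a [shell_spec()]
#' @return A [frame_ensemble()] with `n_frames` frames.
#' @export
build_ensemble <- function(spec) {
  R <- spec$shell_radius; vdw <- spec$atom_vdw
  n_shell <- round(4 * pi * R^2 / spec$spacing^2)
  shell <- R * .fib_sphere(n_shell)
  # fixed corridor holes (frame-independent, so the topology is constant)
  keep <- rep(TRUE, nrow(shell))
  for (ch in spec$channels) {
    hole_r <- ch$base_radius + vdw + 1.0
    keep <- keep & (.ray_dist(shell, ch$axis) >= hole_r)
  }
  shell <- shell[keep, , drop = FALSE]
  sites <- 4 / sqrt(3) * rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1),
                               c(-1, -1, 1))
  static <- rbind(shell, sites)
  kind <- c(rep("SPH", nrow(shell)), rep("SIT", 4L))

  gates <- list()  # per channel: basis, station, m atoms (positions per frame)
  for (ci in seq_along(spec$channels)) {
    ch <- spec$channels[[ci]]
    basis <- .axis_basis(ch$axis)
    c_r <- ch$base_radius + vdw
    stations <- seq(R - 2.5, R + 2.5, by = 0.9)
    coll <- do.call(rbind, lapply(seq_along(stations), function(si) {
      m <- max(6L, ceiling(2 * pi * c_r / 0.9))
      .ring(ch$axis, basis, stations[si], c_r, m, phase = 0.5 * si)
    }))
    static <- rbind(static, coll)
    kind <- c(kind, rep("COL", nrow(coll)))
    gates[[ci]] <- list(axis = ch$axis, basis = basis, station = R,
                        m = as.integer(max(6L, ceiling(2 * pi * c_r / 0.9))))
  }
  n_gate <- vapply(gates, `[[`, integer(1), "m")
  n_static <- nrow(static)
  n_atoms <- n_static + sum(n_gate)

  radii_by_frame <- vapply(spec$channels, designed_radius,
                           numeric(spec$n_frames), t = seq_len(spec$n_frames))
  radii_by_frame <- matrix(radii_by_frame, nrow = spec$n_frames)

  set.seed(spec$seed)
  xyz <- matrix(0, nrow = spec$n_frames, ncol = 3L * n_atoms)
  for (f in seq_len(spec$n_frames)) {
    co <- static
    for (ci in seq_along(gates)) {
      g <- gates[[ci]]
      co <- rbind(co, .ring(g$axis, g$basis, g$station,
                            radii_by_frame[f, ci] + vdw, g$m, phase = 0.25))
    }
    if (spec$jitter > 0)
      co <- co + matrix(rnorm(length(co), 0, spec$jitter), ncol = 3L)
    xyz[f, ] <- as.vector(t(co))
  }

  kind <- c(kind, rep("GAT", sum(n_gate)))
  resno <- seq_len(n_atoms)
  resno[kind == "SIT"] <- 9001:9004
  atoms <- data.frame(serial = seq_len(n_atoms),
                      name = ifelse(kind == "SIT", "CA", "C"),
                      resid = kind, resno = resno,
                      element = "C", vdw = vdw, stringsAsFactors = FALSE)
  frame_ensemble(atoms, xyz)
}

#' Starting-point selectors for synthetic shells
#'
#' Addresses the four site atoms placed by [build_ensemble()]; their centroid
#' is the cavity centre.
#'
#' @return Data frame with columns `resno`, `name`.
#' @export
default_start_selectors <- function() {
  data.frame(resno = 9001:9004, name = "CA", stringsAsFactors = FALSE)
}

#' Exact ground truth of a shell specification
#'
#' @param spec a [shell_spec()]
#' @return List with `per_frame` (n_frames x K matrix of designed radii),
#'   `open` (logical matrix: designed radius >= the channel's open
#'   threshold), and `summary` (one row per channel: frames open, min and
#'   mean designed bottleneck over open frames).
#' @export
ground_truth <- function(spec) {
  K <- length(spec$channels)
  per_frame <- vapply(spec$channels, designed_radius,
                      numeric(spec$n_frames), t = seq_len(spec$n_frames))
  per_frame <- matrix(per_frame, nrow = spec$n_frames)
  open <- vapply(seq_len(K), function(ci)
    per_frame[, ci] >= spec$channels[[ci]]$open_threshold,
    logical(spec$n_frames))
  open <- matrix(open, nrow = spec$n_frames)
  summary <- do.call(rbind, lapply(seq_len(K), function(ci) {
    op <- open[, ci]
    data.frame(channel = ci,
               frames_open = sum(op),
               presence = mean(op),
               min_bottleneck = if (any(op)) min(per_frame[op, ci]) else NA_real_,
               mean_bottleneck = if (any(op)) mean(per_frame[op, ci]) else NA_real_)
  }))
  list(per_frame = per_frame, open = open, summary = summary)
}
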