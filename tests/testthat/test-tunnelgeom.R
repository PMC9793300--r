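test_that("tunnel cost follows the segment rule and throughput = exp(-cost)", {
  # constant radius 1, length 3, wc 2 -> cost 3
  p <- list(nodes = cbind(0:3, 0, 0), radii = rep(1, 4))
  expect_equal(tunnel_cost(p, 2), 3)
  tu <- make_tunnel(p$nodes, p$radii)
  expect_equal(tu$throughput, exp(-3))
  # wc = 0: cost equals geometric length
  expect_equal(tunnel_cost(p, 0), 3)
  # piecewise radii (1, 1, 2) over two 1 A segments: segment radii 1 and 1.5
  p2 <- list(nodes = cbind(0:2, 0, 0), radii = c(1, 1, 2))
  expect_equal(tunnel_cost(p2, 2), 1 / 1^2 + 1 / 1.5^2)
  expect_error(tunnel_cost(list(nodes = p$nodes, radii = c(1, -1, 1, 1)), 2),
               "positive")
})

test_that("bottleneck and length are min radius and polyline length", {
  p <- list(nodes = cbind(c(0, 2, 5), 0, 0), radii = c(1.4, 0.9, 1.1))
  bl <- bottleneck_and_length(p)
  expect_equal(bl[["bottleneck"]], 0.9)
  p2 <- list(nodes = rbind(c(0, 0, 0), c(0, 0, 5)), radii = c(1, 1))
  expect_equal(bottleneck_and_length(p2)[["length"]], 5)
  # random profile: length equals independent pairwise-distance sum
  set.seed(42)
  nodes <- matrix(rnorm(30), ncol = 3)
  brute <- sum(vapply(2:10, function(i)
    sqrt(sum((nodes[i, ] - nodes[i - 1, ])^2)), numeric(1)))
  expect_equal(bottleneck_and_length(list(nodes = nodes,
                                          radii = rep(1, 10)))[["length"]],
               brute)
})

test_that("throughput is monotone in length and radii", {
  base <- list(nodes = cbind(seq(0, 4, length.out = 9), 0, 0),
               radii = rep(1.2, 9))
  t_base <- exp(-tunnel_cost(base, 2))
  longer <- list(nodes = cbind(seq(0, 6, length.out = 9), 0, 0),
                 radii = base$radii)
  expect_lt(exp(-tunnel_cost(longer, 2)), t_base)
  wider <- list(nodes = base$nodes, radii = base$radii + 0.3)
  expect_gt(exp(-tunnel_cost(wider, 2)), t_base)
  expect_true(t_base > 0 && t_base <= 1)
})

test_that("void graph clearance matches closed forms on designed geometries", {
  # 8 atoms at the corners of an 8 A cube, r_vdw 1.5: the centre node's
  # clearance is 4*sqrt(3) - 1.5
  corners <- as.matrix(expand.grid(c(-4, 4), c(-4, 4), c(-4, 4)))
  expect_equal(clearance_at(corners, rep(1.5, 8), rbind(c(0, 0, 0))),
               4 * sqrt(3) - 1.5)
  g <- build_void_graph(corners, rep(1.5, 8),
                        detect_params(grid_spacing = 0.5))
  centre <- which.min(rowSums(g$nodes^2))
  expect_lt(abs(g$clearance[centre] - (4 * sqrt(3) - 1.5)), 0.3)
  # clearance at any node is <= distance to every atom surface
  i <- which.max(g$clearance)
  d_all <- sqrt(rowSums(sweep(corners, 2, g$nodes[i, ])^2)) - 1.5
  expect_true(all(g$clearance[i] <= d_all + 1e-9))
})

test_that("void graph of a tetrahedron has interior nodes with positive clearance", {
  tet <- 3 * rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  g <- build_void_graph(tet, rep(1.0, 4), detect_params(probe_radius = 0.2))
  expect_gt(sum(!g$exterior), 0)
  expect_true(all(g$clearance > 0))
})

test_that("coplanar atoms are rejected as degenerate", {
  flat <- cbind(rnorm(10), rnorm(10), 0)
  expect_error(build_void_graph(flat, rep(1.5, 10)), "coplanar")
  expect_error(detect_tunnels(flat, rep(1.5, 10), c(0, 0, 0)), "coplanar")
})

test_that("a sealed shell yields no tunnels and a start inside an atom errors", {
  sealed <- small_shell(channels = list(
    channel_spec(c(1, 0, 0), 1.2,
                 gating = list(type = "square", period = 2L,
                               open_fraction = 0), closed_radius = 0.2)))
  ens <- build_ensemble(sealed)
  co <- frame_coords(ens, 1)
  expect_length(detect_tunnels(co, ens$atoms$vdw, c(0, 0, 0)), 0)
  # starting point buried in a shell atom
  expect_error(detect_tunnels(co, ens$atoms$vdw, co[1, ]), "inside an atom")
  # starting point far outside the structure
  expect_error(detect_tunnels(co, ens$atoms$vdw, c(50, 0, 0)), "outside")
})

test_that("a single straight channel is found with the designed bottleneck", {
  spec <- small_shell(channels = list(channel_spec(c(1, 0, 0), 1.2)))
  ens <- build_ensemble(spec)
  co <- frame_coords(ens, 1)
  tl <- detect_tunnels(co, ens$atoms$vdw, c(0, 0, 0))
  expect_length(tl, 1)
  expect_lt(abs(tl[[1]]$bottleneck - 1.2), 0.15)
  expect_gte(tl[[1]]$bottleneck, 0.7)  # never below the probe
  # independent dense-grid flood-fill oracle along the channel corridor
  oracle <- oracle_grid_bottleneck(co, ens$atoms$vdw, start = c(0, 0, 0),
                                   box_lo = c(-0.5, -3, -3),
                                   box_hi = c(13.5, 3, 3), x_exit = 12.5)
  expect_lt(abs(tl[[1]]$bottleneck - oracle), 0.2)
})

test_that("two channels give two tunnels ranked by throughput", {
  spec <- small_shell(channels = list(channel_spec(c(1, 0, 0), 1.5),
                                      channel_spec(c(0, 1, 0), 1.0)))
  ens <- build_ensemble(spec)
  tl <- detect_tunnels(frame_coords(ens, 1), ens$atoms$vdw, c(0, 0, 0))
  expect_length(tl, 2)
  # wider channel first (greedy best-throughput extraction)
  expect_gt(tl[[1]]$throughput, tl[[2]]$throughput)
  ends <- t(vapply(tl, function(tu) tu$nodes[nrow(tu$nodes), ], numeric(3)))
  expect_gt(ends[1, 1], 9)  # exits along +x
  expect_gt(ends[2, 2], 9)  # exits along +y
  expect_lt(abs(tl[[1]]$bottleneck - 1.5), 0.15)
  expect_lt(abs(tl[[2]]$bottleneck - 1.0), 0.15)
})

test_that("removing wall atoms never shrinks the tunnel set or bottleneck", {
  spec <- small_shell(channels = list(channel_spec(c(1, 0, 0), 1.0)))
  ens <- build_ensemble(spec)
  co <- frame_coords(ens, 1)
  before <- detect_tunnels(co, ens$atoms$vdw, c(0, 0, 0))
  # widen the corridor: drop the gate ring entirely
  keep <- ens$atoms$resid != "GAT"
  after <- detect_tunnels(co[keep, ], ens$atoms$vdw[keep], c(0, 0, 0))
  expect_gte(length(after), length(before))
  # allow the sub-grid resolution of the refined bottleneck estimate
  expect_gte(after[[1]]$bottleneck, before[[1]]$bottleneck - 0.02)
})

test_that("tunnel profiles satisfy their invariants", {
  spec <- small_shell(channels = list(channel_spec(c(1, 0, 0), 1.3),
                                      channel_spec(c(0, 0, 1), 1.1)))
  ens <- build_ensemble(spec)
  tl <- detect_tunnels(frame_coords(ens, 1), ens$atoms$vdw, c(0, 0, 0))
  for (tu in tl) {
    expect_gte(nrow(tu$nodes), 2)
    expect_true(all(tu$radii > 0))
    expect_equal(tu$bottleneck, min(tu$radii))
    cum <- cumulative_length(tu$nodes)
    expect_equal(cum[1], 0)
    expect_true(all(diff(cum) >= 0))
    expect_equal(tu$length, cum[length(cum)])
    expect_equal(tu$throughput, exp(-tu$cost))
    expect_true(tu$throughput > 0 && tu$throughput <= 1)
  }
})
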