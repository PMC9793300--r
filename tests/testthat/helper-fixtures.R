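# Shared in-code fixtures. Everything is generated at test time; no files.

# a small sealed shell with configurable channels (radius 9 keeps unit tests fast)
small_shell <- function(n_frames = 1, channels = list(channel_spec(c(1, 0, 0), 1.2)),
                        jitter = 0, seed = 1) {
  shell_spec(n_frames = n_frames, channels = channels, shell_radius = 9,
             jitter = jitter, seed = seed)
}

# a tunnel along a given polyline with given radii
make_tunnel <- function(nodes, radii = rep(1, nrow(nodes)), frame = 1L, wc = 2) {
  new_tunnel(nodes = nodes, radii = radii, frame_number = frame,
             weighting_coefficient = wc)
}

# a random smooth-ish polyline from the origin outward (deterministic per seed)
random_path <- function(seed, n_nodes = 12, step = 1.2) {
  set.seed(seed)
  dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
  steps <- matrix(rnorm(3 * (n_nodes - 1), sd = 0.3), ncol = 3)
  steps <- sweep(steps, 2, dir * step, "+")
  rbind(0, apply(steps, 2, cumsum))
}

random_tunnel <- function(seed, frame = 1L) {
  p <- random_path(seed)
  set.seed(seed + 10000)
  make_tunnel(p, radii = runif(nrow(p), 0.8, 2.0), frame = frame)
}

# a single-member cluster whose representative path is the tunnel's path
make_cluster <- function(seed, slice = 1L, id = 1L, frame = 1L, k = 20L) {
  new_tunnel_cluster(list(random_tunnel(seed, frame = frame)),
                     slice_index = slice, cluster_id = id, k = k)
}

# a few multi-tunnel clusters with random pathways (one simulated run)
random_run_clusters <- function(n_clusters = 3, seed = 99) {
  set.seed(seed)
  lapply(seq_len(n_clusters), function(ci) {
    tunnels <- lapply(seq_len(sample(2:4, 1)), function(ti)
      random_tunnel(seed * 50 + ci * 10 + ti, frame = ti))
    new_tunnel_cluster(tunnels, slice_index = 1L, cluster_id = ci)
  })
}

# membership vector -> canonical partition labels (for comparing clusterings)
canon_partition <- function(memb) {
  match(memb, unique(memb))
}

# read every regular file under a directory as raw bytes (byte-identity checks)
dir_bytes <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = FALSE))
  stats::setNames(lapply(files, function(f)
    readBin(file.path(dir, f), "raw", file.size(file.path(dir, f)))), files)
}
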