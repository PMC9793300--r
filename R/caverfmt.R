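#' @name caver_dialect
#' @title The CAVER-dialect cluster file format
#' @description
#' A run is serialized as one directory holding `summary.csv` plus one profile
#' file per cluster (`cluster_001.csv`, ...). Both are RFC-4180 CSV with a
#' `.` decimal point, all floating-point fields in 6-decimal fixed point, and
#' a first line identifying the dialect version:
#'
#' * `summary.csv` — line 1 `# caver-dialect v1 summary`, then header
#'   `cluster_id,frame,tunnel,bottleneck,length,cost,throughput` and one row
#'   per tunnel. `tunnel` is the tunnel's ordinal within its cluster.
#' * `cluster_NNN.csv` — line 1 `# caver-dialect v1 profile`, then header
#'   `cluster_id,frame,tunnel,node,x,y,z,radius` and one row per centreline
#'   node, ordered start to exit.
#'
#' Frame numbers are always global 1-based trajectory frames (continuous
#' numbering across slices). The format is CAVER-like but makes no claim of
#' byte compatibility with CAVER's own output. Writing, reading and rewriting
#' a run is byte-identical.
NULL

.fmt6 <- function(x) sprintf("%.6f", x)

.write_csv_lines <- function(lines, path) {
  con <- file(path, "wb")  # binary: LF endings on every platform
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Write clusters in the CAVER dialect
#'
#' @param clusters list of `tunnel_cluster` objects
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly. See [caver_dialect] for the layout.
#' @export
write_clusters <- function(clusters, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory ", dir, call. = FALSE)
  summary_lines <- c("# caver-dialect v1 summary",
                     "cluster_id,frame,tunnel,bottleneck,length,cost,throughput")
  for (cl in clusters) {
    cid <- cl$cluster_id
    prof_lines <- c("# caver-dialect v1 profile",
                    "cluster_id,frame,tunnel,node,x,y,z,radius")
    for (ti in seq_along(cl$tunnels)) {
      tu <- cl$tunnels[[ti]]
      summary_lines <- c(summary_lines, paste(
        cid, tu$frame_number, ti, .fmt6(tu$bottleneck), .fmt6(tu$length),
        .fmt6(tu$cost), .fmt6(tu$throughput), sep = ","))
      m <- nrow(tu$nodes)
      prof_lines <- c(prof_lines, paste(
        cid, tu$frame_number, ti, seq_len(m), .fmt6(tu$nodes[, 1]),
        .fmt6(tu$nodes[, 2]), .fmt6(tu$nodes[, 3]), .fmt6(tu$radii),
        sep = ","))
    }
    .write_csv_lines(prof_lines, file.path(dir, sprintf("cluster_%03d.csv", cid)))
  }
  .write_csv_lines(summary_lines, file.path(dir, "summary.csv"))
  invisible(dir)
}

# fast CSV body read with per-line error reporting on malformed input
.read_dialect <- function(path, magic, n_cols) {
  first <- readLines(path, n = 1L)
  if (!identical(first, magic))
    stop(path, ": line 1: expected '", magic, "', found '", first, "'",
         call. = FALSE)
  tab <- tryCatch(
    data.table::fread(path, skip = 1L, header = TRUE, sep = ",",
                      colClasses = "numeric", showProgress = FALSE),
    error = function(e) NULL, warning = function(w) NULL)
  bad <- is.null(tab) || ncol(tab) != n_cols ||
    (nrow(tab) > 0L && anyNA(as.matrix(tab)))
  if (bad) {  # slow pass to locate the offending line
    lines <- readLines(path)
    for (i in seq_along(lines)[-(1:2)]) {
      f <- strsplit(lines[i], ",", fixed = TRUE)[[1]]
      if (length(f) != n_cols || anyNA(suppressWarnings(as.numeric(f))))
        stop(path, ": line ", i, ": malformed row '", lines[i], "'",
             call. = FALSE)
    }
    stop(path, ": malformed file", call. = FALSE)
  }
  as.data.frame(tab)
}

# tunnel with all derived fields taken as stored (round-trip stable)
.tunnel_raw <- function(nodes, radii, frame, bottleneck, length, cost,
                        throughput) {
  structure(list(frame_number = as.integer(frame), nodes = nodes,
                 radii = radii, bottleneck = bottleneck, length = length,
                 cost = cost, throughput = throughput), class = "tunnel")
}

#' Read clusters written in the CAVER dialect
#'
#' Full reconstruction, including global frame numbers. Stored per-tunnel
#' summary values (bottleneck, length, cost, throughput) are kept as written,
#' so write-read-write is byte-identical. A malformed row is an error naming
#' the file and line.
#'
#' @param dir directory produced by [write_clusters()] or
#'   [convert_superclusters_to_caver()]
#' @param slice_index slice index to record on the clusters (the dialect
#'   stores global frames, not slice membership)
#' @param k resample points for the recomputed representative paths
#' @return List of `tunnel_cluster` objects ordered by cluster id.
#' @export
read_clusters <- function(dir, slice_index = 1L, k = 20L) {
  spath <- file.path(dir, "summary.csv")
  if (!file.exists(spath)) stop("no summary.csv in ", dir, call. = FALSE)
  smry <- .read_dialect(spath, "# caver-dialect v1 summary", 7L)
  if (nrow(smry) == 0L) return(list())
  clusters <- list()
  for (cid in sort(unique(smry$cluster_id))) {
    ppath <- file.path(dir, sprintf("cluster_%03d.csv", cid))
    if (!file.exists(ppath))
      stop("missing profile file for cluster ", cid, " in ", dir,
           call. = FALSE)
    prof <- .read_dialect(ppath, "# caver-dialect v1 profile", 8L)
    srows <- smry[smry$cluster_id == cid, , drop = FALSE]
    tunnels <- lapply(seq_len(nrow(srows)), function(i) {
      tr <- srows[i, ]
      p <- prof[prof$tunnel == tr$tunnel, , drop = FALSE]
      if (nrow(p) < 2L)
        stop(ppath, ": tunnel ", tr$tunnel, " has fewer than 2 nodes",
             call. = FALSE)
      p <- p[order(p$node), , drop = FALSE]
      .tunnel_raw(nodes = as.matrix(p[, c("x", "y", "z")]), radii = p$radius,
                  frame = tr$frame, bottleneck = tr$bottleneck,
                  length = tr$length, cost = tr$cost,
                  throughput = tr$throughput)
    })
    clusters[[length(clusters) + 1L]] <-
      new_tunnel_cluster(tunnels, slice_index = slice_index,
                         cluster_id = cid, k = k)
  }
  clusters
}

#' Convert superclusters to CAVER-dialect files
#'
#' Superclusters are serialized in the same dialect as per-slice clusters,
#' with cluster ids equal to the super ids and tunnels spanning all member
#' slices' frames. Member provenance (slice index and per-slice cluster id of
#' every member) is recorded in a sidecar `provenance.tsv`.
#'
#' @param superclusters list of `super_cluster` objects
#' @param dir output directory
#' @return `dir`, invisibly.
#' @export
convert_superclusters_to_caver <- function(superclusters, dir) {
  as_clusters <- lapply(superclusters, function(sc) {
    tunnels <- unlist(lapply(sc$members, `[[`, "tunnels"), recursive = FALSE)
    fr <- vapply(tunnels, `[[`, integer(1), "frame_number")
    tunnels <- tunnels[order(fr, seq_along(tunnels))]
    cl <- new_tunnel_cluster(tunnels, slice_index = 0L,
                             cluster_id = sc$super_id,
                             k = nrow(sc$representative_path$nodes))
    cl
  })
  write_clusters(as_clusters, dir)
  prov <- c("super_id\tslice_index\tmember_cluster_id\tmember_old_id")
  for (sc in superclusters) for (m in sc$members) {
    old <- if (!is.null(m$old_id)) m$old_id else NA_integer_
    prov <- c(prov, paste(sc$super_id, m$slice_index, m$cluster_id, old,
                          sep = "\t"))
  }
  .write_csv_lines(prov, file.path(dir, "provenance.tsv"))
  invisible(dir)
}

#' Summary table of superclusters
#'
#' One row per supercluster with the familiar summary columns.
#'
#' @param superclusters list of `super_cluster` objects
#' @return Data frame with columns `cluster_id`, `frames`, `avg_bottleneck`,
#'   `avg_length`, `max_bottleneck`.
#' @export
supercluster_summary <- function(superclusters) {
  do.call(rbind, lapply(superclusters, function(sc) {
    st <- compute_stats(sc)
    data.frame(cluster_id = sc$super_id, frames = st$n_frames,
               avg_bottleneck = st$avg_bottleneck,
               avg_length = st$avg_length,
               max_bottleneck = st$max_bottleneck)
  }))
}

#' Write the supercluster summary as TSV
#'
#' Columns exactly `cluster_id, frames, avg_bottleneck, avg_length,
#' max_bottleneck`; floats in 6-decimal fixed point.
#'
#' @param superclusters list of `super_cluster` objects
#' @param path output file
#' @return `path`, invisibly.
#' @export
write_supercluster_summary <- function(superclusters, path) {
  tab <- supercluster_summary(superclusters)
  lines <- "cluster_id\tframes\tavg_bottleneck\tavg_length\tmax_bottleneck"
  if (!is.null(tab) && nrow(tab))
    lines <- c(lines, paste(tab$cluster_id, tab$frames,
                            .fmt6(tab$avg_bottleneck), .fmt6(tab$avg_length),
                            .fmt6(tab$max_bottleneck), sep = "\t"))
  .write_csv_lines(lines, path)
  invisible(path)
}
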