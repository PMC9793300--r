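`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analysis configuration
#'
#' All tunable parameters of the divide-and-conquer pipeline, with the
#' standard defaults: probe radius 0.7 Angstrom, clustering threshold 3.0
#' Angstrom, weighting coefficient 2, max output clusters 99999, seed 1,
#' presence filter 2%, Ward merge cutoff 1.0 Angstrom.
#'
#' @param probe_radius minimum admissible clearance (Angstrom)
#' @param clustering_threshold per-slice average-linkage cut height (Angstrom)
#' @param weighting_coefficient cost exponent
#' @param max_output_clusters cap on clusters reported per slice
#' @param seed seed recorded in the run (the pipeline itself is
#'   deterministic; the seed feeds synthetic-data generation)
#' @param start_point explicit starting point (length-3, Angstrom), or NULL
#'   to use `start_selectors`
#' @param start_selectors data frame (`resno`, `name`) of atoms whose
#'   per-frame centroid is the starting point
#' @param slice_size frames per slice; NULL analyses the trajectory in one
#'   slice (the "full run")
#' @param first_frame,last_frame optional global frame range restricting the
#'   analysis (CAVER-style keys); NULL means the whole ensemble
#' @param min_presence per-slice presence filter threshold
#' @param merge_cutoff Ward dendrogram cut height (Angstrom)
#' @param total_frames priority scope of the merged ranking; NULL uses the
#'   ensemble length
#' @param grid_spacing void-grid lattice spacing (Angstrom)
#' @param shell_radius,shell_depth exterior definition, see [detect_params()]
#' @param n_resample_points pathway resampling density
#' @param block_radius_cap see [detect_params()]
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(probe_radius = 0.7, clustering_threshold = 3.0,
                            weighting_coefficient = 2,
                            max_output_clusters = 99999L, seed = 1L,
                            start_point = NULL, start_selectors = NULL,
                            slice_size = NULL, first_frame = NULL,
                            last_frame = NULL, min_presence = 0.02,
                            merge_cutoff = 1.0, total_frames = NULL,
                            grid_spacing = 0.5, shell_radius = 3,
                            shell_depth = 2, n_resample_points = 20L,
                            block_radius_cap = 2.5) {
  structure(list(probe_radius = probe_radius,
                 clustering_threshold = clustering_threshold,
                 weighting_coefficient = weighting_coefficient,
                 max_output_clusters = as.integer(max_output_clusters),
                 seed = as.integer(seed), start_point = start_point,
                 start_selectors = start_selectors, slice_size = slice_size,
                 first_frame = first_frame, last_frame = last_frame,
                 min_presence = min_presence, merge_cutoff = merge_cutoff,
                 total_frames = total_frames, grid_spacing = grid_spacing,
                 shell_radius = shell_radius, shell_depth = shell_depth,
                 n_resample_points = as.integer(n_resample_points),
                 block_radius_cap = block_radius_cap),
            class = "analysis_config")
}

# flat key=value echo of a config (sorted keys; deterministic)
.config_lines <- function(config) {
  vals <- lapply(config, function(v) {
    if (is.null(v)) return(NULL)
    if (is.data.frame(v))
      return(paste(sprintf("%d:%s", v$resno, v$name), collapse = ","))
    paste(format(v, scientific = FALSE, trim = TRUE), collapse = ",")
  })
  vals <- vals[!vapply(vals, is.null, logical(1))]
  paste0(names(vals)[order(names(vals))], "=",
         unlist(vals)[order(names(vals))])
}

#' Read a flat key=value configuration file
#'
#' Keys mirror [analysis_config()] arguments, plus the CAVER-style alias
#' `starting_point_atom` for `start_selectors` (and the CAVER keys
#' `first_frame`/`last_frame` restricting the analysed range). Values with
#' commas become numeric vectors; selectors use `resno:name` pairs separated
#' by commas.
#'
#' @param path configuration file
#' @return An `analysis_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), character(1))
  args <- list()
  for (i in seq_along(keys)) {
    k <- trimws(keys[i]); v <- trimws(vals[i])
    if (k == "starting_point_atom") k <- "start_selectors"  # CAVER-style name
    args[[k]] <- if (k == "start_selectors") {
      parts <- strsplit(strsplit(v, ",")[[1]], ":")
      data.frame(resno = as.integer(vapply(parts, `[`, character(1), 1)),
                 name = vapply(parts, `[`, character(1), 2),
                 stringsAsFactors = FALSE)
    } else if (k == "start_point") {
      as.numeric(strsplit(v, ",")[[1]])
    } else {
      as.numeric(v)
    }
  }
  do.call(analysis_config, args)
}

# per-frame starting points for an ensemble under a config
.start_points <- function(ens, config) {
  if (!is.null(config$start_point))
    return(matrix(config$start_point, nrow = n_frames(ens), ncol = 3L,
                  byrow = TRUE))
  if (is.null(config$start_selectors))
    stop("config needs start_point or start_selectors", call. = FALSE)
  t(vapply(seq_len(n_frames(ens)),
           function(i) compute_start_point(ens, config$start_selectors, i),
           numeric(3)))
}

#' Run the divide-and-conquer pipeline
#'
#' End to end: slice the ensemble (global frame numbering preserved), detect
#' tunnels per frame, cluster each slice, filter clusters by presence,
#' renumber by priority, merge all kept clusters into superclusters and
#' compute their summary statistics. Slices are independent: processing them
#' in any order gives identical results.
#'
#' @param ens a `frame_ensemble`
#' @param config an [analysis_config()]
#' @param out_dir optional output directory; when given, per-slice cluster
#'   files, filtered files with id maps, merged supercluster files, the
#'   summary table, a config echo and a run log are written there
#' @param slice_order optional permutation of slice indices fixing the
#'   processing order (results are identical for any order)
#' @return Object of class `tunnel_run`: list with `config`, `slices`,
#'   `slice_results` (per slice: `clusters`, `kept`, `map`, `n_tunnels`),
#'   `superclusters`, `summary`, `n_frames`.
#' @export
run_pipeline <- function(ens, config = analysis_config(), out_dir = NULL,
                         slice_order = NULL) {
  if (!is.null(config$first_frame) || !is.null(config$last_frame)) {
    fn <- ens$frame_numbers
    ens <- extract_slice(ens, list(
      first_frame = config$first_frame %||% fn[1],
      last_frame = config$last_frame %||% fn[length(fn)]))
  }
  n <- n_frames(ens)
  total_frames <- config$total_frames %||% n
  slice_size <- config$slice_size %||% n
  slices <- slice_frames(n, slice_size)
  offset <- ens$frame_numbers[1] - 1L   # slice bounds are global frames
  slices$first_frame <- slices$first_frame + offset
  slices$last_frame <- slices$last_frame + offset
  if (is.null(slice_order)) slice_order <- slices$slice_index
  stopifnot(setequal(slice_order, slices$slice_index))
  dp <- detect_params(probe_radius = config$probe_radius,
                      weighting_coefficient = config$weighting_coefficient,
                      shell_radius = config$shell_radius,
                      shell_depth = config$shell_depth,
                      grid_spacing = config$grid_spacing,
                      block_radius_cap = config$block_radius_cap)
  cp <- cluster_params(clustering_threshold = config$clustering_threshold,
                       n_resample_points = config$n_resample_points)
  vdw <- ens$atoms$vdw

  slice_results <- vector("list", nrow(slices))
  for (si in slice_order) {
    sp <- slices[slices$slice_index == si, ]
    sub <- extract_slice(ens, sp)
    starts <- .start_points(sub, config)
    tunnels <- list()
    for (i in seq_len(n_frames(sub))) {
      tl <- tryCatch(
        detect_tunnels(frame_coords(sub, i), vdw, starts[i, ], dp,
                       frame_number = sub$frame_numbers[i]),
        error = function(e) stop("stage detect, slice ", si, ", frame ",
                                 sub$frame_numbers[i], ": ",
                                 conditionMessage(e), call. = FALSE))
      tunnels <- c(tunnels, tl)
    }
    n_slice <- n_frames(sub)
    clusters <- cluster_slice(tunnels, cp, slice_index = si,
                              n_slice_frames = n_slice)
    clusters <- head(clusters, config$max_output_clusters)
    kept <- filter_clusters(clusters, config$min_presence, n_slice)
    renum <- renumber_by_priority(kept, n = n_slice,
                                  n_presence_frames = n_slice)
    slice_results[[si]] <- list(spec = sp, n_tunnels = length(tunnels),
                                clusters = clusters,
                                kept = renum$clusters, map = renum$map)
  }

  all_kept <- unlist(lapply(slice_results, `[[`, "kept"), recursive = FALSE)
  superclusters <- merge_superclusters(all_kept, cutoff = config$merge_cutoff,
                                       total_frames = total_frames)
  run <- structure(list(config = config, slices = slices,
                        slice_results = slice_results,
                        superclusters = superclusters,
                        summary = supercluster_summary(superclusters),
                        n_frames = n, total_frames = total_frames),
                   class = "tunnel_run")
  if (!is.null(out_dir)) .write_run(run, out_dir)
  run
}

#' @export
print.tunnel_run <- function(x, ...) {
  cat("tunnel_run:", x$n_frames, "frames in", nrow(x$slices), "slice(s),",
      length(x$superclusters), "supercluster(s)\n")
  if (!is.null(x$summary) && nrow(x$summary)) print(head(x$summary, 10))
  invisible(x)
}

.write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  for (si in run$slices$slice_index) {
    sr <- run$slice_results[[si]]
    sdir <- file.path(out_dir, sprintf("slice_%03d", si))
    write_clusters(sr$clusters, file.path(sdir, "clusters"))
    write_clusters(sr$kept, file.path(sdir, "filtered"))
    map <- sr$map
    .write_csv_lines(
      c("old_id\tnew_id\tpresence\tpriority",
        if (nrow(map)) paste(map$old_id, map$new_id, .fmt6(map$presence),
                             .fmt6(map$priority), sep = "\t")),
      file.path(sdir, "id_map.tsv"))
    log_lines <- c(log_lines, sprintf(
      "slice %d: frames %d-%d, tunnels %d, clusters %d, kept %d",
      si, sr$spec$first_frame, sr$spec$last_frame, sr$n_tunnels,
      length(sr$clusters), length(sr$kept)))
  }
  convert_superclusters_to_caver(run$superclusters,
                                 file.path(out_dir, "merged"))
  write_supercluster_summary(run$superclusters,
                             file.path(out_dir, "summary.tsv"))
  .write_csv_lines(.config_lines(run$config),
                   file.path(out_dir, "config_echo.txt"))
  log_lines <- c(log_lines,
                 sprintf("superclusters: %d", length(run$superclusters)))
  .write_csv_lines(log_lines, file.path(out_dir, "log.txt"))
  invisible(out_dir)
}

#' Compare two pipeline runs on the same ensemble
#'
#' Matches the superclusters of a reference run (typically the full-trajectory
#' analysis) against another run (typically the sliced analysis), reports the
#' per-match frame-set Jaccard and summary-statistic deltas, the length of the
#' initial run of rank agreement among major clusters, and any unmatched
#' reference clusters. Major clusters are those present in at least
#' `major_presence` of the trajectory (default 10%).
#'
#' @param run_a reference `tunnel_run`
#' @param run_b other `tunnel_run`
#' @param tol match tolerance in Angstrom (default: reference merge cutoff)
#' @param major_presence presence threshold defining major clusters
#' @return List with `matches` (data frame: ref_id, other_id, distance,
#'   jaccard, frame and stat deltas), `rank_agreement` (number of leading
#'   major ranks on which both runs agree), `majors_ref`, `unmatched_ref`.
#' @export
compare_runs <- function(run_a, run_b, tol = NULL,
                         major_presence = 0.10) {
  if (run_a$n_frames != run_b$n_frames)
    stop("runs cover different ensembles (", run_a$n_frames, " vs ",
         run_b$n_frames, " frames)", call. = FALSE)
  tol <- tol %||% run_a$config$merge_cutoff
  m <- match_clusterings(run_a$superclusters, run_b$superclusters, tol = tol)
  if (nrow(m)) {
    stats_a <- supercluster_summary(run_a$superclusters)
    stats_b <- supercluster_summary(run_b$superclusters)
    m$frames_ref <- stats_a$frames[match(m$ref_id, stats_a$cluster_id)]
    m$frames_other <- stats_b$frames[match(m$other_id, stats_b$cluster_id)]
    m$d_avg_bottleneck <-
      stats_b$avg_bottleneck[match(m$other_id, stats_b$cluster_id)] -
      stats_a$avg_bottleneck[match(m$ref_id, stats_a$cluster_id)]
    m$d_avg_length <-
      stats_b$avg_length[match(m$other_id, stats_b$cluster_id)] -
      stats_a$avg_length[match(m$ref_id, stats_a$cluster_id)]
  }
  total <- run_a$total_frames
  pres_a <- vapply(run_a$superclusters,
                   function(s) length(s$frames_present) / total, numeric(1))
  majors <- vapply(run_a$superclusters, `[[`, integer(1), "super_id")
  majors <- majors[pres_a >= major_presence]
  # leading ranks on which best matches agree: ref rank i -> other rank i
  best_other <- function(rid) {
    mm <- m[m$ref_id == rid, , drop = FALSE]
    if (!nrow(mm)) return(NA_integer_)
    mm$other_id[which.max(mm$jaccard)]
  }
  agree <- 0L
  for (i in seq_along(majors)) {
    if (identical(best_other(majors[i]), i)) agree <- agree + 1L else break
  }
  unmatched <- setdiff(vapply(run_a$superclusters, `[[`, integer(1),
                              "super_id"), m$ref_id)
  list(matches = m, rank_agreement = agree, majors_ref = majors,
       unmatched_ref = unmatched)
}
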