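#' @title Frame ensembles
#' @description A `frame_ensemble` holds an ordered set of coordinate frames
#'   sharing one topology, in the bio3d convention: `xyz` is an
#'   `n_frames x 3*n_atoms` matrix (columns x1,y1,z1,x2,...), `atoms` is a
#'   data frame with one row per atom (serial, name, resid, resno, element,
#'   vdw), and `frame_numbers` are global, 1-based and contiguous within the
#'   ensemble but need not start at 1 (a slice keeps its global numbering).
#' @param atoms data frame with columns serial, name, resid, resno, element, vdw
#' @param xyz numeric matrix, `n_frames` rows, `3 * nrow(atoms)` columns
#' @param frame_numbers integer vector of global frame numbers
#' @return An object of class `frame_ensemble`.
#' @export
frame_ensemble <- function(atoms, xyz, frame_numbers = seq_len(nrow(xyz))) {
  xyz <- as.matrix(xyz)
  stopifnot(is.data.frame(atoms), ncol(xyz) == 3L * nrow(atoms))
  frame_numbers <- as.integer(frame_numbers)
  if (length(frame_numbers) != nrow(xyz))
    stop("frame_numbers length must equal the number of frames", call. = FALSE)
  if (length(frame_numbers) > 1L && any(diff(frame_numbers) != 1L))
    stop("frame_numbers must be strictly increasing and consecutive", call. = FALSE)
  if (!all(is.finite(xyz))) stop("non-finite coordinates", call. = FALSE)
  if (any(atoms$vdw <= 0)) stop("vdw radii must be positive", call. = FALSE)
  structure(list(atoms = atoms, xyz = xyz, frame_numbers = frame_numbers),
            class = "frame_ensemble")
}

#' @export
print.frame_ensemble <- function(x, ...) {
  cat("frame_ensemble:", n_frames(x), "frames x", nrow(x$atoms), "atoms,",
      "global frames", x$frame_numbers[1], "..",
      x$frame_numbers[n_frames(x)], "\n")
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ens a `frame_ensemble`
#' @return Integer frame count.
#' @export
n_frames <- function(ens) nrow(ens$xyz)

#' Coordinates of one frame
#' @param ens a `frame_ensemble`
#' @param i frame position within the ensemble (1..n_frames), not the global
#'   frame number
#' @return `n_atoms x 3` coordinate matrix in Angstrom.
#' @export
frame_coords <- function(ens, i) {
  matrix(ens$xyz[i, ], ncol = 3L, byrow = TRUE)
}

# ---- reading ---------------------------------------------------------------

#' Read a multi-frame structure into a frame ensemble
#'
#' Two on-disk layouts are supported. `format = "pdb"` reads a standard
#' (possibly multi-model) PDB file: each MODEL block is one frame and all
#' models must contain the same atoms in the same order. `format = "table"`
#' reads a single-model PDB topology plus a plain-text coordinate table with
#' columns `frame,serial,x,y,z` (comma- or whitespace-separated, one row per
#' atom per frame; every frame must list every topology serial).
#'
#' Van der Waals radii are assigned per element from [vdw_radii()]; an unknown
#' element is an error naming the offending atom.
#'
#' @param path path to the PDB file (or the coordinate table for
#'   `format = "table"`)
#' @param format `"pdb"` or `"table"`
#' @param topology for `format = "table"`, path to the single-model PDB that
#'   defines the atoms
#' @param radii optional named numeric vector overriding entries of
#'   [vdw_radii()] (names are element symbols)
#' @return A [frame_ensemble()] with `frame_numbers = 1..n`.
#' @export
read_ensemble <- function(path, format = c("pdb", "table"), topology = NULL,
                          radii = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "pdb") .read_ensemble_pdb(path, radii)
  else .read_ensemble_table(path, topology, radii)
}

.check_model_counts <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_starts <- which(startsWith(rec, "MODEL"))
  if (length(model_starts) == 0L) return(invisible(NULL))
  model_ends <- which(startsWith(rec, "ENDMDL"))
  if (length(model_ends) != length(model_starts))
    stop("PDB parse error: ", length(model_starts), " MODEL records but ",
         length(model_ends), " ENDMDL records", call. = FALSE)
  counts <- vapply(seq_along(model_starts), function(k)
    sum(is_atom[model_starts[k]:model_ends[k]]), integer(1))
  if (length(unique(counts)) > 1L) {
    bad <- which(counts != counts[1])[1]
    stop("PDB parse error: model ", bad, " has ", counts[bad],
         " atoms but model 1 has ", counts[1], call. = FALSE)
  }
  invisible(NULL)
}

.read_ensemble_pdb <- function(path, radii) {
  .check_model_counts(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  atoms <- data.frame(serial = as.integer(at$eleno),
                      name = trimws(at$elety),
                      resid = trimws(at$resid),
                      resno = as.integer(at$resno),
                      element = if (!is.null(at$elesy)) at$elesy else "",
                      stringsAsFactors = FALSE)
  atoms <- .assign_vdw(atoms, radii)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  frame_ensemble(atoms, unclass(xyz))
}

.read_ensemble_table <- function(path, topology, radii) {
  if (is.null(topology))
    stop("format = 'table' requires a `topology` PDB", call. = FALSE)
  topo <- .read_ensemble_pdb(topology, radii)
  if (n_frames(topo) != 1L)
    stop("topology PDB must contain exactly one model", call. = FALSE)
  tab <- data.table::fread(path, header = TRUE)
  need <- c("frame", "serial", "x", "y", "z")
  if (!all(need %in% names(tab)))
    stop("coordinate table must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  serials <- topo$atoms$serial
  frames <- sort(unique(tab$frame))
  if (!identical(frames, seq_along(frames)))
    stop("coordinate table frames must be 1..n without gaps", call. = FALSE)
  data.table::setorderv(tab, c("frame", "serial"))
  if (nrow(tab) != length(frames) * length(serials) ||
      !all(tab$serial == rep(sort(serials), length(frames))))
    stop("every frame must list every topology serial exactly once",
         call. = FALSE)
  ord <- order(serials)  # table rows are serial-sorted within frame
  xyz <- matrix(0, nrow = length(frames), ncol = 3L * length(serials))
  m <- cbind(tab$x, tab$y, tab$z)
  for (f in frames) {
    rows <- m[((f - 1L) * length(serials) + 1L):(f * length(serials)), , drop = FALSE]
    rows[ord, ] <- rows  # back to topology atom order
    xyz[f, ] <- as.vector(t(rows))
  }
  frame_ensemble(topo$atoms, xyz)
}

#' Write an ensemble as a multi-model PDB
#'
#' One MODEL/ENDMDL block per frame, atoms in topology order. Frame numbers
#' are recorded in the MODEL record (global numbering is preserved).
#'
#' @param ens a `frame_ensemble`
#' @param path output path
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(ens, path) {
  a <- ens$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n_frames(ens))) {
    co <- frame_coords(ens, i)
    writeLines(sprintf("MODEL     %4d", ens$frame_numbers[i]), con)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-4s%5d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      a$serial, substr(a$name, 1, 4), substr(a$resid, 1, 4), a$resno,
      co[, 1], co[, 2], co[, 3], a$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# ---- starting point --------------------------------------------------------

#' Tunnel-search starting point from atom selectors
#'
#' The starting point is the unweighted centroid of a small set of atoms,
#' each addressed by residue number and atom name (e.g. CG of residue 106).
#' It is recomputed per frame, so the point follows the structure.
#'
#' @param ens a `frame_ensemble`
#' @param selectors a data frame with columns `resno` and `name`, or a list of
#'   `c(resno, name)` pairs
#' @param frame frame position within the ensemble (default 1)
#' @return Length-3 numeric vector (Angstrom).
#' @export
#' @examples
#' # centroid of four atoms addressed by residue number + atom name
compute_start_point <- function(ens, selectors, frame = 1L) {
  sel <- .normalize_selectors(selectors)
  co <- frame_coords(ens, frame)
  pos <- matrix(0, nrow(sel), 3L)
  for (i in seq_len(nrow(sel))) {
    hit <- which(ens$atoms$resno == sel$resno[i] & ens$atoms$name == sel$name[i])
    if (length(hit) != 1L)
      stop("selector (resno=", sel$resno[i], ", name='", sel$name[i],
           "') matches ", length(hit), " atoms (need exactly 1)", call. = FALSE)
    pos[i, ] <- co[hit, ]
  }
  colMeans(pos)
}

.normalize_selectors <- function(selectors) {
  if (is.data.frame(selectors)) {
    stopifnot(all(c("resno", "name") %in% names(selectors)))
    data.frame(resno = as.integer(selectors$resno),
               name = as.character(selectors$name), stringsAsFactors = FALSE)
  } else {
    data.frame(resno = vapply(selectors, function(s) as.integer(s[[1]]), integer(1)),
               name = vapply(selectors, function(s) as.character(s[[2]]), character(1)),
               stringsAsFactors = FALSE)
  }
}

# ---- slicing ---------------------------------------------------------------

#' Partition a trajectory into contiguous slices
#'
#' Slices are `slice_size` frames each; when `n_frames` is not divisible, the
#' final slice holds the (shorter, never empty) remainder. Frame bounds are
#' global and 1-based: slicing 10000 frames by 1250 gives eight slices
#' 1-1250, 1251-2500, ..., 8751-10000.
#'
#' @param n_frames total number of frames
#' @param slice_size frames per slice (1..n_frames)
#' @return Data frame with columns `slice_index`, `first_frame`, `last_frame`.
#' @export
slice_frames <- function(n_frames, slice_size) {
  n_frames <- as.integer(n_frames); slice_size <- as.integer(slice_size)
  if (slice_size <= 0L) stop("slice_size must be positive", call. = FALSE)
  if (slice_size > n_frames)
    stop("slice_size (", slice_size, ") exceeds n_frames (", n_frames, ")",
         call. = FALSE)
  first <- seq.int(1L, n_frames, by = slice_size)
  last <- pmin(first + slice_size - 1L, n_frames)
  data.frame(slice_index = seq_along(first), first_frame = first,
             last_frame = last)
}

#' Extract one slice of an ensemble
#'
#' The sub-ensemble keeps the GLOBAL frame numbers of its frames; numbering is
#' never restarted at 1 inside a slice. Restarted numbering is precisely the
#' failure mode that breaks merging of per-slice results.
#'
#' @param ens a `frame_ensemble`
#' @param spec one row of [slice_frames()] output, or any list with
#'   `first_frame` and `last_frame`
#' @return A `frame_ensemble` covering `first_frame..last_frame`.
#' @export
extract_slice <- function(ens, spec) {
  ff <- as.integer(spec$first_frame); lf <- as.integer(spec$last_frame)
  fn <- ens$frame_numbers
  if (ff > lf || ff < fn[1] || lf > fn[length(fn)])
    stop("slice [", ff, "-", lf, "] out of ensemble range [", fn[1], "-",
         fn[length(fn)], "]", call. = FALSE)
  idx <- match(ff:lf, fn)
  frame_ensemble(ens$atoms, ens$xyz[idx, , drop = FALSE], frame_numbers = ff:lf)
}

#' Concatenate slices back into one ensemble
#'
#' Inverse of [extract_slice()]: slices must share one topology and have
#' contiguous global frame numbers.
#'
#' @param slices list of `frame_ensemble` objects
#' @return A single `frame_ensemble`.
#' @export
bind_slices <- function(slices) {
  stopifnot(length(slices) >= 1L)
  ord <- order(vapply(slices, function(s) s$frame_numbers[1], integer(1)))
  slices <- slices[ord]
  xyz <- do.call(rbind, lapply(slices, `[[`, "xyz"))
  fn <- unlist(lapply(slices, `[[`, "frame_numbers"))
  frame_ensemble(slices[[1]]$atoms, xyz, frame_numbers = fn)
}
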