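test_that("multi-model PDB round trip preserves frames, atoms and numbering", {
  spec <- small_shell(n_frames = 3, jitter = 0.05)
  ens <- build_ensemble(spec)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble_pdb(ens, f)
  back <- read_ensemble(f, format = "pdb")
  expect_equal(n_frames(back), 3L)
  expect_equal(nrow(back$atoms), nrow(ens$atoms))
  expect_equal(back$frame_numbers, 1:3)
  # PDB stores 3 decimals; coordinates agree to that precision
  expect_equal(frame_coords(back, 2), frame_coords(ens, 2), tolerance = 1e-3)
  # pseudo-atoms are carbon, so radii survive the round trip
  expect_equal(back$atoms$vdw, ens$atoms$vdw)
})

test_that("single-model PDB yields a one-frame ensemble", {
  ens <- build_ensemble(small_shell(n_frames = 1))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble_pdb(ens, f)
  expect_equal(n_frames(read_ensemble(f)), 1L)
})

test_that("a model with a missing atom is a parse error naming the model", {
  ens <- build_ensemble(small_shell(n_frames = 3))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble_pdb(ens, f)
  lines <- readLines(f)
  atom_lines <- which(startsWith(lines, "ATOM"))
  # drop one atom from the second model
  n_at <- nrow(ens$atoms)
  writeLines(lines[-atom_lines[n_at + 5L]], f)
  expect_error(read_ensemble(f), "model 2")
})

test_that("unknown element is an error naming the atom", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    sprintf("ATOM  %5d  C   UNK %5d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            1:4, 1:4, c(0, 3, 0, 0), c(0, 0, 3, 0), c(0, 0, 0, 3)),
    "ATOM      5  XQ  UNK     5       1.000   1.000   1.000  1.00  0.00          XQ",
    "END"), f)
  expect_error(read_ensemble(f), "serial 5")
})

test_that("plain-text coordinate table reader matches the PDB reader", {
  spec <- small_shell(n_frames = 2, jitter = 0.05)
  ens <- build_ensemble(spec)
  topo <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble_pdb(extract_slice(ens, list(first_frame = 1, last_frame = 1)),
                     topo)
  tab <- withr::local_tempfile(fileext = ".csv")
  rows <- do.call(rbind, lapply(1:2, function(f) {
    co <- frame_coords(ens, f)
    data.frame(frame = f, serial = ens$atoms$serial, x = co[, 1], y = co[, 2],
               z = co[, 3])
  }))
  write.csv(rows, tab, row.names = FALSE, quote = FALSE)
  back <- read_ensemble(tab, format = "table", topology = topo)
  expect_equal(n_frames(back), 2L)
  expect_equal(frame_coords(back, 2), frame_coords(ens, 2), tolerance = 1e-6)
})

test_that("start point is the centroid of the selected atoms", {
  # four atoms at unit-cube corners
  atoms <- data.frame(serial = 1:4, name = c("CG", "CD2", "N", "N"),
                      resid = "UNK", resno = 1:4, element = "C", vdw = 1.7)
  xyz <- matrix(as.vector(t(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                                  c(1, 1, 0)))), nrow = 1)
  ens <- frame_ensemble(atoms, xyz)
  sel <- data.frame(resno = 1:4, name = c("CG", "CD2", "N", "N"))
  expect_equal(compute_start_point(ens, sel), c(0.5, 0.5, 0))
  # one selector: that atom's position
  expect_equal(compute_start_point(ens, data.frame(resno = 2, name = "CD2")),
               c(1, 0, 0))
  # permutation invariance
  expect_equal(compute_start_point(ens, sel[c(3, 1, 4, 2), ]),
               compute_start_point(ens, sel))
  # translation equivariance
  ens2 <- frame_ensemble(atoms, xyz + rep(c(2, -1, 5), 4))
  expect_equal(compute_start_point(ens2, sel),
               compute_start_point(ens, sel) + c(2, -1, 5))
})

test_that("centroid of a four-atom active-site selection equals the coordinate mean", {
  # CG/CD2/N/N selection on a fixture with known coordinates
  pos <- rbind(c(12.1, 3.4, -2.0), c(10.8, 5.5, 0.3),
               c(14.2, 4.1, 1.7), c(11.5, 2.2, 2.9))
  atoms <- data.frame(serial = 1:4, name = c("CG", "CD2", "N", "N"),
                      resid = c("ASP", "TRP", "PHE", "LEU"),
                      resno = c(106L, 107L, 168L, 246L), element = "C",
                      vdw = 1.7)
  ens <- frame_ensemble(atoms, matrix(as.vector(t(pos)), nrow = 1))
  sel <- data.frame(resno = c(106, 107, 168, 246),
                    name = c("CG", "CD2", "N", "N"))
  expect_equal(compute_start_point(ens, sel), colMeans(pos))
})

test_that("ambiguous or unmatched selectors are errors naming the selector", {
  atoms <- data.frame(serial = 1:4, name = c("CA", "CA", "CB", "N"),
                      resid = "UNK", resno = c(1L, 1L, 1L, 2L),
                      element = "C", vdw = 1.7)
  ens <- frame_ensemble(atoms, matrix(rnorm(12), nrow = 1))
  expect_error(compute_start_point(ens, data.frame(resno = 1, name = "CA")),
               "matches 2")
  expect_error(compute_start_point(ens, data.frame(resno = 9, name = "CA")),
               "matches 0")
})

test_that("slice_frames reproduces the canonical 10000/1250 slicing", {
  s <- slice_frames(10000, 1250)
  expect_equal(nrow(s), 8L)
  expect_equal(s$first_frame, seq(1, 8751, by = 1250))
  expect_equal(s$last_frame, seq(1250, 10000, by = 1250))
})

test_that("slice_frames handles identity and remainder cases", {
  expect_equal(slice_frames(10, 10),
               data.frame(slice_index = 1L, first_frame = 1L, last_frame = 10L))
  s <- slice_frames(10, 4)
  expect_equal(s$first_frame, c(1L, 5L, 9L))
  expect_equal(s$last_frame, c(4L, 8L, 10L))
  expect_error(slice_frames(10, 0), "positive")
  expect_error(slice_frames(10, 11), "exceeds")
})

test_that("slices are disjoint, cover the trajectory, and keep global numbering", {
  for (case in list(c(100, 30), c(64, 8), c(7, 7))) {
    s <- slice_frames(case[1], case[2])
    frames <- unlist(mapply(seq, s$first_frame, s$last_frame,
                            SIMPLIFY = FALSE))
    expect_equal(frames, seq_len(case[1]))  # disjoint cover in order
  }
})

test_that("extract_slice keeps global frame numbers and rejects bad ranges", {
  ens <- build_ensemble(small_shell(n_frames = 10, jitter = 0.05))
  sl <- extract_slice(ens, list(first_frame = 4, last_frame = 7))
  expect_equal(sl$frame_numbers, 4:7)
  expect_equal(frame_coords(sl, 1), frame_coords(ens, 4))
  full <- extract_slice(ens, list(first_frame = 1, last_frame = 10))
  expect_identical(full$xyz, ens$xyz)
  expect_error(extract_slice(ens, list(first_frame = 11, last_frame = 12)),
               "out of ensemble range")
})

test_that("concatenating extracted slices reproduces the ensemble exactly", {
  ens <- build_ensemble(small_shell(n_frames = 10, jitter = 0.05))
  specs <- slice_frames(n_frames(ens), 3)
  parts <- lapply(seq_len(nrow(specs)), function(i)
    extract_slice(ens, specs[i, ]))
  back <- bind_slices(parts)
  expect_identical(back$xyz, ens$xyz)
  expect_identical(back$frame_numbers, ens$frame_numbers)
})
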