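test_that("CSV round trip preserves tracks and lineage", {
  sc <- simulate_lineages(wt_small(), 5, seed = 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_tracks_csv(sc$tracks_observed, f)
  back <- read_tracks_csv(f)
  orig <- sc$tracks_observed
  expect_setequal(back$lineage$cell_id, orig$lineage$cell_id)
  m <- match(orig$lineage$cell_id, back$lineage$cell_id)
  expect_identical(back$lineage$parent_id[m], orig$lineage$parent_id)
  expect_identical(back$lineage$end_reason[m], orig$lineage$end_reason)
  expect_identical(back$lineage$fate[m], orig$lineage$fate)
  expect_equal(nrow(back$points), nrow(orig$points))
  expect_lt(max(abs(back$points$x_um - orig$points$x_um)), 1e-6)
  expect_lt(max(abs(back$points$y_um - orig$points$y_um)), 1e-6)
  expect_identical(back$points$myog, orig$points$myog)
})

test_that("CSV write/read/write is byte-identical", {
  sc <- simulate_lineages(wt_small(), 3, seed = 2)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_tracks_csv(sc$tracks_observed, f1)
  write_tracks_csv(read_tracks_csv(f1), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("CSV reader validates schema and structure", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cell_id,frame,t_min", "a,0,0"), f)
  expect_error(read_tracks_csv(f), "missing mandatory column")

  # two-row minimal file
  writeLines(c("cell_id,parent_id,frame,t_min,x_um,y_um,z_um,myog,fibre_contact",
               "a,,0,0,0,0,0,unknown,unknown",
               "a,,1,10,1,0,0,weird,unknown"), f)
  ts <- read_tracks_csv(f)
  expect_equal(nrow(ts$points), 2)
  expect_identical(ts$points$myog, c("unknown", "unknown"))

  # parent cycle
  writeLines(c("cell_id,parent_id,frame,t_min,x_um,y_um,z_um,myog,fibre_contact",
               "a,b,0,0,0,0,0,unknown,unknown",
               "b,a,0,0,1,0,0,unknown,unknown"), f)
  expect_error(read_tracks_csv(f), "cycle|daughters")

  # non-monotone frames
  writeLines(c("cell_id,parent_id,frame,t_min,x_um,y_um,z_um,myog,fibre_contact",
               "a,,1,10,0,0,0,unknown,unknown",
               "a,,1,10,1,0,0,unknown,unknown"), f)
  expect_error(read_tracks_csv(f), "non-monotone")
})

test_that("empty collection writes a header-only re-readable file", {
  ts <- track_set(tibble::tibble(cell_id = character(), frame = integer(),
                                 t_min = numeric(), x_um = numeric(),
                                 y_um = numeric()), dt = 10)
  f <- withr::local_tempfile(fileext = ".csv")
  write_tracks_csv(ts, f)
  expect_length(readLines(f), 1L)
  expect_equal(nrow(read_tracks_csv(f)$points), 0L)
})

test_that("XML linear chain yields one track without divisions", {
  f <- xml_chain(withr::local_tempfile(fileext = ".xml"))
  ts <- read_tracks_xml(f)
  expect_equal(nrow(ts$lineage), 1L)
  expect_equal(nrow(ts$points), 5L)
  expect_equal(sum(ts$lineage$end_reason == "division"), 0L)
  expect_equal(ts$dt, 10)
  expect_equal(ts$points$x_um, as.numeric(0:4))
})

test_that("XML branch yields a division with daughters born at the branch", {
  f <- xml_division(withr::local_tempfile(fileext = ".xml"))
  ts <- read_tracks_xml(f)
  expect_equal(nrow(ts$lineage), 3L)
  expect_equal(sum(ts$lineage$end_reason == "division"), 1L)
  d <- ts$lineage[!is.na(ts$lineage$parent_id), ]
  expect_equal(nrow(d), 2L)
  mother_end <- ts$lineage$end_t[ts$lineage$end_reason == "division"]
  expect_equal(d$birth_t, rep(mother_end, 2))
})

test_that("a spot with more than two daughters is a structural error", {
  f <- xml_division(withr::local_tempfile(fileext = ".xml"), n_daughters = 3)
  expect_error(read_tracks_xml(f), "more than 2 daughters.*4")
})

test_that("malformed XML raises a parse error", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines("<TrackMate><Model>", f)
  expect_error(read_tracks_xml(f), "malformed XML")
  writeLines("<TrackMate><Model></Model></TrackMate>", f)
  expect_error(read_tracks_xml(f), "Spot")
})

test_that("XML write/read round trip preserves structure and positions", {
  sc <- simulate_lineages(wt_small(), 4, seed = 3)
  f <- withr::local_tempfile(fileext = ".xml")
  write_tracks_xml(sc$tracks_observed, f)
  back <- read_tracks_xml(f)
  orig <- sc$tracks_observed
  expect_equal(nrow(back$lineage), nrow(orig$lineage))
  expect_equal(sum(back$lineage$end_reason == "division"),
               sum(orig$lineage$end_reason == "division"))
  a <- back$points[order(back$points$frame, back$points$x_um), ]
  b <- orig$points[order(orig$points$frame, orig$points$x_um), ]
  expect_lt(max(abs(a$x_um - b$x_um)), 1e-6)
  expect_lt(max(abs(a$y_um - b$y_um)), 1e-6)
})

test_that("division count equals leaves minus roots in full binary trees", {
  for (seed in 1:3) {
    sc <- simulate_lineages(wt_small(), 6, seed = seed)
    li <- sc$tracks_true$lineage
    n_div <- sum(li$end_reason == "division")
    n_root <- sum(is.na(li$parent_id))
    n_leaf <- sum(!(li$cell_id %in% li$parent_id))
    expect_equal(n_div, n_leaf - n_root)
    expect_equal(n_div, nrow(sc$truth$divisions))
  }
})

test_that("gaps longer than max_gap split segments", {
  pts <- tibble::tibble(cell_id = "a", frame = c(0:3, 10:12),
                        t_min = c(0:3, 10:12) * 10,
                        x_um = 0, y_um = 0, z_um = 0)
  ts <- track_set(pts, dt = 10)
  seg <- track_segments(ts, max_gap = 3)
  expect_equal(length(unique(seg$segment)), 2L)
  # short gap does not split, but is flagged
  pts2 <- tibble::tibble(cell_id = "a", frame = c(0, 1, 3),
                         t_min = c(0, 1, 3) * 10, x_um = 0, y_um = 0,
                         z_um = 0)
  seg2 <- track_segments(track_set(pts2, dt = 10), max_gap = 3)
  expect_equal(length(unique(seg2$segment)), 1L)
  expect_true(all(seg2$has_gap))
})

test_that("scene exported with a fixed seed reads back identically", {
  sc <- simulate_lineages(wt_small(), 4, seed = 1)
  d <- withr::local_tempdir()
  export_scene(sc, d)
  inp <- import_scene(d)
  orig <- sc$tracks_observed
  m <- match(orig$lineage$cell_id, inp$tracks$lineage$cell_id)
  expect_identical(inp$tracks$lineage$fate[m], orig$lineage$fate)
  expect_identical(inp$tracks$lineage$end_reason[m], orig$lineage$end_reason)
  expect_lt(max(abs(inp$tracks$points$x_um - orig$points$x_um)), 1e-6)
})
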