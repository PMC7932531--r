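test_that("PressureCSV parses frames in order and applies the range rule", {
  dir <- withr::local_tempdir()
  csv <- write_tiny_pressure_csv(dir, rbind(c(100, 100), c(100, 100), c(100, 100)))
  rec <- read_pressure_csv(csv)
  expect_s3_class(rec, "qsf_recording")
  expect_equal(dim(rec$frames), c(3L, 2L))
  expect_true(all(rec$frames == 100))
  expect_equal(rec$sample_rate, 50)

  # sub-floor values become 0; over-ceiling values clip to 600 and are counted
  csv2 <- write_tiny_pressure_csv(dir, rbind(c(12, 100), c(750, 19.99)))
  expect_message(rec2 <- read_pressure_csv(csv2), "1 sample\\(s\\) clipped")
  expect_equal(rec2$frames[1, ], c(s001 = 0, s002 = 100))
  expect_equal(rec2$frames[2, ], c(s001 = 600, s002 = 0))
  expect_equal(rec2$meta$n_clipped, 1L)
})

test_that("range rule is idempotent and boundary-inclusive", {
  x <- c(0, 12, 19.999, 20, 100, 599.9, 600, 601, 1e4)
  once <- clip_pressure_range(x)
  twice <- clip_pressure_range(as.numeric(once))
  expect_equal(as.numeric(once), as.numeric(twice))
  expect_equal(as.numeric(once), c(0, 0, 0, 20, 100, 599.9, 600, 600, 600))
  expect_equal(attr(twice, "n_clipped"), 0L)
})

test_that("malformed PressureCSV input errors name the offending line", {
  dir <- withr::local_tempdir()
  csv <- write_tiny_pressure_csv(dir, rbind(c(100, 100), c(100, 100)))
  lines <- readLines(csv)

  # wrong frame width
  bad <- c(lines[1:5], "0.02,50")
  writeLines(bad, file.path(dir, "bad1.csv"))
  expect_error(read_pressure_csv(file.path(dir, "bad1.csv")),
               "line 6.*does not match sensor count",
               class = "qsf_parse_error")

  # non-numeric value
  bad <- c(lines[1:5], "0.02,abc,100")
  writeLines(bad, file.path(dir, "bad2.csv"))
  expect_error(read_pressure_csv(file.path(dir, "bad2.csv")),
               "line 6.*non-numeric", class = "qsf_parse_error")

  # broken header
  writeLines(c("# sample_rate_hz=oops", lines[-2]), file.path(dir, "bad3.csv"))
  expect_error(read_pressure_csv(file.path(dir, "bad3.csv")),
               "malformed header", class = "qsf_parse_error")
})

test_that("PressureCSV round-trips recordings written by the package", {
  dir <- withr::local_tempdir()
  set.seed(11)
  vals <- matrix(runif(20, 30, 500), 10, 2)
  csv <- write_tiny_pressure_csv(dir, vals)
  rec <- read_pressure_csv(csv)
  out <- file.path(dir, "roundtrip.csv")
  write_pressure_csv(rec, out)
  rec2 <- read_pressure_csv(out)
  expect_identical(rec2$frames, rec$frames)
  expect_identical(rec2$meta$t_s, rec$meta$t_s)
})

test_that("layout validation rejects degenerate and duplicate sensors", {
  df <- data.frame(sensor_id = c(1, 1), x_min_mm = 0, y_min_mm = 0,
                   x_max_mm = 10, y_max_mm = 10)
  expect_error(sensor_layout(df), "unique", class = "qsf_layout_error")
  df2 <- data.frame(sensor_id = 1, x_min_mm = 0, y_min_mm = 0,
                    x_max_mm = 0, y_max_mm = 10)
  expect_error(sensor_layout(df2), "degenerate", class = "qsf_layout_error")
  expect_error(sensor_layout(df2[0, ]), "at least one",
               class = "qsf_layout_error")
})

test_that("grid sequences round-trip bit-exactly through text files", {
  dir <- withr::local_tempdir()
  set.seed(3)
  for (trial in 1:5) {
    g <- regular_grid(runif(1, -20, 0), runif(1, -20, 0), 5,
                      sample(2:6, 1), sample(2:6, 1))
    frames <- matrix(runif(4 * g$n_rows * g$n_cols, 0, 600),
                     4, g$n_rows * g$n_cols)
    s <- grid_sequence(g, frames)
    p <- file.path(dir, sprintf("seq%d.csv", trial))
    write_grid_sequence(s, p)
    s2 <- read_grid_sequence(p)
    expect_identical(s2$frames, s$frames)
    expect_identical(s2$timestamps, s$timestamps)
    expect_equal(unclass(s2$grid), unclass(s$grid))
  }

  # 1x1 grid, single frame
  s <- grid_sequence(regular_grid(0, 0, 5, 1, 1), matrix(200, 1, 1))
  p <- file.path(dir, "one.csv")
  write_grid_sequence(s, p)
  expect_equal(read_grid_sequence(p)$frames[1, 1], 200)
})

test_that("grid sequence constructor rejects invalid input", {
  g <- regular_grid(0, 0, 5, 2, 2)
  expect_error(grid_sequence(g, list()), "empty sequence", class = "qsf_grid_error")
  expect_error(grid_sequence(g, matrix(1, 2, 3)), "shape", class = "qsf_grid_error")
  expect_error(grid_sequence(g, matrix(1, 2, 4), timestamps = c(1, 1)),
               "strictly increasing", class = "qsf_grid_error")
  expect_error(regular_grid(0, 0, 0, 2, 2), "positive", class = "qsf_grid_error")
})

test_that("area tables validate keys, completeness and sign", {
  tab <- as_area_table(data.frame(subject = c("a", "b"), side = "left",
                                  FI = c(1.5, 0), TCCI = c(0, 0)))
  expect_s3_class(tab, "qsf_area_table")
  expect_equal(nrow(tab), 2L)

  dup <- data.frame(subject = c("a", "a"), side = "left", FI = 1)
  expect_error(as_area_table(dup), "duplicate", class = "qsf_area_error")

  nas <- data.frame(subject = c("a", "b"), side = "left",
                    FI = c(1, NA), CADCAM = c(1, 2))
  expect_error(as_area_table(nas), "missing FI area.*b left",
               class = "qsf_area_error")

  neg <- data.frame(subject = "a", side = "left", FI = -2)
  expect_error(as_area_table(neg), "negative", class = "qsf_area_error")
})

test_that("area tables read from CSV files", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "areas.csv")
  writeLines(c("subject,side,FI,TCCI",
               "S01,left,10.25,0",
               "S01,right,3.5,1.25"), p)
  tab <- read_area_table(p)
  expect_equal(tab$FI, c(10.25, 3.5))
  expect_equal(tab$TCCI, c(0, 1.25))
})
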