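test_that("reader parses the tab-delimited dialect, 9 or 10 columns", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste(c("inclination", "colony", "temperature", "humidity", "date",
            "individual", "frame", "time", "x", "y"), collapse = "\t"),
    "0\tA\t25\t50\t2012-06-01\t3\t1\t0\t0\t0",
    "0\tA\t25\t50\t2012-06-01\t3\t2\t0.04\t0.001\t0"), f)
  tr <- read_trajectory_file(f)
  expect_s3_class(tr, "bw_trajectory")
  expect_length(tr, 2L)
  expect_equal(sqrt(diff(tr$x)^2 + diff(tr$y)^2), 0.001)
  expect_equal(tr$t, c(0, 0.04))
  expect_equal(tr$meta$inclination_label, "0")
  expect_equal(tr$meta$individual_index, "3")

  # 9-column positional layout (no frame column), header without names match
  f9 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(paste0("c", 1:9), collapse = "\t"),
               "0\tA\t25\t50\t2012-06-01\t3\t0\t0\t0",
               "0\tA\t25\t50\t2012-06-01\t3\t0.04\t0.001\t0"), f9)
  tr9 <- read_trajectory_file(f9)
  expect_equal(tr9$t, c(0, 0.04))
  expect_equal(tr9$x, c(0, 0.001))
})

test_that("reader tolerates trailing tabs and reports parse errors by line", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("inclination\tcolony\ttemperature\thumidity\tdate\tindividual\tframe\ttime\tx\ty\t",
               "0\tA\t25\t50\td\t1\t1\t0\t0\t0\t",
               "0\tA\t25\t50\td\t1\t2\t0.04\t0.001\t0\t"), f)
  tr <- read_trajectory_file(f)
  expect_equal(tr$x, c(0, 0.001))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("inclination\tcolony\ttemperature\thumidity\tdate\tindividual\tframe\ttime\tx\ty",
               "0\tA\t25\t50\td\t1\t1\t0\t0\t0",
               "0\tA\t25\t50\td\t1\t2\t0.04\tNA\t0"), bad)
  expect_error(read_trajectory_file(bad), "line 3")
  one <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("h\tx\ty", "0\t0\t0"), one)
  expect_error(read_trajectory_file(one), "2 data rows")
})

test_that("write -> read round trip preserves coordinates and metadata", {
  set.seed(3)
  tr <- trajectory(cumsum(rnorm(50, 0, 1e-3)), cumsum(rnorm(50, 0, 1e-3)),
                   (0:49) * 0.04,
                   meta = list(inclination_label = "0.47", colony_label = "C",
                               temperature = 27.5, humidity = 50,
                               date = "2012-05-29", individual_index = "12"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory_file(tr, f)
  back <- read_trajectory_file(f)
  expect_equal(back$x, tr$x, tolerance = 1e-9)
  expect_equal(back$y, tr$y, tolerance = 1e-9)
  expect_equal(back$t, tr$t, tolerance = 1e-9)
  expect_equal(back$meta$inclination_label, "0.47")
  expect_equal(back$meta$colony_label, "C")
  expect_equal(back$meta$individual_index, "12")
  expect_true(file.exists(paste0(f, ".json")))
})

test_that("trim_start finds the first point 1 cm from the dropping site", {
  # points along +x at 2 mm spacing: 6th point is at exactly 0.010
  tr <- trajectory(0.002 * (0:9), rep(0, 10), 0.04 * (0:9))
  tt <- trim_start(tr, 0.01)
  expect_equal(tt$trim_index, 6L)
  expect_equal(tt$x[1L], 0.010)
  expect_equal(tt$meta$origin, c(0, 0))
  # idempotent at the same d
  expect_equal(trim_start(tt, 0.01)$x, tt$x)

  tr2 <- trajectory(c(0, 0.02, 0.04), c(0, 0, 0), c(0, 1, 2))
  expect_equal(trim_start(tr2, 0.01)$x[1L], 0.02)
  tr3 <- trajectory(c(0, 0.003, 0.005), c(0, 0, 0), c(0, 1, 2))
  expect_error(trim_start(tr3, 0.01), "never reaches")
})

test_that("truncate_exit cuts at the first sample outside the circle", {
  tr <- trajectory(rep(0, 30), 0.01 * (0:29), 0.04 * (0:29))
  tt <- truncate_exit(tr, R = 0.2, center = c(0, 0))
  expect_false(tt$censored)
  expect_length(tt, 22L)              # start + 21 steps, last at 0.21 m
  expect_equal(max(tt$y), 0.21)
  dist <- sqrt(tt$x^2 + tt$y^2)
  expect_equal(sum(dist > 0.2), 1L)   # never two samples outside

  small <- trajectory(c(0, 0.05, 0.08), c(0, 0.05, 0), c(0, 1, 2))
  cs <- truncate_exit(small, R = 0.2, center = c(0, 0))
  expect_true(cs$censored)
  expect_length(cs, 3L)

  jump <- trajectory(c(0, 0.3), c(0, 0), c(0, 1))
  expect_length(truncate_exit(jump, R = 0.2, center = c(0, 0)), 2L)
})

test_that("path length, duration and mean speed", {
  tr <- trajectory(c(0, 0.01, 0.02), c(0, 0, 0), c(0, 1, 2))
  expect_equal(path_length_and_speed(tr),
               list(length = 0.02, duration = 2, mean_speed = 0.01))
  still <- trajectory(c(0, 0, 0) + 0.1, c(0.2, 0.2, 0.2), c(0, 2, 5))
  expect_equal(path_length_and_speed(still)$length, 0)
  expect_equal(path_length_and_speed(still)$mean_speed, 0)
  # densely sampled unit-speed circle arc: length within 0.1% of arc length
  th <- seq(0, pi / 2, length.out = 2000)
  arc <- trajectory(cos(th), sin(th), th)
  expect_equal(path_length_and_speed(arc)$length, pi / 2, tolerance = 1e-3)
})
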