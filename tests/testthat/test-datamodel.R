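test_that("dataset writing and reading round-trips field for field", {
  d <- random_dataset(3, seed = 7, annotate = TRUE)
  dir <- withr::local_tempdir()
  mf <- write_dataset(d, dir)
  d2 <- read_dataset(mf)
  expect_equal(length(d2$samples), 3)
  expect_equal(d2$class_count, d$class_count)
  for (i in 1:3) {
    s1 <- d$samples[[i]]; s2 <- d2$samples[[i]]
    expect_identical(s2$sample_id, s1$sample_id)
    expect_identical(s2$label, s1$label)
    expect_equal(s2$video_stream, s1$video_stream, tolerance = 1e-9)
    expect_equal(s2$sensor_stream, s1$sensor_stream, tolerance = 1e-9)
    expect_equal(s2$annotation, s1$annotation)
    expect_equal(s2$video_rate_hz, s1$video_rate_hz)
  }
})

test_that("write -> read -> write is byte-identical and counts files", {
  d <- random_dataset(1, seed = 3)
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  mf1 <- write_dataset(d, dir1)
  expect_length(readLines(mf1), 1)             # one manifest line
  expect_length(list.files(dir1, pattern = "csv$"), 2)  # two stream CSVs
  mf2 <- write_dataset(read_dataset(mf1), dir2)
  expect_identical(readLines(mf1), readLines(mf2))
  # class count survives the trip in the sidecar
  d5 <- random_dataset(5, C = 5, seed = 9)
  dir5 <- withr::local_tempdir()
  meta <- jsonlite::fromJSON(file.path({write_dataset(d5, dir5); dir5},
                                       "dataset.meta.json"))
  expect_equal(meta$class_count, 5)
})

test_that("round-trip identity holds across many random datasets", {
  dir <- withr::local_tempdir()
  for (k in 1:20) {
    d <- random_dataset(2, C = 2 + k %% 3, seed = 100 + k,
                        Tv = 3 + k %% 5, Ts = 4 + k %% 7,
                        annotate = k %% 2 == 0)
    sub <- file.path(dir, paste0("d", k))
    d2 <- read_dataset(write_dataset(d, sub))
    for (i in seq_along(d$samples)) {
      expect_equal(d2$samples[[i]]$video_stream, d$samples[[i]]$video_stream,
                   tolerance = 1e-9)
      expect_equal(d2$samples[[i]]$sensor_stream, d$samples[[i]]$sensor_stream,
                   tolerance = 1e-9)
    }
  }
})

test_that("reading reports missing files, bad labels and bad cells", {
  d <- random_dataset(2, seed = 5)
  dir <- withr::local_tempdir()
  mf <- write_dataset(d, dir)
  # empty manifest -> empty dataset
  dir0 <- withr::local_tempdir()
  write_dataset(sequence_dataset(list(), 4), dir0)
  d0 <- read_dataset(file.path(dir0, "dataset.jsonl"))
  expect_length(d0$samples, 0)
  expect_error(attnseq_fit(d0, tiny_config()), "empty")
  # missing stream file names the sample
  file.remove(file.path(dir, "r002_sensor.csv"))
  expect_error(read_dataset(mf), "r002")
  # label >= class_count is a schema error
  dir2 <- withr::local_tempdir()
  mf2 <- write_dataset(d, dir2)
  meta <- file.path(dir2, "dataset.meta.json")
  m <- jsonlite::fromJSON(meta); m$class_count <- 1
  jsonlite::write_json(m, meta, auto_unbox = TRUE)
  expect_error(read_dataset(mf2), "class_count")
  # NaN cell is a parse error naming the row
  dir3 <- withr::local_tempdir()
  mf3 <- write_dataset(d, dir3)
  csv <- file.path(dir3, "r001_video.csv")
  lines <- readLines(csv); lines[3] <- sub(",[^,]*$", ",NaN", lines[3])
  writeLines(lines, csv)
  expect_error(read_dataset(mf3), "row 2")
})

test_that("resample_stream interpolates linearly and conserves duration", {
  x <- matrix(rnorm(12), 6, 2)
  expect_identical(resample_stream(x, 10, 10), x)
  # constant stays constant at any rate
  const <- matrix(2.5, 8, 3)
  expect_true(all(abs(resample_stream(const, 40, 17) - 2.5) < 1e-12))
  # hand-computed ramp: 0,1,2,3 @ 4 Hz -> 2 Hz grid spans 0..0.75 s
  r <- resample_stream(matrix(0:3), 4, 2)
  expect_equal(nrow(r), 2)
  expect_equal(as.vector(r), c(0, 3), tolerance = 1e-12)
  # exactness on random affine signals, and duration conservation
  for (k in 1:25) {
    set_global_seed(200 + k)
    T0 <- sample(3:40, 1); d <- sample(1:3, 1)
    src <- runif(1, 5, 120); dst <- runif(1, 5, 120)
    a <- rnorm(d); b <- rnorm(d)
    t <- (seq_len(T0) - 1) / src
    X <- outer(t, a) + matrix(b, T0, d, byrow = TRUE)
    Y <- resample_stream(X, src, dst)
    t2 <- seq(0, t[T0], length.out = nrow(Y))
    expect_lt(max(abs(Y - (outer(t2, a) + matrix(b, nrow(Y), d, byrow = TRUE)))),
              1e-9)
    expect_lt(abs((nrow(Y) - 1) / dst - (T0 - 1) / src), 1 / dst + 1 / src)
  }
  expect_error(resample_stream(matrix(1, 1, 2), 10, 20), "single")
})

test_that("global seeding makes pipelines reproducible and distinct", {
  spec <- tiny_spec(seed = 42)
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  write_dataset(generate_dataset(spec), dir1)
  write_dataset(generate_dataset(spec), dir2)
  expect_identical(readLines(file.path(dir1, "dataset.jsonl")),
                   readLines(file.path(dir2, "dataset.jsonl")))
  v1 <- generate_dataset(tiny_spec(seed = 1))$samples[[1]]$video_stream
  v2 <- generate_dataset(tiny_spec(seed = 2))$samples[[1]]$video_stream
  expect_gt(max(abs(v1 - v2)), 0)
  # the seed is carried through fit and into the report
  d <- generate_dataset(tiny_spec(seed = 3))
  fit <- attnseq_fit(d, tiny_config(seed = 17))
  expect_equal(evaluate_model(fit, d)$seed, 17L)
})

test_that("configuration files round-trip through YAML and JSON", {
  cfg <- tiny_config(relevance = list(R = diag(3) * 0.5))
  for (ext in c("yaml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_run_config(cfg, path)
    cfg2 <- read_run_config(path)
    expect_equal(unclass(cfg2), unclass(cfg), tolerance = 1e-12)
  }
  expect_error(attnseq_config(d_v = 3, d_s = 2, class_count = 1), "class_count")
  expect_error(tiny_config(dropout = 1), "dropout")
  expect_error(tiny_config(lambda_reg = -1), "lambda_reg")
})
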