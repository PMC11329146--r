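test_that("a minimal well-formed CSV reads into a valid panel", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("province,region,year,count",
               "A,R1,2011,10", "A,R1,2012,9", "A,R1,2013,8"), f)
  p <- read_panel(f)
  expect_s3_class(p, "license_panel")
  expect_equal(panel_provinces(p), "A")
  expect_equal(panel_years(p), 2011:2013)
  expect_equal(p$count, c(10L, 9L, 8L))
})

test_that("validation rejects malformed panels with diagnosable errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("province,region,year,count",
               "A,R1,2011,10", "A,R1,2011,9"), f)
  expect_error(read_panel(f), "duplicate.*\\(A, 2011\\)")

  writeLines(c("province,region,year", "A,R1,2011"), f)
  expect_error(read_panel(f), "missing column.*count")

  expect_error(license_panel(data.frame(province = "A", region = "R1",
                                        year = 2011, count = -3)),
               "negative count at row")
  expect_error(license_panel(data.frame(province = "A", region = "R1",
                                        year = 2011, count = 2.5)),
               "non-integer")
  expect_error(license_panel(data.frame(province = c("A", "A"),
                                        region = c("R1", "R2"),
                                        year = 2011:2012, count = c(1, 2))),
               "multiple regions")
  expect_error(read_panel("no/such/file.csv"), "does not exist")
})

test_that("write/read round-trips arbitrary valid panels identically", {
  # property-style: random panels with missing cells, under a fixed seed
  set.seed(42)
  for (rep in 1:10) {
    nR <- sample(1:3, 1); nP <- sample(2:6, 1)
    prov <- sprintf("P%02d", 1:nP)
    reg <- sprintf("R%d", sample(1:nR, nP, replace = TRUE))
    yrs <- 2011:(2011 + sample(3:8, 1))
    grid <- expand.grid(province = prov, year = yrs, stringsAsFactors = FALSE)
    grid$region <- reg[match(grid$province, prov)]
    grid$count <- rpois(nrow(grid), 500)
    grid <- grid[runif(nrow(grid)) > 0.1, ]  # punch missing cells
    p <- license_panel(grid)
    f <- tempfile(fileext = ".csv")
    write_panel(p, f)
    expect_equal(read_panel(f), p)
    # byte-identical on rewrite
    f2 <- tempfile(fileext = ".csv")
    write_panel(read_panel(f), f2)
    expect_identical(readLines(f), readLines(f2))
    unlink(c(f, f2))
  }
})

test_that("a 50-province simulated panel round-trips byte-identically", {
  sim <- simulate_panel(sim_config(seed = 99))
  f <- withr::local_tempfile(fileext = ".csv")
  write_panel(sim$panel, f)
  p2 <- read_panel(f)
  expect_equal(p2, sim$panel)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_panel(p2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("missing cells are absent rows, never zeros; empty panel writes header only", {
  p <- license_panel(data.frame(province = c("A", "A"), region = "R1",
                                year = c(2011L, 2013L), count = c(5L, 7L)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_panel(p, f)
  lines <- readLines(f)
  expect_length(lines, 3L)  # header + 2 rows, 2012 simply absent
  expect_false(any(grepl("2012", lines)))

  empty <- license_panel(data.frame(province = character(), region = character(),
                                    year = integer(), count = integer()))
  write_panel(empty, f)
  expect_identical(readLines(f), "province,region,year,count")
})

test_that("excess mortality follows the baseline-mean percentage formula", {
  expect_equal(compute_excess_mortality(
    c("2015" = 100, "2016" = 100, "2017" = 100, "2018" = 100, "2019" = 100,
      "2020" = 132), 2020, 2015:2019), 32.0)
  expect_equal(compute_excess_mortality(
    c("2018" = 90, "2019" = 110, "2020" = 100), 2020, 2018:2019), 0.0)
  # hand arithmetic: baseline mean 100, target 80 -> -20%
  expect_equal(compute_excess_mortality(
    c("2017" = 90, "2018" = 100, "2019" = 110, "2020" = 80), 2020, 2017:2019),
    -20.0)
  expect_error(compute_excess_mortality(c("2019" = 0, "2020" = 5), 2020, 2019),
               "baseline mean is zero")
  expect_error(compute_excess_mortality(c("2020" = 5), 2020, 2019), "missing")
})

test_that("covariate tables round-trip and reject duplicates", {
  cv <- data.frame(province = c("A", "B"), year = 2020L,
                   excess_mortality_pct = c(32.5, -4.0))
  f <- withr::local_tempfile(fileext = ".csv")
  write_covariates(cv, f)
  expect_equal(read_covariates(f), cv, ignore_attr = TRUE)
  writeLines(c("province,year,excess_mortality_pct",
               "A,2020,1", "A,2020,2"), f)
  expect_error(read_covariates(f), "duplicate")
})

test_that("split_spec enforces disjoint, ordered year sets", {
  s <- split_spec(2011:2019, 2020:2021)
  expect_equal(s$training_years, 2011:2019)
  expect_error(split_spec(2011:2020, 2020:2021), "disjoint")
  expect_error(split_spec(2012:2019, 2011), "strictly after")
})
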