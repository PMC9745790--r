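# Camera-trap data preparation: independence filtering, occasion pooling,
# site aggregation and covariate QC.

test_that("independence filter keeps events >= 30 min from the last retained one", {
  # below-threshold gap collapses
  expect_equal(nrow(filter_independent_events(minute_events(c(0, 29)))), 1)
  # a gap of exactly 30 min is independent (boundary inclusive)
  expect_equal(nrow(filter_independent_events(minute_events(c(0, 30)))), 2)
  # gap measured from the last retained event: 0,20,40,70 keeps {0,40,70}
  kept <- filter_independent_events(minute_events(c(0, 20, 40, 70)))
  mins <- as.numeric(difftime(kept$timestamp,
                              as.POSIXct("2016-12-01 06:00:00", tz = "UTC"),
                              units = "mins"))
  expect_equal(mins, c(0, 40, 70))
})

test_that("independence filter works per camera-species stream and is idempotent", {
  ev <- rbind(minute_events(c(0, 10, 40), camera = "C1"),
              minute_events(c(5, 15), camera = "C2"),
              minute_events(c(0, 10), camera = "C1", species = "human"))
  out <- filter_independent_events(ev)
  expect_equal(sum(out$camera_id == "C1" & out$species == "focal"), 2)
  expect_equal(sum(out$camera_id == "C2"), 1)
  expect_equal(sum(out$species == "human"), 1)
  # idempotence, also on random streams
  expect_equal(filter_independent_events(out), out)
  set.seed(5)
  for (i in 1:20) {
    ev <- minute_events(sort(runif(30, 0, 600)))
    f1 <- filter_independent_events(ev)
    expect_equal(filter_independent_events(f1), f1)
    gaps <- diff(as.numeric(f1$timestamp)) / 60
    expect_true(all(gaps >= 30))
  }
})

test_that("unparseable timestamps are rejected with the record named", {
  ev <- data.frame(camera_id = "C1", timestamp = c("2016-12-01T06:00", "junk"),
                   species = "focal")
  expect_error(filter_independent_events(ev), "unparseable.*junk")
})

test_that("occasion pooling bins events into 3-day windows from activation", {
  dep <- one_deployment(days = 45)
  # 45-day deployment: 15 fully defined occasions
  row <- pool_occasions(minute_events(numeric(0))[0, ], dep)
  expect_equal(row$counts, rep(0L, 15))
  expect_false(any(row$partial))
  # events on days 1, 2, 8 (1-based) -> occasion 1 twice, occasion 3 once
  ev <- minute_events(c(0, 1 * 1440, 7 * 1440) + 360)
  row <- pool_occasions(ev, dep)
  expect_equal(row$counts, c(2L, 0L, 1L, rep(0L, 12)))
})

test_that("13-day deployment yields 4 full, 1 partial and 10 missing occasions", {
  dep <- one_deployment(days = 13)
  row <- pool_occasions(minute_events(numeric(0))[0, ], dep)
  expect_equal(row$counts[1:5], rep(0L, 5))
  expect_true(all(is.na(row$counts[6:15])))
  expect_equal(which(row$partial), 5L)
  # sensitivity toggle: partial occasions dropped
  row2 <- pool_occasions(minute_events(numeric(0))[0, ], dep,
                         include_partial = FALSE)
  expect_true(is.na(row2$counts[5]))
})

test_that("events outside the active period are excluded with a warning", {
  dep <- one_deployment(days = 13)
  ev <- minute_events(c(360, 20 * 1440))  # day 1 and day 21
  expect_warning(row <- pool_occasions(ev, dep), "outside the active period")
  expect_equal(sum(row$counts, na.rm = TRUE), 1)
})

test_that("site aggregation stacks replicate-major columns and preserves totals", {
  dep1 <- one_deployment("C1", "S01")
  dep2 <- one_deployment("C2", "S01")
  dep3 <- one_deployment("C3", "S02")
  r1 <- pool_occasions(minute_events(c(0, 3000), camera = "C1"), dep1)
  r2 <- pool_occasions(minute_events(5000, camera = "C2"), dep2)
  r3 <- pool_occasions(minute_events(numeric(0))[0, ], dep3)
  cm <- aggregate_to_sites(list(r1, r2, r3))
  expect_s3_class(cm, "count_matrix")
  expect_equal(dim(cm$counts), c(2L, 30L))      # 2 replicates x 15 occasions
  expect_equal(sum(cm$counts, na.rm = TRUE), 3) # total preserved
  # single-camera site has missing cells in the surplus replicate block
  expect_true(all(is.na(cm$counts["S02", 16:30])))
  expect_equal(unname(cm$counts["S01", 1:15]), r1$counts)
  expect_equal(unname(cm$counts["S01", 16:30]), r2$counts)
  # one camera per site: matrix identical to the per-camera rows
  cm1 <- aggregate_to_sites(list(r1, r3))
  expect_equal(unname(cm1$counts[1, ]), r1$counts)
  expect_equal(cm1$n_replicates, 1L)
})

test_that("a site with two cameras among four-replicate sites gets 30 missing cells", {
  rows <- c(lapply(1:4, function(k)
    pool_occasions(minute_events(numeric(0))[0, ],
                   one_deployment(paste0("A", k), "S01"))),
    lapply(1:2, function(k)
      pool_occasions(minute_events(numeric(0))[0, ],
                     one_deployment(paste0("B", k), "S02"))))
  cm <- aggregate_to_sites(rows)
  expect_equal(ncol(cm$counts), 60L)
  expect_equal(sum(is.na(cm$counts["S02", ])), 30L)
  expect_equal(sum(!is.na(cm$counts["S02", ])), 30L)
})

test_that("capture rate is photographs per trap-night", {
  expect_equal(capture_rate(0, 40), 0)
  expect_equal(capture_rate(12, 40), 0.3)
  expect_error(capture_rate(5, 0), "zero effort")
  expect_error(capture_rate(-1, 10), "non-negative")
})

test_that("Z-standardization centers, scales and round-trips", {
  covs <- site_covariates(data.frame(site_id = c("a", "b", "c"),
                                     x = c(1, 2, 3), y = c(10, 30, 20)))
  z <- standardize_covariates(covs)
  expect_equal(z$x, c(-1, 0, 1))
  expect_true(is_standardized <- attr(z, "standardized"))
  expect_lt(abs(mean(z$y)), 1e-8)
  expect_equal(sd(z$y), 1)
  back <- unstandardize_covariates(z)
  expect_equal(back$x, covs$x, tolerance = 1e-10)
  expect_equal(back$y, covs$y, tolerance = 1e-10)
  expect_error(standardize_covariates(
    site_covariates(data.frame(site_id = c("a", "b", "c"), x = c(5, 5, 5)))),
    "zero-variance.*x")
})

test_that("collinearity screen flags |r| >= 0.7 pairs", {
  set.seed(11)
  x <- rnorm(50)
  covs <- site_covariates(data.frame(
    site_id = sprintf("S%02d", 1:50), x = x, dup = x,
    near = 0.9 * x + rnorm(50, sd = 0.1),
    ortho = rep(c(1, -1), 25) * 0 + rnorm(50)))
  fl <- collinearity_screen(covs)
  expect_true(any(fl$var1 == "x" & fl$var2 == "dup" & fl$r == 1))
  expect_true(any((fl$var1 == "x" & fl$var2 == "near") |
                  (fl$var1 == "near" & fl$var2 == "x")))
  expect_false("ortho" %in% c(fl$var1, fl$var2))
  # orthogonal contrasts are not flagged
  covs2 <- site_covariates(data.frame(site_id = c("a", "b", "c", "d"),
                                      c1 = c(1, 1, -1, -1),
                                      c2 = c(1, -1, 1, -1)))
  expect_equal(nrow(collinearity_screen(covs2)), 0)
})
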