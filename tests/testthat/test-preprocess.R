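make_records <- function(lat, lon, uncertainty = NA, species = "sp",
                         date = as.Date("2005-06-01")) {
  data.frame(species = species, lon = lon, lat = lat, date = date,
             uncertainty_m = uncertainty)
}

test_that("coordinate-precision and uncertainty filters follow the rules", {
  recs <- data.frame(
    species = "sp",
    lon = c("-65.123", "-65.123", "-65.123", "not-a-number", "-65.123"),
    lat = c("10.12", "10.123", "10.123", "10.123", "10.120"),
    date = as.Date("2005-06-01"),
    uncertainty_m = c(1000, 30000, 1000, 1000, NA)
  )
  out <- filter_po(recs, quiet = TRUE)
  rem <- attr(out, "removed")
  # row 1: only 2 decimals on lat; row 2: uncertainty 30,000 m > 25,000 m;
  # row 4: unparseable; rows 3 and 5 survive ("10.120" has 3 textual
  # decimals; missing uncertainty passes)
  expect_equal(nrow(out), 2)
  expect_equal(unname(rem), c(1, 1, 1))
  # numeric coordinates: trailing zeros are invisible, so 10.120 stored as
  # a double fails the precision rule while 10.123 passes
  out_num <- filter_po(make_records(lat = c(10.12, 10.123, 10.120),
                                    lon = rep(-65.123, 3)), quiet = TRUE)
  expect_equal(out_num$lat, 10.123)
})

test_that("filtering is idempotent", {
  sys <- small_system()
  once <- filter_po(sys$po$records, quiet = TRUE)
  twice <- filter_po(once, quiet = TRUE)
  expect_equal(twice[names(once)], once, ignore_attr = TRUE)
  expect_equal(unname(attr(twice, "removed")), c(0, 0, 0))
})

test_that("deduplication keeps one row per (species, date, lat, lon)", {
  r <- rbind(
    make_records(10.123, -65.123, date = as.Date("2005-06-01")),
    make_records(10.123, -65.123, date = as.Date("2005-06-01")),
    make_records(10.123, -65.123, date = as.Date("2006-06-01")),
    make_records(10.124, -65.123, date = as.Date("2005-06-01"))
  )
  out <- deduplicate_po(r)
  expect_equal(nrow(out), 3)  # same place, different date: both kept
  # order independence
  out_rev <- deduplicate_po(r[rev(seq_len(nrow(r))), ])
  expect_equal(out_rev, out)
  expect_equal(nrow(deduplicate_po(r[0, ])), 0)
})

test_that("gridded counts split periods at the boundary year and conserve records", {
  g <- build_grid(extent_km = c(-200, 200, -200, 200))
  ll <- laea_inverse(c(-150, -150, 150, 150), c(-150, 50, 50, 50))
  recs <- data.frame(species = "sp", lon = ll$lon, lat = ll$lat,
                     date = as.Date(c("2013-12-31", "2014-01-01",
                                      "2005-03-05", "2020-07-09")))
  counts <- grid_po_counts(recs, g, period_split_year = 2013)
  expect_equal(sum(counts[, 1]), 2)  # 2013 belongs to period 1
  expect_equal(sum(counts[, 2]), 2)  # 2014 to period 2
  expect_equal(sum(counts), nrow(recs))
  # a record outside the analysis year window is excluded and reported
  recs2 <- rbind(recs, data.frame(species = "sp", lon = ll$lon[1],
                                  lat = ll$lat[1],
                                  date = as.Date("1950-01-01")))
  counts2 <- grid_po_counts(recs2, g, period_split_year = 2013)
  expect_equal(sum(counts2), 4)
  expect_equal(attr(counts2, "n_outside_window"), 1L)
  # three records in one cell tally to 3
  recs3 <- recs[c(3, 3, 3), ]
  expect_equal(max(grid_po_counts(recs3, g, 2013)), 3)
})

test_that("count conservation holds on simulated records", {
  sys <- small_system(seed = 12)
  dedup <- deduplicate_po(filter_po(sys$po$records, quiet = TRUE))
  counts <- grid_po_counts(dedup, sys$grid,
                           period_split_year = max(sys$config$period1_years))
  expect_equal(sum(counts),
               nrow(dedup) - attr(counts, "n_outside_extent") -
                 attr(counts, "n_outside_window"))
})

test_that("blob construction merges exactly the overlapping survey discs", {
  surveys <- data.frame(
    survey_id = 1:3,
    x = c(0, 15, 500), y = c(0, 0, 0),
    area_km2 = c(314.159265, 314.159265, 100),
    effort_days = c(100, 50, 70),
    start_date = as.Date(rep("2005-01-01", 3)),
    end_date = as.Date(rep("2005-12-01", 3))
  )
  blobs <- build_blobs(surveys, period_split_year = 2013)
  expect_equal(length(blobs$blobs), 2)
  merged <- blobs$blobs[[1]]
  expect_equal(merged$discs$r, c(10, 10), tolerance = 1e-6)  # r = sqrt(A/pi)
  expect_equal(merged$effort_days, 150)
  # union area of two overlapping discs: less than the sum, more than one
  expect_lt(merged$area_km2, 2 * 314.159265)
  expect_gt(merged$area_km2, 314.159265)
  # closed-form union of two radius-10 circles at distance 15
  d <- 15; r <- 10
  lens <- 2 * r^2 * acos(d / (2 * r)) - d / 2 * sqrt(4 * r^2 - d^2)
  expect_equal(merged$area_km2, 2 * pi * r^2 - lens, tolerance = 0.05)
})

test_that("blob construction is permutation-invariant and rejects bad surveys", {
  sys <- small_system(seed = 22)
  surveys <- sys$pa$surveys
  b1 <- build_blobs(surveys, period_split_year = 2013)
  perm <- surveys[sample(nrow(surveys)), ]
  b2 <- build_blobs(perm, period_split_year = 2013)
  expect_equal(lapply(b1$blobs, `[[`, "survey_ids"),
               lapply(b2$blobs, `[[`, "survey_ids"))
  expect_equal(vapply(b1$blobs, `[[`, numeric(1), "area_km2"),
               vapply(b2$blobs, `[[`, numeric(1), "area_km2"))
  bad <- surveys; bad$area_km2[1] <- 0
  expect_error(build_blobs(bad, 2013), "non-positive area")
  noeff <- surveys; noeff$effort_days[2] <- NA
  expect_message(build_blobs(noeff, 2013), "missing effort")
})

test_that("surveys spanning the period boundary go to their midpoint period", {
  s <- data.frame(survey_id = 1:2, x = c(0, 500), y = 0, area_km2 = 100,
                  effort_days = 10,
                  start_date = as.Date(c("2013-01-01", "2013-10-01")),
                  end_date = as.Date(c("2015-06-30", "2014-04-01")))
  b <- build_blobs(s, period_split_year = 2013)
  periods <- vapply(b$blobs, `[[`, integer(1), "period")
  ids <- vapply(b$blobs, function(x) x$survey_ids, integer(1))
  # survey 1 midpoint is in 2014 (period 2); survey 2 midpoint in 2013
  expect_equal(periods[ids == 1], 2L)
  expect_equal(periods[ids == 2], 1L)
})

test_that("absences are generated where no member survey detected the species", {
  surveys <- data.frame(
    survey_id = 1:3, x = c(0, 10, 400), y = c(0, 0, 0),
    area_km2 = rep(300, 3), effort_days = rep(50, 3),
    start_date = as.Date(rep("2005-01-01", 3)),
    end_date = as.Date(rep("2005-12-01", 3))
  )
  blobs <- build_blobs(surveys, 2013)
  det <- data.frame(survey_id = 2, species = "puma")
  blobs <- generate_absences(blobs, det, species = c("puma", "tapir"))
  pa <- attr(blobs, "pa_table")
  expect_equal(nrow(pa), 4)  # 2 blobs x 2 species
  expect_equal(pa$y[pa$species == "puma"],
               c(1L, 0L))  # merged blob detected; isolated one did not
  expect_true(all(pa$y[pa$species == "tapir"] == 0))
  expect_error(generate_absences(blobs, data.frame(survey_id = 1,
                                                   species = "yeti"),
                                 species = "puma"), "not in the species list")
  empty <- build_blobs(surveys[0, ], 2013)
  expect_equal(nrow(attr(generate_absences(empty, NULL, "puma"),
                         "pa_table")), 0)
})

test_that("the effort ratio is period-2 records over period-1 records", {
  expect_equal(effort_ratio(c(100, 127)), 1.27)
  expect_equal(effort_ratio(c(150, 150)), 1)
  expect_equal(effort_ratio(c(200, 150)), 0.75)
  expect_error(effort_ratio(c(0, 10)), "undefined")
  recs <- data.frame(date = as.Date(c("2005-01-01", "2013-12-31",
                                      "2014-06-01", "2020-01-01",
                                      "2021-12-31")))
  expect_equal(effort_ratio(recs, period_split_year = 2013), 1.5)
})

test_that("assembled model data aligns blobs, weights and counts", {
  sys <- small_system(seed = 42)
  data <- small_isdm_data(sys)
  nb <- length(sys$pa$blobs$blobs)
  expect_equal(dim(data$blob_W), c(nb, nrow(sys$grid$cells)))
  expect_equal(unname(rowSums(data$blob_W)), rep(1, nb), tolerance = 1e-9)
  expect_true(all(data$po_counts >= 0))
  expect_equal(data$effort_ratio, sys$config$effort_ratio_true)
  expect_equal(length(data$blob_y), nb)
  expect_error(assemble_isdm_data(sys$grid, sys$po$counts, sys$pa$blobs,
                                  effort_ratio = -1), "positive")
})
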