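# Grouping, filtering, area assignment, matrix construction, CSV round trips.

test_that("assign_group implements the seasonal and regional rules", {
  # full-grown spring migrants in the southern region
  expect_equal(assign_group("full_grown", 4, "SouthernGermanySwitzerland"),
               "Southern_spring")
  expect_equal(assign_group("full_grown", 3, "NorthernGermany"), "Central_spring")
  expect_equal(assign_group("full_grown", 5, "Switzerland"), "Southern_spring")
  # chicks and June/July full-growns belong to the breeding groups
  expect_equal(assign_group("chick", 6, "Germany", lat = 53.5), "Central_breeding")
  expect_equal(assign_group("chick", 6, "Germany", lat = 51.9), "Southern_breeding")
  expect_equal(assign_group("full_grown", 7, "NorthernGermany"), "Central_breeding")
  # autumn rule covers chicks and full-growns Aug-Oct
  expect_equal(assign_group("full_grown", 9, "SouthernGermanySwitzerland"),
               "Southern_autumn")
  expect_equal(assign_group("chick", 9, "NorthernGermany"), "Central_autumn")
  # chicks outside Aug-Oct fall back to breeding (configurable)
  expect_equal(assign_group("chick", 5, "NorthernGermany"), "Central_breeding")
  expect_equal(assign_group("chick", 9, "NorthernGermany",
                            config = mc_config(chick_autumn_rule = FALSE)),
               "Central_breeding")
  # Sweden and Finland are never split by season or age
  expect_equal(assign_group("full_grown", 9, "Sweden"), "SWE")
  expect_equal(assign_group("chick", 12, "Finland"), "FIN")
  # the 52 N split is north-inclusive
  expect_equal(assign_group("chick", 6, "Germany", lat = 52), "Central_breeding")
  # no group exists for full-grown central/southern birds ringed Nov-Feb
  expect_error(assign_group("full_grown", 12, "NorthernGermany"), "unassignable")
  expect_error(assign_group("full_grown", 6, "nowhere"), "unknown region")
})

test_that("assign_wintering_area partitions the sub-Saharan domain", {
  expect_equal(assign_wintering_area(-20, 25), "Southern")
  expect_equal(assign_wintering_area(-15.4, 25), "Southern") # south-inclusive
  expect_equal(assign_wintering_area(-2, 18), "Central")
  expect_equal(assign_wintering_area(5, 0), "Western")
  expect_equal(assign_wintering_area(15, 15), "Western")     # west-inclusive
  expect_equal(assign_wintering_area(0, 30.0), "Central")
  expect_equal(assign_wintering_area(0, 30.1), "Eastern")
  expect_equal(assign_wintering_area(40, 5), "outside")      # Europe
  expect_error(assign_wintering_area(95, 0), "latitude")
  # property: every valid sub-Saharan coordinate maps to exactly one area
  set.seed(1)
  lat <- runif(500, -35, 15)
  lon <- runif(500, -17, 45)
  out <- assign_wintering_area(lat, lon)
  expect_true(all(out %in% area_labels()))
  # boundaries are respected under a reconfigured rift longitude
  expect_equal(assign_wintering_area(0, 31, mc_config(rift_lon = 32)), "Central")
})

test_that("filter_wintering_reencounters keeps Nov-Feb sub-Saharan records", {
  rec <- data.frame(
    ring_id = paste0("r", 1:5),
    age_at_ringing = "full_grown",
    ringing_date = as.Date("2000-06-15"),
    ringing_lat = 47, ringing_lon = 8,
    reencounter_date = as.Date(c("2001-01-10", "2001-07-10", "2000-12-24",
                                 "2001-01-05", NA)),
    reencounter_lat = c(-20, -20, 40, -1, NA),
    reencounter_lon = c(25, 25, 5, 18, NA)
  )
  kept <- filter_wintering_reencounters(rec)
  expect_equal(kept$ring_id, c("r1", "r4"))
  expect_equal(kept$area, c("Southern", "Central"))
  bad <- rec
  bad$reencounter_date[1] <- as.Date("1999-01-01")
  expect_error(filter_wintering_reencounters(bad), "before ringing")
})

test_that("build_reencounter_matrices tabulates, pads and deduplicates", {
  rec <- data.frame(
    ring_id = c("a", "a", "b", "c", "d"), # 'a' reencountered twice: counted once
    group = c("SWE", "SWE", "SWE", "Southern_breeding", "FIN"),
    area = c("Western", "Western", "Southern", "Central", "Eastern"),
    age_class = c("ad", "ad", "ad", "juv", "ad"),
    known = c(TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  n_ringed <- data.frame(group = c("SWE", "Southern_breeding"),
                         age_class = c("ad", "juv"), n_ringed = c(10, 7))
  rd <- build_reencounter_matrices(rec, n_ringed)
  expect_equal(unname(rd$R_ad_known["SWE", ]), c(1, 0, 0, 1, 8))
  expect_equal(unname(rd$R_juv_known["Southern_breeding", ]), c(0, 1, 0, 0, 6))
  expect_equal(unname(rd$R_ad_unknown["FIN", ]), c(0, 0, 1, 0))
  # record conservation: every deduplicated record lands in exactly one cell
  expect_equal(sum(rd$R_ad_known[, 1:4]) + sum(rd$R_juv_known[, 1:4]) +
                 sum(rd$R_ad_unknown) + sum(rd$R_juv_unknown), 4)
  # all-zero unknown rows are flagged as carrying no likelihood
  expect_true(rd$zero_unknown_rows$ad[["SWE"]])
  expect_false(rd$zero_unknown_rows$ad[["FIN"]])
  # more reencounters than birds ringed is an inconsistency
  n_bad <- data.frame(group = "SWE", age_class = "ad", n_ringed = 1)
  expect_error(build_reencounter_matrices(rec, n_bad), "more reencounters")
})

test_that("reencounter CSV round trip is exact and schema errors are named", {
  b <- make_study_like_bundle(seed = 5)
  rd <- b$data$rings
  known <- withr::local_tempfile(fileext = ".csv")
  unknown <- withr::local_tempfile(fileext = ".csv")
  write_reencounters(rd, known, unknown)
  back <- read_reencounters(known, unknown)
  expect_equal(back$R_ad_known, rd$R_ad_known)
  expect_equal(back$R_juv_known, rd$R_juv_known)
  expect_equal(back$R_ad_unknown, rd$R_ad_unknown)
  expect_equal(back$N_ad, rd$N_ad)
  # corrupt a count: the reader names the offending column/row
  df <- read.csv(known)
  df$area_Western[2] <- -1
  write.csv(df, known, row.names = FALSE)
  expect_error(read_reencounters(known, unknown), "area_Western")
})

test_that("isotope CSV round trip preserves values and standardization", {
  b <- make_study_like_bundle(seed = 5)
  iso <- b$data$isotopes
  path <- withr::local_tempfile(fileext = ".csv")
  write_isotopes(iso, path)
  back <- read_isotopes(path)
  expect_equal(back$values, iso$values)
  expect_equal(back$pop, iso$pop)
  expect_equal(back$standardization_constants, iso$standardization_constants)
  # standardized columns are z-scores of the raw data
  expect_equal(unname(colMeans(back$standardized)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(back$standardized, 2, sd)), c(1, 1), tolerance = 1e-12)
  writeLines("individual_id,population,d13C,d15N", path)
  expect_error(read_isotopes(path), "no rows")
})

test_that("parasite tables validate and round-trip the study's instance", {
  pd <- table3_parasites()
  expect_equal(pd$G_nb["Central", "GRW09"], 74)
  expect_equal(pd$H_nb["Central", 1], 2767)
  nb <- withr::local_tempfile(fileext = ".csv")
  bp <- withr::local_tempfile(fileext = ".csv")
  write_parasites(pd, nb, bp)
  back <- read_parasites(nb, bp)
  expect_equal(back$G_nb, pd$G_nb)
  expect_equal(back$H_nb, pd$H_nb)
  expect_equal(back$G_b, pd$G_b)
  expect_equal(back$H_b, pd$H_b)
  # infected > sampled and negative entries are schema errors naming the cell
  expect_error(parasite_data(pd$G_nb + 1000, pd$H_nb, pd$G_b, pd$H_b),
               "infected exceeds sampled")
  H_bad <- pd$H_nb; H_bad[2, 3] <- -5
  expect_error(parasite_data(pd$G_nb, H_bad, pd$G_b, pd$H_b), "\\[2,3\\]")
})

test_that("config files read from JSON and reject unknown keys", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"rift_lon": 31.5, "mu_SC_sd": 0.1}', path)
  cfg <- read_config(path)
  expect_equal(cfg$config$rift_lon, 31.5)
  expect_equal(cfg$priors$mu_SC_sd, 0.1)
  writeLines('{"no_such_option": 1}', path)
  expect_error(read_config(path), "unknown config entries")
})
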