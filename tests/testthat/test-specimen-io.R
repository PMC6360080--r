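test_that("specimen tables round-trip through CSV losslessly", {
  sp <- generate_species("Escallonia demo", 3, c(3, 1), diag(0.02, 2), 1.2, 0.4,
                         elevation_range = c(1300, 2200), seed = 11)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_specimens(sp, tf)
  back <- read_specimens(tf)
  expect_equal(as.data.frame(back), as.data.frame(sp), tolerance = 1e-12)
  # aggregate-after-round-trip matches aggregate-before
  expect_equal(specimen_means(back), specimen_means(sp), tolerance = 1e-12)
})

test_that("a voucher-style row with 3 replicates yields 3-element leaf vectors", {
  row <- tibble::tibble(
    species = "Escallonia harrisii", specimen_id = "USZ-0422",
    leaf_length_1 = 15.1, leaf_length_2 = 16.4, leaf_length_3 = 17.0,
    leaf_width_1 = 2.1, leaf_width_2 = 2.6, leaf_width_3 = 2.4,
    flower_count = 2, elevation = 1350
  )
  tf <- withr::local_tempfile(fileext = ".csv")
  write_specimens(row, tf)
  back <- read_specimens(tf)
  expect_equal(nrow(back), 1L)
  expect_equal(unlist(back[paste0("leaf_length_", 1:3)], use.names = FALSE),
               c(15.1, 16.4, 17.0))
  expect_equal(specimen_means(back)$leaf_length, mean(c(15.1, 16.4, 17.0)))
})

test_that("validation rejects bad tables with informative errors", {
  good <- generate_species("sp", 3, c(3, 1), diag(0.02, 2), 1, 0.2, seed = 1)
  bad_fc <- good; bad_fc$flower_count[2] <- 0
  expect_error(validate_specimens(bad_fc), "flower_count")
  no_col <- good[setdiff(names(good), "leaf_width_2")]
  expect_error(validate_specimens(no_col), "leaf_width_2")
  neg <- good; neg$leaf_length_1[1] <- -4
  expect_error(validate_specimens(neg), "positive")
  chr <- good; chr$flower_count <- as.character(chr$flower_count)
  chr$flower_count[3] <- "many"
  expect_error(validate_specimens(chr), "not numeric")
})

test_that("missing leaf replicates warn by default and fail in strict mode", {
  sp <- generate_species("sp", 4, c(3, 1), diag(0.02, 2), 1, 0.2, seed = 2)
  sp$leaf_length_3[2] <- NA
  expect_warning(validate_specimens(sp), "fewer than 3")
  expect_error(validate_specimens(sp, strict = TRUE), "strict")
  m <- suppressWarnings(specimen_means(validate_specimens(sp)))
  expect_equal(m$leaf_length[2],
               mean(c(sp$leaf_length_1[2], sp$leaf_length_2[2])))
})

test_that("aggregation averages replicates and groups by species", {
  df <- tibble::tibble(
    species = c("b", "a", "b"), specimen_id = c("1", "2", "3"),
    leaf_length_1 = c(10, 5, 7), leaf_length_2 = c(20, 5, 7),
    leaf_length_3 = c(30, 5, 7),
    leaf_width_1 = 1, leaf_width_2 = 2, leaf_width_3 = 3,
    flower_count = c(4L, 9L, 2L)
  )
  m <- specimen_means(df)
  expect_equal(m$leaf_length[1], 20)
  expect_equal(m$flower_count, c(4L, 9L, 2L))
  d <- descriptive_stats(m)
  expect_equal(d$n[d$species == "b"], 2L)
  expect_equal(d$n[d$species == "a"], 1L)
})

test_that("minimum-sample-size filter keeps n >= min_n and reports exclusions", {
  mk <- function(sp, n) generate_species(sp, n, c(3, 1), diag(0.02, 2), 1, 0.2,
                                         seed = nchar(sp))
  means <- specimen_means(dplyr::bind_rows(
    mk("two", 2), mk("three", 3), mk("four", 4), mk("fives", 5)
  ))
  kept <- suppressMessages(filter_min_n(means, min_n = 4))
  expect_setequal(unique(kept$species), c("four", "fives"))
  excl <- attr(kept, "excluded")
  expect_setequal(excl$species, c("two", "three"))
  # brute-force oracle: exactly the species whose row count is >= 4 survive
  tab <- table(means$species)
  expect_setequal(unique(kept$species), names(tab)[tab >= 4])
})

test_that("descriptive statistics agree with direct recomputation", {
  set.seed(31)
  sp <- generate_species("sp", 20, c(3.5, 2.2),
                         matrix(c(0.04, 0.02, 0.02, 0.05), 2), 3, 0.6,
                         seed = 31)
  m <- specimen_means(sp)
  d <- descriptive_stats(m)
  ll <- rowMeans(cbind(sp$leaf_length_1, sp$leaf_length_2, sp$leaf_length_3))
  expect_equal(d$leaf_length_min, min(ll))
  expect_equal(d$leaf_length_mean, sum(ll) / length(ll))
  expect_equal(d$leaf_length_max, max(ll))
  expect_equal(d$flower_count_mean, sum(sp$flower_count) / nrow(sp))
  # ordering invariant min <= mean <= max on every trait triplet
  for (tr in c("leaf_length", "leaf_width", "flower_count")) {
    expect_lte(d[[paste0(tr, "_min")]], d[[paste0(tr, "_mean")]])
    expect_lte(d[[paste0(tr, "_mean")]], d[[paste0(tr, "_max")]])
  }
})

test_that("degenerate single-specimen and constant-count species collapse correctly", {
  one <- specimen_means(generate_species("solo", 1, c(3, 1), diag(0.02, 2),
                                         2, 0.4, seed = 5))
  d1 <- descriptive_stats(one)
  expect_equal(d1$leaf_length_min, d1$leaf_length_max)
  expect_equal(d1$flower_count_min, d1$flower_count_mean)
  ones <- specimen_means(generate_species("unifloral", 8, c(2.7, 2),
                                          diag(0.02, 2), 0, 0, seed = 6))
  d2 <- descriptive_stats(ones)
  expect_equal(c(d2$flower_count_min, d2$flower_count_mean, d2$flower_count_max),
               c(1, 1, 1))
})

test_that("specimen order never affects downstream results", {
  panel <- three_species_panel(seed = 19)
  means <- specimen_means(panel)
  perm <- means[sample.int(nrow(means)), ]
  expect_equal(descriptive_stats(means), descriptive_stats(perm))
  e1 <- estimate_bivariate(means)
  e2 <- estimate_bivariate(perm)
  expect_equal(e1, e2, tolerance = 1e-12, ignore_attr = TRUE)
  ctl <- test_ctl()
  cfg <- morphogap_config(grid_size = 129, n_rep = ctl$n_rep,
                          n_inner = ctl$n_inner)
  s1 <- suppressMessages(run_all_pairs(means, "far away", cfg))
  s2 <- suppressMessages(run_all_pairs(perm, "far away", cfg))
  expect_equal(s1$decisions, s2$decisions, tolerance = 1e-12)
})
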