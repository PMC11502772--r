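test_that("CSV trait tables load, reject duplicates, and round-trip", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("species_id,ph,sm",
               "sp1,1.2,",
               "sp2,0.8,3.5",
               "sp3,2.1,1.1"), f)
  tm <- load_trait_table(f)
  expect_equal(dim(tm), c(3L, 2L))
  expect_equal(sum(is.na(tm$values)), 1L)
  expect_true(is.na(tm$values["sp1", "sm"]))

  writeLines(c("species_id,ph", "sp1,1", "sp1,2"), f)
  expect_error(load_trait_table(f), "sp1")

  writeLines(c("species_id,ph,notatrait", "sp1,1,2"), f)
  expect_warning(tm2 <- load_trait_table(f), "notatrait")
  expect_equal(colnames(tm2$values), "ph")
  expect_error(load_trait_table(f, unknown = "error"), "notatrait")

  # full synthetic 12-trait table: write -> read is bitwise equal
  sim <- cached_compilation(500, 42)
  f2 <- tempfile(fileext = ".csv")
  write_trait_table(sim$traits, f2)
  back <- load_trait_table(f2, transform = "log_scaled")
  expect_identical(back$values, sim$traits$values)
  expect_identical(back$woodiness, sim$traits$woodiness)
})

test_that("log-scale transform follows the stated conventions", {
  tm <- trait_matrix(matrix(c(1, 10, 100), 3, 1,
                            dimnames = list(NULL, "ph")))
  out <- log_scale_transform(tm)
  # logs 0,1,2 standardised with the population-SD convention
  expect_close(out$values[, 1], c(-1, 0, 1) / sqrt(2 / 3), 1e-10)
  expect_identical(out$transform, "log_scaled")

  # per-trait mean 0 / SD 1 invariant over observed entries
  sim <- cached_compilation(500, 42)
  raw <- simulate_trait_matrix(two_block_target(0.5), 300, seed = 4,
                               raw_scale = TRUE)
  raw$values[sample(length(raw$values), 100)] <- NA
  raw <- trait_matrix(raw$values, transform = "raw")
  sc <- log_scale_transform(raw)
  for (j in seq_len(ncol(sc$values))) {
    v <- sc$values[, j][!is.na(sc$values[, j])]
    expect_lt(abs(mean(v)), 1e-10)
    expect_lt(abs(sqrt(mean((v - mean(v))^2)) - 1), 1e-10)
  }

  # zero values leave the domain of log and become missing
  tm0 <- trait_matrix(matrix(c(1, 10, 100, 5), 4, 1,
                             dimnames = list(NULL, "ph")))
  tm0$values[4, 1] <- 0  # bypass the raw-scale positivity check
  expect_warning(out0 <- log_scale_transform(tm0), "non-positive")
  expect_true(is.na(out0$values[4, 1]))
  expect_equal(sum(!is.na(out0$values)), 3L)

  # transform is a one-way state machine
  expect_error(log_scale_transform(out), "raw")
  # a trait with < 2 observations cannot be scaled
  tm1 <- trait_matrix(matrix(c(1, NA, NA, 2, 3, 4), 3, 2,
                             dimnames = list(NULL, c("a", "b"))))
  expect_error(suppressWarnings(log_scale_transform(tm1)), "< 2 observed")
})

test_that("outlier masking removes extreme z-scores and is idempotent", {
  set.seed(1)
  v <- matrix(rnorm(500), 500, 1, dimnames = list(NULL, "t1"))
  v <- apply(v, 2, function(z) (z - mean(z)) / sqrt(mean((z - mean(z))^2)))
  v[1, 1] <- 6
  colnames(v) <- "t1"
  tm <- trait_matrix(v, transform = "log_scaled")
  out <- mask_outliers(tm, z_threshold = 4)
  expect_true(is.na(out$values[1, 1]))
  expect_gte(attr(out, "n_masked")[["t1"]], 1L)

  # infinite threshold: identity
  out_inf <- mask_outliers(tm, z_threshold = Inf)
  expect_identical(out_inf$values, tm$values)

  # standard-normal column at n = 10000: expected removals 2 n Phi(-4),
  # about 0.6, so at most a handful
  set.seed(2)
  big <- matrix(rnorm(10000), ncol = 1, dimnames = list(NULL, "t1"))
  big <- apply(big, 2, function(z) (z - mean(z)) / sqrt(mean((z - mean(z))^2)))
  colnames(big) <- "t1"
  outb <- mask_outliers(trait_matrix(big, transform = "log_scaled"), 4)
  expect_lte(sum(attr(outb, "n_masked")), 5)

  # fixpoint: a second pass removes nothing
  out2 <- mask_outliers(out, z_threshold = 4)
  expect_identical(out2$values, out$values)
  expect_equal(sum(attr(out2, "n_masked")), 0L)

  expect_error(mask_outliers(tm, z_threshold = 0), "positive")
})

test_that("trait-set and growth-form subsetting matches the study grid", {
  sim <- cached_compilation(500, 42)
  g <- subset_traits(sim$traits, trait_selector("GSPFF", "none", "all"))
  expect_equal(ncol(g$values), 6L)

  rdl <- subset_traits(sim$traits, trait_selector("RES", "Dr+Lr", "all"))
  expect_identical(colnames(rdl$values), c("SRL", "D", "RTD", "RN", "Dr", "Lr"))

  # the 3 x 4 grid enumerates exactly twelve trait sets
  grid <- expand.grid(bs = c("UPFS", "GSPFF", "RES"),
                      inc = c("none", "Dr", "Lr", "Dr+Lr"),
                      stringsAsFactors = FALSE)
  sizes <- mapply(function(b, i)
    length(selector_traits(trait_selector(b, i))), grid$bs, grid$inc)
  expect_equal(nrow(grid), 12L)
  expect_equal(unname(sizes[grid$bs == "UPFS" & grid$inc == "Dr+Lr"]), 12)

  w <- subset_traits(sim$traits, trait_selector("UPFS", "none", "woody"))
  expect_true(all(w$woodiness == "woody"))
  expect_lt(nrow(w$values), nrow(sim$traits$values))

  no_wood <- trait_matrix(sim$traits$values, transform = "log_scaled")
  expect_error(subset_traits(no_wood, trait_selector("UPFS", "none", "woody")),
               "woodiness")
})

test_that("transform and subset commute up to column re-scaling", {
  tgt <- build_block_correlation(default_blocks())
  raw <- simulate_trait_matrix(tgt, 400, seed = 6, raw_scale = TRUE,
                               mu = 1, sigma = 0.4)
  sel <- trait_selector("GSPFF", "Dr", "all")
  a <- subset_traits(log_scale_transform(raw), sel)            # transform first
  b <- log_scale_transform(subset_traits(raw, sel, rescale = FALSE))
  expect_identical(colnames(a$values), colnames(b$values))
  expect_close(a$values, b$values, 1e-10)
})

test_that("species_means averages duplicate records per species", {
  df <- data.frame(species_id = c("a", "a", "b"),
                   ph = c(1, 3, 5), sm = c(NA, 4, NA))
  out <- species_means(df)
  expect_equal(out$ph, c(2, 5))
  expect_equal(out$sm, c(4, NA))
})
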