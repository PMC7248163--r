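test_that("the template is exactly mirror-symmetric with zero profile", {
  tpl <- skull_template()
  expect_equal(nrow(tpl$points), 21L)
  bil <- subset(tpl$points, side %in% c("L", "R"))
  for (nm in unique(bil$name)) {
    L <- bil[bil$name == nm & bil$side == "L", c("x", "y", "z")]
    R <- bil[bil$name == nm & bil$side == "R", c("x", "y", "z")]
    expect_equal(unlist(L) * c(-1, 1, 1), unlist(R), ignore_attr = TRUE)
  }
  expect_true(all(tpl$points$x[tpl$points$side == "M"] == 0))
  expect_true(all(compute_profile(tpl)$magnitude == 0))
})

test_that("generate_landmarks is the identity for an empty spec", {
  expect_equal(generate_landmarks()$points, skull_template("synthetic")$points)
})

test_that("generation is deterministic under a fixed seed", {
  spec <- list(displacements = data.frame(name = "Go", side = "R",
                                          dx = -2, dy = 1, dz = 3),
               rotation_deg = c(5, -3, 8), translation_mm = c(10, 0, -4),
               noise_sd_mm = 0.5, seed = 123L)
  s1 <- do.call(generate_landmarks, spec)
  s2 <- do.call(generate_landmarks, spec)
  expect_identical(write_landmarks(s1, format = "csv"),
                   write_landmarks(s2, format = "csv"))
  # a different seed changes the noise
  spec$seed <- 124L
  expect_false(identical(write_landmarks(do.call(generate_landmarks, spec),
                                         format = "csv"),
                         write_landmarks(s1, format = "csv")))
  # generation must not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(do.call(generate_landmarks, spec)); after <- runif(1)
  expect_identical(before, after)
})

test_that("displacement + rigid pose recovers the known index", {
  s <- generate_landmarks(
    displacements = data.frame(name = "Me", side = "M", dx = 6, dy = 0, dz = 0),
    rotation_deg = c(31, -12, 7), translation_mm = c(40, -25, 13))
  p <- compute_profile(s)
  nz <- p[p$magnitude > 1e-9, ]
  expect_identical(nz$landmark, "Me")
  expect_equal(nz$magnitude, 6.707756754140476, tolerance = 1e-9)
  expect_identical(nz$direction, "left")
  expect_error(generate_landmarks(displacements = data.frame(
    name = "Xq", side = "M", dx = 1, dy = 0, dz = 0)),
    "unknown landmark", class = "fai_validation_error")
})

test_that("JSON asymmetry specs drive the generator", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(
    displacements = data.frame(name = "Or", side = "L",
                               dx = 3, dy = 0, dz = 0),
    rotation_deg = c(0, 0, 0), translation_mm = c(0, 0, 0),
    noise_sd_mm = 0, seed = 5), dataframe = "rows", auto_unbox = TRUE), f)
  s <- generate_from_spec(f)
  expect_equal(bilateral_index(s, "Or")$magnitude, 4.103867149751316,
               tolerance = 1e-9)
  # seed argument overrides the spec's seed
  spec2 <- jsonlite::toJSON(list(
    displacements = data.frame(name = "Or", side = "L",
                               dx = 3, dy = 0, dz = 0),
    noise_sd_mm = 0.5, seed = 5), dataframe = "rows", auto_unbox = TRUE)
  sa <- generate_from_spec(as.character(spec2), seed = 9L)
  sb <- generate_landmarks(displacements = data.frame(
    name = "Or", side = "L", dx = 3, dy = 0, dz = 0),
    noise_sd_mm = 0.5, seed = 9L)
  expect_equal(sa$points, sb$points)
})

test_that("mirror is an involution that negates profiles; template self-mirrors", {
  tpl <- skull_template()
  expect_equal(mirror_landmarks(tpl)$points[order(mirror_landmarks(tpl)$points$name,
                                                  mirror_landmarks(tpl)$points$side), ],
               tpl$points[order(tpl$points$name, tpl$points$side), ],
               tolerance = 1e-12, ignore_attr = TRUE)
  for (seed in 1:6) {
    s <- random_perturbed_set(seed)
    m <- mirror_landmarks(s)
    mm <- mirror_landmarks(m)
    expect_equal(mm$points[order(mm$points$name, mm$points$side), c("x", "y", "z")],
                 s$points[order(s$points$name, s$points$side), c("x", "y", "z")],
                 tolerance = 1e-9, ignore_attr = TRUE)
    p <- compute_profile(s); pm <- compute_profile(m)
    expect_equal(pm$signed_value, -p$signed_value, tolerance = 1e-9)
    expect_equal(pm$magnitude, p$magnitude, tolerance = 1e-9)
  }
})

test_that("noisy replicates recover a pure transverse displacement unbiasedly", {
  # noiseless truth over a displacement grid matches the brute-force oracle
  for (delta in 1:10) {
    s <- generate_landmarks(displacements = data.frame(
      name = "Me", side = "M", dx = delta, dy = 0, dz = 0))
    expect_equal(midsagittal_index(s, "Me")$magnitude,
                 oracle_midsagittal(s, "Me")$magnitude, tolerance = 1e-9)
  }
  # with 0.5 mm placement noise the mean recovered index stays within 3 SE
  truth <- 6.707756754140476
  reps <- vapply(1:200, function(i) {
    s <- generate_landmarks(displacements = data.frame(
      name = "Me", side = "M", dx = 6, dy = 0, dz = 0),
      noise_sd_mm = 0.5, seed = 5000L + i)
    midsagittal_index(s, "Me")$magnitude
  }, numeric(1))
  se <- stats::sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - truth), 3 * se + 1e-12)
  # pure noise, no displacement: |index| strictly positive in expectation,
  # which is why normal subjects still show nonzero normative means
  null_reps <- vapply(1:100, function(i) {
    s <- generate_landmarks(noise_sd_mm = 0.5, seed = 9000L + i)
    midsagittal_index(s, "Me")$magnitude
  }, numeric(1))
  expect_true(all(null_reps > 0))
  expect_gt(mean(null_reps), 0.1)
})
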