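# Expected magnitudes below were computed with the independent hand-distance
# oracle (sqrt of summed squared distance differences to the references)
# before the implementation was written; see helper-oracle.R.

disp <- function(name, side, dx, dy = 0, dz = 0)
  data.frame(name = name, side = side, dx = dx, dy = dy, dz = dz,
             stringsAsFactors = FALSE)

test_that("bilateral index reproduces the worked oracle examples", {
  # Or(L) 35 -> 38 transversely: components to S, N, MidZ then RSS
  s <- generate_landmarks(displacements = disp("Or", "L", 3))
  r <- bilateral_index(s, "Or")
  o <- oracle_bilateral(s, "Or")
  expect_equal(r$magnitude, 4.103867149751316, tolerance = 1e-10)
  expect_equal(r$magnitude, o$magnitude, tolerance = 1e-12)
  expect_identical(r$direction, "left")
  expect_equal(r$signed_value, r$magnitude)
  expect_equal(unname(r$components),
               c(.edist(c(0,0,0), c(38,65,15)) - .edist(c(0,0,0), c(-35,65,15)),
                 .edist(c(0,75,35), c(38,65,15)) - .edist(c(0,75,35), c(-35,65,15)),
                 .edist(c(0,60,25), c(38,65,15)) - .edist(c(0,60,25), c(-35,65,15))),
               tolerance = 1e-12)

  # Go(L) purely vertical -6: nonzero magnitude, no transverse deviation
  s <- generate_landmarks(displacements = disp("Go", "L", 0, 0, -6))
  r <- bilateral_index(s, "Go")
  expect_equal(r$magnitude, 8.617745363892002, tolerance = 1e-10)
  expect_identical(r$direction, "none")
  expect_equal(r$signed_value, r$magnitude)  # '+' by convention

  # mirror-symmetric template: exactly zero
  r0 <- bilateral_index(skull_template(), "Or")
  expect_identical(r0$magnitude, 0)
  expect_identical(r0$direction, "none")
})

test_that("midsagittal index reproduces the worked oracle examples", {
  s <- generate_landmarks(displacements = disp("Me", "M", 6))
  r <- midsagittal_index(s, "Me")
  expect_equal(r$magnitude, 6.707756754140476, tolerance = 1e-10)
  expect_identical(r$direction, "left")
  expect_equal(r$signed_value, r$magnitude)
  # components are left-minus-right distance differences to Z and Po pairs
  expect_equal(unname(r$components),
               c(.edist(c(45,60,25), c(6,70,-100)) - .edist(c(-45,60,25), c(6,70,-100)),
                 .edist(c(60,-10,-10), c(6,70,-100)) - .edist(c(-60,-10,-10), c(6,70,-100))),
               tolerance = 1e-12)

  # mirrored displacement: same magnitude, right deviation, negative sign
  s2 <- generate_landmarks(displacements = disp("Me", "M", -6))
  r2 <- midsagittal_index(s2, "Me")
  expect_equal(r2$magnitude, r$magnitude, tolerance = 1e-12)
  expect_identical(r2$direction, "right")
  expect_equal(r2$signed_value, -r$magnitude, tolerance = 1e-12)

  expect_identical(midsagittal_index(skull_template(), "Me")$magnitude, 0)
})

test_that("compute_profile covers present landmarks in canonical order", {
  p <- compute_profile(skull_template())
  expect_identical(p$landmark,
                   c("Or", "Co", "ANS", "U6", "U1", "L1", "L6", "Go", "B", "Me"))
  expect_true(all(p$magnitude == 0))
  expect_true(all(p$direction == "none"))

  # partial set: references + Me only
  pts <- subset(skull_template()$points,
                name %in% c("N", "S", "Z", "Po", "Me"))
  p1 <- compute_profile(landmark_set(pts))
  expect_identical(p1$landmark, "Me")

  # locality: only the displaced landmarks become nonzero
  s <- generate_landmarks(displacements = rbind(disp("Me", "M", 6),
                                                disp("Or", "L", 3)))
  p2 <- compute_profile(s)
  nz <- p2$landmark[p2$magnitude > 0]
  expect_setequal(nz, c("Me", "Or"))
  expect_equal(p2$magnitude[p2$landmark == "Me"], 6.707756754140476,
               tolerance = 1e-10)
})

test_that("profiles match the brute-force oracle on randomized sets", {
  for (seed in 1:25) {
    s <- random_perturbed_set(seed)
    oracle_profile_check(s, compute_profile(s))
  }
})

test_that("indices are invariant under rigid transforms", {
  for (seed in 1:8) {
    s <- random_perturbed_set(seed, pose = FALSE)
    p <- compute_profile(s)
    for (k in 1:4) {
      rig <- random_rigid(seed * 100 + k)
      p2 <- compute_profile(apply_rigid_set(s, rig))
      expect_equal(p2$magnitude, p$magnitude, tolerance = 1e-6)
      expect_identical(p2$direction, p$direction)
      expect_equal(p2$signed_value, p$signed_value, tolerance = 1e-6)
    }
  }
})

test_that("label swap negates signed values; reflection alone is identity", {
  for (seed in 1:10) {
    s <- random_perturbed_set(seed)
    p <- compute_profile(s)
    ps <- compute_profile(swap_labels(s))
    expect_equal(ps$magnitude, p$magnitude, tolerance = 1e-9)
    expect_equal(ps$signed_value, -p$signed_value, tolerance = 1e-9)
    flip <- c(left = "right", right = "left", none = "none")
    expect_identical(ps$direction, unname(flip[p$direction]))
    # reflection across the reference plane is an isometry of all distances
    pr <- compute_profile(reflect_set(s))
    expect_equal(pr$signed_value, p$signed_value, tolerance = 1e-9)
    expect_identical(pr$direction, p$direction)
  }
})

test_that("scaling all coordinates by k scales every magnitude by k", {
  for (seed in 1:5) {
    s <- random_perturbed_set(seed, pose = FALSE)
    p <- compute_profile(s)
    for (k in c(0.5, 2, 3.7)) {
      sk <- s
      sk$points[, c("x", "y", "z")] <- k * sk$points[, c("x", "y", "z")]
      pk <- compute_profile(sk)
      expect_equal(pk$magnitude, k * p$magnitude, tolerance = 1e-8)
      expect_identical(pk$direction, p$direction)
    }
  }
})

test_that("bilateral magnitude is zero iff the pair is coincident or mirror-symmetric", {
  tpl <- skull_template()
  pl <- midsagittal_plane(tpl)
  set.seed(99)
  for (i in 1:20) {
    q <- c(runif(1, 5, 50), runif(1, -40, 70), runif(1, -90, 20))
    pts <- tpl$points
    # mirror image of q across the reference plane (template plane is x = 0)
    qm <- q - 2 * signed_plane_distance(pl, q) * pl$normal
    pts[pts$name == "Or" & pts$side == "L", c("x", "y", "z")] <- q
    pts[pts$name == "Or" & pts$side == "R", c("x", "y", "z")] <- qm
    expect_lt(landmark_set(pts) |> bilateral_index("Or") |> getElement("magnitude"),
              1e-9)
    # coincident pair is also equidistant from all references
    pts[pts$name == "Or" & pts$side == "R", c("x", "y", "z")] <- q
    expect_identical(bilateral_index(landmark_set(pts), "Or")$magnitude, 0)
    # a generic asymmetric position is nonzero
    pts[pts$name == "Or" & pts$side == "R", c("x", "y", "z")] <- qm + c(1, 2, 0.5)
    expect_gt(bilateral_index(landmark_set(pts), "Or")$magnitude, 1e-3)
  }
})

test_that("midline magnitude grows strictly with transverse displacement", {
  mags <- vapply(0:15, function(delta) {
    s <- generate_landmarks(displacements = disp("Me", "M", delta))
    midsagittal_index(s, "Me")$magnitude
  }, numeric(1))
  expect_identical(mags[1], 0)
  expect_true(all(diff(mags) > 0))
})

test_that("profile serialization round-trips in CSV and JSON", {
  p <- compute_profile(random_perturbed_set(3))
  pj <- read_profile(write_profile(p, format = "json"), format = "json")
  expect_equal(as.data.frame(pj), as.data.frame(p), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(pj, "components"), attr(p, "components"),
               tolerance = 1e-12)
  pc <- read_profile(write_profile(p, format = "csv"), format = "csv")
  expect_equal(pc$signed_value, p$signed_value, tolerance = 1e-12)
  expect_identical(pc$direction, p$direction)
})
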