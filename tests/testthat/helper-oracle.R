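# Independent brute-force oracles: plain coordinate arithmetic on the raw
# landmark table, sharing no code with the package's geometry/index path.

.edist <- function(a, b) sqrt(sum((a - b)^2))

.pt <- function(set, name, side = "M") {
  i <- which(set$points$name == name & set$points$side == side)
  as.numeric(set$points[i, c("x", "y", "z")])
}

# unsigned point-to-plane distance via tetrahedron volume / triangle area
.perp <- function(A, B, C, P) {
  v1 <- B - A; v2 <- C - A; w <- P - A
  cr <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  abs(sum(cr * w)) / sqrt(sum(cr^2))
}

oracle_bilateral <- function(set, nm, tol = 1e-6) {
  PL <- .pt(set, nm, "L"); PR <- .pt(set, nm, "R")
  S <- .pt(set, "S"); N <- .pt(set, "N")
  MidZ <- (.pt(set, "Z", "L") + .pt(set, "Z", "R")) / 2
  comps <- vapply(list(S, N, MidZ),
                  function(r) .edist(r, PL) - .edist(r, PR), numeric(1))
  mag <- sqrt(sum(comps^2))
  dl <- .perp(N, S, MidZ, PL); dr <- .perp(N, S, MidZ, PR)
  dir <- if (dl - dr > tol) "left" else if (dr - dl > tol) "right" else "none"
  list(magnitude = mag, direction = dir,
       signed = if (dir == "right") -mag else mag)
}

oracle_midsagittal <- function(set, nm, tol = 1e-6) {
  m <- .pt(set, nm, "M")
  dZL <- .edist(.pt(set, "Z", "L"), m); dZR <- .edist(.pt(set, "Z", "R"), m)
  dPL <- .edist(.pt(set, "Po", "L"), m); dPR <- .edist(.pt(set, "Po", "R"), m)
  mag <- sqrt((dZL - dZR)^2 + (dPL - dPR)^2)
  s <- (dZR - dZL) + (dPR - dPL)
  dir <- if (s > tol) "left" else if (s < -tol) "right" else "none"
  list(magnitude = mag, direction = dir,
       signed = if (dir == "right") -mag else mag)
}

oracle_profile_check <- function(set, profile, tol = 1e-9) {
  bil <- c("Or", "Co", "Go", "U6", "L6")
  for (i in seq_len(nrow(profile))) {
    nm <- profile$landmark[i]
    o <- if (nm %in% bil) oracle_bilateral(set, nm) else oracle_midsagittal(set, nm)
    expect_equal(profile$magnitude[i], o$magnitude, tolerance = 0,
                 info = nm)
    expect_lt(abs(profile$magnitude[i] - o$magnitude), tol)
    expect_identical(profile$direction[i], o$direction)
    expect_lt(abs(profile$signed_value[i] - o$signed), tol)
  }
  invisible(TRUE)
}

# randomized perturbed set: a handful of landmark displacements, optional pose
random_perturbed_set <- function(seed, max_disp = 6, pose = TRUE,
                                 noise_sd = 0) {
  set.seed(seed)
  cand <- data.frame(
    name = c("Or", "Co", "Go", "U6", "L6", "ANS", "U1", "L1", "B", "Me"),
    side = c("L", "R", "L", "R", "L", "M", "M", "M", "M", "M"),
    stringsAsFactors = FALSE)
  pick <- cand[sample(nrow(cand), sample(2:6, 1)), , drop = FALSE]
  pick$dx <- stats::runif(nrow(pick), -max_disp, max_disp)
  pick$dy <- stats::runif(nrow(pick), -max_disp, max_disp)
  pick$dz <- stats::runif(nrow(pick), -max_disp, max_disp)
  rot <- if (pose) stats::runif(3, -30, 30) else c(0, 0, 0)
  tra <- if (pose) stats::runif(3, -50, 50) else c(0, 0, 0)
  generate_landmarks(displacements = pick, rotation_deg = rot,
                     translation_mm = tra, noise_sd_mm = noise_sd,
                     seed = seed + 1000L)
}

# independent random rigid transform (rotation via QR, det fixed to +1)
random_rigid <- function(seed) {
  set.seed(seed)
  M <- matrix(stats::rnorm(9), 3)
  Q <- qr.Q(qr(M))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  list(R = Q, t = stats::runif(3, -100, 100))
}

apply_rigid_set <- function(set, rigid) {
  xyz <- as.matrix(set$points[, c("x", "y", "z")])
  set$points[, c("x", "y", "z")] <- sweep(xyz %*% t(rigid$R), 2, rigid$t, "+")
  set
}

# reflection across the N-S-MidZ plane without touching side labels
reflect_set <- function(set) {
  N <- .pt(set, "N"); S <- .pt(set, "S")
  MidZ <- (.pt(set, "Z", "L") + .pt(set, "Z", "R")) / 2
  v1 <- S - N; v2 <- MidZ - N
  n <- c(v1[2] * v2[3] - v1[3] * v2[2],
         v1[3] * v2[1] - v1[1] * v2[3],
         v1[1] * v2[2] - v1[2] * v2[1])
  n <- n / sqrt(sum(n^2))
  xyz <- as.matrix(set$points[, c("x", "y", "z")])
  d <- (xyz - matrix(N, nrow(xyz), 3, byrow = TRUE)) %*% n
  set$points[, c("x", "y", "z")] <- xyz - 2 * d %*% t(n)
  set
}

template_csv_lines <- function() write_landmarks(skull_template(), format = "csv")
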