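# Synthetic landmark generator: the test substrate standing in for patient
# CTs. Starts from an exactly mirror-symmetric "unit skull" template, applies
# named per-landmark displacements (the known asymmetry), then isotropic
# Gaussian landmark-placement noise, then a rigid pose (intrinsic z-y-x
# rotation + translation). All randomness is seeded and reproducible.

SKULL_TEMPLATE_POINTS <- local({
  bi <- function(nm, x, y, z)
    data.frame(name = nm, side = c("L", "R"),
               x = c(x, -x), y = y, z = z, stringsAsFactors = FALSE)
  mid <- function(nm, y, z)
    data.frame(name = nm, side = "M", x = 0, y = y, z = z,
               stringsAsFactors = FALSE)
  rbind(
    mid("S", 0, 0), mid("N", 75, 35),
    bi("Z", 45, 60, 25), bi("Po", 60, -10, -10),
    bi("Or", 35, 65, 15), bi("Co", 55, -5, -15), bi("Go", 50, 5, -80),
    bi("U6", 25, 45, -70), bi("L6", 27, 45, -75),
    mid("ANS", 80, -45), mid("U1", 82, -60), mid("L1", 82, -65),
    mid("B", 78, -85), mid("Me", 70, -100)
  )
})

#' Symmetric skull template
#'
#' The canonical bilaterally symmetric landmark configuration (mm): every
#' bilateral pair is an exact mirror pair across the x = 0 plane (positive x
#' is the anatomical left) and every midline landmark lies on x = 0, so
#' \code{\link{compute_profile}} on the template is identically zero.
#'
#' @param subject,timepoint labels for the returned set.
#' @return a \code{landmark_set} with all 14 landmark names (24 points).
#' @export
#' @examples
#' skull_template()
skull_template <- function(subject = "template", timepoint = "T0") {
  landmark_set(SKULL_TEMPLATE_POINTS, subject = subject, timepoint = timepoint)
}

rotation_matrix_zyx <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cz <- cos(a[1]); sz <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cx <- cos(a[3]); sx <- sin(a[3])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  Rz %*% Ry %*% Rx
}

#' Apply a rigid transform to a landmark set
#'
#' Rotation (intrinsic z-y-x angles, degrees) followed by translation (mm),
#' applied to every point. Labels are untouched: the asymmetry index is
#' invariant under this operation.
#'
#' @param set a \code{landmark_set}.
#' @param rotation_deg numeric length-3 rotation angles in degrees.
#' @param translation_mm numeric length-3 translation in mm.
#' @return the transformed \code{landmark_set}.
#' @export
rigid_transform <- function(set, rotation_deg = c(0, 0, 0),
                            translation_mm = c(0, 0, 0)) {
  R <- rotation_matrix_zyx(rotation_deg)
  xyz <- as.matrix(set$points[, c("x", "y", "z")])
  xyz <- xyz %*% t(R)
  xyz <- sweep(xyz, 2, translation_mm, "+")
  set$points[, c("x", "y", "z")] <- xyz
  set
}

#' Generate a landmark set with known asymmetry
#'
#' Starts from \code{\link{skull_template}}, adds the requested per-landmark
#' displacement vectors (the ground-truth asymmetry), then independent
#' zero-mean Gaussian placement noise per coordinate, then the rigid pose.
#' Noise precedes the pose by convention (it models landmark-picking error in
#' the scanner frame; for isotropic noise the order is statistically
#' irrelevant but must be fixed for seeded reproducibility).
#'
#' @param displacements \code{NULL}, or a data frame with columns \code{name},
#'   \code{side} (\code{"M"} or empty for midline), \code{dx}, \code{dy},
#'   \code{dz} in mm.
#' @param rotation_deg,translation_mm rigid pose (see
#'   \code{\link{rigid_transform}}).
#' @param noise_sd_mm SD of the Gaussian placement noise per coordinate, mm.
#' @param seed integer seed for the noise; the global RNG state is restored
#'   afterwards. Same spec + seed gives an identical set.
#' @param subject,timepoint labels.
#' @return a \code{landmark_set}.
#' @export
#' @examples
#' s <- generate_landmarks(
#'   displacements = data.frame(name = "Me", side = "M", dx = 6, dy = 0, dz = 0),
#'   rotation_deg = c(10, -5, 3), translation_mm = c(12, -4, 7))
#' compute_profile(s)  # only Me nonzero, ~6.71 mm left
generate_landmarks <- function(displacements = NULL,
                               rotation_deg = c(0, 0, 0),
                               translation_mm = c(0, 0, 0),
                               noise_sd_mm = 0, seed = NULL,
                               subject = "synthetic", timepoint = "T0") {
  set <- skull_template(subject = subject, timepoint = timepoint)
  if (!is.null(displacements) && nrow(displacements)) {
    d <- as.data.frame(displacements, stringsAsFactors = FALSE)
    need <- c("name", "dx", "dy", "dz")
    if (!all(need %in% names(d)))
      parse_error("displacements need columns name, side, dx, dy, dz")
    if (is.null(d$side)) d$side <- "M"
    d$side <- toupper(trimws(as.character(d$side)))
    d$side[is.na(d$side) | d$side == ""] <- "M"
    d$name <- canonical_name(d$name)
    for (i in seq_len(nrow(d))) {
      j <- which(set$points$name == d$name[i] & set$points$side == d$side[i])
      if (is.na(d$name[i]) || !length(j))
        validation_error(sprintf(
          "displacement %d references unknown landmark '%s' side '%s'",
          i, displacements$name[i], d$side[i]))
      set$points[j, c("x", "y", "z")] <-
        set$points[j, c("x", "y", "z")] + c(d$dx[i], d$dy[i], d$dz[i])
    }
  }
  if (noise_sd_mm < 0) validation_error("noise SD must be >= 0")
  if (noise_sd_mm > 0) {
    n <- nrow(set$points)
    noise <- with_seed(seed, matrix(stats::rnorm(3 * n, 0, noise_sd_mm), n, 3))
    set$points[, c("x", "y", "z")] <- set$points[, c("x", "y", "z")] + noise
  }
  rigid_transform(set, rotation_deg, translation_mm)
}

# run expr under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a landmark set from a JSON asymmetry spec
#'
#' Spec keys: \code{displacements} (list of \code{{name, side, dx, dy, dz}}),
#' \code{rotation_deg}, \code{translation_mm}, \code{noise_sd_mm},
#' \code{seed}, \code{subject}, \code{timepoint}; all optional.
#'
#' @param path JSON file path or character vector of JSON text.
#' @param seed overrides the spec's seed when non-\code{NULL}.
#' @return a \code{landmark_set}.
#' @export
generate_from_spec <- function(path, seed = NULL) {
  txt <- if (length(path) == 1L && file.exists(path))
    readLines(path, warn = FALSE) else as.character(path)
  spec <- tryCatch(jsonlite::fromJSON(paste(txt, collapse = "\n"),
                                      simplifyDataFrame = TRUE),
                   error = function(e) parse_error(
                     sprintf("malformed asymmetry spec: %s",
                             conditionMessage(e))))
  getd <- function(key, default) if (is.null(spec[[key]])) default else spec[[key]]
  generate_landmarks(
    displacements = getd("displacements", NULL),
    rotation_deg = getd("rotation_deg", c(0, 0, 0)),
    translation_mm = getd("translation_mm", c(0, 0, 0)),
    noise_sd_mm = getd("noise_sd_mm", 0),
    seed = if (!is.null(seed)) seed else getd("seed", NULL),
    subject = getd("subject", "synthetic"),
    timepoint = getd("timepoint", "T0"))
}

#' Mirror a landmark set across its midsagittal plane
#'
#' Reflects every point across the N-S-MidZ plane and swaps the L/R side
#' labels. An involution; the symmetric template is its own mirror image, and
#' profiles are identical under this operation (reflect + relabel), while a
#' label swap alone negates every signed value.
#'
#' @param set a \code{landmark_set}.
#' @return the mirrored \code{landmark_set}.
#' @export
mirror_landmarks <- function(set) {
  plane <- midsagittal_plane(set)
  xyz <- as.matrix(set$points[, c("x", "y", "z")])
  sd <- xyz %*% plane$normal + plane$offset
  xyz <- xyz - 2 * sd %*% t(plane$normal)
  set$points[, c("x", "y", "z")] <- xyz
  set$points$side <- swap_sides(set$points$side)
  set
}

#' Swap the L/R labels of a landmark set
#'
#' Relabels without moving any point, which negates every signed index value
#' and flips left/right directions while preserving magnitudes.
#'
#' @param set a \code{landmark_set}.
#' @return the relabelled \code{landmark_set}.
#' @export
swap_labels <- function(set) {
  set$points$side <- swap_sides(set$points$side)
  set
}

swap_sides <- function(side) {
  out <- side
  out[side == "L"] <- "R"
  out[side == "R"] <- "L"
  out
}
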