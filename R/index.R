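# The core computation: a signed facial asymmetry index per measurement
# landmark, built purely from inter-landmark distances so it is invariant to
# the rigid frame the coordinates arrive in.
#
# Bilateral landmarks (Or, Co, Go, U6, L6): for each of the three midline
# references S, N and MidZ, take the difference between its distance to the
# left and to the right member of the pair; the index magnitude is the root
# of the sum of the squared differences. The deviation direction is the side
# whose perpendicular distance to the N-S-MidZ plane is longer.
#
# Midline landmarks (ANS, U1, L1, B, Me): distance differences to the Z pair
# and the Po pair; direction is the side whose references are closer (a point
# deviated left is closer to the left-side references).
#
# Sign convention: left deviation positive, right deviation negative.

# tie tolerance in mm below which no transverse direction is assigned
DIRECTION_TOL <- 1e-6

new_asymmetry_result <- function(landmark, components, direction) {
  magnitude <- sqrt(sum(components^2))
  signed <- if (direction == "right") -magnitude else magnitude
  structure(list(landmark = landmark, magnitude = magnitude,
                 direction = direction, signed_value = signed,
                 components = components),
            class = "asymmetry_result")
}

#' @export
print.asymmetry_result <- function(x, ...) {
  cat(sprintf("%s: index %.4f mm, deviation %s (signed %+.4f)\n",
              x$landmark, x$magnitude, x$direction, x$signed_value))
  invisible(x)
}

#' Facial asymmetry index of a bilateral landmark
#'
#' For each reference landmark r in (S, N, MidZ) the component
#' d_r = dist(r, P_L) - dist(r, P_R) is computed; the magnitude is
#' sqrt(sum d_r^2). It is 0 exactly when the pair sits in a 3D-symmetric
#' position relative to the three references. The deviation direction is the
#' side with the longer unsigned perpendicular distance to the midsagittal
#' (N-S-MidZ) plane; when the two perpendicular distances differ by less than
#' \code{tol} the direction is \code{"none"} (e.g. purely vertical
#' asymmetry) and the signed value carries \code{+} by convention.
#'
#' @param set a \code{landmark_set}.
#' @param landmark a bilateral measurement landmark name (Or, Co, Go, U6, L6).
#' @param tol tie tolerance in mm for the direction rule.
#' @return an \code{asymmetry_result} with fields \code{landmark},
#'   \code{magnitude} (mm, >= 0), \code{direction} (left/right/none),
#'   \code{signed_value} (mm) and \code{components} (the three d_r).
#' @export
#' @examples
#' s <- generate_landmarks(displacements = data.frame(
#'   name = "Or", side = "L", dx = 3, dy = 0, dz = 0))
#' bilateral_index(s, "Or")  # ~4.10 mm, deviated left
bilateral_index <- function(set, landmark, tol = DIRECTION_TOL) {
  if (!identical(laterality_of(landmark), "bilateral"))
    validation_error(sprintf("'%s' is not a bilateral landmark", landmark))
  pl_pt <- get_point(set, landmark, "L")
  pr_pt <- get_point(set, landmark, "R")
  refs <- list(get_point(set, "S"), get_point(set, "N"), derive_midz(set))
  comps <- vapply(refs, function(r)
    point_distance(r, pl_pt) - point_distance(r, pr_pt), numeric(1))
  names(comps) <- c("S", "N", "MidZ")
  plane <- midsagittal_plane(set)
  dl <- abs(signed_plane_distance(plane, pl_pt))
  dr <- abs(signed_plane_distance(plane, pr_pt))
  direction <- if (dl - dr > tol) "left" else if (dr - dl > tol) "right" else "none"
  new_asymmetry_result(landmark, comps, direction)
}

#' Facial asymmetry index of a midline landmark
#'
#' Components are the distance differences to the two bilateral reference
#' pairs: d_Z = dist(Z_L, m) - dist(Z_R, m) and d_Po = dist(Po_L, m) -
#' dist(Po_R, m); the magnitude is sqrt(d_Z^2 + d_Po^2), zero exactly when the
#' point lies on the true midsagittal plane of the references. Direction is
#' taken from s = (dist(Z_R, m) - dist(Z_L, m)) + (dist(Po_R, m) -
#' dist(Po_L, m)): a point deviated to the left is closer to the left-side
#' references, so s > tol means left, s < -tol right, otherwise none.
#'
#' @param set a \code{landmark_set}.
#' @param landmark a midline measurement landmark name (ANS, U1, L1, B, Me).
#' @param tol tie tolerance in mm.
#' @return an \code{asymmetry_result}; components named \code{Z}, \code{Po}.
#' @export
#' @examples
#' s <- generate_landmarks(displacements = data.frame(
#'   name = "Me", side = "M", dx = 6, dy = 0, dz = 0))
#' midsagittal_index(s, "Me")  # ~6.71 mm, deviated left
midsagittal_index <- function(set, landmark, tol = DIRECTION_TOL) {
  if (!identical(laterality_of(landmark), "midline"))
    validation_error(sprintf("'%s' is not a midline landmark", landmark))
  m <- get_point(set, landmark, "M")
  dz <- point_distance(get_point(set, "Z", "L"), m) -
        point_distance(get_point(set, "Z", "R"), m)
  dpo <- point_distance(get_point(set, "Po", "L"), m) -
         point_distance(get_point(set, "Po", "R"), m)
  s <- -(dz + dpo)  # right-minus-left distance differences
  direction <- if (s > tol) "left" else if (s < -tol) "right" else "none"
  new_asymmetry_result(landmark, c(Z = dz, Po = dpo), direction)
}

#' Asymmetry profile over all measurement landmarks present
#'
#' Applies \code{\link{bilateral_index}} to each present bilateral measurement
#' landmark and \code{\link{midsagittal_index}} to each present midline
#' measurement landmark, in the canonical axis order Or, Co, ANS, U6, U1, L1,
#' L6, Go, B, Me. Absent landmarks are simply omitted, so a partial dentition
#' never blocks the analysis.
#'
#' @param set a \code{landmark_set}.
#' @param tol tie tolerance in mm passed to the per-landmark indices.
#' @return an \code{asymmetry_profile}: a data frame with columns
#'   \code{landmark}, \code{magnitude}, \code{direction}, \code{signed_value},
#'   plus attributes \code{components} (named list of the per-reference
#'   distance differences), \code{subject} and \code{timepoint}.
#' @export
#' @examples
#' compute_profile(skull_template())  # all magnitudes 0
compute_profile <- function(set, tol = DIRECTION_TOL) {
  tbl <- landmark_names()
  results <- list()
  for (nm in MEASUREMENT_ORDER) {
    lat <- tbl$laterality[tbl$name == nm]
    present <- if (lat == "bilateral")
      has_point(set, nm, "L") && has_point(set, nm, "R")
    else has_point(set, nm, "M")
    if (!present) next
    results[[nm]] <- if (lat == "bilateral")
      bilateral_index(set, nm, tol) else midsagittal_index(set, nm, tol)
  }
  as_profile(results, subject = set$subject, timepoint = set$timepoint)
}

as_profile <- function(results, subject = "", timepoint = "") {
  df <- data.frame(
    landmark = vapply(results, `[[`, character(1), "landmark"),
    magnitude = vapply(results, `[[`, numeric(1), "magnitude"),
    direction = vapply(results, `[[`, character(1), "direction"),
    signed_value = vapply(results, `[[`, numeric(1), "signed_value"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(df,
            components = lapply(results, `[[`, "components"),
            subject = subject, timepoint = timepoint,
            class = c("asymmetry_profile", "data.frame"))
}

#' @export
print.asymmetry_profile <- function(x, ...) {
  cat(sprintf("<asymmetry_profile> subject='%s' timepoint='%s'\n",
              attr(x, "subject"), attr(x, "timepoint")))
  print.data.frame(x, row.names = FALSE, digits = 5)
  invisible(x)
}

# profile serialization --------------------------------------------------------

#' Write an asymmetry profile to CSV or JSON
#'
#' CSV columns: \code{landmark,magnitude,direction,signed_value}. JSON is an
#' array of objects additionally carrying the per-reference \code{components}.
#'
#' @param profile an \code{asymmetry_profile}.
#' @param path output path or \code{NULL} to return the text.
#' @param format \code{"csv"} or \code{"json"}.
#' @return (invisibly) the text lines.
#' @export
write_profile <- function(profile, path = NULL, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    lines <- c("landmark,magnitude,direction,signed_value",
               sprintf("%s,%s,%s,%s", profile$landmark,
                       fmt_num(profile$magnitude), profile$direction,
                       fmt_num(profile$signed_value)))
  } else {
    comps <- attr(profile, "components")
    rows <- lapply(seq_len(nrow(profile)), function(i)
      list(landmark = profile$landmark[i],
           magnitude = profile$magnitude[i],
           direction = profile$direction[i],
           signed_value = profile$signed_value[i],
           components = as.list(comps[[profile$landmark[i]]])))
    lines <- strsplit(jsonlite::toJSON(rows, auto_unbox = TRUE, digits = NA,
                                       pretty = TRUE), "\n")[[1]]
  }
  if (!is.null(path)) writeLines(lines, path, useBytes = TRUE)
  invisible(lines)
}

#' Read an asymmetry profile written by \code{\link{write_profile}}
#'
#' @param path file path or character vector of lines.
#' @param format \code{"auto"}, \code{"csv"} or \code{"json"}.
#' @return an \code{asymmetry_profile}.
#' @export
read_profile <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  txt <- if (length(path) == 1L && file.exists(path)) {
    if (format == "auto")
      format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
    readLines(path, warn = FALSE)
  } else as.character(path)
  if (format == "auto")
    format <- if (grepl("^\\s*\\[", paste(txt, collapse = ""))) "json" else "csv"
  if (format == "json") {
    rows <- jsonlite::fromJSON(paste(txt, collapse = "\n"),
                               simplifyDataFrame = FALSE)
    results <- lapply(rows, function(r)
      structure(list(landmark = r$landmark, magnitude = r$magnitude,
                     direction = r$direction, signed_value = r$signed_value,
                     components = unlist(r$components)),
                class = "asymmetry_result"))
    names(results) <- vapply(results, `[[`, character(1), "landmark")
    as_profile(results)
  } else {
    df <- utils::read.csv(text = txt, stringsAsFactors = FALSE)
    if (!all(c("landmark", "magnitude", "direction", "signed_value") %in% names(df)))
      parse_error("profile CSV must have columns landmark,magnitude,direction,signed_value")
    structure(df[, c("landmark", "magnitude", "direction", "signed_value")],
              components = NULL, subject = "", timepoint = "",
              class = c("asymmetry_profile", "data.frame"))
  }
}
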