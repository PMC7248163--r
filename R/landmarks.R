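# Landmark data model and file I/O.
#
# A landmark set is a validated table of named anatomical points for one
# subject and timepoint. Coordinates are millimetres in an arbitrary rigid
# frame: the analysis uses inter-landmark distances only, so no axis
# convention is assumed. Patient left/right is carried by the side label,
# never by coordinate sign.

#' Canonical landmark names and laterality classes
#'
#' The closed vocabulary of anatomical landmarks. Bilateral landmarks occur
#' as a left/right pair; midline landmarks are single points nominally on the
#' midsagittal plane. \code{MidZ} (midpoint of the two Z points) is always
#' derived, never an input landmark.
#'
#' @return A data frame with columns \code{name} (canonical symbol),
#'   \code{laterality} (\code{"bilateral"} or \code{"midline"}), \code{role}
#'   (\code{"reference"} or \code{"measurement"}) and \code{definition}.
#' @export
#' @examples
#' landmark_names()
landmark_names <- function() {
  data.frame(
    name = c("S", "N", "Z", "Po",
             "Or", "Co", "Go", "U6", "L6",
             "ANS", "U1", "L1", "B", "Me"),
    laterality = c("midline", "midline", "bilateral", "bilateral",
                   "bilateral", "bilateral", "bilateral", "bilateral",
                   "bilateral",
                   "midline", "midline", "midline", "midline", "midline"),
    role = c("reference", "reference", "reference", "reference",
             "measurement", "measurement", "measurement", "measurement",
             "measurement",
             "measurement", "measurement", "measurement", "measurement",
             "measurement"),
    definition = c(
      "sella: center of the pituitary fossa",
      "nasion: nasofrontal suture at the midline",
      "frontozygomatic suture point (most inferior point on the zygomaticomaxillary suture)",
      "porion: most superior point of the external auditory meatus",
      "orbitale: lowest point of the orbital rim",
      "condylion: most superior point of the condyle",
      "gonion: most inferior and posterior point at the angle of the mandible",
      "central point of the pulp cavity of the upper first molar",
      "central point of the pulp cavity of the lower first molar",
      "anterior nasal spine",
      "superior contact point of the upper central incisors",
      "superior contact point of the lower central incisors",
      "B point: deepest point of the bony concavity in the mandibular midline",
      "menton: lowest border of the mandible"),
    stringsAsFactors = FALSE
  )
}

# Measurement landmarks in canonical profile / chart axis order.
MEASUREMENT_ORDER <- c("Or", "Co", "ANS", "U6", "U1", "L1", "L6", "Go", "B", "Me")

# Reference landmarks that every set must contain.
REQUIRED_REFERENCES <- list(
  c("N", "M"), c("S", "M"),
  c("Z", "L"), c("Z", "R"),
  c("Po", "L"), c("Po", "R")
)

# Accepted long-form aliases (lower-cased key -> canonical symbol).
LANDMARK_ALIASES <- c(
  "sella" = "S", "nasion" = "N", "z point" = "Z", "porion" = "Po",
  "orbitale" = "Or", "condylion" = "Co", "gonion" = "Go",
  "upper first molar" = "U6", "lower first molar" = "L6",
  "anterior nasal spine" = "ANS", "upper incisor" = "U1",
  "lower incisor" = "L1", "b point" = "B", "menton" = "Me"
)

# condition helpers -----------------------------------------------------------

fai_error <- function(msg, class) {
  stop(structure(class = c(class, "fai_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

validation_error <- function(msg) fai_error(msg, "fai_validation_error")
parse_error <- function(msg) fai_error(msg, "fai_parse_error")

#' Canonicalize a landmark name
#'
#' Case-insensitive match against the canonical symbols and accepted
#' long-form aliases ("Gonion", "Menton", "B point", ...).
#'
#' @param name character vector of raw names.
#' @return character vector of canonical symbols.
#' @keywords internal
canonical_name <- function(name) {
  tbl <- landmark_names()
  low <- tolower(trimws(name))
  out <- tbl$name[match(low, tolower(tbl$name))]
  alias <- unname(LANDMARK_ALIASES[low])
  out[is.na(out)] <- alias[is.na(out)]
  out
}

laterality_of <- function(name) {
  tbl <- landmark_names()
  tbl$laterality[match(name, tbl$name)]
}

# landmark_set ----------------------------------------------------------------

#' Construct a validated landmark set
#'
#' Validates and canonicalizes a table of landmark coordinates. Names are
#' matched case-insensitively (aliases such as "Gonion" accepted); the side
#' must be \code{"L"} or \code{"R"} for bilateral landmarks and \code{"M"}
#' (or empty, canonicalized to \code{"M"}) for midline landmarks. The six
#' reference landmarks N, S, Z(L/R) and Po(L/R) are mandatory; measurement
#' landmarks are individually optional, but a bilateral landmark must be
#' present as a full L/R pair or not at all.
#'
#' @param data data frame with columns \code{name}, \code{side}, \code{x},
#'   \code{y}, \code{z} (coordinates in mm).
#' @param subject,timepoint free-text labels.
#' @return An object of class \code{landmark_set}: a list with elements
#'   \code{subject}, \code{timepoint} and \code{points} (the canonical table).
#' @export
#' @examples
#' tpl <- skull_template()
#' head(tpl$points)
landmark_set <- function(data, subject = "", timepoint = "") {
  need <- c("name", "side", "x", "y", "z")
  if (!all(need %in% names(data)))
    parse_error(sprintf("landmark table must have columns %s",
                        paste(need, collapse = ",")))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  n <- nrow(data)
  if (n == 0L) validation_error("landmark table is empty")

  raw_name <- as.character(data$name)
  if (any(tolower(trimws(raw_name)) == "midz"))
    validation_error(sprintf(
      "row %d: MidZ is derived, not input",
      which(tolower(trimws(raw_name)) == "midz")[1]))
  cname <- canonical_name(raw_name)
  if (anyNA(cname)) {
    bad <- which(is.na(cname))[1]
    validation_error(sprintf("row %d: unknown landmark name '%s'",
                             bad, raw_name[bad]))
  }

  side <- toupper(trimws(as.character(data$side)))
  side[is.na(side) | side == ""] <- "M"
  lat <- laterality_of(cname)
  bad <- which(lat == "bilateral" & !(side %in% c("L", "R")))
  if (length(bad))
    validation_error(sprintf(
      "row %d: bilateral landmark '%s' needs side L or R (got '%s')",
      bad[1], cname[bad[1]], side[bad[1]]))
  bad <- which(lat == "midline" & side != "M")
  if (length(bad))
    validation_error(sprintf(
      "row %d: midline landmark '%s' must have empty or 'M' side (got '%s')",
      bad[1], cname[bad[1]], side[bad[1]]))

  coords <- vapply(c("x", "y", "z"), function(cl) {
    v <- suppressWarnings(as.numeric(data[[cl]]))
    v
  }, numeric(n))
  coords <- matrix(coords, nrow = n)
  if (anyNA(coords) || any(!is.finite(coords))) {
    bad <- which(apply(coords, 1L, function(r) anyNA(r) || any(!is.finite(r))))[1]
    validation_error(sprintf(
      "row %d ('%s'): coordinates must be finite numbers", bad, cname[bad]))
  }

  key <- paste(cname, side)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    validation_error(sprintf("duplicate landmark entry: %s",
                             sub(" ", "/", dup)))
  }

  # orphan bilateral sides
  for (nm in unique(cname[lat == "bilateral"])) {
    s <- side[cname == nm]
    if (!setequal(s, c("L", "R")))
      validation_error(sprintf(
        "bilateral landmark '%s' present with side %s only (needs L/R pair)",
        nm, paste(s, collapse = ",")))
  }

  for (ref in REQUIRED_REFERENCES) {
    if (!any(cname == ref[1] & side == ref[2]))
      validation_error(sprintf(
        "missing required reference landmark %s%s", ref[1],
        if (ref[2] == "M") "" else paste0("(", ref[2], ")")))
  }

  pts <- data.frame(name = cname, side = side,
                    x = coords[, 1], y = coords[, 2], z = coords[, 3],
                    stringsAsFactors = FALSE)
  structure(list(subject = as.character(subject),
                 timepoint = as.character(timepoint),
                 points = pts),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> subject='%s' timepoint='%s' (%d landmarks)\n",
              x$subject, x$timepoint, nrow(x$points)))
  print(x$points, row.names = FALSE)
  invisible(x)
}

#' Look up one landmark position
#'
#' @param set a \code{landmark_set}.
#' @param name canonical landmark name.
#' @param side \code{"L"}, \code{"R"} or \code{"M"}.
#' @param required error (rather than return \code{NULL}) when absent.
#' @return numeric xyz vector in mm, or \code{NULL} if absent and not required.
#' @export
get_point <- function(set, name, side = "M", required = TRUE) {
  i <- which(set$points$name == name & set$points$side == side)
  if (!length(i)) {
    if (required)
      validation_error(sprintf("landmark %s%s not present in set", name,
                               if (side == "M") "" else paste0("(", side, ")")))
    return(NULL)
  }
  as.numeric(set$points[i, c("x", "y", "z")])
}

has_point <- function(set, name, side = "M") {
  any(set$points$name == name & set$points$side == side)
}

#' Midpoint of the two frontozygomatic suture points
#'
#' MidZ, the midpoint of the line between Z(L) and Z(R). Together with nasion
#' and sella it defines the midsagittal reference plane. It commutes with any
#' rigid transform applied to the whole set.
#'
#' @param set a \code{landmark_set} containing both Z points.
#' @return numeric xyz vector in mm.
#' @export
#' @examples
#' derive_midz(skull_template())  # (0, 60, 25)
derive_midz <- function(set) {
  (get_point(set, "Z", "L") + get_point(set, "Z", "R")) / 2
}

# I/O -------------------------------------------------------------------------

#' Read a landmark file
#'
#' CSV dialect: UTF-8, comma-delimited, header \code{name,side,x,y,z}, one
#' landmark per row, coordinates in mm, side one of L/R/M/empty. JSON dialect:
#' an object with keys \code{subject}, \code{timepoint} and \code{landmarks}
#' (a list of \code{{name, side, x, y, z}}).
#'
#' @param path file path, or a character vector of lines.
#' @param format \code{"auto"} (by extension / first character), \code{"csv"}
#'   or \code{"json"}.
#' @param subject,timepoint labels used for CSV input (JSON carries its own).
#' @return a validated \code{landmark_set}.
#' @export
read_landmarks <- function(path, format = c("auto", "csv", "json"),
                           subject = "", timepoint = "") {
  format <- match.arg(format)
  txt <- if (length(path) == 1L && file.exists(path)) {
    if (format == "auto")
      format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
    readLines(path, warn = FALSE, encoding = "UTF-8")
  } else as.character(path)
  if (format == "auto")
    format <- if (grepl("^\\s*\\{", paste(txt, collapse = ""))) "json" else "csv"

  if (format == "json") {
    obj <- tryCatch(jsonlite::fromJSON(paste(txt, collapse = "\n"),
                                       simplifyDataFrame = TRUE),
                    error = function(e) parse_error(
                      sprintf("malformed JSON landmark file: %s",
                              conditionMessage(e))))
    if (is.null(obj$landmarks)) parse_error("JSON landmark file lacks 'landmarks'")
    lm <- as.data.frame(obj$landmarks, stringsAsFactors = FALSE)
    if (is.null(lm$side)) lm$side <- ""
    lm$side[is.na(lm$side)] <- ""
    landmark_set(lm,
                 subject = if (!is.null(obj$subject)) obj$subject else subject,
                 timepoint = if (!is.null(obj$timepoint)) obj$timepoint else timepoint)
  } else {
    df <- tryCatch(utils::read.csv(text = txt, stringsAsFactors = FALSE,
                                   colClasses = "character"),
                   error = function(e) parse_error(
                     sprintf("malformed CSV landmark file: %s",
                             conditionMessage(e))))
    if (!identical(names(df), c("name", "side", "x", "y", "z")))
      parse_error("CSV header must be exactly 'name,side,x,y,z'")
    landmark_set(df, subject = subject, timepoint = timepoint)
  }
}

#' Write a landmark set
#'
#' Emits the canonical CSV or JSON dialect (see \code{\link{read_landmarks}}).
#' Coordinates are written with enough digits that a read/write round trip
#' reproduces them beyond 6 decimal places.
#'
#' @param set a \code{landmark_set}.
#' @param path output path, or \code{NULL} to return the text.
#' @param format \code{"csv"} or \code{"json"}.
#' @return (invisibly) the emitted text, as a character vector of lines.
#' @export
write_landmarks <- function(set, path = NULL, format = c("csv", "json")) {
  format <- match.arg(format)
  p <- set$points
  if (format == "csv") {
    lines <- c("name,side,x,y,z",
               sprintf("%s,%s,%s,%s,%s", p$name, p$side,
                       fmt_num(p$x), fmt_num(p$y), fmt_num(p$z)))
  } else {
    obj <- list(subject = set$subject, timepoint = set$timepoint,
                landmarks = lapply(seq_len(nrow(p)), function(i)
                  list(name = p$name[i], side = p$side[i],
                       x = p$x[i], y = p$y[i], z = p$z[i])))
    lines <- strsplit(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                       pretty = TRUE), "\n")[[1]]
  }
  if (!is.null(path)) writeLines(lines, path, useBytes = TRUE)
  invisible(lines)
}

# 17 significant digits round-trips doubles exactly through decimal text
fmt_num <- function(x) {
  out <- formatC(x, format = "g", digits = 17)
  trimws(out)
}
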