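# Normative reference ranges and symmetry classification.
#
# The packaged table holds, per measurement landmark, the mean and SD of the
# absolute asymmetry index observed in a 25-subject normal-occlusion male
# cohort with clinically balanced faces (menton within 4 mm of the
# midsagittal plane). A landmark is classified asymmetric when its |index|
# exceeds mean + z * SD; z defaults to 1.96 (two-sided 5% normal quantile)
# and is configurable because the source chart's "(p = 0.05)" band is
# ambiguous between 1, 1.96 and 2 SD.

NORMATIVE_DEFAULTS <- data.frame(
  landmark = c("Or", "Co", "ANS", "U6", "U1", "L1", "L6", "Go", "B", "Me"),
  mean_abs = c(2.12, 3.38, 1.77, 2.81, 2.05, 1.97, 2.35, 3.36, 2.18, 2.37),
  sd_abs   = c(1.28, 1.41, 0.83, 1.61, 1.07, 1.07, 1.53, 1.29, 1.05, 1.17),
  stringsAsFactors = FALSE
)

#' Packaged normative asymmetry-index table
#'
#' Mean and SD of the absolute asymmetry index per measurement landmark in
#' the normal standard group (n = 25, males, normal occlusion). Units mm.
#'
#' @param z multiplier on the SD for the symmetry threshold
#'   (threshold = mean_abs + z * sd_abs).
#' @return a \code{normative_table}: data frame with columns \code{landmark},
#'   \code{mean_abs}, \code{sd_abs} and attribute \code{z}.
#' @export
#' @examples
#' normative_table()
normative_table <- function(z = 1.96) {
  if (!is.finite(z) || z < 0) validation_error("z multiplier must be >= 0")
  structure(NORMATIVE_DEFAULTS, z = z,
            provenance = "normal standard group, n = 25 (absolute index values)",
            class = c("normative_table", "data.frame"))
}

#' Load a normative table, optionally overriding the packaged defaults
#'
#' The override file is CSV with columns \code{landmark,mean_abs,sd_abs};
#' a comment line \code{# z=<float>} before the header overrides the z
#' multiplier. Entries replace the packaged defaults per landmark.
#'
#' @param path override CSV path, or \code{NULL} for the packaged defaults.
#' @param z z multiplier; a \code{# z=} line in the file takes precedence.
#' @return a \code{normative_table}.
#' @export
load_normative <- function(path = NULL, z = 1.96) {
  tab <- normative_table(z)
  if (is.null(path)) return(tab)
  lines <- readLines(path, warn = FALSE)
  zline <- grep("^#\\s*z\\s*=", lines, value = TRUE)
  if (length(zline)) {
    zval <- suppressWarnings(as.numeric(sub("^#\\s*z\\s*=\\s*", "", zline[1])))
    if (is.na(zval)) parse_error("malformed '# z=' line in normative override")
    attr(tab, "z") <- zval
  }
  body <- lines[!grepl("^#", lines)]
  df <- tryCatch(utils::read.csv(text = body, stringsAsFactors = FALSE),
                 error = function(e) parse_error(
                   sprintf("malformed normative override: %s",
                           conditionMessage(e))))
  if (!all(c("landmark", "mean_abs", "sd_abs") %in% names(df)))
    parse_error("normative override needs columns landmark,mean_abs,sd_abs")
  df$landmark <- canonical_name(df$landmark)
  if (anyNA(df$landmark))
    validation_error("normative override contains an unknown landmark name")
  if (any(!is.finite(df$mean_abs)) || any(!is.finite(df$sd_abs)) ||
      any(df$mean_abs < 0) || any(df$sd_abs < 0))
    validation_error("normative mean/SD must be finite and non-negative")
  i <- match(df$landmark, tab$landmark)
  if (anyNA(i))
    validation_error("normative override names a non-measurement landmark")
  tab$mean_abs[i] <- df$mean_abs
  tab$sd_abs[i] <- df$sd_abs
  attr(tab, "provenance") <- sprintf("override: %s", path)
  tab
}

#' Classify a profile against normative ranges
#'
#' A landmark is \code{asymmetric} when |signed index| strictly exceeds
#' threshold = mean_abs + z * sd_abs; boundary values classify as
#' \code{symmetric} (the chart's coloured band is the symmetric region
#' inclusive of its outline). The deviation direction never changes the
#' verdict.
#'
#' @param profile an \code{asymmetry_profile}.
#' @param table a \code{normative_table}.
#' @return data frame with columns \code{landmark}, \code{signed_value},
#'   \code{direction}, \code{threshold}, \code{verdict}.
#' @export
#' @examples
#' p <- compute_profile(skull_template())
#' classify(p, normative_table())  # all symmetric
classify <- function(profile, table = normative_table()) {
  z <- attr(table, "z")
  i <- match(profile$landmark, table$landmark)
  if (anyNA(i))
    validation_error(sprintf("no normative entry for landmark '%s'",
                             profile$landmark[which(is.na(i))[1]]))
  threshold <- table$mean_abs[i] + z * table$sd_abs[i]
  data.frame(landmark = profile$landmark,
             signed_value = profile$signed_value,
             direction = profile$direction,
             threshold = threshold,
             verdict = ifelse(abs(profile$signed_value) > threshold,
                              "asymmetric", "symmetric"),
             stringsAsFactors = FALSE)
}

#' Menton screening for the normal standard group
#'
#' Inclusion screen used to define the normative cohort: the perpendicular
#' distance from menton to the midsagittal (N-S-MidZ) plane must be strictly
#' under the threshold (default 4 mm).
#'
#' @param set a \code{landmark_set} containing Me and the reference landmarks.
#' @param threshold inclusion threshold in mm (strict \code{<}).
#' @return list with \code{distance} (mm, unsigned), \code{threshold} and
#'   logical \code{included}.
#' @export
#' @examples
#' menton_screen(skull_template())  # distance 0, included
menton_screen <- function(set, threshold = 4) {
  me <- get_point(set, "Me", "M")
  d <- abs(signed_plane_distance(midsagittal_plane(set), me))
  list(distance = d, threshold = threshold, included = d < threshold)
}
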