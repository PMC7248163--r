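# Reporting: pre/post comparison records, the polygonal (radar) chart of
# signed index values against the normative bands, and a structured report.

#' Compare two asymmetry profiles
#'
#' Matches the two profiles (conventionally pre- and post-operative) by
#' landmark and tabulates the change. \code{delta} is post - pre on the
#' signed values; \code{improvement} is |pre| - |post| (movement toward
#' perfect symmetry; negative means worsening, and a sign crossing such as
#' +7.28 to -1.45 still counts its full reduction in magnitude). Landmarks
#' present in only one profile are listed in the \code{unmatched} attribute.
#'
#' @param pre,post \code{asymmetry_profile}s of the same subject.
#' @param table a \code{normative_table} for the per-timepoint verdicts.
#' @return data frame with columns \code{landmark}, \code{pre}, \code{post},
#'   \code{delta}, \code{improvement}, \code{pre_verdict},
#'   \code{post_verdict}; attribute \code{unmatched}.
#' @export
#' @examples
#' pre <- compute_profile(generate_landmarks(displacements = data.frame(
#'   name = "Me", side = "M", dx = 6, dy = 0, dz = 0)))
#' post <- compute_profile(skull_template())
#' compare_profiles(pre, post)
compare_profiles <- function(pre, post, table = normative_table()) {
  shared <- pre$landmark[pre$landmark %in% post$landmark]
  if (!length(shared))
    validation_error("profiles share no landmarks; nothing to compare")
  unmatched <- c(setdiff(pre$landmark, shared), setdiff(post$landmark, shared))
  iv <- match(shared, pre$landmark)
  jv <- match(shared, post$landmark)
  cls_pre <- classify(pre, table)
  cls_post <- classify(post, table)
  out <- data.frame(
    landmark = shared,
    pre = pre$signed_value[iv],
    post = post$signed_value[jv],
    delta = post$signed_value[jv] - pre$signed_value[iv],
    improvement = abs(pre$signed_value[iv]) - abs(post$signed_value[jv]),
    pre_verdict = cls_pre$verdict[iv],
    post_verdict = cls_post$verdict[jv],
    stringsAsFactors = FALSE
  )
  structure(out, unmatched = unmatched,
            class = c("comparison_records", "data.frame"))
}

# chart geometry ---------------------------------------------------------------

chart_scale <- function(values, table) {
  thr <- table$mean_abs + attr(table, "z") * table$sd_abs
  max(max(abs(values), 0), max(thr)) * 1.1
}

# map signed mm value to radius fraction in [0, 1]; the zero line sits at 0.5
radius_frac <- function(v, scale) (v + scale) / (2 * scale)

polygon_xy <- function(values, scale, cx, cy, r) {
  k <- length(values)
  ang <- pi / 2 - 2 * pi * (seq_len(k) - 1) / k  # first axis at 12 o'clock
  fr <- radius_frac(values, scale)
  list(x = cx + r * fr * cos(ang), y = cy - r * fr * sin(ang))
}

svg_path <- function(xy, class, style) {
  d <- paste0("M", paste(sprintf("%.4f %.4f", xy$x, xy$y), collapse = " L"), " Z")
  sprintf("<path class=\"%s\" d=\"%s\" %s/>", class, d, style)
}

profile_values_for_chart <- function(profile, landmarks) {
  v <- stats::setNames(rep(0, length(landmarks)), landmarks)
  i <- match(profile$landmark, landmarks)
  v[i[!is.na(i)]] <- profile$signed_value[!is.na(i)]
  v
}

#' Render the polygonal asymmetry chart
#'
#' A radar chart with one axis per measurement landmark in canonical order.
#' Radial position encodes the signed index (left deviation outward-positive,
#' the zero line at mid-radius). The symmetric band is drawn at +/- mean_abs
#' (inner, green) and +/- (mean_abs + z * sd_abs) (outer, light green) per
#' landmark; outside the outer band is the asymmetric region. One polygon per
#' profile: first red (conventionally pre-op), second blue (post-op). SVG
#' output is plain deterministic text; PNG uses base graphics.
#'
#' @param profiles a single \code{asymmetry_profile} or a list of one or two.
#' @param table a \code{normative_table}.
#' @param path output file ending in \code{.svg} or \code{.png}.
#' @return (invisibly) \code{path}.
#' @export
render_chart <- function(profiles, table = normative_table(), path) {
  if (inherits(profiles, "asymmetry_profile")) profiles <- list(profiles)
  if (!length(profiles) || !all(vapply(profiles, inherits, logical(1),
                                       "asymmetry_profile")))
    validation_error("profiles must be one or two asymmetry_profile objects")
  if (!all(unlist(lapply(profiles, `[[`, "landmark")) %in% table$landmark))
    validation_error("every profiled landmark needs a normative entry")
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("svg", "png"))
    validation_error(sprintf("unknown chart extension '.%s' (use .svg or .png)", ext))

  lms <- table$landmark
  z <- attr(table, "z")
  thr <- table$mean_abs + z * table$sd_abs
  vals <- lapply(profiles, profile_values_for_chart, landmarks = lms)
  scale <- chart_scale(unlist(vals), table)
  cols <- c("#cc2222", "#2244cc")

  if (ext == "svg") {
    cx <- 260; cy <- 250; r <- 190
    lines <- c(
      "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
      "<svg xmlns=\"http://www.w3.org/2000/svg\" width=\"520\" height=\"500\" viewBox=\"0 0 520 500\">",
      "<rect width=\"520\" height=\"500\" fill=\"#ffffff\"/>",
      # asymmetric (grey) region: full disc under the bands
      sprintf("<circle cx=\"%d\" cy=\"%d\" r=\"%d\" fill=\"#dddddd\"/>", cx, cy, r),
      svg_path(polygon_xy(thr, scale, cx, cy, r), "band-outer",
               "fill=\"#ccebc5\" stroke=\"#66aa66\" stroke-width=\"1\""),
      svg_path(polygon_xy(table$mean_abs, scale, cx, cy, r), "band-inner",
               "fill=\"#7fc97f\" stroke=\"#338833\" stroke-width=\"1\""),
      svg_path(polygon_xy(-table$mean_abs, scale, cx, cy, r), "band-inner-neg",
               "fill=\"none\" stroke=\"#338833\" stroke-width=\"1\""),
      svg_path(polygon_xy(-thr, scale, cx, cy, r), "band-outer-neg",
               "fill=\"none\" stroke=\"#66aa66\" stroke-width=\"1\""),
      svg_path(polygon_xy(rep(0, length(lms)), scale, cx, cy, r), "zero",
               "fill=\"none\" stroke=\"#555555\" stroke-width=\"0.8\" stroke-dasharray=\"4 3\"")
    )
    # axes + labels
    ang <- pi / 2 - 2 * pi * (seq_along(lms) - 1) / length(lms)
    lines <- c(lines,
      sprintf("<line x1=\"%d\" y1=\"%d\" x2=\"%.4f\" y2=\"%.4f\" stroke=\"#999999\" stroke-width=\"0.5\"/>",
              cx, cy, cx + r * cos(ang), cy - r * sin(ang)),
      sprintf("<text x=\"%.4f\" y=\"%.4f\" font-size=\"13\" font-family=\"sans-serif\" text-anchor=\"middle\">%s</text>",
              cx + (r + 16) * cos(ang), cy - (r + 16) * sin(ang) + 4, lms))
    for (i in seq_along(vals))
      lines <- c(lines, svg_path(
        polygon_xy(vals[[i]], scale, cx, cy, r), "profile",
        sprintf("fill=\"none\" stroke=\"%s\" stroke-width=\"2\"", cols[i])))
    lines <- c(lines, "</svg>")
    writeLines(lines, path, useBytes = TRUE)
  } else {
    grDevices::png(path, width = 600, height = 600)
    on.exit(grDevices::dev.off())
    graphics::par(mar = c(1, 1, 1, 1))
    graphics::plot.new()
    graphics::plot.window(xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3), asp = 1)
    draw <- function(v, col, fill = NA, lty = 1) {
      xy <- polygon_xy(v, scale, 0, 0, 1)
      graphics::polygon(xy$x, -xy$y, border = col, col = fill, lty = lty, lwd = 2)
    }
    graphics::symbols(0, 0, circles = 1, inches = FALSE, add = TRUE,
                      bg = "#dddddd", fg = NA)
    draw(thr, "#66aa66", "#ccebc5")
    draw(table$mean_abs, "#338833", "#7fc97f")
    draw(-table$mean_abs, "#338833")
    draw(-thr, "#66aa66")
    draw(rep(0, length(lms)), "#555555", lty = 2)
    ang <- pi / 2 - 2 * pi * (seq_along(lms) - 1) / length(lms)
    graphics::text(1.18 * cos(ang), 1.18 * sin(ang), lms)
    for (i in seq_along(vals)) draw(vals[[i]], cols[i])
  }
  invisible(path)
}

# structured report -------------------------------------------------------------

#' Render a structured pre/post comparison report
#'
#' Produces a machine-readable JSON document and a human-readable text
#' summary from comparison records, optionally including the menton screening
#' record and reliability statistics. Landmarks whose |change in signed
#' index| exceeds \code{change_threshold} are flagged as changed.
#'
#' @param comparison records from \code{\link{compare_profiles}}.
#' @param screening optional result of \code{\link{menton_screen}}.
#' @param reliability optional result of \code{\link{reliability_report}}.
#' @param change_threshold mm change regarded as a real difference.
#' @return list of class \code{fai_report} with elements \code{json} (one
#'   string) and \code{text} (character lines); the JSON re-parses to the
#'   comparison records.
#' @export
render_report <- function(comparison, screening = NULL, reliability = NULL,
                          change_threshold = 0.5) {
  if (!nrow(comparison)) validation_error("empty comparison: nothing to report")
  obj <- list(comparison = lapply(seq_len(nrow(comparison)), function(i)
    as.list(comparison[i, , drop = FALSE])))
  if (!is.null(screening)) obj$screening <- screening
  if (!is.null(reliability)) obj$reliability <- reliability
  json <- as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                        pretty = TRUE))
  changed <- abs(comparison$delta) > change_threshold
  txt <- c("Pre/post asymmetry comparison",
           sprintf("  %-4s pre %+8.2f -> post %+8.2f  improvement %+7.2f  [%s -> %s]%s",
                   comparison$landmark, comparison$pre, comparison$post,
                   comparison$improvement, comparison$pre_verdict,
                   comparison$post_verdict,
                   ifelse(changed, "  CHANGED", "")))
  if (any(changed))
    txt <- c(txt, sprintf("Landmarks changed beyond %.1f mm: %s",
                          change_threshold,
                          paste(comparison$landmark[changed], collapse = ", ")))
  else
    txt <- c(txt, sprintf("No landmark changed beyond %.1f mm.", change_threshold))
  if (!is.null(screening))
    txt <- c(txt, sprintf(
      "Menton screen: perpendicular distance %.2f mm -> %s (threshold %.1f mm)",
      screening$distance,
      if (screening$included) "included" else "excluded", screening$threshold))
  if (!is.null(reliability))
    txt <- c(txt, sprintf(
      "Reliability: Dahlberg SE %.4f mm; paired t = %.4f, p = %.4f (n = %d)",
      reliability$dahlberg_se, reliability$t_statistic,
      reliability$p_value, reliability$n))
  structure(list(json = json, text = txt, records = comparison),
            class = "fai_report")
}

#' @export
print.fai_report <- function(x, ...) {
  writeLines(x$text)
  invisible(x)
}

#' Parse the JSON emitted by \code{\link{render_report}} back into records
#'
#' @param json a JSON string.
#' @return the comparison records data frame.
#' @export
parse_report_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyDataFrame = TRUE)
  df <- as.data.frame(obj$comparison, stringsAsFactors = FALSE)
  structure(df, class = c("comparison_records", "data.frame"))
}
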