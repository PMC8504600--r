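#' Write a profile or measurement to CSV
#'
#' One profile per file: `# key=value` header lines carrying the geometry
#' metadata (`field_cm`, `depth_cm`, `plane`, `ssd_cm`, `kind`), then a
#' `position_mm,value` column header and the data rows at full precision.
#'
#' @param obj A [beam_profile()] or [discrete_measurement()].
#' @param path Output file path.
#' @param extra Optional named character vector of additional header keys
#'   (preserved on read).
#' @return `path`, invisibly.
#' @export
write_profile <- function(obj, path, extra = NULL) {
  if (inherits(obj, "beam_profile")) {
    kind <- "truth"
    pos <- obj$positions_mm
    val <- obj$values
  } else if (inherits(obj, "discrete_measurement")) {
    kind <- "measurement"
    pos <- obj$positions_mm
    val <- obj$readings
  } else stop("obj must be a beam_profile or discrete_measurement")
  header <- c(kind = kind)
  g <- obj$geometry
  if (!is.null(g))
    header <- c(header, field_cm = format(g$field_size_cm),
                depth_cm = format(g$depth_cm), plane = g$plane,
                ssd_cm = format(g$ssd_cm))
  if (!is.null(obj$noise_seed))
    header <- c(header, noise_seed = format(obj$noise_seed))
  if (!is.null(extra)) header <- c(header, extra)
  lines <- c(sprintf("# %s=%s", names(header), header),
             "position_mm,value",
             sprintf("%.17g,%.17g", pos, val))
  writeLines(lines, path)
  invisible(path)
}

#' Read a profile or measurement from CSV
#'
#' Parses the dialect written by [write_profile()].  Files with
#' `kind=measurement` return a [discrete_measurement()] (and must carry
#' `field_cm`, `depth_cm` and `plane` metadata); anything else returns a
#' [beam_profile()].  Unknown header keys are preserved in `$meta`.
#'
#' @param path Input file path.
#' @return A [beam_profile()] or [discrete_measurement()].
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  is_header <- grepl("^#", lines)
  hdr <- lines[is_header]
  m <- regmatches(hdr, regexec("^#[ \t]*([^= \t]+)[ \t]*=[ \t]*(.*)$", hdr))
  bad <- which(lengths(m) != 3L)
  if (length(bad))
    stop(sprintf("%s: malformed header at line %d: '%s'",
                 path, which(is_header)[bad[1]], hdr[bad[1]]))
  meta <- stats::setNames(trimws(vapply(m, `[[`, character(1), 3L)),
                          vapply(m, `[[`, character(1), 2L))
  body <- lines[!is_header]
  body_lineno <- which(!is_header)
  if (length(body) < 2L || body[1] != "position_mm,value")
    stop(path, ": missing 'position_mm,value' column header")
  fields <- strsplit(body[-1], ",", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad))
    stop(sprintf("%s: malformed row at line %d: '%s'",
                 path, body_lineno[bad[1] + 1L], body[bad[1] + 1L]))
  pos <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 1L)))
  val <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  bad <- which(!is.finite(pos) | !is.finite(val))
  if (length(bad))
    stop(sprintf("%s: non-numeric row at line %d", path,
                 body_lineno[bad[1] + 1L]))
  if (any(diff(pos) <= 0))
    stop(path, ": positions are not strictly increasing")
  kind <- if ("kind" %in% names(meta)) meta[["kind"]] else "truth"
  known <- c("kind", "field_cm", "depth_cm", "plane", "ssd_cm", "noise_seed")
  extra_meta <- meta[setdiff(names(meta), known)]
  geometry <- NULL
  if (kind == "measurement") {
    for (key in c("field_cm", "depth_cm", "plane"))
      if (!key %in% names(meta))
        stop(sprintf("%s: measurement file is missing required header '%s'",
                     path, key))
  }
  if (all(c("field_cm", "depth_cm", "plane") %in% names(meta)))
    geometry <- beam_geometry(
      as.numeric(meta[["field_cm"]]), as.numeric(meta[["depth_cm"]]),
      meta[["plane"]],
      ssd_cm = if ("ssd_cm" %in% names(meta)) as.numeric(meta[["ssd_cm"]])
               else 90)
  obj <- if (kind == "measurement") {
    seed <- if ("noise_seed" %in% names(meta))
      as.integer(meta[["noise_seed"]]) else NULL
    discrete_measurement(pos, val, geometry = geometry, noise_seed = seed)
  } else {
    beam_profile(pos, val, geometry = geometry, normalize = FALSE)
  }
  if (length(extra_meta)) obj$meta <- as.list(extra_meta)
  obj
}
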