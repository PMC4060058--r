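#' Read and write contour files
#'
#' Two plain-text dialects are supported and round-tripped losslessly:
#'
#' * CSV with columns `contour_id, label, vertex_index, x_mm, y_mm`, one row
#'   per vertex, vertices in order;
#' * a JSON ROI document `{section_id, contours: [{label, vertices: [[x, y],
#'   ...]}, ...]}`.
#'
#' Contours are normalised on read (counter-clockwise, unrepeated first
#' vertex), so files written in other conventions are accepted.
#'
#' @param path File path.
#' @param check Passed to [contour()].
#' @return `read_contours_csv()` and `read_contours_json()` return a named
#'   list of [contour()] objects (names are contour labels).
#' @name contour_io
NULL

#' @rdname contour_io
#' @export
read_contours_csv <- function(path, check = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("contour_id", "label", "vertex_index", "x_mm", "y_mm")
  if (!all(need %in% names(df)))
    stop("malformed contour CSV '", path, "': need columns ",
         paste(need, collapse = ", "))
  if (nrow(df) == 0L) stop("malformed contour CSV '", path, "': no vertex rows")
  bad <- which(!is.finite(df$x_mm) | !is.finite(df$y_mm))
  if (length(bad))
    stop("malformed contour CSV '", path, "': non-numeric coordinate at line ",
         bad[1L] + 1L)
  out <- lapply(split(df, df$contour_id), function(d) {
    d <- d[order(d$vertex_index), ]
    contour(d$x_mm, d$y_mm, label = d$label[1L], check = check)
  })
  names(out) <- vapply(out, `[[`, character(1L), "label")
  out[order(names(out))]
}

#' @param contours Named list of [contour()] objects.
#' @param section_id Section identifier stored in the JSON dialect.
#' @rdname contour_io
#' @export
write_contours_csv <- function(contours, path) {
  rows <- lapply(seq_along(contours), function(i) {
    ct <- .check_contour(contours[[i]])
    v <- ct$vertices
    data.frame(contour_id = i, label = ct$label,
               vertex_index = seq_len(nrow(v)),
               x_mm = v[, 1L], y_mm = v[, 2L], stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname contour_io
#' @export
read_contours_json <- function(path, check = TRUE) {
  doc <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (is.null(doc$contours)) stop("malformed ROI JSON '", path, "': no 'contours' field")
  cs <- doc$contours
  verts <- if (is.data.frame(cs)) cs$vertices else lapply(cs, `[[`, "vertices")
  labs <- if (is.data.frame(cs)) cs$label else vapply(cs, `[[`, character(1L), "label")
  out <- mapply(function(v, lab) contour(as.matrix(v), label = lab, check = check),
                verts, labs, SIMPLIFY = FALSE)
  names(out) <- labs
  out[order(names(out))]
}

#' @rdname contour_io
#' @export
write_contours_json <- function(contours, path, section_id = "section") {
  doc <- list(
    section_id = section_id,
    contours = lapply(unname(contours), function(ct) {
      ct <- .check_contour(ct)
      list(label = ct$label, vertices = unname(ct$vertices))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.status_levels <- c("fully_traceable", "not_fully_traceable", "not_observed",
                    "not_measured")
.level_order <- c("medullary", "hatchling", paste0("cgm", 1:9), "surface")

#' Read and write measurement tables
#'
#' The measurement-table CSV carries one row per individual, element, side,
#' and growth level, with columns `individual, element, side, level,
#' circumference_mm, area_mm2, thickness_mm, status, partial_year`. Levels
#' are `medullary`, `hatchling`, `cgm1` ... `cgm5`, `surface`. Absent values
#' keep their reason through the `status` sentinels `fully_traceable`,
#' `not_fully_traceable`, `not_observed`, `not_measured` (empty measurement
#' cells alone would lose the distinction). `partial_year` is a logical flag
#' marking surface rows whose outermost growth mark merges with the
#' periosteal surface.
#'
#' @param path File path.
#' @param x Measurement data frame.
#' @return `read_measurements()` returns the validated data frame.
#' @name measurement_io
NULL

#' @rdname measurement_io
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_measurements(df)
}

#' @rdname measurement_io
#' @export
write_measurements <- function(x, path) {
  utils::write.csv(validate_measurements(x), path, row.names = FALSE)
  invisible(path)
}

#' Validate a measurement table
#'
#' Checks the schema, the status sentinels, and the monotonicity invariant
#' that fully traceable circumferences strictly increase from the innermost
#' growth mark outward to the periosteal surface within each element side.
#'
#' @param x Measurement data frame.
#' @return The data frame, with `level` ordered and `partial_year` logical.
#' @export
validate_measurements <- function(x) {
  need <- c("individual", "element", "side", "level", "circumference_mm",
            "area_mm2", "thickness_mm", "status", "partial_year")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("measurement table lacks columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(x$status), .status_levels)
  if (length(bad))
    stop("unknown status sentinel(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(x$level), .level_order)
  if (length(bad))
    stop("unknown level(s): ", paste(bad, collapse = ", "))
  x$partial_year <- as.logical(x$partial_year)
  x$circumference_mm <- as.numeric(x$circumference_mm)
  x$area_mm2 <- as.numeric(x$area_mm2)
  x$thickness_mm <- as.numeric(x$thickness_mm)
  if (any(x$status == "fully_traceable" &
          grepl("^(cgm|surface)", x$level) & is.na(x$circumference_mm)))
    stop("fully_traceable growth levels must carry a circumference")
  for (key in split(x, list(x$individual, x$element, x$side), drop = TRUE)) {
    lv <- key[grepl("^(cgm[0-9]+|surface)$", key$level) &
                key$status == "fully_traceable", ]
    lv <- lv[order(match(lv$level, .level_order)), ]
    circ <- lv$circumference_mm
    if (length(circ) > 1L && any(diff(circ) <= 0))
      stop(sprintf(
        "data-integrity error: circumferences do not increase outward for %s %s (%s)",
        key$individual[1L], key$element[1L], key$side[1L]))
  }
  x[order(x$individual, x$element, x$side, match(x$level, .level_order)), ,
    drop = FALSE]
}

#' Analysis configuration
#'
#' Bundles the tunable parameters of the pipeline with their defaults: the
#' growing-season length used to convert annual increments to daily rates,
#' the significance level of the paired tests, the narrow-zone detection
#' fraction, the surface-merge fraction for partial-year flagging, the
#' random seed, and the report rounding.
#'
#' @param growing_days Growing days per year (D > 0); 214 by default, an
#'   active-season estimate for Louisiana alligators.
#' @param alpha Significance level for paired tests, in (0, 1].
#' @param narrow_zone_theta Fraction of the median annual increment below
#'   which two adjacent marks outline a narrow zone, in (0, 1].
#' @param merge_delta Relative surface-to-last-mark gap below which the
#'   outermost mark is treated as merging with the surface, in (0, 1].
#' @param seed Optional integer seed for the synthetic generator.
#' @param digits Decimal places for formatted report output.
#' @return A list of class `run_config`.
#' @export
run_config <- function(growing_days = 214, alpha = 0.05,
                       narrow_zone_theta = 0.5, merge_delta = 0.05,
                       seed = NULL, digits = 2L) {
  stopifnot(growing_days > 0, alpha > 0, alpha <= 1,
            narrow_zone_theta > 0, narrow_zone_theta <= 1,
            merge_delta > 0, merge_delta <= 1)
  structure(list(growing_days = growing_days, alpha = alpha,
                 narrow_zone_theta = narrow_zone_theta,
                 merge_delta = merge_delta, seed = seed,
                 digits = as.integer(digits)),
            class = "run_config")
}

# Half-up rounding used for report output, matching printed tables
# (base round() is round-half-even). The 1e-9 guard keeps values that are
# exactly .5 in decimal, but a few ulps below it in binary, rounding up.
round_half_up <- function(x, digits = 2L) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5 + 1e-9) / s
}
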