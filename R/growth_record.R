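#' Per-element growth-mark records
#'
#' Converts a validated measurement table (see [read_measurements()]) into a
#' list of `element_record` objects, one per individual, element, and side.
#' A record holds the medullary measurements, the hatchling (year-0)
#' reference, the ordered growth-mark series with traceability statuses, and
#' the periosteal-surface row with its partial-year flag. Growth marks are
#' numbered from the innermost observed mark outward.
#'
#' @param x Measurement data frame.
#' @return Named list of `element_record` objects, names
#'   `"<individual>.<element>.<side>"`.
#' @export
element_records <- function(x) {
  x <- validate_measurements(x)
  keys <- split(x, list(x$individual, x$element, x$side), drop = TRUE)
  recs <- lapply(keys, function(d) {
    d <- d[order(match(d$level, .level_order)), ]
    med <- d[d$level == "medullary", ]
    hat <- d[d$level == "hatchling", ]
    sur <- d[d$level == "surface", ]
    cgm <- d[grepl("^cgm[0-9]+$", d$level), ]
    marks <- data.frame(
      index = as.integer(sub("^cgm", "", cgm$level)),
      circumference_mm = cgm$circumference_mm,
      area_mm2 = cgm$area_mm2,
      thickness_mm = cgm$thickness_mm,
      status = cgm$status,
      stringsAsFactors = FALSE
    )
    marks <- marks[order(marks$index), , drop = FALSE]
    structure(list(
      individual = d$individual[1L],
      element = d$element[1L],
      side = d$side[1L],
      medullary_circumference = if (nrow(med)) med$circumference_mm[1L] else NA_real_,
      medullary_area = if (nrow(med)) med$area_mm2[1L] else NA_real_,
      hatchling = if (nrow(hat))
        list(circumference_mm = hat$circumference_mm[1L],
             area_mm2 = hat$area_mm2[1L],
             thickness_mm = hat$thickness_mm[1L]) else NULL,
      marks = marks,
      surface_circumference = if (nrow(sur)) sur$circumference_mm[1L] else NA_real_,
      surface_area = if (nrow(sur)) sur$area_mm2[1L] else NA_real_,
      surface_thickness = if (nrow(sur)) sur$thickness_mm[1L] else NA_real_,
      surface_partial_year = if (nrow(sur)) isTRUE(sur$partial_year[1L]) else FALSE
    ), class = "element_record")
  })
  recs
}

#' @export
print.element_record <- function(x, ...) {
  cat(sprintf("<element_record: %s %s (%s), %d marks, medullary %.4g mm>\n",
              x$individual, x$element, x$side, nrow(x$marks),
              x$medullary_circumference))
  invisible(x)
}

#' Hatchling baseline per element
#'
#' Extracts the year-0 reference measures (circumference, cortical area,
#' radial thickness) for each element from the hatchling rows of a
#' measurement table. One baseline per element, shared across individuals.
#'
#' @param x Measurement data frame.
#' @return Data frame with columns `element`, `circumference_mm`,
#'   `area_mm2`, `thickness_mm`.
#' @export
hatchling_baseline <- function(x) {
  x <- validate_measurements(x)
  h <- x[x$level == "hatchling", ]
  if (!nrow(h)) stop("configuration error: measurement table has no hatchling rows")
  out <- do.call(rbind, lapply(split(h, h$element), function(d) {
    data.frame(element = d$element[1L],
               circumference_mm = d$circumference_mm[1L],
               area_mm2 = d$area_mm2[1L],
               thickness_mm = d$thickness_mm[!is.na(d$thickness_mm)][1L],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Can growth marks have been lost to medullary expansion?
#'
#' The hatchling diaphyseal circumference bounds the year-0 cortex. If a
#' juvenile element's medullary cavity circumference is strictly larger than
#' the homologous hatchling circumference, medullary expansion may have
#' destroyed the earliest growth marks and the innermost observed mark need
#' not be the first formed.
#'
#' @param record An `element_record`.
#' @param baseline A [hatchling_baseline()] data frame.
#' @return `TRUE` if early-mark loss is possible, else `FALSE`.
#' @export
assess_cgm_loss <- function(record, baseline) {
  stopifnot(inherits(record, "element_record"))
  i <- match(record$element, baseline$element)
  if (is.na(i))
    stop("configuration error: no hatchling baseline for element '",
         record$element, "'")
  isTRUE(record$medullary_circumference > baseline$circumference_mm[i])
}

# Consecutive mark-to-mark thickness increments of a record: only pairs of
# adjacent indices with both cumulative values measured contribute.
.mark_increments <- function(record) {
  m <- record$marks
  m <- m[!is.na(m$thickness_mm), , drop = FALSE]
  if (nrow(m) < 2L)
    return(data.frame(from = integer(), to = integer(), increment = numeric()))
  adj <- which(diff(m$index) == 1L)
  data.frame(from = m$index[adj], to = m$index[adj + 1L],
             increment = m$thickness_mm[adj + 1L] - m$thickness_mm[adj])
}

#' Detect narrow-zone landmark years
#'
#' Two adjacent growth marks outline a narrow zone when the cumulative
#' radial thickness added between them falls below a fraction `theta` of the
#' element's median annual increment. A narrow zone records a year of
#' unusually prolonged growth arrest and serves as a natural landmark for
#' aligning incomplete records. The median is taken over consecutive
#' fully-measured mark-to-mark increments (hatchling and surface levels are
#' not marks and do not contribute).
#'
#' @param record An `element_record`.
#' @param theta Detection fraction, default 0.5.
#' @return Data frame with columns `from`, `to` (mark indices of the pair)
#'   and `increment` (mm); zero rows when fewer than 3 marks are measurable
#'   or no pair qualifies.
#' @export
detect_narrow_zone <- function(record, theta = 0.5) {
  stopifnot(inherits(record, "element_record"), theta > 0, theta <= 1)
  inc <- .mark_increments(record)
  n_meas <- sum(!is.na(record$marks$thickness_mm))
  if (n_meas < 3L || nrow(inc) < 2L)
    return(inc[integer(0L), , drop = FALSE])
  med <- stats::median(inc$increment)
  inc[inc$increment < theta * med, , drop = FALSE]
}

#' Retrocalculate growth marks destroyed by medullary expansion
#'
#' Estimates how many inner marks an incomplete element record has lost, by
#' aligning it to a complete reference record from the same individual. When
#' both records contain exactly one detected narrow zone, the zone is used
#' as a landmark and the number missing is the difference of the zone's mark
#' index between the two records. Otherwise (no zone, or ambiguous multiple
#' zones, in either record) the count difference between the records is
#' used, floored at zero; ambiguity triggers a warning because landmark
#' alignment is then unreliable.
#'
#' @param record The incomplete `element_record` (flagged by
#'   [assess_cgm_loss()]).
#' @param ref A complete reference `element_record`
#'   ([assess_cgm_loss()] must be `FALSE` for it, as certified by the
#'   caller's baseline comparison).
#' @param baseline A [hatchling_baseline()] data frame used to certify the
#'   reference.
#' @param theta Narrow-zone detection fraction, passed to
#'   [detect_narrow_zone()].
#' @return List with `missing` (integer count of destroyed marks) and
#'   `realigned` (data frame mapping each observed mark `index` to its
#'   realigned `year`).
#' @export
retrocalculate_missing <- function(record, ref, baseline, theta = 0.5) {
  stopifnot(inherits(record, "element_record"), inherits(ref, "element_record"))
  if (assess_cgm_loss(ref, baseline))
    stop("invalid-reference error: reference record is itself flagged for mark loss")
  zr <- detect_narrow_zone(ref, theta)
  ze <- detect_narrow_zone(record, theta)
  if (nrow(zr) == 1L && nrow(ze) == 1L) {
    missing <- zr$from - ze$from
    if (missing < 0L)
      stop("alignment error: narrow zone of the incomplete record lies outside the reference")
  } else {
    if (nrow(zr) > 1L || nrow(ze) > 1L)
      warning("multiple narrow zones detected; falling back to count alignment")
    missing <- max(nrow(ref$marks) - nrow(record$marks), 0L)
  }
  missing <- as.integer(missing)
  realigned <- data.frame(index = record$marks$index,
                          year = record$marks$index + missing)
  list(missing = missing, realigned = realigned)
}

#' Flag a record whose outermost mark merges with the surface
#'
#' When the outermost growth mark lies very close to or merges with the
#' periosteal surface, the zone between that mark and the surface represents
#' less than a year of growth. The record is flagged either when the input
#' row already carried the flag (the printed tables' asterisk) or when the
#' relative gap `(T_surface - T_last) / T_last` falls below `delta`.
#' Downstream rate computations exclude the flagged final zone.
#'
#' @param record An `element_record`.
#' @param delta Relative-gap threshold, default 0.05.
#' @return The record with `surface_partial_year` updated.
#' @export
flag_partial_year <- function(record, delta = 0.05) {
  stopifnot(inherits(record, "element_record"), delta > 0, delta <= 1)
  if (record$surface_partial_year) return(record)
  tl <- record$marks$thickness_mm
  tl <- tl[!is.na(tl)]
  ts <- record$surface_thickness
  if (length(tl) && !is.na(ts)) {
    last <- tl[length(tl)]
    if (last > 0 && (ts - last) / last < delta)
      record$surface_partial_year <- TRUE
  }
  record
}
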