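#' Annual increments and apposition rates for one element record
#'
#' Converts the cumulative cortical radial-thickness series of one element
#' (hatchling year-0 value, growth marks, periosteal surface) into annual
#' thickness increments and average daily apposition rates.
#'
#' Differencing rules:
#' * the hatchling entry is year 0; its "annual" thickness is its own
#'   cumulative value, and no rate is reported for it (embryonic growth
#'   days are unknown);
#' * a growth mark's increment is its cumulative thickness minus that of the
#'   immediately preceding mark (the hatchling value for mark 1); zones
#'   bounded by an unmeasured mark propagate absence to both adjacent
#'   entries;
#' * when the record carries the partial-year flag (the printed tables'
#'   asterisk, or [flag_partial_year()] applied beforehand) and the
#'   outermost measured mark lies within `delta` of the surface, that mark
#'   merges with the surface: it receives no increment of its own and is
#'   skipped as the surface's predecessor. The flag is taken from the record
#'   as given: it records the histological observation of a mark merging
#'   with the surface, and a small final-year increment alone (a bone that
#'   simply grew little in its last year) must not trigger the merge;
#' * the surface increment is measured from the outermost remaining measured
#'   mark (growth since that mark formed), and carries the partial-year flag
#'   when the record is flagged.
#'
#' Rates are `1000 * increment / growing_days` in micrometres per day;
#' negative increments raise a data-integrity error (resorption of the
#' outer cortex is not modelled).
#'
#' @param record An `element_record` (see [element_records()]).
#' @param growing_days Growing days per year, default 214.
#' @param delta Surface-merge fraction, see [flag_partial_year()].
#' @return Data frame with columns `level`, `year`, `cumulative_mm`,
#'   `annual_mm`, `rate_um_day`, `excluded` (`""`, `"not_traceable"`, or
#'   `"partial_year"`) and `partial_year` (flag on the surface rate).
#' @export
annual_growth <- function(record, growing_days = 214, delta = 0.05) {
  stopifnot(inherits(record, "element_record"), growing_days > 0)
  h <- record$hatchling
  marks <- record$marks
  ts <- record$surface_thickness
  lev <- c("hatchling", paste0("cgm", marks$index), "surface")
  cum <- c(if (is.null(h)) NA_real_ else h$thickness_mm, marks$thickness_mm, ts)
  n <- length(cum)
  ann <- rep(NA_real_, n)
  rate <- rep(NA_real_, n)
  excl <- rep("", n)
  excl[is.na(cum)] <- "not_traceable"

  # partial-year merge: outermost measured mark absorbed into the surface
  merged <- integer(0L)
  meas_marks <- which(!is.na(cum) & seq_len(n) > 1L & seq_len(n) < n)
  if (record$surface_partial_year && length(meas_marks) && !is.na(ts)) {
    last <- meas_marks[length(meas_marks)]
    if (cum[last] > 0 && (ts - cum[last]) / cum[last] < delta) {
      merged <- last
      excl[last] <- "partial_year"
    }
  }

  ann[1L] <- cum[1L]  # year-0 entry equals itself; never rated
  for (i in seq_len(n)[-1L]) {
    if (i %in% merged || is.na(cum[i])) next
    prev <- if (i == n) {
      cand <- setdiff(meas_marks, merged)
      if (length(cand)) cand[length(cand)] else if (!is.na(cum[1L])) 1L else NA_integer_
    } else if (!is.na(cum[i - 1L]) && !((i - 1L) %in% merged)) i - 1L else NA_integer_
    if (is.na(prev)) next
    d <- cum[i] - cum[prev]
    if (d < 0)
      stop(sprintf("data-integrity error: decreasing cumulative thickness at %s (%s %s)",
                   lev[i], record$individual, record$element))
    ann[i] <- d
    rate[i] <- 1000 * d / growing_days
  }
  data.frame(
    level = lev,
    year = c(0L, marks$index, NA_integer_),
    cumulative_mm = cum,
    annual_mm = ann,
    rate_um_day = rate,
    excluded = excl,
    partial_year = c(rep(FALSE, n - 1L), record$surface_partial_year),
    stringsAsFactors = FALSE
  )
}

#' Apposition rate from an annual thickness increment
#'
#' `1000 * increment / growing_days`, in micrometres of radial cortex per
#' growing day.
#'
#' @param increment_mm Annual thickness increment(s), mm; must be
#'   non-negative.
#' @param growing_days Growing days per year, default 214.
#' @return Rate(s) in um/day.
#' @export
apposition_rate <- function(increment_mm, growing_days = 214) {
  stopifnot(growing_days > 0)
  if (any(increment_mm < 0, na.rm = TRUE))
    stop("negative annual increment: outer-cortex resorption is not modelled")
  1000 * increment_mm / growing_days
}

#' Annual cortical-area increments
#'
#' Differences a cumulative cortical-area series exactly as
#' [annual_growth()] differences thicknesses: each measured level minus its
#' immediately preceding measured level (hatchling for the first mark),
#' entries bounded by an absent value staying absent.
#'
#' @param record An `element_record`.
#' @return Data frame with columns `level`, `cumulative_mm2`, `annual_mm2`.
#' @export
annual_area <- function(record) {
  stopifnot(inherits(record, "element_record"))
  h <- record$hatchling
  lev <- c("hatchling", paste0("cgm", record$marks$index), "surface")
  cum <- c(if (is.null(h)) NA_real_ else h$area_mm2,
           record$marks$area_mm2, record$surface_area)
  n <- length(cum)
  ann <- rep(NA_real_, n)
  ann[1L] <- cum[1L]
  for (i in seq_len(n)[-1L]) {
    prev <- if (i == n) max(which(!is.na(cum[-n])), -Inf) else i - 1L
    if (!is.finite(prev) || is.na(cum[i]) || is.na(cum[prev])) next
    d <- cum[i] - cum[prev]
    if (d < 0)
      stop(sprintf("data-integrity error: decreasing cumulative area at %s (%s %s)",
                   lev[i], record$individual, record$element))
    ann[i] <- d
  }
  data.frame(level = lev, cumulative_mm2 = cum, annual_mm2 = ann,
             stringsAsFactors = FALSE)
}

#' Annual growth table for a whole measurement set
#'
#' Runs [annual_growth()] over every element of every individual (one side,
#' left by default, matching the convention that radial thicknesses are
#' measured on the left element) and binds the results into one report
#' table. Elements without any thickness measurements (e.g. scapulae and
#' coracoids, whose cortical drift precludes a stable centroid) are skipped.
#'
#' @param x Measurement data frame.
#' @param side Which side's thickness series to use, default `"left"`.
#' @param growing_days Growing days per year, default 214.
#' @param delta Surface-merge fraction, default 0.05.
#' @return Data frame with columns `individual`, `element`, plus the
#'   [annual_growth()] columns, at full precision.
#' @export
growth_table <- function(x, side = "left", growing_days = 214, delta = 0.05) {
  recs <- element_records(x)
  recs <- Filter(function(r) r$side == side, recs)
  out <- lapply(recs, function(r) {
    if (all(is.na(r$marks$thickness_mm)) && is.na(r$surface_thickness))
      return(NULL)
    g <- annual_growth(r, growing_days = growing_days, delta = delta)
    cbind(individual = r$individual, element = r$element, g,
          stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
  rownames(out) <- NULL
  out
}

#' Format a growth table for report output
#'
#' Rounds the numeric columns to the printed precision (half-up, 2 decimal
#' places by default); internal computation stays at full precision.
#'
#' @param gt A [growth_table()].
#' @param digits Decimal places.
#' @return The rounded table.
#' @export
format_growth_table <- function(gt, digits = 2L) {
  for (col in c("cumulative_mm", "annual_mm", "rate_um_day"))
    gt[[col]] <- round_half_up(gt[[col]], digits)
  gt
}

#' Annual and cumulative growth curves
#'
#' Builds per-element annual and cumulative (ontogenetic) curves from a
#' [growth_table()]. The cumulative curve is the running sum of
#' non-excluded annual values on top of the year-0 baseline, i.e. for a
#' complete record it telescopes back to the surface cumulative value.
#' Elements whose inner marks were destroyed by medullary expansion start
#' at their first measurable year and are not connected to the origin.
#'
#' @param gt A [growth_table()].
#' @return Data frame with columns `individual`, `element`, `level`, `year`,
#'   `annual_mm`, `cumulative_mm` (surface rows carry the year after the
#'   last mark; the hatchling baseline is the year-0 point).
#' @export
growth_curves <- function(gt) {
  parts <- split(gt, list(gt$individual, gt$element), drop = TRUE)
  out <- lapply(parts, function(d) {
    d <- d[d$excluded != "partial_year", , drop = FALSE]
    yr <- d$year
    yr[d$level == "surface"] <- max(c(yr[!is.na(yr)], 0L)) + 1L
    keep <- !is.na(d$annual_mm)
    data.frame(individual = d$individual[keep], element = d$element[keep],
               level = d$level[keep], year = yr[keep],
               annual_mm = d$annual_mm[keep],
               cumulative_mm = d$cumulative_mm[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$individual, out$element, out$year), , drop = FALSE]
}

#' Plot annual and cumulative growth curves
#'
#' One panel of annual increments and one of cumulative thickness per
#' individual, elements as separate lines, in base graphics.
#'
#' @param gt A [growth_table()].
#' @param individual Individual to plot; defaults to the first.
#' @return Invisibly, the [growth_curves()] data used.
#' @export
plot_growth_curves <- function(gt, individual = NULL) {
  gc <- growth_curves(gt)
  if (is.null(individual)) individual <- gc$individual[1L]
  gc <- gc[gc$individual == individual, , drop = FALSE]
  elems <- sort(unique(gc$element))
  cols <- grDevices::hcl.colors(max(length(elems), 3L), "Dark 3")
  op <- graphics::par(mfrow = c(1L, 2L), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (what in c("annual_mm", "cumulative_mm")) {
    graphics::plot(NA, xlim = range(gc$year), ylim = range(gc[[what]], na.rm = TRUE),
                   xlab = "growth mark count", ylab = paste(what, "(mm)"),
                   main = individual)
    for (i in seq_along(elems)) {
      d <- gc[gc$element == elems[i], ]
      graphics::lines(d$year, d[[what]], col = cols[i], type = "b", pch = 16)
    }
    graphics::legend("topleft", legend = elems, col = cols[seq_along(elems)],
                     lty = 1, pch = 16, bty = "n", cex = 0.7)
  }
  invisible(gc)
}
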