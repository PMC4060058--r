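#' Default element parameters for the synthetic skeleton
#'
#' Base (hatchling) mean radius, mean annual radial increment, log-normal
#' dispersion, and medullary-resorption multiplier per element. Increment
#' means are ordered femur > tibia > humerus > ulna > radius ~ fibula, the
#' qualitative ordering of apposition rates across juvenile alligator limb
#' elements; base radii correspond to hatchling diaphyseal circumferences of
#' a few mm. The radius resorbs slowly (it retains the most complete mark
#' record), the femur fastest.
#'
#' @return Data frame with columns `element`, `base_radius_mm`,
#'   `mean_increment_mm`, `sdlog`, `resorption_multiplier`.
#' @export
default_elements <- function() {
  data.frame(
    element = c("femur", "tibia", "humerus", "ulna", "radius", "fibula"),
    base_radius_mm = c(1.07, 0.63, 0.65, 0.42, 0.54, 0.56),
    mean_increment_mm = c(0.60, 0.52, 0.48, 0.34, 0.28, 0.28),
    sdlog = 0.15,
    resorption_multiplier = c(1.5, 1.3, 1.2, 1.0, 0.2, 0.7),
    stringsAsFactors = FALSE
  )
}

#' Configuration of the synthetic growth-ring generator
#'
#' Defines one simulated individual: nested annual apposition contours per
#' element with element-specific log-normal increment distributions, an
#' elliptical base shape with a small Fourier perturbation, concentric
#' medullary resorption that destroys inner marks, a hatchling (year-0)
#' baseline, independent left/right multiplicative measurement noise, and an
#' optional narrow-zone low-growth year.
#'
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @param n_years Number of completed growth years (= marks formed).
#' @param elements Element parameter table, see [default_elements()].
#' @param aspect Ratio of ellipse semi-axes a/b of the base shape.
#' @param fourier_amplitude Upper bound of the uniform per-harmonic radial
#'   perturbation amplitudes (harmonics 2-4).
#' @param resorption_rate Medullary resorption front speed, mm per year,
#'   scaled per element by its `resorption_multiplier`.
#' @param narrow_zone_year Mark index n such that marks n and n + 1 are
#'   closely spaced (the increment laid down in year n + 1 is multiplied by
#'   `narrow_zone_multiplier`); `NA` disables the narrow zone.
#' @param narrow_zone_multiplier Increment multiplier of the narrow-zone
#'   year, default 0.3.
#' @param bilateral_sigma Standard deviation of the per-side log-normal
#'   measurement-scale factor, default 0.01.
#' @param partial_final_year If `TRUE` the individual dies just after the
#'   final mark forms, leaving it merging with the surface (the asterisk
#'   situation); if `FALSE` a substantial part of the current season's
#'   growth separates mark and surface.
#' @param increment_scale Scalar multiplying every mean increment
#'   (captive/wild growth-rate variants).
#' @param n_vertices Vertices per contour (multiple of 4 keeps vertices on
#'   both axes).
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(seed = NULL, n_years = 5L,
                              elements = default_elements(),
                              aspect = 1.35, fourier_amplitude = 0.03,
                              resorption_rate = 0.15,
                              narrow_zone_year = 3L,
                              narrow_zone_multiplier = 0.3,
                              bilateral_sigma = 0.01,
                              partial_final_year = FALSE,
                              increment_scale = 1,
                              n_vertices = 120L) {
  stopifnot(n_years >= 1L, all(elements$mean_increment_mm > 0),
            all(elements$sdlog >= 0), aspect >= 1, fourier_amplitude >= 0,
            resorption_rate >= 0, bilateral_sigma >= 0,
            narrow_zone_multiplier > 0, increment_scale > 0,
            n_vertices >= 8L)
  if (!is.na(narrow_zone_year) && !is.null(narrow_zone_year))
    stopifnot(narrow_zone_year >= 1L, narrow_zone_year < n_years)
  structure(as.list(environment()), class = "simulation_config")
}

# Radial base-shape function: ellipse plus low-order Fourier perturbation.
.base_radii <- function(theta, r0, aspect, eps, phases) {
  a <- r0 * sqrt(aspect); b <- r0 / sqrt(aspect)
  r <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  pert <- rep(0, length(theta))
  for (k in seq_along(eps))
    pert <- pert + eps[k] * cos((k + 1L) * theta + phases[k])
  r * (1 + pert)
}

.polar_contour <- function(theta, r, label, scale = 1) {
  contour(scale * r * cos(theta), scale * r * sin(theta),
          label = label, check = FALSE)
}

#' Generate one synthetic individual with ground truth
#'
#' Builds, per element and side, the nested contour set (medullary boundary,
#' surviving growth marks, periosteal surface), derives the measurement
#' table by running the geometry engine ([measure_section()]) on the traced
#' contours exactly as for real data, and returns the generating truth.
#'
#' Year-k marks are the base shape dilated radially by the cumulative
#' increment, so contours are star-convex and nested by construction. The
#' medullary resorption front is a circle centred on the initial centroid
#' that advances `resorption_rate * resorption_multiplier` mm per year from
#' half the minimum hatchling radius; marks whose maximum radial extent lies
#' inside the front are destroyed (deleted and counted as resorbed, the
#' survivors renumbered from the innermost observed), while marks the front
#' only partially overlaps become `not_fully_traceable` sentinel rows
#' without measurements. Left and right differ by one independent
#' multiplicative log-normal factor per side applied to all of that side's
#' contours. The hatchling baseline is the unscaled year-0 shape.
#'
#' @param cfg A [simulation_config()].
#' @param individual_id Identifier written into the measurement table.
#' @return List of class `synthetic_individual` with `contours`
#'   (element -> side -> named contour list), `hatchling` (element -> year-0
#'   contour), `measurements` (measurement table, see
#'   [validate_measurements()]), and `truth` (list with per-element/side
#'   data frame `marks_summary`: marks formed, resorbed count, partially
#'   traceable count, narrow-zone index, side factor; and `increments`:
#'   noiseless per-year radial increments).
#' @export
generate_individual <- function(cfg, individual_id = "SIM-1") {
  stopifnot(inherits(cfg, "simulation_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  theta <- seq(0, 2 * pi, length.out = cfg$n_vertices + 1L)[-(cfg$n_vertices + 1L)]
  nz <- cfg$narrow_zone_year
  has_nz <- !is.null(nz) && !is.na(nz)

  contours <- list(); hatchling <- list()
  meas <- list(); summ <- list(); incs <- list()
  for (e in seq_len(nrow(cfg$elements))) {
    el <- cfg$elements$element[e]
    r0 <- cfg$elements$base_radius_mm[e]
    m <- cfg$elements$mean_increment_mm[e] * cfg$increment_scale
    s <- cfg$elements$sdlog[e]
    eps <- stats::runif(3L, 0, cfg$fourier_amplitude)
    phases <- stats::runif(3L, 0, 2 * pi)
    base <- .base_radii(theta, r0, cfg$aspect, eps, phases)

    inc <- if (s > 0) stats::rlnorm(cfg$n_years, log(m) - s^2 / 2, s)
           else rep(m, cfg$n_years)
    if (has_nz) inc[nz + 1L] <- inc[nz + 1L] * cfg$narrow_zone_multiplier
    cum <- cumsum(inc)
    season <- if (cfg$partial_final_year) 0.1 * m else 0.6 * m
    r_surf <- base + cum[cfg$n_years] + season

    r_med0 <- 0.5 * min(base)
    front <- r_med0 + cfg$resorption_rate *
      cfg$elements$resorption_multiplier[e] * cfg$n_years
    if (front >= min(r_surf))
      stop("generation error: resorption front reaches the periosteal surface for ",
           el)
    mark_max <- vapply(cum, function(ci) max(base + ci), numeric(1L))
    mark_min <- vapply(cum, function(ci) min(base + ci), numeric(1L))
    resorbed <- mark_max < front
    partial <- !resorbed & mark_min < front
    keep <- !resorbed
    new_index <- cumsum(keep) * keep  # renumber survivors from innermost

    hatch_ct <- .polar_contour(theta, base, "hatchling_surface")
    hatchling[[el]] <- hatch_ct
    hf <- principal_frame(annular_section(hatch_ct))
    meas[[paste(el, "hatch")]] <- do.call(rbind, lapply(c("left", "right"), function(sd)
      data.frame(individual = individual_id, element = el, side = sd,
                 level = "hatchling", circumference_mm = perimeter(hatch_ct),
                 area_mm2 = enclosed_area(hatch_ct),
                 thickness_mm = radial_profile(hf, hatch_ct)$mean,
                 status = "fully_traceable", partial_year = FALSE,
                 stringsAsFactors = FALSE)))

    contours[[el]] <- list()
    for (sd in c("left", "right")) {
      f <- exp(stats::rnorm(1L, 0, cfg$bilateral_sigma))
      cts <- list(.polar_contour(theta, rep(front, length(theta)), "medullary", f))
      for (y in which(keep & !partial))
        cts <- c(cts, list(.polar_contour(theta, base + cum[y],
                                          paste0("cgm", new_index[y]), f)))
      cts <- c(cts, list(.polar_contour(theta, r_surf, "surface", f)))
      names(cts) <- vapply(cts, `[[`, character(1L), "label")
      contours[[el]][[sd]] <- cts

      ms <- measure_section(cts)
      rows <- data.frame(individual = individual_id, element = el, side = sd,
                         level = ms$level, circumference_mm = ms$circumference_mm,
                         area_mm2 = ms$area_mm2, thickness_mm = ms$thickness_mm,
                         status = "fully_traceable",
                         partial_year = ms$level == "surface" & cfg$partial_final_year,
                         stringsAsFactors = FALSE)
      for (y in which(partial))
        rows <- rbind(rows, data.frame(
          individual = individual_id, element = el, side = sd,
          level = paste0("cgm", new_index[y]), circumference_mm = NA_real_,
          area_mm2 = NA_real_, thickness_mm = NA_real_,
          status = "not_fully_traceable", partial_year = FALSE,
          stringsAsFactors = FALSE))
      meas[[paste(el, sd)]] <- rows
      summ[[paste(el, sd)]] <- data.frame(
        element = el, side = sd, marks_formed = cfg$n_years,
        resorbed = sum(resorbed), partially_traceable = sum(partial),
        narrow_zone_year = if (has_nz) nz else NA_integer_,
        side_factor = f, stringsAsFactors = FALSE)
    }
    incs[[el]] <- data.frame(element = el, year = seq_len(cfg$n_years),
                             increment_mm = inc, cumulative_mm = cum,
                             stringsAsFactors = FALSE)
  }
  measurements <- validate_measurements(do.call(rbind, meas))
  rownames(measurements) <- NULL
  truth <- list(marks_summary = do.call(rbind, c(summ, make.row.names = FALSE)),
                increments = do.call(rbind, c(incs, make.row.names = FALSE)))
  structure(list(contours = contours, hatchling = hatchling,
                 measurements = measurements, truth = truth, config = cfg,
                 individual_id = individual_id),
            class = "synthetic_individual")
}

#' @export
print.synthetic_individual <- function(x, ...) {
  cat(sprintf("<synthetic_individual '%s': %d elements, %d growth years>\n",
              x$individual_id, length(x$contours), x$config$n_years))
  invisible(x)
}

#' Generate a cohort of synthetic individuals
#'
#' Independent individuals with per-individual seeds derived from the
#' configuration seed, and an optional per-individual increment scale
#' (e.g. faster-growing captive versus slower wild animals).
#'
#' @param n_individuals Number of individuals.
#' @param cfg A [simulation_config()]; its `seed` must be set, individual i
#'   uses `seed + i`.
#' @param scale Scalar or length-`n_individuals` vector of increment scale
#'   factors.
#' @return List of `synthetic_individual` objects named `SIM-<i>`.
#' @export
generate_cohort <- function(n_individuals, cfg, scale = 1) {
  stopifnot(inherits(cfg, "simulation_config"), n_individuals >= 1L)
  if (is.null(cfg$seed)) stop("generate_cohort requires a seeded configuration")
  scale <- rep_len(scale, n_individuals)
  out <- lapply(seq_len(n_individuals), function(i) {
    ci <- cfg
    ci$seed <- cfg$seed + i
    ci$increment_scale <- cfg$increment_scale * scale[i]
    generate_individual(ci, individual_id = sprintf("SIM-%d", i))
  })
  names(out) <- sprintf("SIM-%d", seq_len(n_individuals))
  out
}

#' Measure a skeleton of traced contour sets
#'
#' Runs the geometry engine over a nested list of contour sets
#' (element -> side -> contours) and assembles a measurement table, the
#' tracing-to-table step applied to whole individuals.
#'
#' @param skeleton Nested list: `skeleton[[element]][[side]]` is a list of
#'   [contour()] objects including `"medullary"` and `"surface"`.
#' @param individual_id Identifier for the table rows.
#' @return A validated measurement data frame (without hatchling rows, which
#'   come from a separate neonate individual).
#' @export
measure_skeleton <- function(skeleton, individual_id = "IND-1") {
  rows <- list()
  for (el in names(skeleton)) for (sd in names(skeleton[[el]])) {
    ms <- measure_section(skeleton[[el]][[sd]])
    rows[[paste(el, sd)]] <- data.frame(
      individual = individual_id, element = el, side = sd, level = ms$level,
      circumference_mm = ms$circumference_mm, area_mm2 = ms$area_mm2,
      thickness_mm = ms$thickness_mm, status = "fully_traceable",
      partial_year = FALSE, stringsAsFactors = FALSE)
  }
  out <- validate_measurements(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Pipeline estimate of per-element mean annual increments
#'
#' Convenience used in parameter-recovery checks: measured consecutive
#' mark-to-mark thickness increments per element, averaged over sides and
#' individuals.
#'
#' @param individuals List of `synthetic_individual` objects.
#' @param side Sides to pool, default both.
#' @return Data frame with columns `element`, `mean_increment_mm`, `n`.
#' @export
estimate_increments <- function(individuals, side = c("left", "right")) {
  rows <- list()
  for (ind in individuals) {
    recs <- element_records(ind$measurements)
    for (r in recs) {
      if (!r$side %in% side) next
      inc <- .mark_increments(r)
      if (nrow(inc))
        rows[[length(rows) + 1L]] <- data.frame(element = r$element,
                                                increment = inc$increment)
    }
  }
  rows <- do.call(rbind, rows)
  out <- do.call(rbind, lapply(split(rows, rows$element), function(d)
    data.frame(element = d$element[1L], mean_increment_mm = mean(d$increment),
               n = nrow(d), stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
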