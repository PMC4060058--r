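#' Packaged alligator measurement tables
#'
#' The complete published measurement data for three juvenile American
#' alligators (MOR-OST 1648, wild-caught; MOR-OST 1649 and 1650, captive)
#' plus the hatchling reference MOR-OST 1647, shipped as plain-text CSV:
#'
#' * `alligator_measurements()` - per individual, element, side, and growth
#'   level: diaphyseal/growth-mark circumference (mm), cortical area (mm^2),
#'   cumulative cortical radial thickness (mm, left elements), traceability
#'   status sentinels, and the partial-year (surface-merge) flag.
#' * `alligator_growth_published()` - the published annual-growth report
#'   (cumulative/annual thickness and apposition rate per level), used as
#'   the recomputation reference.
#' * `alligator_paired_published()` - the published left/right paired-test
#'   summaries (mean |difference|, SD, n, p, confidence half-width,
#'   rejection), used as the recomputation reference.
#'
#' @return A data frame; see each description.
#' @name alligator_fixtures
NULL

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "skeletochron")
  if (path == "") path <- file.path("inst", "extdata", file)  # pre-install use
  path
}

#' @rdname alligator_fixtures
#' @export
alligator_measurements <- function() {
  read_measurements(.extdata("alligator_table1.csv"))
}

#' @rdname alligator_fixtures
#' @export
alligator_growth_published <- function() {
  df <- utils::read.csv(.extdata("alligator_table3.csv"), stringsAsFactors = FALSE)
  df$partial_year <- as.logical(df$partial_year)
  df
}

#' @rdname alligator_fixtures
#' @export
alligator_paired_published <- function() {
  df <- utils::read.csv(.extdata("alligator_table2.csv"), stringsAsFactors = FALSE)
  df$reject <- as.logical(df$reject)
  df
}
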