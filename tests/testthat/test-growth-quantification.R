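test_that("annual thickness differences follow the published convention", {
  m <- alligator_measurements()
  gt <- growth_table(m)

  pick <- function(ind, el, lev, col)
    gt[gt$individual == ind & gt$element == el & gt$level == lev, col]
  # 1648 femur: surface 2.81 - cgm3 2.43 = 0.38
  expect_equal(pick("MOR-OST 1648", "femur", "surface", "annual_mm"), 0.38)
  # 1650 tibia: cgm2 2.06 - cgm1 1.50 = 0.56
  expect_equal(pick("MOR-OST 1650", "tibia", "cgm2", "annual_mm"), 0.56)
  # hatchling entry equals itself and has no rate
  expect_equal(pick("MOR-OST 1648", "femur", "hatchling", "annual_mm"), 0.71)
  expect_true(is.na(pick("MOR-OST 1648", "femur", "hatchling", "rate_um_day")))
  # zones bounded by an untraceable mark stay absent
  expect_true(is.na(pick("MOR-OST 1648", "femur", "cgm2", "annual_mm")))

  const <- record_from_thickness(c(1, 1, 1), 1, hatchling = 1)
  expect_equal(annual_growth(const)$annual_mm[-1L], c(0, 0, 0, 0))

  dec <- record_from_thickness(c(1, 2, 1.5), 2.5, hatchling = 0.5)
  expect_error(annual_growth(dec), "data-integrity")
})

test_that("apposition rates convert increments over the growing season", {
  expect_equal(apposition_rate(0.38), 1000 * 0.38 / 214)
  expect_equal(round(apposition_rate(0.38), 2), 1.78)
  expect_equal(round(apposition_rate(0.28), 2), 1.31)
  expect_equal(apposition_rate(0), 0)
  expect_error(apposition_rate(-0.1), "negative")
  # rates scale inversely with the season length
  r <- record_from_thickness(c(1, 1.5, 2), 2.6, hatchling = 0.5)
  g1 <- annual_growth(r, growing_days = 214)
  g2 <- annual_growth(r, growing_days = 428)
  expect_equal(g2$rate_um_day, g1$rate_um_day / 2)
})

test_that("the partial-year flag excludes the merging mark from rates", {
  m <- alligator_measurements()
  gt <- growth_table(m)
  hum <- gt[gt$individual == "MOR-OST 1649" & gt$element == "humerus", ]
  # cgm5 (3.14) merges with the surface (3.20): no increment of its own
  expect_equal(hum$excluded[hum$level == "cgm5"], "partial_year")
  expect_true(is.na(hum$annual_mm[hum$level == "cgm5"]))
  # surface increment measured from cgm4 (2.70)
  expect_equal(hum$annual_mm[hum$level == "surface"], 0.50)
  expect_true(hum$partial_year[hum$level == "surface"])

  # flagged element whose outermost mark is NOT within delta keeps it:
  # 1648 fibula surface 1.30 vs cgm3 1.17 (gap 11%)
  fib <- gt[gt$individual == "MOR-OST 1648" & gt$element == "fibula", ]
  expect_equal(fib$excluded[fib$level == "cgm3"], "")
  expect_equal(fib$annual_mm[fib$level == "surface"], 0.13)

  # unflagged element with a small final increment is NOT merged:
  # 1649 radius surface 1.84 vs cgm4 1.78
  rad <- gt[gt$individual == "MOR-OST 1649" & gt$element == "radius", ]
  expect_equal(rad$annual_mm[rad$level == "cgm4"], 0.26)
  expect_equal(rad$annual_mm[rad$level == "surface"], 0.06)
})

test_that("annual areas difference the cumulative cortical areas", {
  m <- alligator_measurements()
  rad <- element_records(m)[["MOR-OST 1648.radius.left"]]
  aa <- annual_area(rad)
  # cgm3 4.22 - cgm2 3.21 = 1.01
  expect_equal(aa$annual_mm2[aa$level == "cgm3"], 1.01)
  expect_equal(aa$annual_mm2[aa$level == "surface"], 5.47 - 4.22)

  const <- record_from_thickness(c(1, 1, 1), 1, hatchling = 1)
  const$marks$area_mm2 <- c(2, 2, 2); const$surface_area <- 2
  const$hatchling$area_mm2 <- 2
  expect_equal(annual_area(const)$annual_mm2[-1L], rep(0, 4))

  # synthetic concentric rings: annual areas match the geometry engine
  cfg <- simulation_config(seed = 31, bilateral_sigma = 0, resorption_rate = 0,
                           narrow_zone_year = NA, fourier_amplitude = 0)
  ind <- generate_individual(cfg)
  fem <- element_records(ind$measurements)[["SIM-1.femur.left"]]
  aa2 <- annual_area(fem)
  cts <- ind$contours$femur$left
  ring <- enclosed_area(cts$cgm2) - enclosed_area(cts$cgm1)
  expect_equal(aa2$annual_mm2[aa2$level == "cgm2"], ring, tolerance = 1e-9)
})

test_that("telescoping: measurable annual increments sum to the span", {
  set.seed(3)
  for (i in 1:5) {
    thick <- cumsum(runif(5, 0.1, 0.6))
    r <- record_from_thickness(thick, max(thick) + 0.3, hatchling = 0.05)
    g <- annual_growth(r)
    ann <- g$annual_mm[g$level != "hatchling"]
    expect_equal(sum(ann), g$cumulative_mm[g$level == "surface"] - 0.05)
  }
})

test_that("growth curves telescope to the surface and honour exclusions", {
  m <- alligator_measurements()
  gt <- growth_table(m)
  gc <- growth_curves(gt)
  # complete record: cumulative endpoint equals the surface value
  rad50 <- gc[gc$individual == "MOR-OST 1650" & gc$element == "fibula", ]
  expect_equal(max(rad50$cumulative_mm), 2.17)
  # partial-year merged marks are absent from the curves
  hum <- gc[gc$individual == "MOR-OST 1649" & gc$element == "humerus", ]
  expect_false(any(hum$cumulative_mm == 3.14))
  # elements with destroyed inner marks start away from the origin
  # (the hatchling baseline remains as the separate year-0 point)
  uln <- gc[gc$individual == "MOR-OST 1650" & gc$element == "ulna" &
              gc$level != "hatchling", ]
  expect_gte(min(uln$year, na.rm = TRUE), 3L)
})

test_that("report formatting rounds half-up to table precision", {
  gt <- data.frame(cumulative_mm = c(1.005, 2.675), annual_mm = c(0.125, NA),
                   rate_um_day = c(1.776, 0.584))
  out <- format_growth_table(gt)
  expect_equal(out$cumulative_mm, c(1.01, 2.68))
  expect_equal(out$annual_mm, c(0.13, NA))
  expect_equal(out$rate_um_day, c(1.78, 0.58))
})
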