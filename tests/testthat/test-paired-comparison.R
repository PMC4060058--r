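test_that("pairing keeps mutually fully-traceable growth levels only", {
  m <- alligator_measurements()
  recs <- element_records(m)
  pr <- pair_measurements(recs[["MOR-OST 1650.ulna.left"]],
                          recs[["MOR-OST 1650.ulna.right"]])
  expect_equal(pr$level, c("cgm2", "cgm3", "cgm4", "cgm5", "surface"))
  expect_equal(nrow(pr), 5L)

  # 1648 scapula shares only the surface
  pr2 <- pair_measurements(recs[["MOR-OST 1648.scapula.left"]],
                           recs[["MOR-OST 1648.scapula.right"]])
  expect_equal(pr2$level, "surface")

  # identical records pair with zero differences
  self <- pair_measurements(recs[["MOR-OST 1650.ulna.left"]],
                            recs[["MOR-OST 1650.ulna.left"]])
  expect_equal(self$left, self$right)

  expect_error(pair_measurements(recs[["MOR-OST 1650.ulna.left"]],
                                 recs[["MOR-OST 1650.tibia.right"]]),
               "not a left/right pair")
})

test_that("paired t reproduces the published ulna and radius rows", {
  m <- alligator_measurements()
  recs <- element_records(m)
  uln <- paired_t(pair_measurements(recs[["MOR-OST 1650.ulna.left"]],
                                    recs[["MOR-OST 1650.ulna.right"]]))
  expect_lt(abs(uln$mean_abs_difference - 0.27), 0.02)
  expect_lt(abs(uln$sd_differences - 0.10), 0.02)
  expect_lt(abs(uln$ci_half_width - 0.12), 0.03)
  expect_true(uln$reject)

  rad <- paired_t(pair_measurements(recs[["MOR-OST 1648.radius.left"]],
                                    recs[["MOR-OST 1648.radius.right"]]))
  expect_lt(abs(rad$mean_abs_difference - 0.02), 0.02)
  expect_lt(abs(rad$sd_differences - 0.11), 0.02)
  expect_lt(abs(rad$ci_half_width - 0.17), 0.03)
  expect_false(rad$reject)
})

test_that("paired t handles degenerate difference sets deterministically", {
  same <- data.frame(level = c("cgm1", "cgm2"), left = c(1, 2), right = c(1, 2))
  r <- paired_t(same)
  expect_equal(r$p_value, 1)
  expect_true(r$degenerate)
  expect_false(r$reject)

  shifted <- data.frame(level = c("cgm1", "cgm2"), left = c(1, 2),
                        right = c(1.5, 2.5))
  r2 <- paired_t(shifted)
  expect_equal(r2$p_value, 0)
  expect_true(r2$degenerate)
  expect_true(r2$reject)

  expect_error(paired_t(same[1L, ]), "at least 2 pairs")
})

test_that("paired t is invariant to swapping sides", {
  set.seed(17)
  for (i in 1:10) {
    n <- sample(3:6, 1L)
    pr <- data.frame(level = paste0("cgm", 1:n),
                     left = sort(runif(n, 5, 20)))
    pr$right <- pr$left + rnorm(n, 0, 0.3)
    a <- paired_t(pr)
    b <- paired_t(data.frame(level = pr$level, left = pr$right, right = pr$left))
    expect_equal(a$mean_abs_difference, b$mean_abs_difference)
    expect_equal(a$sd_differences, b$sd_differences)
    expect_equal(a$p_value, b$p_value)
  }
})

test_that("the whole-skeleton comparison reproduces the published table", {
  m <- alligator_measurements()
  cmp <- suppressMessages(compare_elements(m))
  pub <- alligator_paired_published()
  expect_equal(nrow(cmp), 20L)

  j <- merge(cmp, pub, by = c("individual", "element"))
  consistent <- j$n_pairs.x == j$n_pairs.y
  # two published rows use a level subset that Table 1 does not identify
  expect_equal(paste(j$individual, j$element)[!consistent],
               c("MOR-OST 1648 femur", "MOR-OST 1649 coracoid"))
  jm <- j[consistent, ]
  expect_lt(max(abs(jm$mean_abs_difference - jm$mean_diff_mm)), 0.02)
  expect_lt(max(abs(jm$sd_differences - jm$sd_mm)), 0.02)
  expect_equal(jm$reject.x, jm$reject.y)

  # confidence half-widths reproduce except two rows whose printed values
  # are inconsistent with any +/-0.005 perturbation of the printed inputs
  ci_dev <- abs(jm$ci_half_width.x - jm$ci_half_width.y)
  off <- paste(jm$individual, jm$element)[ci_dev > 0.03]
  expect_setequal(off, c("MOR-OST 1648 humerus", "MOR-OST 1650 radius"))

  # elements with a single shared level are skipped and logged
  expect_true("MOR-OST 1648 scapula" %in% attr(cmp, "skipped"))
})

test_that("pooled left/right regression behaves and degenerates sanely", {
  m <- alligator_measurements()
  reg <- left_right_regression(m)
  expect_equal(reg$n_points, 77L)
  expect_gte(reg$r_squared, 0)
  expect_lte(reg$r_squared, 1)
  # single-level elements join the pooled regression
  expect_true(any(reg$points$individual == "MOR-OST 1648" &
                    reg$points$element == "scapula"))

  # perfectly equal pairs: slope 1, intercept 0, R^2 = 1
  recs <- element_records(m)
  both <- m
  left <- both[both$side == "left", ]
  right <- left; right$side <- "right"
  sym <- validate_measurements(rbind(left, right))
  regs <- suppressWarnings(left_right_regression(sym))  # exact fit warns in summary.lm
  expect_equal(regs$slope, 1, tolerance = 1e-12)
  expect_equal(regs$intercept, 0, tolerance = 1e-12)
  expect_equal(regs$r_squared, 1, tolerance = 1e-12)
})
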