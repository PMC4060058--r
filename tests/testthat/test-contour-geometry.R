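test_that("perimeter and area match closed forms", {
  sq <- contour(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(perimeter(sq), 4)
  expect_equal(enclosed_area(sq), 1)

  tri <- contour(c(0, 4, 0), c(0, 0, 3))
  expect_equal(perimeter(tri), 12)
  expect_equal(enclosed_area(tri), 6)

  ngon <- ellipse_contour(1, 1, n = 100)
  expect_equal(perimeter(ngon), 200 * sin(pi / 100), tolerance = 1e-12)
  expect_equal(enclosed_area(ngon), 50 * sin(2 * pi / 100), tolerance = 1e-12)
})

test_that("contour construction normalises and rejects degenerate input", {
  # clockwise input reversed to counter-clockwise, closing vertex dropped
  cw <- contour(c(0, 0, 1, 1, 0), c(0, 1, 1, 0, 0))
  expect_equal(nrow(cw$vertices), 4L)
  expect_gt(skeletochron:::.signed_area(cw$vertices), 0)

  expect_error(contour(c(0, 1), c(0, 1)), "fewer than 3")
  expect_error(contour(c(0, 1, 2), c(0, 0, 0)), "zero enclosed area")
  # bow-tie self-intersection (asymmetric so the net signed area is nonzero)
  expect_error(contour(c(0, 3, 2, 0), c(0, 1, 0, 2)), "self-intersecting")
})

test_that("cortical area composes and enforces nesting", {
  outer <- contour(c(-1, 1, 1, -1), c(-1, -1, 1, 1))
  inner <- contour(c(-.5, .5, .5, -.5), c(-.5, -.5, .5, .5))
  expect_equal(cortical_area(annular_section(outer, inner)), 3)
  expect_equal(cortical_area(annular_section(outer)), 4)

  ngons <- annular_section(ellipse_contour(2, 2, 100), ellipse_contour(1, 1, 100))
  expect_equal(cortical_area(ngons), 150 * sin(2 * pi / 100), tolerance = 1e-12)

  shifted <- contour(c(2, 3, 3, 2), c(0, 0, 1, 1))
  expect_error(annular_section(outer, shifted), "nesting error")
  expect_error(annular_section(inner, outer), "nesting error")
})

test_that("region centroid follows signed-area composition", {
  conc <- annular_section(ellipse_contour(2, 2, 60), ellipse_contour(0.7, 0.7, 60))
  expect_equal(unname(region_centroid(conc)), c(0, 0), tolerance = 1e-12)

  outer <- contour(c(-2, 2, 2, -2), c(-2, -2, 2, 2))
  inner <- contour(c(.5, 1.5, 1.5, .5), c(-.5, -.5, .5, .5))
  expect_equal(unname(region_centroid(annular_section(outer, inner))),
               c(-1 / 15, 0), tolerance = 1e-12)
})

test_that("principal frame finds symmetry axes and is rotation-equivariant", {
  rect <- annular_section(contour(c(-2, 2, 2, -2), c(-1, -1, 1, 1)))
  fr <- principal_frame(rect)
  expect_equal(unname(fr$major_axis), c(1, 0))
  expect_equal(unname(fr$minor_axis), c(0, 1))
  expect_gte(fr$eigenvalues[1L], fr$eigenvalues[2L])
  expect_equal(sum(fr$major_axis * fr$minor_axis), 0)

  rot <- principal_frame(annular_section(
    ellipse_contour(2, 1, 200, rotation = pi / 6)))
  ang <- atan2(rot$major_axis[2L], rot$major_axis[1L]) %% pi
  expect_equal(ang, pi / 6, tolerance = 1e-9)

  # annulus between similar ellipses keeps the major axis of the ellipses
  ann <- annular_section(ellipse_contour(3, 1, 160), ellipse_contour(1.5, 0.5, 160))
  fa <- principal_frame(ann)
  expect_equal(abs(fa$major_axis[1L]), 1, tolerance = 1e-9)

  # isotropic sections fall back to the coordinate frame deterministically
  iso <- principal_frame(annular_section(ellipse_contour(1, 1, 120)))
  expect_equal(unname(iso$major_axis), c(1, 0))
  expect_equal(unname(iso$minor_axis), c(0, 1))
})

test_that("four-ray radial profile measures centroid-to-boundary distances", {
  circ <- ellipse_contour(1.3, 1.3, 120)
  fr <- principal_frame(annular_section(circ))
  rp <- radial_profile(fr, circ)
  expect_equal(unname(rp$distances), rep(1.3, 4), tolerance = 1e-3)
  expect_equal(rp$mean, 1.3, tolerance = 1e-3)

  ell <- ellipse_contour(1.5, 0.8, 120)
  fr2 <- principal_frame(annular_section(contour(c(-3, 3, 3, -3), c(-1, -1, 1, 1))))
  rp2 <- radial_profile(fr2, ell)
  expect_equal(unname(rp2$distances), c(1.5, 1.5, 0.8, 0.8))
  expect_equal(rp2$mean, (1.5 + 0.8) / 2)

  # centroid outside the contour: no crossing along some ray
  far <- contour(c(10, 11, 11, 10), c(10, 10, 11, 11))
  expect_error(radial_profile(fr, far), "geometry error")
})

test_that("radial profile agrees with a brute-force edge scan on random polygons", {
  set.seed(421)
  for (i in 1:20) {
    s <- random_nested_pair()
    fr <- principal_frame(s)
    for (ct in list(s$outer, s$inner)) {
      rp <- radial_profile(fr, ct)
      dirs <- rbind(fr$major_axis, -fr$major_axis, fr$minor_axis, -fr$minor_axis)
      for (k in 1:4)
        expect_equal(rp$distances[[k]],
                     edge_scan_distance(fr$centroid, dirs[k, ], ct$vertices),
                     tolerance = 1e-10)
    }
  }
})

test_that("geometry invariants hold on random star-convex polygons", {
  set.seed(99)
  for (i in 1:30) {
    ct <- random_star_polygon(n = 60)
    # isoperimetric inequality
    expect_gte(perimeter(ct)^2, 4 * pi * enclosed_area(ct))
    # rigid-motion invariance
    th <- runif(1, 0, 2 * pi); sh <- runif(2, -5, 5)
    v <- ct$vertices %*% rbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
    v <- sweep(v, 2, sh, "+")
    moved <- contour(v)
    expect_equal(perimeter(moved), perimeter(ct), tolerance = 1e-9)
    expect_equal(enclosed_area(moved), enclosed_area(ct), tolerance = 1e-9)
  }
})

test_that("cortical area is additive and nested profiles are ordered", {
  set.seed(7)
  for (i in 1:10) {
    s <- random_nested_pair()
    expect_equal(cortical_area(s) + enclosed_area(s$inner),
                 enclosed_area(s$outer), tolerance = 1e-12)
    fr <- principal_frame(s)
    ri <- radial_profile(fr, s$inner)$distances
    ro <- radial_profile(fr, s$outer)$distances
    expect_true(all(ri < ro))
  }
})

test_that("centroid and moments agree with the exact triangle-fan oracle", {
  set.seed(1234)
  for (i in 1:30) {
    s <- random_nested_pair()
    fan <- fan_region_stats(s$outer$vertices, s$inner$vertices,
                            apex = colMeans(s$inner$vertices))
    expect_equal(cortical_area(s), fan$area, tolerance = 1e-9)
    expect_equal(unname(region_centroid(s)), fan$centroid, tolerance = 1e-9)
    fr <- principal_frame(s)
    expect_equal(unname(fr$second_moments["Iyy"]), fan$vxx, tolerance = 1e-8)
    expect_equal(unname(fr$second_moments["Ixx"]), fan$vyy, tolerance = 1e-8)
    expect_equal(unname(fr$second_moments["Ixy"]), fan$vxy, tolerance = 1e-8)
  }
})

test_that("centroid agrees with a rasterisation oracle", {
  set.seed(5)
  for (i in 1:3) {
    s <- random_nested_pair(n = 60)
    g <- grid_region_stats(s$outer$vertices, s$inner$vertices, n = 400L)
    cen <- region_centroid(s)
    expect_lt(max(abs(unname(cen) - g$centroid)), 1e-3)
    expect_lt(abs(cortical_area(s) - g$area) / g$area, 5e-3)
  }
})
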