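test_that("hemisphere geometry derivation matches closed forms", {
  g <- derive_geometry(spine_config())
  geom <- attr(g, "geometry")
  # 0.1 um^3 hemispheric head -> 363 nm radius
  expect_equal(geom$head_radius * 1e3, 363, tolerance = 1e-3)
  expect_equal(geom$cleft_radius, geom$head_radius)
  # identity: V = 2*pi/3 -> radius exactly 1 um
  g2 <- derive_geometry(spine_config("geometry.head_volume" = 2 * pi / 3,
                                     "geometry.shaft_radius" = 1.0),
                        force = TRUE)
  expect_equal(attr(g2, "geometry")$head_radius, 1, tolerance = 1e-12)
  # PSD compartment volume = fraction x head volume
  expect_equal(geom$psd_volume, 0.1 * 0.1, tolerance = 1e-12)
  expect_equal(geom$psd_volume + geom$cyt_volume, geom$head_volume)
})

test_that("geometry derivation is pure and validates inputs", {
  a <- derive_geometry(spine_config())
  b <- derive_geometry(spine_config())
  expect_identical(a, b)
  expect_error(derive_geometry(spine_config("geometry.head_volume" = -1)),
               "positive")
  # surface-to-volume validity window rejects extreme geometries unless forced
  tiny <- spine_config("geometry.head_volume" = 1e-4)
  expect_error(derive_geometry(tiny), "surface-to-volume")
  expect_s3_class(derive_geometry(tiny, force = TRUE), "tbl_df")
  sv <- attr(derive_geometry(spine_config()), "geometry")
  expect_gt(sv$sv_spine, 4); expect_lt(sv$sv_spine, 20)
  expect_gte(sv$sv_shaft, 1); expect_lte(sv$sv_shaft, 4)
})

test_that("zone classification uses (0,150], (150,365] boundaries", {
  expect_equal(zone_of(c(1, 100, 150)), rep("synaptic", 3))
  expect_equal(zone_of(c(150.1, 257, 365)), rep("perisynaptic", 3))
  expect_equal(zone_of(c(365.1, 500, 5000)), rep("extrasynaptic", 3))
  expect_error(zone_of(-5), "non-negative")
})
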