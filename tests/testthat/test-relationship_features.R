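test_that("I, H, T have the right values, ranges and symmetries", {
  expect_equal(rel_interaction(1, 1), 1)
  expect_equal(rel_interaction(1, 3), 3)
  expect_equal(rel_interaction(3, 3), 9)
  expect_equal(rel_harmonic(2, 2), 2)
  expect_equal(rel_harmonic(1, 3), 1.5)
  expect_equal(rel_tangent(2, 2), 0)
  expect_equal(rel_tangent(3, 1), 0.5)
  expect_equal(rel_tangent(2, 3), tan(atan(2) - atan(3)))

  # exhaustive over the 9 calibrated score pairs
  grid <- expand.grid(a = 1:3, b = 1:3)
  I <- rel_interaction(grid$a, grid$b)
  H <- rel_harmonic(grid$a, grid$b)
  T_ <- rel_tangent(grid$a, grid$b)
  expect_true(all(I >= 1 & I <= 9))
  expect_true(all(H >= 1 & H <= 3))
  expect_true(all(T_ >= -0.5 & T_ <= 0.5))
  expect_equal(max(abs(T_)), 0.5)   # extrema at (1,3)/(3,1)
  expect_equal(I, rel_interaction(grid$b, grid$a))          # symmetric
  expect_equal(H, rel_harmonic(grid$b, grid$a))             # symmetric
  expect_equal(T_, -rel_tangent(grid$b, grid$a))            # antisymmetric
  expect_true(all(H <= (grid$a + grid$b) / 2))              # AM-HM
  expect_true(all(pmin(grid$a, grid$b) <= H &
                    H <= pmax(grid$a, grid$b)))

  expect_error(rel_interaction(0.5, 2), "domain")
  expect_error(rel_harmonic(2, 4), "domain")
  expect_error(rel_tangent(0, 1), "domain")
})

test_that("relationship vector has canonical order and length 315", {
  v <- build_relationship_vector(rep(2, 15))
  expect_length(v, 315)
  expect_true(all(v[seq(1, 315, 3)] == 4))  # I of (2,2)
  expect_true(all(v[seq(2, 315, 3)] == 2))  # H of (2,2)
  expect_true(all(v[seq(3, 315, 3)] == 0))  # T of (2,2)

  # canonical positions (0-based enumeration of the pair-major ordering)
  expect_equal(rel_position(1, 2, "I") - 1L, 0L)
  expect_equal(rel_position(14, 15, "T") - 1L, 314L)

  s <- c(1, 3, rep(2, 13))
  v2 <- build_relationship_vector(s)
  expect_equal(unname(v2[rel_position(1, 2, "I")]), 3)
  expect_equal(unname(v2[rel_position(1, 2, "H")]), 1.5)
  expect_equal(unname(v2[rel_position(1, 2, "T")]), -0.5)
  expect_error(build_relationship_vector(rep(2, 14)), "15")

  # permutation covariance: swapping two items permutes positions and
  # flips T where the pair order reverses
  s_a <- c(1, 2, 3, rep(2, 12))
  s_b <- s_a; s_b[c(1, 3)] <- s_b[c(3, 1)]
  va <- build_relationship_vector(s_a)
  vb <- build_relationship_vector(s_b)
  expect_equal(unname(va[rel_position(1, 2, "I")]),
               unname(vb[rel_position(2, 3, "I")]))
  expect_equal(unname(va[rel_position(1, 2, "T")]),
               -unname(vb[rel_position(2, 3, "T")]))
})

test_that("grid layout, assembly and flattening are mutually inverse", {
  layout <- grid_layout()
  expect_equal(nrow(layout), 360)
  expect_equal(sum(layout$kind == "zero"), 16)
  expect_equal(layout$position[layout$kind == "zero"],
               c(29:35, 351:359))

  sis <- rep(1, 15); conf <- rep(0, 14)
  rel <- build_relationship_vector(calibrate_sis(rep(0, 15)))
  g <- assemble_grid(sis, conf, rel)
  expect_equal(dim(g), c(18, 20))
  expect_equal(g[1, 1], 1)
  expect_equal(flatten_grid(g)[30:36], rep(0, 7))    # positions 29-35
  expect_equal(flatten_grid(g)[352:360], rep(0, 9))  # positions 351-359
  expect_equal(flatten_grid(g), c(sis, conf, rep(0, 7), rel, rep(0, 9)),
               ignore_attr = TRUE)
  expect_error(assemble_grid(sis, conf[-1], rel), "validation")

  # two subjects differing only in SIS item 11 differ in 1 + 14*3 cells
  s1 <- rep(2, 15); s2 <- s1; s2[11] <- 3
  g1 <- assemble_grid(s1, conf, build_relationship_vector(s1))
  g2 <- assemble_grid(s2, conf, build_relationship_vector(s2))
  expect_equal(sum(g1 != g2), 43)
})

test_that("cohort grids carry SIS, confounders and relationship blocks", {
  co <- small_cohort()
  g <- build_feature_grids(co)
  expect_equal(dim(g), c(18, 20, n_subjects(co)))
  flat <- flatten_grid(g[, , 1])
  expect_equal(flat[1:15], unname(co$sis_cal[1, ]))
  expect_equal(flat[16:29],
               unname(unlist(co$data[1, cohort_columns$confounders])))
  expect_equal(flat[37:351],
               unname(build_relationship_vector(co$sis_cal[1, ])))
  # ablation grids: relationship block zeroed, base block identical
  g0 <- build_feature_grids(co, use_relationship = FALSE)
  expect_equal(g0[, , 3][1, ], g[, , 3][1, ])
  expect_true(all(flatten_grid(g0[, , 3])[37:351] == 0))
})
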