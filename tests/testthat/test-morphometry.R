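square <- function(side, x0 = 0, y0 = 0)
  cbind(c(0, side, side, 0) + x0, c(0, 0, side, side) + y0)

test_that("areas and diameters match closed forms on simple shapes", {
  sq <- outline_polygon("M1", "I1", square(100), 37)
  expect_equal(polygon_area(sq), 10000)
  expect_equal(max_diameter(sq), 100 * sqrt(2))

  rect <- outline_polygon("M2", "I1",
                          cbind(c(0, 400, 400, 0), c(0, 0, 100, 100)), 37)
  expect_equal(polygon_area(rect), 40000)
  expect_equal(max_diameter(rect), sqrt(400^2 + 100^2))
  expect_equal(max_diameter(rect), 412.31, tolerance = 1e-4)

  circ <- circle_outline(100, 64)
  expect_equal(polygon_area(circ), pi * 100^2, tolerance = 0.01)
})

test_that("the mean over repeated tracings is used as the area", {
  tr <- list(square(sqrt(9000)), square(sqrt(10000)), square(sqrt(11000)))
  o <- outline_polygon("M1", "I1", tr, 37)
  expect_equal(polygon_area(o), 10000)
})

test_that("orientation does not change the area", {
  cw <- outline_polygon("M1", "I1", square(100)[4:1, ], 37)
  expect_equal(polygon_area(cw), 10000)
})

test_that("degenerate and self-intersecting tracings are rejected by id", {
  expect_error(outline_polygon("M9", "I1",
                               cbind(c(0, 1, 2), c(0, 1, 2)), 37),
               "M9")
  bowtie <- cbind(c(0, 1, 1, 0), c(0, 1, 0, 1))
  expect_error(outline_polygon("M8", "I1", bowtie, 37),
               "M8.*self-intersecting")
})

test_that("classification partitions by elongation with ties going up", {
  # circle: e = 1 -> fragmented
  expect_equal(classify_morphology(pi * 100^2, 200), "fragmented")
  # 8:1 rod approximated by its bounding rectangle: e well above 2.5
  area <- 800 * 100; d <- sqrt(800^2 + 100^2)
  expect_equal(classify_morphology(area, d), "long_tubular")
  # boundary cases at the default thresholds (area pi so 2 sqrt(area/pi) = 2)
  expect_equal(classify_morphology(pi, 2 * 1.3), "short_tubular")
  expect_equal(classify_morphology(pi, 2 * 2.5), "long_tubular")
  expect_equal(classify_morphology(pi, 2 * 1.2999), "fragmented")

  expect_error(morph_thresholds(2.5, 1.3), "frag_cut < long_cut")

  set.seed(2)
  for (rep in 1:20) {
    cls <- classify_morphology(stats::runif(1, 1, 1e6),
                               stats::runif(1, 1, 1e4))
    expect_true(cls %in% c("fragmented", "short_tubular", "long_tubular"))
  }
})

test_that("area and diameter transform correctly under isometries and scaling", {
  v <- square(150)
  base <- outline_polygon("M1", "I1", v, 37)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- outline_polygon("M1", "I1", v %*% R + 1000, 37)
  expect_equal(polygon_area(moved), polygon_area(base))
  expect_equal(max_diameter(moved), max_diameter(base))

  scaled <- outline_polygon("M1", "I1", 3 * v, 37)
  expect_equal(polygon_area(scaled), 9 * polygon_area(base))
  expect_equal(max_diameter(scaled), 3 * max_diameter(base))
})

test_that("field summaries report counts, density and proportions", {
  sh <- synth_shapes(10, field_area_um2 = 4.95, seed = 21)
  rec <- morph_quantify(sh$outlines)
  fs <- field_summary(rec)
  expect_equal(fs$count, 10L)
  expect_equal(fs$density_per_um2, 10 / 4.95)
  expect_equal(fs$density_per_um2, 2.0202, tolerance = 1e-4)
  props <- fs[, c("prop_fragmented", "prop_short_tubular",
                  "prop_long_tubular")]
  expect_equal(sum(unlist(props)), 1)

  empty <- field_summary(rec[0, ], images = "I_EMPTY",
                         field_area_um2 = c(I_EMPTY = 4.95))
  expect_equal(empty$count, 0L)
  expect_equal(empty$flag, "undefined: empty image")
})

test_that("the shape generator is seeded and its classes are recovered", {
  a <- synth_shapes(25, seed = 5)
  b <- synth_shapes(25, seed = 5)
  expect_identical(a, b)

  frag <- synth_shapes(30, mix = c(fragmented = 1, short_tubular = 0,
                                   long_tubular = 0), seed = 6)
  rec <- morph_quantify(frag$outlines)
  expect_true(all(rec$class == "fragmented"))

  # zero-jitter shapes land inside their class's elongation band
  clean <- synth_shapes(20, jitter = 0, seed = 7)
  rec <- morph_quantify(clean$outlines)
  bands <- list(fragmented = c(0.95, 1.25), short_tubular = c(1.35, 2.35),
                long_tubular = c(2.6, 4.1))
  for (i in seq_len(nrow(rec))) {
    band <- bands[[clean$true_class[i]]]
    expect_gte(rec$elongation[i], band[1])
    expect_lte(rec$elongation[i], band[2])
  }

  mixed <- synth_shapes(200, jitter = 0.03, seed = 8)
  rec <- morph_quantify(mixed$outlines)
  expect_gte(mean(rec$class == mixed$true_class), 0.95)
})

test_that("outline CSV reading reconstructs the polygons", {
  sh <- synth_shapes(5, seed = 9)
  rows <- do.call(rbind, lapply(sh$outlines, function(o)
    data.frame(mito_id = o$mito_id, image_id = o$image_id, tracing_index = 1L,
               vertex_index = seq_len(nrow(o$tracings[[1]])),
               x_nm = o$tracings[[1]][, 1], y_nm = o$tracings[[1]][, 2],
               field_area_um2 = o$field_area_um2)))
  f <- tempfile(fileext = ".csv")
  utils::write.csv(rows, f, row.names = FALSE)
  back <- read_outlines(f)
  expect_equal(length(back), 5L)
  expect_equal(vapply(back, polygon_area, numeric(1)),
               vapply(sh$outlines, polygon_area, numeric(1)))
  file.remove(f)
})
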