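square_map <- function(size = 10, canvas = 100, class = "tumor", ps = 1) {
  layout <- tibble::tibble(class = class, x = 10, y = 20, w = size, h = size)
  simulate_tissue_specimen(canvas, canvas, layout, pixel_size = ps)$map
}

test_that("a specimen with one nucleus places it inside its class region", {
  layout <- tibble::tibble(class = "tumor", x = 40, y = 40, w = 10, h = 10)
  nuclei <- tibble::tibble(class = "tumor", n = 1, area_mean = 25)
  sp <- simulate_tissue_specimen(100, 100, layout, nuclei, pixel_size = 1)
  expect_equal(nrow(sp$nuclei), 1)
  with_parents <- assign_parents(sp$nuclei, sp$map)
  expect_equal(with_parents$parent, "tumor")
  expect_equal(sp$nuclei$area, 25)
})

test_that("degenerate nucleus spread yields exact aggregate values", {
  layout <- tibble::tibble(class = "tumor", x = 0, y = 0, w = 50, h = 50)
  nuclei <- tibble::tibble(class = "tumor", n = 50, area_mean = 30, area_sd = 0)
  sp <- simulate_tissue_specimen(60, 60, layout, nuclei, seed = 4)
  agg <- nuclear_aggregates(assign_parents(sp$nuclei, sp$map))
  expect_equal(agg$tumor_all_area_mean, 30)
  expect_equal(agg$tumor_all_area_var, 0)
})

test_that("specimen simulation is deterministic and rejects conflicts", {
  layout <- tibble::tibble(
    class = c("tumor", "stroma"), x = c(0, 30), y = c(0, 0),
    w = c(20, 20), h = c(20, 20)
  )
  nuclei <- tibble::tibble(class = c("tumor", "stroma"), n = c(20, 10),
                           area_mean = c(30, 20), area_sd = c(5, 3))
  a <- simulate_tissue_specimen(60, 40, layout, nuclei, seed = 9)
  b <- simulate_tissue_specimen(60, 40, layout, nuclei, seed = 9)
  expect_identical(a$map$grid, b$map$grid)
  expect_identical(a$nuclei, b$nuclei)

  clash <- tibble::tibble(
    class = c("tumor", "necrosis"), x = c(0, 10), y = c(0, 10),
    w = c(20, 20), h = c(20, 20)
  )
  expect_error(simulate_tissue_specimen(60, 40, clash), "conflicting classes")
})

test_that("region features of a solid square match closed forms", {
  map <- square_map(10, 100, ps = 1)
  rf <- region_features(map, "tumor")
  expect_false(rf$absent)
  expect_equal(rf$all_area, 100)
  expect_equal(rf$area_fraction, 100 / 10000)
  # single component: union equals largest connected component
  expect_equal(rf$lcc_area, rf$all_area)
  expect_equal(rf$lcc_major_axis, rf$all_major_axis)
  # moment ellipse of a 10x10 square: mu20 = mu02 = (10^2 - 1) / 12
  expect_equal(rf$all_major_axis, 4 * sqrt(99 / 12))
  expect_equal(rf$all_eccentricity, 0)
  expect_equal(rf$all_solidity, 1)
  expect_equal(rf$all_perimeter, 40)
})

test_that("an absent class yields zero features and a flag", {
  map <- square_map(10, 100, class = "stroma")
  rf <- region_features(map, "necrosis")
  expect_true(rf$absent)
  expect_equal(rf$all_area, 0)
  expect_equal(rf$lcc_major_axis, 0)
  expect_error(region_features(map, "vessel"), "not in palette")
})

test_that("shape descriptors agree with a brute-force moment oracle", {
  withr::local_seed(31)
  for (rep in 1:50) {
    mask <- matrix(runif(12 * 15) < 0.45, 12, 15)
    if (!any(mask)) mask[3, 4] <- TRUE
    grid <- matrix(0L, 12, 15)
    grid[mask] <- 1L
    map <- tissue_map(grid, pixel_size = 1)
    rf <- region_features(map, "tumor")
    orc <- oracle_mask_moments(mask, ps = 1)
    expect_equal(rf$all_area, orc$area)
    expect_equal(rf$all_major_axis, orc$major, tolerance = 1e-10)
    expect_equal(rf$all_minor_axis, orc$minor, tolerance = 1e-10)
    expect_equal(rf$all_eccentricity, orc$eccentricity, tolerance = 1e-10)
  }
})

test_that("composition ratios handle equal areas and empty denominators", {
  layout <- tibble::tibble(
    class = c("tumor", "stroma"), x = c(0, 20), y = c(0, 0),
    w = c(10, 10), h = c(10, 10)
  )
  map <- simulate_tissue_specimen(40, 20, layout)$map
  cf <- composition_features(map)
  expect_equal(cf$ratio_tumor_to_stroma, 1.0)
  expect_true(is.na(cf$ratio_tumor_to_necrosis))
  expect_false(is.na(cf$ratio_necrosis_to_tumor) && FALSE) # necrosis/tumor = 0
  expect_equal(cf$ratio_necrosis_to_tumor, 0)
})

test_that("patch entropy is one bit for half-tumor half-stroma patches", {
  # every 8x8 patch of this map is exactly half tumor, half stroma
  grid <- matrix(rep(c(1L, 2L), each = 4, times = 32), nrow = 16, ncol = 16)
  map <- tissue_map(grid, pixel_size = 1)
  cf <- composition_features(map, patch = 8)
  expect_equal(cf$entropy_tumor, 1.0)
  expect_equal(cf$entropy_stroma, 1.0)
})

test_that("parent assignment uses the centroid pixel and flags background", {
  layout <- tibble::tibble(class = "necrosis", x = 5, y = 5, w = 5, h = 5)
  map <- simulate_tissue_specimen(20, 20, layout)$map
  nuclei <- tibble::tibble(
    id = c("a", "b", "c"), x = c(7.2, 1.0, 5.0), y = c(7.8, 1.0, 5.0),
    area = 10, diameter = 2 * sqrt(10 / pi), circularity = 0.9,
    eosin_mean = 0.5, eosin_var = 0.01,
    hematoxylin_mean = 0.5, hematoxylin_var = 0.01, cell_type = "other"
  )
  res <- assign_parents(nuclei, map)
  # (5.0, 5.0) sits on the first necrosis pixel: boundary takes that pixel
  expect_equal(res$parent, c("necrosis", "background", "necrosis"))
  expect_equal(res$excluded, c(FALSE, TRUE, FALSE))

  bad <- nuclei
  bad$x[1] <- 25
  expect_error(assign_parents(bad, map), "outside")
})

test_that("nuclear percentiles follow the linear-interpolation convention", {
  nuclei <- tibble::tibble(
    id = letters[1:5], x = 1:5 - 0.5, y = rep(0.5, 5),
    area = c(10, 20, 30, 40, 50), diameter = 2 * sqrt(c(10, 20, 30, 40, 50) / pi),
    circularity = 0.8, eosin_mean = 0.5, eosin_var = 0.01,
    hematoxylin_mean = 0.5, hematoxylin_var = 0.01,
    cell_type = "other", parent = "tumor", excluded = FALSE
  )
  agg <- nuclear_aggregates(nuclei)
  expect_equal(agg$tumor_all_area_p50, 30)
  expect_equal(agg$tumor_all_area_p10,
               unname(quantile(c(10, 20, 30, 40, 50), 0.1, type = 7)))
  # no lymphocytes: fraction 0, lymphocyte stratum missing
  expect_equal(agg$tumor_lymphocyte_fraction, 0)
  expect_true(is.na(agg$tumor_lymphocyte_area_mean))
  # empty parent stratum entirely missing
  expect_true(is.na(agg$stroma_all_area_mean))
  expect_true(is.na(agg$stroma_lymphocyte_fraction))
})

test_that("the embedding covers the registry and is deterministic", {
  layout <- tibble::tibble(
    class = c("tumor", "stroma", "fat"), x = c(0, 30, 0), y = c(0, 0, 30),
    w = c(25, 25, 20), h = c(25, 25, 20)
  )
  nuclei <- tibble::tibble(
    class = c("tumor", "stroma"), n = c(40, 25), area_mean = c(32, 18),
    area_sd = c(6, 4), lymphocyte_prob = c(0.2, 0.4)
  )
  sp <- simulate_tissue_specimen(64, 64, layout, nuclei, seed = 12)
  emb <- embed_specimen(sp$map, sp$nuclei)
  expect_identical(names(emb), histo_feature_registry())
  expect_identical(emb, embed_specimen(sp$map, sp$nuclei))
  # published signature members are registered features
  expect_true("tumor_all_area" %in% names(emb))
  expect_true("stroma_all_major_axis" %in% names(emb))
  expect_true("tumor_all_area_mean" %in% names(emb))
  expect_equal(emb$relative_specimen_size, mean(sp$map$grid != 0))
})

test_that("areas scale with the squared pixel size and lengths linearly", {
  layout <- tibble::tibble(class = "tumor", x = 2, y = 3, w = 12, h = 7)
  m1 <- simulate_tissue_specimen(30, 30, layout, pixel_size = 1)$map
  m2 <- simulate_tissue_specimen(30, 30, layout, pixel_size = 2)$map
  r1 <- region_features(m1, "tumor")
  r2 <- region_features(m2, "tumor")
  expect_equal(r2$all_area, 4 * r1$all_area)
  expect_equal(r2$all_major_axis, 2 * r1$all_major_axis)
  expect_equal(r2$all_perimeter, 2 * r1$all_perimeter)
  # dimensionless features are invariant
  expect_equal(r2$all_eccentricity, r1$all_eccentricity)
  expect_equal(r2$all_solidity, r1$all_solidity)
  expect_equal(r2$area_fraction, r1$area_fraction)
})

test_that("rotating the map by 90 degrees leaves the features invariant", {
  withr::local_seed(77)
  grid <- matrix(sample(0:2, 40 * 40, replace = TRUE, prob = c(0.5, 0.3, 0.2)),
                 40, 40)
  map <- tissue_map(grid, pixel_size = 1)
  rot <- tissue_map(t(grid)[ncol(grid):1, ], pixel_size = 1)
  for (cl in c("tumor", "stroma")) {
    a <- region_features(map, cl)
    b <- region_features(rot, cl)
    expect_equal(a$all_area, b$all_area)
    expect_equal(a$area_fraction, b$area_fraction)
    expect_equal(a$all_major_axis, b$all_major_axis, tolerance = 1e-9)
    expect_equal(a$all_minor_axis, b$all_minor_axis, tolerance = 1e-9)
  }
  ca <- composition_features(map, patch = 40)
  cb <- composition_features(rot, patch = 40)
  expect_equal(ca$entropy_tumor, cb$entropy_tumor, tolerance = 1e-9)
})

test_that("tissue maps round-trip through indexed PNG plus palette sidecar", {
  layout <- tibble::tibble(class = c("tumor", "fat"), x = c(0, 15), y = c(0, 0),
                           w = c(10, 5), h = c(10, 8))
  map <- simulate_tissue_specimen(25, 15, layout, pixel_size = 0.5)$map
  path <- withr::local_tempfile(fileext = ".png")
  write_tissue_map(map, path)
  back <- read_tissue_map(path)
  expect_identical(back$grid, map$grid)
  expect_identical(back$palette, map$palette)
  expect_equal(back$pixel_size, map$pixel_size)
})
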