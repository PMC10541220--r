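test_that("discretization handles degenerate, identity and uniform cases", {
  img <- matrix(5, 4, 4)
  mask <- matrix(TRUE, 4, 4)
  expect_true(all(discretize(img, mask, 8)[mask] == 1L))

  img2 <- matrix(0:31, 4, 8)
  gl2 <- discretize(img2, matrix(TRUE, 4, 8), 32)
  expect_equal(as.vector(gl2), 1:32)

  expect_error(discretize(img, matrix(FALSE, 4, 4), 8), "empty")
  expect_error(discretize(img, mask, 1), "n_bins")

  set.seed(1)
  img3 <- matrix(runif(20000), 100, 200)
  gl3 <- discretize(img3, matrix(TRUE, 100, 200), 8)
  shares <- tabulate(gl3, 8) / 20000
  expect_true(all(abs(shares - 1 / 8) < 0.01))
})

test_that("first-order features match closed forms on tiny regions", {
  img <- matrix(c(1, 2, 3, 4), 2, 2)
  mask <- matrix(TRUE, 2, 2)
  fo <- first_order_features(img, mask)
  expect_equal(unname(fo["fo_mean"]), 2.5)
  expect_equal(unname(fo["fo_median"]), 2.5)
  expect_equal(unname(fo["fo_range"]), 3)
  expect_equal(unname(fo["fo_energy"]), 30)
  expect_equal(unname(fo["fo_total_energy"]), 30)
  expect_equal(unname(fo["fo_variance"]), 1.25)
  expect_equal(unname(fo["fo_sd"]), sqrt(1.25))

  sym <- matrix(c(-1, 0, 1, 99), 2, 2)
  msk <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  expect_equal(unname(first_order_features(sym + 10, msk)["fo_skewness"]), 0)
  expect_error(first_order_features(img, matrix(c(TRUE, rep(FALSE, 3)),
                                                2, 2)), ">= 2")
})

test_that("first-order features agree with the naive oracle", {
  for (seed in 1:8) {
    patch <- random_patch(8, seed)
    got <- first_order_features(patch$image, patch$mask)
    want <- oracle_first_order(patch$image[patch$mask])
    expect_equal(got, want[names(got)], tolerance = 1e-12)
  }
})

test_that("zone matrices match trivial cases and the flood-fill oracle", {
  gl <- matrix(1L, 3, 3)
  zm <- glszm(gl, matrix(TRUE, 3, 3))
  expect_equal(zm$n_zones, 1L)
  expect_equal(zm$counts[1, 9], 1L)

  gl2 <- matrix(c(1L, 2L, 1L, 2L), 2, 2)   # rows [[1,1],[2,2]]
  zm2 <- glszm(gl2)
  expect_equal(zm2$n_zones, 2L)
  expect_equal(sum(zm2$counts[, 2]), 2L)

  for (seed in 1:6) {
    set.seed(seed)
    gl3 <- matrix(sample.int(4L, 100, replace = TRUE), 10, 10)
    gl3[matrix(runif(100) < 0.2, 10, 10)] <- NA_integer_
    if (!any(!is.na(gl3))) next
    for (conn in c(4L, 8L)) {
      zm3 <- glszm(gl3, connectivity = conn)
      zones <- oracle_glszm_zones(gl3, conn)
      expect_equal(zm3$counts,
                   oracle_zone_counts(zones, nrow(zm3$counts),
                                      ncol(zm3$counts)),
                   ignore_attr = TRUE)
      expect_equal(zm3$n_zones, nrow(zones))
    }
  }
})

test_that("GLSZM features match closed forms and the enumeration oracle", {
  zm <- glszm(matrix(1L, 3, 3))
  f <- glszm_features(zm)
  expect_equal(unname(f["szm_large_area_emphasis"]), 81)
  expect_equal(unname(f["szm_small_area_emphasis"]), 1 / 81)
  expect_equal(unname(f["szm_zone_percentage"]), 1 / 9)
  expect_equal(unname(f["szm_gray_level_nonuniformity"]), 1)

  f2 <- glszm_features(glszm(matrix(c(1L, 2L, 1L, 2L), 2, 2)))
  expect_equal(unname(f2["szm_small_area_emphasis"]), 0.25)
  expect_equal(unname(f2["szm_high_gray_level_zone_emphasis"]), 2.5)

  for (seed in 1:6) {
    set.seed(seed + 50)
    gl <- matrix(sample.int(5L, 144, replace = TRUE), 12, 12)
    zm3 <- glszm(gl)
    zones <- oracle_glszm_zones(gl, 8L)
    want <- oracle_glszm_features(zones, n_pixels = 144)
    got <- glszm_features(zm3)
    expect_equal(got, want[names(got)], tolerance = 1e-12)
  }
})

test_that("zone mass is conserved and size-only features are label-invariant", {
  for (seed in 1:5) {
    set.seed(seed + 100)
    gl <- matrix(sample.int(6L, 81, replace = TRUE), 9, 9)
    zm <- glszm(gl)
    expect_equal(sum(sweep(zm$counts, 2, seq_len(ncol(zm$counts)), "*")),
                 81)
    # bijective gray-level relabeling g -> 7 - g preserves the zones
    f1 <- glszm_features(zm)
    f2 <- glszm_features(glszm(7L - gl))
    size_only <- c("szm_small_area_emphasis", "szm_large_area_emphasis",
                   "szm_zone_percentage", "szm_size_zone_nonuniformity")
    expect_equal(f1[size_only], f2[size_only], tolerance = 1e-12)
  }
})

test_that("first-order moments are shift invariant", {
  patch <- random_patch(10, 77)
  f1 <- first_order_features(patch$image, patch$mask)
  f2 <- first_order_features(patch$image + 3.7, patch$mask)
  for (nm in c("fo_variance", "fo_skewness", "fo_kurtosis", "fo_sd"))
    expect_equal(f1[[nm]], f2[[nm]], tolerance = 1e-9)
  expect_equal(f2[["fo_mean"]], f1[["fo_mean"]] + 3.7, tolerance = 1e-12)
  expect_equal(f2[["fo_median"]], f1[["fo_median"]] + 3.7,
               tolerance = 1e-12)
})

test_that("correlation pruning keeps/drops features as specified", {
  set.seed(9)
  X <- matrix(rnorm(200), 50, 4,
              dimnames = list(NULL, c("a", "b", "c", "d")))
  X[, 2] <- X[, 1]                       # duplicate column
  expect_equal(prune_correlated(X, 0.95), c("a", "c", "d"))
  expect_equal(prune_correlated(X, 0), "a")

  Xi <- matrix(rnorm(500 * 6), 500, 6,
               dimnames = list(NULL, letters[1:6]))
  expect_equal(prune_correlated(Xi, 0.95), letters[1:6])

  Xc <- cbind(X[, 1, drop = FALSE], const = rep(1, 50))
  expect_equal(prune_correlated(Xc, 0.5), c("a", "const"))
  expect_error(prune_correlated(X[1, , drop = FALSE], 0.9), "samples")
})

test_that("the catalogue holds 19 + 16 = 35 uniquely named features", {
  cat <- feature_catalogue()
  expect_length(cat$first_order, 19)
  expect_length(cat$glszm, 16)
  expect_length(cat$all, 35)
  expect_false(anyDuplicated(cat$all) > 0)
  patch <- random_patch(9, 5)
  expect_identical(names(compute_region_features(patch$image, patch$mask)),
                   cat$all)
})
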