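test_that("volumes round-trip losslessly through TIFF, NRRD and NIfTI", {
  set.seed(42)
  occ <- array(stats::runif(32 * 32 * 10) > 0.7, c(32, 32, 10))
  g <- voxel_grid(occ, 0.012, label = "BD")
  for (ext in c(".tif", ".nrrd", ".nii.gz")) {
    path <- withr::local_tempfile(fileext = ext)
    write_volume(g, path)
    back <- read_volume(path, voxel_size_mm = if (ext == ".tif") 0.012
                        else NULL)
    expect_identical(back$occupancy, g$occupancy, info = ext)
    expect_equal(back$voxel_size_mm, 0.012, info = ext)
  }
})

test_that("degenerate grids survive the round trip", {
  for (occ in list(array(FALSE, c(32, 32, 10)),   # all-zero stack
                   array(TRUE, c(1, 1, 1)))) {    # 1x1x1 grid
    g <- voxel_grid(occ, 0.0065)
    path <- withr::local_tempfile(fileext = ".nrrd")
    write_volume(g, path)
    back <- read_volume(path)
    expect_identical(back$occupancy, g$occupancy)
    expect_identical(dim(back), dim(g))
    expect_equal(sum(back$occupancy), sum(occ))
  }
})

test_that("any nonzero value is foreground and binarization is idempotent", {
  vals <- array(0L, c(4, 4, 3)); vals[1, 1, 1] <- 255L; vals[2, 2, 2] <- 7L
  g <- voxel_grid(vals, 0.012)
  expect_identical(sort(unique(as.integer(g$occupancy))), c(0L, 1L))
  expect_equal(sum(g$occupancy), 2)
  expect_identical(voxel_grid(g$occupancy, 0.012)$occupancy, g$occupancy)

  # a {0, 255} uint8 NRRD written independently of the package's writer
  path <- withr::local_tempfile(fileext = ".nrrd")
  con <- file(path, "wb")
  writeLines(c("NRRD0004", "type: uint8", "dimension: 3", "sizes: 4 4 3",
               "spacings: 0.012 0.012 0.012", "encoding: raw", ""),
             con, sep = "\n")
  writeBin(as.integer(vals), con, size = 1)
  close(con)
  back <- read_volume(path)
  expect_equal(sum(back$occupancy), 2)
  expect_equal(back$voxel_size_mm, 0.012)
})

test_that("anisotropic headers error naming the spacings; arg overrides header", {
  arr <- array(0L, c(4, 4, 4)); arr[2, 2, 2] <- 1L
  path <- withr::local_tempfile(fileext = ".nii")
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(0.010, 0.012, 0.012)
  RNifti::writeNifti(img, path)
  expect_error(read_volume(path), "anisotropic")

  path2 <- withr::local_tempfile(fileext = ".nii")
  img2 <- RNifti::asNifti(arr)
  RNifti::pixdim(img2) <- c(0.012, 0.012, 0.012)
  RNifti::writeNifti(img2, path2)
  expect_warning(g <- read_volume(path2, voxel_size_mm = 0.010), "overrides")
  expect_equal(g$voxel_size_mm, 0.010)
  expect_error(read_volume(withr::local_tempfile(fileext = ".tif")),
               "no such file")
})

test_that("component census counts 26-connected components", {
  occ <- array(FALSE, c(20, 12, 12))
  occ[3:18, 4:8, 4:8] <- TRUE          # solid bar
  rep1 <- validate_mask(voxel_grid(occ, 0.012))
  expect_equal(rep1$n_components_26conn, 1)
  expect_equal(rep1$n_foreground_voxels, 16 * 5 * 5)
  expect_equal(nrow(rep1$flagged_twigs), 0)

  occ[1, 11, 11] <- TRUE               # plus an isolated voxel
  rep2 <- validate_mask(voxel_grid(occ, 0.012))
  expect_equal(rep2$n_components_26conn, 2)
  expect_equal(rep2$smallest_component_voxels, 1)

  rep3 <- validate_mask(voxel_grid(occ, 0.012), prune_below = 4)
  expect_equal(rep3$n_pruned_components, 1)
  expect_equal(sum(rep3$pruned_grid$occupancy), 16 * 5 * 5)

  empty <- validate_mask(voxel_grid(array(FALSE, c(5, 5, 5)), 0.012))
  expect_equal(empty$n_components_26conn, 0)
})

test_that("terminal twigs below the four-voxel cross-section are flagged", {
  occ <- array(FALSE, c(40, 13, 13))
  occ[3:22, 4:8, 4:8] <- TRUE     # 5x5 bar: cross-section 25 voxels
  occ[23:32, 6, 6] <- TRUE        # attached 1-voxel-thick 10-voxel spur
  g <- voxel_grid(occ, 0.012)

  # brute-force cross-section counts orthogonal to the (axis-aligned) parts
  expect_equal(sum(occ[10, , ]), 25) # bar body
  expect_equal(sum(occ[28, , ]), 1)  # spur body: below the 4-voxel cut-off

  rep <- validate_mask(g, min_cross_section_voxels = 4)
  expect_gte(nrow(rep$flagged_twigs), 1)
  expect_true(all(rep$flagged_twigs$max_cross_section_voxels < 4))
  # the flagged endpoint lies in the spur, i.e. beyond the bar's end
  expect_true(any(rep$flagged_twigs$x_mm > 22 * 0.012))

  # the bar alone carries no flags
  occ2 <- array(FALSE, c(40, 13, 13)); occ2[3:22, 4:8, 4:8] <- TRUE
  expect_equal(nrow(validate_mask(voxel_grid(occ2, 0.012))$flagged_twigs), 0)
})
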