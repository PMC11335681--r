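test_that("PNG write/read round-trips masks exactly and images within quantization", {
  cfg <- slim_phantom_config(32L)
  set.seed(3)
  s <- generate_slice(cfg, "rt", 0L)
  d <- file.path(tempdir(), "io_rt")
  dir.create(d, showWarnings = FALSE)
  rec <- pancseg:::write_slice(s, d)
  back <- read_slice(rec$image_path, rec$pancreas_mask_path,
                     rec$tumor_mask_path, case_id = "rt")
  expect_lte(max(abs(back$image - s$image)), 1 / 255 + 1e-12)
  expect_equal(back$pancreas_mask, s$pancreas_mask)
  expect_equal(back$tumor_mask, s$tumor_mask)
})

test_that("missing and malformed masks are handled as documented", {
  cfg <- slim_phantom_config(32L)
  set.seed(4)
  s <- generate_slice(cfg, "mm", 0L)
  d <- file.path(tempdir(), "io_mm")
  dir.create(d, showWarnings = FALSE)
  rec <- pancseg:::write_slice(s, d)
  expect_warning(r <- read_slice(rec$image_path, NULL, rec$tumor_mask_path),
                 "empty mask")
  expect_true(all(r$pancreas_mask == 0))
  # wrong-size mask errors
  small <- file.path(d, "small_mask.png")
  png::writePNG(matrix(1, 8, 8), small)
  expect_error(read_slice(rec$image_path, small, NULL), "8x8")
  expect_error(read_slice(file.path(d, "nope.png")), "does not exist")
})

test_that("nifti volume-to-slice conversion applies the labeled-only rule", {
  cfg <- slim_phantom_config(32L, slices_per_case = 10L,
                             tumor_slice_range = c(5L, 5L))
  slices <- generate_case(cfg, 77L)
  has_tumor <- vapply(slices, function(s) sum(s$tumor_mask) > 0, logical(1))
  vol_path <- file.path(tempdir(), "vol.nii.gz")
  lab_path <- file.path(tempdir(), "lab.nii.gz")
  write_nifti_stack(lapply(slices, function(s) s$image * 1000 - 200), vol_path)
  labels <- lapply(slices, function(s) s$pancreas_mask + s$tumor_mask)
  write_nifti_stack(labels, lab_path)

  out1 <- file.path(tempdir(), "conv_lab")
  recs <- nifti_to_slices(vol_path, lab_path, out1, keep_rule = "labeled_only")
  expect_equal(nrow(recs), sum(has_tumor))    # brute-force slice count
  expect_equal(sort(recs$slice_index), which(has_tumor) - 1L)

  out2 <- file.path(tempdir(), "conv_all")
  recs_all <- nifti_to_slices(vol_path, lab_path, out2, keep_rule = "all")
  expect_equal(nrow(recs_all), 10L)

  # windowed image round-trips monotonically: masks must match originals
  r1 <- read_slice(recs$image_path[1], recs$pancreas_mask_path[1],
                   recs$tumor_mask_path[1])
  first_kept <- which(has_tumor)[1]
  expect_equal(r1$tumor_mask, slices[[first_kept]]$tumor_mask)

  # empty label volume, labeled_only -> empty manifest, no error
  empty_lab <- file.path(tempdir(), "empty_lab.nii.gz")
  write_nifti_stack(lapply(slices, function(s) s$image * 0), empty_lab)
  recs0 <- nifti_to_slices(vol_path, empty_lab, file.path(tempdir(), "conv0"),
                           keep_rule = "labeled_only")
  expect_equal(nrow(recs0), 0L)

  # shape mismatch errors naming both shapes
  short_lab <- file.path(tempdir(), "short_lab.nii.gz")
  write_nifti_stack(labels[1:3], short_lab)
  expect_error(nifti_to_slices(vol_path, short_lab, tempdir()),
               "32x32x10.*32x32x3")
})

test_that("case-level splitting is deterministic, case-disjoint and correctly sized", {
  make_manifest <- function(n_cases, slices_each = 3L) {
    tibble::tibble(
      case_id = rep(sprintf("case%03d", seq_len(n_cases)), each = slices_each),
      slice_index = rep(seq_len(slices_each) - 1L, n_cases),
      image_path = "x.png", pancreas_mask_path = "p.png",
      tumor_mask_path = "t.png", has_tumor = TRUE)
  }
  m <- split_cases(make_manifest(10L), 0.8, seed = 2L)
  expect_equal(length(unique(m$case_id[m$split == "train"])), 8L)
  by_case <- tapply(m$split, m$case_id, function(x) length(unique(x)))
  expect_true(all(by_case == 1L))
  m2 <- split_cases(make_manifest(10L), 0.8, seed = 2L)
  expect_identical(m$split, m2$split)

  # the real-data regime: 281 cases at the published train fraction
  m281 <- split_cases(make_manifest(281L, 1L), 216 / 281, seed = 1L)
  expect_equal(length(unique(m281$case_id[m281$split == "train"])), 216L)
  expect_equal(length(unique(m281$case_id[m281$split == "test"])), 65L)

  expect_error(split_cases(make_manifest(10L), 1.2), "between 0 and 1")
  expect_error(split_cases(make_manifest(1L), 0.5), "at least 2")
})

test_that("manifest JSON round-trips through write and read", {
  cfg <- slim_phantom_config(32L, slices_per_case = 2L,
                             tumor_slice_range = c(1L, 1L), seed = 9L)
  d <- file.path(tempdir(), "mf")
  unlink(d, recursive = TRUE)
  m <- generate_dataset(cfg, 1L, d)
  back <- pancseg:::read_manifest(file.path(d, "manifest.json"))
  expect_equal(nrow(back), nrow(m))
  expect_equal(back$case_id, m$case_id)
  expect_equal(back$has_tumor, m$has_tumor)
})
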