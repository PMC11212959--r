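test_that("fROI selection takes exactly the top voxels with the ceiling rule", {
  set.seed(2)
  stat <- sample(seq(-3, 6, length.out = 50))
  m <- voxel_map(1:50, stat, data.frame(A = rnorm(50)))
  sel <- select_froi(m, 0.10)
  expect_length(sel, 5L)
  expect_equal(sort(stat[sel], decreasing = TRUE),
               sort(stat, decreasing = TRUE)[1:5])
  # all-equal statistics: deterministic tie-break by voxel id
  m_tie <- voxel_map(1:50, rep(1, 50), data.frame(A = rnorm(50)))
  expect_equal(select_froi(m_tie, 0.10), 1:5)
  expect_identical(select_froi(m_tie, 0.10), select_froi(m_tie, 0.10))
  # ceiling rule over every mask size 1..1000
  for (n in 1:1000) {
    expect_length(select_froi(voxel_map(seq_len(n), seq_len(n),
                                        data.frame(A = numeric(n))), 0.10),
                  ceiling(0.10 * n))
  }
  expect_error(select_froi(m, 0), "fraction")
  expect_error(voxel_map(integer(0), numeric(0), data.frame(A = numeric(0))),
               "empty mask")
})

test_that("condition responses average over the selected voxels", {
  resp <- data.frame(A = rep(2.5, 10), B = rep(-1, 10))
  m <- voxel_map(1:10, 10:1, resp)
  r <- extract_condition_responses(m, 1:10, participant = "p1")
  expect_equal(unname(r$response), c(2.5, -1))
  r1 <- extract_condition_responses(m, 4L)
  expect_equal(unname(r1$response), c(2.5, -1))
  expect_equal(r1$n_voxels_selected, 1L)
  expect_error(extract_condition_responses(m, integer(0)), "empty")
  expect_error(extract_condition_responses(m, 11L), "outside")
})

test_that("noise-free synthetic maps recover planted effects exactly", {
  eff <- c(Sentence = 1.5, Backward = 0.9)
  m <- simulate_voxel_data(n_voxels = 200, effects = eff, noise_sd = 0,
                           signal_fraction = 0.2, seed = 6)
  sel <- select_froi(m, 0.10)
  expect_true(all(sel %in% attr(m, "signal_voxels")))
  r <- extract_condition_responses(m, sel)
  expect_equal(r$response, eff)
  # signal_fraction 1: every voxel is a signal voxel
  m1 <- simulate_voxel_data(n_voxels = 50, effects = eff, noise_sd = 0,
                            signal_fraction = 1, seed = 7)
  expect_equal(attr(m1, "signal_voxels"), 1:50)
})

test_that("selection enriches true signal voxels above chance", {
  m <- simulate_voxel_data(n_voxels = 500, noise_sd = 1,
                           signal_fraction = 0.1, seed = 8)
  sel <- select_froi(m, 0.10)
  frac_signal <- mean(sel %in% attr(m, "signal_voxels"))
  expect_gt(frac_signal, 0.8)  # chance would be 0.1
})

test_that("lateralization index formula, classification, and antisymmetry", {
  expect_equal(lateralization_index(10, 10)$index, 0)
  expect_false(lateralization_index(10, 10)$right_lateralized)
  expect_equal(lateralization_index(0, 7)$index, -1)
  expect_true(lateralization_index(0, 7)$right_lateralized)
  # observed values from strongly right-lateralized individuals classify
  expect_true(lateralization_index(99, 501)$index <= -0.25)
  expect_true(lateralization_index(99, 501)$right_lateralized)
  # boundary: exactly -0.25 is right-lateralized
  expect_true(lateralization_index(3, 5)$right_lateralized)
  expect_error(lateralization_index(0, 0), "undefined")
  set.seed(4)
  for (rep in 1:20) {
    a <- sample.int(100, 1); b <- sample.int(100, 1)
    expect_equal(lateralization_index(a, b)$index,
                 -lateralization_index(b, a)$index)
  }
  expect_equal(count_significant_voxels(c(0.5, 3.2, 4.1, 1), 3.09), 2L)
})

test_that("model tables dummy-code against the reference condition", {
  eff <- c(Sentence = 1.5, Backward = 0.9, Nonsense = 1.45, WordList = 0.7,
           Jabberwocky = 0.7, NonwordList = 0.4)
  responses <- lapply(1:6, function(p) {
    m <- simulate_voxel_data(n_voxels = 300, effects = eff, noise_sd = 1,
                             seed = 100 + p)
    extract_condition_responses(m, select_froi(m),
                                participant = sprintf("p%02d", p),
                                roi_label = "parcel1")
  })
  mt <- build_model_table(responses, reference = "Sentence")
  expect_equal(nrow(mt$table), 36L)
  expect_equal(ncol(mt$coding), 5L)  # six conditions, five contrasts
  ref_rows <- mt$table[mt$table$condition == "Sentence",
                       grep("^d_", names(mt$table))]
  expect_true(all(ref_rows == 0))
  # OLS on the fixed part recovers the planted contrasts
  fit <- lm(response ~ d_Backward + d_Nonsense + d_WordList + d_Jabberwocky +
              d_NonwordList, data = mt$table)
  est <- coef(fit)
  expect_equal(unname(est["(Intercept)"]), 1.5, tolerance = 0.15)
  expect_equal(unname(est["d_Backward"]), 0.9 - 1.5, tolerance = 0.2)
  expect_equal(unname(est["d_NonwordList"]), 0.4 - 1.5, tolerance = 0.2)
  # two conditions: a single dummy column
  mt2 <- build_model_table(responses = lapply(responses, function(r) {
    r$response <- r$response[c("Sentence", "Backward")]; r
  }), reference = "Sentence")
  expect_equal(ncol(mt2$coding), 1L)
  expect_error(build_model_table(responses, reference = "Missing"),
               "not present")
})

test_that("voxel maps round-trip through dense TSV", {
  m <- simulate_voxel_data(n_voxels = 40, noise_sd = 0.5, seed = 11)
  p <- tempfile(fileext = ".tsv")
  on.exit(unlink(p))
  write_voxel_map_tsv(m, p)
  back <- read_voxel_map_tsv(p, mask_label = m$mask_label)
  expect_equal(back$localizer_stat, m$localizer_stat, tolerance = 1e-9)
  expect_equal(back$condition_responses, m$condition_responses,
               tolerance = 1e-9)
  expect_equal(select_froi(back), select_froi(m))
})

test_that("voxel maps load from NIfTI volumes", {
  skip_if_not_installed("RNifti")
  dims <- c(5, 5, 4)
  arr <- function(x) array(x, dim = dims)
  td <- tempfile("nii")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  set.seed(12)
  mask <- arr(runif(prod(dims)) < 0.5)
  stat <- arr(rnorm(prod(dims)))
  respA <- arr(rnorm(prod(dims))); respB <- arr(rnorm(prod(dims)))
  paths <- file.path(td, c("mask.nii", "stat.nii", "a.nii", "b.nii"))
  RNifti::writeNifti(arr(as.numeric(mask)), paths[1])
  RNifti::writeNifti(stat, paths[2])
  RNifti::writeNifti(respA, paths[3])
  RNifti::writeNifti(respB, paths[4])
  m <- read_voxel_map_nifti(paths[2], paths[1],
                            c(A = paths[3], B = paths[4]),
                            mask_label = "vol")
  expect_equal(length(m$voxel_id), sum(mask))
  expect_equal(m$localizer_stat, as.vector(stat)[as.vector(mask)],
               tolerance = 1e-6)
  expect_equal(m$condition_responses$B, as.vector(respB)[as.vector(mask)],
               tolerance = 1e-6)
})
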