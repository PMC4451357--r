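# ICV slice scoring and the 50%-of-max / undersampling key-slice rule.

make_set <- function(vols, labels) {
  labeled_volume_set(vols, labels, coronal_axis = 2L)
}

test_that("ICV is zero when class means coincide and matches the closed form for a single-slice contrast", {
  base <- array(runif(6 * 5 * 4), dim = c(6, 5, 4))
  # identical class means: each class holds the same two volumes
  vols <- list(base, base + 1, base, base + 1)
  icv <- compute_icv(make_set(vols, c(0, 0, 1, 1)))
  expect_equal(icv$icv, rep(0, 5))
  expect_error(select_key_slices(icv), "all-zero")

  # constant difference c on exactly one coronal slice of M voxels
  c_val <- 2.5
  bump <- array(0, dim = c(6, 5, 4))
  bump[, 3, ] <- c_val
  vols2 <- list(base, base, base + bump, base + bump)
  icv2 <- compute_icv(make_set(vols2, c(0, 0, 1, 1)))
  expect_equal(icv2$icv[3], c_val^2 * 6 * 4)
  expect_equal(icv2$icv[-3], rep(0, 4))
  # plain-norm variant takes the square root
  icv2p <- compute_icv(make_set(vols2, c(0, 0, 1, 1)), norm = "plain")
  expect_equal(icv2p$icv, sqrt(icv2$icv))
})

test_that("ICV equals a brute-force per-voxel loop on a random cohort", {
  set.seed(5)
  vols <- replicate(6, array(rnorm(4 * 7 * 3), dim = c(4, 7, 3)),
                    simplify = FALSE)
  labels <- c(0, 0, 0, 1, 1, 1)
  icv <- compute_icv(make_set(vols, labels))
  brute <- sapply(1:7, function(k) {
    s <- 0
    for (i in 1:4) for (j in 1:3) {
      m_ad <- mean(sapply(which(labels == 1), function(s_) vols[[s_]][i, k, j]))
      m_nc <- mean(sapply(which(labels == 0), function(s_) vols[[s_]][i, k, j]))
      s <- s + (m_ad - m_nc)^2
    }
    s
  })
  expect_equal(icv$icv, brute, tolerance = 1e-12)
})

test_that("ICV properties: squared-norm homogeneity and label-swap symmetry", {
  set.seed(6)
  vols <- replicate(5, array(rnorm(3 * 6 * 3), dim = c(3, 6, 3)),
                    simplify = FALSE)
  labels <- c(0, 0, 1, 1, 1)
  v1 <- compute_icv(make_set(vols, labels))$icv
  v_scaled <- compute_icv(make_set(lapply(vols, `*`, 3), labels))$icv
  expect_equal(v_scaled, 9 * v1, tolerance = 1e-12)
  v_swap <- compute_icv(make_set(vols, 1 - labels))$icv
  expect_equal(v_swap, v1, tolerance = 1e-12)
  expect_error(compute_icv(make_set(vols, labels)$volumes), "labeled_volume_set")
})

test_that("key-slice rule: threshold, anchoring and stride", {
  prof <- function(v) structure(data.frame(slice = seq_along(v), icv = v),
                                class = c("icv_profile", "data.frame"),
                                axis = 2L, norm = "squared")
  # flat positive profile: every slice is a candidate; stride from slice 1
  flat <- prof(rep(1, 100))
  expect_equal(select_key_slices(flat, undersample = 10)$key_indices,
               seq(1, 91, by = 10))
  # candidate run 5..15 with stride 10 keeps 5 and 15
  v <- rep(0.1, 30); v[5:15] <- 1
  expect_equal(select_key_slices(v |> prof(), fraction = 0.5,
                                 undersample = 10)$key_indices, c(5L, 15L))
  # gap in the candidate set: stride counts slice offsets, not candidates
  v2 <- rep(0.01, 40); v2[c(1:3, 21:23)] <- 1
  expect_equal(select_key_slices(prof(v2), undersample = 10)$key_indices,
               c(1L, 21L))
  # threshold fraction is relative: rescaling the profile changes nothing
  expect_equal(select_key_slices(prof(v2 * 77), undersample = 10)$key_indices,
               c(1L, 21L))
  expect_error(select_key_slices(prof(v2), fraction = 1.5), "fraction")
})

test_that("slice extraction is a faithful, ordered identity and round-trips", {
  ph <- tiny_phantom()
  data <- ph$data
  sel <- select_key_slices(compute_icv(data), undersample = 3)
  stacks <- extract_slices(data, sel)
  expect_length(stacks, length(sel$key_indices))
  k1 <- stacks[[1]]$key_index
  for (i in c(1, 5, 14))
    expect_identical(stacks[[1]]$images[i, , ], data$volumes[[i]][, k1, ])
  # re-insertion reproduces the original planes bit-exactly
  rebuilt <- assign_plane(array(0, dim = data$shape), 2L, k1,
                          stacks[[1]]$images[3, , ])
  expect_identical(rebuilt[, k1, ], data$volumes[[3]][, k1, ])
  expect_error(extract_slices(data, c(1L, 99L)), "out of range")
})
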