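test_that("THSP extraction tracks one spatial column through time", {
  frames <- array(0L, dim = c(5, 4, 3))
  for (t in 1:3) frames[, , t] <- matrix(seq_len(20) * t, 5, 4)
  thsp <- extract_thsp(frames, column_index = 1)
  expect_equal(dim(thsp), c(5L, 3L))
  for (t in 1:3) expect_equal(unclass(thsp)[, t], frames[, 2, t])
  expect_equal(attr(thsp, "column_index"), 1L)

  # constant stack -> identical THSP columns
  cst <- array(7L, dim = c(5, 4, 3))
  tc <- extract_thsp(cst, 0)
  expect_true(all(tc == 7L))

  # out-of-range column and too-few frames fail
  expect_error(extract_thsp(frames, column_index = 4), "out of range")
  expect_error(extract_thsp(frames[, , 1, drop = FALSE], 0), "2 frames")
})

test_that("mid-column default maps the 256th column to 0-based index 255", {
  frames <- array(sample(0:255, 8 * 512 * 2, replace = TRUE),
                  dim = c(8, 512, 2))
  thsp <- extract_thsp(frames)
  expect_equal(attr(thsp, "column_index"), 255L)
  expect_equal(unclass(thsp)[, 1], frames[, 256, 1])
})

test_that("co-occurrence matrix counts consecutive intensity pairs", {
  # one static row: both transitions 5 -> 5
  com1 <- build_com(matrix(c(5L, 5L, 5L), 1, 3), gray_levels = 8)
  expect_equal(com1$counts[6, 6], 2)
  expect_equal(sum(com1$counts), 2)
  expect_equal(sum(com1$counts) - com1$counts[6, 6], 0)

  # hand-enumerated two-row THSP: transitions 0->1 and 1->0
  com2 <- build_com(matrix(c(0L, 1L, 1L, 0L), 2, 2, byrow = TRUE),
                    gray_levels = 2)
  expect_equal(com2$counts, matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(com2$normalized, matrix(c(0, 1, 1, 0), 2, 2))

  # gray_levels below the observed maximum is rejected
  expect_error(build_com(matrix(c(0L, 3L), 1, 2), gray_levels = 3),
               "smaller than observed")
})

test_that("COM conserves the transition count and row-normalizes", {
  set.seed(11)
  for (rep in 1:20) {
    h <- sample(2:16, 1); tt <- sample(2:16, 1); g <- sample(2:8, 1)
    thsp <- random_thsp(h, tt, g)
    com <- build_com(thsp, g)
    expect_equal(sum(com$counts), h * (tt - 1))
    rs <- rowSums(com$normalized)
    expect_true(all(abs(rs - 1) < 1e-12 | rs == 0))
  }
})

test_that("inertia moment matches hand computation and the diagonal law", {
  expect_equal(inertia_moment(matrix(c(0, 1, 1, 0), 2, 2))$ba, 2)
  expect_equal(inertia_moment(diag(4))$ba, 0)
})

test_that("vectorized inertia moment equals the triple-loop oracle", {
  set.seed(7)
  for (rep in 1:50) {
    h <- sample(2:16, 1); tt <- sample(2:16, 1); g <- sample(2:8, 1)
    thsp <- random_thsp(h, tt, g)
    im <- inertia_moment(build_com(thsp, g))$ba
    oracle <- im_bruteforce(thsp, g)
    if (oracle > 0) expect_lt(abs(im - oracle) / oracle, 1e-12)
    else expect_equal(im, 0)
  }
})

test_that("inertia moment is invariant to a global additive intensity shift", {
  set.seed(21)
  for (rep in 1:10) {
    thsp <- random_thsp(8, 10, 6)
    shift <- sample(1:5, 1)
    im0 <- inertia_moment(build_com(thsp, 6))$ba
    im1 <- inertia_moment(build_com(thsp + shift, 6 + shift))$ba
    expect_equal(im1, im0, tolerance = 1e-14)
  }
})

test_that("inertia moment is zero iff every THSP row is constant in time", {
  static <- matrix(rep(c(3L, 5L, 0L), each = 4), 3, 4, byrow = TRUE)
  expect_equal(inertia_moment(build_com(static, 8))$ba, 0)
  moving <- static; moving[2, 3] <- 6L
  expect_gt(inertia_moment(build_com(moving, 8))$ba, 0)
})

test_that("prefix windows use floor(window x frame_rate) frames", {
  p <- speckle_sim_params(height = 8, width = 8, n_frames = 512,
                          frame_rate = 12.5, rho = 0.7, seed = 5)
  seq <- simulate_speckle_sequence(p)
  tab <- ba_over_windows(seq, c(10, 20, 30, 40))
  expect_equal(tab$n_frames, c(125L, 250L, 375L, 500L))
  expect_equal(tab$window_s, c(10, 20, 30, 40))

  # "all" reaches the full 512-frame recording
  tab_all <- ba_over_windows(seq, list("all"))
  expect_equal(tab_all$n_frames, 512L)

  # a window longer than the recording fails
  expect_error(ba_over_windows(seq, 60), "needs")
})

test_that("a static stack has zero activity in every window", {
  p <- speckle_sim_params(height = 16, width = 16, n_frames = 150,
                          frame_rate = 12.5, rho = 1, seed = 2)
  seq <- simulate_speckle_sequence(p)
  tab <- ba_over_windows(seq, c(10, 12))
  expect_equal(tab$ba, c(0, 0))
})

test_that("window correlation is 1 for the reference and affine copies", {
  set.seed(3)
  ba10 <- rnorm(10, 3000, 400)
  m <- cbind(`10` = ba10, `20` = 2 * ba10 + 100, `40` = rnorm(10, 3000, 400))
  r <- window_correlation(m, 1L)
  expect_identical(unname(r[1]), 1)
  expect_equal(unname(r[2]), 1)
  expect_true(abs(r[3]) <= 1)

  expect_error(window_correlation(cbind(a = rep(1, 5), b = rnorm(5))),
               "zero variance")
  expect_error(window_correlation(m[1:2, ]), "3 samples")
})
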