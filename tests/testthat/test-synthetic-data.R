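test_that("speckle generator validates its parameters", {
  expect_error(speckle_sim_params(height = 4), "8 x 8")
  expect_error(speckle_sim_params(n_frames = 1), "at least 2")
  expect_error(speckle_sim_params(rho = 1.2), "rho")
  expect_error(speckle_sim_params(rho = -0.1), "rho")
})

test_that("rho = 1 yields a static stack and rho = 0 independent frames", {
  p <- speckle_sim_params(height = 32, width = 32, n_frames = 20, rho = 1,
                          seed = 4)
  s <- simulate_speckle_sequence(p)
  expect_equal(max(abs(sweep(s$frames, c(1, 2), s$frames[, , 1]))), 0)

  p0 <- speckle_sim_params(height = 32, width = 32, n_frames = 20, rho = 0,
                           seed = 4)
  s0 <- simulate_speckle_sequence(p0)
  r <- cor(as.vector(s0$frames[, , 1]), as.vector(s0$frames[, , 2]))
  expect_lt(abs(r), 0.15)
})

test_that("quantized intensities stay inside the configured bit depth", {
  s <- simulate_speckle_sequence(
    speckle_sim_params(height = 16, width = 16, n_frames = 10, rho = 0.5,
                       seed = 1))
  expect_true(is.integer(s$frames))
  expect_gte(min(s$frames), 0L)
  expect_lte(max(s$frames), 255L)
  s64 <- simulate_speckle_sequence(
    speckle_sim_params(height = 16, width = 16, n_frames = 10, rho = 0.5,
                       bit_depth = 64, seed = 1))
  expect_lte(max(s64$frames), 63L)
})

test_that("raw speckle intensity is near negative-exponential (CV ~ 1)", {
  for (sd_seed in 1:5) {
    raw <- simulate_speckle_sequence(
      speckle_sim_params(height = 64, width = 64, n_frames = 2, rho = 0.5,
                         grain_sigma = 1, seed = sd_seed),
      quantize = FALSE)
    f <- raw$frames[, , 1]
    expect_equal(sd(f) / mean(f), 1, tolerance = 0.1)
  }
})

test_that("lower temporal correlation produces higher activity", {
  # paired comparison over seeds: BA(rho = 0.3) > BA(rho = 0.9) every time
  wins <- vapply(1:20, function(sd) {
    ba <- vapply(c(0.3, 0.9), function(r) {
      p <- speckle_sim_params(height = 32, width = 32, n_frames = 40,
                              rho = r, seed = sd)
      biospeckle_activity(simulate_speckle_sequence(p))$ba
    }, numeric(1))
    ba[1] > ba[2]
  }, logical(1))
  # sign test: under no effect, 20/20 wins has probability 2^-20
  expect_true(all(wins))
})

test_that("patch generator hits the requested gray contrast", {
  # 1 d regime: strong positive contrast
  pp <- patch_sim_params(con = 30.943, seed = 31)
  pair <- simulate_skin_patch_pair(pp)
  # realized Con within 3 SE of target (SE of mean gray over 65^2 px, sd ~ 8)
  se <- sqrt(2) * 8 / 65
  expect_lt(abs(contrast_con(pair$ss, pair$is_) - 30.943), 3 * se + 0.5)

  # 1 h regime: negative contrast, injured skin brighter
  neg <- simulate_skin_patch_pair(patch_sim_params(con = -13.064, seed = 32))
  expect_lt(contrast_con(neg$ss, neg$is_), 0)
  expect_gt(mean(neg$is_$pixels), mean(neg$ss$pixels))

  # all channel values stay within the 8-bit range
  expect_gte(min(pair$is_$pixels), 0L)
  expect_lte(max(pair$is_$pixels), 255L)
})

test_that("zero-contrast pairs show no systematic gray difference", {
  pvals <- vapply(1:50, function(sd) {
    pp <- patch_sim_params(con = 0, n_lenticels = 0, seed = sd)
    pair <- simulate_skin_patch_pair(pp)
    g1 <- as.vector(0.299 * pair$ss$pixels[, , 1] +
                      0.587 * pair$ss$pixels[, , 2] +
                      0.114 * pair$ss$pixels[, , 3])
    g2 <- as.vector(0.299 * pair$is_$pixels[, , 1] +
                      0.587 * pair$is_$pixels[, , 2] +
                      0.114 * pair$is_$pixels[, , 3])
    t.test(g1, g2)$p.value
  }, numeric(1))
  # contrast is matched exactly by construction, so none should reject
  expect_lt(mean(pvals < 0.01), 0.2)
})

test_that("contrast pushing channels outside 8 bits is rejected", {
  expect_error(patch_sim_params(con = 120, mean_rgb_ss = c(100, 100, 100)),
               "outside")
})

test_that("dataset generation is deterministic and validates n_per_class", {
  pp <- patch_sim_params(seed = 0)
  d1 <- generate_dataset(3, "rgb", pp, seed = 99)
  d2 <- generate_dataset(3, "rgb", pp, seed = 99)
  expect_identical(d1, d2)
  expect_equal(length(d1), 6L)
  expect_equal(sort(unique(vapply(d1, `[[`, character(1), "label"))),
               c("IS", "SS"))
  expect_error(generate_dataset(0, "rgb", pp), "at least 2")

  sp <- speckle_sim_params(height = 16, width = 16, n_frames = 10)
  s1 <- generate_dataset(2, "speckle", sp, class_rhos = c(0.95, 0.5),
                         seed = 5)
  s2 <- generate_dataset(2, "speckle", sp, class_rhos = c(0.95, 0.5),
                         seed = 5)
  expect_identical(s1, s2)
  expect_false(identical(s1[[1]]$sequence$frames, s1[[2]]$sequence$frames))
})
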