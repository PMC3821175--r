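# Line-profile colocalization: raster extraction, thresholding, peak
# calling, nearest-peak distances, paired and shuffled correlations.

make_ridge <- function(nrow = 20, ncol = 20, col_center = 10, sigma = 1.5,
                       baseline = 1, amp = 10) {
  outer(rep(1, nrow), seq_len(ncol), function(r, c)
    baseline + amp * exp(-(c - col_center)^2 / (2 * sigma^2)))
}

test_that("profile extraction averages perpendicular to the scan line", {
  const <- matrix(7, 20, 20)
  pr <- extract_line_profile(const, const, cbind(c(2, 18), c(10, 10)),
                             width_pixels = 6)
  expect_true(all(abs(pr$ch1 - 7) < 1e-9))
  expect_true(all(abs(pr$ch2 - 7) < 1e-9))

  # single bright column crossed perpendicularly: direct averaging oracle
  img <- matrix(1, 20, 20); img[, 10] <- 31
  pr <- extract_line_profile(img, img, cbind(c(2, 18), c(10, 10)),
                             width_pixels = 6)
  i_pk <- which.max(pr$ch1)
  expect_equal(pr$position_nm[i_pk] / 100 + 2, 10, tolerance = 0.5)
  # perpendicular samples run along the bright column: full height kept
  expect_equal(max(pr$ch1), 31, tolerance = 1e-6)
  expect_equal(pr$ch1[1], 1, tolerance = 1e-6)

  # six- vs eight-pixel width: identical peak position on a symmetric ridge
  ridge <- make_ridge()
  line <- cbind(c(2, 18), c(10, 10))
  p6 <- extract_line_profile(ridge, ridge, line, width_pixels = 6)
  p8 <- extract_line_profile(ridge, ridge, line, width_pixels = 8)
  expect_equal(which.max(p6$ch1), which.max(p8$ch1))

  expect_error(extract_line_profile(const, const,
                                    cbind(c(2, 30), c(10, 10))),
               "vertex 2")
  expect_error(extract_line_profile(const, const, line, width_pixels = 5),
               "even")
})

test_that("the threshold rule matches hand arithmetic", {
  # constant positive trace: SD = 0, threshold = the constant
  thr <- estimate_threshold(rep(4, 20), seq(0, 1900, by = 100))
  expect_equal(as.numeric(thr), 4)

  # worked 11-point trace at 100 nm spacing: floor 2 at index 2,
  # 600 nm window covers indices 1-5, sample SD of (0,2,2,2,2)
  trace <- c(0, 2, 2, 2, 2, 2, 2, 10, 30, 10, 2)
  thr <- estimate_threshold(trace, seq(0, 1000, by = 100))
  expect_equal(as.numeric(thr), 2 + 3.5 * sd(c(0, 2, 2, 2, 2)))
  expect_equal(attr(thr, "floor"), 2)

  # monotone in the SD multiplier whenever SD > 0
  thr7 <- estimate_threshold(trace, seq(0, 1000, by = 100),
                             sd_multiplier = 7)
  expect_gt(as.numeric(thr7), as.numeric(thr))

  # adding a punctum far from the floor window leaves it unchanged
  far <- c(trace, 0 * 1:20 + 2, 500, 2)
  thr_far <- estimate_threshold(far, seq(0, 100 * (length(far) - 1),
                                         by = 100))
  expect_equal(as.numeric(thr_far), as.numeric(thr))

  expect_error(estimate_threshold(rep(0, 10), seq(0, 900, by = 100)),
               "non-zero floor")
})

test_that("peak calling finds punctum centers, plateaus and merges", {
  pos <- seq(0, 10000, by = 100)
  g <- function(c0, a = 100, s = 200) a * exp(-(pos - c0)^2 / (2 * s^2))

  pk <- detect_peaks(5 + g(4000), pos, threshold = 20)
  expect_length(pk$position_nm, 1)
  expect_lt(abs(pk$position_nm - 4000), 101)

  pk <- detect_peaks(5 + g(3000) + g(4000), pos, threshold = 20)
  expect_length(pk$position_nm, 2)

  # plateau reports its centroid
  y <- rep(1, 41); y[18:22] <- 9
  pk <- detect_peaks(y, seq(0, 4000, by = 100), threshold = 5)
  expect_equal(pk$position_nm, mean(seq(1700, 2100, by = 100)))

  # maxima closer than min_separation merge, keeping the higher
  y <- rep(1, 41); y[10] <- 8; y[12] <- 6
  pk <- detect_peaks(y, seq(0, 4000, by = 100), threshold = 5,
                     min_separation_nm = 250)
  expect_length(pk$position_nm, 1)
  expect_equal(pk$height_afu, 8)

  # recall 10/10 against generator truth at high SNR
  p <- sim_profile_pair(n_puncta = 10, length_nm = 30000, noise_sd = 2,
                        punctum_amp_range = c(80, 150), seed = 6)
  thr <- estimate_threshold(p$ch1, p$position_nm)
  pk <- detect_peaks(p$ch1, p$position_nm, thr)
  truth <- p$ground_truth$ch1_centers_nm
  hits <- vapply(truth, function(c0)
    any(abs(pk$position_nm - c0) < 200), TRUE)
  expect_true(all(hits))
})

test_that("nearest-peak distances respect the 800 nm cutoff", {
  mk <- function(pos) structure(list(channel = "x", position_nm = pos,
                                     height_afu = rep(1, length(pos)),
                                     threshold = 0), class = "peak_set")
  nd <- nearest_peak_distances(mk(c(100, 500)), mk(c(100, 500)))
  expect_equal(nd$distances_nm, c(0, 0))

  nd <- nearest_peak_distances(mk(c(100, 2000)), mk(c(400, 2300)))
  expect_equal(nd$distances_nm, c(300, 300))

  # exhaustive nearest-neighbour oracle: ref {0, 2000}, other {100, 950}
  nd <- nearest_peak_distances(mk(c(0, 2000)), mk(c(100, 950)))
  expect_equal(nd$distances_nm, 100)
  expect_equal(nd$n_unmatched, 1)

  # directional by design
  a <- mk(c(0, 400)); b <- mk(200)
  expect_equal(nearest_peak_distances(a, b)$n_matched, 2)
  expect_equal(nearest_peak_distances(b, a)$n_matched, 1)
})

test_that("paired correlation behaves as a Pearson r over retained pixels", {
  pos <- seq(0, 49900, by = 100)
  set.seed(21)
  x <- abs(rnorm(500, 10, 3))
  pr <- line_profile_pair(pos, x, 2 * x + 5)
  expect_equal(as.numeric(paired_correlation(pr, rule = "all")), 1)

  pr <- line_profile_pair(pos, x, max(x) + 1 - x)
  expect_equal(as.numeric(paired_correlation(pr, rule = "all")), -1)

  # null oracle: two independent noise channels
  pr <- line_profile_pair(pos, abs(rnorm(500, 10, 3)),
                          abs(rnorm(500, 10, 3)))
  expect_lt(abs(paired_correlation(pr, rule = "all")), 0.15)

  # swapping channels leaves r unchanged
  p <- sim_profile_pair(seed = 8)
  swapped <- line_profile_pair(p$position_nm, p$ch2, p$ch1)
  expect_equal(as.numeric(paired_correlation(p)),
               as.numeric(paired_correlation(swapped)))

  expect_error(paired_correlation(
    line_profile_pair(pos, rep(1, 500), rep(2, 500)), rule = "all"),
    "variance")
})

test_that("shuffled correlations count pairs and collapse when degenerate", {
  p <- sim_profile_pair(seed = 9)
  dup <- lapply(1:3, function(i)
    line_profile_pair(p$position_nm, p$ch1, p$ch2,
                      animal_id = paste0("a", i)))
  sc <- shuffled_correlation(dup)
  expect_length(sc$r, 6)  # all ordered mismatched pairs of 3 animals
  expect_equal(unname(sc$r),
               rep(as.numeric(paired_correlation(p, rule = "either")), 6),
               tolerance = 1e-9)

  pairs <- lapply(1:10, function(i)
    sim_profile_pair(seed = 100 + i, animal_id = paste0("a", i)))
  sc <- shuffled_correlation(pairs)
  expect_length(sc$r, 90)
  expect_lt(abs(sc$mean_r), 0.1)  # chance-level overlap

  expect_error(shuffled_correlation(pairs[1]), ">= 2 animals")
})

test_that("per-animal summaries recover generator offsets", {
  res1 <- analyze_coloc(sim_profile_pair(seed = 1))
  s1 <- summarize_coloc(list(res1))
  expect_true(is.na(s1$sem[1]))  # single animal: SEM undefined

  # offset recovery: mean distance within pixel size of truth
  for (off in c(0, 100, 300)) {
    res <- lapply(1:6, function(i)
      analyze_coloc(sim_profile_pair(offset_mean_nm = off,
                                     offset_sd_nm = 0, noise_sd = 1,
                                     seed = 200 + i,
                                     animal_id = paste0("a", i))))
    s <- summarize_coloc(res)
    d <- s$mean[s$measure == "mean_distance_nm"]
    expect_lt(abs(d - off), 100 + 1e-9)
  }

  # offset with spread: recovery within 3 SEM over 12 animals
  res <- lapply(1:12, function(i)
    analyze_coloc(sim_profile_pair(offset_mean_nm = 300, offset_sd_nm = 50,
                                   noise_sd = 1, seed = 300 + i,
                                   animal_id = paste0("a", i))))
  s <- summarize_coloc(res)
  d <- s[s$measure == "mean_distance_nm", ]
  expect_lt(abs(d$mean - 300), 3 * d$sem + 100)
})
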