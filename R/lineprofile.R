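#' Construct a dual-channel line profile
#'
#' Fluorescence intensities of two channels sampled on a shared,
#' uniform position grid along a scan line (positions in nm, zero at
#' the first sample; intensities in arbitrary fluorescence units).
#'
#' @param position_nm strictly increasing uniform position grid (nm).
#' @param ch1,ch2 intensity vectors (AFU, `>= 0`), same length as
#'   `position_nm`.
#' @param animal_id animal label (the unit of replication downstream).
#' @param ground_truth optional generator ground truth.
#' @return An object of class `line_profile_pair`.
#' @export
line_profile_pair <- function(position_nm, ch1, ch2, animal_id = "a1",
                              ground_truth = NULL) {
  n <- length(position_nm)
  .assert(length(ch1) == n && length(ch2) == n,
          "positions and channels must have equal length")
  .assert(n >= 2, "need at least 2 samples")
  dp <- diff(position_nm)
  .assert(all(dp > 0) && max(abs(dp - dp[1])) < 1e-6 * dp[1],
          "positions must be strictly increasing and uniform")
  .assert(all(ch1 >= 0) && all(ch2 >= 0), "intensities must be non-negative")
  structure(list(animal_id = animal_id,
                 position_nm = as.numeric(position_nm),
                 ch1 = as.numeric(ch1), ch2 = as.numeric(ch2),
                 pixel_nm = dp[1], ground_truth = ground_truth),
            class = "line_profile_pair")
}

#' @export
print.line_profile_pair <- function(x, ...) {
  cat(sprintf("line_profile_pair '%s': %d px at %g nm (%.3g um)\n",
              x$animal_id, length(x$position_nm), x$pixel_nm,
              diff(range(x$position_nm)) / 1000))
  invisible(x)
}

#' Read / write line profiles as CSV
#'
#' Columns: `position_nm`, `ch1_afu`, `ch2_afu`, `animal_id`. A file
#' may hold several animals; `read_profile_csv` returns a list of
#' [line_profile_pair()] objects, one per animal.
#'
#' @param pairs a [line_profile_pair()] or list of them.
#' @param path CSV file path.
#' @export
write_profile_csv <- function(pairs, path) {
  if (inherits(pairs, "line_profile_pair")) pairs <- list(pairs)
  df <- do.call(rbind, lapply(pairs, function(p)
    data.frame(position_nm = p$position_nm, ch1_afu = p$ch1,
               ch2_afu = p$ch2, animal_id = p$animal_id)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .assert(all(c("position_nm", "ch1_afu", "ch2_afu", "animal_id")
              %in% names(df)), "missing line-profile columns")
  lapply(split(df, df$animal_id), function(d)
    line_profile_pair(d$position_nm, d$ch1_afu, d$ch2_afu,
                      animal_id = d$animal_id[1]))
}

# bilinear interpolation of a matrix at fractional (row, col)
.bilinear <- function(img, r, c) {
  r0 <- floor(r); c0 <- floor(c)
  r0 <- pmin(pmax(r0, 1), nrow(img) - 1L)
  c0 <- pmin(pmax(c0, 1), ncol(img) - 1L)
  fr <- r - r0; fc <- c - c0
  img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    img[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    img[cbind(r0 + 1, c0 + 1)] * fr * fc
}

#' Extract an averaged line profile from a two-channel raster
#'
#' Samples the image along a polyline at one-pixel steps and averages
#' `width_pixels` samples perpendicular to the local line direction per
#' position, per channel — the line-scan quantification used for
#' nerve-cord staining.
#'
#' @param ch1,ch2 numeric matrices (rows = y, cols = x), equal size.
#' @param polyline two-column matrix of (x, y) vertices in pixel
#'   coordinates (1-based).
#' @param width_pixels perpendicular averaging width; even, `>= 2`
#'   (six or eight in the original protocol).
#' @param pixel_nm physical pixel size (nm), used for the output grid.
#' @param animal_id label for the resulting profile.
#' @return A [line_profile_pair()]; positions are nm along the polyline
#'   from its first vertex.
#' @export
extract_line_profile <- function(ch1, ch2, polyline, width_pixels = 6,
                                 pixel_nm = 100, animal_id = "a1") {
  .assert(is.matrix(ch1) && is.matrix(ch2) && all(dim(ch1) == dim(ch2)),
          "channels must be equal-size matrices")
  .assert(width_pixels >= 2 && width_pixels %% 2 == 0,
          "width_pixels must be even and >= 2")
  polyline <- as.matrix(polyline)
  .assert(ncol(polyline) == 2 && nrow(polyline) >= 2,
          "polyline needs >= 2 (x, y) vertices")
  for (v in seq_len(nrow(polyline))) {
    x <- polyline[v, 1]; y <- polyline[v, 2]
    .assert(x >= 1 && x <= ncol(ch1) && y >= 1 && y <= nrow(ch1),
            "polyline vertex %d (x=%g, y=%g) lies outside the raster",
            v, x, y)
  }

  # arc-length parameterize at one-pixel steps
  seglen <- sqrt(rowSums(diff(polyline)^2))
  total <- sum(seglen)
  s_grid <- seq(0, total, by = 1)
  cum <- c(0, cumsum(seglen))
  pts <- matrix(0, length(s_grid), 2)
  dirs <- matrix(0, length(s_grid), 2)
  for (k in seq_along(s_grid)) {
    seg <- max(1L, findInterval(s_grid[k], cum, rightmost.closed = TRUE))
    seg <- min(seg, nrow(polyline) - 1L)
    f <- (s_grid[k] - cum[seg]) / seglen[seg]
    pts[k, ] <- polyline[seg, ] + f * (polyline[seg + 1, ] - polyline[seg, ])
    dirs[k, ] <- (polyline[seg + 1, ] - polyline[seg, ]) / seglen[seg]
  }
  normal <- cbind(-dirs[, 2], dirs[, 1])
  # width_pixels symmetric offsets straddling the line at half-pixel steps
  offs <- seq(-(width_pixels - 1) / 2, (width_pixels - 1) / 2, by = 1)

  avg_channel <- function(img) {
    out <- numeric(length(s_grid))
    for (k in seq_along(s_grid)) {
      xs <- pts[k, 1] + offs * normal[k, 1]
      ys <- pts[k, 2] + offs * normal[k, 2]
      out[k] <- mean(.bilinear(img, ys, xs))
    }
    out
  }
  line_profile_pair(position_nm = s_grid * pixel_nm,
                    ch1 = pmax(avg_channel(ch1), 0),
                    ch2 = pmax(avg_channel(ch2), 0),
                    animal_id = animal_id)
}

#' Read a two-channel TIFF as matrices
#'
#' Thin wrapper for feeding microscope exports to
#' [extract_line_profile()]; requires the `tiff` package.
#'
#' @param path TIFF file with at least two channels/planes.
#' @return list with matrices `ch1`, `ch2`.
#' @export
read_two_channel_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to read TIFF files", call. = FALSE)
  img <- tiff::readTIFF(path, all = TRUE)
  if (is.list(img) && length(img) >= 2)
    return(list(ch1 = as.matrix(img[[1]]), ch2 = as.matrix(img[[2]])))
  a <- if (is.list(img)) img[[1]] else img
  .assert(length(dim(a)) == 3 && dim(a)[3] >= 2,
          "TIFF must contain two channels or planes")
  list(ch1 = a[, , 1], ch2 = a[, , 2])
}

#' Detection threshold: lowest non-zero value + 3.5 x local SD
#'
#' Finds the lowest non-zero intensity of the trace, computes the SD of
#' the trace within a window (default 600 nm) centered on that
#' position (clipped at the profile ends, zero-valued pixels included),
#' and returns `lowest_nonzero + sd_multiplier * SD`. SD is the sample
#' standard deviation (n - 1).
#'
#' @param intensity one channel's intensities (AFU).
#' @param position_nm matching position grid (nm).
#' @param sd_multiplier multiplier on the local SD; default 3.5.
#' @param window_nm full window width centered on the floor pixel (nm).
#' @return threshold (AFU), with attributes `floor`, `sd`,
#'   `floor_position_nm`.
#' @examples
#' estimate_threshold(c(0, 2, 2, 2, 2, 2, 2, 10, 30, 10, 2),
#'                    seq(0, 1000, by = 100))
#' @export
estimate_threshold <- function(intensity, position_nm,
                               sd_multiplier = 3.5, window_nm = 600) {
  .assert(length(intensity) == length(position_nm), "length mismatch")
  nz <- which(intensity > 0)
  .assert(length(nz) > 0, "no non-zero floor: trace is identically zero")
  i_floor <- nz[which.min(intensity[nz])]
  in_win <- abs(position_nm - position_nm[i_floor]) <= window_nm / 2
  .assert(sum(in_win) >= 3, "fewer than 3 samples in the SD window")
  s <- stats::sd(intensity[in_win])
  thr <- intensity[i_floor] + sd_multiplier * s
  structure(thr, floor = intensity[i_floor], sd = s,
            floor_position_nm = position_nm[i_floor])
}

#' Call fluorescence peaks above a threshold
#'
#' Local maxima strictly above `threshold` are reported as punctum
#' centers. Plateaus (runs of equal values) report their centroid
#' position. Maxima closer than `min_separation_nm` are merged, keeping
#' the higher.
#'
#' @param intensity one channel's intensities (AFU).
#' @param position_nm matching position grid (nm).
#' @param threshold AFU threshold, typically from
#'   [estimate_threshold()]; a manual override is allowed (and should
#'   be recorded by the caller).
#' @param min_separation_nm merge radius for nearby maxima (nm).
#' @param channel label stored in the result.
#' @return A `peak_set`: list with `channel`, `position_nm`,
#'   `height_afu`, `threshold`. May be empty.
#' @export
detect_peaks <- function(intensity, position_nm, threshold,
                         min_separation_nm = 200, channel = "ch1") {
  .assert(length(intensity) == length(position_nm), "length mismatch")
  n <- length(intensity)
  pos <- numeric(0); hts <- numeric(0)
  i <- 2L
  while (i <= n - 1L) {
    if (intensity[i] > threshold && intensity[i] > intensity[i - 1L]) {
      j <- i
      while (j < n && intensity[j + 1L] == intensity[i]) j <- j + 1L
      if (j == n || intensity[j + 1L] < intensity[i]) {
        pos <- c(pos, mean(position_nm[i:j]))  # plateau centroid
        hts <- c(hts, intensity[i])
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  # merge peaks closer than min_separation_nm, keeping the higher
  if (length(pos) > 1) {
    keep <- rep(TRUE, length(pos))
    ord <- order(hts, decreasing = TRUE)
    for (k in ord) {
      if (!keep[k]) next
      close <- which(keep & abs(pos - pos[k]) < min_separation_nm)
      close <- setdiff(close, k)
      keep[close[hts[close] <= hts[k]]] <- FALSE
    }
    pos <- pos[keep]; hts <- hts[keep]
  }
  ord <- order(pos)
  structure(list(channel = channel, position_nm = pos[ord],
                 height_afu = hts[ord], threshold = as.numeric(threshold)),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set [%s]: %d peaks above %.3g AFU\n",
              x$channel, length(x$position_nm), x$threshold))
  invisible(x)
}

#' Nearest-peak distances between two channels
#'
#' For each reference peak, the absolute distance along the scan line
#' to the nearest peak of the other channel. Pairs farther than
#' `max_nm` (default 800 nm) are recorded as unmatched and excluded
#' from the distance list. The operation is directional (ref vs other).
#'
#' @param ref,other [detect_peaks()] results from the same profile.
#' @param max_nm matching cutoff (nm).
#' @return list with `distances_nm` (matched only), `matched` (logical
#'   per ref peak), `n_matched`, `n_unmatched`, `mean_distance_nm`.
#' @export
nearest_peak_distances <- function(ref, other, max_nm = 800) {
  rp <- ref$position_nm; op <- other$position_nm
  if (!length(rp))
    return(list(distances_nm = numeric(0), matched = logical(0),
                n_matched = 0L, n_unmatched = 0L,
                mean_distance_nm = NA_real_))
  d <- if (length(op)) vapply(rp, function(p) min(abs(p - op)), 0)
       else rep(Inf, length(rp))
  matched <- d <= max_nm
  list(distances_nm = d[matched], matched = matched,
       n_matched = sum(matched), n_unmatched = sum(!matched),
       mean_distance_nm = if (any(matched)) mean(d[matched]) else NA_real_)
}

# pixels retained for correlation under the stated rule
.retained <- function(ch1, ch2, thr1, thr2,
                      rule = c("either", "both", "all")) {
  rule <- match.arg(rule)
  switch(rule,
         either = ch1 > thr1 | ch2 > thr2,
         both   = ch1 > thr1 & ch2 > thr2,
         all    = rep(TRUE, length(ch1)))
}

#' Paired pixel-by-pixel intensity correlation
#'
#' Pearson correlation of the two channels over retained pixels. By
#' default a pixel is retained when at least one channel exceeds its
#' threshold (`rule = "either"`); `"both"` and `"all"` are available.
#'
#' @param pair a [line_profile_pair()].
#' @param thr1,thr2 per-channel thresholds (AFU); default 0 retains
#'   every above-zero pixel under `"either"`.
#' @param rule pixel retention rule: `"either"`, `"both"` or `"all"`.
#' @return Pearson r, with attribute `n_pixels`.
#' @export
paired_correlation <- function(pair, thr1 = 0, thr2 = 0,
                               rule = c("either", "both", "all")) {
  keep <- .retained(pair$ch1, pair$ch2, thr1, thr2, match.arg(rule))
  x <- pair$ch1[keep]; y <- pair$ch2[keep]
  .assert(length(x) >= 3, "fewer than 3 retained pixels")
  .assert(stats::sd(x) > 0 && stats::sd(y) > 0,
          "zero variance in a retained channel")
  structure(stats::cor(x, y), n_pixels = length(x))
}

#' Between-animal shuffled correlations (colocalization null)
#'
#' Correlates channel 1 of one animal against channel 2 of a different
#' animal: the chance level of pixel overlap. The default scheme uses
#' all ordered mismatched pairs with profiles truncated to the shorter
#' length; `scheme = "random"` draws `n_random` mismatched pairs.
#'
#' @param pairs list of [line_profile_pair()] across `>= 2` animals.
#' @param scheme `"all"` (every ordered mismatched pair) or `"random"`.
#' @param n_random number of random pairs when `scheme = "random"`.
#' @param seed seed for the random scheme.
#' @inheritParams paired_correlation
#' @return list with `r` (vector of correlations), `mean_r`, and the
#'   pair index table `pairs_used`.
#' @export
shuffled_correlation <- function(pairs, scheme = c("all", "random"),
                                 n_random = 100, seed = 1,
                                 thr1 = 0, thr2 = 0,
                                 rule = c("either", "both", "all")) {
  scheme <- match.arg(scheme); rule <- match.arg(rule)
  .assert(length(pairs) >= 2, "shuffled correlation needs >= 2 animals")
  idx <- expand.grid(i = seq_along(pairs), j = seq_along(pairs))
  idx <- idx[idx$i != idx$j, , drop = FALSE]
  if (scheme == "random") {
    set.seed(seed)
    idx <- idx[sample(nrow(idx), min(n_random, nrow(idx))), , drop = FALSE]
  }
  rs <- mapply(function(i, j) {
    n <- min(length(pairs[[i]]$ch1), length(pairs[[j]]$ch2))
    x <- pairs[[i]]$ch1[seq_len(n)]; y <- pairs[[j]]$ch2[seq_len(n)]
    keep <- .retained(x, y, thr1, thr2, rule)
    if (sum(keep) < 3 || stats::sd(x[keep]) == 0 || stats::sd(y[keep]) == 0)
      return(NA_real_)
    stats::cor(x[keep], y[keep])
  }, idx$i, idx$j)
  list(r = as.numeric(rs), mean_r = mean(rs, na.rm = TRUE),
       pairs_used = idx)
}

#' Full colocalization analysis of one animal's profile
#'
#' Thresholds both channels, calls peaks, computes nearest-peak
#' distances (ref = channel 1) and the paired pixel correlation.
#'
#' @param pair a [line_profile_pair()].
#' @param sd_multiplier,window_nm threshold parameters, see
#'   [estimate_threshold()].
#' @param max_nm nearest-peak cutoff (nm).
#' @param min_separation_nm peak merge radius (nm).
#' @param thr1,thr2 manual threshold overrides (AFU); `NULL` uses the
#'   automatic rule. Overrides are recorded in the result.
#' @param rule correlation pixel-retention rule.
#' @return A `coloc_result`: paired r, peak sets, distances, and the
#'   thresholds used.
#' @export
analyze_coloc <- function(pair, sd_multiplier = 3.5, window_nm = 600,
                          max_nm = 800, min_separation_nm = 200,
                          thr1 = NULL, thr2 = NULL,
                          rule = c("either", "both", "all")) {
  rule <- match.arg(rule)
  manual <- c(!is.null(thr1), !is.null(thr2))
  if (is.null(thr1))
    thr1 <- estimate_threshold(pair$ch1, pair$position_nm,
                               sd_multiplier, window_nm)
  if (is.null(thr2))
    thr2 <- estimate_threshold(pair$ch2, pair$position_nm,
                               sd_multiplier, window_nm)
  p1 <- detect_peaks(pair$ch1, pair$position_nm, thr1,
                     min_separation_nm, channel = "ch1")
  p2 <- detect_peaks(pair$ch2, pair$position_nm, thr2,
                     min_separation_nm, channel = "ch2")
  nd <- nearest_peak_distances(p1, p2, max_nm)
  r <- tryCatch(paired_correlation(pair, as.numeric(thr1),
                                   as.numeric(thr2), rule),
                error = function(e) NA_real_)
  structure(list(animal_id = pair$animal_id,
                 paired_r = as.numeric(r),
                 peaks_ch1 = p1, peaks_ch2 = p2,
                 distances_nm = nd$distances_nm,
                 mean_distance_nm = nd$mean_distance_nm,
                 n_matched = nd$n_matched, n_unmatched = nd$n_unmatched,
                 threshold_ch1 = as.numeric(thr1),
                 threshold_ch2 = as.numeric(thr2),
                 manual_override = manual, rule = rule),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf(paste0("coloc_result '%s': paired r = %.3f; %d/%d ref peaks",
                     " matched, mean distance %.0f nm\n"),
              x$animal_id, x$paired_r, x$n_matched,
              x$n_matched + x$n_unmatched, x$mean_distance_nm))
  invisible(x)
}

#' Group summary of per-animal colocalization results
#'
#' The animal is the unit of replication: returns mean +/- SEM and n of
#' the paired correlation and of the per-animal mean peak distance.
#'
#' @param results list of [analyze_coloc()] results.
#' @return data frame with rows `paired_r` and `mean_distance_nm`.
#' @export
summarize_coloc <- function(results) {
  .assert(length(results) >= 1, "need at least one animal")
  r <- .mean_sem(vapply(results, function(x) x$paired_r, 0))
  d <- .mean_sem(vapply(results, function(x) x$mean_distance_nm, 0))
  data.frame(measure = c("paired_r", "mean_distance_nm"),
             mean = c(r$mean, d$mean), sem = c(r$sem, d$sem),
             n = c(r$n, d$n))
}
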