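# Docked-vesicle spatial statistics from serial-section EM.
# Distances (nm) run from the dense-projection edge along the membrane;
# rows with distance_nm = NA are vesicle-free profiles kept so the
# per-profile normalization uses the full profile census.

.em_check <- function(dataset) {
  .assert(all(c("synapse_id", "profile_id", "distance_nm")
              %in% names(dataset)), "missing EM dataset columns")
  d <- dataset$distance_nm
  .assert(all(is.na(d) | d >= 0), "distances must be non-negative")
}

#' Docked-vesicle distance histogram
#'
#' Sorts vesicle distances into half-open bins `[k*bin, (k+1)*bin)`
#' (default 33 nm, one serial-section thickness) and divides each bin
#' count by the total number of profiles, yielding vesicles per
#' profile per bin; the histogram is then integrated and normalized
#' into a cumulative fraction.
#'
#' @param dataset an `em_dataset` data frame (see [sim_em_dataset()] /
#'   [read_em_csv()]); include only profiles containing a dense
#'   projection.
#' @param bin_nm bin width (nm).
#' @param max_nm histogram extent (nm); defaults to cover the data.
#' @return A `docked_histogram`: data frame with `bin_lo_nm`,
#'   `bin_hi_nm`, `vesicles_per_profile`, `cumulative_fraction`
#'   (all-NA cumulative, flagged via attribute `empty`, when the
#'   dataset holds no vesicles), plus attributes `n_profiles`,
#'   `n_vesicles`.
#' @export
build_histogram <- function(dataset, bin_nm = 33, max_nm = NULL) {
  .em_check(dataset)
  n_prof <- length(unique(dataset$profile_id))
  .assert(n_prof > 0, "zero profiles")
  d <- dataset$distance_nm[!is.na(dataset$distance_nm)]
  if (is.null(max_nm))
    max_nm <- if (length(d)) (floor(max(d) / bin_nm) + 1) * bin_nm else bin_nm
  edges <- seq(0, max_nm, by = bin_nm)
  counts <- vapply(seq_len(length(edges) - 1L), function(k)
    sum(d >= edges[k] & d < edges[k + 1L]), 0L)
  per_prof <- counts / n_prof
  empty <- length(d) == 0
  cum <- if (empty) rep(NA_real_, length(counts)) else cumsum(counts) / sum(counts)
  out <- data.frame(bin_lo_nm = edges[-length(edges)],
                    bin_hi_nm = edges[-1],
                    vesicles_per_profile = per_prof,
                    cumulative_fraction = cum)
  attr(out, "counts") <- counts
  attr(out, "n_profiles") <- n_prof
  attr(out, "n_vesicles") <- length(d)
  attr(out, "empty") <- empty
  class(out) <- c("docked_histogram", "data.frame")
  out
}

#' Per-synapse region summary of docked vesicles
#'
#' For each synapse (a contiguous set of serial profiles containing a
#' dense projection — the unit of replication), the vesicle count in
#' each membrane region is divided by the synapse's profile count.
#' Regions follow the half-open convention: `<165` is `[0, 165)`,
#' `<231` is `[0, 231)`, `232-330` is `[231, 330)` and `>330` is
#' `[330, Inf)`, so the middle and outer regions tile the membrane
#' without a gap.
#'
#' @param dataset an `em_dataset` data frame.
#' @param region_edges_nm inner edges separating the tiling regions;
#'   default `c(165, 231, 330)`.
#' @return A list with `per_synapse` (data frame: one row per synapse
#'   with vesicles-per-profile in each region and in total) and
#'   `summary` (mean +/- SEM over synapses per region).
#' @export
region_summary <- function(dataset, region_edges_nm = c(165, 231, 330)) {
  .em_check(dataset)
  syn <- split(dataset, dataset$synapse_id)
  .assert(length(syn) >= 1, "need at least one synapse")
  e <- region_edges_nm
  rows <- lapply(syn, function(g) {
    n_prof <- length(unique(g$profile_id))
    .assert(n_prof > 0, "synapse with zero profiles")
    d <- g$distance_nm[!is.na(g$distance_nm)]
    lt231 <- sum(d < e[2]) / n_prof
    mid <- sum(d >= e[2] & d < e[3]) / n_prof
    gt <- sum(d >= e[3]) / n_prof
    data.frame(synapse_id = g$synapse_id[1],
               n_profiles = n_prof,
               lt165 = sum(d < e[1]) / n_prof,
               lt231 = lt231,
               mid_231_330 = mid,
               gt330 = gt,
               # the regions tile the membrane, so their sum is the total
               total = lt231 + mid + gt)
  })
  per_syn <- do.call(rbind, rows)
  rownames(per_syn) <- NULL
  cols <- c("lt165", "lt231", "mid_231_330", "gt330", "total")
  summ <- do.call(rbind, lapply(cols, function(cn) {
    ms <- .mean_sem(per_syn[[cn]])
    data.frame(region = cn, mean = ms$mean, sem = ms$sem, n = ms$n)
  }))
  list(per_synapse = per_syn, summary = summ)
}

#' Per-profile vesicle totals
#'
#' Average docked-vesicle count per single profile (profile as the
#' unit of replication), with SEM.
#'
#' @param dataset an `em_dataset` data frame.
#' @return list with `per_profile` (named counts) and `mean`, `sem`,
#'   `n` (SEM is NA for a single profile).
#' @export
em_totals <- function(dataset) {
  .em_check(dataset)
  .assert(nrow(dataset) > 0, "empty dataset")
  counts <- vapply(split(dataset, dataset$profile_id), function(g)
    sum(!is.na(g$distance_nm)), 0)
  ms <- .mean_sem(counts)
  list(per_profile = counts, mean = ms$mean, sem = ms$sem, n = ms$n)
}
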