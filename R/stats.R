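#' Mean, SEM and n of one group
#'
#' SEM is the sample SD divided by sqrt(n); for a single measurement
#' the SEM is undefined and returned as NA.
#'
#' @param x numeric measurements (one value per replicate — animal or
#'   synapse depending on the stage).
#' @return list with `mean`, `sem`, `n`.
#' @examples
#' describe_group(c(2, 4, 6))  # mean 4, SEM 2/sqrt(3)
#' @export
describe_group <- function(x) {
  .assert(length(x) >= 1, "empty group")
  .mean_sem(x)
}

#' Two-tailed Student's t test
#'
#' Classic pooled-variance Student's t by default (`welch = FALSE`),
#' with paired and Welch variants available.
#'
#' @param a,b numeric measurement vectors.
#' @param paired paired test on difference scores (equal lengths).
#' @param welch use the Welch (unequal-variance) statistic.
#' @return list with `test`, `statistic` (t), `df`, `p_value`.
#' @export
group_t_test <- function(a, b, paired = FALSE, welch = FALSE) {
  if (paired) .assert(length(a) == length(b) && length(a) >= 2,
                      "paired test needs equal lengths >= 2")
  else .assert(length(a) >= 2 && length(b) >= 2,
               "each group needs n >= 2")
  .assert(stats::sd(c(a - if (paired) b else 0,
                      if (paired) NULL else b)) > 0,
          "degenerate (zero-variance) data")
  ht <- stats::t.test(a, b, paired = paired,
                      var.equal = !welch && !paired,
                      alternative = "two.sided")
  list(test = if (paired) "paired t" else if (welch) "Welch t"
       else "Student t (pooled)",
       statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' One-way ANOVA with Student-Newman-Keuls post hoc
#'
#' One-way fixed-effects ANOVA followed by the SNK stepwise procedure
#' on the ordered group means: ranges of span p are compared against
#' studentized-range critical values `qtukey(1 - alpha, p, df_error)`
#' (computed numerically, so any group size is supported; unequal n
#' uses the harmonic-mean standard error). A range found
#' non-significant renders all pairs inside it non-significant —
#' decisions are therefore consistent across spans and across alpha
#' levels, and invariant to group input order.
#'
#' @param groups named list of numeric vectors (>= 3 groups, each
#'   n >= 2) — or a data frame with columns `value` and `group`.
#' @param alpha significance levels for the post hoc decisions.
#' @return list with `f_statistic`, `df`, `p_value`, `group_means`,
#'   and `snk` — a data frame of all pairs with the studentized-range
#'   statistic and a logical decision column per alpha level.
#' @examples
#' set.seed(1)
#' g <- list(a = rnorm(10), b = rnorm(10), c = rnorm(10, 5))
#' anova_snk(g)$snk
#' @export
anova_snk <- function(groups, alpha = c(0.05, 0.01, 0.001)) {
  if (is.data.frame(groups))
    groups <- split(groups$value, groups$group)
  .assert(length(groups) >= 3, "SNK requires >= 3 groups")
  .assert(all(vapply(groups, length, 0L) >= 2), "each group needs n >= 2")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))

  df <- data.frame(value = unlist(groups, use.names = FALSE),
                   group = factor(rep(names(groups),
                                      vapply(groups, length, 0L))))
  fit <- stats::aov(value ~ group, data = df)
  an <- stats::anova(fit)
  mse <- an[["Mean Sq"]][2]
  df_err <- an[["Df"]][2]

  means <- vapply(groups, mean, 0)
  ns <- vapply(groups, length, 0L)
  ord <- order(means)
  m <- means[ord]; nn <- ns[ord]; labs <- names(groups)[ord]
  k <- length(m)

  pairs <- list()
  for (a_lv in alpha) {
    # non-significant ranges found so far, as (lo, hi) index pairs
    nonsig <- matrix(numeric(0), ncol = 2)
    dec <- matrix(NA, k, k)
    for (span in k:2) {
      for (i in seq_len(k - span + 1L)) {
        j <- i + span - 1L
        contained <- nrow(nonsig) > 0 &&
          any(nonsig[, 1] <= i & nonsig[, 2] >= j)
        if (contained) { dec[i, j] <- FALSE; next }
        se <- sqrt(mse / 2 * (1 / nn[i] + 1 / nn[j]))
        q <- (m[j] - m[i]) / se
        sig <- q > stats::qtukey(1 - a_lv, span, df_err)
        dec[i, j] <- sig
        if (!sig) nonsig <- rbind(nonsig, c(i, j))
      }
    }
    pairs[[as.character(a_lv)]] <- dec
  }

  idx <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  snk <- data.frame(group1 = labs[idx[, 1]], group2 = labs[idx[, 2]],
                    diff = m[idx[, 2]] - m[idx[, 1]],
                    span = idx[, 2] - idx[, 1] + 1L)
  for (a_lv in alpha)
    snk[[sprintf("sig_%g", a_lv)]] <-
      pairs[[as.character(a_lv)]][idx]

  list(test = "one-way ANOVA + SNK",
       f_statistic = an[["F value"]][1],
       df = c(an[["Df"]][1], df_err),
       p_value = an[["Pr(>F)"]][1],
       group_means = stats::setNames(means, names(groups)),
       mse = mse, snk = snk)
}
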