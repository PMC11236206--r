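#' Global Extinction Risk (GER)
#'
#' Posterior probability that the patch extinction probability exceeds the
#' critical threshold for the dormancy duration, `P(p_ext > p_c(H) | Obs)`,
#' estimated as the fraction of joint posterior draws `(p_ext, H)` with
#' `p_ext > p_c(H)`.  This is algebraically the mixture over `h` of the
#' conditional exceedance probabilities weighted by `P(H = h | Obs)`.
#'
#' @param samples A `boa_posterior` from [fit_posterior()].
#' @param table A `pc_table` covering every sampled `H`.
#' @param segment Segment index or id.
#' @return A probability in \[0, 1\].
#' @export
compute_ger <- function(samples, table, segment = 1L) {
  k <- resolve_segment(samples, segment)
  if (!length(samples$H)) stop("empty posterior sample")
  mean(samples$p_ext[, k] > pc_lookup(table, samples$H))
}

#' Lowest non-rejected dormancy duration (H_inf)
#'
#' The smallest dormancy duration not rejected by a test at level `alpha`
#' under the posterior of `H`: the smallest `h` with
#' `P(H <= h | Obs) >= alpha`.
#'
#' @param samples A `boa_posterior`.
#' @param alpha Significance level (default 0.05).
#' @return An integer in `0:H_max` (always defined: `h = H_max` satisfies
#'   the condition).
#' @export
compute_h_inf <- function(samples, alpha = 0.05) {
  if (!length(samples$H)) stop("empty posterior sample")
  cum <- cumsum(tabulate(samples$H + 1L, nbins = samples$H_max + 1L)) /
    length(samples$H)
  as.integer(which(cum >= alpha)[1] - 1L)
}

#' Maximal Global Extinction Risk (MaxGER)
#'
#' Conditional exceedance probability at the lowest plausible dormancy
#' duration: `P(p_ext > p_c(H_inf) | H = H_inf, Obs)`.  Unlike the GER it
#' does not average over dormancy durations the data cannot distinguish,
#' so it does not dilute the risk when medium and long dormancy durations
#' receive similar posterior mass.  If fewer than `floor` draws satisfy
#' `H = H_inf`, the estimate falls back to conditioning on `H <= H_inf`
#' and the result is flagged, so that a conditional probability is never
#' silently reported from a handful of draws.
#'
#' @param samples A `boa_posterior`.
#' @param table A `pc_table`.
#' @param segment Segment index or id.
#' @param alpha Significance level defining `H_inf`.
#' @param floor Minimum number of conditioning draws before falling back.
#' @return A probability with attributes `n_cond` (conditioning draw
#'   count) and `fallback` (logical).
#' @export
compute_maxger <- function(samples, table, segment = 1L, alpha = 0.05,
                           floor = 50L) {
  k <- resolve_segment(samples, segment)
  h_inf <- compute_h_inf(samples, alpha)
  sel <- samples$H == h_inf
  fallback <- FALSE
  if (sum(sel) < floor) {
    sel <- samples$H <= h_inf
    fallback <- TRUE
  }
  if (!sum(sel)) stop("no posterior draws to condition on")
  val <- mean(samples$p_ext[sel, k] > pc_lookup(table, h_inf))
  structure(val, n_cond = sum(sel), fallback = fallback, h_inf = h_inf)
}

#' Local Extinction Risk (LER)
#'
#' Posterior mean of the patch extinction probability of a street portion.
#'
#' @param samples A `boa_posterior`.
#' @param segment Segment index or id.
#' @return A probability in \[0, 1\].
#' @export
compute_ler <- function(samples, segment = 1L) {
  k <- resolve_segment(samples, segment)
  if (!length(samples$H)) stop("empty posterior sample")
  mean(samples$p_ext[, k])
}

#' Standardised Mean Difference between two posteriors
#'
#' `|mean1 - mean2| / sqrt((sd1^2 + sd2^2) / 2)`: the absolute difference
#' of the posterior means of `p_ext` in two street portions in units of
#' their pooled posterior standard deviation.
#'
#' @param mean1,sd1 Posterior mean and standard deviation for portion 1.
#' @param mean2,sd2 Same for portion 2.
#' @return A non-negative number; 0 when both means are equal, `Inf` when
#'   both standard deviations are 0 and the means differ.
#' @export
compute_smd <- function(mean1, sd1, mean2, sd2) {
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be non-negative")
  num <- abs(mean1 - mean2)
  den <- sqrt((sd1^2 + sd2^2) / 2)
  if (den == 0) {
    if (num == 0) return(0)
    warning("zero pooled standard deviation with different means")
    return(Inf)
  }
  num / den
}

#' Pairwise SMD between the portions of a posterior summary
#'
#' @param summary A `boa_posterior_summary` from [summary.boa_posterior()].
#' @return A symmetric matrix of SMD values (zero diagonal).
#' @export
smd_matrix <- function(summary) {
  sg <- summary$segments
  K <- nrow(sg)
  out <- matrix(0, K, K, dimnames = list(sg$segment, sg$segment))
  for (i in seq_len(K)) for (j in seq_len(K))
    if (i != j)
      out[i, j] <- compute_smd(sg$p_ext_mean[i], sg$p_ext_sd[i],
                               sg$p_ext_mean[j], sg$p_ext_sd[j])
  out
}

#' Extinction-risk report for every street portion
#'
#' Computes the GER, MaxGER (with its conditioning dormancy duration
#' `H_inf`) and LER for each segment of a posterior sample.
#'
#' @param samples A `boa_posterior`.
#' @param table A `pc_table`.
#' @param alpha Significance level for `H_inf`.
#' @param floor MaxGER conditioning-draw floor (see [compute_maxger()]).
#' @return A data frame of class `risk_report` with columns `species`,
#'   `segment`, `GER`, `MaxGER`, `H_inf`, `LER`, `n_cond`,
#'   `maxger_fallback`.
#' @export
risk_report <- function(samples, table, alpha = 0.05, floor = 50L) {
  K <- ncol(samples$p_ext)
  rows <- lapply(seq_len(K), function(k) {
    mg <- compute_maxger(samples, table, k, alpha, floor)
    data.frame(
      species = samples$species,
      segment = samples$segment_ids[k],
      GER = compute_ger(samples, table, k),
      MaxGER = as.numeric(mg),
      H_inf = attr(mg, "h_inf"),
      LER = compute_ler(samples, k),
      n_cond = attr(mg, "n_cond"),
      maxger_fallback = attr(mg, "fallback")
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("risk_report", "data.frame")
  out
}

# Map a segment id or index to a column of the draw matrices.
resolve_segment <- function(samples, segment) {
  if (is.character(segment)) {
    k <- match(segment, samples$segment_ids)
    if (is.na(k)) stop("unknown segment id: ", segment)
    return(k)
  }
  k <- as.integer(segment)
  if (k < 1L || k > ncol(samples$p_ext)) stop("segment index out of range")
  k
}
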