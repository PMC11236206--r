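#' Emission log-probability of one observation
#'
#' Probability of observing plants (1) or no plants (0) in a patch given
#' its hidden seed-bank entry at the start of the generation.  A patch with
#' a viable seed bank germinates plants which survive the extinction step
#' with probability `1 - p_ext`; under the noisy variant every plant-free
#' patch then shows plants with probability `epsilon` (noise plants behave
#' like real plants, so a viable patch is observed occupied with
#' probability `(1 - p_ext) + p_ext * epsilon`).
#'
#' @param state_entry Hidden entry: 0 for an empty seed bank, otherwise the
#'   cohort age (must not exceed `H + 1`).  Vectorised.
#' @param observed Observed value, 0 or 1 (vectorised, recycled).
#' @param params A [boa_params()] object.
#' @return Log-probability (vectorised over entries).
#' @export
emission_logprob <- function(state_entry, observed, params) {
  if (any(state_entry < 0L | state_entry > params$H + 1L))
    stop("state entries must be 0 (empty) or an age in 1:(H+1)")
  if (any(!observed %in% c(0L, 1L))) stop("observations must be 0 or 1")
  p <- params$p_ext; e <- params$epsilon
  viable <- state_entry > 0L
  n <- max(length(state_entry), length(observed))
  viable <- rep_len(viable, n); observed <- rep_len(observed, n)
  out <- numeric(n)
  out[viable & observed == 1L] <- log1p(-p * (1 - e))
  out[viable & observed == 0L] <- log(p) + log1p(-e)
  out[!viable & observed == 1L] <- log(e)
  out[!viable & observed == 0L] <- log1p(-e)
  out
}

#' Exact log-likelihood of one patch's observation row
#'
#' Conditional on the complete observation matrix, each patch's hidden
#' seed-bank age propagates deterministically: it resets to age 1 one
#' generation after the patch or an in-bounds neighbour was observed
#' occupied, and otherwise increments until the cohort loses viability.
#' Only the initial age is latent, so the likelihood of a patch's row is a
#' sum over the `H + 2` initial entries (empty with prior mass `1 - s`,
#' each age in `1:(H+1)` with mass `s / (H + 1)`) of products of emission
#' probabilities.
#'
#' @param patch Patch (row) index.
#' @param obs An [occupancy_matrix()]; rows `patch - 1` to `patch + 1`
#'   (in bounds) must contain no missing entries, as they drive the
#'   deterministic seed-bank propagation.
#' @param params A [boa_params()] object.
#' @return Log-likelihood of the patch's observation row.
#' @export
patch_loglik <- function(patch, obs, params) {
  N <- nrow(obs)
  if (patch < 1L || patch > N) stop("patch index out of range")
  rows <- max(1L, patch - 1L):min(N, patch + 1L)
  sub <- obs[rows, , drop = FALSE]
  if (anyNA(sub))
    stop("missing entries in the rows driving this patch; impute first")
  storage.mode(sub) <- "integer"
  ll <- boa_patch_logliks(sub, params$s, params$p_ext, params$H,
                          params$epsilon)
  ll[match(patch, rows)]
}

# Complete-data log-likelihood of one segment (integer 0/1 matrix, no NA).
segment_loglik <- function(obs, s, p_ext, H, eps) {
  boa_segment_loglik_cpp(obs, s, p_ext, as.integer(H), eps)
}

#' Exact log-likelihood of a metapopulation dataset
#'
#' Total log-likelihood of all street portions of one species under the
#' (noisy) BOA hidden Markov model, with the maximal dormancy duration `H`
#' and noise intensity `epsilon` shared across portions and the initial
#' seed occupancy `s` and patch extinction probability `p_ext` specific to
#' each portion.  Conditional on the full observation matrix the hidden
#' propagation of each patch depends only on its own initial state, so the
#' likelihood factorises exactly over patches.
#'
#' @param dataset A [metapop_dataset()].
#' @param H Shared maximal dormancy duration.
#' @param epsilon Shared noise intensity.
#' @param s,p_ext Numeric vectors, one entry per street portion (scalars
#'   are recycled).
#' @param imputations Optional list (one element per segment) of 0/1
#'   values replacing that segment's missing entries in column-major
#'   order.  Required whenever a segment contains missing entries.
#' @return Total log-likelihood (may be `-Inf` for observation patterns
#'   impossible under the given `H`, e.g. a recolonisation after a year in
#'   which a patch and both neighbours were empty when `H = 0` and
#'   `epsilon = 0`).
#' @export
dataset_loglik <- function(dataset, H, epsilon, s, p_ext,
                           imputations = NULL) {
  K <- length(dataset$segments)
  s <- rep_len(s, K); p_ext <- rep_len(p_ext, K)
  if (!is.null(imputations) && length(imputations) != K)
    stop("imputations must have one element per segment")
  tot <- 0
  for (k in seq_len(K)) {
    m <- dataset$segments[[k]]
    if (anyNA(m)) {
      if (is.null(imputations))
        stop("segment ", k, " has missing entries; supply imputations")
      idx <- which(is.na(m))
      imp <- imputations[[k]]
      if (length(imp) != length(idx))
        stop("imputations for segment ", k, " must cover every missing entry")
      m[idx] <- as.integer(imp)
    }
    mm <- unclass(m)
    attributes(mm) <- list(dim = dim(m))
    storage.mode(mm) <- "integer"
    tot <- tot + segment_loglik(mm, s[k], p_ext[k], H, epsilon)
    if (tot == -Inf) return(-Inf)
  }
  tot
}
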