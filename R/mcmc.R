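#' Configuration for posterior sampling
#'
#' Settings of the Metropolis-within-Gibbs sampler targeting the posterior
#' of the (noisy) BOA process parameters.  Priors are uniform: `s_k` and
#' `p_ext_k` on (0, 1) for each street portion, `H` discrete uniform on
#' `{0, ..., H_max}`, `epsilon` uniform on `(0, epsilon_max)` unless fixed
#' at zero (plain-process inference).
#'
#' @param n_chains Number of independent chains (at least 2 for the split
#'   R-hat convergence diagnostic).
#' @param n_iterations Iterations per chain, including burn-in.
#' @param n_burnin Burn-in iterations discarded per chain; the proposal
#'   scales adapt during burn-in towards a 20-45% acceptance rate.
#' @param H_max Upper bound on the maximal dormancy duration (default 10,
#'   matched to the order of 10 observation years beyond which dormancy
#'   durations are not identifiable).
#' @param epsilon_max Upper bound on the noise intensity (default 0.1).
#' @param epsilon_fixed If `TRUE`, `epsilon` is held at 0 (plain BOA
#'   inference).
#' @param p_ext_fixed Optional known value of `p_ext` shared by all
#'   segments (mainly for validation studies); `NULL` to sample it.
#' @param proposal_scale Initial random-walk standard deviation on the
#'   logit scale for the continuous parameters.
#' @param n_missing_updates Number of missing-entry flip proposals per
#'   sweep (capped at the number of missing entries).
#' @param rhat_threshold Split R-hat above which a convergence warning is
#'   flagged on the output.
#' @param seed Optional integer seed.
#' @return An object of class `boa_config`.
#' @export
inference_config <- function(n_chains = 2L, n_iterations = 1500L,
                             n_burnin = 500L, H_max = 10L,
                             epsilon_max = 0.1, epsilon_fixed = FALSE,
                             p_ext_fixed = NULL, proposal_scale = 0.6,
                             n_missing_updates = 20L,
                             rhat_threshold = 1.05, seed = NULL) {
  stopifnot(n_chains >= 1L, n_iterations > n_burnin, n_burnin >= 0L,
            H_max >= 0L, epsilon_max > 0, epsilon_max <= 1,
            proposal_scale > 0)
  structure(list(
    n_chains = as.integer(n_chains),
    n_iterations = as.integer(n_iterations),
    n_burnin = as.integer(n_burnin),
    H_max = as.integer(H_max),
    epsilon_max = epsilon_max,
    epsilon_fixed = isTRUE(epsilon_fixed),
    p_ext_fixed = p_ext_fixed,
    proposal_scale = proposal_scale,
    n_missing_updates = as.integer(n_missing_updates),
    rhat_threshold = rhat_threshold,
    seed = seed
  ), class = "boa_config")
}

# Split R-hat (Gelman-Rubin with each chain split in two halves).
split_rhat <- function(draws, chain) {
  halves <- list()
  for (cid in unique(chain)) {
    x <- draws[chain == cid]
    n2 <- floor(length(x) / 2)
    if (n2 < 2) return(NA_real_)
    halves <- c(halves, list(x[seq_len(n2)], x[(length(x) - n2 + 1):length(x)]))
  }
  m <- length(halves); n <- length(halves[[1]])
  mns <- vapply(halves, mean, numeric(1))
  vrs <- vapply(halves, var, numeric(1))
  W <- mean(vrs); B <- n * var(mns)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Initial per-segment parameter guesses from the observed data.
init_segment_params <- function(m) {
  first <- which(colSums(!is.na(m)) > 0)[1]
  s0 <- if (is.na(first)) 0.5 else mean(m[, first], na.rm = TRUE)
  num <- 0L; den <- 0L
  if (ncol(m) > 1L) {
    for (t in seq_len(ncol(m) - 1L)) {
      occ <- which(m[, t] == 1L & !is.na(m[, t + 1L]))
      den <- den + length(occ)
      num <- num + sum(m[occ, t + 1L] == 0L)
    }
  }
  p0 <- if (den > 0L) num / den else 0.5
  c(s = min(max(s0, 0.05), 0.95), p = min(max(p0, 0.05), 0.95))
}

#' Sample the posterior of the (noisy) BOA process parameters
#'
#' Metropolis-within-Gibbs sampler for the posterior of the shared maximal
#' dormancy duration `H` and noise intensity `epsilon` and the per-segment
#' initial seed occupancy `s_k` and patch extinction probability
#' `p_ext_k`, given yearly presence/absence records.  Continuous
#' parameters use random-walk proposals on the logit scale with adaptive
#' scaling during burn-in; `H` uses a symmetric uniform proposal on
#' `{0, ..., H_max}`; missing observations are treated as latent 0/1
#' variables updated by single-entry flips accepted on the complete-data
#' likelihood ratio.
#'
#' @param dataset A [metapop_dataset()] (all segments of one species).
#' @param config An [inference_config()].
#' @return An object of class `boa_posterior`: retained draws of `H`,
#'   `epsilon`, `s` and `p_ext` (matrices with one column per segment),
#'   chain/iteration labels, imputed values for the missing entries,
#'   acceptance rates, split R-hat diagnostics and a convergence warning
#'   flag (non-convergence is flagged, never an error).
#' @export
fit_posterior <- function(dataset, config = inference_config()) {
  if (!inherits(dataset, "metapop_dataset")) dataset <- metapop_dataset(dataset)
  if (!is.null(config$seed)) set.seed(config$seed)
  K <- length(dataset$segments)
  segs <- lapply(dataset$segments, function(m) {
    mm <- unclass(m); attributes(mm) <- list(dim = dim(m))
    storage.mode(mm) <- "integer"
    mm
  })
  miss_idx <- lapply(segs, function(m) which(is.na(m)))
  n_miss <- vapply(miss_idx, length, integer(1))
  if (all(vapply(segs, function(m) all(is.na(m)), logical(1))))
    stop("uninformative data: every observation is missing")

  Hmax <- config$H_max
  emax <- config$epsilon_max
  n_keep <- config$n_iterations - config$n_burnin
  tot_keep <- n_keep * config$n_chains

  H_draws <- integer(tot_keep)
  eps_draws <- numeric(tot_keep)
  s_draws <- matrix(0, tot_keep, K)
  p_draws <- matrix(0, tot_keep, K)
  chain_id <- integer(tot_keep)
  iter_id <- integer(tot_keep)
  imp_draws <- if (sum(n_miss) > 0 && sum(n_miss) <= 500)
    matrix(NA_integer_, tot_keep, sum(n_miss)) else NULL
  acc <- c(s = 0, p = 0, H = 0, eps = 0, miss = 0)
  prop <- c(s = 0, p = 0, H = 0, eps = 0, miss = 0)

  seg_ll <- function(cur_obs, k, s, p, H, eps)
    segment_loglik(cur_obs[[k]], s, p, H, eps)

  accept_lr <- function(lr) {
    if (is.na(lr) || lr == -Inf) return(FALSE)
    if (lr == Inf) return(TRUE)
    log(runif(1)) < lr
  }

  row <- 0L
  for (ch in seq_len(config$n_chains)) {
    # --- initialisation -------------------------------------------------
    cur_obs <- segs
    for (k in seq_len(K))
      if (n_miss[k] > 0) cur_obs[[k]][miss_idx[[k]]] <- 0L
    init <- vapply(dataset$segments, init_segment_params, numeric(2))
    s_cur <- pmin(pmax(init["s", ] + runif(K, -0.02, 0.02), 0.02), 0.98)
    p_cur <- init["p", ]
    if (!is.null(config$p_ext_fixed)) p_cur <- rep(config$p_ext_fixed, K)
    eps_cur <- if (config$epsilon_fixed) 0 else min(0.01, emax / 2)
    # start H at the smallest dormancy duration (preferring 1) under which
    # the data have positive likelihood
    ll_for_H <- function(h) sum(vapply(seq_len(K), function(k)
      seg_ll(cur_obs, k, s_cur[k], p_cur[k], h, eps_cur), numeric(1)))
    H_cur <- NA_integer_
    for (h in unique(c(1L, 0L, seq_len(Hmax)))) {
      if (h > Hmax) next
      if (is.finite(ll_for_H(h))) { H_cur <- h; break }
    }
    if (is.na(H_cur))
      stop("data have zero likelihood for every dormancy duration up to H_max")
    ll_cur <- vapply(seq_len(K), function(k)
      seg_ll(cur_obs, k, s_cur[k], p_cur[k], H_cur, eps_cur), numeric(1))

    sc_s <- rep(config$proposal_scale, K)
    sc_p <- rep(config$proposal_scale, K)
    sc_e <- config$proposal_scale
    a_s <- n_s <- rep(0, K); a_p <- n_p <- rep(0, K); a_e <- n_e <- 0

    for (it in seq_len(config$n_iterations)) {
      # continuous per-segment parameters: logit random walk, uniform prior
      for (k in seq_len(K)) {
        th <- qlogis(s_cur[k]) + rnorm(1, 0, sc_s[k])
        s_new <- plogis(th)
        ll_new <- seg_ll(cur_obs, k, s_new, p_cur[k], H_cur, eps_cur)
        lr <- ll_new - ll_cur[k] +
          log(s_new * (1 - s_new)) - log(s_cur[k] * (1 - s_cur[k]))
        n_s[k] <- n_s[k] + 1; prop["s"] <- prop["s"] + 1
        if (accept_lr(lr)) {
          s_cur[k] <- s_new; ll_cur[k] <- ll_new
          a_s[k] <- a_s[k] + 1; acc["s"] <- acc["s"] + 1
        }
        if (is.null(config$p_ext_fixed)) {
          th <- qlogis(p_cur[k]) + rnorm(1, 0, sc_p[k])
          p_new <- plogis(th)
          ll_new <- seg_ll(cur_obs, k, s_cur[k], p_new, H_cur, eps_cur)
          lr <- ll_new - ll_cur[k] +
            log(p_new * (1 - p_new)) - log(p_cur[k] * (1 - p_cur[k]))
          n_p[k] <- n_p[k] + 1; prop["p"] <- prop["p"] + 1
          if (accept_lr(lr)) {
            p_cur[k] <- p_new; ll_cur[k] <- ll_new
            a_p[k] <- a_p[k] + 1; acc["p"] <- acc["p"] + 1
          }
        }
      }
      # shared dormancy duration: symmetric uniform proposal
      H_new <- sample.int(Hmax + 1L, 1L) - 1L
      prop["H"] <- prop["H"] + 1
      if (H_new != H_cur) {
        ll_new <- vapply(seq_len(K), function(k)
          seg_ll(cur_obs, k, s_cur[k], p_cur[k], H_new, eps_cur), numeric(1))
        lr <- sum(ll_new) - sum(ll_cur)
        if (accept_lr(lr)) {
          H_cur <- H_new; ll_cur <- ll_new; acc["H"] <- acc["H"] + 1
        }
      } else acc["H"] <- acc["H"] + 1
      # shared noise intensity on (0, epsilon_max)
      if (!config$epsilon_fixed) {
        u <- eps_cur / emax
        th <- qlogis(u) + rnorm(1, 0, sc_e)
        u_new <- plogis(th)
        eps_new <- u_new * emax
        ll_new <- vapply(seq_len(K), function(k)
          seg_ll(cur_obs, k, s_cur[k], p_cur[k], H_cur, eps_new), numeric(1))
        lr <- sum(ll_new) - sum(ll_cur) +
          log(u_new * (1 - u_new)) - log(u * (1 - u))
        n_e <- n_e + 1; prop["eps"] <- prop["eps"] + 1
        if (accept_lr(lr)) {
          eps_cur <- eps_new; ll_cur <- ll_new
          a_e <- a_e + 1; acc["eps"] <- acc["eps"] + 1
        }
      }
      # missing-observation augmentation: single-entry flips
      if (sum(n_miss) > 0) {
        for (j in seq_len(min(config$n_missing_updates, sum(n_miss)))) {
          k <- sample.int(K, 1L, prob = n_miss / sum(n_miss))
          e <- miss_idx[[k]][sample.int(n_miss[k], 1L)]
          cand <- cur_obs[[k]]
          cand[e] <- 1L - cand[e]
          ll_new <- segment_loglik(cand, s_cur[k], p_cur[k], H_cur, eps_cur)
          lr <- ll_new - ll_cur[k]
          prop["miss"] <- prop["miss"] + 1
          if (accept_lr(lr)) {
            cur_obs[[k]] <- cand; ll_cur[k] <- ll_new
            acc["miss"] <- acc["miss"] + 1
          }
        }
      }
      # adapt proposal scales during burn-in towards ~30% acceptance
      if (it <= config$n_burnin && it %% 50L == 0L) {
        adj <- function(sc, a, n) {
          r <- ifelse(n > 0, a / n, 0.3)
          pmin(pmax(sc * exp(r - 0.3), 0.02), 10)
        }
        sc_s <- adj(sc_s, a_s, n_s); a_s[] <- 0; n_s[] <- 0
        sc_p <- adj(sc_p, a_p, n_p); a_p[] <- 0; n_p[] <- 0
        sc_e <- adj(sc_e, a_e, n_e); a_e <- 0; n_e <- 0
      }
      if (it > config$n_burnin) {
        row <- row + 1L
        H_draws[row] <- H_cur
        eps_draws[row] <- eps_cur
        s_draws[row, ] <- s_cur
        p_draws[row, ] <- p_cur
        chain_id[row] <- ch
        iter_id[row] <- it
        if (!is.null(imp_draws))
          imp_draws[row, ] <- unlist(lapply(seq_len(K), function(k)
            cur_obs[[k]][miss_idx[[k]]]), use.names = FALSE)
      }
    }
  }

  rhat <- c(
    setNames(vapply(seq_len(K), function(k)
      split_rhat(p_draws[, k], chain_id), numeric(1)),
      paste0("p_ext.", names(dataset$segments))),
    epsilon = if (!config$epsilon_fixed) split_rhat(eps_draws, chain_id)
              else NA_real_
  )
  not_converged <- any(rhat > config$rhat_threshold, na.rm = TRUE)

  structure(list(
    H = H_draws, epsilon = eps_draws, s = s_draws, p_ext = p_draws,
    chain = chain_id, iteration = iter_id,
    imputations = imp_draws,
    segment_ids = names(dataset$segments),
    species = dataset$species,
    H_max = Hmax, epsilon_max = emax,
    acceptance = ifelse(prop > 0, acc / prop, NA_real_),
    rhat = rhat, not_converged = not_converged,
    config = config
  ), class = "boa_posterior")
}

#' @export
print.boa_posterior <- function(x, ...) {
  cat(sprintf(
    "BOA posterior: %d draws (%d chains), %d segment(s), H_max = %d\n",
    length(x$H), max(x$chain), ncol(x$p_ext), x$H_max))
  if (isTRUE(x$not_converged))
    cat("  warning: split R-hat above threshold; treat results with caution\n")
  invisible(x)
}

#' Summarise posterior draws
#'
#' Per-segment posterior means, standard deviations and equal-tailed
#' credible intervals of `p_ext` (and `s`), the posterior distribution of
#' the maximal dormancy duration `P(H = h | Obs)`, and the posterior mean
#' of `epsilon`.
#'
#' @param object A `boa_posterior` from [fit_posterior()].
#' @param prob Credible-interval probability (default 0.95).
#' @param ... Unused.
#' @return An object of class `boa_posterior_summary` with components
#'   `segments` (data frame), `H_prob` (named vector summing to 1),
#'   `epsilon` (mean, sd, interval) and the convergence diagnostics.
#' @export
summary.boa_posterior <- function(object, prob = 0.95, ...) {
  if (!length(object$H)) stop("no retained draws to summarise")
  a <- (1 - prob) / 2
  K <- ncol(object$p_ext)
  segdf <- data.frame(
    segment = object$segment_ids,
    s_mean = colMeans(object$s),
    s_sd = apply(object$s, 2, sd),
    p_ext_mean = colMeans(object$p_ext),
    p_ext_sd = apply(object$p_ext, 2, sd),
    p_ext_lo = apply(object$p_ext, 2, quantile, probs = a),
    p_ext_hi = apply(object$p_ext, 2, quantile, probs = 1 - a),
    row.names = NULL
  )
  H_prob <- tabulate(object$H + 1L, nbins = object$H_max + 1L) /
    length(object$H)
  names(H_prob) <- 0:object$H_max
  structure(list(
    species = object$species,
    segments = segdf,
    H_prob = H_prob,
    epsilon = c(mean = mean(object$epsilon), sd = sd(object$epsilon),
                lo = unname(quantile(object$epsilon, a)),
                hi = unname(quantile(object$epsilon, 1 - a))),
    prob = prob,
    n_draws = length(object$H),
    rhat = object$rhat,
    not_converged = object$not_converged
  ), class = "boa_posterior_summary")
}

#' @export
print.boa_posterior_summary <- function(x, ...) {
  cat(sprintf("Posterior summary (%d draws)\n", x$n_draws))
  cat("Per-segment patch extinction probability:\n")
  print(x$segments, digits = 3)
  cat("P(H = h | Obs):\n")
  print(round(x$H_prob, 3))
  cat(sprintf("P(H >= 1 | Obs) = %.3f\n", 1 - x$H_prob[["0"]]))
  cat(sprintf("epsilon: mean %.4f (%.0f%% CI %.4f-%.4f)\n",
              x$epsilon[["mean"]], 100 * x$prob, x$epsilon[["lo"]],
              x$epsilon[["hi"]]))
  if (isTRUE(x$not_converged))
    cat("warning: split R-hat above threshold\n")
  invisible(x)
}
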