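# Independent likelihood oracle: joint enumeration over every initial
# seed-bank configuration of the whole line, propagating the hidden states
# forward through the observed matrix and multiplying the defining
# per-entry observation probabilities.  Deliberately ignores the per-patch
# factorisation used by the package.
oracle_matrix_lik <- function(obs, s, p, H, eps = 0) {
  N <- nrow(obs); Tn <- ncol(obs)
  grid <- do.call(expand.grid, rep(list(0:(H + 1)), N))
  tot <- 0
  for (r in seq_len(nrow(grid))) {
    st <- as.integer(grid[r, ])
    pr <- prod(ifelse(st == 0, 1 - s, s / (H + 1)))
    for (t in seq_len(Tn)) {
      for (i in seq_len(N)) {
        viable <- st[i] > 0
        o <- obs[i, t]
        pe <- if (viable) {
          if (o == 1) (1 - p) + p * eps else p * (1 - eps)
        } else {
          if (o == 1) eps else 1 - eps
        }
        pr <- pr * pe
      }
      if (pr == 0) break
      ns <- integer(N)
      for (i in seq_len(N)) {
        nbr <- obs[i, t] == 1 ||
          (i > 1 && obs[i - 1, t] == 1) ||
          (i < N && obs[i + 1, t] == 1)
        if (nbr) ns[i] <- 1L
        else if (st[i] > 0 && st[i] + 1L <= H + 1L) ns[i] <- st[i] + 1L
        else ns[i] <- 0L
      }
      st <- ns
    }
    tot <- tot + pr
  }
  tot
}

# All binary matrices of a given shape, as a list (for normalisation checks).
all_binary_matrices <- function(N, Tn) {
  n <- N * Tn
  lapply(0:(2^n - 1), function(code) {
    bits <- as.integer(intToBits(code))[seq_len(n)]
    matrix(bits, N, Tn)
  })
}

# Deterministic toy posterior objects for the risk-metric tests.
toy_posterior <- function(H, p_ext, s = NULL, H_max = 10L) {
  n <- length(H)
  p_ext <- matrix(p_ext, nrow = n)
  if (is.null(s)) s <- matrix(0.5, n, ncol(p_ext))
  structure(list(
    H = as.integer(H), epsilon = rep(0, n), s = s, p_ext = p_ext,
    chain = rep(1L, n), iteration = seq_len(n),
    segment_ids = paste0("seg", seq_len(ncol(p_ext))),
    species = "toy", H_max = as.integer(H_max), epsilon_max = 0.1,
    rhat = NA_real_, not_converged = FALSE
  ), class = "boa_posterior")
}

# Small threshold table with chosen values (for metric arithmetic tests).
toy_pc_table <- function(p_c, H = seq_along(p_c) - 1L) {
  tab <- data.frame(H = as.integer(H), p_c = p_c, mcse = 0.005,
                    N = 100L, T_gen = 100L, n_reps = 10L, tol = 0.005)
  class(tab) <- c("pc_table", "data.frame")
  tab
}
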