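#' Draw the initial seed-bank state
#'
#' Each of the `N` patches independently holds viable seeds with probability
#' `params$s`; a seeded patch receives a cohort age drawn uniformly from
#' `{1, ..., H + 1}` (every viable age is reachable at time 0), otherwise
#' the patch seed bank is empty.  States are integer vectors: 0 encodes an
#' empty seed bank, a positive entry the age of the youngest viable cohort
#' at the start of the germination step.
#'
#' @param N Number of patches (at least 1).
#' @param params A [boa_params()] object.
#' @param seed Optional integer seed for reproducibility.
#' @return Integer vector of length `N` (0 = empty, otherwise age in
#'   `1:(H+1)`).
#' @export
boa_initial_state <- function(N, params, seed = NULL) {
  if (!is.numeric(N) || length(N) != 1L || N < 1)
    stop("N must be a positive patch count")
  N <- as.integer(N)
  if (!is.null(seed)) set.seed(seed)
  seeded <- runif(N) < params$s
  ages <- integer(N)
  ages[seeded] <- sample.int(params$H + 1L, sum(seeded), replace = TRUE)
  ages
}

#' Advance the BOA process by one generation
#'
#' One generation: (1) patches with a viable seed bank germinate plants;
#' (2) each patch with plants is wiped by an extinction event with
#' probability `p_ext`, then (noisy variant only) each plant-free patch
#' shows plants with probability `epsilon`; the presence/absence pattern is
#' recorded at this point; (3) surviving (and noise-generated) plants
#' deposit fresh seeds in their own patch and the two in-bounds neighbours
#' before dying; seeds dispersing past either end of the line are lost.
#' Unreplenished cohorts age by one generation and lose viability past age
#' `H + 1`.
#'
#' @param state Integer state vector as returned by [boa_initial_state()].
#' @param params A [boa_params()] object; `state` must be valid for
#'   `params$H` (no age above `H + 1`).
#' @return A list with components `state` (next generation's seed-bank
#'   ages) and `obs` (binary presence/absence vector recorded after the
#'   extinction step).
#' @export
boa_step <- function(state, params) {
  N <- length(state)
  if (any(state < 0L) || any(state > params$H + 1L))
    stop("invalid seed-bank state for this maximal dormancy duration")
  viable <- state > 0L
  obs <- viable & (runif(N) >= params$p_ext)
  if (params$epsilon > 0)
    obs <- obs | (!obs & runif(N) < params$epsilon)
  nbr <- obs
  if (N > 1L) {
    nbr[-1L] <- nbr[-1L] | obs[-N]
    nbr[-N] <- nbr[-N] | obs[-1L]
  }
  nxt <- state + (state > 0L)
  nxt[nxt > params$H + 1L] <- 0L
  nxt[nbr] <- 1L
  list(state = as.integer(nxt), obs = as.integer(obs))
}

#' Simulate a BOA process trajectory
#'
#' Applies [boa_initial_state()] followed by `T` generations of
#' [boa_step()], recording all hidden seed-bank states and the yearly
#' presence/absence observations (taken after the extinction step, before
#' seed production).
#'
#' @param params A [boa_params()] object.
#' @param N Number of patches.
#' @param T_gen Number of generations to simulate.
#' @param seed Optional integer seed; stored in the result so a trajectory
#'   is fully reproducible.
#' @return An object of class `boa_trajectory`: a list with `hidden`
#'   (`N x (T_gen + 1)` integer matrix of seed-bank ages, column `t + 1`
#'   being the state at the start of generation `t + 1`), `obs` (an
#'   [occupancy_matrix()] with no missing entries), `params` and `seed`.
#' @export
boa_simulate <- function(params, N, T_gen, seed = NULL) {
  if (!is.numeric(N) || N < 1 || !is.numeric(T_gen) || T_gen < 1)
    stop("N and T_gen must be positive")
  N <- as.integer(N); T_gen <- as.integer(T_gen)
  if (!is.null(seed)) set.seed(seed)
  hidden <- matrix(0L, N, T_gen + 1L)
  obs <- matrix(0L, N, T_gen)
  state <- boa_initial_state(N, params)
  hidden[, 1L] <- state
  for (t in seq_len(T_gen)) {
    stp <- boa_step(state, params)
    state <- stp$state
    hidden[, t + 1L] <- state
    obs[, t] <- stp$obs
  }
  structure(list(hidden = hidden, obs = occupancy_matrix(obs),
                 params = params, seed = seed),
            class = "boa_trajectory")
}

#' @export
print.boa_trajectory <- function(x, ...) {
  cat(sprintf(
    "BOA trajectory: %d patches, %d generations, final occupancy %d/%d\n",
    nrow(x$obs), ncol(x$obs), sum(x$obs[, ncol(x$obs)]), nrow(x$obs)))
  print(x$params)
  invisible(x)
}

#' Corrupt an occupancy matrix with observation errors
#'
#' Flips each absence (0) to a presence with probability `fp_rate` (false
#' positives) and each presence (1) to an absence with probability
#' `fn_rate` (false negatives), independently across entries.  External
#' colonisation is not emulated here: it corresponds to simulating with
#' `epsilon > 0` while inferring with `epsilon` fixed at zero.
#'
#' @param obs An [occupancy_matrix()] without missing entries.
#' @param fp_rate,fn_rate False positive / false negative rates in \[0, 1\].
#' @param seed Optional integer seed.
#' @return The corrupted occupancy matrix (attributes preserved).
#' @export
corrupt_observations <- function(obs, fp_rate = 0, fn_rate = 0, seed = NULL) {
  if (anyNA(obs)) stop("cannot corrupt a matrix with missing entries")
  if (fp_rate < 0 || fp_rate > 1 || fn_rate < 0 || fn_rate > 1)
    stop("error rates must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  out <- obs
  u <- matrix(runif(length(out)), nrow(out))
  zeros <- out == 0L
  out[zeros & u < fp_rate] <- 1L
  out[!zeros & u < fn_rate] <- 0L
  out
}
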