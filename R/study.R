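#' Design a simulation study of the extinction-risk metrics
#'
#' Describes a grid of true BOA parameter sets, lattice sizes and
#' monitoring durations, an optional data-corruption mechanism, and the
#' inference mode, for [run_study()].  Each cell of the design is
#' replicated (30 replicates by default, matching the metric-comparison
#' protocol) by simulating a trajectory, optionally corrupting its
#' observations, fitting the posterior, and computing the risk metrics.
#'
#' Corruption types: `"none"`; `"fp"` / `"fn"` flip observations with the
#' given rate ([corrupt_observations()]); `"external"` simulates under a
#' noisy process with `epsilon = rate` (weak external colonisation) while
#' the truth used for scoring keeps `H` and `p_ext` unchanged.
#'
#' @param H,p_ext,s,N,T_gen Vectors of true parameter values; their full
#'   crossing forms the design grid.
#' @param replicates Replicate simulations per cell.
#' @param corruption_type One of `"none"`, `"fp"`, `"fn"`, `"external"`.
#' @param corruption_rate Corruption intensity in \[0, 0.1\].
#' @param config An [inference_config()] describing the inference arm
#'   (plain BOA: `epsilon_fixed = TRUE`; noisy: `epsilon_max` 0.05 or 0.1).
#' @param seed Base seed; replicate seeds are derived deterministically.
#' @return An object of class `boa_study_design`.
#' @export
study_design <- function(H = c(0L, 2L), p_ext = 0.5, s = 0.5, N = 50L,
                         T_gen = 10L, replicates = 30L,
                         corruption_type = c("none", "fp", "fn", "external"),
                         corruption_rate = 0,
                         config = inference_config(n_iterations = 700L,
                                                   n_burnin = 250L),
                         seed = 1L) {
  corruption_type <- match.arg(corruption_type)
  if (replicates < 1) stop("replicates must be at least 1")
  if (corruption_rate < 0 || corruption_rate > 0.1)
    stop("corruption rates above 0.1 are outside the regime studied")
  grid <- expand.grid(H = as.integer(H), p_ext = p_ext, s = s,
                      N = as.integer(N), T_gen = as.integer(T_gen),
                      KEEP.OUT.ATTRS = FALSE)
  structure(list(grid = grid, replicates = as.integer(replicates),
                 corruption_type = corruption_type,
                 corruption_rate = corruption_rate,
                 config = config, seed = as.integer(seed)),
            class = "boa_study_design")
}

#' Run a simulation study of the GER and MaxGER metrics
#'
#' For every cell of the design and every replicate: simulate a BOA
#' trajectory at the true parameters, apply the corruption mechanism, fit
#' the posterior under the configured inference mode, and score the GER,
#' MaxGER, `H_inf` and the posterior mean of `p_ext`.  Replicate-level
#' failures are recorded and skipped, never aborting the study.
#'
#' @param design A [study_design()].
#' @param table A `pc_table` covering `0:H_max`.
#' @return An object of class `boa_study_result`: `replicates` (one row
#'   per replicate) and `cells` (per-cell averages: `avg_MaxGER`,
#'   `avg_GER`, `rmse_p_ext`, `mean_abs_H_err`, error count).
#' @export
run_study <- function(design, table) {
  grid <- design$grid
  reps <- design$replicates
  out <- vector("list", nrow(grid) * reps)
  r <- 0L
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    for (j in seq_len(reps)) {
      r <- r + 1L
      seed_ij <- (design$seed + 7919L * i + 104729L * j) %% .Machine$integer.max
      rec <- data.frame(cell = i, rep = j, H_true = g$H, p_ext_true = g$p_ext,
                        s_true = g$s, N = g$N, T_gen = g$T_gen,
                        MaxGER = NA_real_, GER = NA_real_,
                        H_inf = NA_integer_, p_ext_mean = NA_real_,
                        error = NA_character_)
      res <- tryCatch({
        sim_eps <- if (design$corruption_type == "external")
          design$corruption_rate else 0
        pars <- boa_params(s = g$s, p_ext = g$p_ext, H = g$H,
                           epsilon = sim_eps)
        traj <- boa_simulate(pars, g$N, g$T_gen, seed = seed_ij)
        obs <- traj$obs
        if (design$corruption_type == "fp")
          obs <- corrupt_observations(obs, fp_rate = design$corruption_rate)
        if (design$corruption_type == "fn")
          obs <- corrupt_observations(obs, fn_rate = design$corruption_rate)
        cfg <- design$config
        cfg$seed <- seed_ij + 1L
        fit <- fit_posterior(metapop_dataset(obs), cfg)
        mg <- compute_maxger(fit, table)
        rec$MaxGER <- as.numeric(mg)
        rec$H_inf <- attr(mg, "h_inf")
        rec$GER <- compute_ger(fit, table)
        rec$p_ext_mean <- compute_ler(fit)
        rec
      }, error = function(e) { rec$error <- conditionMessage(e); rec })
      out[[r]] <- res
    }
  }
  repl <- do.call(rbind, out)
  cells <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    d <- repl[repl$cell == i & is.na(repl$error), , drop = FALSE]
    data.frame(
      cell = i, grid[i, ],
      n_ok = nrow(d),
      n_err = sum(repl$cell == i) - nrow(d),
      avg_MaxGER = mean(d$MaxGER),
      avg_GER = mean(d$GER),
      rmse_p_ext = sqrt(mean((d$p_ext_mean - d$p_ext_true)^2)),
      mean_abs_H_err = mean(abs(d$H_inf - d$H_true)),
      sd_MaxGER = sd(d$MaxGER),
      row.names = NULL
    )
  }))
  structure(list(replicates = repl, cells = cells, design = design),
            class = "boa_study_result")
}

#' @export
print.boa_study_result <- function(x, ...) {
  cat(sprintf("BOA metric study: %d cells x %d replicates (%s corruption)\n",
              nrow(x$cells), x$design$replicates,
              x$design$corruption_type))
  print(x$cells, digits = 3)
  invisible(x)
}

#' Compare the MaxGER and GER metrics across a study
#'
#' Reports, for each cell, the difference `avg_MaxGER - avg_GER` and flags
#' the near-threshold region (true `p_ext` within `margin` of `p_c(H)`)
#' where the MaxGER is expected to react earlier and reach higher values
#' than the GER.
#'
#' @param result A `boa_study_result`.
#' @param table The `pc_table` used for the study.
#' @param margin Half-width of the near-threshold band (default 0.05).
#' @return A data frame with per-cell metric differences and flags.
#' @export
compare_metrics <- function(result, table, margin = 0.05) {
  cells <- result$cells
  pc <- pc_lookup(table, cells$H)
  data.frame(
    cell = cells$cell, H_true = cells$H, p_ext_true = cells$p_ext,
    p_c = pc,
    avg_MaxGER = cells$avg_MaxGER, avg_GER = cells$avg_GER,
    maxger_minus_ger = cells$avg_MaxGER - cells$avg_GER,
    near_threshold = abs(cells$p_ext - pc) <= margin
  )
}
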