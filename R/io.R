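#' Read / write occupancy matrices as CSV
#'
#' The on-disk dialect is a plain UTF-8 CSV: a header row of consecutive
#' year labels, one row per patch in street order, and cells restricted to
#' the tokens `0`, `1` and `NA` (missing observation).  An optional YAML
#' sidecar `<path>.meta.yaml` carries the species name and street-portion
#' id.  `write_occupancy()` followed by `read_occupancy()` reproduces the
#' matrix bit-exactly.
#'
#' @param path CSV file path.
#' @return `read_occupancy()` returns an [occupancy_matrix()];
#'   `write_occupancy()` returns `path` invisibly.
#' @export
read_occupancy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 2L) stop("occupancy CSV needs a header and one patch row")
  fields <- strsplit(lines, ",", fixed = TRUE)
  years <- suppressWarnings(as.integer(sub("^X", "", fields[[1]])))
  if (anyNA(years)) stop("header row must contain integer year labels")
  if (length(years) > 1L && any(diff(years) != 1L))
    stop("years must be strictly increasing and consecutive")
  n_col <- length(years)
  vals <- matrix(NA_integer_, length(lines) - 1L, n_col)
  for (i in seq_len(length(lines) - 1L)) {
    f <- fields[[i + 1L]]
    if (length(f) != n_col)
      stop(sprintf("row %d has %d cells, expected %d", i, length(f), n_col))
    bad <- !f %in% c("0", "1", "NA")
    if (any(bad))
      stop(sprintf("illegal token '%s' at row %d, column %d",
                   f[which(bad)[1]], i, which(bad)[1]))
    vals[i, ] <- suppressWarnings(as.integer(f))
  }
  species <- segment_id <- NULL
  meta_path <- paste0(path, ".meta.yaml")
  if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    species <- meta$species
    segment_id <- meta$segment_id
  }
  m <- occupancy_matrix(vals, years = years, segment_id = segment_id,
                        species = species)
  full_miss <- colSums(!is.na(m)) == 0L
  if (any(full_miss))
    attr(m, "fully_missing_years") <- attr(m, "years")[full_miss]
  m
}

#' @rdname read_occupancy
#' @param x An [occupancy_matrix()].
#' @export
write_occupancy <- function(x, path) {
  if (!inherits(x, "occupancy_matrix")) x <- occupancy_matrix(x)
  tokens <- ifelse(is.na(x), "NA", as.character(unclass(x)))
  dim(tokens) <- dim(x)
  lines <- c(paste(attr(x, "years"), collapse = ","),
             apply(tokens, 1, paste, collapse = ","))
  writeLines(lines, path)
  species <- attr(x, "species"); segment_id <- attr(x, "segment_id")
  if (!is.na(species) || !is.na(segment_id)) {
    meta <- list()
    if (!is.na(species)) meta$species <- species
    if (!is.na(segment_id)) meta$segment_id <- segment_id
    yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  }
  invisible(path)
}

#' Retain sufficiently occupied (species, street portion) pairs
#'
#' Keeps each occupancy matrix whose mean occupancy over its non-missing
#' entries is at least `threshold` (ties at exactly the threshold are
#' kept).  Matrices with every entry missing are dropped with a warning.
#' This reproduces the data-preparation rule of focusing on species
#' observed in an average of at least 10 percent of a portion's tree bases.
#'
#' @param matrices A list of [occupancy_matrix()] objects.
#' @param threshold Minimal mean occupancy (default 0.10).
#' @return The retained sub-list.
#' @export
filter_occupancy <- function(matrices, threshold = 0.10) {
  if (inherits(matrices, "occupancy_matrix")) matrices <- list(matrices)
  keep <- vapply(matrices, function(m) {
    if (all(is.na(m))) {
      warning("dropping a matrix with every entry missing")
      return(FALSE)
    }
    mean(m, na.rm = TRUE) >= threshold
  }, logical(1))
  matrices[keep]
}

#' Export posterior draws and summaries as tidy CSV
#'
#' `write_posterior_draws()` writes one row per draw per parameter
#' (columns `chain`, `iteration`, `parameter`, `segment`, `value`);
#' `write_posterior_summary()` writes the per-segment summary table with
#' the `P(H = h | Obs)` distribution appended as `H_prob_<h>` rows.
#'
#' @param samples A `boa_posterior`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_posterior_draws <- function(samples, path) {
  K <- ncol(samples$p_ext)
  blocks <- list(
    data.frame(chain = samples$chain, iteration = samples$iteration,
               parameter = "H", segment = NA_character_,
               value = samples$H),
    data.frame(chain = samples$chain, iteration = samples$iteration,
               parameter = "epsilon", segment = NA_character_,
               value = samples$epsilon)
  )
  for (k in seq_len(K)) {
    id <- samples$segment_ids[k]
    blocks <- c(blocks, list(
      data.frame(chain = samples$chain, iteration = samples$iteration,
                 parameter = "s", segment = id, value = samples$s[, k]),
      data.frame(chain = samples$chain, iteration = samples$iteration,
                 parameter = "p_ext", segment = id,
                 value = samples$p_ext[, k])
    ))
  }
  write.csv(do.call(rbind, blocks), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_posterior_draws
#' @export
write_posterior_summary <- function(samples, path) {
  sm <- summary(samples)
  seg <- sm$segments
  out <- cbind(seg, t(replicate(nrow(seg), sm$H_prob)))
  names(out)[(ncol(seg) + 1):ncol(out)] <-
    paste0("H_prob_", names(sm$H_prob))
  out$epsilon_mean <- sm$epsilon[["mean"]]
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an extinction-risk report as CSV
#'
#' @param report A `risk_report` from [risk_report()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_risk_report <- function(report, path) {
  write.csv(as.data.frame(report), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an inference configuration from a YAML file
#'
#' Keys mirror the arguments of [inference_config()]; unknown keys are an
#' error so that typos do not silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return An [inference_config()] object.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(inference_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  do.call(inference_config, vals)
}
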