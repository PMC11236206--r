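#' Observed occupancy matrix for one street portion
#'
#' An occupancy matrix records the yearly presence/absence of standing
#' plants in each patch (tree base) of one portion of street: one row per
#' patch in physical order along the street, one column per consecutive
#' survey year.  Entries are 1 (plants observed), 0 (no plants) or `NA`
#' (not surveyed; a fully untracked year is a column of `NA`).
#'
#' @param values Matrix (or object coercible to one) with entries 0, 1 or
#'   `NA`.
#' @param years Integer vector of consecutive survey years labelling the
#'   columns; defaults to `1:ncol(values)`.
#' @param segment_id Optional label for the street portion.
#' @param species Optional species label.
#' @return An integer matrix of class `occupancy_matrix` with attributes
#'   `years`, `segment_id` and `species`.
#' @export
occupancy_matrix <- function(values, years = NULL, segment_id = NULL,
                             species = NULL) {
  values <- as.matrix(values)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("occupancy matrix must have at least one patch and one year")
  ok <- is.na(values) | values == 0 | values == 1
  if (!all(ok))
    stop("occupancy entries must be 0, 1 or NA")
  storage.mode(values) <- "integer"
  if (is.null(years)) years <- seq_len(ncol(values))
  years <- as.integer(years)
  if (length(years) != ncol(values))
    stop("length(years) must match the number of columns")
  if (ncol(values) > 1L && any(diff(years) != 1L))
    stop("years must be strictly increasing and consecutive")
  dimnames(values) <- NULL
  structure(values, years = years,
            segment_id = if (is.null(segment_id)) NA_character_ else as.character(segment_id),
            species = if (is.null(species)) NA_character_ else as.character(species),
            class = c("occupancy_matrix", "matrix", "array"))
}

#' @export
print.occupancy_matrix <- function(x, ...) {
  cat(sprintf(
    "Occupancy matrix: %d patches x %d years (%s), %d missing entries\n",
    nrow(x), ncol(x),
    paste(range(attr(x, "years")), collapse = "-"),
    sum(is.na(x))
  ))
  if (!is.na(attr(x, "species")) || !is.na(attr(x, "segment_id")))
    cat(sprintf("  species: %s   segment: %s\n",
                attr(x, "species"), attr(x, "segment_id")))
  m <- unclass(x)
  attributes(m) <- list(dim = dim(x))
  print(m, ...)
  invisible(x)
}

#' Group occupancy matrices of one species into a dataset
#'
#' A metapopulation dataset collects the occupancy matrices of one species
#' over several portions of street.  Inference treats the maximal dormancy
#' duration and the noise intensity as shared across portions, while the
#' initial seed occupancy and patch extinction probability are estimated
#' per portion.
#'
#' @param segments A list of [occupancy_matrix()] objects (or a single one).
#' @param species Optional species label.
#' @return An object of class `metapop_dataset`.
#' @export
metapop_dataset <- function(segments, species = NULL) {
  if (inherits(segments, "occupancy_matrix")) segments <- list(segments)
  if (!length(segments)) stop("a dataset needs at least one segment")
  segments <- lapply(segments, function(m) {
    if (!inherits(m, "occupancy_matrix")) occupancy_matrix(m) else m
  })
  ids <- vapply(segments, function(m) attr(m, "segment_id"), character(1))
  if (anyNA(ids)) ids[is.na(ids)] <- paste0("segment", which(is.na(ids)))
  names(segments) <- ids
  structure(list(species = if (is.null(species)) NA_character_ else as.character(species),
                 segments = segments),
            class = "metapop_dataset")
}

#' @export
print.metapop_dataset <- function(x, ...) {
  cat(sprintf("Metapopulation dataset: species %s, %d street portion(s)\n",
              x$species, length(x$segments)))
  for (nm in names(x$segments)) {
    m <- x$segments[[nm]]
    cat(sprintf("  %s: %d patches x %d years, %d missing\n",
                nm, nrow(m), ncol(m), sum(is.na(m))))
  }
  invisible(x)
}
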