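#' BOA process parameters
#'
#' Bundle the parameters of the (noisy) BOA process: the initial proportion
#' `s` of patches containing viable seeds, the per-generation patch
#' extinction probability `p_ext`, the maximal dormancy duration `H`
#' (complete generations a seed cohort can skip without losing viability;
#' cohorts deposited more than `H + 1` generations ago are never viable),
#' and the noise intensity `epsilon` of the noisy variant (each plant-free
#' patch shows plants with probability `epsilon` after the extinction step).
#' `epsilon = 0` recovers the plain BOA process exactly.
#'
#' @param s Initial proportion of patches holding viable seeds, in \[0, 1\].
#' @param p_ext Patch extinction probability per generation, in \[0, 1\].
#' @param H Maximal dormancy duration, a non-negative integer.
#' @param epsilon Noise intensity, in \[0, 1\]; 0 for the plain process.
#' @return An object of class `boa_params`.
#' @examples
#' boa_params(s = 0.5, p_ext = 0.4, H = 2)
#' @export
boa_params <- function(s, p_ext, H, epsilon = 0) {
  stopifnot(
    is.numeric(s), length(s) == 1L, s >= 0, s <= 1,
    is.numeric(p_ext), length(p_ext) == 1L, p_ext >= 0, p_ext <= 1,
    is.numeric(H), length(H) == 1L, H >= 0, H == as.integer(H),
    is.numeric(epsilon), length(epsilon) == 1L, epsilon >= 0, epsilon <= 1
  )
  structure(
    list(s = as.numeric(s), p_ext = as.numeric(p_ext),
         H = as.integer(H), epsilon = as.numeric(epsilon)),
    class = "boa_params"
  )
}

#' @export
print.boa_params <- function(x, ...) {
  cat(sprintf(
    "BOA process parameters: s = %.3g, p_ext = %.3g, H = %d, epsilon = %.3g%s\n",
    x$s, x$p_ext, x$H, x$epsilon,
    if (x$epsilon == 0) " (plain process)" else " (noisy variant)"
  ))
  invisible(x)
}
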