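#' xpsdamage: in situ XPS monitoring of radiation damage to DNA
#'
#' Constrained Voigt deconvolution of core-level XPS regions on Shirley
#' backgrounds, P2p-normalized damage time series with strand-break,
#' base-damage and hydration indices, a layered-slab photon/electron
#' transport model, and a ground-truth synthetic spectrum generator.
#'
#' @keywords internal
"_PACKAGE"

#' @importFrom stats setNames median approx aggregate lm predict runif rpois
#'   sd fft
#' @importFrom utils read.table write.table modifyList packageVersion
NULL
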