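#' Shirley inelastic background
#'
#' Classic fixed-point Shirley iteration.  With endpoint intensities
#' \code{I_lo} (low-BE edge) and \code{I_hi} (high-BE edge), each defined as
#' the mean over the outermost \code{nEdge} points, the background satisfies
#' \deqn{B(E) = I_{hi} + (I_{lo} - I_{hi}) \, A_{>E} / A_{tot},}
#' where the areas are integrals of the net signal (counts minus the current
#' background) above/over the whole window, so the background at any energy
#' is proportional to the integrated peak intensity at lower binding
#' energies.  Iteration stops when the maximum relative change falls below
#' \code{tol} or after \code{maxIter} iterations.
#'
#' Net signal that goes negative during the iteration is clipped to zero for
#' the area integrals (and noted in the attributes).
#'
#' @param object a \linkS4class{Spectrum}, or a numeric vector of counts
#'   (then \code{x} must give the grid).
#' @param nEdge number of points averaged at each edge (>= 1).
#' @param tol relative-change convergence tolerance.
#' @param maxIter iteration cap.
#' @param x binding-energy grid when \code{object} is a numeric vector.
#' @param iLo,iHi optional endpoint intensities overriding the edge means
#'   (used to de-bias the endpoints from peak tails once a peak estimate
#'   exists).
#' @return numeric background curve, same length as the input, with
#'   attributes \code{converged} (logical), \code{iterations} (count) and
#'   \code{clipped} (logical: negative net signal encountered).
#' @examples
#' x <- seq(280, 292, by = 0.05)
#' y <- voigtProfile(x, 286, 1000, 1.2, 0) + 50 - 40 * (x > 286)
#' b <- shirleyBackground(Spectrum("C1s", x, pmax(y, 0)))
#' attr(b, "converged")
#' @export
shirleyBackground <- function(object, nEdge = 5L, tol = 1e-6, maxIter = 100L,
                              x = NULL, iLo = NULL, iHi = NULL) {
  if (is(object, "Spectrum")) {
    y <- object@counts
    x <- object@bindingEnergy
  } else {
    y <- as.numeric(object)
    if (is.null(x)) stop("x grid required for numeric input")
  }
  if (nEdge < 1L) stop("nEdge must be >= 1")
  if (anyNA(y) || any(!is.finite(y)) || anyNA(x) || any(!is.finite(x)))
    stop("non-finite input to shirleyBackground")
  n <- length(y)
  if (n < 2L * nEdge) stop("spectrum too short for the requested edge width")

  if (is.null(iLo)) iLo <- mean(y[seq_len(nEdge)])          # low-BE edge
  if (is.null(iHi)) iHi <- mean(y[seq(n - nEdge + 1L, n)])  # high-BE edge
  b <- rep(iLo, n)
  clipped <- FALSE
  convergedFlag <- FALSE
  iter <- 0L
  for (iter in seq_len(maxIter)) {
    s <- y - b
    if (any(s < 0)) { clipped <- TRUE; s <- pmax(s, 0) }
    # cumulative trapezoid of net signal from the low-BE end
    cumA <- c(0, cumsum(diff(x) * (s[-1] + s[-n]) / 2))
    atot <- cumA[n]
    bNew <- if (atot > 0) iLo + (iHi - iLo) * cumA / atot else
      iLo + (iHi - iLo) * (x - x[1]) / (x[n] - x[1])
    delta <- max(abs(bNew - b)) / max(abs(bNew), .Machine$double.eps)
    b <- bNew
    if (delta < tol) { convergedFlag <- TRUE; break }
  }
  attr(b, "converged")  <- convergedFlag
  attr(b, "iterations") <- iter
  attr(b, "clipped")    <- clipped
  b
}
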