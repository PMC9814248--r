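# Constrained Voigt deconvolution of a region spectrum.
#
# Bound-constrained Levenberg-Marquardt (minpack.lm::nls.lm) on
# counts - background - sum(components), with the Shirley background
# computed once from the raw data and held fixed.  Free parameters per
# component: area (>= 0), center (within its bounds), Gaussian and
# Lorentzian FWHM (within global bounds).  Doublet links remove the
# secondary line's parameters (area = primary/ratio, center = primary +
# splitting, widths tied); an optional shared Gaussian width collapses all
# Gaussian FWHMs into one parameter.

# ---- parameter mapping -----------------------------------------------------

.doubletSecondaries <- function(m)
  vapply(m@doublets, function(d) d$secondary, character(1))

.paramSpec <- function(m) {
  sec <- .doubletSecondaries(m)
  nm <- character(); lo <- numeric(); hi <- numeric(); st <- numeric()
  add <- function(name, lower, upper, start) {
    nm <<- c(nm, name); lo <<- c(lo, lower); hi <<- c(hi, upper)
    st <<- c(st, start)
  }
  for (p in m@components) {
    if (p@label %in% sec) next
    if (!("area" %in% p@fixed))
      add(paste0("area_", p@label), 0, Inf, p@area)
    if (!("center" %in% p@fixed))
      add(paste0("center_", p@label), p@centerBounds[1], p@centerBounds[2],
          p@center)
    if (!m@sharedGaussianWidth && !("gaussianFwhm" %in% p@fixed))
      add(paste0("gw_", p@label), p@gaussianBounds[1], p@gaussianBounds[2],
          p@gaussianFwhm)
    if (!("lorentzianFwhm" %in% p@fixed))
      add(paste0("lw_", p@label), p@lorentzianBounds[1], p@lorentzianBounds[2],
          p@lorentzianFwhm)
  }
  if (m@sharedGaussianWidth) {
    gb <- sapply(m@components, function(p) p@gaussianBounds)
    add("gw_shared", max(gb[1, ]), min(gb[2, ]),
        mean(vapply(m@components, function(p) p@gaussianFwhm, numeric(1))))
  }
  list(names = nm, lower = lo, upper = hi, start = st)
}

# per-component (area, center, gw, lw) given a named free-parameter vector
.componentParams <- function(m, par) {
  sec <- .doubletSecondaries(m)
  byLabel <- list()
  getp <- function(name, default) if (name %in% names(par)) par[[name]] else
    default
  for (p in m@components) {
    if (p@label %in% sec) next
    gw <- if (m@sharedGaussianWidth) getp("gw_shared", p@gaussianFwhm) else
      getp(paste0("gw_", p@label), p@gaussianFwhm)
    byLabel[[p@label]] <- c(
      area = getp(paste0("area_", p@label), p@area),
      center = getp(paste0("center_", p@label), p@center),
      gw = gw, lw = getp(paste0("lw_", p@label), p@lorentzianFwhm))
  }
  for (d in m@doublets) {
    pr <- byLabel[[d$primary]]
    byLabel[[d$secondary]] <- c(area = unname(pr["area"]) / d$ratio,
                                center = unname(pr["center"]) + d$splitting,
                                gw = unname(pr["gw"]), lw = unname(pr["lw"]))
  }
  labs <- componentLabels(m)
  byLabel[labs]
}

.modelCurve <- function(m, par, x, shape = "voigt") {
  cp <- .componentParams(m, par)
  y <- numeric(length(x))
  for (v in cp)
    y <- y + voigtProfile(x, v["center"], v["area"], v["gw"], v["lw"],
                          shape = shape)
  y
}

# Analytic Jacobian of the weighted residuals w.r.t. the free parameters
# (negative component-sum derivatives, plus background-offset columns).
.residualJacobian <- function(m, par, x, sw, parNames, stepShape = NULL) {
  J <- matrix(0, length(x), length(parNames),
              dimnames = list(NULL, parNames))
  cp <- .componentParams(m, par)
  sec <- .doubletSecondaries(m)
  prim <- vapply(m@doublets, function(d) d$primary, character(1))
  addCols <- function(lab, g, areaScale = 1) {
    # map component-parameter gradients onto free-parameter columns
    nmA <- paste0("area_", lab); nmC <- paste0("center_", lab)
    nmG <- if (m@sharedGaussianWidth) "gw_shared" else paste0("gw_", lab)
    nmL <- paste0("lw_", lab)
    if (nmA %in% parNames) J[, nmA] <<- J[, nmA] - g$dA * areaScale * sw
    if (nmC %in% parNames) J[, nmC] <<- J[, nmC] - g$dC * sw
    if (nmG %in% parNames) J[, nmG] <<- J[, nmG] - g$dGw * sw
    if (nmL %in% parNames) J[, nmL] <<- J[, nmL] - g$dLw * sw
  }
  for (p in m@components) {
    v <- cp[[p@label]]
    g <- .voigtGrad(x, v[["center"]], v[["area"]], v[["gw"]], v[["lw"]])
    if (p@label %in% sec) {
      d <- m@doublets[[match(p@label, sec)]]
      addCols(d$primary, g, areaScale = 1 / d$ratio)
    } else {
      addCols(p@label, g)
    }
  }
  if (!is.null(stepShape)) {
    if ("bg_lo" %in% parNames) J[, "bg_lo"] <- -(1 - stepShape) * sw
    if ("bg_hi" %in% parNames) J[, "bg_hi"] <- -stepShape * sw
  }
  J
}

# d(component areas)/d(free parameters), ncomp x npar
.areaJacobian <- function(m, parNames) {
  labs <- componentLabels(m)
  M <- matrix(0, length(labs), length(parNames),
              dimnames = list(labs, parNames))
  sec <- .doubletSecondaries(m)
  for (p in m@components) {
    nm <- paste0("area_", p@label)
    if (nm %in% parNames) M[p@label, nm] <- 1
  }
  for (d in m@doublets) {
    nm <- paste0("area_", d$primary)
    if (nm %in% parNames) M[d$secondary, nm] <- 1 / d$ratio
  }
  M
}

# ---- fitting ---------------------------------------------------------------

#' Fit a region model to a spectrum
#'
#' Deconvolutes a region spectrum into a (frozen) Shirley or linear
#' background plus constrained Voigt components by bound-constrained
#' least squares, and attaches covariance-based one-sigma area
#' uncertainties.  The stored arrays satisfy
#' \code{counts == componentSum + backgroundCurve + residuals} exactly.
#'
#' Non-convergence is never silent: the result carries
#' \code{converged = FALSE}.  Parameters ending on a bound are recorded in
#' the result's messages.
#'
#' @param s a \linkS4class{Spectrum} (already windowed to the region).
#' @param m a \linkS4class{RegionModel} whose components lie inside the
#'   spectrum window.
#' @param weighting \code{"poisson"} (weights 1/max(counts, 1); default) or
#'   \code{"none"}.
#' @param shape line shape passed to \code{\link{voigtProfile}}.
#' @param initAreasFromData if TRUE (default) starting areas are rescaled so
#'   their sum matches the background-subtracted net area.
#' @param nEdge,bgTol,bgMaxIter Shirley background settings.
#' @param reiterateBackground number of background refresh cycles: after a
#'   fit pass the Shirley endpoints are re-derived from the de-peaked
#'   spectrum (removing the peak-tail bias of the raw edge means), the
#'   background recomputed, and the fit repeated; the background stays
#'   frozen within each optimization.  Default 1; set 0 to keep the
#'   background from the raw data only.
#' @param fitBackgroundOffsets add two free linear parameters adjusting the
#'   background's endpoint intensities along the Shirley step shape
#'   (default TRUE).  The frozen background fixes the step shape; the
#'   offsets absorb the peak-tail bias of the edge means and carry the
#'   background's share of the uncertainty into the covariance.
#' @param maxIter,ftol,ptol optimizer settings (minpack.lm).
#' @param scaleCovariance multiply the covariance by the reduced chi-square
#'   (residual-variance estimate), default TRUE.
#' @return a \linkS4class{FitResult}.
#' @examples
#' x <- seq(278, 296, by = 0.05)
#' truth <- voigtProfile(x, 285, 4000, 1.3, 0.2) +
#'          voigtProfile(x, 286.5, 8000, 1.3, 0.2) + 100
#' fit <- fitRegion(Spectrum("C1s", x, truth),
#'                  dnaRegionModels()$C1s[c("C1s_285", "C1s_286")])
#' componentAreas(fit)
#' @export
fitRegion <- function(s, m, weighting = c("poisson", "none"),
                      shape = "voigt", initAreasFromData = TRUE,
                      nEdge = 5L, bgTol = 1e-6, bgMaxIter = 100L,
                      reiterateBackground = 1L, fitBackgroundOffsets = TRUE,
                      maxIter = 200L, ftol = 1e-10, ptol = 1e-6,
                      scaleCovariance = TRUE) {
  stopifnot(is(s, "Spectrum"), is(m, "RegionModel"))
  weighting <- match.arg(weighting)
  x <- s@bindingEnergy; y <- s@counts; n <- length(x)
  ctr <- vapply(m@components, function(p) p@center, numeric(1))
  if (any(ctr < min(x)) || any(ctr > max(x)))
    stop("model components lie outside the spectrum window")
  ps <- .paramSpec(m)
  if (fitBackgroundOffsets) {
    ps$names <- c(ps$names, "bg_lo", "bg_hi")
    ps$lower <- c(ps$lower, -Inf, -Inf)
    ps$upper <- c(ps$upper, Inf, Inf)
    ps$start <- c(ps$start, 0, 0)
  }
  p <- length(ps$names)
  if (p >= n / 3)
    stop(sprintf("too many free parameters (%d) for %d grid points", p, n))
  w <- if (weighting == "poisson") 1 / pmax(y, 1) else rep(1, n)
  sw <- sqrt(w)

  bg <- .fitBackground(s, m, nEdge, bgTol, bgMaxIter)
  messages <- character()
  for (cycle in seq_len(1L + max(0L, reiterateBackground))) {
    start <- ps$start; names(start) <- ps$names
    if (initAreasFromData && any(grepl("^area_", ps$names))) {
      net <- y - bg
      aNet <- max(sum((net[-1] + net[-n]) / 2 * diff(x)), 0)
      cp0 <- .componentParams(m, setNames(start, ps$names))
      tot0 <- sum(vapply(cp0, function(v) v["area"], numeric(1)))
      if (tot0 > 0 && aNet > 0) {
        ia <- grepl("^area_", ps$names)
        start[ia] <- pmax(start[ia] * aNet / tot0, 1e-12)
      }
    }
    S <- .stepShape(bg, x)
    resFun <- function(par) {
      names(par) <- ps$names
      bgAdj <- if (fitBackgroundOffsets)
        par[["bg_lo"]] * (1 - S) + par[["bg_hi"]] * S else 0
      (y - bg - bgAdj - .modelCurve(m, par, x, shape)) * sw
    }
    if (p > 0L) {
      ctl <- minpack.lm::nls.lm.control(maxiter = maxIter, ftol = ftol,
                                        ptol = ptol)
      jacFun <- function(par) {
        names(par) <- ps$names
        .residualJacobian(m, par, x, sw, ps$names,
                          stepShape = if (fitBackgroundOffsets) S else NULL)
      }
      fit <- minpack.lm::nls.lm(par = start, lower = ps$lower,
                                upper = ps$upper, fn = resFun, jac = jacFun,
                                control = ctl)
      par <- fit$par; names(par) <- ps$names
      convergedFlag <- fit$info %in% c(1, 2, 3, 4)
      nIter <- fit$niter
      if (!convergedFlag)
        messages <- c(messages, paste0("optimizer did not converge: ",
                                       fit$message))
      atB <- .boundHits(par, ps)
      if (length(atB))
        messages <- c(messages,
                      paste0("parameter at bound: ",
                             paste(atB, collapse = ", ")))
    } else {
      par <- setNames(numeric(0), character(0))
      convergedFlag <- TRUE
      nIter <- 0
    }
    if (cycle <= max(0L, reiterateBackground)) {
      peaks <- .modelCurve(m, par, x, shape)
      bg <- .fitBackgroundFromResidual(s, m, peaks, nEdge, bgTol, bgMaxIter)
      ps$start <- unname(par)      # warm-start the refreshed-background pass
      if (fitBackgroundOffsets)    # offsets restart at zero on the new bg
        ps$start[match(c("bg_lo", "bg_hi"), ps$names)] <- 0
    }
  }
  if (fitBackgroundOffsets) {
    S <- .stepShape(bg, x)
    bg <- bg + par[["bg_lo"]] * (1 - S) + par[["bg_hi"]] * S
  }

  mFit <- .modelWithParams(m, par)
  comp <- .modelCurve(m, par, x, shape)
  covShape <- if (fitBackgroundOffsets) .stepShape(bg, x) else NULL
  resid <- y - bg - comp
  rss <- sum(resid^2 * w)
  dof <- max(n - p, 1L)
  redChi2 <- rss / dof

  parCov <- par
  if (fitBackgroundOffsets)
    parCov[match(c("bg_lo", "bg_hi"), ps$names)] <- 0
  unc <- .covarianceAtOptimum(m, parCov, ps, x, y, bg, sw, shape,
                              scale = if (scaleCovariance) redChi2 else 1,
                              stepShape = covShape)
  messages <- c(messages, unc$messages)

  labs <- componentLabels(m)
  cp <- .componentParams(m, par)
  areas <- vapply(cp, function(v) v["area"], numeric(1))
  gas <- vapply(m@components, function(pp) pp@isGasPhase, logical(1))
  M <- .areaJacobian(m, ps$names)
  areaSig <- if (p > 0L) sqrt(pmax(diag(M %*% unc$covariance %*% t(M)), 0))
             else rep(0, length(labs))
  new("FitResult",
      model = mFit,
      spectrumInfo = list(region = s@region, timepoint = s@timepoint,
                          atmosphere = s@atmosphere),
      bindingEnergy = x, counts = y, backgroundCurve = as.numeric(bg),
      residuals = resid,
      componentAreas = data.frame(label = labs, area = unname(areas),
                                  sigma = unname(areaSig), isGasPhase = gas,
                                  stringsAsFactors = FALSE),
      covariance = unc$covariance, parNames = ps$names, areaJacobian = M,
      reducedChiSquare = redChi2, converged = convergedFlag,
      nIterations = as.numeric(nIter), messages = messages, weights = w,
      options = list(weighting = weighting, shape = shape,
                     fitBackgroundOffsets = fitBackgroundOffsets))
}

.boundHits <- function(par, ps) {
  eps <- 1e-8 * pmax(abs(ps$upper - ps$lower), 1)
  bad <- !is.finite(eps)
  eps[bad] <- (1e-8 * pmax(abs(par), 1))[bad]
  hit <- (is.finite(ps$lower) & par <= ps$lower + eps) |
         (is.finite(ps$upper) & par >= ps$upper - eps)
  ps$names[hit]
}

# normalized step shape of a background curve (0 at the low-BE end,
# 1 at the high-BE end); linear ramp when the background is flat
.stepShape <- function(bg, x) {
  lo <- bg[1]; hi <- bg[length(bg)]
  if (abs(hi - lo) > 1e-12 * max(abs(bg), 1))
    pmin(pmax((bg - lo) / (hi - lo), 0), 1)
  else (x - x[1]) / (x[length(x)] - x[1])
}

.fitBackground <- function(s, m, nEdge, bgTol, bgMaxIter) {
  if (m@background == "linear") {
    x <- s@bindingEnergy; y <- s@counts; n <- length(y)
    iLo <- mean(y[seq_len(nEdge)]); iHi <- mean(y[seq(n - nEdge + 1L, n)])
    iLo + (iHi - iLo) * (x - x[1]) / (x[n] - x[1])
  } else {
    as.numeric(shirleyBackground(s, nEdge = nEdge, tol = bgTol,
                                 maxIter = bgMaxIter))
  }
}

# Background refresh: the Shirley fixed point is re-run on the raw data,
# but with the endpoint intensities taken from the de-peaked curve
# (data minus the current peak estimate).  This removes the peak-tail bias
# of the edge means; the generator's step background is then an exact
# fixed point of the operator.
.fitBackgroundFromResidual <- function(s, m, peaks, nEdge, bgTol, bgMaxIter) {
  y <- s@counts; n <- length(y)
  base <- y - peaks
  iLo <- mean(base[seq_len(nEdge)])
  iHi <- mean(base[seq(n - nEdge + 1L, n)])
  as.numeric(shirleyBackground(y, nEdge = nEdge, tol = bgTol,
                               maxIter = bgMaxIter, x = s@bindingEnergy,
                               iLo = iLo, iHi = iHi))
}

.modelWithParams <- function(m, par) {
  cp <- .componentParams(m, par)
  comps <- lapply(m@components, function(p) {
    v <- cp[[p@label]]
    p@area <- unname(v["area"]); p@center <- unname(v["center"])
    p@gaussianFwhm <- unname(v["gw"]); p@lorentzianFwhm <- unname(v["lw"])
    p
  })
  m@components <- comps
  m
}

# ---- uncertainties ---------------------------------------------------------

# central differences, falling back to one-sided steps at parameter bounds
.numericJacobian <- function(f, par, lower = rep(-Inf, length(par)),
                             upper = rep(Inf, length(par))) {
  p <- length(par)
  f0 <- f(par)
  J <- matrix(0, length(f0), p)
  for (j in seq_len(p)) {
    h <- max(1e-7 * abs(par[j]), 1e-9)
    hUp <- min(h, (upper[j] - par[j]))
    hDn <- min(h, (par[j] - lower[j]))
    if (hUp <= 0) { hUp <- 0 }
    if (hDn <= 0) { hDn <- 0 }
    if (hUp + hDn <= 0) next
    up <- par; up[j] <- up[j] + hUp
    dn <- par; dn[j] <- dn[j] - hDn
    J[, j] <- (f(up) - f(dn)) / (hUp + hDn)
  }
  colnames(J) <- names(par)
  J
}

.covarianceAtOptimum <- function(m, par, ps, x, y, bg, sw, shape, scale,
                                 stepShape = NULL) {
  p <- length(par)
  if (p == 0L)
    return(list(covariance = matrix(0, 0, 0), messages = character()))
  modelFun <- function(pp) {
    names(pp) <- ps$names
    bgAdj <- if (!is.null(stepShape))
      pp[["bg_lo"]] * (1 - stepShape) + pp[["bg_hi"]] * stepShape else 0
    (y - bg - bgAdj - .modelCurve(m, pp, x, shape)) * sw
  }
  J <- .residualJacobian(m, par, x, sw, ps$names, stepShape = stepShape)
  # parameters sitting on a bound cannot vary into the forbidden side;
  # treat them as fixed for the covariance (their rows/columns are zero)
  pinned <- .boundHits(par, ps)
  free <- !(ps$names %in% pinned)
  msgs <- character()
  Jf <- J[, free, drop = FALSE]
  pf <- ncol(Jf)
  nmf <- ps$names[free]
  if (pf == 0L) {
    cov <- matrix(0, p, p, dimnames = list(ps$names, ps$names))
    return(list(covariance = cov, messages = msgs))
  }
  # equilibrate columns so rank detection reflects degeneracy, not units
  cn <- sqrt(colSums(Jf^2))
  cn[cn == 0] <- 1
  N <- crossprod(sweep(Jf, 2, cn, "/"))  # scaled Gauss-Newton normal matrix
  sv <- svd(N)
  tolr <- max(sv$d) * 1e-10
  rank <- sum(sv$d > tolr)
  if (rank < pf) {
    implicated <- unique(unlist(lapply(seq(rank + 1, pf), function(k)
      nmf[abs(sv$v[, k]) > 0.3])))
    msgs <- c(msgs, paste0(
      "rank-deficient normal matrix; pseudo-inverse used; degenerate ",
      "directions involve: ", paste(implicated, collapse = ", ")))
    dInv <- ifelse(sv$d > tolr, 1 / sv$d, 0)
  } else {
    dInv <- 1 / sv$d
  }
  covf <- sv$v %*% (dInv * t(sv$u)) * scale
  covf <- covf / outer(cn, cn)           # undo the equilibration
  covf <- (covf + t(covf)) / 2
  cov <- matrix(0, p, p, dimnames = list(ps$names, ps$names))
  cov[nmf, nmf] <- covf
  list(covariance = cov, messages = msgs)
}

#' Per-area one-sigma uncertainties of a fit
#'
#' Recomputes the covariance (residual-variance estimate times the inverse
#' Gauss-Newton normal matrix at the optimum) from a stored
#' \linkS4class{FitResult} and propagates it through the area
#' parameterization (doublet-linked areas included).  A rank-deficient
#' normal matrix falls back to the pseudo-inverse with a warning naming the
#' degenerate parameters.
#'
#' @param fr a converged \linkS4class{FitResult}.
#' @param scaleCovariance multiply by the reduced chi-square (default TRUE).
#' @return named numeric vector of area sigmas (one per component).
#' @export
estimateUncertainties <- function(fr, scaleCovariance = TRUE) {
  stopifnot(is(fr, "FitResult"))
  if (!fr@converged)
    warning("uncertainties requested for a non-converged fit")
  m <- fr@model
  ps <- .paramSpec(m)
  useOff <- isTRUE(fr@options$fitBackgroundOffsets)
  if (useOff) {
    ps$names <- c(ps$names, "bg_lo", "bg_hi")
    ps$lower <- c(ps$lower, -Inf, -Inf)
    ps$upper <- c(ps$upper, Inf, Inf)
    ps$start <- c(ps$start, 0, 0)
  }
  par <- ps$start; names(par) <- ps$names     # model holds fitted values
  unc <- .covarianceAtOptimum(m, par, ps, fr@bindingEnergy, fr@counts,
                              fr@backgroundCurve, sqrt(fr@weights),
                              fr@options$shape %||% "voigt",
                              scale = if (scaleCovariance)
                                fr@reducedChiSquare else 1,
                              stepShape = if (useOff)
                                .stepShape(fr@backgroundCurve,
                                           fr@bindingEnergy) else NULL)
  if (length(unc$messages)) warning(paste(unc$messages, collapse = "; "))
  M <- .areaJacobian(m, ps$names)
  sig <- sqrt(pmax(diag(M %*% unc$covariance %*% t(M)), 0))
  setNames(sig, componentLabels(m))
}

#' Fit every timepoint of a series for one region
#'
#' Each timepoint is fitted independently; by default each fit is
#' warm-started from the previous timepoint's optimum, which stabilizes
#' component identity along the time axis.
#'
#' @param series a \linkS4class{SpectrumSeries}.
#' @param m \linkS4class{RegionModel} for the region.
#' @param region region label (default: the model's).
#' @param window optional c(low, high) eV applied via
#'   \code{\link{extractRegion}}.
#' @param warmStart warm-start successive timepoints (default TRUE).
#' @param ... passed to \code{\link{fitRegion}}.
#' @return list of \linkS4class{FitResult}, ordered by timepoint.
#' @export
fitRegionSeries <- function(series, m, region = m@region, window = NULL,
                            warmStart = TRUE, ...) {
  sel <- Filter(function(s) s@region == region, series@spectra)
  if (!length(sel)) stop("no spectra for region ", region)
  out <- vector("list", length(sel))
  mCur <- m
  for (i in seq_along(sel)) {
    s <- sel[[i]]
    if (!is.null(window)) s <- extractRegion(s, window)
    fr <- fitRegion(s, mCur, ...)
    out[[i]] <- fr
    if (warmStart) mCur <- fr@model
  }
  out
}
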