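# Normalized time series and damage/hydration indices.
#
# All region intensities are normalized on the total P2p area at the same
# timepoint (phosphorus occurs exactly once per nucleotide, making P2p the
# internal reference), and expressed as a percentage of the region's total
# at the start of the irradiation.  Error propagation assumes independence
# between regions (they are acquired as separate scans); the P2p variance
# contribution is included in every ratio.

.fitRegionOf <- function(fr) fr@spectrumInfo$region
.fitTimeOf   <- function(fr) fr@spectrumInfo$timepoint

# total non-gas area of a fit and its sigma (through the full covariance)
.totalArea <- function(fr, gasExcluded = TRUE) {
  ca <- fr@componentAreas
  keep <- if (gasExcluded) !ca$isGasPhase else rep(TRUE, nrow(ca))
  tot <- sum(ca$area[keep])
  if (length(fr@parNames)) {
    u <- colSums(fr@areaJacobian[keep, , drop = FALSE])
    sig <- sqrt(max(drop(t(u) %*% fr@covariance %*% u), 0))
  } else sig <- 0
  c(total = tot, sigma = sig)
}

#' P2p-normalized area time series
#'
#' Converts per-timepoint fit results into, per region, the time series of
#' normalized areas (component area / total P2p area at the same timepoint)
#' and percent-of-initial values (normalized area as a percentage of the
#' region's non-gas total at the first timepoint), with propagated sigmas.
#' Gas-phase components are excluded from region totals (and from the
#' reference total) but their own series are reported.
#'
#' Timepoints without a usable reference fit are dropped with a warning.
#'
#' @param fits list of \linkS4class{FitResult} covering one condition:
#'   one fit per region per timepoint, including the reference region.
#' @param reference reference region label (default \code{"P2p"}).
#' @return named list of \linkS4class{AreaSeries}, one per non-reference
#'   region (the reference region's own series is included last).
#' @export
normalizeSeries <- function(fits, reference = "P2p") {
  regs <- vapply(fits, .fitRegionOf, character(1))
  tps  <- vapply(fits, .fitTimeOf, numeric(1))
  if (!any(regs == reference))
    stop("no fits for reference region ", reference)
  refFits <- fits[regs == reference]
  refT <- tps[regs == reference]
  refTot <- vapply(refFits, .totalArea, numeric(2))
  ok <- refTot["total", ] > 0
  if (!all(ok)) {
    warning("dropping timepoints with nonpositive reference area: ",
            paste(refT[!ok], collapse = ", "))
    refFits <- refFits[ok]; refT <- refT[ok]
    refTot <- refTot[, ok, drop = FALSE]
  }
  out <- list()
  for (r in unique(regs)) {
    rf <- fits[regs == r]
    rt <- tps[regs == r]
    keep <- rt %in% refT
    if (!all(keep)) {
      warning(sprintf("region %s: dropping timepoints without reference: %s",
                      r, paste(rt[!keep], collapse = ", ")))
      rf <- rf[keep]; rt <- rt[keep]
    }
    if (!length(rf)) next
    rows <- list()
    for (i in seq_along(rf)) {
      fr <- rf[[i]]
      ip <- match(rt[i], refT)
      pTot <- refTot["total", ip]; pSig <- refTot["sigma", ip]
      ca <- fr@componentAreas
      normA <- ca$area / pTot
      relP2 <- (pSig / pTot)^2
      normS <- sqrt((ca$sigma / pTot)^2 + normA^2 * relP2)
      rows[[i]] <- data.frame(
        timepoint = rt[i], component = ca$label, isGasPhase = ca$isGasPhase,
        normalizedArea = normA, normalizedSigma = normS,
        stringsAsFactors = FALSE)
    }
    d <- do.call(rbind, rows)
    t0 <- min(d$timepoint)
    d0 <- d[d$timepoint == t0 & !d$isGasPhase, ]
    s0 <- sum(d0$normalizedArea)
    s0sig <- sqrt(sum(d0$normalizedSigma^2))
    if (s0 <= 0) stop("region ", r, ": nonpositive total at first timepoint")
    d$percentOfInitial <- 100 * d$normalizedArea / s0
    relS0 <- (s0sig / s0)^2
    d$percentSigma <- ifelse(
      d$normalizedArea > 0,
      d$percentOfInitial * sqrt((d$normalizedSigma / d$normalizedArea)^2 +
                                  relS0),
      100 * d$normalizedSigma / s0)
    rownames(d) <- NULL
    out[[r]] <- new("AreaSeries", region = r, data = d)
  }
  out
}

# start/end value and sigma of a (summed) normalized-area series
.startEnd <- function(d, method = "endpoint") {
  agg <- stats::aggregate(cbind(v = d$normalizedArea,
                                s2 = d$normalizedSigma^2),
                          by = list(timepoint = d$timepoint), FUN = sum)
  agg <- agg[order(agg$timepoint), ]
  if (nrow(agg) < 2L) stop("need at least two timepoints")
  if (method == "trend") {
    fitv <- stats::lm(v ~ timepoint, data = agg)
    pr <- stats::predict(fitv, newdata = data.frame(
      timepoint = c(agg$timepoint[1], agg$timepoint[nrow(agg)])),
      se.fit = TRUE)
    list(start = pr$fit[1], end = pr$fit[2],
         startSig = pr$se.fit[1], endSig = pr$se.fit[2])
  } else {
    list(start = agg$v[1], end = agg$v[nrow(agg)],
         startSig = sqrt(agg$s2[1]), endSig = sqrt(agg$s2[nrow(agg)]))
  }
}

.fractionalDecrease <- function(se) {
  if (se$start <= 0) stop("undefined index: start area <= 0")
  r <- se$end / se$start
  relSig <- sqrt(ifelse(se$end > 0, (se$endSig / se$end)^2, 0) +
                   (se$startSig / se$start)^2)
  c(value = 1 - r, sigma = abs(r) * relSig)
}

#' Strand-break index
#'
#' Fractional start-to-end decrease of the P2p-normalized C1s component at
#' 286 eV, the line carrying the backbone C-O-P bond whose cleavage marks
#' strand-break formation.
#'
#' @param series the C1s \linkS4class{AreaSeries}.
#' @param component component label (default \code{"C1s_286"}).
#' @param method \code{"endpoint"} (first vs last timepoint, default) or
#'   \code{"trend"} (endpoints of a straight-line fit through all
#'   timepoints).
#' @return c(value, sigma).
#' @export
strandBreakIndex <- function(series, component = "C1s_286",
                             method = c("endpoint", "trend")) {
  method <- match.arg(method)
  d <- seriesData(series)
  d <- d[d$component == component, ]
  if (!nrow(d))
    stop("component ", component, " not present in the series")
  .fractionalDecrease(.startEnd(d, method))
}

#' Base-damage index
#'
#' Fractional start-to-end decrease of the summed non-gas N1s signal
#' (nitrogen occurs exclusively in the nucleobases, so total-N loss tracks
#' base damage and base release).
#'
#' @param series the N1s \linkS4class{AreaSeries}.
#' @param method as in \code{\link{strandBreakIndex}}.
#' @return c(value, sigma).
#' @export
baseDamageIndex <- function(series, method = c("endpoint", "trend")) {
  method <- match.arg(method)
  d <- seriesData(series)
  d <- d[!d$isGasPhase, ]
  if (!nrow(d)) stop("no non-gas N1s components in the series")
  .fractionalDecrease(.startEnd(d, method))
}

#' Water molecules per nucleotide
#'
#' Sensitivity-corrected O1s-water to P2p intensity ratio.  With one
#' phosphorus atom per nucleotide (the conversion assumption), the
#' RSF-corrected atomic ratio O(water) : P equals the number of water
#' molecules per nucleotide.
#'
#' @param o1sFit \linkS4class{FitResult} of the O1s region containing a
#'   water component.
#' @param p2pFit \linkS4class{FitResult} of the P2p doublet.
#' @param rsf named numeric with entries \code{O1s} and \code{P2p}
#'   (relative sensitivity factors), e.g. \code{defaultRsf()}.
#' @param waterLabel label of the water component (default: the first
#'   component whose group is \code{"Water"}).
#' @return c(value, sigma).
#' @export
waterPerNucleotide <- function(o1sFit, p2pFit, rsf = defaultRsf(),
                               waterLabel = NULL) {
  if (!all(c("O1s", "P2p") %in% names(rsf)))
    stop("configuration error: rsf table must provide 'O1s' and 'P2p'")
  if (is.null(waterLabel)) {
    grp <- vapply(o1sFit@model@components, function(p) p@group, character(1))
    wi <- which(grp == "Water")
    if (!length(wi)) stop("no water component in the O1s model")
    waterLabel <- o1sFit@model@components[[wi[1]]]@label
  }
  ca <- o1sFit@componentAreas
  i <- match(waterLabel, ca$label)
  if (is.na(i)) stop("water component ", waterLabel, " not in the fit")
  aw <- ca$area[i]; sw <- ca$sigma[i]
  pt <- .totalArea(p2pFit, gasExcluded = TRUE)
  if (pt["total"] <= 0) stop("nonpositive P2p area")
  v <- (aw / rsf[["O1s"]]) / (pt["total"] / rsf[["P2p"]])
  rel <- sqrt(ifelse(aw > 0, (sw / aw)^2, 0) +
                (pt["sigma"] / pt["total"])^2)
  sig <- if (aw > 0) v * rel else
    (sw / rsf[["O1s"]]) / (pt["total"] / rsf[["P2p"]])
  c(value = unname(v), sigma = unname(sig))
}

#' Assemble a damage report
#'
#' @param series named list of \linkS4class{AreaSeries} as returned by
#'   \code{\link{normalizeSeries}} (must contain C1s and N1s).
#' @param o1sFit,p2pFit optional fits for the water-per-nucleotide index.
#' @param rsf sensitivity-factor table for the water index.
#' @param condition condition metadata stored in the report.
#' @param method index method, see \code{\link{strandBreakIndex}}.
#' @return a \linkS4class{DamageReport}.
#' @export
damageReport <- function(series, o1sFit = NULL, p2pFit = NULL,
                         rsf = defaultRsf(), condition = list(),
                         method = "endpoint") {
  sb <- strandBreakIndex(series[["C1s"]], method = method)
  bd <- baseDamageIndex(series[["N1s"]], method = method)
  wpn <- if (!is.null(o1sFit) && !is.null(p2pFit))
    waterPerNucleotide(o1sFit, p2pFit, rsf) else
      c(value = NA_real_, sigma = NA_real_)
  ratios <- do.call(rbind, lapply(names(series), function(r) {
    d <- seriesData(series[[r]])
    do.call(rbind, lapply(unique(d$component), function(cc) {
      dc <- d[d$component == cc, ]
      if (length(unique(dc$timepoint)) < 2L) return(NULL)
      se <- .startEnd(dc, "endpoint")
      if (se$start <= 0) return(NULL)
      fd <- .fractionalDecrease(se)
      data.frame(region = r, component = cc, ratio = 1 - fd[["value"]],
                 sigma = fd[["sigma"]], stringsAsFactors = FALSE)
    }))
  }))
  new("DamageReport", condition = condition, strandBreak = sb,
      baseDamage = bd, waterPerNucleotide = wpn,
      endStartRatios = ratios %||% data.frame())
}

#' Relative sensitivity factors for Al K-alpha quantification
#'
#' Reads the shipped RSF table (relative photoionization cross sections at
#' 1486.6 eV, C1s = 1; see the table's provenance header) or a user table
#' with columns \code{line} and \code{rsf}.
#'
#' @param path TSV with columns \code{line}, \code{rsf}; default: the
#'   shipped table.
#' @return named numeric vector of sensitivity factors.
#' @export
readRsf <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("line", "rsf") %in% names(tab)))
    stop("configuration error: rsf table needs columns 'line' and 'rsf'")
  setNames(tab$rsf, tab$line)
}

#' @rdname readRsf
#' @export
defaultRsf <- function() {
  readRsf(system.file("extdata", "rsf_alka.tsv", package = "xpsdamage",
                      mustWork = TRUE))
}
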