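# Desk-scale photon + secondary-electron transport in a layered slab.
#
# Photon physics at 1.4 keV is photoelectric absorption only (the dominant
# inelastic channel at this energy); free paths are sampled from layer-wise
# exponential attenuation at normal incidence.  At a photoelectric event in
# a condensed layer the mean core-level binding energy is deposited at the
# absorption site (the Auger relaxation cascade is short-ranged on the
# scale of the scoring layer) and the photoelectron carries the remainder,
# emitted with the unpolarized dipole angular distribution about the beam
# axis (sin^2 theta, the beta = 2 pattern of the dominant s subshells).
# The photoelectron is transported as a straight track in the continuous-
# slowing-down approximation (density-scaled mass stopping power) until the
# energy cut, where it thermalizes and deposits the residual locally.  Both
# simplifications are switchable: photoelectronMode = "full" folds the
# binding energy into the track, angular = "isotropic" drops the dipole
# pattern.  Electrons born
# in gas layers are not propagated into the condensed stack: at mbar
# pressures elastic scattering randomizes their trajectories over mm paths,
# so straight-track delivery would be unphysical; their energy is tallied
# to the gas layer.  All tallies are restricted per region; the scoring
# region is the top of the film (the depth XPS probes).

.prepareGeometry <- function(g, energy, xsTable = NULL) {
  mats <- lapply(g@layers, `[[`, "material")
  th   <- vapply(g@layers, `[[`, numeric(1), "thickness")    # nm
  mu   <- vapply(mats, attenuationCoefficient, numeric(1), energy = energy,
                 table = xsTable)                            # 1/cm
  phase <- vapply(mats, function(m) m@phase, character(1))
  nl <- length(th)
  if (any(phase == "gas" & cumsum(phase == "condensed") > 0))
    stop("configuration error: gas layers must lie above all condensed layers")
  tau <- mu * th * 1e-7
  condIdx <- which(phase == "condensed")
  if (!length(condIdx)) {
    return(list(nLayers = nl, thickness = th, mu = mu, phase = phase,
                tau = tau, cumTau = cumsum(tau), condIdx = integer(0),
                gasOnly = TRUE))
  }
  rho <- vapply(mats, function(m) m@density, numeric(1))
  condTh <- th[condIdx]
  condRho <- rho[condIdx]
  condOffset <- c(0, cumsum(condTh))[seq_along(condIdx)]   # nm from cond. top
  Xmax <- sum(condTh)
  filmLayer <- nl
  xf <- Xmax - th[filmLayer]                  # film top, nm from cond. top
  ts <- g@scoringDepth
  # region boundaries within the condensed stack (nm)
  Rb <- sort(unique(c(0, cumsum(condTh), xf, xf + ts)))
  regName <- character(length(Rb) - 1L)
  for (j in seq_along(regName)) {
    mid <- (Rb[j] + Rb[j + 1]) / 2
    regName[j] <- if (mid < xf) "adsorbate"
      else if (mid < xf + ts) "scoring" else "filmBelow"
  }
  list(nLayers = nl, thickness = th, mu = mu, phase = phase, tau = tau,
       cumTau = cumsum(tau), condIdx = condIdx, condTh = condTh,
       condRho = condRho, condOffset = condOffset, Xmax = Xmax,
       xf = xf, ts = ts, Rb = Rb, regName = regName,
       mdSlope = condRho * 1e-7)              # g/cm^2 per nm in each segment
}

# mass depth (g/cm^2) from the top of the condensed stack, vectorized in x
.massDepth <- function(x, geo) {
  md <- numeric(length(x))
  b <- c(0, cumsum(geo$condTh))
  for (i in seq_along(geo$condTh))
    md <- md + geo$mdSlope[i] * pmin(pmax(x - b[i], 0), geo$condTh[i])
  md
}

#' Simulate normally incident photons through a slab geometry
#'
#' @param g a \linkS4class{SlabGeometry}.
#' @param n number of photon histories (>= 1).
#' @param energy photon energy, eV.
#' @param seed RNG seed; identical (seed, n, geometry) gives bitwise
#'   identical results.
#' @param electronTransport if FALSE the photon energy is deposited at the
#'   absorption point (pure-photon mode).
#' @param cut electron thermalization cut, eV.
#' @param photoelectronMode \code{"minus-binding"} (default): a mean core
#'   binding energy is deposited at the absorption site (local
#'   Auger-cascade proxy) and the photoelectron carries the remainder.
#'   \code{"full"}: the photoelectron carries the full photon energy.
#' @param meanBindingEnergy eV deposited locally in
#'   \code{"minus-binding"} mode; the default 400 eV is the
#'   cross-section-weighted mean core-edge energy of the DNA constituents.
#' @param angular photoelectron angular distribution about the beam axis:
#'   \code{"dipole"} (unpolarized beta = 2 pattern, default) or
#'   \code{"isotropic"}.
#' @param uniforms optional n-by-3 matrix of uniforms (gas survival,
#'   condensed-stack depth, photoelectron direction; used by
#'   \code{\link{compareAtmospheres}} for common random numbers; overrides
#'   \code{seed}).  Sampling the gas column and the condensed stack from
#'   separate streams keeps film histories identical across conditions,
#'   which is what makes the common-random-number contrast sharp.
#' @param details if TRUE, attach the per-history scoring-layer deposits as
#'   attribute \code{"histories"}.
#' @param xsTable optional cross-section table.
#' @return a \linkS4class{TransportResult}.
#' @export
simulatePhotons <- function(g, n, energy = 1486.6, seed = 1,
                            electronTransport = TRUE, cut = 20,
                            photoelectronMode = c("minus-binding", "full"),
                            meanBindingEnergy = 400,
                            angular = c("dipole", "isotropic"),
                            uniforms = NULL,
                            details = FALSE, xsTable = NULL) {
  angular <- match.arg(angular)
  stopifnot(is(g, "SlabGeometry"), n >= 1)
  photoelectronMode <- match.arg(photoelectronMode)
  geo <- .prepareGeometry(g, energy, xsTable)
  n <- as.integer(n)
  if (is.null(uniforms)) {
    set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
    uniforms <- cbind(stats::runif(n), stats::runif(n), stats::runif(n))
  }
  u1 <- uniforms[, 1]; u2 <- uniforms[, 2]; u3 <- uniforms[, 3]
  tauGasTot <- sum(geo$tau[geo$phase == "gas"])
  if (isTRUE(geo$gasOnly)) {
    absorbed <- -log(u1) < tauGasTot
    return(new("TransportResult",
      nHistories = n, energy = energy,
      meanDeposit = 0, meanDepositSE = 0,
      ionizationFraction = 0, ionizationFractionSE = 0,
      thermalizedElectrons = 0, thermalizedElectronsSE = 0,
      layerDeposits = c(gas = energy * mean(absorbed), adsorbate = 0,
                        scoring = 0, filmBelow = 0, escaped = 0,
                        transmitted = energy * mean(!absorbed)),
      seed = if (is.null(seed)) NA_real_ else seed))
  }
  # gas column and condensed stack are sampled from separate uniform
  # streams so that, under common random numbers, film histories are
  # identical across atmospheres except the few absorbed in the gas
  condTau <- geo$tau[geo$condIdx]
  cumCond <- cumsum(condTau)
  tauCondTot <- cumCond[length(cumCond)]
  inGas <- -log(u1) < tauGasTot
  tauC <- -log(u2)
  transmitted <- !inGas & tauC >= tauCondTot
  condLayer <- findInterval(tauC, c(0, cumCond), rightmost.closed = FALSE)

  depScoring <- numeric(n)
  depGas <- numeric(n); depAds <- numeric(n); depBelow <- numeric(n)
  escaped <- numeric(n); transDep <- numeric(n)
  ionized <- logical(n); thermal <- numeric(n)
  transDep[transmitted] <- energy
  depGas[inGas] <- energy

  inCond <- !transmitted & !inGas
  if (any(inCond)) {
    ci <- condLayer[inCond]                  # index within condensed stack
    li <- geo$condIdx[ci]                    # global layer index
    tauBefore <- c(0, cumCond)[ci]
    dNm <- (tauC[inCond] - tauBefore) / geo$mu[li] * 1e7  # nm inside layer
    x0 <- geo$condOffset[ci] + dNm
    isFilm <- li == geo$nLayers
    ionized[inCond] <- isFilm & (dNm <= geo$ts)

    if (!electronTransport) {
      reg <- findInterval(x0, geo$Rb, rightmost.closed = TRUE)
      reg <- pmin(pmax(reg, 1L), length(geo$regName))
      rn <- geo$regName[reg]
      depScoring[inCond] <- ifelse(rn == "scoring", energy, 0)
      depAds[inCond] <- ifelse(rn == "adsorbate", energy, 0)
      depBelow[inCond] <- ifelse(rn == "filmBelow", energy, 0)
    } else {
      e0 <- energy
      local0 <- 0
      if (photoelectronMode == "minus-binding") {
        local0 <- min(meanBindingEnergy, energy)
        e0 <- energy - local0
      }
      mu_d <- .sampleDirection(u3[inCond], angular)
      tr <- .trackElectrons(x0, mu_d, e0, cut, geo)
      depScoring[inCond] <- tr$scoring
      depAds[inCond] <- tr$adsorbate
      depBelow[inCond] <- tr$filmBelow
      escaped[inCond] <- tr$escaped
      thermal[inCond] <- tr$thermalScoring
      if (local0 > 0) {
        reg <- findInterval(x0, geo$Rb, rightmost.closed = TRUE)
        rn <- geo$regName[pmin(pmax(reg, 1L), length(geo$regName))]
        depScoring[inCond] <- depScoring[inCond] + (rn == "scoring") * local0
        depAds[inCond] <- depAds[inCond] + (rn == "adsorbate") * local0
        depBelow[inCond] <- depBelow[inCond] + (rn == "filmBelow") * local0
      }
    }
  }

  res <- new("TransportResult",
    nHistories = n, energy = energy,
    meanDeposit = mean(depScoring),
    meanDepositSE = stats::sd(depScoring) / sqrt(n),
    ionizationFraction = mean(ionized),
    ionizationFractionSE = sqrt(mean(ionized) * (1 - mean(ionized)) / n),
    thermalizedElectrons = mean(thermal),
    thermalizedElectronsSE = stats::sd(thermal) / sqrt(n),
    layerDeposits = c(gas = mean(depGas), adsorbate = mean(depAds),
                      scoring = mean(depScoring), filmBelow = mean(depBelow),
                      escaped = mean(escaped), transmitted = mean(transDep)),
    seed = if (is.null(seed)) NA_real_ else seed)
  if (details) attr(res, "histories") <- depScoring
  res
}

# Sample the direction cosine (relative to the beam/depth axis) of the
# photoelectron.  Dipole: pdf (3/4)(1 - mu^2) on [-1, 1], the unpolarized
# beta = 2 pattern; inverted in closed form via the trigonometric cubic
# root.  Isotropic: uniform in mu.
.sampleDirection <- function(u, angular) {
  if (angular == "isotropic") return(2 * u - 1)
  cc <- 2 - 4 * u                       # mu^3 - 3 mu + cc = 0, root in [-1,1]
  theta <- acos(pmin(pmax(cc / 2, -1), 1)) / 3
  2 * cos(theta + 4 * pi / 3)
}

# Straight-track CSDA transport of electrons born in the condensed stack.
# x0: birth depth (nm from condensed top); mu: direction cosine in (-1, 1);
# e0: initial kinetic energy (eV); cut: thermalization cut (eV).
.trackElectrons <- function(x0, mu, e0, cut, geo) {
  m <- length(x0)
  rt <- .rangeTable()
  R0 <- .rangeOfEnergy(e0, rt)
  P0 <- R0 - .rangeOfEnergy(cut, rt)          # usable mass path, g/cm^2
  cmu <- pmax(abs(mu), 1e-12)
  down <- mu >= 0
  md0 <- .massDepth(x0, geo)
  mdB <- .massDepth(geo$Rb, geo)              # at region boundaries
  Efun <- function(p) .energyOfRange(pmax(R0 - p, 0), rt)

  nReg <- length(geo$regName)
  dep <- matrix(0, m, nReg)
  for (j in seq_len(nReg)) {
    # mass path at which the track enters / leaves region j
    pLoB <- (mdB[j]     - md0) / cmu          # signed, for down-going
    pHiB <- (mdB[j + 1] - md0) / cmu
    paD <- pmin(pmax(pLoB, 0), P0); pbD <- pmin(pmax(pHiB, 0), P0)
    pLoU <- (md0 - mdB[j + 1]) / cmu          # for up-going
    pHiU <- (md0 - mdB[j]) / cmu
    paU <- pmin(pmax(pLoU, 0), P0); pbU <- pmin(pmax(pHiU, 0), P0)
    pa <- ifelse(down, paD, paU)
    pb <- ifelse(down, pbD, pbU)
    act <- pb > pa
    if (any(act))
      dep[act, j] <- Efun(pa[act]) - Efun(pb[act])
  }
  # exit mass path: bottom for down-going, surface for up-going
  pExit <- ifelse(down, (mdB[length(mdB)] - md0) / cmu, md0 / cmu)
  stops <- pExit >= P0
  escapedE <- ifelse(stops, 0, Efun(pExit))
  # stopping location and residual (cut) deposit
  thermalScoring <- numeric(m)
  if (any(stops)) {
    mdStop <- md0 + ifelse(down, 1, -1) * cmu * P0
    regStop <- findInterval(mdStop, mdB, rightmost.closed = TRUE)
    regStop <- pmin(pmax(regStop, 1L), nReg)
    idx <- which(stops)
    dep[cbind(idx, regStop[idx])] <- dep[cbind(idx, regStop[idx])] + cut
    thermalScoring[idx] <- as.numeric(geo$regName[regStop[idx]] == "scoring")
  }
  agg <- function(name) {
    cols <- which(geo$regName == name)
    if (!length(cols)) numeric(m) else rowSums(dep[, cols, drop = FALSE])
  }
  list(scoring = agg("scoring"), adsorbate = agg("adsorbate"),
       filmBelow = agg("filmBelow"), escaped = escapedE,
       thermalScoring = thermalScoring)
}

#' Closed-form charged-particle-equilibrium deposit estimate
#'
#' Gas/adsorbate transmission factor times \code{mu_film * scoringDepth *
#' energy}: under charged-particle equilibrium the energy deposited in a
#' thin scoring layer equals the photon energy absorbed in it.  Requires a
#' film much thicker than the scoring depth (ratio >= 5).
#'
#' @param g a \linkS4class{SlabGeometry}.
#' @param energy photon energy, eV.
#' @param xsTable optional cross-section table.
#' @return estimated mean deposit, eV per incident photon.
#' @export
analyticDepositEstimate <- function(g, energy = 1486.6, xsTable = NULL) {
  geo <- .prepareGeometry(g, energy, xsTable)
  film <- geo$nLayers
  if (geo$thickness[film] < 5 * geo$ts)
    stop("not applicable: film must be >= 5x the scoring depth; ",
         "use the Monte Carlo instead")
  trans <- exp(-sum(geo$tau[-film]))
  trans * geo$mu[film] * (geo$ts * 1e-7) * energy
}

#' Analytic photoionization fraction within the scoring depth
#'
#' Beer-Lambert: transmission through the layers above the film times
#' \code{1 - exp(-mu_film * scoringDepth)}.
#'
#' @inheritParams analyticDepositEstimate
#' @return fraction of incident photons.
#' @export
analyticIonizationFraction <- function(g, energy = 1486.6, xsTable = NULL) {
  geo <- .prepareGeometry(g, energy, xsTable)
  film <- geo$nLayers
  trans <- exp(-sum(geo$tau[-film]))
  trans * (1 - exp(-geo$mu[film] * geo$ts * 1e-7))
}

#' Compare transport tallies across atmospheres
#'
#' Runs the same photon transport through geometries differing only in
#' their gas (and adsorbate) layers, using common random numbers (the same
#' uniform stream per history index) to sharpen the contrast estimate.
#'
#' @param geometries named list of \linkS4class{SlabGeometry} (e.g. from
#'   \code{\link{defaultGeometry}} for vacuum/N2/H2O); their film layers
#'   and scoring depths must match.
#' @param n histories per condition.
#' @param seed RNG seed for the shared stream.
#' @param energy photon energy, eV.
#' @param ... passed to \code{\link{simulatePhotons}}.
#' @return list with elements \code{results} (named list of
#'   \linkS4class{TransportResult}), \code{maxRelDiff} (named numeric: max
#'   pairwise relative difference of meanDeposit, ionizationFraction,
#'   thermalizedElectrons) and \code{maxRelDiffSE} (standard error of the
#'   meanDeposit contrast at the maximizing pair, from the paired
#'   per-history differences).
#' @export
compareAtmospheres <- function(geometries, n, seed = 1, energy = 1486.6,
                               ...) {
  stopifnot(length(geometries) >= 2, !is.null(names(geometries)))
  films <- lapply(geometries, function(g) {
    ly <- g@layers[[length(g@layers)]]
    list(st = ly$material@stoichiometry, rho = ly$material@density,
         th = ly$thickness, ts = g@scoringDepth)
  })
  for (i in seq_along(films)[-1])
    if (!isTRUE(all.equal(films[[1]], films[[i]])))
      stop("configuration error: film layers differ across conditions")
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  U <- cbind(stats::runif(n), stats::runif(n), stats::runif(n))
  results <- lapply(geometries, simulatePhotons, n = n, energy = energy,
                    seed = seed, uniforms = U, details = TRUE, ...)
  tallies <- c(meanDeposit = "meanDeposit",
               ionizationFraction = "ionizationFraction",
               thermalizedElectrons = "thermalizedElectrons")
  maxRel <- setNames(numeric(length(tallies)), names(tallies))
  seAtMax <- NA_real_
  nms <- names(results)
  for (tl in names(tallies)) {
    best <- 0; bestSE <- NA_real_
    for (i in seq_along(nms)) for (j in seq_along(nms)) {
      if (j <= i) next
      a <- slot(results[[i]], tl); b <- slot(results[[j]], tl)
      mid <- (abs(a) + abs(b)) / 2
      rel <- if (mid > 0) abs(a - b) / mid else 0
      if (rel >= best) {
        best <- rel
        if (tl == "meanDeposit") {
          d <- attr(results[[i]], "histories") -
            attr(results[[j]], "histories")
          bestSE <- stats::sd(d) / sqrt(n) / max(mid, .Machine$double.eps)
        }
      }
    }
    maxRel[tl] <- best
    if (tl == "meanDeposit") seAtMax <- bestSE
  }
  list(results = results, maxRelDiff = maxRel, maxRelDiffSE = seAtMax)
}
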