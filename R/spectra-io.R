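# Reading/writing spectra and tabular outputs.
#
# Primary exchange format is delimited text: a '# key: value' header block
# followed by a two-column table (binding_energy, counts).  A minimal VAMAS
# (ISO 14976) reader covers single-block REGULAR-scan files and rejects
# everything else loudly.

#' Read a spectrum from file
#'
#' @param path file path.
#' @param dialect \code{"tsv"} (default), \code{"csv"}, or \code{"vamas"}.
#'   TSV/CSV files consist of an optional \code{# key: value} header block
#'   (keys: region, timepoint, atmosphere, excitation_energy) followed by a
#'   table with columns \code{binding_energy} and \code{counts}.  Row order
#'   is irrelevant.
#' @param region,timepoint,atmosphere override or supply metadata missing
#'   from the file.
#' @return a validated \linkS4class{Spectrum} with an ascending grid.
#' @export
readSpectrum <- function(path, dialect = c("tsv", "csv", "vamas"),
                         region = NULL, timepoint = NULL, atmosphere = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "vamas") return(.readVamas(path, region = region,
                                            timepoint = timepoint,
                                            atmosphere = atmosphere))
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3L) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  sep <- if (dialect == "csv") "," else "\t"
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop("format error: no table in ", path)
  tab <- utils::read.table(text = body, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("binding_energy", "counts") %in% names(tab)))
    stop("format error: columns 'binding_energy' and 'counts' required, got: ",
         paste(names(tab), collapse = ", "))
  be <- as.numeric(tab$binding_energy)
  y  <- as.numeric(tab$counts)
  if (anyNA(be) || anyNA(y)) stop("format error: non-numeric values in table")
  if (any(y < 0)) {
    bad <- which(y < 0)[1L]
    stop(sprintf("validation error: negative counts in row %d (BE = %g eV)",
                 bad, be[bad]))
  }
  Spectrum(
    region = region %||% meta$region %||%
      stop("region missing from header and not supplied"),
    bindingEnergy = be, counts = y,
    timepoint = as.numeric(timepoint %||% meta$timepoint %||% 0),
    atmosphere = atmosphere %||% meta$atmosphere %||% "vacuum",
    excitationEnergy = as.numeric(meta$excitation_energy %||% 1486.6),
    meta = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a spectrum as delimited text
#'
#' Writes the \code{# key: value} header block plus the two-column table.
#' \code{readSpectrum} on the result reproduces the object.
#'
#' @param s a \linkS4class{Spectrum}.
#' @param path output path.
#' @param dialect \code{"tsv"} or \code{"csv"}.
#' @param overwrite allow replacing an existing file.
#' @return \code{path}, invisibly.
#' @export
writeSpectrum <- function(s, path, dialect = c("tsv", "csv"),
                          overwrite = FALSE) {
  dialect <- match.arg(dialect)
  if (file.exists(path) && !overwrite)
    stop("file exists (use overwrite = TRUE): ", path)
  sep <- if (dialect == "csv") "," else "\t"
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    sprintf("# region: %s", s@region),
    sprintf("# timepoint: %.17g", s@timepoint),
    sprintf("# atmosphere: %s", s@atmosphere),
    sprintf("# excitation_energy: %.17g", s@excitationEnergy),
    paste("binding_energy", "counts", sep = sep),
    paste(sprintf("%.17g", s@bindingEnergy), sprintf("%.17g", s@counts),
          sep = sep)), con)
  invisible(path)
}

#' Extract a binding-energy window
#'
#' Returns the grid points with \code{window[1] <= BE <= window[2]} (closed
#' on both ends).  The window must overlap the grid by at least 8 points.
#'
#' @param s a \linkS4class{Spectrum}.
#' @param window numeric length 2, eV.
#' @return a \linkS4class{Spectrum} restricted to the window.
#' @export
extractRegion <- function(s, window) {
  stopifnot(is(s, "Spectrum"), length(window) == 2L)
  window <- sort(as.numeric(window))
  keep <- s@bindingEnergy >= window[1] & s@bindingEnergy <= window[2]
  if (!any(keep))
    stop(sprintf("window error: [%g, %g] eV does not intersect the %s grid",
                 window[1], window[2], s@region))
  if (sum(keep) < 8L)
    stop(sprintf("window error: only %d grid points in window (need >= 8)",
                 sum(keep)))
  Spectrum(s@region, s@bindingEnergy[keep], s@counts[keep], s@timepoint,
           s@atmosphere, s@excitationEnergy, s@meta)
}

# ---- tabular outputs -------------------------------------------------------

.areaSeriesFrame <- function(seriesList) {
  do.call(rbind, lapply(seriesList, function(as) {
    d <- as@data
    cbind(data.frame(region = as@region, stringsAsFactors = FALSE), d)
  }))
}

#' Write the analysis report
#'
#' Writes the time-resolved area series as TSV, the damage report as JSON,
#' and a small JSON manifest.  Reading a written table back reproduces its
#' values to full stored precision.
#'
#' @param series list of \linkS4class{AreaSeries} (may be empty).
#' @param report a \linkS4class{DamageReport}, or NULL.
#' @param dir output directory (created if needed).
#' @param overwrite allow replacing existing files.
#' @return named character vector of the files written, invisibly.
#' @export
writeReport <- function(series, report = NULL, dir, overwrite = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c(areaSeries = file.path(dir, "area_series.tsv"),
             damageReport = file.path(dir, "damage_report.json"),
             manifest = file.path(dir, "report_manifest.json"))
  if (!overwrite) {
    ex <- files[file.exists(files)]
    if (is.null(report)) ex <- setdiff(ex, files[["damageReport"]])
    if (length(ex))
      stop("output exists (use overwrite = TRUE): ", paste(ex, collapse = ", "))
  }
  cols <- c("region", "timepoint", "component", "isGasPhase",
            "normalizedArea", "normalizedSigma", "percentOfInitial",
            "percentSigma")
  if (length(series)) {
    df <- .areaSeriesFrame(series)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  } else {
    df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  }
  utils::write.table(df, files[["areaSeries"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  written <- files[c("areaSeries", "manifest")]
  if (!is.null(report)) {
    jsonlite::write_json(damageReportAsList(report), files[["damageReport"]],
                         auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
    written <- files
  }
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package = as.character(utils::packageVersion("xpsdamage")),
    files = as.list(basename(setdiff(written, files[["manifest"]]))))
  jsonlite::write_json(manifest, files[["manifest"]], auto_unbox = TRUE)
  invisible(written)
}

#' @rdname writeReport
#' @param report a \linkS4class{DamageReport}.
#' @export
damageReportAsList <- function(report) {
  list(
    condition = report@condition,
    strand_break_index = list(value = unname(report@strandBreak[1]),
                              sigma = unname(report@strandBreak[2])),
    base_damage_index = list(value = unname(report@baseDamage[1]),
                             sigma = unname(report@baseDamage[2])),
    water_per_nucleotide = list(value = unname(report@waterPerNucleotide[1]),
                                sigma = unname(report@waterPerNucleotide[2])),
    end_start_ratios = report@endStartRatios)
}

#' Read back a written area-series table
#'
#' @param path the \code{area_series.tsv} written by \code{writeReport}.
#' @return list of \linkS4class{AreaSeries}, one per region (empty list for
#'   a header-only file).
#' @export
readAreaSeries <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!nrow(tab)) return(list())
  lapply(split(tab, tab$region), function(d) {
    rg <- d$region[1]
    d$region <- NULL
    rownames(d) <- NULL
    new("AreaSeries", region = rg, data = d)
  })
}

# ---- minimal VAMAS (ISO 14976) subset --------------------------------------

# Single-block, NORM experiment mode, REGULAR scan mode only.
.readVamas <- function(path, region = NULL, timepoint = NULL,
                       atmosphere = NULL) {
  lines <- readLines(path, warn = FALSE)
  cur <- new.env(parent = emptyenv()); cur$i <- 0L
  nxt <- function() { cur$i <- cur$i + 1L
    if (cur$i > length(lines)) stop("VAMAS error: truncated file")
    trimws(lines[cur$i]) }
  nxtNum <- function() { v <- suppressWarnings(as.numeric(nxt()))
    if (is.na(v)) stop("VAMAS error: expected a number at line ", cur$i); v }
  nxtInt <- function() as.integer(nxtNum())

  if (!grepl("VAMAS Surface Chemical Analysis Standard Data Transfer Format",
             nxt(), fixed = TRUE))
    stop("VAMAS error: missing format identifier line")
  for (k in 1:4) nxt()                      # institution..experiment ids
  nc <- nxtInt(); for (k in seq_len(nc)) nxt()   # experiment comment
  mode <- nxt()
  if (mode != "NORM")
    stop("VAMAS error: only experiment mode NORM is supported, got ", mode)
  scan <- nxt()
  if (scan != "REGULAR")
    stop("VAMAS error: only scan mode REGULAR is supported, got ", scan)
  nxtInt()                                  # number of spectral regions
  nev <- nxtInt()                           # experimental variables
  if (nev != 0L)
    stop("VAMAS error: experimental variables are not supported")
  nincl <- nxtInt()
  if (nincl != 0L)
    stop("VAMAS error: parameter inclusion lists are not supported")
  nman <- nxtInt(); if (nman != 0L)
    stop("VAMAS error: manually entered items are not supported")
  nupE <- nxtInt(); nupB <- nxtInt()
  if (nupE != 0L || nupB != 0L)
    stop("VAMAS error: future-upgrade entries are not supported")
  nblocks <- nxtInt()
  if (nblocks != 1L)
    stop("VAMAS error: only single-block files are supported, got ",
         nblocks, " blocks")

  nxt()                                     # block identifier
  nxt()                                     # sample identifier
  for (k in 1:7) nxt()                      # date/time + GMT offset
  nc <- nxtInt(); for (k in seq_len(nc)) nxt()   # block comment
  tech <- nxt()
  if (tech != "XPS") stop("VAMAS error: only technique XPS is supported")
  nxt()                                     # source label
  exciteE <- nxtNum()                       # characteristic energy (eV)
  for (k in 1:5) nxt()       # source strength, beam widths, angles
  nxt()                      # analyser mode
  nxtNum()                   # pass energy
  nxtNum()                   # transfer-lens magnification
  nxtNum()                   # work function
  nxtNum()                   # target bias
  for (k in 1:4) nxt()       # analysis widths + take-off angles
  species <- nxt()
  transition <- nxt()
  nxtNum()                   # charge of detected particle
  absLabel <- tolower(nxt())
  absUnits <- nxt()
  if (!grepl("binding", absLabel) || absUnits != "eV")
    stop("VAMAS error: only a binding-energy abscissa in eV is supported")
  absStart <- nxtNum()
  absIncr  <- nxtNum()
  ncorr <- nxtInt()
  if (ncorr < 1L) stop("VAMAS error: no corresponding variables")
  for (k in seq_len(ncorr)) { nxt(); nxt() }  # labels + units
  nxt()                      # signal mode
  nxtNum()                   # dwell
  nxtNum()                   # number of scans
  nxtNum()                   # time correction
  for (k in 1:3) nxt()       # sample tilt/rotation
  npar <- nxtInt(); for (k in seq_len(3L * npar)) nxt()
  nOrd <- nxtInt()
  if (nOrd %% ncorr != 0L)
    stop("VAMAS error: ordinate count not divisible by variable count")
  npts <- nOrd %/% ncorr
  for (k in seq_len(2L * ncorr)) nxtNum()   # min/max per variable
  vals <- numeric(nOrd)
  for (k in seq_len(nOrd)) vals[k] <- nxtNum()
  counts <- vals[seq(1L, nOrd, by = ncorr)]
  be <- absStart + absIncr * (seq_len(npts) - 1L)
  Spectrum(
    region = region %||% paste0(gsub("\\s+", "", species),
                                gsub("\\s+", "", transition)),
    bindingEnergy = be, counts = counts,
    timepoint = timepoint %||% 0,
    atmosphere = atmosphere %||% "vacuum",
    excitationEnergy = exciteE,
    meta = list(source = "vamas", file = basename(path)))
}
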