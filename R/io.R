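# Container I/O, map export and the command-line surface.

#' Write / read a decay cube container
#'
#' Serializes the cube (counts, grid metadata, optional truth and IRF)
#' to a single schema-checked archive. The round trip is lossless
#' (bit-exact counts). A file without an IRF reads fine, but
#' estimation functions, which all require an IRF, will then refuse.
#'
#' @param cube a [DecayCube-class].
#' @param path file path.
#' @param irf optional [InstrumentResponse-class] stored alongside.
#' @return `readDecayCube` returns a list with `cube` and `irf`
#'   (NULL when the file carries none).
#' @export
writeDecayCube <- function(cube, path, irf = NULL) {
  stopifnot(is(cube, "DecayCube"))
  obj <- list(schema = "flimkit-decay-cube", version = 1L,
              counts = cube@counts, n_bins = nBins(cube),
              period_ns = period(cube), rate = cube@rate)
  if (length(cube@truth)) {
    d <- dim(cube)
    obj$truth <- list(alpha1 = matrix(alpha1(cube@truth), d[1], d[2]),
                      tau1 = matrix(tau1(cube@truth), d[1], d[2]),
                      tau2 = matrix(tau2(cube@truth), d[1], d[2]))
  }
  if (!is.null(irf)) {
    obj$irf <- irfWeights(irf)
    obj$irf_fwhm <- irf@fwhm
    obj$irf_onset <- irf@onset
  }
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname writeDecayCube
#' @export
readDecayCube <- function(path) {
  obj <- tryCatch(suppressWarnings(readRDS(path)), error = function(e)
    stop("unreadable or truncated decay-cube file: ", conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$schema, "flimkit-decay-cube"))
    stop("not a flimkit decay-cube archive (missing key 'schema')")
  for (key in c("counts", "period_ns", "n_bins"))
    if (is.null(obj[[key]]))
      stop(sprintf("malformed decay-cube archive: missing key '%s'", key))
  grid <- histogramGrid(obj$n_bins, obj$period_ns)
  truth <- if (!is.null(obj$truth))
    lifetimeParams(as.vector(obj$truth$alpha1), as.vector(obj$truth$tau1),
                   as.vector(obj$truth$tau2))
    else lifetimeParams(numeric(0), numeric(0), numeric(0))
  cube <- decayCube(obj$counts, grid = grid, truth = truth,
                    rate = if (is.null(obj$rate)) NA_real_ else obj$rate)
  irf <- if (!is.null(obj$irf)) irfFromWeights(obj$irf, grid) else NULL
  list(cube = cube, irf = irf)
}

#' Export a single decay histogram as CSV
#'
#' Columns `bin_center_ns,count`.
#'
#' @param h a [DecayHistogram-class].
#' @param path file path.
#' @return the path, invisibly.
#' @export
writeHistogramCSV <- function(h, path) {
  utils::write.csv(data.frame(bin_center_ns = binCenters(h),
                              count = counts(h)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Export lifetime maps as float TIFFs, a mask TIFF and a pseudocolor PNG
#'
#' Each map plane is written as a 32-bit float TIFF in ns; failed pixels
#' (mask TRUE, including estimates clamped at the lifetime ceiling) are
#' written to an 8-bit mask TIFF and rendered white in the pseudocolor
#' PNG, which maps `[0, tau_ceiling]` ns onto a perceptually uniform
#' palette.
#'
#' @param maps named list of numeric H x W matrices (as produced by
#'   [fitCube()] / [inferImage()]); the `tau_apparent` plane drives the
#'   pseudocolor rendering.
#' @param mask logical H x W matrix of failed pixels (NULL = none).
#' @param path_prefix output path prefix.
#' @param tau_ceiling color-scale ceiling in ns (default 6).
#' @return character vector of the files written.
#' @export
exportFlimMaps <- function(maps, mask = NULL, path_prefix,
                           tau_ceiling = 6) {
  planes <- maps[vapply(maps, is.numeric, logical(1))]
  if (!length(planes)) stop("no numeric map planes to export")
  d <- dim(planes[[1]])
  if (is.null(mask)) mask <- matrix(FALSE, d[1], d[2])
  mask <- mask | Reduce(`|`, lapply(planes, function(p) !is.finite(p)))
  files <- character(0)
  for (nm in names(planes)) {
    p <- planes[[nm]]
    p[!is.finite(p)] <- 0
    f <- paste0(path_prefix, "_", nm, ".tif")
    tiff::writeTIFF(p / tau_ceiling, f, bits.per.sample = 32L)
    files <- c(files, f)
  }
  fm <- paste0(path_prefix, "_failed_mask.tif")
  tiff::writeTIFF(matrix(as.numeric(mask), d[1], d[2]), fm,
                  bits.per.sample = 8L)
  files <- c(files, fm)
  ta <- planes[[if ("tau_apparent" %in% names(planes)) "tau_apparent"
                else 1L]]
  ta[!is.finite(ta)] <- 0
  pal <- grDevices::hcl.colors(256, "viridis")
  idx <- pmin(pmax(round(ta / tau_ceiling * 255) + 1, 1), 256)
  rgbv <- grDevices::col2rgb(pal[idx]) / 255
  img <- array(0, c(d[1], d[2], 3))
  for (k in 1:3) {
    plane <- matrix(rgbv[k, ], d[1], d[2])
    plane[mask] <- 1      # failed pixels render white
    img[, , k] <- plane
  }
  fp <- paste0(path_prefix, "_pseudocolor.png")
  png::writePNG(img, fp)
  c(files, fp)
}

#' Read a float TIFF map written by [exportFlimMaps()] back to ns
#'
#' @param path TIFF path.
#' @param tau_ceiling the ceiling the map was scaled with.
#' @return numeric matrix in ns.
#' @export
readFlimMap <- function(path, tau_ceiling = 6) {
  tiff::readTIFF(path) * tau_ceiling
}

# ---- run configuration ----

#' Read and validate a run configuration YAML
#'
#' A run is reproducible from (config, seed) alone. Recognized keys
#' (all optional, with defaults): `grid: {n_bins, period}`,
#' `irf: {fwhm, onset}`, `pattern: {height, width, fg, bg}` where fg/bg
#' hold `{alpha1, tau1, tau2}`, and `rate`.
#'
#' @param path YAML file path.
#' @return a validated config list.
#' @export
readRunConfig <- function(path) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  grid <- histogramGrid(cfg$grid$n_bins %||% 256L,
                        cfg$grid$period %||% 50)
  irf <- gaussianIRF(grid, fwhm = cfg$irf$fwhm %||% 0.5,
                     onset = cfg$irf$onset %||% 5)
  pat <- cfg$pattern
  fg <- if (is.null(pat$fg)) lifetimeParams(0.5, 1.5, 3.5)
        else lifetimeParams(pat$fg$alpha1, pat$fg$tau1, pat$fg$tau2)
  bg <- if (is.null(pat$bg)) lifetimeParams(0.8, 1.0, 3.0)
        else lifetimeParams(pat$bg$alpha1, pat$bg$tau1, pat$bg$tau2)
  pattern <- glyphPattern(pat$height %||% 14L, pat$width %||% 47L,
                          fg = fg, bg = bg)
  list(grid = grid, irf = irf, pattern = pattern,
       rate = cfg$rate %||% 150)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- command-line surface ----

.cliUsage <- function() {
  cat(paste0(
    "usage: flimkit <simulate|estimate|metrics|benchmark> [options]\n",
    "  simulate  --out FILE [--config YAML] [--seed N]\n",
    "  estimate  --input CUBE --out PREFIX [--method td_mle|td_lse|dfd_lse|gan]\n",
    "            [--bundle FILE]\n",
    "  metrics   --ref TIFF --test TIFF --out JSON\n",
    "  benchmark --out CSV [--config YAML] [--seed N] [--rates 50,150,1500]\n",
    "            [--methods td_mle,td_lse,dfd_lse]\n"))
  invisible(2L)
}

.cliArgs <- function(argv) {
  out <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    if (i == length(argv)) stop("missing value for ", a)
    out[[substring(a, 3)]] <- argv[i + 1L]
    i <- i + 2L
  }
  out
}

#' Command-line entry point
#'
#' Thin dispatcher over the package's functions; see the `flimkit`
#' script in `inst/scripts`. Subcommands: `simulate` (glyph-pattern
#' benchmark cube), `estimate` (per-pixel lifetime maps + CSV + TIFF/PNG
#' export), `metrics` (quality report between two maps), `benchmark`
#' (MSE table over methods x photon rates).
#'
#' @param argv character vector of command-line arguments.
#' @return integer exit code (0 success, 2 usage error, 1 failure).
#' @export
cliMain <- function(argv) {
  if (!length(argv) ||
      !argv[1] %in% c("simulate", "estimate", "metrics", "benchmark"))
    return(.cliUsage())
  cmd <- argv[1]
  code <- tryCatch({
    opt <- .cliArgs(argv[-1])
    seed <- as.integer(opt$seed %||% "1")
    switch(cmd,
      simulate = {
        cfg <- readRunConfig(opt$config)
        cube <- simulateBenchmarkImage(cfg$pattern, rate = cfg$rate,
                                       irf = cfg$irf, seed = seed)
        writeDecayCube(cube, opt$out, irf = cfg$irf)
        message("wrote ", opt$out)
      },
      estimate = {
        rd <- readDecayCube(opt$input)
        if (is.null(rd$irf))
          stop("cube file carries no IRF: estimation refused")
        method <- opt$method %||% "td_mle"
        maps <- if (method == "gan") {
          if (is.null(opt$bundle)) stop("--bundle is required for gan")
          inferImage(loadBundle(opt$bundle), rd$cube, rd$irf)
        } else {
          fitCube(rd$cube, rd$irf, method = method)
        }
        exportFlimMaps(maps, maps$failed, opt$out)
        df <- data.frame(
          pixel = seq_along(maps$tau_apparent),
          tau_apparent = as.vector(maps$tau_apparent),
          alpha1 = as.vector(maps$alpha1),
          tau1 = as.vector(maps$tau1), tau2 = as.vector(maps$tau2),
          failed = as.vector(maps$failed))
        utils::write.csv(df, paste0(opt$out, "_fits.csv"),
                         row.names = FALSE)
        message("wrote ", opt$out, "_*")
      },
      metrics = {
        a <- readFlimMap(opt$ref); b <- readFlimMap(opt$test)
        rep <- qualityReport(b, a)
        # JSON has no Inf: identical images give an infinite PSNR
        rep <- lapply(rep, function(v)
          if (is.numeric(v) && !is.finite(v)) as.character(v) else v)
        jsonlite::write_json(rep, opt$out, auto_unbox = TRUE, digits = NA)
        message("wrote ", opt$out)
      },
      benchmark = {
        cfg <- readRunConfig(opt$config)
        rates <- as.numeric(strsplit(opt$rates %||% "50,150,1500",
                                     ",")[[1]])
        methods <- strsplit(opt$methods %||% "td_mle,td_lse,dfd_lse",
                            ",")[[1]]
        rows <- list()
        for (r in rates) {
          cube <- simulateBenchmarkImage(cfg$pattern, rate = r,
                                         irf = cfg$irf, seed = seed)
          truth <- matrix(apparentLifetime(truthParams(cube)),
                          dim(cube)[1], dim(cube)[2])
          for (m in methods) {
            maps <- fitCube(cube, cfg$irf, method = m)
            rows[[length(rows) + 1L]] <- data.frame(
              method = m, rate = r,
              mse = mseMap(maps$tau_apparent, truth)$mean)
          }
        }
        utils::write.csv(do.call(rbind, rows), opt$out,
                         row.names = FALSE)
        message("wrote ", opt$out)
      })
    0L
  }, error = function(e) {
    message("flimkit ", cmd, ": ", conditionMessage(e))
    1L
  })
  code
}
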