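#' FID series container
#'
#' A time-resolved NMR acquisition: one complex free-induction decay per
#' transient block, with the acquisition metadata needed for processing and
#' for T1 saturation correction.
#'
#' @param blocks complex matrix (blocks x points) of time-domain samples, or
#'   a complex vector for a single block.
#' @param sw spectral width, Hz. The dwell time is `1/sw`.
#' @param sfrq spectrometer frequency for the observed nucleus, MHz.
#' @param timestamps block midpoint times, min; strictly increasing.
#' @param acq_time acquisition time per transient, s.
#' @param relax_delay relaxation delay per transient, s.
#' @param pulse_angle pulse angle, degrees.
#' @param transients transients co-added per FID block.
#' @return An object of class `fid_series`.
#' @export
fid_series <- function(blocks, sw, sfrq, timestamps,
                       acq_time = NULL, relax_delay = 0, pulse_angle = 90,
                       transients = 1) {
  if (is.vector(blocks)) blocks <- matrix(blocks, nrow = 1L)
  if (!is.complex(blocks)) storage.mode(blocks) <- "complex"
  if (sw <= 0 || sfrq <= 0) stop("'sw' and 'sfrq' must be positive")
  if (length(timestamps) != nrow(blocks))
    stop("one timestamp per block required")
  if (nrow(blocks) > 1L && any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing")
  if (is.null(acq_time)) acq_time <- ncol(blocks) / sw
  structure(list(blocks = blocks, sw = sw, dwell = 1 / sw, sfrq = sfrq,
                 timestamps = as.numeric(timestamps), acq_time = acq_time,
                 relax_delay = relax_delay, pulse_angle = pulse_angle,
                 transients = transients),
            class = "fid_series")
}

#' @export
print.fid_series <- function(x, ...) {
  cat(sprintf("FID series: %d block(s) x %d points, sw %.0f Hz, sfrq %.2f MHz\n",
              nrow(x$blocks), ncol(x$blocks), x$sw, x$sfrq))
  cat(sprintf("repetition %.2f s (%.2f acq + %.2f relax), %d transients, %g deg\n",
              x$acq_time + x$relax_delay, x$acq_time, x$relax_delay,
              x$transients, x$pulse_angle))
  invisible(x)
}

#' Exponential apodization (line broadening)
#'
#' Multiplies every FID block by the decaying envelope `exp(-pi * lb * t)`,
#' adding `lb` Hz to the Lorentzian line width in exchange for
#' signal-to-noise. `lb = 0` is the identity and the first sample (t = 0) is
#' always unchanged.
#'
#' @param fid a [fid_series()].
#' @param lb line broadening, Hz (>= 0).
#' @return The apodized `fid_series`.
#' @export
apodize_exponential <- function(fid, lb) {
  stopifnot(inherits(fid, "fid_series"))
  if (!is.numeric(lb) || length(lb) != 1L || lb < 0)
    stop("'lb' must be a single non-negative number")
  t <- (seq_len(ncol(fid$blocks)) - 1L) * fid$dwell
  env <- exp(-pi * lb * t)
  fid$blocks <- sweep(fid$blocks, 2L, env, `*`)
  fid
}

#' Spectrum container
#'
#' @param ppm chemical-shift axis, ppm, monotone descending.
#' @param intensity real intensities, same length as `ppm`.
#' @param sfrq spectrometer frequency, MHz (for Hz conversions).
#' @param phase zero/first-order phase applied, degrees.
#' @param baseline baseline model applied.
#' @return An object of class `nmr_spectrum`.
#' @export
nmr_spectrum <- function(ppm, intensity, sfrq, phase = c(0, 0),
                         baseline = "none") {
  if (length(ppm) != length(intensity)) stop("ppm/intensity length mismatch")
  if (any(diff(ppm) >= 0)) stop("ppm axis must be monotone descending")
  structure(list(ppm = ppm, intensity = intensity, sfrq = sfrq,
                 phase = phase, baseline = baseline), class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("spectrum: %d points, %.2f..%.2f ppm\n",
              length(x$ppm), max(x$ppm), min(x$ppm)))
  invisible(x)
}

next_pow2 <- function(n) 2L^ceiling(log2(n))

#' Fourier transform one FID block into a spectrum
#'
#' Zero-fills (padding to a power of two, so non-power-of-two lengths never
#' fail), Fourier-transforms, applies zero/first-order phase correction, and
#' optionally subtracts a polynomial baseline. The frequency axis is
#' referenced to the spectrometer frequency and returned in descending ppm.
#' The first FID point is halved before the transform (standard practice to
#' suppress the DC baseline offset of a discretely sampled decay).
#'
#' @param fid a [fid_series()].
#' @param block block index to transform.
#' @param zero_fill zero-filling factor (>= 1; data length is padded to
#'   `zero_fill` times the next power of two).
#' @param phase numeric `c(p0, p1)` in degrees, or `"auto"` to choose `p0`
#'   minimizing negative intensity.
#' @param baseline `"none"` or `"poly"` (polynomial of degree
#'   `baseline_degree` fitted to the low-signal quantile of the spectrum).
#' @param baseline_degree degree of the baseline polynomial.
#' @return An [nmr_spectrum()].
#' @export
fid_to_spectrum <- function(fid, block = 1L, zero_fill = 2, phase = c(0, 0),
                            baseline = c("none", "poly"), baseline_degree = 2) {
  stopifnot(inherits(fid, "fid_series"))
  baseline <- match.arg(baseline)
  x <- fid$blocks[block, ]
  x[1L] <- x[1L] / 2
  n <- max(1L, next_pow2(length(x))) * max(1L, round(zero_fill))
  xp <- c(x, complex(real = rep(0, n - length(x))))
  sp <- stats::fft(xp)
  # reorder to frequency axis -sw/2 .. sw/2 - df
  half <- n %/% 2
  sp <- c(sp[(half + 1L):n], sp[1:half])
  freq <- (seq_len(n) - 1L - half) * fid$sw / n
  ppm <- freq / fid$sfrq

  if (identical(phase, "auto")) {
    negpen <- function(p0) {
      re <- Re(sp * exp(-1i * p0 * pi / 180))
      sum(pmin(re, 0)^2)
    }
    p0 <- stats::optimize(negpen, c(-180, 180))$minimum
    phase <- c(p0, 0)
  }
  ph <- exp(-1i * (phase[1L] + phase[2L] * (seq_len(n) - 1L) / n) * pi / 180)
  intens <- Re(sp * ph)

  # descending ppm (NMR convention)
  ord <- order(ppm, decreasing = TRUE)
  ppm <- ppm[ord]; intens <- intens[ord]
  if (baseline == "poly") {
    thr <- stats::quantile(abs(intens), 0.5)
    low <- abs(intens) <= thr
    if (sum(low) > baseline_degree + 1L) {
      bl <- stats::lm(y ~ poly(x, baseline_degree),
                      data = data.frame(x = ppm[low], y = intens[low]))
      intens <- intens - stats::predict(bl, newdata = data.frame(x = ppm))
    }
  }
  nmr_spectrum(ppm, intens, fid$sfrq, phase = phase, baseline = baseline)
}

#' Peak window
#'
#' A ppm interval assigned to one species, with the number of Lorentzian
#' components expected inside it (an FBP anomer pair contributes several).
#'
#' @param species species name.
#' @param low,high ppm bounds, `low < high`.
#' @param components expected Lorentzian component count (>= 1).
#' @param nuclei number of contributing nuclei per molecule for this species
#'   (areas are divided by it during quantification).
#' @return An object of class `peak_window`.
#' @export
peak_window <- function(species, low, high, components = 1L, nuclei = 1L) {
  if (low >= high) stop("'low' must be below 'high'")
  if (components < 1L) stop("'components' must be >= 1")
  structure(list(species = species, low = low, high = high,
                 components = as.integer(components),
                 nuclei = as.integer(nuclei)), class = "peak_window")
}

#' Box-integrate a spectrum window
#'
#' Trapezoidal area of the real intensity over the window's ppm range.
#' Linear in intensity; the area unit is intensity x ppm.
#'
#' @param spec an [nmr_spectrum()].
#' @param window a [peak_window()].
#' @return Raw area (numeric scalar).
#' @export
integrate_window <- function(spec, window) {
  stopifnot(inherits(spec, "nmr_spectrum"), inherits(window, "peak_window"))
  sel <- spec$ppm >= window$low & spec$ppm <= window$high
  if (sum(sel) < 2L)
    stop("window [", window$low, ", ", window$high,
         "] ppm contains fewer than 2 spectral points")
  x <- rev(spec$ppm[sel]); y <- rev(spec$intensity[sel])  # ascending ppm
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

## Unit-area Lorentzian in x (ppm), FWHM w, centre x0.
lorentz <- function(x, x0, w, area = 1) {
  hw <- w / 2
  area * hw / pi / ((x - x0)^2 + hw^2)
}

#' Deconvolve a window into Lorentzian components
#'
#' Least-squares fit of `n` Lorentzians (position, FWHM, area each) to the
#' real intensity inside a window, via Levenberg-Marquardt with non-negative
#' area bounds. Initial positions default to the `n` strongest local maxima.
#' With `baseline = "linear"` a local linear term is fitted alongside the
#' Lorentzians, absorbing the slowly varying tails of peaks outside the
#' window (the standard guard against cross-talk in crowded regions).
#' Non-convergence is reported with the residual norm, never silently.
#'
#' @param spec an [nmr_spectrum()].
#' @param window a [peak_window()].
#' @param n number of components (default: the window's `components`).
#' @param init_pos optional initial positions, ppm.
#' @param baseline `"none"` or `"linear"` (local baseline within the window).
#' @return Data frame with `position_ppm`, `width_hz`, `area`, plus
#'   attributes `converged`, `residual_norm` and `degenerate` (TRUE when the
#'   window holds no signal).
#' @export
deconvolve_lorentzians <- function(spec, window, n = window$components,
                                   init_pos = NULL,
                                   baseline = c("none", "linear")) {
  baseline <- match.arg(baseline)
  stopifnot(inherits(spec, "nmr_spectrum"), inherits(window, "peak_window"))
  sel <- spec$ppm >= window$low & spec$ppm <= window$high
  x <- rev(spec$ppm[sel]); y <- rev(spec$intensity[sel])
  if (length(x) < 3L * n)
    stop("window too narrow for ", n, " Lorentzian components")
  scale <- max(abs(y))
  if (scale == 0 || max(y) <= 0) {
    out <- data.frame(position_ppm = rep(mean(x), n),
                      width_hz = NA_real_, area = 0)
    attr(out, "degenerate") <- TRUE
    attr(out, "converged") <- TRUE
    attr(out, "residual_norm") <- 0
    return(out)
  }
  if (is.null(init_pos)) {
    ismax <- which(diff(sign(diff(y))) < 0) + 1L
    if (!length(ismax)) ismax <- which.max(y)
    ismax <- ismax[order(y[ismax], decreasing = TRUE)]
    init_pos <- x[ismax[seq_len(min(n, length(ismax)))]]
    while (length(init_pos) < n)
      init_pos <- c(init_pos, mean(range(x)) +
                      stats::runif(1, -1, 1) * diff(range(x)) / 4)
  }
  w0 <- rep(diff(range(x)) / (4 * n), n)
  a0 <- rep(sum(abs(y)) * mean(diff(x)) / n, n)
  nb <- if (baseline == "linear") 2L else 0L
  par0 <- c(init_pos, w0, a0, rep(0, nb))
  lo <- c(rep(min(x), n), rep(mean(diff(x)) / 2, n), rep(0, n),
          rep(-Inf, nb))
  hi <- c(rep(max(x), n), rep(diff(range(x)) * 2, n), rep(Inf, n),
          rep(Inf, nb))
  xc <- mean(range(x))
  model <- function(p) {
    pos <- p[1:n]; w <- p[n + 1:n]; a <- p[2 * n + 1:n]
    out <- rowSums(vapply(seq_len(n),
                          function(k) lorentz(x, pos[k], w[k], a[k]),
                          numeric(length(x))))
    if (nb > 0L) out <- out + p[3 * n + 1L] + p[3 * n + 2L] * (x - xc)
    out
  }
  fit <- minpack.lm::nls.lm(par0, lower = lo, upper = hi,
                            fn = function(p) model(p) - y,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 300, ftol = 1e-14, ptol = 1e-14))
  p <- fit$par
  res_norm <- sqrt(sum((model(p) - y)^2))
  converged <- fit$info %in% 1:4
  if (!converged)
    warning("Lorentzian deconvolution did not converge (residual norm ",
            signif(res_norm, 4), ")")
  ord <- order(p[1:n])
  out <- data.frame(position_ppm = p[1:n][ord],
                    width_hz = (p[n + 1:n] * spec$sfrq)[ord],
                    area = p[2 * n + 1:n][ord])
  attr(out, "degenerate") <- FALSE
  attr(out, "converged") <- converged
  attr(out, "residual_norm") <- res_norm
  out
}

#' T1 saturation correction factor
#'
#' Under rapid pulsing the longitudinal magnetization does not fully recover
#' between pulses; the steady-state signal of a species with relaxation time
#' `t1` at repetition time `trep` and pulse angle `theta` is attenuated by
#' `(1 - E)/(1 - E cos(theta))` with `E = exp(-trep/t1)` relative to a fully
#' relaxed acquisition. The correction factor is the reciprocal: `>= 1`, and
#' `1/(1 - E)` for a 90 degree pulse.
#'
#' @param t1 spin-lattice relaxation time, s.
#' @param trep repetition time (acquisition + relaxation delay), s.
#' @param angle pulse angle, degrees (default 90).
#' @return Correction factor (>= 1). Vectorized over `t1`.
#' @export
saturation_correction <- function(t1, trep, angle = 90) {
  if (any(t1 <= 0) || trep <= 0) stop("'t1' and 'trep' must be positive")
  E <- exp(-trep / t1)
  ct <- cos(angle * pi / 180)
  (1 - E * ct) / (1 - E)
}

#' Relaxation calibration
#'
#' Per-species saturation correction factors, as derived from a fully
#' relaxed reference spectrum of a metabolite cocktail (or computed from
#' measured T1 values via [saturation_correction()]).
#'
#' @param factors named numeric vector of correction factors (>= 1); must
#'   include the internal standard.
#' @param t1 optional named vector of T1 values, s (metadata).
#' @return An object of class `relaxation_calibration`.
#' @export
relaxation_calibration <- function(factors, t1 = NULL) {
  if (is.null(names(factors)) || any(factors < 1))
    stop("'factors' must be a named vector of correction factors >= 1")
  structure(list(factors = factors, t1 = t1),
            class = "relaxation_calibration")
}

#' Quantify an FID series into metabolite progress curves
#'
#' Processes every block of an FID series (exponential apodization,
#' transform, per-window quantification) and converts raw areas to
#' concentrations by reference to the internal standard:
#' `conc = (area_sp / area_std) * conc_std * (cal_sp / cal_std) *
#' (nuclei_std / nuclei_sp)`, where areas are summed over all windows
#' assigned to a species. Blocks in which the standard's area vanishes are
#' marked invalid and excluded with a log entry; negative concentrations
#' from noise are clipped to zero and flagged.
#'
#' @param fids a [fid_series()].
#' @param windows list of [peak_window()]s; must include one for the
#'   standard's species.
#' @param cal a [relaxation_calibration()] covering every quantified species.
#' @param standard list/vector with `species` and `conc` (mM) of the
#'   internal standard.
#' @param method `"box"` (integration) or `"deconv"` (Lorentzian
#'   deconvolution, summed component areas).
#' @param deconv_baseline baseline mode passed to
#'   [deconvolve_lorentzians()] (`"none"` or `"linear"`).
#' @param lb line broadening applied before transform, Hz.
#' @param assay_id assay identifier attached to the output.
#' @param ... passed to [fid_to_spectrum()] (e.g. `phase`, `baseline`).
#' @return Tidy data frame (`assay_id`, `time_min`, `species`, `conc_mM`,
#'   `flag`) with an attribute `log` of processing messages.
#' @export
quantify_series <- function(fids, windows, cal, standard,
                            method = c("box", "deconv"),
                            deconv_baseline = "none", lb = 8.5,
                            assay_id = "assay1", ...) {
  stopifnot(inherits(fids, "fid_series"),
            inherits(cal, "relaxation_calibration"))
  method <- match.arg(method)
  std_sp <- standard[["species"]]; std_conc <- as.numeric(standard[["conc"]])
  wsp <- vapply(windows, `[[`, "", "species")
  if (!std_sp %in% wsp)
    stop("no peak window supplied for the internal standard '", std_sp, "'")
  if (!std_sp %in% names(cal$factors))
    stop("calibration lacks the internal standard")
  species <- unique(wsp)
  nuclei <- vapply(species, function(sp)
    windows[[match(sp, wsp)]]$nuclei, 1L)
  miss <- setdiff(species, names(cal$factors))
  if (length(miss))
    stop("calibration lacks factors for: ", paste(miss, collapse = ", "))

  fids_a <- apodize_exponential(fids, lb)
  nb <- nrow(fids_a$blocks)
  log <- character()
  rows <- list()
  for (b in seq_len(nb)) {
    spec <- fid_to_spectrum(fids_a, block = b, ...)
    areas <- stats::setNames(numeric(length(species)), species)
    for (w in windows) {
      a <- if (method == "box") integrate_window(spec, w)
           else sum(deconvolve_lorentzians(spec, w,
                                           baseline = deconv_baseline)$area)
      areas[[w$species]] <- areas[[w$species]] + a
    }
    if (!is.finite(areas[[std_sp]]) || areas[[std_sp]] <= 0) {
      log <- c(log, sprintf(
        "block %d: internal standard area non-positive; block excluded", b))
      next
    }
    for (sp in setdiff(species, std_sp)) {
      conc <- areas[[sp]] / areas[[std_sp]] * std_conc *
        (cal$factors[[sp]] / cal$factors[[std_sp]]) *
        (nuclei[[std_sp]] / nuclei[[sp]])
      flag <- "ok"
      if (conc < 0) {
        log <- c(log, sprintf("block %d: %s clipped from %.4g to 0",
                              b, sp, conc))
        conc <- 0; flag <- "clipped"
      }
      rows[[length(rows) + 1L]] <-
        data.frame(assay_id = assay_id, time_min = fids_a$timestamps[b],
                   species = sp, conc_mM = conc, flag = flag)
    }
  }
  if (!length(rows)) stop("no quantifiable blocks in the series")
  out <- do.call(rbind, rows)
  attr(out, "log") <- log
  out
}

## ---------------------------------------------------------------------------
## Portable JSON serialization of FID series, and a Varian-dialect reader.

#' Read/write FID series as portable JSON
#'
#' The JSON layout stores acquisition metadata plus per-block real/imaginary
#' sample arrays; it is the interchange format used for synthetic data.
#'
#' @param fid a [fid_series()].
#' @param path file path.
#' @return `read_fid_json` returns a `fid_series`.
#' @export
write_fid_json <- function(fid, path) {
  stopifnot(inherits(fid, "fid_series"))
  obj <- list(sw = fid$sw, sfrq = fid$sfrq, timestamps = fid$timestamps,
              acq_time = fid$acq_time, relax_delay = fid$relax_delay,
              pulse_angle = fid$pulse_angle, transients = fid$transients,
              blocks = lapply(seq_len(nrow(fid$blocks)), function(b)
                list(re = Re(fid$blocks[b, ]), im = Im(fid$blocks[b, ]))))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_fid_json
#' @export
read_fid_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  blocks <- t(vapply(seq_len(nrow(obj$blocks)), function(b)
    complex(real = obj$blocks$re[[b]], imaginary = obj$blocks$im[[b]]),
    complex(length(obj$blocks$re[[1L]]))))
  fid_series(blocks, sw = obj$sw, sfrq = obj$sfrq,
             timestamps = obj$timestamps, acq_time = obj$acq_time,
             relax_delay = obj$relax_delay, pulse_angle = obj$pulse_angle,
             transients = obj$transients)
}

#' Read a Varian-dialect fid/procpar directory
#'
#' Minimal reader for the Varian/Agilent acquisition layout: a `procpar`
#' text file of acquisition parameters and a big-endian binary `fid` file
#' (file header, then per-block headers and interleaved real/imaginary
#' samples as int16, int32 or float32). Block timestamps are derived from
#' the repetition time and transient count: block `i` is stamped at its
#' midpoint `(i - 1/2) * nt * (at + d1) / 60` minutes.
#'
#' @param dir directory containing `fid` and `procpar`.
#' @return A [fid_series()].
#' @export
read_varian <- function(dir) {
  fid_path <- file.path(dir, "fid")
  pp_path <- file.path(dir, "procpar")
  if (!file.exists(fid_path) || !file.exists(pp_path))
    stop("'", dir, "' does not contain Varian 'fid' and 'procpar' files")
  pp <- parse_procpar(pp_path)
  num <- function(nm, default = NULL) {
    v <- pp[[nm]]
    if (is.null(v)) {
      if (is.null(default)) stop("procpar lacks parameter '", nm, "'")
      default
    } else as.numeric(v[1L])
  }
  sw <- num("sw"); sfrq <- num("sfrq"); at <- num("at", NA)
  d1 <- num("d1", 0); nt <- num("nt", 1)

  con <- file(fid_path, "rb"); on.exit(close(con))
  hdr <- readBin(con, "integer", n = 6L, size = 4L, endian = "big")
  names(hdr) <- c("nblocks", "ntraces", "np", "ebytes", "tbytes", "bbytes")
  readBin(con, "integer", n = 1L, size = 2L, endian = "big")  # vers_id
  status <- readBin(con, "integer", n = 1L, size = 2L, endian = "big")
  is_float <- bitwAnd(status, 8L) != 0L                       # S_FLOAT bit
  nbheaders <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  blocks <- matrix(complex(real = 0), hdr[["nblocks"]], hdr[["np"]] %/% 2L)
  for (b in seq_len(hdr[["nblocks"]])) {
    readBin(con, "raw", n = 28L * max(1L, nbheaders))  # block header(s)
    raw_n <- hdr[["np"]] * hdr[["ntraces"]]
    vals <- if (hdr[["ebytes"]] == 2L)
      readBin(con, "integer", n = raw_n, size = 2L, endian = "big")
    else if (is_float)
      readBin(con, "numeric", n = raw_n, size = 4L, endian = "big")
    else
      readBin(con, "integer", n = raw_n, size = 4L, endian = "big")
    if (hdr[["ntraces"]] > 1L) {  # co-added transients stored separately
      vals <- rowSums(matrix(vals, nrow = hdr[["np"]]))
    }
    blocks[b, ] <- complex(real = vals[c(TRUE, FALSE)],
                           imaginary = vals[c(FALSE, TRUE)])
  }
  if (is.na(at)) at <- (hdr[["np"]] %/% 2L) / sw
  trep <- at + d1
  ts <- (seq_len(hdr[["nblocks"]]) - 0.5) * nt * trep / 60
  fid_series(blocks, sw = sw, sfrq = sfrq, timestamps = ts, acq_time = at,
             relax_delay = d1, pulse_angle = num("pw90", 90), transients = nt)
}

#' Write a Varian-dialect fid/procpar directory
#'
#' Counterpart of [read_varian()] (float32 samples); used to build test
#' fixtures and to exchange synthetic series with Varian-reading software.
#'
#' @param fid a [fid_series()].
#' @param dir output directory (created if needed).
#' @export
write_varian <- function(fid, dir) {
  stopifnot(inherits(fid, "fid_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  np <- 2L * ncol(fid$blocks); nb <- nrow(fid$blocks)
  con <- file(file.path(dir, "fid"), "wb"); on.exit(close(con))
  writeBin(as.integer(c(nb, 1L, np, 4L, np * 4L, np * 4L + 28L)),
           con, size = 4L, endian = "big")
  writeBin(as.integer(c(0L, 8L)), con, size = 2L, endian = "big")  # S_FLOAT
  writeBin(1L, con, size = 4L, endian = "big")                     # nbheaders
  for (b in seq_len(nb)) {
    writeBin(as.integer(c(0L, 9L, b, 0L)), con, size = 2L, endian = "big")
    writeBin(as.integer(fid$transients), con, size = 4L, endian = "big")
    writeBin(rep(0, 4), con, size = 4L, endian = "big")  # lpval rpval lvl tlt
    inter <- as.vector(rbind(Re(fid$blocks[b, ]), Im(fid$blocks[b, ])))
    writeBin(inter, con, size = 4L, endian = "big")
  }
  pp <- file.path(dir, "procpar")
  lines <- character()
  for (nm in c("sw", "sfrq", "at", "d1", "nt")) {
    val <- switch(nm, sw = fid$sw, sfrq = fid$sfrq, at = fid$acq_time,
                  d1 = fid$relax_delay, nt = fid$transients)
    lines <- c(lines,
               paste(nm, "2 1 1e9 -1e9 0 1 1 0 1 64"),
               paste("1", format(val, digits = 15)),
               "0")
  }
  writeLines(lines, pp)
  invisible(dir)
}

## Minimal procpar parser: "name ..." header line, then "n val1 val2 ...",
## then an enumeration line. Returns a named list of value vectors.
parse_procpar <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list(); i <- 1L
  while (i <= length(lines)) {
    head_tok <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(head_tok) >= 2L && grepl("^[A-Za-z_]", head_tok[1L])) {
      nm <- head_tok[1L]
      i <- i + 1L
      if (i > length(lines)) break
      val_tok <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
      nv <- suppressWarnings(as.integer(val_tok[1L]))
      vals <- val_tok[-1L]
      while (!is.na(nv) && length(vals) < nv && i < length(lines) &&
             !grepl("^[A-Za-z_]", lines[i + 1L])) {
        i <- i + 1L
        vals <- c(vals, strsplit(trimws(lines[i]), "\\s+")[[1L]])
      }
      out[[nm]] <- gsub('^"|"$', "", vals)
      i <- i + 1L
      if (i <= length(lines) && !grepl("^[A-Za-z_]", lines[i])) i <- i + 1L
    } else i <- i + 1L
  }
  out
}
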