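#' Progress curve
#'
#' One species' concentration time course in one assay.
#'
#' @param assay_id assay identifier.
#' @param species species name.
#' @param time time points in minutes, strictly increasing.
#' @param conc concentrations in mM (non-negative).
#' @param valid logical validity flags (points excluded from spline fits).
#' @return An object of class `progress_curve`.
#' @export
progress_curve <- function(assay_id, species, time, conc,
                           valid = rep(TRUE, length(time))) {
  time <- as.numeric(time); conc <- as.numeric(conc)
  if (length(time) != length(conc) || length(valid) != length(time))
    stop("time, conc and valid must have equal length")
  if (any(diff(time) <= 0)) stop("time points must be strictly increasing")
  if (any(conc < 0)) stop("negative concentrations; clip and flag upstream")
  structure(list(assay_id = assay_id, species = species,
                 time = time, conc = conc, valid = as.logical(valid)),
            class = "progress_curve")
}

#' @export
print.progress_curve <- function(x, ...) {
  cat(sprintf("progress curve: %s / %s, %d points (%d valid), t = %.3g..%.3g min\n",
              x$assay_id, x$species, length(x$time), sum(x$valid),
              min(x$time), max(x$time)))
  invisible(x)
}

#' Assay run metadata
#'
#' @param id assay identifier.
#' @param initial named vector of nominal initial concentrations (mM).
#' @param reference_id id of the maximal-rate reference assay of the same
#'   session/extract (NULL if this assay is itself the reference).
#' @param protein_conc protein concentration, mg mL^-1.
#' @param correction named vector of effective-concentration correction
#'   factors (> 0, default 1), e.g. `c(ATP = 0.2)` when only one fifth of
#'   total ATP is Mg-bound and hence kinetically effective.
#' @return An object of class `assay_run`.
#' @export
assay_run <- function(id, initial = numeric(), reference_id = NULL,
                      protein_conc = 1, correction = numeric()) {
  if (length(correction) && (is.null(names(correction)) || any(correction <= 0)))
    stop("'correction' must be a named vector of positive factors")
  structure(list(id = id, initial = initial, reference_id = reference_id,
                 protein_conc = protein_conc, correction = correction),
            class = "assay_run")
}

## Tidy-table <-> curve conversion -----------------------------------------

#' Convert progress curves to/from a tidy table
#'
#' The tidy layout (`assay_id`, `time_min`, `species`, `conc_mM`, `flag`)
#' is the on-disk CSV interchange format of the toolkit.
#'
#' @param curves list of [progress_curve()] objects.
#' @return `curves_to_table`: a data frame; `table_to_curves`: a named list
#'   of `progress_curve` (names `assay_id.species`).
#' @export
curves_to_table <- function(curves) {
  do.call(rbind, lapply(curves, function(cv)
    data.frame(assay_id = cv$assay_id, time_min = cv$time,
               species = cv$species, conc_mM = cv$conc,
               flag = ifelse(cv$valid, "ok", "invalid"))))
}

#' @rdname curves_to_table
#' @param tab a tidy progress table.
#' @export
table_to_curves <- function(tab) {
  stopifnot(all(c("assay_id", "time_min", "species", "conc_mM") %in% names(tab)))
  if (is.null(tab$flag)) tab$flag <- "ok"
  out <- list()
  for (key in unique(paste(tab$assay_id, tab$species, sep = "."))) {
    sub <- tab[paste(tab$assay_id, tab$species, sep = ".") == key, ]
    sub <- sub[order(sub$time_min), ]
    out[[key]] <- progress_curve(sub$assay_id[1L], sub$species[1L],
                                 sub$time_min, pmax(sub$conc_mM, 0),
                                 sub$flag == "ok")
  }
  out
}

#' @rdname curves_to_table
#' @param path CSV file path.
#' @export
write_progress_csv <- function(tab, path) {
  if (is.list(tab) && !is.data.frame(tab)) tab <- curves_to_table(tab)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname curves_to_table
#' @export
read_progress_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

## Spline fitting -----------------------------------------------------------

#' Fit a smoothing spline to one progress curve
#'
#' Fits a cubic smoothing spline to the valid points of a progress curve.
#' By default the smoothing level is chosen by generalized cross-validation,
#' which interpolates smooth noise-free data and smooths noisy data just
#' enough to absorb the noise without flattening curvature. Alternatively a
#' target mean squared residual (an externally known noise variance) can be
#' supplied, and the smoothing parameter is root-searched so the fit's
#' residual MSE matches it. Mass conservation is never assumed: each species
#' is fitted independently.
#'
#' @param curve a [progress_curve()] with at least 4 valid points.
#' @param smoothing `NULL` (default) for generalized cross-validation, `0`
#'   for exact interpolation, or a target mean squared residual in mM^2.
#' @return An object of class `progress_spline`; evaluate with
#'   [predict.progress_spline()].
#' @export
fit_smoothing_spline <- function(curve, smoothing = NULL) {
  stopifnot(inherits(curve, "progress_curve"))
  if (!is.null(smoothing) && smoothing < 0) stop("'smoothing' must be >= 0")
  x <- curve$time[curve$valid]; y <- curve$conc[curve$valid]
  if (length(x) < 4L)
    stop(sprintf("curve %s/%s has %d valid points; at least 4 are needed",
                 curve$assay_id, curve$species, length(x)))
  scale2 <- max(mean(y^2), .Machine$double.eps)
  if (is.null(smoothing)) {
    fit <- stats::smooth.spline(x, y, keep.data = FALSE, all.knots = TRUE)
    mse <- mean((stats::predict(fit, x)$y - y)^2)
    if (mse <= 1e-12 * scale2) {
      # effectively noise-free: use the exact interpolating spline
      f <- stats::splinefun(x, y, method = "fmm")
      obj <- list(kind = "interpolating", fun = f, rss = 0, spar = NA_real_)
    } else {
      obj <- list(kind = "smoothing", fit = fit,
                  rss = mse * length(y), spar = fit$spar)
    }
  } else if (smoothing <= 1e-12 * scale2) {
    f <- stats::splinefun(x, y, method = "fmm")
    obj <- list(kind = "interpolating", fun = f, rss = 0, spar = NA_real_)
  } else {
    target <- smoothing
    mse_at <- function(spar) {
      fit <- stats::smooth.spline(x, y, spar = spar, keep.data = FALSE,
                                  all.knots = TRUE)
      mean((stats::predict(fit, x)$y - y)^2)
    }
    lo <- -1.5; hi <- 2.0
    spar <- if (mse_at(lo) >= target) lo
            else if (mse_at(hi) <= target) hi
            else stats::uniroot(function(s) mse_at(s) - target,
                                c(lo, hi), tol = 1e-4)$root
    fit <- stats::smooth.spline(x, y, spar = spar, keep.data = FALSE,
                                all.knots = TRUE)
    obj <- list(kind = "smoothing", fit = fit,
                rss = sum((stats::predict(fit, x)$y - y)^2), spar = spar)
  }
  obj$assay_id <- curve$assay_id
  obj$species <- curve$species
  obj$range <- range(x)
  obj$times <- x
  class(obj) <- "progress_spline"
  obj
}

#' Evaluate a fitted progress spline
#'
#' @param object a `progress_spline`.
#' @param t times (min) inside the fitted range.
#' @param deriv derivative order (0 = concentration, 1 = rate of change).
#' @param ... unused.
#' @return Numeric vector.
#' @export
predict.progress_spline <- function(object, t, deriv = 0, ...) {
  if (object$kind == "interpolating") object$fun(t, deriv = deriv)
  else stats::predict(object$fit, t, deriv = deriv)$y
}

#' @export
print.progress_spline <- function(x, ...) {
  cat(sprintf("%s spline: %s / %s on [%.3g, %.3g] min (spar %.3g, RSS %.3g)\n",
              x$kind, x$assay_id, x$species, x$range[1], x$range[2],
              x$spar, x$rss))
  invisible(x)
}

## Rate extraction ----------------------------------------------------------

#' Reaction rates from spline-fitted progress curves
#'
#' Differentiates the per-species splines of one assay and combines them into
#' instantaneous reaction-rate samples. The reaction rate at each time is the
#' stoichiometry-signed mean of the available species derivatives (substrates
#' contribute `-dC/dt`, products `+dC/dt`); species consumed by known side
#' reactions can be excluded from the average via `exclude`. Each sample
#' carries the complete interpolated concentration vector, so the target rate
#' law can be evaluated at it directly. First and last samples of the assay
#' are down-weighted (weight 0.5) because spline derivatives are least
#' reliable at the interval ends.
#'
#' @param assay an [assay_run()].
#' @param splines named list (by species) of [fit_smoothing_spline()] results.
#' @param scheme a [reaction_scheme()] naming substrates and products.
#' @param times sample times (min); default: union of the measured time
#'   points of the splined curves. Times outside a spline's support are
#'   skipped with a message.
#' @param exclude species excluded from the rate average (but kept in the
#'   concentration vector), e.g. `"ADP"` when background reactions consume it.
#' @return Data frame of rate samples: `assay_id`, `time`, `rate` (mM/min),
#'   `weight`, and one concentration column per species (effective
#'   concentrations after the assay's correction factors).
#' @export
rates_from_splines <- function(assay, splines, scheme, times = NULL,
                               exclude = character()) {
  stopifnot(inherits(assay, "assay_run"), inherits(scheme, "reaction_scheme"))
  if (is.null(times))
    times <- sort(unique(unlist(lapply(splines, `[[`, "times"))))
  lo <- max(vapply(splines, function(s) s$range[1], 0))
  hi <- min(vapply(splines, function(s) s$range[2], 0))
  keep <- times >= lo & times <= hi
  if (!all(keep))
    message(sum(!keep), " sample time(s) outside common spline support skipped")
  times <- times[keep]
  if (!length(times)) stop("no sample times inside the common spline support")

  use <- setdiff(intersect(c(scheme$substrates, scheme$products),
                           names(splines)), exclude)
  if (!length(use))
    stop("no usable species: scheme species not found among splines")
  contrib <- vapply(use, function(sp) {
    sgn <- if (sp %in% scheme$substrates) -1 else 1
    sgn * predict(splines[[sp]], times, deriv = 1)
  }, numeric(length(times)))
  rate <- rowMeans(matrix(contrib, nrow = length(times)))

  conc <- lapply(names(splines), function(sp)
    pmax(predict(splines[[sp]], times), 0))
  names(conc) <- names(splines)
  # species without splines: carry the assay's nominal (constant) level
  for (sp in setdiff(names(assay$initial), names(conc)))
    conc[[sp]] <- rep(assay$initial[[sp]], length(times))
  for (sp in names(assay$correction))
    if (sp %in% names(conc)) conc[[sp]] <- conc[[sp]] * assay$correction[[sp]]

  w <- rep(1, length(times))
  w[c(1L, length(w))] <- 0.5
  cbind(data.frame(assay_id = assay$id, time = times, rate = rate, weight = w),
        as.data.frame(conc))
}

#' Build a pooled rate dataset from a tidy progress table
#'
#' Convenience pipeline: splits a tidy table by assay, spline-fits every
#' species, differentiates, and pools the resulting rate samples across
#' assays — the input expected by [global_fit_problem()].
#'
#' @param tab tidy progress table (`assay_id`, `time_min`, `species`,
#'   `conc_mM`, optional `flag`).
#' @param scheme a [reaction_scheme()].
#' @param assays optional named list of [assay_run()] objects (defaults to
#'   bare runs with no metadata).
#' @param exclude species excluded from the rate average (side-reaction
#'   casualties such as ADP — or ATP where pyruvate kinase maintains it).
#' @param smoothing passed to [fit_smoothing_spline()]: a scalar, `NULL`,
#'   or a function of the [progress_curve()] returning the per-curve target
#'   (e.g. half the known noise variance when smoothing for derivatives).
#' @return Pooled rate-sample data frame.
#' @export
build_rate_dataset <- function(tab, scheme, assays = NULL,
                               exclude = character(), smoothing = NULL) {
  stopifnot(is.data.frame(tab))
  out <- list()
  for (id in unique(tab$assay_id)) {
    sub <- tab[tab$assay_id == id, ]
    curves <- table_to_curves(sub)
    splines <- lapply(curves, function(cv)
      fit_smoothing_spline(cv, smoothing = if (is.function(smoothing))
        smoothing(cv) else smoothing))
    names(splines) <- vapply(curves, `[[`, "", "species")
    run <- if (!is.null(assays) && id %in% names(assays)) assays[[id]]
           else assay_run(id)
    out[[id]] <- rates_from_splines(run, splines, scheme, exclude = exclude)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Conservation defect diagnostic
#'
#' Splines are fitted without assuming mass conservation; this reports how
#' strongly a supposedly conserved sum (e.g. G6P + F6P for an isomerase)
#' actually drifts, as the maximum absolute deviation of the summed splines
#' from their initial value, relative to that value.
#'
#' @param splines named list of `progress_spline` objects.
#' @param species species whose concentrations should sum to a constant.
#' @param n number of evaluation points on the common support.
#' @return Relative conservation defect (dimensionless, >= 0).
#' @export
conservation_defect <- function(splines, species, n = 101L) {
  lo <- max(vapply(splines[species], function(s) s$range[1], 0))
  hi <- min(vapply(splines[species], function(s) s$range[2], 0))
  tt <- seq(lo, hi, length.out = n)
  tot <- rowSums(vapply(species, function(sp) predict(splines[[sp]], tt),
                        numeric(n)))
  abs(max(abs(tot - tot[1L])) / tot[1L])
}

## Equilibrium inference and pre-equilibration handling ---------------------

#' Infer a species concentration from equilibrium with its isomer
#'
#' When a species is spectrally obscured (low F6P hidden under accumulating
#' FBP peaks) but a fast isomerase keeps it equilibrated with an easily
#' quantified partner, its concentration follows from the equilibrium
#' constant: `f6p = keq * g6p`.
#'
#' @param g6p concentration of the quantifiable partner (mM, >= 0).
#' @param keq equilibrium constant (> 0), product over substrate.
#' @return Inferred concentration (mM). Vectorized.
#' @export
infer_equilibrium_species <- function(g6p, keq) {
  if (any(g6p < 0)) stop("concentrations must be non-negative")
  if (keq <= 0) stop("'keq' must be positive")
  keq * g6p
}

#' Split an assay at the isomerase-equilibration boundary
#'
#' Data acquired before the fast upstream reaction (PGI) has equilibrated
#' violate the equilibrium assumption used to infer obscured species, so
#' fits to the downstream reaction use only the post-equilibration segment.
#' The boundary is the earliest time after which the mass-action ratio stays
#' within `rel_tol` of `keq`; the removed points are returned separately for
#' model validation rather than discarded.
#'
#' @param tab tidy progress table of one assay (see [curves_to_table()]),
#'   containing both `substrate` and `product` species.
#' @param keq equilibrium constant (product/substrate).
#' @param rel_tol relative tolerance of the equilibrium band (default 0.05).
#' @param substrate,product species names forming the ratio (default
#'   `"G6P"`, `"F6P"`).
#' @return List with `retained` (tidy table, t >= boundary), `held_out`
#'   (tidy table, t < boundary), `boundary_time` (min) and `flagged`
#'   (TRUE when the criterion is never met and nothing is retained).
#' @export
exclude_pre_equilibration <- function(tab, keq, rel_tol = 0.05,
                                      substrate = "G6P", product = "F6P") {
  stopifnot(is.data.frame(tab), rel_tol >= 0, keq > 0)
  s <- tab[tab$species == substrate, ]
  p <- tab[tab$species == product, ]
  if (!nrow(s) || !nrow(p))
    stop("assay table must contain both '", substrate, "' and '", product, "'")
  s <- s[order(s$time_min), ]
  pc <- stats::approx(p$time_min, p$conc_mM, xout = s$time_min, rule = 2)$y
  ratio <- pc / pmax(s$conc_mM, .Machine$double.eps)
  ok <- abs(ratio - keq) / keq <= rel_tol
  # earliest index from which the band holds for every later point
  from <- rev(cumprod(rev(ok))) == 1
  if (!any(from)) {
    warning("assay '", tab$assay_id[1L],
            "': equilibrium criterion never met; all points held out")
    return(list(retained = tab[0, ], held_out = tab,
                boundary_time = NA_real_, flagged = TRUE))
  }
  boundary <- s$time_min[which(from)[1L]]
  list(retained = tab[tab$time_min >= boundary, ],
       held_out = tab[tab$time_min < boundary, ],
       boundary_time = boundary, flagged = FALSE)
}

## Maximal-rate normalization -----------------------------------------------

#' Representative maximal rate of a reference assay
#'
#' Each experimental session includes a maximal-rate assay (saturating
#' substrate, no product); all rates of the session are normalized to its
#' representative rate. Because products accumulate from the first instant
#' (and for an isomerase inhibit strongly), a time-window average
#' underestimates the maximal rate in an activity-dependent way - a faster
#' extract self-limits faster - so the default estimator extrapolates the
#' rate back to the mixing time: a quadratic in time is fitted to the rate
#' samples of the early window (first time quartile, capped at
#' `max_conversion` conversion of the dominant species) and evaluated at
#' t = 0, where all sessions share the same nominal composition. The
#' `"plateau"` method (median over the same window) is available for
#' reactions whose rate genuinely plateaus.
#'
#' @param samples rate-sample data frame from [rates_from_splines()].
#' @param method `"initial"` (extrapolation to t = 0, default) or
#'   `"plateau"` (window median).
#' @param max_conversion fractional change of the dominant species that ends
#'   the early window (default 0.2).
#' @return Positive scalar rate (mM/min).
#' @export
reference_maximal_rate <- function(samples, method = c("initial", "plateau"),
                                   max_conversion = 0.2) {
  stopifnot(is.data.frame(samples), nrow(samples) > 0)
  method <- match.arg(method)
  samples <- samples[order(samples$time), ]
  tcut <- min(samples$time) + 0.25 * diff(range(samples$time))
  conc_cols <- setdiff(names(samples),
                       c("assay_id", "time", "rate", "weight"))
  if (length(conc_cols)) {
    dom <- conc_cols[which.max(vapply(conc_cols,
                                      function(cc) samples[[cc]][1L], 0))]
    c0 <- samples[[dom]][1L]
    ok <- abs(samples[[dom]] - c0) <= max_conversion * c0
    t_conv <- if (all(ok)) max(samples$time)
              else samples$time[max(1L, which(!ok)[1L] - 1L)]
    tcut <- min(tcut, t_conv)
  }
  sel <- samples$time <= tcut
  if (sum(sel) < 3L) sel <- seq_len(min(3L, nrow(samples)))
  tt <- samples$time[sel]; vv <- abs(samples$rate[sel])
  r <- if (method == "plateau" || sum(sel) < 4L) {
    stats::median(vv)
  } else {
    unname(stats::predict(stats::lm(vv ~ tt + I(tt^2)),
                          newdata = data.frame(tt = 0)))
  }
  if (!is.finite(r) || r <= 0)
    stop("reference assay yields a non-positive plateau rate")
  r
}

#' Normalize rate samples to a session reference rate
#'
#' Divides all rates by the session's reference maximal rate, making sessions
#' with different extracts/spectrometer days comparable; the reference
#' assay's own plateau maps to 1. Re-scaling to physical units is done after
#' the global fit by multiplying the fitted `vf` by an externally determined
#' maximal rate.
#'
#' @param samples rate-sample data frame.
#' @param reference_rate positive scalar from [reference_maximal_rate()].
#' @return The data frame with `rate` divided by `reference_rate` (and an
#'   attribute `reference_rate`).
#' @export
normalize_to_reference <- function(samples, reference_rate) {
  if (!is.numeric(reference_rate) || length(reference_rate) != 1L ||
      !is.finite(reference_rate) || reference_rate <= 0)
    stop("missing or non-positive reference rate for this session")
  samples$rate <- samples$rate / reference_rate
  attr(samples, "reference_rate") <- reference_rate
  samples
}
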