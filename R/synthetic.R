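#' Noise model for synthetic data
#'
#' @param conc_add_sd additive concentration noise sd, mM.
#' @param conc_mult_sd multiplicative concentration noise sd (fraction of
#'   the true value). The default 3% matches the scatter typical of
#'   progress-curve peak integrals.
#' @param fid_noise_sd complex Gaussian noise sd per FID point, in the same
#'   arbitrary intensity unit as the synthetic signal (about 2 gives a
#'   spectral signal-to-noise ratio of roughly 50 for a 5 mM
#'   single-phosphorus species under the default synthesis scale and 8.5 Hz
#'   line broadening).
#' @param lw_hz natural Lorentzian line width of synthetic resonances, Hz.
#' @return List of class `noise_model`.
#' @export
noise_model <- function(conc_add_sd = 0, conc_mult_sd = 0.03,
                        fid_noise_sd = 0, lw_hz = 1.5) {
  stopifnot(conc_add_sd >= 0, conc_mult_sd >= 0, fid_noise_sd >= 0, lw_hz >= 0)
  structure(list(conc_add_sd = conc_add_sd, conc_mult_sd = conc_mult_sd,
                 fid_noise_sd = fid_noise_sd, lw_hz = lw_hz),
            class = "noise_model")
}

#' Synthetic progress-curve scenario
#'
#' Describes a multi-assay experiment generated from a known rate law:
#' assays (initial concentrations), shared time grid, per-session maximal
#' rate jitter, noise model and seed.
#'
#' @param law `rate_law` object or registry name.
#' @param params true [rate_law_params()].
#' @param assays named list: each element a named vector of initial
#'   concentrations (mM) covering the law's species.
#' @param times sampling time grid, min: either one numeric vector shared by
#'   all assays, or a named list with one grid per assay (acquisition
#'   schedules routinely differ between assays of one study).
#' @param noise a [noise_model()].
#' @param sessions optional integer vector assigning each assay to a
#'   session; each session gets its own Vf factor drawn from
#'   `vf_jitter_sd` (lognormal).
#' @param vf_jitter_sd sd of log session Vf jitter (0 = none).
#' @param side optional side-reaction model emulating ancillary activities
#'   of a cell extract: a function `f(conc, v)` of the named concentration
#'   vector and the instantaneous main-reaction rate, returning named
#'   additional dC/dt contributions (mM/min). Part of the generating ground
#'   truth; the fitted rate law never sees it except through the measured
#'   concentrations.
#' @param seed mandatory integer seed.
#' @return List of class `scenario_spec`.
#' @export
scenario_spec <- function(law, params, assays, times,
                          noise = noise_model(), sessions = NULL,
                          vf_jitter_sd = 0, side = NULL, seed) {
  if (missing(seed)) stop("'seed' is mandatory for scenario specs")
  if (is.character(law)) law <- get_rate_law(law)
  stopifnot(inherits(params, "rate_law_params"), length(assays) >= 1L)
  if (is.null(names(assays)))
    names(assays) <- paste0("assay", seq_along(assays))
  if (is.null(sessions)) sessions <- rep(1L, length(assays))
  if (!is.list(times)) {
    times <- stats::setNames(rep(list(as.numeric(times)), length(assays)),
                             names(assays))
  } else {
    if (!setequal(names(times), names(assays)))
      stop("per-assay 'times' must be named after the assays")
    times <- lapply(times, as.numeric)[names(assays)]
  }
  structure(list(law = law, params = params, assays = assays,
                 times = times, noise = noise,
                 sessions = as.integer(sessions),
                 vf_jitter_sd = vf_jitter_sd, side = side,
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Default PGI scenario
#'
#' Five assays spanning 0-10 mM in both reaction directions, including an
#' 8.5 mM pure-F6P start, generated from the published PGI parameter set at
#' 0.1 mg mL^-1 protein (placing full equilibration at 10-65 min, the time
#' scale of a 31P-NMR progress curve). Each assay is sampled with 40 FID
#' blocks from the first block midpoint (0.5 min) to just past its own
#' equilibration.
#'
#' @param noise a [noise_model()] (default noiseless).
#' @param seed integer seed.
#' @param n_times points per time course.
#' @param protein_conc mg mL^-1.
#' @return A [scenario_spec()].
#' @export
pgi_scenario <- function(noise = noise_model(conc_mult_sd = 0), seed = 42L,
                         n_times = 40L, protein_conc = 0.1) {
  # grid ends ~110% of each assay's time to reach 1% of Keq (at 0.1 mg/mL)
  t_end <- c(fwd10 = 50, fwd5 = 26, fwd2 = 12, rev85 = 70, rev4 = 34) *
    0.1 / protein_conc
  scenario_spec(
    law = "pgi", params = pgi_table_params(protein_conc = protein_conc),
    assays = list(fwd10 = c(G6P = 10, F6P = 0),
                  fwd5  = c(G6P = 5,  F6P = 0),
                  fwd2  = c(G6P = 2,  F6P = 0),
                  rev85 = c(G6P = 0,  F6P = 8.5),
                  rev4  = c(G6P = 0,  F6P = 4)),
    times = lapply(t_end, function(te) seq(0.5, te, length.out = n_times)),
    noise = noise, seed = seed)
}

#' Default PFK scenario
#'
#' Six assays crossing F6P in \{3, 10\} mM and ATP in \{2.5, 5\} mM with the
#' PEP inhibitor at 0, 4 and 8 mM, 100 FID blocks over 75 min (45 s of
#' transients per block), generated from the published PFK parameter set. In a cell extract PEP is not static: as the
#' PFK reaction releases ADP, pyruvate kinase phosphorylates it back to ATP
#' at PEP's expense, so PEP declines over the course (sweeping through the
#' low-concentration region that identifies its half-saturation constant)
#' while ATP is largely maintained. The scenario emulates this with a
#' pyruvate-kinase side reaction running at the PFK rate scaled by a PEP
#' Michaelis term (`K` 0.3 mM): `dPEP = -v_pk`, `dADP = v - v_pk`,
#' `dATP = -v + v_pk`.
#'
#' @inheritParams pgi_scenario
#' @param t_end last time point, min.
#' @return A [scenario_spec()].
#' @export
pfk_scenario <- function(noise = noise_model(conc_mult_sd = 0), seed = 42L,
                         n_times = 100L, t_end = 75) {
  pyruvate_kinase <- function(conc, v) {
    v_pk <- v * conc[["PEP"]] / (conc[["PEP"]] + 0.3)
    c(PEP = -v_pk, ADP = -v_pk, ATP = v_pk)
  }
  scenario_spec(
    law = "pfk", params = pfk_table_params(),
    assays = list(
      a1 = c(F6P = 3,  ATP = 2.5, FBP = 0, ADP = 0, PEP = 0),
      a2 = c(F6P = 10, ATP = 5,   FBP = 0, ADP = 0, PEP = 0),
      a3 = c(F6P = 3,  ATP = 5,   FBP = 0, ADP = 0, PEP = 4),
      a4 = c(F6P = 10, ATP = 2.5, FBP = 0, ADP = 0, PEP = 4),
      a5 = c(F6P = 3,  ATP = 5,   FBP = 0, ADP = 0, PEP = 8),
      a6 = c(F6P = 10, ATP = 2.5, FBP = 0, ADP = 0, PEP = 8)),
    times = seq(5 / 6, t_end, length.out = n_times),
    noise = noise, side = pyruvate_kinase, seed = seed)
}

## Forward ODE of a single reaction under its scheme stoichiometry:
## substrates -v, products +v, modifiers constant unless a side-reaction
## model adds its own contributions.
reaction_ode <- function(law, theta, y0, times, side = NULL) {
  scheme <- law$scheme
  deriv <- function(t, y, p) {
    yc <- pmax(y, 0)
    conc <- as.data.frame(as.list(yc))
    v <- law$rate(conc, theta)
    dy <- stats::setNames(rep(0, length(y)), names(y))
    dy[scheme$substrates] <- -v
    dy[scheme$products] <- dy[scheme$products] + v
    if (!is.null(side)) {
      extra <- side(yc, v)
      dy[names(extra)] <- dy[names(extra)] + extra
    }
    list(dy)
  }
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-11)
  as.data.frame(sol)
}

#' Simulate noisy progress curves from a known rate law
#'
#' Integrates the scenario's rate law forward from each assay's initial
#' concentrations, samples the exact solution on the time grid, and applies
#' seeded multiplicative/additive concentration noise (negatives clipped to
#' zero and flagged). The exact (noise-free) trajectories and the generating
#' parameters are returned alongside for parameter-recovery tests.
#'
#' @param spec a [scenario_spec()].
#' @return List with `curves` (tidy table: `assay_id`, `time_min`,
#'   `species`, `conc_mM`, `flag`), `truth` (list: `params`, `theta`,
#'   `session_vf`, `exact` tidy table), and `sessions` (assay -> session).
#' @export
simulate_noisy_timecourses <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  n_sess <- max(spec$sessions)
  sess_vf <- exp(stats::rnorm(n_sess, 0, spec$vf_jitter_sd))
  theta0 <- params_to_theta(spec$params)
  noisy <- exact <- list()
  for (i in seq_along(spec$assays)) {
    id <- names(spec$assays)[i]
    theta <- theta0
    theta[["vf"]] <- theta[["vf"]] * sess_vf[spec$sessions[i]] *
      spec$params$protein_conc
    y0 <- spec$assays[[i]]
    miss <- setdiff(spec$law$species, names(y0))
    if (length(miss))
      stop("assay '", id, "' lacks initial concentrations for: ",
           paste(miss, collapse = ", "))
    tms <- spec$times[[id]]
    ode_times <- if (tms[1L] > 0) c(0, tms) else tms
    sol <- reaction_ode(spec$law, theta, y0, ode_times, side = spec$side)
    sol <- sol[match(tms, ode_times), ]
    for (sp in names(y0)) {
      true_c <- sol[[sp]]
      eps <- true_c * stats::rnorm(length(true_c), 0, spec$noise$conc_mult_sd) +
        stats::rnorm(length(true_c), 0, spec$noise$conc_add_sd)
      obs <- true_c + eps
      flag <- ifelse(obs < 0, "clipped", "ok")
      obs <- pmax(obs, 0)
      noisy[[length(noisy) + 1L]] <-
        data.frame(assay_id = id, time_min = tms, species = sp,
                   conc_mM = obs, flag = flag)
      exact[[length(exact) + 1L]] <-
        data.frame(assay_id = id, time_min = tms, species = sp,
                   conc_mM = true_c, flag = "ok")
    }
  }
  list(curves = do.call(rbind, noisy),
       truth = list(params = spec$params, theta = theta0,
                    session_vf = sess_vf, exact = do.call(rbind, exact)),
       sessions = stats::setNames(spec$sessions, names(spec$assays)))
}

#' Default 31P resonance map for the glycolytic assay system
#'
#' Chemical shifts, relative component weights, T1 values and phosphorus
#' counts for the species of the PGI/PFK assays. FBP appears as a quartet
#' (two peaks per anomer pair) around 2.4 ppm with F6P in between - the
#' documented hard case for box integration; ATP and ADP contribute several
#' phosphorus resonances; TEP is the internal chemical-shift anchor.
#'
#' @return Data frame: `species`, `ppm`, `weight` (relative area fraction of
#'   the species' signal), `t1` (s), `nuclei`.
#' @export
default_peak_map <- function() {
  data.frame(
    species = c("TEP", "G6P", "F6P",
                "FBP", "FBP", "FBP", "FBP",
                "ATP", "ATP", "ATP", "ADP", "ADP", "PEP", "Pi", "AMP"),
    ppm = c(0.45, 3.35, 2.42,
            2.65, 2.58, 2.32, 2.25,
            -5.5, -10.6, -19.2, -6.1, -10.1, -1.2, 2.95, 3.75),
    weight = c(1, 1, 1,
               0.25, 0.25, 0.25, 0.25,
               1 / 3, 1 / 3, 1 / 3, 0.5, 0.5, 1, 1, 1),
    t1 = c(6.0, 0.5, 0.5, 0.4, 0.4, 0.4, 0.4,
           0.2, 0.2, 0.2, 0.2, 0.2, 1.0, 1.0, 0.4),
    nuclei = c(1L, 1L, 1L, 2L, 2L, 2L, 2L,
               3L, 3L, 3L, 2L, 2L, 1L, 1L, 1L))
}

#' Default peak windows matching [default_peak_map()]
#'
#' One window per resonance (FBP's quartet yields four windows summed per
#' species), each `half_width` ppm wide to either side.
#'
#' @param species subset of species to window (default: all in the map).
#' @param half_width window half-width, ppm.
#' @return List of [peak_window()]s.
#' @export
default_peak_windows <- function(species = NULL, half_width = 0.15) {
  pm <- default_peak_map()
  if (!is.null(species)) pm <- pm[pm$species %in% species, ]
  lapply(seq_len(nrow(pm)), function(i)
    peak_window(pm$species[i], pm$ppm[i] - half_width, pm$ppm[i] + half_width,
                components = 1L, nuclei = pm$nuclei[i]))
}

#' Relaxation calibration from the default peak map
#'
#' @param trep repetition time, s.
#' @param angle pulse angle, degrees.
#' @param species subset (default: all).
#' @return A [relaxation_calibration()].
#' @export
default_calibration <- function(trep, angle = 90, species = NULL) {
  pm <- unique(default_peak_map()[, c("species", "t1")])
  if (!is.null(species)) pm <- pm[pm$species %in% species, ]
  relaxation_calibration(
    stats::setNames(saturation_correction(pm$t1, trep, angle), pm$species),
    t1 = stats::setNames(pm$t1, pm$species))
}

#' Synthesize an FID series from concentration trajectories
#'
#' Inverse of the quantification chain: builds complex FIDs in which each
#' species contributes exponentially decaying resonances at its mapped
#' chemical shifts, with amplitude proportional to concentration x nuclei x
#' component weight, attenuated by the T1 saturation factor of the pulse
#' sequence. The internal standard is present in every block at constant
#' concentration. Complex Gaussian noise and the natural line width come
#' from the noise model.
#'
#' @param trajectories tidy table (`time_min`, `species`, `conc_mM`) of one
#'   assay.
#' @param peak_map resonance table as in [default_peak_map()]; species
#'   without trajectory rows (other than the standard) are silent.
#' @param acq list of acquisition parameters: `sw` (Hz), `sfrq` (MHz), `np`
#'   (complex points), `acq_time` (s), `relax_delay` (s), `pulse_angle`
#'   (deg), `transients`.
#' @param standard list/vector with `species` and `conc` (mM).
#' @param noise a [noise_model()].
#' @param seed integer seed for the FID noise.
#' @param scale intensity per mM of a single-nucleus fully-relaxed species
#'   (arbitrary unit; quantification is ratio-based).
#' @return A [fid_series()].
#' @export
synthesize_fid_series <- function(trajectories, peak_map = default_peak_map(),
                                  acq = list(sw = 10000, sfrq = 242.87,
                                             np = 4096, acq_time = NULL,
                                             relax_delay = 0.5,
                                             pulse_angle = 90,
                                             transients = 1),
                                  standard = list(species = "TEP", conc = 10),
                                  noise = noise_model(), seed = 1L) {
  stopifnot(is.data.frame(trajectories),
            all(c("time_min", "species", "conc_mM") %in% names(trajectories)))
  set.seed(seed)
  np <- acq$np %||% 4096L
  sw <- acq$sw %||% 10000
  sfrq <- acq$sfrq %||% 242.87
  at <- acq$acq_time %||% (np / sw)
  d1 <- acq$relax_delay %||% 0.5
  angle <- acq$pulse_angle %||% 90
  trep <- at + d1
  tvec <- (seq_len(np) - 1L) / sw
  r2 <- pi * noise$lw_hz
  times <- sort(unique(trajectories$time_min))
  blocks <- matrix(complex(real = 0), length(times), np)
  sat <- 1 / saturation_correction(peak_map$t1, trep, angle)
  for (b in seq_along(times)) {
    sub <- trajectories[trajectories$time_min == times[b], ]
    conc <- stats::setNames(sub$conc_mM, sub$species)
    conc[[standard[["species"]]]] <- as.numeric(standard[["conc"]])
    sig <- complex(real = rep(0, np))
    for (k in seq_len(nrow(peak_map))) {
      sp <- peak_map$species[k]
      if (!sp %in% names(conc) || conc[[sp]] <= 0) next
      amp <- conc[[sp]] * peak_map$nuclei[k] * peak_map$weight[k] * sat[k]
      fhz <- peak_map$ppm[k] * sfrq
      sig <- sig + amp * exp(2i * pi * fhz * tvec - r2 * tvec)
    }
    if (noise$fid_noise_sd > 0)
      sig <- sig + complex(real = stats::rnorm(np, 0, noise$fid_noise_sd),
                           imaginary = stats::rnorm(np, 0, noise$fid_noise_sd))
    blocks[b, ] <- sig
  }
  fid_series(blocks, sw = sw, sfrq = sfrq, timestamps = times,
             acq_time = at, relax_delay = d1, pulse_angle = angle,
             transients = acq$transients %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a scenario specification from YAML
#'
#' YAML layout: `law`, `params` (vf, half_sat map, h, alpha, keq),
#' `assays` (map of initial-concentration maps), `times` (either
#' `{from, to, points}` or an explicit list; the key is `points`, not `n`,
#' because bare `n` is a YAML 1.1 boolean), `noise` (conc_add_sd etc.),
#' `vf_jitter_sd`, `sessions`, `seed`.
#'
#' @param path YAML file.
#' @return A [scenario_spec()].
#' @export
read_scenario_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  p <- y$params
  params <- rate_law_params(vf = p$vf, half_sat = unlist(p$half_sat),
                            h = p$h %||% 1, alpha = p$alpha %||% 1,
                            keq = p$keq,
                            protein_conc = p$protein_conc %||% 1)
  times <- if (!is.null(y$times$points))
    seq(y$times$from %||% 0, y$times$to, length.out = y$times$points)
  else unlist(y$times)
  scenario_spec(law = y$law, params = params,
                assays = lapply(y$assays, unlist), times = times,
                noise = do.call(noise_model, y$noise %||% list()),
                sessions = y$sessions,
                vf_jitter_sd = y$vf_jitter_sd %||% 0, seed = y$seed)
}
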