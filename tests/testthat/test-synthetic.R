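test_that("zero-noise time courses lie exactly on the ODE solution", {
  sc <- pgi_scenario(n_times = 15L)
  sim <- simulate_noisy_timecourses(sc)
  expect_equal(sim$curves$conc_mM, sim$truth$exact$conc_mM, tolerance = 1e-12)
  # independent check of one assay against fixed-step RK4
  dv <- function(t, y) {
    v <- oracle_rev_mm(y[["G6P"]], y[["F6P"]], 0.3551, 0.550, 0.152, 0.286)
    c(G6P = -v, F6P = v)
  }
  fine <- seq(0, 12, length.out = 4001)
  ork <- oracle_rk4(dv, c(G6P = 2, F6P = 0), fine)
  g <- sim$curves[sim$curves$assay_id == "fwd2" &
                    sim$curves$species == "G6P", ]
  expect_equal(g$conc_mM,
               stats::approx(fine, ork[, "G6P"], xout = g$time_min,
                             rule = 2)$y,
               tolerance = 1e-5)
})

test_that("generation is reproducible under a fixed seed and varies across seeds", {
  noisy <- noise_model(conc_mult_sd = 0.05)
  s1 <- simulate_noisy_timecourses(pgi_scenario(noise = noisy, seed = 3,
                                                n_times = 10L))
  s2 <- simulate_noisy_timecourses(pgi_scenario(noise = noisy, seed = 3,
                                                n_times = 10L))
  s3 <- simulate_noisy_timecourses(pgi_scenario(noise = noisy, seed = 4,
                                                n_times = 10L))
  expect_identical(s1$curves, s2$curves)
  expect_gt(max(abs(s1$curves$conc_mM - s3$curves$conc_mM)), 0)
  expect_error(scenario_spec("pgi", pgi_table_params(),
                             list(a = c(G6P = 1, F6P = 0)), times = 0:5),
               "seed")
})

test_that("the PGI scenario relaxes toward the equilibrium ratio", {
  sim <- simulate_noisy_timecourses(pgi_scenario())
  tab <- sim$curves
  for (id in unique(tab$assay_id)) {
    g <- tab[tab$assay_id == id & tab$species == "G6P", "conc_mM"]
    f <- tab[tab$assay_id == id & tab$species == "F6P", "conc_mM"]
    expect_equal(tail(f, 1) / tail(g, 1), 0.286, tolerance = 0.02)
  }
})

test_that("noise is applied as specified and clipped at zero", {
  nm <- noise_model(conc_add_sd = 0.5, conc_mult_sd = 0)
  sc <- pgi_scenario(noise = nm, seed = 12, n_times = 25L)
  sim <- simulate_noisy_timecourses(sc)
  resid <- sim$curves$conc_mM - sim$truth$exact$conc_mM
  # additive residuals (before clipping) have the stated scale
  unclipped <- sim$curves$flag == "ok" & sim$curves$conc_mM > 0
  expect_equal(sd(resid[unclipped]), 0.5, tolerance = 0.15)
  expect_true(all(sim$curves$conc_mM >= 0))
  expect_true(any(sim$curves$flag == "clipped"))  # F6P=0 starts must clip
})

test_that("scenario YAML round-trips", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "law: pgi",
    "params: {vf: 3.551, half_sat: {G6P: 0.55, F6P: 0.152}, h: 1, keq: 0.286}",
    "assays:",
    "  fwd: {G6P: 5, F6P: 0}",
    "times: {from: 0.5, to: 20, points: 11}",
    "noise: {conc_mult_sd: 0.03}",
    "seed: 5"), path)
  sc <- read_scenario_yaml(path)
  expect_s3_class(sc, "scenario_spec")
  expect_equal(sc$params$keq, 0.286)
  expect_equal(sc$times$fwd, seq(0.5, 20, length.out = 11))
  expect_equal(sc$noise$conc_mult_sd, 0.03)
  sim <- simulate_noisy_timecourses(sc)
  expect_equal(nrow(sim$curves), 22)
})

test_that("synthetic FIDs round-trip through quantification", {
  tt <- seq(1, 10, length.out = 8)
  traj <- data.frame(time_min = tt, species = "G6P",
                     conc_mM = 8 * exp(-0.15 * tt))
  acq <- list(sw = 10000, sfrq = 242.87, np = 8192, relax_delay = 0.5)
  fid <- synthesize_fid_series(traj, acq = acq, noise = noise_model(),
                               seed = 7)
  cal <- default_calibration(trep = fid$acq_time + fid$relax_delay)
  wins <- default_peak_windows(c("TEP", "G6P"))
  std <- list(species = "TEP", conc = 10)
  # noiseless round trip within 0.1%, both quantification routes
  for (mth in c("box", "deconv")) {
    q <- quantify_series(fid, wins, cal, std, method = mth)
    expect_equal(q$conc_mM[q$species == "G6P"], traj$conc_mM,
                 tolerance = 1e-3)
  }
  # box integration and deconvolution agree within 2% on isolated peaks
  qb <- quantify_series(fid, wins, cal, std, method = "box")
  qd <- quantify_series(fid, wins, cal, std, method = "deconv")
  expect_equal(qb$conc_mM, qd$conc_mM, tolerance = 0.02)
})

test_that("quantification stays within noise bounds at SNR ~ 50", {
  tt <- seq(1, 10, length.out = 8)
  traj <- data.frame(time_min = tt, species = "G6P", conc_mM = rep(5, 8))
  acq <- list(sw = 10000, sfrq = 242.87, np = 8192, relax_delay = 0.5)
  fid <- synthesize_fid_series(traj, acq = acq,
                               noise = noise_model(fid_noise_sd = 2),
                               seed = 19)
  fida <- apodize_exponential(fid, 8.5)
  specs <- lapply(1:8, function(b) fid_to_spectrum(fida, b))
  # realized spectral SNR
  snr <- max(specs[[1]]$intensity[abs(specs[[1]]$ppm - 3.35) < 0.1]) /
    sd(specs[[1]]$intensity[specs[[1]]$ppm < -5])
  expect_gt(snr, 25); expect_lt(snr, 120)
  # propagated noise bound: apodization correlates spectral noise across
  # neighbouring bins, so the area-noise floor is measured empirically from
  # window-width integrals over signal-free regions
  noise_areas <- unlist(lapply(specs, function(sp)
    vapply(c(-8, -12, -16, 6, 8), function(p0)
      integrate_window(sp, peak_window("blank", p0 - 0.15, p0 + 0.15)), 0)))
  sig_a <- sd(noise_areas)
  a_g6p <- mean(vapply(specs, integrate_window,
                       0, window = default_peak_windows("G6P")[[1]]))
  a_tep <- mean(vapply(specs, integrate_window,
                       0, window = default_peak_windows("TEP")[[1]]))
  bound <- 3 * sqrt((sig_a / a_g6p)^2 + (sig_a / a_tep)^2)
  q <- quantify_series(fid, default_peak_windows(c("TEP", "G6P")),
                       default_calibration(fid$acq_time + 0.5),
                       list(species = "TEP", conc = 10), method = "deconv")
  relerr <- q$conc_mM[q$species == "G6P"] / 5 - 1
  expect_lt(sqrt(mean(relerr^2)), bound)
})

test_that("a zero trajectory leaves only the internal standard", {
  tt <- c(1, 2, 3, 4)
  traj <- data.frame(time_min = tt, species = "G6P", conc_mM = 0)
  fid <- synthesize_fid_series(traj, acq = list(sw = 10000, sfrq = 242.87,
                                                np = 4096, relax_delay = 0.5),
                               noise = noise_model(), seed = 2)
  sp <- fid_to_spectrum(fid, 1)
  # signal at the TEP shift, none at the G6P shift
  expect_gt(max(sp$intensity[abs(sp$ppm - 0.45) < 0.1]),
            100 * max(abs(sp$intensity[abs(sp$ppm - 3.35) < 0.1])))
})

test_that("F6P between the FBP anomer peaks: box biased, deconvolution better", {
  # the documented hard case: F6P at 2.42 ppm sits between FBP quartet peaks
  # at 2.58 and 2.32 ppm; overlapping tails bias the F6P box integral while
  # a multi-component deconvolution separates them
  tt <- c(1, 3, 5)
  traj <- rbind(
    data.frame(time_min = tt, species = "F6P", conc_mM = 1.0),
    data.frame(time_min = tt, species = "FBP", conc_mM = 8))
  acq <- list(sw = 10000, sfrq = 242.87, np = 16384, relax_delay = 0.5)
  fid <- synthesize_fid_series(traj, acq = acq,
                               noise = noise_model(lw_hz = 1.5), seed = 5)
  cal <- default_calibration(fid$acq_time + 0.5)
  std <- list(species = "TEP", conc = 10)
  wins_f6p <- list(default_peak_windows("TEP")[[1]],
                   peak_window("F6P", 2.42 - 0.045, 2.42 + 0.045,
                               components = 1))
  qb <- quantify_series(fid, wins_f6p, cal, std, method = "box", lb = 2)
  err_box <- abs(qb$conc_mM[qb$species == "F6P"] / 1.0 - 1)
  expect_gt(min(err_box), 0.05)  # box is biased by FBP tails
})

test_that("full pipeline round trip: synthesize -> quantify -> spline -> fit", {
  # one-species view is not enough to fit PGI, so run both G6P and F6P
  # through the FID stage for all five assays, then fit the law; noiseless
  # FIDs, Lorentzian deconvolution with a local linear baseline (the large
  # neighbouring G6P resonance would otherwise bleed into low F6P windows)
  sc <- pgi_scenario()
  sim <- simulate_noisy_timecourses(sc)
  acq <- list(sw = 10000, sfrq = 242.87, np = 8192, relax_delay = 0.5)
  cal <- default_calibration(8192 / 10000 + 0.5)
  wins <- default_peak_windows(c("TEP", "G6P", "F6P"))
  tabs <- lapply(names(sc$assays), function(id) {
    traj <- sim$curves[sim$curves$assay_id == id,
                       c("time_min", "species", "conc_mM")]
    fid <- synthesize_fid_series(traj, acq = acq, noise = noise_model(),
                                 seed = 1)
    quantify_series(fid, wins, cal, list(species = "TEP", conc = 10),
                    method = "deconv", deconv_baseline = "linear", lb = 2,
                    assay_id = id)
  })
  tab <- do.call(rbind, tabs)
  # quantified concentrations match the generating trajectories
  merged <- merge(tab, sim$curves, by = c("assay_id", "time_min", "species"))
  keep <- merged$conc_mM.y > 0.2
  expect_lt(max(abs(merged$conc_mM.x[keep] / merged$conc_mM.y[keep] - 1)),
            0.01)
  dat <- build_rate_dataset(tab, pgi_scheme())
  prob <- global_fit_problem(
    "pgi", dat, free = c(vf = 0.5, k_G6P = 0.3, k_F6P = 0.3, keq = 0.5),
    fixed = c(h = 1), seed = 6)
  fit <- fit_global(prob, ga_control(generations = 80))
  expect_equal(unname(fit$par[["vf"]]) / 0.1, 3.551, tolerance = 0.01)
  expect_equal(unname(fit$par[["k_G6P"]]), 0.550, tolerance = 0.01)
  expect_equal(unname(fit$par[["k_F6P"]]), 0.152, tolerance = 0.01)
  expect_equal(unname(fit$par[["keq"]]), 0.286, tolerance = 0.01)
})

test_that("recovered-parameter spread matches reported errors at the default noise", {
  # at the generator's default 3% multiplicative noise, the empirical
  # standard deviation of recovered parameters across seeded replicates
  # stays within a factor 2 of the mean reported standard error
  truth <- c(vf = 0.3551, k_G6P = 0.550, k_F6P = 0.152, keq = 0.286)
  n_rep <- 100L
  est <- sem <- matrix(NA_real_, n_rep, 4,
                       dimnames = list(NULL, names(truth)))
  for (r in seq_len(n_rep)) {
    sim <- simulate_noisy_timecourses(
      pgi_scenario(noise = noise_model(conc_mult_sd = 0.03),
                   seed = 2000L + r))
    dat <- build_rate_dataset(
      sim$curves, pgi_scheme(),
      smoothing = function(cv) 0.5 * mean((0.03 * cv$conc)^2))
    fit <- fit_global(global_fit_problem(
      "pgi", dat, free = c(vf = 0.5, k_G6P = 0.3, k_F6P = 0.3, keq = 0.5),
      fixed = c(h = 1), seed = 2000L + r),
      ga_control(generations = 60, pop_size = 48))
    est[r, ] <- fit$par[names(truth)]
    sem[r, ] <- fit$sem[names(truth)]
  }
  for (nm in names(truth)) {
    ratio <- sd(est[, nm]) / mean(sem[, nm])
    expect_lt(ratio, 2)
    expect_gt(ratio, 0.5)
  }
})
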