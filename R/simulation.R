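#' Mg-nucleotide rapid-equilibrium partition
#'
#' Partitions total ATP and ADP pools into Mg-bound and free forms under
#' rapid equilibrium with a clamped free Mg2+ concentration:
#' `MgATP / ATP_free = K_atp * [Mg]` (and likewise for ADP), with
#' `complexed + free = total` per nucleotide. Binding constants are in
#' M^-1 as conventionally tabulated; concentrations in mM.
#'
#' @param total_atp,total_adp total nucleotide pools, mM (>= 0). Vectorized.
#' @param free_mg free Mg2+ concentration, mM (>= 0).
#' @param K_atp,K_adp association constants, M^-1 (defaults 1e4 and 1e3).
#' @return List with `MgATP`, `ATP_free`, `MgADP`, `ADP_free` (mM).
#' @examples
#' mg_partition(5, 0, free_mg = 1)$MgATP  # 10/11 of the pool Mg-bound
#' @export
mg_partition <- function(total_atp, total_adp, free_mg = 1,
                         K_atp = 1e4, K_adp = 1e3) {
  if (any(total_atp < 0) || any(total_adp < 0) || any(free_mg < 0) ||
      K_atp < 0 || K_adp < 0)
    stop("all inputs must be non-negative")
  fa <- (K_atp / 1000) * free_mg  # K [M^-1] * Mg [mM] / 1000 -> dimensionless
  fd <- (K_adp / 1000) * free_mg
  list(MgATP = total_atp * fa / (1 + fa),
       ATP_free = total_atp / (1 + fa),
       MgADP = total_adp * fd / (1 + fd),
       ADP_free = total_adp / (1 + fd))
}

#' Minimal coupled PGI-PFK model
#'
#' The two-enzyme validation model: reversible PGI (G6P <-> F6P), the
#' bi-substrate irreversible Hill PFK (F6P + ATP -> FBP + ADP, PEP
#' inhibitor), rapid-equilibrium Mg binding of ATP and ADP at a clamped free
#' Mg2+ level, and a first-order background hydrolysis consuming MgADP to
#' AMP + Pi + Mg2+. The hydrolysis driver is configurable: `"mgatp"` makes
#' the rate `k_hyd * [MgATP]` (background ATP hydrolysis compensated by
#' adenylate kinase), `"mgadp"` makes it an elementary first-order decay
#' `k_hyd * [MgADP]`.
#'
#' @param pgi [rate_law_params()] of the reversible PGI law (half_sat order
#'   G6P, F6P; `keq` set).
#' @param pfk [rate_law_params()] of the PFK law (half_sat order F6P, ATP,
#'   PEP). When `atp_species = "MgATP"` the ATP half-saturation should be the
#'   Mg-corrected value.
#' @param K_mgatp,K_mgadp Mg association constants, M^-1.
#' @param free_mg clamped free Mg2+ concentration, mM.
#' @param k_hyd first-order hydrolysis rate constant, min^-1.
#' @param hydrolysis hydrolysis driver, `"mgatp"` (default) or `"mgadp"`.
#' @param atp_species which ATP pool PFK sees: `"MgATP"` (the true
#'   substrate; default) or `"total"`.
#' @return Object of class `minimal_model`.
#' @export
minimal_model <- function(pgi = pgi_table_params(),
                          pfk = pfk_table_params(mg_corrected = TRUE),
                          K_mgatp = 1e4, K_mgadp = 1e3, free_mg = 1,
                          k_hyd = 2e-4,
                          hydrolysis = c("mgatp", "mgadp"),
                          atp_species = c("MgATP", "total")) {
  stopifnot(inherits(pgi, "rate_law_params"), inherits(pfk, "rate_law_params"))
  if (is.null(pgi$keq)) stop("PGI law must be reversible (keq set)")
  if (K_mgatp <= 0 || K_mgadp <= 0) stop("Mg binding constants must be > 0")
  structure(list(pgi = pgi, pfk = pfk, K_mgatp = K_mgatp, K_mgadp = K_mgadp,
                 free_mg = free_mg, k_hyd = k_hyd,
                 hydrolysis = match.arg(hydrolysis),
                 atp_species = match.arg(atp_species),
                 species = c("G6P", "F6P", "FBP", "ATP", "ADP",
                             "AMP", "Pi", "PEP")),
            class = "minimal_model")
}

## Derivatives of the minimal model; state in mM, time in min. ATP/ADP are
## total pools; Mg speciation is substituted algebraically at each call
## (rapid equilibrium), avoiding artificial stiffness.
minimal_model_deriv <- function(t, y, model) {
  y <- pmax(y, 0)
  part <- mg_partition(y[["ATP"]], y[["ADP"]], model$free_mg,
                       model$K_mgatp, model$K_mgadp)
  v_pgi <- rate_reversible_hill_uni(y[["G6P"]], y[["F6P"]], model$pgi)
  atp_eff <- if (model$atp_species == "MgATP") part$MgATP else y[["ATP"]]
  v_pfk <- rate_irreversible_hill_bi(y[["F6P"]], atp_eff, y[["PEP"]],
                                     model$pfk)
  v_hyd <- model$k_hyd *
    if (model$hydrolysis == "mgatp") part$MgATP else part$MgADP
  v_hyd <- min(v_hyd, 1e6)  # guard; never negative by construction
  list(c(G6P = -v_pgi,
         F6P =  v_pgi - v_pfk,
         FBP =  v_pfk,
         ATP = -v_pfk,
         ADP =  v_pfk - v_hyd,
         AMP =  v_hyd,
         Pi  =  v_hyd,
         PEP =  0),
       v_pgi = v_pgi, v_pfk = v_pfk, v_hyd = v_hyd)
}

#' Simulate the minimal coupled model
#'
#' Integrates the minimal PGI-PFK model from measured initial concentrations
#' with a stiff-capable solver (`deSolve::ode`, lsoda). With PFK inactive the
#' PGI sub-system relaxes to the mass-action ratio `F6P/G6P = Keq`; with all
#' rate constants zero the state is constant.
#'
#' @param model a [minimal_model()].
#' @param y0 named initial concentrations (mM); missing species default to 0.
#' @param t_grid increasing time grid, min.
#' @param ... passed to [deSolve::ode()] (e.g. `rtol`, `atol`).
#' @return Object of class `sim_trajectory`: data frame `conc` (time +
#'   species columns + instantaneous fluxes) and solver `diagnostics`.
#' @export
simulate_minimal_model <- function(model, y0, t_grid, ...) {
  stopifnot(inherits(model, "minimal_model"))
  if (any(diff(t_grid) <= 0)) stop("'t_grid' must be strictly increasing")
  full0 <- stats::setNames(rep(0, length(model$species)), model$species)
  unknown <- setdiff(names(y0), model$species)
  if (length(unknown))
    stop("unknown species in y0: ", paste(unknown, collapse = ", "))
  full0[names(y0)] <- y0
  sol <- deSolve::ode(y = full0, times = t_grid,
                      func = function(t, y, p) minimal_model_deriv(t, y, model),
                      parms = NULL, method = "lsoda",
                      rtol = 1e-9, atol = 1e-10, ...)
  diag <- utils::capture.output(deSolve::diagnostics.deSolve(sol))
  conc <- as.data.frame(sol)
  structure(list(conc = conc, model = model, diagnostics = diag),
            class = "sim_trajectory")
}

#' @export
print.sim_trajectory <- function(x, ...) {
  cat("simulated trajectory:", nrow(x$conc), "time points,",
      "t =", min(x$conc$time), "..", max(x$conc$time), "min\n")
  print(utils::head(x$conc[, c("time", x$model$species)], 3))
  invisible(x)
}

#' Compare a simulated trajectory with experimental progress curves
#'
#' Interpolates the simulation onto each curve's measured times and reports
#' per-species and pooled root-mean-square error and bias
#' (simulation - experiment).
#'
#' @param traj a `sim_trajectory` from [simulate_minimal_model()].
#' @param curves list of [progress_curve()] objects (or a tidy table).
#' @return Data frame with one row per species plus a `pooled` row:
#'   `species`, `n`, `rmse`, `bias` (mM).
#' @export
compare_to_experiment <- function(traj, curves) {
  stopifnot(inherits(traj, "sim_trajectory"))
  if (is.data.frame(curves)) curves <- table_to_curves(curves)
  tmin <- min(traj$conc$time); tmax <- max(traj$conc$time)
  rows <- list(); resid_all <- numeric()
  for (cv in curves) {
    if (!cv$species %in% names(traj$conc)) next
    tt <- cv$time[cv$time >= tmin & cv$time <= tmax & cv$valid]
    if (!length(tt))
      stop("curve ", cv$assay_id, "/", cv$species,
           " has no overlap with the simulated time span")
    sim <- stats::approx(traj$conc$time, traj$conc[[cv$species]], xout = tt)$y
    obs <- cv$conc[match(tt, cv$time)]
    d <- sim - obs
    rows[[length(rows) + 1L]] <-
      data.frame(species = cv$species, n = length(d),
                 rmse = sqrt(mean(d^2)), bias = mean(d))
    resid_all <- c(resid_all, d)
  }
  if (!length(rows)) stop("no comparable species between trajectory and curves")
  out <- do.call(rbind, rows)
  rbind(out, data.frame(species = "pooled", n = length(resid_all),
                        rmse = sqrt(mean(resid_all^2)),
                        bias = mean(resid_all)))
}

#' Write a simulated trajectory to CSV
#'
#' @param traj a `sim_trajectory`.
#' @param path output file.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(traj$conc, path, row.names = FALSE)
  invisible(path)
}
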