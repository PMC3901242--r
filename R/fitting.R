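#' Global fit problem
#'
#' Bundles everything the global fitter needs: the rate law, the pooled
#' rate-sample dataset, which parameters are free (with bounds) or fixed,
#' and a seed making the whole fit reproducible.
#'
#' Parameters are searched in log space, which enforces positivity; bounds
#' default to `init * c(1e-3, 1e3)`.
#'
#' @param law a `rate_law` object or registry name (see [get_rate_law()]).
#' @param data rate-sample data frame: columns `rate` (mM/min), optionally
#'   `assay_id`, `time`, `weight`, plus one concentration column per species
#'   the law needs (see [rates_from_splines()]).
#' @param free named numeric vector of initial guesses for free parameters.
#' @param fixed named numeric vector of fixed parameters.
#' @param lower,upper named bounds on free parameters (positive, finite).
#' @param seed integer seed for the genetic-algorithm stage.
#' @return An object of class `fit_problem`.
#' @export
global_fit_problem <- function(law, data, free, fixed = numeric(),
                               lower = NULL, upper = NULL, seed = 1L) {
  if (is.character(law)) law <- get_rate_law(law)
  stopifnot(inherits(law, "rate_law"), is.data.frame(data), nrow(data) > 0)
  if (!"rate" %in% names(data)) stop("dataset needs a 'rate' column")
  missing_sp <- setdiff(law$species, names(data))
  if (length(missing_sp))
    stop("dataset lacks concentration columns: ",
         paste(missing_sp, collapse = ", "))
  if (is.null(names(free)) || !length(free))
    stop("'free' must be a named vector of initial guesses")
  if (!is.null(law$par_names)) {
    unknown <- setdiff(c(names(free), names(fixed)), law$par_names)
    if (length(unknown))
      stop("parameters not used by law '", law$name, "': ",
           paste(unknown, collapse = ", "))
  }
  if (is.null(lower)) lower <- free * 1e-3
  if (is.null(upper)) upper <- free * 1e3
  lower <- lower[names(free)]; upper <- upper[names(free)]
  if (any(!is.finite(lower)) || any(!is.finite(upper)) ||
      any(lower <= 0) || any(upper <= lower))
    stop("bounds must be finite, positive, and lower < upper")
  if (any(free < lower) || any(free > upper))
    stop("initial guesses must lie inside the bounds")
  if (!"weight" %in% names(data)) data$weight <- 1
  structure(list(law = law, data = data, free = free, fixed = fixed,
                 lower = lower, upper = upper, seed = as.integer(seed)),
            class = "fit_problem")
}

#' Weighted residual vector of a parameter point
#'
#' `r_i = sqrt(w_i) * (v_model(c_i; theta) - v_obs,i)`. Non-finite model
#' values are replaced by a large penalty (and counted), so the optimizer is
#' steered away rather than crashing.
#'
#' @param theta_free named numeric vector of free parameter values.
#' @param problem a [global_fit_problem()].
#' @return Numeric vector, one residual per sample.
#' @export
residuals_global <- function(theta_free, problem) {
  theta <- c(theta_free, problem$fixed)
  v <- tryCatch(law_rate(problem$law, problem$data, theta),
                error = function(e) rep(NA_real_, nrow(problem$data)))
  r <- sqrt(problem$data$weight) * (v - problem$data$rate)
  bad <- !is.finite(r)
  if (any(bad)) {
    r[bad] <- 1e6
    attr(r, "n_penalized") <- sum(bad)
  }
  r
}

rss_of <- function(theta_free, problem) sum(residuals_global(theta_free, problem)^2)

#' Genetic-algorithm settings
#'
#' Knobs of the global-search stage: population size, generation count,
#' tournament size, per-gene Gaussian mutation (applied in log-parameter
#' space), uniform-crossover rate and elite count. Candidates of equal
#' fitness are resolved by lowest index, keeping runs deterministic.
#'
#' @param pop_size individuals per generation.
#' @param generations number of generations.
#' @param elitism elites copied unchanged into the next generation.
#' @param tournament tournament size for parent selection.
#' @param mutation_sd standard deviation of log-space Gaussian mutation.
#' @param mutation_rate per-gene mutation probability.
#' @param crossover_rate probability of uniform crossover per mating.
#' @return List of class `ga_control`.
#' @export
ga_control <- function(pop_size = 64L, generations = 200L, elitism = 2L,
                       tournament = 2L, mutation_sd = 0.3,
                       mutation_rate = 0.4, crossover_rate = 0.7) {
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 elitism = as.integer(elitism),
                 tournament = as.integer(tournament),
                 mutation_sd = mutation_sd, mutation_rate = mutation_rate,
                 crossover_rate = crossover_rate), class = "ga_control")
}

## GA over log-parameters; returns list(par, rss). Deterministic given the
## RNG state set by the caller.
run_ga <- function(problem, ctrl) {
  lo <- log(problem$lower); hi <- log(problem$upper)
  npar <- length(lo); np <- ctrl$pop_size
  pop <- matrix(stats::runif(np * npar, lo, hi), nrow = np, byrow = TRUE)
  pop[1L, ] <- pmin(pmax(log(problem$free), lo), hi)  # seed the initial guess
  fitness <- apply(pop, 1L, function(g) {
    th <- exp(g); names(th) <- names(problem$free); rss_of(th, problem)
  })
  for (gen in seq_len(ctrl$generations)) {
    ord <- order(fitness)           # ties -> lowest index (order is stable)
    elite <- pop[ord[seq_len(ctrl$elitism)], , drop = FALSE]
    newpop <- matrix(NA_real_, np, npar)
    newpop[seq_len(ctrl$elitism), ] <- elite
    for (i in seq.int(ctrl$elitism + 1L, np)) {
      pick <- function() {
        cand <- sample.int(np, ctrl$tournament)
        cand[which.min(fitness[cand])]
      }
      p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
      child <- if (stats::runif(1) < ctrl$crossover_rate) {
        mask <- stats::runif(npar) < 0.5
        ifelse(mask, p1, p2)
      } else p1
      mut <- stats::runif(npar) < ctrl$mutation_rate
      child[mut] <- child[mut] + stats::rnorm(sum(mut), sd = ctrl$mutation_sd)
      newpop[i, ] <- pmin(pmax(child, lo), hi)
    }
    pop <- newpop
    fitness <- apply(pop, 1L, function(g) {
      th <- exp(g); names(th) <- names(problem$free); rss_of(th, problem)
    })
  }
  best <- which.min(fitness)
  par <- exp(pop[best, ]); names(par) <- names(problem$free)
  list(par = par, rss = fitness[best])
}

## Numeric Jacobian of the residual vector wrt the (linear-scale) free
## parameters, central differences with relative step.
residual_jacobian <- function(theta_free, problem, rel_step = 1e-6) {
  n <- nrow(problem$data); p <- length(theta_free)
  J <- matrix(NA_real_, n, p, dimnames = list(NULL, names(theta_free)))
  for (j in seq_len(p)) {
    dh <- max(abs(theta_free[j]), 1e-12) * rel_step
    up <- theta_free; up[j] <- up[j] + dh
    dn <- theta_free; dn[j] <- dn[j] - dh
    J[, j] <- (residuals_global(up, problem) -
               residuals_global(dn, problem)) / (2 * dh)
  }
  J
}

## Residual-variance-scaled covariance from the Jacobian, with SVD guard for
## unidentifiable directions (tiny singular values -> Inf SEM, not garbage).
cov_from_jacobian <- function(J, rss, dof) {
  s2 <- rss / dof
  sv <- svd(J)
  tol <- max(sv$d) * 1e-10
  ok <- sv$d > tol
  if (!any(ok)) stop("residual Jacobian is numerically zero")
  dinv2 <- ifelse(ok, 1 / sv$d^2, Inf)
  if (all(ok)) {
    cv <- sv$v %*% (dinv2 * t(sv$v)) * s2
  } else {
    cv <- sv$v[, ok, drop = FALSE] %*%
      (dinv2[ok] * t(sv$v[, ok, drop = FALSE])) * s2
    # mark unidentifiable directions on the diagonal
    bad_dir <- sv$v[, !ok, drop = FALSE]
    diag(cv)[rowSums(abs(bad_dir) > 0.5) > 0] <- Inf
  }
  dimnames(cv) <- list(colnames(J), colnames(J))
  list(cov = cv, rank_deficient = !all(ok))
}

## One Levenberg-Marquardt refinement in log-parameter space.
lm_refine <- function(problem, start_par) {
  lm <- minpack.lm::nls.lm(
    par = log(start_par),
    lower = log(problem$lower), upper = log(problem$upper),
    fn = function(lg) {
      th <- exp(lg); names(th) <- names(problem$free)
      residuals_global(th, problem)
    },
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14))
  par <- exp(lm$par); names(par) <- names(problem$free)
  list(par = par, rss = sum(residuals_global(par, problem)^2),
       info = lm$info)
}

#' Global fit: genetic-algorithm search refined by Levenberg-Marquardt
#'
#' Two-stage global fit of a rate law to pooled rate samples: a seeded
#' genetic algorithm searches the (log-scale) parameter box, and its best
#' individual is refined by Levenberg-Marquardt least squares. Because the
#' least-squares surface of saturation-type laws is multimodal along
#' half-saturation parameters (a half-saturation far above the sampled
#' concentration range is locally as good as any other large value), the
#' refinement is multi-started: besides the GA optimum, LM also starts from
#' the GA optimum with each half-saturation (`k_*`) parameter reset to each
#' decade inside its bounds; the lowest-RSS refinement wins (ties: first).
#' The result never worsens the GA optimum; if LM cannot improve it, the GA
#' solution is returned with `convergence = FALSE`. Identical problem and
#' seed give identical results.
#'
#' @param problem a [global_fit_problem()].
#' @param ga a [ga_control()]; pass `generations = 0` to skip the GA and
#'   refine the initial guess directly.
#' @param multistart logical; scan half-saturation decades in the
#'   refinement stage (default TRUE).
#' @return Object of class `global_fit`: `par` (free estimates), `fixed`,
#'   `sem`, `cov`, `rss`, `n`, `p`, `r2`, `convergence`, `ga_rss`, `seed`.
#' @seealso [parameter_errors()], [goodness_of_fit()], [truncation_scan()]
#' @export
fit_global <- function(problem, ga = ga_control(), multistart = TRUE) {
  stopifnot(inherits(problem, "fit_problem"))
  n <- nrow(problem$data); p <- length(problem$free)
  if (n <= p) stop("need more samples than free parameters")
  set.seed(problem$seed)
  start <- if (ga$generations > 0L) run_ga(problem, ga)
           else list(par = problem$free, rss = rss_of(problem$free, problem))

  starts <- list(start$par)
  if (isTRUE(multistart)) {
    for (nm in grep("^k_", names(problem$free), value = TRUE)) {
      decades <- 10^seq(ceiling(log10(problem$lower[[nm]]) + 0.01),
                        floor(log10(problem$upper[[nm]]) - 0.01))
      for (v in decades) {
        s <- start$par; s[[nm]] <- v
        starts[[length(starts) + 1L]] <- s
      }
    }
  }
  refs <- lapply(starts, function(s) lm_refine(problem, s))
  best <- refs[[which.min(vapply(refs, `[[`, 0, "rss"))]]
  converged <- best$info %in% 1:4 && best$rss <= start$rss + 1e-12
  par <- if (best$rss <= start$rss) best$par else start$par
  rss <- min(best$rss, start$rss)

  J <- residual_jacobian(par, problem)
  cv <- cov_from_jacobian(J, rss, n - p)
  sem <- sqrt(pmax(diag(cv$cov), 0))
  v_obs <- problem$data$rate
  theta <- c(par, problem$fixed)
  v_fit <- law_rate(problem$law, problem$data, theta)
  tss <- sum((v_obs - mean(v_obs))^2)
  r2 <- if (tss > 0) 1 - sum((v_fit - v_obs)^2) / tss else NA_real_

  structure(list(par = par, fixed = problem$fixed, sem = sem, cov = cv$cov,
                 rank_deficient = cv$rank_deficient, rss = rss, n = n, p = p,
                 r2 = r2, convergence = converged, ga_rss = start$rss,
                 lm_info = best$info, seed = problem$seed,
                 law = problem$law$name, problem = problem),
            class = "global_fit")
}

#' @export
print.global_fit <- function(x, ...) {
  cat(sprintf("global fit of '%s' law: %d samples, %d free parameters\n",
              x$law, x$n, x$p))
  tab <- data.frame(estimate = x$par, sem = x$sem)
  print(format(tab, digits = 4))
  if (length(x$fixed))
    cat("fixed:", paste(names(x$fixed), signif(x$fixed, 4), sep = " = ",
                        collapse = ", "), "\n")
  cat(sprintf("RSS %.4g, R^2 %.4f, converged: %s\n",
              x$rss, x$r2, x$convergence))
  invisible(x)
}

#' Standard errors of fitted parameters
#'
#' Parameter covariance is the Jacobian approximation to the inverse Hessian
#' scaled by the residual variance, `cov = (J'J)^-1 * RSS/(n - p)`; reported
#' errors are the square roots of its diagonal. Unidentifiable directions
#' (rank-deficient Jacobian) yield infinite errors and a flag rather than
#' silent numbers.
#'
#' @param fit a `global_fit`.
#' @return Named vector of standard errors.
#' @export
parameter_errors <- function(fit) {
  stopifnot(inherits(fit, "global_fit"))
  fit$sem
}

#' Goodness of fit
#'
#' `R^2 = 1 - RSS/TSS` over the pooled observed rates. A zero-variance
#' dataset has no defined R^2 and errors out.
#'
#' @param fit a `global_fit`.
#' @param data optional dataset to evaluate on (default: the fitted one).
#' @return R^2 (<= 1; 1 iff the fit is exact).
#' @export
goodness_of_fit <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "global_fit"))
  if (is.null(data)) data <- fit$problem$data
  v_obs <- data$rate
  tss <- sum((v_obs - mean(v_obs))^2)
  if (tss == 0) stop("zero-variance dataset: R^2 undefined")
  v_fit <- law_rate(fit$problem$law, data, c(fit$par, fit$fixed))
  1 - sum((v_fit - v_obs)^2) / tss
}

#' Truncation-stability scan
#'
#' Refits the rate law after sequentially deleting the latest-time (i.e.
#' closest-to-equilibrium) samples of every assay: step `k` removes the `k`
#' last samples of each assay. Parameter errors are reported under two
#' degrees-of-freedom conventions: rescaled (`dof = n_k - p`, reflecting the
#' truncation) and original (`dof = n_0 - p`), which separates the error
#' contribution of losing data in general from that of specifically losing
#' near-equilibrium data. Refits start from the baseline solution and use
#' Levenberg-Marquardt only.
#'
#' @param problem a [global_fit_problem()] whose data has `assay_id` and
#'   `time` columns.
#' @param max_remove maximum number of points removed per assay (must leave
#'   every assay non-empty and the pooled dof positive; the scan stops early
#'   with a warning otherwise).
#' @param ga [ga_control()] for the baseline fit.
#' @return Object of class `truncation_scan`: `baseline` fit, and `steps`, a
#'   data frame with one row per truncation step (pooled points removed, RSS,
#'   estimates, and both SEM conventions) plus the per-step fits in
#'   `fits`.
#' @export
truncation_scan <- function(problem, max_remove, ga = ga_control()) {
  stopifnot(inherits(problem, "fit_problem"))
  if (!all(c("assay_id", "time") %in% names(problem$data)))
    stop("truncation scan needs 'assay_id' and 'time' columns")
  baseline <- fit_global(problem, ga)
  p <- baseline$p
  n0 <- baseline$n
  fits <- vector("list", max_remove + 1L)
  fits[[1L]] <- baseline
  rows <- list()
  rows[[1L]] <- .scan_row(0L, 0L, baseline, n0)
  dat <- problem$data
  shortest <- min(table(dat$assay_id))
  if (max_remove >= shortest)
    stop("max_remove must be smaller than the shortest assay (",
         shortest, " points)")
  for (k in seq_len(max_remove)) {
    keep <- unlist(lapply(split(seq_len(nrow(dat)), dat$assay_id),
                          function(idx) {
      ord <- idx[order(dat$time[idx])]
      ord[seq_len(length(ord) - k)]
    }))
    dk <- dat[sort(keep), ]
    if (nrow(dk) - p <= 0) {
      warning("scan stopped at step ", k, ": degrees of freedom exhausted")
      break
    }
    pk <- problem
    pk$data <- dk
    pk$free <- baseline$par       # warm start from the baseline solution
    fit_k <- fit_global(pk, ga_control(generations = 0L), multistart = FALSE)
    fits[[k + 1L]] <- fit_k
    rows[[k + 1L]] <- .scan_row(k, n0 - nrow(dk), fit_k, n0)
  }
  steps <- do.call(rbind, rows)
  structure(list(baseline = baseline, steps = steps,
                 fits = fits[seq_along(rows)]),
            class = "truncation_scan")
}

.scan_row <- function(k, removed_total, fit, n0) {
  sem_resc <- fit$sem
  # original-dof convention: same covariance shape, variance scaled by
  # RSS/(n0 - p) instead of RSS/(n_k - p)
  sem_orig <- fit$sem * sqrt((fit$n - fit$p) / (n0 - fit$p))
  out <- data.frame(step = k, removed_per_assay = k,
                    removed_total = removed_total,
                    n = fit$n, rss = fit$rss)
  for (nm in names(fit$par)) {
    out[[nm]] <- fit$par[[nm]]
    out[[paste0("sem_rescaled_", nm)]] <- sem_resc[[nm]]
    out[[paste0("sem_original_", nm)]] <- sem_orig[[nm]]
  }
  out
}

#' @export
print.truncation_scan <- function(x, ...) {
  cat("truncation scan:", nrow(x$steps) - 1L, "truncation steps\n")
  print(x$steps[, 1:5])
  invisible(x)
}

#' Serialize a fit result to JSON
#'
#' @param fit a `global_fit`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "global_fit"))
  obj <- list(law = fit$law, parameters = as.list(fit$par),
              fixed = as.list(fit$fixed), sem = as.list(fit$sem),
              covariance = unname(apply(fit$cov, 1L, as.list)),
              rss = fit$rss, n = fit$n, p = fit$p, r2 = fit$r2,
              seed = fit$seed, convergence = fit$convergence)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
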