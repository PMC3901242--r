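## Pluggable rate-law registry.
##
## A registered law couples a reaction scheme to an algebraic form and to a
## flat parameter vector ("theta") used by the global fitter:
##   vf, k_<species> (one per species the law binds), and optionally
##   h, alpha, keq. Swapping the algebraic form of a law does not touch the
## fitter, which only sees theta and a rate(conc, theta) callback.

.law_registry <- new.env(parent = emptyenv())

#' Define a rate law for the registry
#'
#' @param name registry key.
#' @param scheme a [reaction_scheme()].
#' @param form one of `"reversible_hill_uni"`, `"irreversible_hill_bi"`,
#'   `"irreversible_mm"`, or a function `f(conc, theta)` taking a data frame
#'   of concentrations (one column per species, mM) and a named parameter
#'   vector, returning rates in mM/min.
#' @return An object of class `rate_law`.
#' @examples
#' law <- define_rate_law("pgi", pgi_scheme(), "reversible_hill_uni")
#' law_rate(law, data.frame(G6P = 1, F6P = 0.5),
#'          c(vf = 3.551, k_G6P = 0.55, k_F6P = 0.152, h = 1, keq = 0.286))
#' @export
define_rate_law <- function(name, scheme, form) {
  stopifnot(inherits(scheme, "reaction_scheme"))
  builtin <- is.character(form) && length(form) == 1L
  if (builtin) {
    form <- match.arg(form, c("reversible_hill_uni", "irreversible_hill_bi",
                              "irreversible_mm"))
    species <- switch(form,
      reversible_hill_uni = c(scheme$substrates[1L], scheme$products[1L]),
      irreversible_hill_bi = c(scheme$substrates[1:2], scheme$modifiers[1L]),
      irreversible_mm = scheme$substrates[1L])
    par_names <- switch(form,
      reversible_hill_uni  = c("vf", paste0("k_", species), "h", "keq"),
      irreversible_hill_bi = c("vf", paste0("k_", species), "h", "alpha"),
      irreversible_mm      = c("vf", paste0("k_", species)))
    fn <- switch(form,
      reversible_hill_uni = function(conc, theta) {
        rate_reversible_hill_uni(conc[[species[1L]]], conc[[species[2L]]],
                                 theta_to_params(theta, species))
      },
      irreversible_hill_bi = function(conc, theta) {
        rate_irreversible_hill_bi(conc[[species[1L]]], conc[[species[2L]]],
                                  conc[[species[3L]]],
                                  theta_to_params(theta, species))
      },
      irreversible_mm = function(conc, theta) {
        rate_irreversible_mm(conc[[species[1L]]],
                             theta_to_params(theta, species))
      })
  } else {
    stopifnot(is.function(form))
    species <- unique(c(scheme$substrates, scheme$products, scheme$modifiers))
    par_names <- NULL  # caller-defined; fitter takes names from the problem
    fn <- form
    form <- "custom"
  }
  structure(list(name = name, scheme = scheme, form = form,
                 species = species, par_names = par_names, rate = fn),
            class = "rate_law")
}

#' @export
print.rate_law <- function(x, ...) {
  cat("rate law '", x$name, "' (", x$form, ")\n", sep = "")
  print(x$scheme)
  if (!is.null(x$par_names))
    cat("parameters:", paste(x$par_names, collapse = ", "), "\n")
  invisible(x)
}

## Build rate_law_params from a flat theta vector. `species` fixes the order
## of half-saturations (k_<species> entries).
theta_to_params <- function(theta, species) {
  ks <- theta[paste0("k_", species)]
  names(ks) <- species
  rate_law_params(
    vf = unname(theta[["vf"]]),
    half_sat = ks,
    h = if ("h" %in% names(theta)) unname(theta[["h"]]) else 1,
    alpha = if ("alpha" %in% names(theta)) unname(theta[["alpha"]]) else 1,
    keq = if ("keq" %in% names(theta)) unname(theta[["keq"]]) else NULL)
}

## Flatten a rate_law_params object into a fitter theta vector.
params_to_theta <- function(params, with_h = TRUE) {
  th <- c(vf = params$vf)
  ks <- params$half_sat
  names(ks) <- paste0("k_", names(params$half_sat))
  th <- c(th, ks)
  if (with_h) th <- c(th, h = params$h)
  if (params$alpha != 1 || !is.null(params$keq)) {
    if (is.null(params$keq)) th <- c(th, alpha = params$alpha)
    else th <- c(th, keq = params$keq)
  }
  th
}

#' Register / look up rate laws
#'
#' The registry makes laws addressable by name from configuration files.
#' The built-in laws `"pgi"` (uni-uni reversible Michaelis-Menten/Hill) and
#' `"pfk"` (bi-substrate irreversible Hill with PEP inhibition) are always
#' available.
#'
#' @param law a `rate_law` from [define_rate_law()].
#' @param name registry key.
#' @return `get_rate_law` returns the `rate_law`; `list_rate_laws` the keys.
#' @export
register_rate_law <- function(law) {
  stopifnot(inherits(law, "rate_law"))
  assign(law$name, law, envir = .law_registry)
  invisible(law)
}

#' @rdname register_rate_law
#' @export
get_rate_law <- function(name) {
  if (!exists(name, envir = .law_registry, inherits = FALSE))
    stop("unknown rate law '", name, "'; see list_rate_laws()")
  get(name, envir = .law_registry, inherits = FALSE)
}

#' @rdname register_rate_law
#' @export
list_rate_laws <- function() sort(ls(.law_registry))

#' Evaluate a registered law on a concentration table
#'
#' @param law `rate_law` object or registry name.
#' @param conc data frame with one named column per species (mM).
#' @param theta named parameter vector (`vf`, `k_<species>`, `h`, `alpha`,
#'   `keq` as applicable).
#' @return Numeric vector of rates, mM/min.
#' @export
law_rate <- function(law, conc, theta) {
  if (is.character(law)) law <- get_rate_law(law)
  missing_sp <- setdiff(law$species, names(conc))
  if (length(missing_sp))
    stop("concentration table lacks species: ",
         paste(missing_sp, collapse = ", "))
  law$rate(conc, theta)
}

.register_builtin_laws <- function() {
  register_rate_law(define_rate_law("pgi", pgi_scheme(), "reversible_hill_uni"))
  register_rate_law(define_rate_law("pfk", pfk_scheme(), "irreversible_hill_bi"))
  register_rate_law(define_rate_law(
    "mm", reaction_scheme("S", "P"), "irreversible_mm"))
}

.onLoad <- function(libname, pkgname) {
  .register_builtin_laws()
}

#' Read a fitting configuration file
#'
#' YAML layout:
#' ```
#' law: pfk                    # registry name
#' parameters:
#'   vf:    {init: 0.5, lower: 1e-3, upper: 10, free: true}
#'   k_F6P: {init: 0.5, free: true}
#'   h:     {init: 1.0, free: false}
#' ```
#' Unstated bounds default to `init * c(1e-3, 1e3)`.
#'
#' @param path YAML file.
#' @return List with `law` (name), `free`, `fixed`, `lower`, `upper`.
#' @export
read_fit_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$law)) stop("fit config must name a 'law'")
  pars <- cfg$parameters
  free <- fixed <- lower <- upper <- numeric()
  for (nm in names(pars)) {
    p <- pars[[nm]]
    init <- as.numeric(p$init)
    if (isFALSE(p$free)) {
      fixed[nm] <- init
    } else {
      free[nm]  <- init
      lower[nm] <- if (!is.null(p$lower)) as.numeric(p$lower) else init * 1e-3
      upper[nm] <- if (!is.null(p$upper)) as.numeric(p$upper) else init * 1e3
    }
  }
  list(law = cfg$law, free = free, fixed = fixed, lower = lower, upper = upper)
}
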