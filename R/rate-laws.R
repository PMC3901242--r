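#' Reaction scheme
#'
#' Describes the species layout of one enzymatic reaction: ordered substrates
#' and products, optional allosteric modifiers with effect sign, and whether
#' the reaction is treated as reversible (requiring an equilibrium constant).
#'
#' @param substrates character vector of substrate species names (at least one).
#' @param products character vector of product species names (may be empty for
#'   an irreversible sink written without explicit products).
#' @param modifiers character vector of modifier species names.
#' @param modifier_sign numeric vector of +1 (activator) / -1 (inhibitor),
#'   recycled along `modifiers`.
#' @param reversible logical; reversible schemes need `keq` in their parameters.
#' @return An object of class `reaction_scheme`.
#' @examples
#' pgi_scheme()
#' reaction_scheme("F6P", c("FBP"), modifiers = "PEP", modifier_sign = -1,
#'                 reversible = FALSE)
#' @export
reaction_scheme <- function(substrates, products = character(),
                            modifiers = character(), modifier_sign = -1,
                            reversible = FALSE) {
  stopifnot(is.character(substrates), is.character(products),
            is.character(modifiers))
  if (length(substrates) < 1L)
    stop("a reaction scheme needs at least one substrate")
  all_sp <- c(substrates, products, modifiers)
  if (anyDuplicated(all_sp))
    stop("species names must be unique across substrate/product/modifier roles")
  structure(list(
    substrates    = substrates,
    products      = products,
    modifiers     = modifiers,
    modifier_sign = rep_len(as.numeric(modifier_sign),
                            length.out = max(length(modifiers), 1L))[
                              seq_along(modifiers)],
    reversible    = isTRUE(reversible)
  ), class = "reaction_scheme")
}

#' @export
print.reaction_scheme <- function(x, ...) {
  arrow <- if (x$reversible) "<->" else "->"
  cat(paste(x$substrates, collapse = " + "), arrow,
      paste(x$products, collapse = " + "), "\n")
  if (length(x$modifiers))
    cat("modifiers:",
        paste0(ifelse(x$modifier_sign < 0, "(-)", "(+)"), x$modifiers,
               collapse = ", "), "\n")
  invisible(x)
}

#' Rate-law parameter set
#'
#' Bundles the parameters of one generalized Hill rate law: maximal forward
#' rate, half-saturation constants, Hill coefficient, allosteric modifier
#' effect, equilibrium constant, and the protein concentration used to convert
#' specific activity into volumetric rate.
#'
#' `vf` is stored as a specific activity (umol min^-1 mg^-1); multiplying by
#' `protein_conc` (mg mL^-1) gives mM min^-1, the unit used in simulations
#' (1 umol/mL == 1 mM). The default `protein_conc = 1` makes the two scales
#' coincide numerically. `keq` is dimensionless.
#'
#' @param vf maximal forward rate (> 0), specific activity.
#' @param half_sat named numeric vector of half-saturation concentrations in
#'   mM (all > 0); names are species names.
#' @param h Hill coefficient (> 0, dimensionless). 1 = no cooperativity.
#' @param alpha modifier effect (> 0): `alpha < 1` inhibitor, `> 1` activator,
#'   `= 1` neutral.
#' @param keq equilibrium constant (> 0, dimensionless) for reversible laws;
#'   `NULL` for irreversible laws.
#' @param protein_conc protein concentration in mg mL^-1 (> 0).
#' @return An object of class `rate_law_params`.
#' @examples
#' pgi_table_params()
#' rate_law_params(1, c(S = 0.5), h = 2)
#' @export
rate_law_params <- function(vf, half_sat, h = 1, alpha = 1, keq = NULL,
                            protein_conc = 1) {
  if (!is.numeric(vf) || length(vf) != 1L || !is.finite(vf) || vf <= 0)
    stop("'vf' must be a single positive number")
  if (!is.numeric(half_sat) || is.null(names(half_sat)) ||
      any(!nzchar(names(half_sat))))
    stop("'half_sat' must be a named numeric vector of species half-saturations")
  if (any(!is.finite(half_sat)) || any(half_sat <= 0))
    stop("every half-saturation constant must be positive and finite")
  for (nm in c("h", "alpha", "protein_conc")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive number", nm))
  }
  if (!is.null(keq) &&
      (!is.numeric(keq) || length(keq) != 1L || !is.finite(keq) || keq <= 0))
    stop("'keq' must be a single positive number (or NULL for irreversible laws)")
  structure(list(vf = vf, half_sat = half_sat, h = h, alpha = alpha,
                 keq = keq, protein_conc = protein_conc),
            class = "rate_law_params")
}

#' @export
print.rate_law_params <- function(x, ...) {
  cat("rate-law parameters\n")
  cat("  Vf   :", x$vf, "umol/min/mg\n")
  for (nm in names(x$half_sat))
    cat(sprintf("  %s_0.5: %g mM\n", nm, x$half_sat[[nm]]))
  cat("  h    :", x$h, "  alpha:", x$alpha, "\n")
  if (!is.null(x$keq)) cat("  Keq  :", x$keq, "\n")
  invisible(x)
}

## Maximal volumetric forward rate in mM/min.
vf_volumetric <- function(params) params$vf * params$protein_conc

#' Reversible Hill rate law, uni-uni
#'
#' Rate of a one-substrate / one-product reversible reaction under the
#' generalized reversible Hill equation,
#' \deqn{v = V_f\,\sigma\,(1 - \Gamma/K_{eq})\,
#'       \frac{(\sigma+\pi)^{h-1}}{1 + (\sigma+\pi)^h},}
#' with scaled concentrations \eqn{\sigma = s/S_{0.5}}, \eqn{\pi = p/P_{0.5}}
#' and the mass-action ratio \eqn{\Gamma = p/s} of unscaled concentrations.
#' With `h = 1` this reduces to the reversible Michaelis-Menten equation
#' \eqn{v = V_f \sigma (1-\Gamma/K_{eq}) / (1 + \sigma + \pi)}.
#'
#' The numerator is evaluated in the algebraically equivalent form
#' \eqn{V_f(\sigma - p/(S_{0.5} K_{eq}))} so that `s = 0` with `p > 0` gives
#' the finite (negative) reverse-rate limit instead of a division failure;
#' \eqn{\Gamma} at `s = p = 0` is defined as 0 and the rate is 0.
#'
#' @param s substrate concentration(s), mM (>= 0). Vectorized.
#' @param p product concentration(s), mM (>= 0). Vectorized.
#' @param params [rate_law_params()] with `half_sat` of length 2 (substrate
#'   first, product second) and `keq` set.
#' @return Rate in mM min^-1 (given `protein_conc` in `params`); the sign
#'   follows the thermodynamic driving force `1 - Gamma/Keq`.
#' @examples
#' v <- rate_reversible_hill_uni(1, 0.5, pgi_table_params())
#' @seealso [haldane_reverse_vmax()], [rate_irreversible_hill_bi()]
#' @export
rate_reversible_hill_uni <- function(s, p, params) {
  stopifnot(inherits(params, "rate_law_params"))
  if (is.null(params$keq))
    stop("reversible rate law requires 'keq' in the parameter set")
  if (length(params$half_sat) < 2L)
    stop("uni-uni reversible law needs substrate and product half-saturations")
  if (any(s < 0) || any(p < 0)) stop("concentrations must be non-negative")
  ks <- params$half_sat[[1L]]; kp <- params$half_sat[[2L]]
  h <- params$h
  sig <- s / ks; pii <- p / kp
  tot <- sig + pii
  # Vf*sigma*(1 - Gamma/Keq) == Vf*(sigma - p/(ks*keq)); finite at s = 0
  drive <- sig - p / (ks * params$keq)
  v <- vf_volumetric(params) * drive * tot^(h - 1) / (1 + tot^h)
  v[tot == 0] <- 0  # Gamma at (0,0) defined as 0, rate 0
  v
}

#' Irreversible bi-substrate Hill rate law with one allosteric modifier
#'
#' Rate of a two-substrate irreversible reaction under a bi-substrate Hill
#' equation with a single (typically inhibitory) allosteric modifier,
#' \deqn{v = V_f\,\frac{(\sigma_1\sigma_2)^h}
#'      {M + \sigma_1^h + \sigma_2^h + (\sigma_1\sigma_2)^h}, \quad
#'      M = \frac{1 + \mu^h}{1 + \alpha\,\mu^h},}
#' with \eqn{\sigma_i = s_i/S_{i,0.5}} and \eqn{\mu = m/M_{0.5}}. The modifier
#' term `M` occupies the position of the constant 1 in the uni-substrate
#' reversible Hill equation; the modifier exponent equals the reaction's `h`.
#' `alpha < 1` makes the modifier an inhibitor, `alpha = 1` neutral.
#'
#' @param s1,s2 substrate concentrations, mM (>= 0). Vectorized.
#' @param m modifier concentration, mM (>= 0). Vectorized.
#' @param params [rate_law_params()] with `half_sat` of length 3
#'   (substrate 1, substrate 2, modifier).
#' @return Rate in mM min^-1, in `[0, Vf)`.
#' @examples
#' rate_irreversible_hill_bi(3, 2.5, 4, pfk_table_params())
#' @export
rate_irreversible_hill_bi <- function(s1, s2, m, params) {
  stopifnot(inherits(params, "rate_law_params"))
  if (length(params$half_sat) < 3L)
    stop("bi-substrate modifier law needs 3 half-saturations (s1, s2, modifier)")
  if (any(s1 < 0) || any(s2 < 0) || any(m < 0))
    stop("concentrations must be non-negative")
  h <- params$h
  o1 <- (s1 / params$half_sat[[1L]])^h
  o2 <- (s2 / params$half_sat[[2L]])^h
  mu <- (m  / params$half_sat[[3L]])^h
  M <- (1 + mu) / (1 + params$alpha * mu)
  vf_volumetric(params) * o1 * o2 / (M + o1 + o2 + o1 * o2)
}

#' Irreversible Michaelis-Menten rate law
#'
#' Classical one-substrate irreversible hyperbola
#' \eqn{v = V_f\,s/(K_s + s)}, used for initial-rate saturation curves.
#'
#' @param s substrate concentration, mM (>= 0). Vectorized.
#' @param params [rate_law_params()] whose first `half_sat` entry is `Ks`.
#' @return Rate in `[0, Vf)`, with `v(Ks) = Vf/2`.
#' @export
rate_irreversible_mm <- function(s, params) {
  stopifnot(inherits(params, "rate_law_params"))
  if (any(s < 0)) stop("concentrations must be non-negative")
  ks <- params$half_sat[[1L]]
  vf_volumetric(params) * s / (ks + s)
}

#' Reverse maximal rate from the Haldane relationship
#'
#' For the uni-uni reversible (Michaelis-Menten / Hill) law, thermodynamic
#' consistency ties the reverse maximal rate to the forward parameters:
#' \deqn{V_r = \frac{V_f\,P_{0.5}}{S_{0.5}\,K_{eq}}.}
#' Substituting this `Vr` back into the two-parameter numerator form
#' `Vf*sigma - Vr*pi` reproduces a vanishing rate exactly on the equilibrium
#' line `p/s = Keq`.
#'
#' @param params [rate_law_params()] of a reversible uni-uni law (needs
#'   substrate and product half-saturations plus `keq`).
#' @return `Vr`, in the same units as `vf`.
#' @examples
#' haldane_reverse_vmax(pgi_table_params())  # 3.431 for the E. coli PGI fit
#' @export
haldane_reverse_vmax <- function(params) {
  stopifnot(inherits(params, "rate_law_params"))
  if (is.null(params$keq))
    stop("Haldane relationship requires 'keq' (reversible scheme)")
  if (length(params$half_sat) < 2L)
    stop("need substrate and product half-saturations")
  params$vf * params$half_sat[[2L]] / (params$half_sat[[1L]] * params$keq)
}

#' Published E. coli PGI parameter set
#'
#' Reversible Michaelis-Menten parameters for phosphoglucose isomerase
#' (G6P <-> F6P) fitted to 31P-NMR progress curves: Vf 3.551 umol/min/mg,
#' G6P_0.5 0.550 mM, F6P_0.5 0.152 mM, Keq 0.286, h = 1.
#'
#' @param protein_conc mg mL^-1 for unit conversion (default 1).
#' @return A [rate_law_params()] object.
#' @export
pgi_table_params <- function(protein_conc = 1) {
  rate_law_params(vf = 3.551, half_sat = c(G6P = 0.550, F6P = 0.152),
                  h = 1, keq = 0.286, protein_conc = protein_conc)
}

#' Published E. coli PFK parameter set
#'
#' Irreversible bi-substrate Hill parameters for phosphofructokinase
#' (F6P + ATP -> FBP + ADP, PEP inhibitor): Vf 0.4435 umol/min/mg,
#' F6P_0.5 0.4174 mM, ATP_0.5 0.5444 mM, PEP_0.5 0.0863 mM, alpha 0.3797,
#' h 1.883. With `mg_corrected = TRUE` the ATP half-saturation is replaced by
#' 0.1089 mM, the value obtained when the effective (Mg-bound) ATP is taken
#' as one fifth of total ATP.
#'
#' @param protein_conc mg mL^-1 for unit conversion (default 1).
#' @param mg_corrected use the Mg-corrected ATP_0.5 (default FALSE).
#' @return A [rate_law_params()] object.
#' @export
pfk_table_params <- function(protein_conc = 1, mg_corrected = FALSE) {
  rate_law_params(vf = 0.4435,
                  half_sat = c(F6P = 0.4174,
                               ATP = if (mg_corrected) 0.1089 else 0.5444,
                               PEP = 0.0863),
                  h = 1.883, alpha = 0.3797, protein_conc = protein_conc)
}

#' Canonical reaction schemes
#'
#' `pgi_scheme()`: G6P <-> F6P, reversible, no modifiers.
#' `pfk_scheme()`: F6P + ATP -> FBP + ADP, irreversible, PEP inhibitor.
#'
#' @return A [reaction_scheme()] object.
#' @export
pgi_scheme <- function() {
  reaction_scheme("G6P", "F6P", reversible = TRUE)
}

#' @rdname pgi_scheme
#' @export
pfk_scheme <- function() {
  reaction_scheme(c("F6P", "ATP"), c("FBP", "ADP"),
                  modifiers = "PEP", modifier_sign = -1, reversible = FALSE)
}
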