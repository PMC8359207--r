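#' Physical constants used by the qSIP calculations
#'
#' Central registry of the linear coefficients relating CsCl buoyant density,
#' GC content and per-nucleotide molecular weight, plus the maximum heavy-DNA
#' mass increments for \eqn{^{13}}C and \eqn{^{15}}N labelling.
#'
#' All GC contents are proportions in \[0, 1\]; densities are g ml\eqn{^{-1}};
#' molecular weights are g mol\eqn{^{-1}} per average nucleotide pair.
#'
#' Components:
#' \describe{
#'   \item{density_intercept, density_slope}{buoyant density of unlabelled DNA
#'     as a linear function of GC: \eqn{\rho = 1.646057 + 0.083506\,G}
#'     (classical CsCl density--GC relation used throughout qSIP).}
#'   \item{mw_intercept, mw_gc_slope}{light (unlabelled) molecular weight per
#'     nucleotide: \eqn{M_{light} = 307.691 + 0.496\,G}.}
#'   \item{c_max_intercept, c_max_slope}{maximum mass gain per nucleotide under
#'     full \eqn{^{13}}C substitution: \eqn{9.974564 - 0.4987282\,G} (carbon
#'     count per base pair depends weakly on GC).}
#'   \item{n_max_AG, n_max_T, n_max_C}{maximum mass gain per base under full
#'     \eqn{^{15}}N substitution: A and G have five nitrogen atoms (4.985),
#'     T two (1.994), C three (2.991).}
#'   \item{dual_max_slope, dual_max_intercept}{the combined dual-isotope
#'     maximum increment actually used by the analysis path:
#'     \eqn{M_{heavymax} - M_{light} = 0.0025\,G + 13.416}. Note this printed
#'     relation is not exactly the sum of the carbon term and the averaged
#'     per-base nitrogen terms (that sum is \eqn{13.464 - 0.0002\,G}); see
#'     \code{\link{max_heavy_mw_dual}} for the \code{per_element} alternative.}
#'   \item{density_min, density_max}{plausible CsCl buoyant-density range used
#'     for input validation.}
#' }
#'
#' @format A named list of numeric scalars.
#' @seealso \code{\link{max_heavy_mw_dual}}, \code{\link{gc_from_light_density}}
#' @export
qsip_constants <- list(
  # density <-> GC (unlabelled DNA in CsCl)
  density_intercept = 1.646057,
  density_slope     = 0.083506,
  # GC -> light molecular weight per nucleotide
  mw_intercept      = 307.691,
  mw_gc_slope       = 0.496,
  # full 13C substitution, per nucleotide
  c_max_intercept   = 9.974564,
  c_max_slope       = -0.4987282,
  # full 15N substitution, per base (5, 2 and 3 N atoms)
  n_max_AG          = 4.985,
  n_max_T           = 1.994,
  n_max_C           = 2.991,
  # combined 13C + 15N maximum increment (analysis default)
  dual_max_slope     = 0.0025,
  dual_max_intercept = 13.416,
  # input validation bounds for CsCl buoyant densities
  density_min = 1.55,
  density_max = 1.85
)
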