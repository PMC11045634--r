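#' Model parameters
#'
#' Returns the full parameter set of the hybrid invasion model, with defaults
#' taken from the published parameterisation of the system (rates in days,
#' lengths in cm, densities in g cm^-3). Fields:
#'
#' \describe{
#'   \item{D_E, D_F, D_b, D_m}{diffusion coefficients (cm^2 d^-1). The
#'     epithelial (ECC) and fibroblast (CAF) coefficients multiply the density
#'     itself (degenerate porous-medium mobility \code{D * c}); TGF-beta and
#'     MMP diffuse linearly.}
#'   \item{chi_E, chi_F}{haptotaxis coefficients (cm^2 d^-1). ECCs drift up
#'     the matrix gradient, CAFs down it.}
#'   \item{rho_cE, rho_cF}{logistic proliferation rates (d^-1).}
#'   \item{rho_bF, rho_mF, rho_mE, rho_vF}{production rates of TGF-beta, MMP
#'     (by CAFs and by ECCs) and matrix. \code{rho_mE} has no published value;
#'     it defaults to \code{rho_mF}.}
#'   \item{lambda_F, lambda_b, lambda_m}{decay rates (d^-1).}
#'   \item{lambda_vM, lambda_vE}{matrix degradation coefficients for the
#'     agent-footprint term and the MMP-ECC complex term; both default to the
#'     single published matrix degradation rate.}
#'   \item{V_thr}{maximum mesenchymal (MCC) cell speed (cm d^-1).}
#'   \item{sigma}{MCC jump-noise scale (cm d^-1/2).}
#'   \item{mu_v}{MCC velocity drift coefficient as published (cm^2 d^-1);
#'     inert: the saturated drift law is fully determined by \code{V_thr}.}
#'   \item{lam_cpp}{compound-Poisson reorientation rate (d^-1); not published,
#'     default 50 (several reorientations per day).}
#'   \item{L, k, b_T}{EMT logistic rate ceiling (d^-1), steepness and
#'     TGF-beta threshold (g cm^-3).}
#'   \item{C_ref}{ECC density gate for EMT (g cm^-3); not published, default
#'     0.5 (half the logistic carrying-capacity scale).}
#'   \item{m_cell}{mass converted per EMT event (g); \code{NA} means
#'     \code{C_ref} times the partition-cell volume, resolved at run time.}
#'   \item{mu_E_EMT, mu_M_MET}{phenotype-switch prefactors, default 1 (the
#'     published rates live inside the Poisson intensities).}
#'   \item{r_met}{MET rate per solitary cell (d^-1).}
#'   \item{lam_intra}{intravasation rate per MCC (d^-1); not published,
#'     default 1e-1 (same order as MET).}
#'   \item{p_survive}{probability a circulating tumour cell survives transit
#'     (0.001, i.e. 0.1\%).}
#'   \item{v_max, v_min}{matrix density bounds (g cm^-3), \code{v_min = 0.9
#'     v_max}.}
#'   \item{K}{agent footprint cube side (cm); \code{NA} means one
#'     partition-cell side, resolved at run time.}
#'   \item{mmp_diffusion}{\code{"D_m"} (default) or \code{"D_E"}: which
#'     coefficient diffuses MMP (the source prints both in different places).}
#'   \item{normalize_carrying_capacity}{if TRUE, the logistic competition
#'     uses matrix density rescaled by \code{v_max} so that 1 is the carrying
#'     capacity; default FALSE (as printed).}
#'   \item{boundary}{agent wall rule: \code{"reflect"} (mirror, default) or
#'     \code{"last_position"}.}
#'   \item{drift_mode}{\code{"magnitude"} (saturate |grad|, keep direction;
#'     default) or \code{"componentwise"}.}
#'   \item{safety, dt_max}{explicit time-step safety factor and cap (d).}
#' }
#'
#' @param ... named overrides of any default. Unknown names raise an error
#'   with a nearest-name suggestion.
#' @return a list of class \code{"msim_params"}.
#' @examples
#' p <- model_params(chi_E = 0)
#' p$D_E
#' @export
model_params <- function(...) {
  p <- list(
    # diffusion (cm^2/d)
    D_E = 8.64e-8, D_F = 10 * 8.64e-8, D_b = 1e3 * 8.64e-8, D_m = 1e3 * 8.64e-8,
    # haptotaxis (cm^2/d)
    chi_E = 1e-3, chi_F = 1e-3,
    # proliferation (1/d)
    rho_cE = 1.2, rho_cF = 1e-3,
    # production
    rho_bF = 1e-3, rho_mF = 1e-3, rho_mE = 1e-3, rho_vF = 1e-3,
    # decay (1/d)
    lambda_F = 2.62e-2, lambda_b = 2.62e-2, lambda_m = 2.62e-2,
    # matrix degradation
    lambda_vM = 1.8383, lambda_vE = 1.8383,
    # solitary-cell migration
    V_thr = 2.16, sigma = 30, mu_v = 100, lam_cpp = 50,
    jump_law = "halfnorm",
    # EMT / MET
    L = 5e-3, k = 1e6, b_T = 1e-3, C_ref = 0.5, m_cell = NA_real_,
    mu_E_EMT = 1, mu_M_MET = 1, r_met = 1e-1,
    # metastasis network
    lam_intra = 1e-1, p_survive = 1e-3,
    # environment
    v_max = 1.06, v_min = 0.9 * 1.06,
    # discretisation / policy
    K = NA_real_,
    mmp_diffusion = "D_m",
    normalize_carrying_capacity = FALSE,
    boundary = "reflect",
    drift_mode = "magnitude",
    safety = 0.4, dt_max = 1e-2
  )
  ov <- list(...)
  if (length(ov)) {
    if (is.null(names(ov)) || any(names(ov) == ""))
      stop("all parameter overrides must be named")
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) {
      near <- vapply(bad, function(b) {
        d <- utils::adist(b, names(p))
        names(p)[which.min(d)]
      }, character(1))
      stop("unknown parameter(s): ",
           paste(sprintf("'%s' (did you mean '%s'?)", bad, near),
                 collapse = ", "))
    }
    p[names(ov)] <- ov
  }
  rates <- c("D_E", "D_F", "D_b", "D_m", "chi_E", "chi_F", "rho_cE", "rho_cF",
             "rho_bF", "rho_mF", "rho_mE", "rho_vF", "lambda_F", "lambda_b",
             "lambda_m", "lambda_vM", "lambda_vE", "L", "k", "b_T", "C_ref",
             "r_met", "lam_intra", "lam_cpp", "sigma")
  for (r in rates) if (p[[r]] < 0) stop("parameter '", r, "' must be >= 0")
  if (p$V_thr <= 0) stop("V_thr must be > 0")
  if (p$p_survive < 0 || p$p_survive > 1) stop("p_survive must be in [0, 1]")
  structure(p, class = "msim_params")
}

#' @export
print.msim_params <- function(x, ...) {
  cat("<msim_params>\n")
  nm <- names(x)
  for (i in seq_along(x))
    cat(sprintf("  %-28s %s\n", nm[i], format(x[[i]])))
  invisible(x)
}

## Resolve the NA placeholders that depend on the partition geometry.
resolve_params <- function(p, part) {
  if (is.na(p$K)) p$K <- min(part$m_spacing)
  if (is.na(p$m_cell)) p$m_cell <- p$C_ref * part$m_volume
  p
}
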