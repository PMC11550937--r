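#' Parameters of the phage-bacteria co-culture model
#'
#' Bundles the life-cycle and observation parameters of the mass-action
#' susceptible/infected/resistant/free-phage (S/I/R/P) co-culture model used
#' by [simulate_growth_curve()]. Defaults describe a fast-growing
#' streptococcal culture in rich medium challenged by a lytic podovirus in a
#' 24 h plate-reader killing assay.
#'
#' @param r Intrinsic bacterial growth rate (1/h).
#' @param K Carrying capacity (cells/mL).
#' @param delta Phage adsorption rate constant (mL/(PFU*h)).
#' @param tau Mean latent period (h); lysis is modelled as an exponential
#'   stage with mean `tau`.
#' @param beta Burst size (PFU released per lysed cell).
#' @param lam Free-phage decay rate (1/h).
#' @param mu_res Rate of resistant-mutant emergence (1/h); 0 disables
#'   resistance.
#' @param od_per_cell OD600 units per (cells/mL); the default puts a culture
#'   at carrying capacity `K = 1e9` at OD600 = 1.
#' @param noise_sd Additive plate-reader noise standard deviation (OD units).
#' @param S0 Initial susceptible density (cells/mL).
#' @param P0 Initial free-phage density (PFU/mL); 0 gives a phage-free
#'   control.
#'
#' @return A list of class `coculture_params`.
#' @examples
#' coculture_params(P0 = 1e6)
#' @export
coculture_params <- function(r = 0.8, K = 1e9, delta = 1e-9, tau = 0.5,
                             beta = 50, lam = 0.01, mu_res = 0,
                             od_per_cell = 1e-9, noise_sd = 0.01,
                             S0 = 1e6, P0 = 0) {
  p <- list(
    r = r, K = K, delta = delta, tau = tau, beta = beta, lam = lam,
    mu_res = mu_res, od_per_cell = od_per_cell, noise_sd = noise_sd,
    S0 = S0, P0 = P0
  )
  validate_coculture_params(p)
  structure(p, class = "coculture_params")
}

validate_coculture_params <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num)) {
    abort(paste0("non-finite or non-scalar parameter(s): ",
                 paste(names(p)[!num], collapse = ", ")))
  }
  neg <- vapply(p, function(x) x < 0, logical(1))
  if (any(neg)) {
    abort(paste0("negative parameter(s): ",
                 paste(names(p)[neg], collapse = ", ")))
  }
  if (p$K <= 0) abort("K must be > 0")
  if (p$tau <= 0) abort("tau must be > 0")
  if (p$od_per_cell <= 0) abort("od_per_cell must be > 0")
  invisible(p)
}

#' @export
print.coculture_params <- function(x, ...) {
  cat("<coculture_params>\n")
  cat(sprintf("  growth: r = %g /h, K = %g cells/mL\n", x$r, x$K))
  cat(sprintf("  phage:  delta = %g mL/(PFU*h), tau = %g h, beta = %g, lam = %g /h\n",
              x$delta, x$tau, x$beta, x$lam))
  cat(sprintf("  resistance: mu_res = %g /h\n", x$mu_res))
  cat(sprintf("  observation: od_per_cell = %g, noise_sd = %g\n",
              x$od_per_cell, x$noise_sd))
  cat(sprintf("  inoculum: S0 = %g cells/mL, P0 = %g PFU/mL\n", x$S0, x$P0))
  invisible(x)
}
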