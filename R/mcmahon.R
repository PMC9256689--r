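# Closed-form dose response of plasmid topological forms and the
# nonlinear fit that extracts SSB (mu) and DSB (phi) yields from gel
# band fractions.
#
#   SC(D) = S0 exp(-(mu + phi) D)
#   OC(D) = exp(-phi D) [exp(-0.5 mu^2 rho D^2)(S0 + C0) - S0 exp(-mu D)]
#   L(D)  = 1 - (S0 + C0) exp(-(phi D + 0.5 mu^2 rho D^2))
#
# SC + OC + L == 1 identically. mu and phi are per plasmid per dose
# unit; rho is the probability that two SSBs on opposite strands within
# the pairing window combine into a DSB.

#' Supercoiled fraction at dose D
#' @param D dose (>= 0), in the dataset's dose unit.
#' @param S0 unirradiated supercoiled fraction.
#' @param mu SSB yield per plasmid per dose unit.
#' @param phi DSB yield per plasmid per dose unit.
#' @return fraction in `[0, 1]`.
#' @export
sc_fraction <- function(D, S0, mu, phi) {
  stopifnot(all(D >= 0))
  S0 * exp(-(mu + phi) * D)
}

#' Open-circular fraction at dose D
#' @inheritParams sc_fraction
#' @param C0 unirradiated open-circular fraction.
#' @param rho DSB-from-two-SSBs pairing probability.
#' @export
oc_fraction <- function(D, S0, C0, mu, phi, rho) {
  stopifnot(all(D >= 0))
  exp(-phi * D) *
    (exp(-0.5 * mu^2 * rho * D^2) * (S0 + C0) - S0 * exp(-mu * D))
}

#' Linear fraction at dose D
#' @inheritParams oc_fraction
#' @export
l_fraction <- function(D, S0, C0, mu, phi, rho) {
  stopifnot(all(D >= 0))
  1 - (S0 + C0) * exp(-(phi * D + 0.5 * mu^2 * rho * D^2))
}

#' Default SSB-pairing probability for an n-bp plasmid
#'
#' Fraction of opposite-strand sites within the `window`-bp pairing
#' range: `2 * (2 * window + 1) / n_bp`.
#'
#' @param n_bp plasmid size in bp (pBR322: 4361).
#' @param window pairing window in bp.
#' @return rho.
#' @export
default_rho <- function(n_bp, window = 10) 2 * (2 * window + 1) / n_bp

#' Validate and package a gel dose-response dataset
#'
#' @param doses dose values (>= 0), first point expected at 0.
#' @param sc,oc,l band fractions per dose, each in `[0, 1]`.
#' @param tol tolerance on `sc + oc + l == 1` per lane.
#' @return object of class `gel_dataset`: data.frame `data` plus `S0`,
#'   `C0` taken from the zero-dose lane.
#' @export
gel_dataset <- function(doses, sc, oc, l, tol = 0.05) {
  stopifnot(length(doses) == length(sc), length(sc) == length(oc),
            length(oc) == length(l))
  if (any(doses < 0)) stop("doses must be non-negative")
  if (any(c(sc, oc, l) < -1e-9) || any(c(sc, oc, l) > 1 + 1e-9))
    stop("fractions must lie in [0, 1]")
  bad <- which(abs(sc + oc + l - 1) > tol)
  if (length(bad))
    stop("fractions do not sum to 1 (within ", tol, ") at dose(s): ",
         paste(doses[bad], collapse = ", "))
  o <- order(doses)
  df <- data.frame(dose = doses[o], sc = sc[o], oc = oc[o], l = l[o])
  i0 <- which(df$dose == 0)[1]
  if (is.na(i0)) stop("dataset needs an unirradiated (dose 0) lane")
  structure(list(data = df, S0 = df$sc[i0], C0 = df$oc[i0]),
            class = "gel_dataset")
}

#' Read a gel dataset from CSV
#'
#' Expects columns `dose_Gy, sc, oc, l`.
#' @param path CSV path.
#' @param ... passed to [gel_dataset()].
#' @return a `gel_dataset`.
#' @export
read_gel <- function(path, ...) {
  df <- utils::read.csv(path)
  need <- c("dose_Gy", "sc", "oc", "l")
  if (!all(need %in% names(df)))
    stop("gel CSV must have columns ", paste(need, collapse = ", "))
  gel_dataset(df$dose_Gy, df$sc, df$oc, df$l, ...)
}

#' Write a gel dataset to CSV
#' @param gel a `gel_dataset`.
#' @param path output path.
#' @export
write_gel <- function(gel, path) {
  df <- gel$data
  names(df)[1] <- "dose_Gy"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Fit the open-circular dose response for (mu, phi)
#'
#' Nonlinear least squares of the OC(D) model with `rho` held fixed and
#' `S0`, `C0` read from the zero-dose lane. A multi-start grid over
#' initial (mu, phi) guards against local minima; the start with the
#' lowest residual sum of squares wins.
#'
#' @param gel a `gel_dataset` with at least 4 dose points.
#' @param rho fixed pairing probability (see [default_rho()]).
#' @param init_mu,init_phi initial-value grids for the multi-start.
#' @param lower lower parameter bounds.
#' @return object of class `mcmahon_fit`: list with `mu`, `phi` (per
#'   plasmid per dose unit), `rho`, `S0`, `C0`, `covariance`,
#'   `r_squared`, `sse`, and the underlying `nls` fit.
#' @export
fit_oc <- function(gel, rho,
                   init_mu = c(0.5, 2, 10, 40, 80),
                   init_phi = c(0.05, 0.5, 2, 8),
                   lower = c(mu = 0, phi = 0)) {
  stopifnot(inherits(gel, "gel_dataset"))
  df <- gel$data
  if (nrow(df) < 4) stop("need at least 4 dose points")
  if (stats::var(df$oc) == 0 || all(df$oc == 0))
    stop("degenerate OC data: no dose response to fit")
  S0 <- gel$S0; C0 <- gel$C0
  best <- NULL
  for (m0 in init_mu) for (p0 in init_phi) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        oc ~ oc_fraction(dose, S0, C0, mu, phi, rho),
        data = df, start = list(mu = m0, phi = p0),
        lower = unname(lower),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse - 1e-12)
      best <- list(fit = fit, sse = sse)
  }
  if (is.null(best))
    stop("OC fit did not converge from any start; check the data scale")
  co <- stats::coef(best$fit)
  if (any(co <= unname(lower) + 1e-12))
    warning("parameter at its lower bound; estimate may be clipped")
  vc <- tryCatch(stats::vcov(best$fit), error = function(e) NULL)
  ss_tot <- sum((df$oc - mean(df$oc))^2)
  structure(list(mu = unname(co["mu"]), phi = unname(co["phi"]),
                 rho = rho, S0 = S0, C0 = C0,
                 covariance = vc,
                 r_squared = 1 - best$sse / ss_tot,
                 sse = best$sse, fit = best$fit),
            class = "mcmahon_fit")
}

#' @export
print.mcmahon_fit <- function(x, ...) {
  cat(sprintf(
    "McMahon OC fit: mu = %.4g, phi = %.4g (rho = %.4g, R^2 = %.4f)\n",
    x$mu, x$phi, x$rho, x$r_squared))
  invisible(x)
}

#' Convert a per-plasmid yield to per-Gbp (and back)
#'
#' `yield_Gbp = yield_plasmid / (n_bp * 1e-9)`.
#'
#' @param yield_plasmid yield per plasmid per dose unit.
#' @param n_bp plasmid size in bp.
#' @return yield per Gbp per dose unit.
#' @export
per_plasmid_to_per_gbp <- function(yield_plasmid, n_bp)
  yield_plasmid / (n_bp * 1e-9)

#' @rdname per_plasmid_to_per_gbp
#' @param yield_gbp yield per Gbp per dose unit.
#' @export
per_gbp_to_per_plasmid <- function(yield_gbp, n_bp)
  yield_gbp * (n_bp * 1e-9)

#' Generate a synthetic gel dose-response dataset
#'
#' Forward-model fractions with optional truncated Gaussian noise,
#' renormalised to sum to one per lane. A stand-in for densitometry of
#' a real gel.
#'
#' @param mu,phi,rho model parameters (per plasmid per dose unit).
#' @param S0,C0 unirradiated supercoiled / open-circular fractions.
#' @param doses dose grid (should include 0).
#' @param noise_sd Gaussian noise level on each band (0 = exact model).
#'   With `relative_noise = TRUE` (default) this is a fractional level --
#'   each band intensity is multiplied by `1 + N(0, noise_sd)`, matching
#'   how densitometry noise scales with band intensity; otherwise it is
#'   an absolute SD added to each fraction.
#' @param relative_noise whether `noise_sd` is proportional to the band
#'   intensity.
#' @param seed RNG seed.
#' @return a `gel_dataset`.
#' @export
generate_gel_data <- function(mu, phi, rho, S0 = 0.9, C0 = 0.1,
                              doses = seq(0, 1, length.out = 10),
                              noise_sd = 0, relative_noise = TRUE,
                              seed = 1L) {
  stopifnot(mu >= 0, phi >= 0, rho >= 0)
  sc <- sc_fraction(doses, S0, mu, phi)
  oc <- oc_fraction(doses, S0, C0, mu, phi, rho)
  l <- l_fraction(doses, S0, C0, mu, phi, rho)
  if (noise_sd > 0) {
    set.seed(seed)
    jitter <- function(v) {
      e <- stats::rnorm(length(v), 0, noise_sd)
      pmax(0, if (relative_noise) v * (1 + e) else v + e)
    }
    sc <- jitter(sc); oc <- jitter(oc); l <- jitter(l)
    tot <- sc + oc + l
    sc <- sc / tot; oc <- oc / tot; l <- l / tot
  }
  gel_dataset(doses, sc, oc, l, tol = 1e-6)
}
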