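#' Haemorheological model parameters
#'
#' Bundles the constants of the empirical blood-rheology laws used by the
#' flow simulator: plasma viscosity, red-blood-cell volume, and the
#' coefficients of the in-vitro relative apparent viscosity law, the
#' Fahraeus tube/discharge haematocrit relation and the phase-separation
#' (bifurcation) rule.  All laws are pure closed forms of the vessel
#' diameter (in micrometres) and haematocrit.
#'
#' Internal unit system: micrometres, milliseconds, Pascal, femtolitres.
#' Viscosity is therefore carried in Pa.ms, numerically equal to mPa.s.
#'
#' @param mu_p Plasma viscosity in Pa.ms (= mPa.s). Default 1.2.
#' @param v_rbc Volume of a single red blood cell in fL (= um^3).
#'   Default 49 (mouse).
#' @param viscosity_haematocrit Which haematocrit the apparent-viscosity
#'   law is evaluated with: `"tube"` (default) or `"discharge"`.
#' @param ht_warn Tube-haematocrit level above which [tube_haematocrit()]
#'   emits a warning (physical packing cap). Default 0.9.
#' @return An object of class `rheology_params` (a named list).
#' @examples
#' p <- rheology_params()
#' relative_viscosity(0.3, 4.5)
#' @export
rheology_params <- function(mu_p = 1.2, v_rbc = 49,
                            viscosity_haematocrit = c("tube", "discharge"),
                            ht_warn = 0.9) {
  stopifnot(is.numeric(mu_p), length(mu_p) == 1L, mu_p > 0,
            is.numeric(v_rbc), length(v_rbc) == 1L, v_rbc > 0,
            is.numeric(ht_warn), length(ht_warn) == 1L, ht_warn > 0)
  viscosity_haematocrit <- match.arg(viscosity_haematocrit)
  structure(list(mu_p = mu_p, v_rbc = v_rbc,
                 viscosity_haematocrit = viscosity_haematocrit,
                 ht_warn = ht_warn),
            class = "rheology_params")
}

#' Tube haematocrit of a vessel from its particle count
#'
#' The tube haematocrit is the instantaneous volume fraction of red blood
#' cells in a cylindrical vessel segment:
#' `H_t = n_rbc * V_rbc / (pi/4 d^2 l)`.
#'
#' Values above the physical packing cap are reported with a warning but
#' not clamped; the advection logic of the forward simulator keeps them
#' unreachable in ordinary runs.
#'
#' @param n_rbc Number of RBCs in the vessel (vectorised).
#' @param v_rbc RBC volume in fL.
#' @param d Vessel diameter in um.
#' @param l Vessel length in um.
#' @param ht_warn Warning threshold, default 0.9.
#' @return Tube haematocrit (dimensionless), same length as the longest
#'   argument.
#' @export
tube_haematocrit <- function(n_rbc, v_rbc, d, l, ht_warn = 0.9) {
  if (any(d <= 0) || any(l <= 0)) {
    stop("tube_haematocrit: vessel diameter and length must be positive")
  }
  if (any(n_rbc < 0) || any(v_rbc < 0)) {
    stop("tube_haematocrit: n_rbc and v_rbc must be non-negative")
  }
  ht <- n_rbc * v_rbc / (d^2 * pi / 4 * l)
  if (any(ht > ht_warn)) {
    warning(sprintf("tube haematocrit exceeds %.2f in %d vessel(s) (max %.3f)",
                    ht_warn, sum(ht > ht_warn), max(ht)))
  }
  ht
}

# Fahraeus relation coefficient r(d): ratio of tube to discharge
# haematocrit at vanishing haematocrit; r(d) -> 1 as d -> Inf.
fahraeus_r <- function(d) {
  1 + 1.7 * exp(-0.415 * d) - 0.6 * exp(-0.011 * d)
}

#' Discharge haematocrit from tube haematocrit (Fahraeus effect)
#'
#' Inverts the empirical Fahraeus relation
#' `H_t / H_d = H_d + (1 - H_d) r(d)` with
#' `r(d) = 1 + 1.7 exp(-0.415 d) - 0.6 exp(-0.011 d)` (d in um),
#' i.e. solves the quadratic `(1 - r) H_d^2 + r H_d - H_t = 0` for the
#' root in `[H_t, 1]`.  Because RBCs travel faster than the bulk, the
#' discharge haematocrit always satisfies `H_d >= H_t`.
#'
#' @param h_t Tube haematocrit in `[0, 1]` (vectorised).
#' @param d Vessel diameter in um.
#' @return Discharge haematocrit `H_d`.
#' @export
discharge_from_tube <- function(h_t, d) {
  if (any(h_t < 0) || any(h_t > 1)) {
    stop("discharge_from_tube: tube haematocrit must lie in [0, 1]")
  }
  if (any(d <= 0)) stop("discharge_from_tube: diameter must be positive")
  n <- max(length(h_t), length(d))
  h_t <- rep_len(h_t, n)
  d <- rep_len(d, n)
  r <- fahraeus_r(d)
  a <- 1 - r
  hd <- ifelse(abs(a) < 1e-10,
               h_t / r,
               (-r + sqrt(r^2 + 4 * a * h_t)) / (2 * a))
  bad <- !is.finite(hd) | hd < -1e-12 | hd > 1 + 1e-12
  if (any(bad)) {
    stop("discharge_from_tube: no root in [0, 1] for supplied inputs")
  }
  pmin(pmax(hd, 0), 1)
}

# H_d/H_t ratio with a well-defined H_t -> 0 limit of 1/r(d).
# Uses the identity H_d/H_t = 1/(H_d + (1 - H_d) r(d)).
hd_ht_ratio <- function(h_t, d) {
  hd <- discharge_from_tube(h_t, d)
  1 / (hd + (1 - hd) * fahraeus_r(d))
}

# Apparent relative viscosity of blood at discharge haematocrit 0.45,
# in-vitro parameterization (d in um).
mu_045 <- function(d) {
  220 * exp(-1.3 * d) + 3.2 - 2.44 * exp(-0.06 * d^0.645)
}

# Shape exponent of the haematocrit dependence of the viscosity law.
visc_exponent_c <- function(d) {
  (0.8 + exp(-0.075 * d)) * (-1 + 1 / (1 + 1e-11 * d^12)) +
    1 / (1 + 1e-11 * d^12)
}

#' Relative apparent viscosity of blood in a microvessel
#'
#' In-vitro empirical law for the Fahraeus-Lindqvist effect:
#' `mu_rel = 1 + (mu_0.45(d) - 1) * ((1-H)^C - 1) / ((1-0.45)^C - 1)`
#' with `mu_0.45(d) = 220 exp(-1.3 d) + 3.2 - 2.44 exp(-0.06 d^0.645)`
#' and the published diameter-dependent exponent `C(d)`.
#'
#' @param h Haematocrit in `[0, 1)` (tube haematocrit in the default
#'   model configuration; vectorised).
#' @param d Vessel diameter in um.
#' @return Relative apparent viscosity (dimensionless, `>= 1` for
#'   `h >= 0`).
#' @export
relative_viscosity <- function(h, d) {
  if (any(h < 0) || any(h >= 1)) {
    stop("relative_viscosity: haematocrit must lie in [0, 1)")
  }
  if (any(d <= 0)) stop("relative_viscosity: diameter must be positive")
  m45 <- mu_045(d)
  cc <- visc_exponent_c(d)
  1 + (m45 - 1) * (((1 - h)^cc - 1) / ((1 - 0.45)^cc - 1))
}

#' Phase-separation probability at a divergent bifurcation
#'
#' Empirical logit law for the fraction of RBC flux entering daughter
#' vessel `a` given the fractional blood flow `FQ_B` into it.  With
#' `X0 = 0.4 / D_parent`, `B = 1 + 6.98 (1 - H_d,parent) / D_parent` and
#' `A = -6.96 / D_parent * ln(D_a / D_b)`:
#' below `FQ_B <= X0` no RBCs enter (`0`), above `FQ_B >= 1 - X0` all do
#' (`1`), and in between
#' `logit(FQ_E) = A + B logit((FQ_B - X0) / (1 - 2 X0))`.
#' The returned value is used as the probability that an individual RBC
#' reaching the bifurcation is assigned to daughter `a`.
#'
#' @param fq_b Fractional blood flow into daughter `a`, in `[0, 1]`.
#' @param hd_parent Discharge haematocrit of the parent vessel.
#' @param d_parent,d_a,d_b Parent and daughter diameters in um.
#' @return Probability in `[0, 1]` (vectorised over `fq_b`).
#' @export
phase_separation_probability <- function(fq_b, hd_parent, d_parent, d_a, d_b) {
  if (any(fq_b < 0) || any(fq_b > 1)) {
    stop("phase_separation_probability: fq_b must lie in [0, 1]")
  }
  if (any(c(d_parent, d_a, d_b) <= 0)) {
    stop("phase_separation_probability: diameters must be positive")
  }
  if (any(hd_parent < 0) || any(hd_parent >= 1)) {
    stop("phase_separation_probability: hd_parent must lie in [0, 1)")
  }
  x0 <- 0.4 / d_parent
  if (any(x0 >= 0.5)) {
    # parent thinner than 0.8 um: cutoff regions overlap, fall back to
    # flow-proportional assignment
    return(fq_b)
  }
  b <- 1 + 6.98 * (1 - hd_parent) / d_parent
  a <- -6.96 / d_parent * log(d_a / d_b)
  n <- max(length(fq_b), length(a), length(b), length(x0))
  fq_b <- rep_len(fq_b, n)
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  x0 <- rep_len(x0, n)
  out <- numeric(n)
  lo <- fq_b <= x0
  hi <- fq_b >= 1 - x0
  mid <- !lo & !hi
  out[lo] <- 0
  out[hi] <- 1
  if (any(mid)) {
    x <- (fq_b[mid] - x0[mid]) / (1 - 2 * x0[mid])
    lg <- a[mid] + b[mid] * log(x / (1 - x))
    out[mid] <- 1 / (1 + exp(-lg))
  }
  out
}
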