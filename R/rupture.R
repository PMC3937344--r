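# Rupture competition between two serially loaded Bell bonds under a
# linear force ramp. Both bonds feel the same force at all times (serial
# load, linker compliance ignored); the first to rupture decides whether
# the fluorescent label is transferred.

# Force at which the combined cumulative hazard reaches `target`.
# Monotone in F, solved by bisection-backed uniroot on an expanding bracket.
force_at_total_cumhaz <- function(sample, reference, loading_rate, target) {
  f <- function(F) bond_cumhaz(sample, F, loading_rate) +
    bond_cumhaz(reference, F, loading_rate) - target
  hi <- 10 * max(sample$f_beta, reference$f_beta)
  while (f(hi) < 0) hi <- hi * 2
  stats::uniroot(f, c(0, hi), tol = 1e-10)$root
}

#' Probability that the reference bond ruptures first
#'
#' Computes \eqn{P(\mathrm{ref\ first}) = \int_0^{F_{max}}
#' \frac{h_{ref}(F)}{r} \exp\!\big(-\tfrac{1}{r}\int_0^F (h_{ref} +
#' h_{s})\,dF'\big) dF} by adaptive quadrature: the density of the first
#' rupture event under the combined hazard, split by which bond fired.
#' This is the model's ground-truth transfer probability — the fraction of
#' constructs whose fluorophore ends up on the protein surface — and the
#' quantity the Normalized Fluorescence estimates. With no force cap the
#' two outcome probabilities sum to one; identical bonds give exactly 1/2,
#' the matched-stability point at which NF = 0.5.
#'
#' @param sample,reference [bell_bond()] objects for the protein-DNA bond
#'   and the DNA reference duplex.
#' @param ramp A [ramp_protocol()].
#' @param abs_tol Absolute quadrature tolerance.
#' @return Probability in \[0, 1\].
#' @examples
#' b <- bell_bond(1e-4, 10)
#' reference_rupture_probability(b, b, ramp_protocol(100))  # 0.5 by symmetry
#' @export
reference_rupture_probability <- function(sample, reference,
                                          ramp = ramp_protocol(),
                                          abs_tol = 1e-8) {
  stopifnot(inherits(sample, "bell_bond"), inherits(reference, "bell_bond"),
            inherits(ramp, "ramp_protocol"))
  r <- ramp$loading_rate
  # integrate out to where combined survival < 1e-12
  f_hi <- force_at_total_cumhaz(sample, reference, r, -log(1e-12))
  upper <- if (is.null(ramp$f_max)) f_hi else min(ramp$f_max, f_hi)
  integrand <- function(F) {
    (bond_hazard(reference, F) / r) *
      exp(-(bond_cumhaz(sample, F, r) + bond_cumhaz(reference, F, r)))
  }
  res <- tryCatch(
    stats::integrate(integrand, 0, upper, abs.tol = abs_tol,
                     rel.tol = abs_tol, subdivisions = 1000L),
    error = function(e) stop(
      "numerical error: competing-hazards quadrature did not converge (",
      conditionMessage(e), "); upper limit ", signif(upper, 6), " pN"))
  min(max(res$value, 0), 1)
}

#' Kinetic Monte Carlo of the rupture competition
#'
#' Samples rupture events of the serial bond pair by inverse-CDF sampling
#' of the combined time-varying hazard: for each replicate, the rupture
#' force solves \eqn{\Lambda_{tot}(F) = -\log U}, then the rupturing bond
#' is a Bernoulli draw with probability \eqn{h_{ref}(F)/h_{tot}(F)}. With a
#' force cap, replicates whose drawn force exceeds the cap survive the ramp
#' (neither bond ruptures). Reproducible under a fixed seed; the empirical
#' reference fraction converges to [reference_rupture_probability()].
#'
#' @inheritParams reference_rupture_probability
#' @param n Number of replicates (>= 0).
#' @param seed Integer RNG seed.
#' @return A data frame with columns `replicate`, `reference_ruptured`,
#'   `sample_ruptured`, `rupture_force_pN` (NA for surviving replicates).
#' @examples
#' b <- bell_bond(1e-4, 10)
#' out <- simulate_rupture(b, b, ramp_protocol(100), n = 1000, seed = 1)
#' mean(out$reference_ruptured)
#' @export
simulate_rupture <- function(sample, reference, ramp = ramp_protocol(),
                             n, seed) {
  stopifnot(inherits(sample, "bell_bond"), inherits(reference, "bell_bond"),
            inherits(ramp, "ramp_protocol"))
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 0 ||
      n != round(n))
    stop("invalid input: 'n' must be a single non-negative integer")
  n <- as.integer(n)
  empty <- data.frame(replicate = integer(0),
                      reference_ruptured = logical(0),
                      sample_ruptured = logical(0),
                      rupture_force_pN = numeric(0))
  if (n == 0L) return(empty)
  set.seed(as.integer(seed))
  r <- ramp$loading_rate
  target <- -log(stats::runif(n))          # cumulative hazard at rupture
  force <- solve_rupture_force(sample, reference, r, target)
  survived <- if (is.null(ramp$f_max)) rep(FALSE, n) else force > ramp$f_max
  p_ref <- bond_hazard(reference, force) /
    (bond_hazard(reference, force) + bond_hazard(sample, force))
  ref_wins <- stats::runif(n) < p_ref
  data.frame(
    replicate = seq_len(n),
    reference_ruptured = ref_wins & !survived,
    sample_ruptured = !ref_wins & !survived,
    rupture_force_pN = ifelse(survived, NA_real_, force)
  )
}

# Vectorised inversion of the combined cumulative hazard. Equal force
# scales admit a closed form; otherwise safeguarded Newton iterations on
# the convex, strictly increasing cumulative hazard.
solve_rupture_force <- function(sample, reference, loading_rate, target) {
  a_s <- sample$k0 * sample$f_beta / loading_rate
  a_r <- reference$k0 * reference$f_beta / loading_rate
  if (sample$f_beta == reference$f_beta) {
    return(sample$f_beta * log1p(target / (a_s + a_r)))
  }
  # start from the closed form with the smaller force scale (overestimates
  # the cumulative hazard -> underestimates F, Newton then climbs)
  fb0 <- min(sample$f_beta, reference$f_beta)
  F <- fb0 * log1p(target * loading_rate / ((sample$k0 + reference$k0) * fb0))
  for (i in 1:100) {
    g <- bond_cumhaz(sample, F, loading_rate) +
      bond_cumhaz(reference, F, loading_rate) - target
    dg <- (bond_hazard(sample, F) + bond_hazard(reference, F)) / loading_rate
    step <- g / dg
    F <- pmax(F - step, 0)
    if (max(abs(g) / pmax(target, 1e-300)) < 1e-12) break
  }
  F
}

#' Calibrate a sample bond to target transfer probabilities
#'
#' Solves for the Bell parameters (k0, f_beta) of a sample bond such that
#' its reference-rupture probabilities against shear reference duplexes of
#' given lengths match target values — the inverse problem of expressing a
#' measured NF table as an effective protein-DNA bond. Minimises the sum of
#' squared probability residuals over (log k0, log f_beta) with
#' Nelder-Mead.
#'
#' @param targets Data frame with columns `reference_n_bp` and `nf_mean`
#'   (the target transfer probabilities, in \[0, 1\]).
#' @param per_bp_params Per-bp rule for the reference bonds.
#' @param ramp A [ramp_protocol()].
#' @param init Optional starting [bell_bond()].
#' @param label Label for the returned bond.
#' @return A list with `bond` (the calibrated [bell_bond()]), `achieved`
#'   (probabilities at the solution) and `rmse`.
#' @export
calibrate_sample_bond <- function(targets,
                                  per_bp_params = default_per_bp_params(),
                                  ramp = ramp_protocol(), init = NULL,
                                  label = "sample") {
  stopifnot(is.data.frame(targets),
            all(c("reference_n_bp", "nf_mean") %in% names(targets)),
            nrow(targets) >= 1)
  refs <- lapply(targets$reference_n_bp,
                 function(n) bond_from_duplex(duplex_spec(n), per_bp_params))
  if (is.null(init))
    init <- bell_bond(per_bp_params$k0_1 *
                        exp(-per_bp_params$dg_per_bp * 20),
                      per_bp_params$f_beta_1)
  probs_for <- function(par) {
    b <- bell_bond(exp(par[1]), exp(par[2]), label)
    vapply(refs, function(rb) reference_rupture_probability(b, rb, ramp),
           numeric(1))
  }
  obj <- function(par) sum((probs_for(par) - targets$nf_mean)^2)
  fit <- stats::optim(c(log(init$k0), log(init$f_beta)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  bond <- bell_bond(exp(fit$par[1]), exp(fit$par[2]), label)
  achieved <- probs_for(fit$par)
  list(bond = bond, achieved = achieved,
       rmse = sqrt(mean((achieved - targets$nf_mean)^2)))
}
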