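#' Bell-model molecular bond
#'
#' Constructs a bond whose force-dependent off-rate follows the Bell model,
#' \eqn{k(F) = k_0 \exp(F / F_\beta)}: the dissociation rate grows
#' exponentially with the applied force. This single-exponential hazard is
#' the simplest monotone kinetic law consistent with "the weaker bond
#' ruptures first" and is the standard model of force spectroscopy.
#'
#' @param k0 Zero-force off-rate in 1/s; must be > 0.
#' @param f_beta Force scale in pN (the force increase that multiplies the
#'   off-rate by e); must be > 0.
#' @param label Optional text label (e.g. motif or duplex name).
#' @return An object of class `bell_bond` with fields `k0`, `f_beta`, `label`.
#' @seealso [bond_from_duplex()], [reference_rupture_probability()]
#' @examples
#' b <- bell_bond(k0 = 1e-4, f_beta = 10, label = "sample")
#' bond_hazard(b, force = c(0, 10, 20))
#' @export
bell_bond <- function(k0, f_beta, label = "") {
  if (!is.numeric(k0) || length(k0) != 1L || !is.finite(k0) || k0 <= 0)
    stop("invalid input: 'k0' must be a single positive number (1/s)")
  if (!is.numeric(f_beta) || length(f_beta) != 1L || !is.finite(f_beta) ||
      f_beta <= 0)
    stop("invalid input: 'f_beta' must be a single positive number (pN)")
  structure(list(k0 = as.numeric(k0), f_beta = as.numeric(f_beta),
                 label = as.character(label)[1L]),
            class = "bell_bond")
}

#' @export
print.bell_bond <- function(x, ...) {
  cat(sprintf("Bell bond%s: k0 = %g /s, f_beta = %g pN\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              x$k0, x$f_beta))
  invisible(x)
}

#' Instantaneous rupture hazard of a Bell bond
#'
#' @param bond A [bell_bond()].
#' @param force Force(s) in pN (vectorised).
#' @return Hazard rate(s) in 1/s.
#' @export
bond_hazard <- function(bond, force) {
  stopifnot(inherits(bond, "bell_bond"))
  bond$k0 * exp(force / bond$f_beta)
}

# Cumulative hazard accumulated while ramping from force 0 to `force`
# at `loading_rate` pN/s:  (k0 * f_beta / r) * (exp(F/f_beta) - 1).
bond_cumhaz <- function(bond, force, loading_rate) {
  (bond$k0 * bond$f_beta / loading_rate) * expm1(force / bond$f_beta)
}

#' DNA reference duplex specification
#'
#' Describes a reference duplex by its length in base pairs and its loading
#' geometry. In shear geometry all base pairs are loaded in parallel, so
#' longer duplexes are mechanically stronger; zipper geometry (sequential
#' peeling) is carried as a label but no default kinetic parametrisation is
#' provided for it.
#'
#' @param n_bp Integer number of base pairs, >= 1.
#' @param geometry `"shear"` or `"zipper"`.
#' @return An object of class `duplex_spec`.
#' @export
duplex_spec <- function(n_bp, geometry = c("shear", "zipper")) {
  if (!is.numeric(n_bp) || length(n_bp) != 1L || !is.finite(n_bp) ||
      n_bp < 1 || n_bp != round(n_bp))
    stop("invalid input: 'n_bp' must be a single integer >= 1")
  geometry <- match.arg(geometry)
  structure(list(n_bp = as.integer(n_bp), geometry = geometry),
            class = "duplex_spec")
}

#' Default per-base-pair Bell parametrisation for shear duplexes
#'
#' The zero-force off-rate decreases exponentially with duplex length,
#' `k0(n) = k0_1 * exp(-dg_per_bp * n)`, while the force scale grows
#' linearly, `f_beta(n) = f_beta_1 + f_beta_per_bp * (n - 1)` (constant by
#' default). `dg_per_bp` is an effective, loading-rate-dependent
#' stability increment per base pair chosen so that 20 bp and 40 bp
#' references span the observable transfer-probability range; it is a
#' simulator scale, not a thermodynamic free energy.
#'
#' @return A named list with `k0_1`, `dg_per_bp`, `f_beta_1`, `f_beta_per_bp`.
#' @export
default_per_bp_params <- function() {
  list(k0_1 = 0.01, dg_per_bp = 0.07, f_beta_1 = 10, f_beta_per_bp = 0)
}

#' Map a reference duplex to a Bell bond
#'
#' Applies a monotone per-base-pair rule (see [default_per_bp_params()]):
#' more base pairs give a strictly lower zero-force off-rate and a
#' non-decreasing force scale, so longer shear duplexes always rupture less
#' often against a fixed sample bond.
#'
#' @param duplex A [duplex_spec()].
#' @param per_bp_params Named list as returned by [default_per_bp_params()].
#' @return A [bell_bond()] labelled `"ref_<n>bp"`.
#' @examples
#' bond_from_duplex(duplex_spec(20))
#' @export
bond_from_duplex <- function(duplex, per_bp_params = default_per_bp_params()) {
  stopifnot(inherits(duplex, "duplex_spec"))
  if (duplex$geometry != "shear")
    stop("unsupported geometry: no default per-bp rule for '",
         duplex$geometry, "' duplexes")
  p <- per_bp_params
  req <- c("k0_1", "dg_per_bp", "f_beta_1", "f_beta_per_bp")
  if (!all(req %in% names(p)))
    stop("invalid input: per_bp_params must supply ",
         paste(req, collapse = ", "))
  if (p$dg_per_bp < 0 || p$f_beta_per_bp < 0)
    stop("invalid input: per-bp rule must be monotone ",
         "(dg_per_bp >= 0, f_beta_per_bp >= 0)")
  bell_bond(k0 = p$k0_1 * exp(-p$dg_per_bp * duplex$n_bp),
            f_beta = p$f_beta_1 + p$f_beta_per_bp * (duplex$n_bp - 1L),
            label = sprintf("ref_%dbp", duplex$n_bp))
}

#' Linear force-ramp protocol
#'
#' The two surfaces are separated at constant velocity, so force on the
#' serial bond pair grows linearly in time, `F(t) = loading_rate * t`,
#' until one bond ruptures (or until `f_max`, if given).
#'
#' @param loading_rate Loading rate in pN/s; must be > 0.
#' @param f_max Optional force cap in pN (NULL = ramp until rupture).
#' @return An object of class `ramp_protocol`.
#' @export
ramp_protocol <- function(loading_rate = 100, f_max = NULL) {
  if (!is.numeric(loading_rate) || length(loading_rate) != 1L ||
      !is.finite(loading_rate) || loading_rate <= 0)
    stop("invalid input: 'loading_rate' must be a single positive number")
  if (!is.null(f_max)) {
    if (!is.numeric(f_max) || length(f_max) != 1L || !is.finite(f_max) ||
        f_max <= 0)
      stop("invalid input: 'f_max' must be NULL or a single positive number")
    f_max <- as.numeric(f_max)
  }
  structure(list(loading_rate = as.numeric(loading_rate), f_max = f_max),
            class = "ramp_protocol")
}
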