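# Reference-length calibration: within the probed range the mean NF falls
# linearly with the number of base pairs in the reference duplex, so a
# protein-DNA bond can be assigned the length of the reference duplex that
# matches its stability (NF = 0.5), and two motifs can be compared in
# units of DNA base pairs.

#' Linear NF-vs-reference-length model for one motif
#'
#' Ordinary least squares of the per-condition mean NF on the reference
#' duplex length (exact interpolation for two points). Zeroed (no-binding)
#' conditions must be excluded by the caller. Evaluation outside the
#' fitted length range is extrapolation and is flagged as such downstream.
#'
#' @param points Data frame with columns `reference_n_bp` and `nf_mean`.
#' @param motif_label Label stored on the model.
#' @return An object of class `linear_nf_model` with `slope` (NF per bp),
#'   `intercept` (NF), `fit_range` (bp) and `n_points`.
#' @examples
#' fit_linear_nf_model(data.frame(reference_n_bp = c(20, 40),
#'                                nf_mean = c(0.65, 0.32)), "high")
#' @export
fit_linear_nf_model <- function(points, motif_label = "") {
  stopifnot(is.data.frame(points),
            all(c("reference_n_bp", "nf_mean") %in% names(points)))
  if (length(unique(points$reference_n_bp)) < 2)
    stop("insufficient data: need >= 2 distinct reference lengths, got ",
         length(unique(points$reference_n_bp)))
  fit <- stats::lm(nf_mean ~ reference_n_bp, data = points)
  cf <- stats::coef(fit)
  structure(list(motif_label = motif_label,
                 slope = unname(cf["reference_n_bp"]),
                 intercept = unname(cf["(Intercept)"]),
                 fit_range = range(points$reference_n_bp),
                 n_points = nrow(points)),
            class = "linear_nf_model")
}

#' @export
print.linear_nf_model <- function(x, ...) {
  cat(sprintf(
    "NF(L) = %.4f %+.5f * L  [motif '%s', fitted on %d points, %g-%g bp]\n",
    x$intercept, x$slope, x$motif_label, x$n_points,
    x$fit_range[1], x$fit_range[2]))
  invisible(x)
}

#' Predict NF at a reference length
#'
#' @param object A `linear_nf_model`.
#' @param newdata Numeric vector of reference lengths in bp.
#' @param ... Unused.
#' @export
predict.linear_nf_model <- function(object, newdata, ...) {
  object$intercept + object$slope * newdata
}

#' Reference length matching the protein-DNA bond stability
#'
#' Solves the linear model for NF = 0.5: at that point the reference
#' duplex ruptures as often as the protein-DNA bond, so its length is the
#' bond's strength in base-pair units. Solutions outside the fitted length
#' range are flagged as extrapolation.
#'
#' @param model A [fit_linear_nf_model()] result with nonzero slope.
#' @return List with `length_bp` and logical `extrapolated`.
#' @examples
#' m <- fit_linear_nf_model(data.frame(reference_n_bp = c(20, 40),
#'                                     nf_mean = c(0.65, 0.32)))
#' matched_reference_length(m)  # ~29.1 bp
#' @export
matched_reference_length <- function(model) {
  stopifnot(inherits(model, "linear_nf_model"))
  if (abs(model$slope) < 1e-12)
    stop("degenerate model: slope is zero, NF never crosses 0.5")
  L <- (0.5 - model$intercept) / model$slope
  list(length_bp = L,
       extrapolated = L < model$fit_range[1] || L > model$fit_range[2])
}

#' Binding-strength difference between motifs in base pairs
#'
#' Expresses how much more strongly a protein binds one DNA motif than
#' another as an equivalent number of DNA base pairs, by either of two
#' routes:
#' \describe{
#'   \item{`matched_pair`}{find a cross-motif pair of conditions whose NF
#'     estimates are [equal_within_errors()]; the bp difference of their
#'     reference duplexes is the strength difference (0 when two motifs
#'     are indistinguishable at the same reference length; if several
#'     pairs qualify, the one with the smallest mean-NF gap is taken).}
#'   \item{`linear_model`}{fit a [fit_linear_nf_model()] per motif and
#'     take the difference of their [matched_reference_length()] values.}
#' }
#'
#' @param conditions Data frame with columns `motif_label`,
#'   `reference_n_bp`, `nf_mean`, `nf_sd`, `status` (e.g. the `pads` table
#'   of [quantify_image_set()], or per-condition aggregates). Only
#'   `fitted` rows are used; zeroed conditions never enter.
#' @param method `"matched_pair"` (default — the assay's direct argument)
#'   or `"linear_model"`.
#' @param motifs Optional character vector of exactly two motif labels to
#'   compare; default: the two motifs present after filtering.
#' @return An object of class `equivalent_bp_result` with `motif_a`,
#'   `motif_b`, `delta_bp`, `method` and the supporting `pair` or
#'   `models`.
#' @export
equivalent_bp_difference <- function(conditions,
                                     method = c("matched_pair",
                                                "linear_model"),
                                     motifs = NULL) {
  method <- match.arg(method)
  stopifnot(is.data.frame(conditions),
            all(c("motif_label", "reference_n_bp", "nf_mean", "nf_sd",
                  "status") %in% names(conditions)))
  fitted <- conditions[conditions$status == "fitted", , drop = FALSE]
  if (!is.null(motifs)) {
    stopifnot(length(motifs) == 2)
    fitted <- fitted[fitted$motif_label %in% motifs, , drop = FALSE]
  }
  if (nrow(fitted) == 0)
    stop("insufficient data: no fitted conditions to compare")

  if (method == "matched_pair") {
    idx <- utils::combn(nrow(fitted), 2)
    best <- NULL
    gaps <- character(0)
    for (k in seq_len(ncol(idx))) {
      i <- idx[1, k]; j <- idx[2, k]
      if (fitted$motif_label[i] == fitted$motif_label[j]) next
      gap <- abs(fitted$nf_mean[i] - fitted$nf_mean[j])
      err <- fitted$nf_sd[i] + fitted$nf_sd[j]
      gaps <- c(gaps, sprintf(
        "%s@%dbp vs %s@%dbp: |dNF| = %.3f, errors sum %.3f",
        fitted$motif_label[i], fitted$reference_n_bp[i],
        fitted$motif_label[j], fitted$reference_n_bp[j], gap, err))
      if (gap <= err && (is.null(best) || gap < best$gap))
        best <- list(i = i, j = j, gap = gap)
    }
    if (is.null(best))
      stop("no match: no cross-motif pair is equal within errors.\n",
           "Pairwise gaps:\n  ",
           paste(gaps, collapse = "\n  "))
    a <- fitted[best$i, ]; b <- fitted[best$j, ]
    return(structure(list(
      motif_a = a$motif_label, motif_b = b$motif_label,
      delta_bp = abs(a$reference_n_bp - b$reference_n_bp),
      method = "matched_pair",
      pair = rbind(a, b)), class = "equivalent_bp_result"))
  }

  # linear_model route
  motif_set <- unique(fitted$motif_label)
  n_lengths <- vapply(motif_set, function(m)
    length(unique(fitted$reference_n_bp[fitted$motif_label == m])),
    integer(1))
  eligible <- motif_set[n_lengths >= 2]
  if (length(eligible) != 2)
    stop("insufficient data: linear_model needs exactly two motifs with ",
         ">= 2 reference lengths each (eligible: ",
         paste(eligible, collapse = ", "), "); use 'motifs' to select")
  models <- lapply(eligible, function(m)
    fit_linear_nf_model(fitted[fitted$motif_label == m, ], m))
  lens <- lapply(models, matched_reference_length)
  structure(list(
    motif_a = eligible[1], motif_b = eligible[2],
    delta_bp = abs(lens[[1]]$length_bp - lens[[2]]$length_bp),
    method = "linear_model",
    models = models, matched_lengths = lens),
    class = "equivalent_bp_result")
}

#' @export
print.equivalent_bp_result <- function(x, ...) {
  cat(sprintf(
    "Binding-strength difference %s vs %s: %.2f bp (method: %s)\n",
    x$motif_a, x$motif_b, x$delta_bp, x$method))
  invisible(x)
}

#' NF attenuation on doubling the reference length
#'
#' Given mean NF at a reference length L and at 2L, returns NF(2L)/NF(L)
#' — a ratio near one half is the signature of the linear NF-length
#' relationship over that range.
#'
#' @param model_points Data frame with columns `reference_n_bp` and
#'   `nf_mean`, exactly two rows whose lengths are in a 2:1 ratio.
#' @return The ratio NF(2L)/NF(L).
#' @examples
#' halving_ratio(data.frame(reference_n_bp = c(20, 40),
#'                          nf_mean = c(0.65, 0.32)))
#' @export
halving_ratio <- function(model_points) {
  stopifnot(is.data.frame(model_points),
            all(c("reference_n_bp", "nf_mean") %in% names(model_points)))
  if (nrow(model_points) != 2)
    stop("invalid input: exactly two points required")
  p <- model_points[order(model_points$reference_n_bp), ]
  if (p$reference_n_bp[2] != 2 * p$reference_n_bp[1])
    stop("invalid input: second length must be twice the first (got ",
         p$reference_n_bp[1], " and ", p$reference_n_bp[2], ")")
  p$nf_mean[2] / p$nf_mean[1]
}
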