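#' Reduced two-dimensional map in (p_a, p_B)
#'
#' Because frequencies sum to one, the dynamics are fully described by the
#' deleterious-allele and epiallele frequencies.  This applies one
#' generation of the full recursion to the embedded state
#' `(p_A = 1 - p_a - p_B, p_B, p_a)` and returns the updated pair.
#'
#' @param x numeric length-2 vector `c(p_a, p_B)`.
#' @param params a [model_params()] object.
#' @return Numeric length-2 vector `c(p_a, p_B)` after one generation.
#' @export
reduced_step <- function(x, params) {
  stopifnot(is.numeric(x), length(x) == 2L)
  if (any(!is.finite(x)) || any(x < 0) || sum(x) > 1 + .freq_tol)
    stop("invalid reduced state: need p_a, p_B >= 0 and p_a + p_B <= 1",
         call. = FALSE)
  p <- cpp_step(c(1 - x[1] - x[2], x[2], x[1]), par_vector(params))
  c(p[3], p[2])
}

#' Numerical Jacobian of the reduced map
#'
#' Central finite differences of [reduced_step()] with a per-coordinate
#' step of `rel_step * max(abs(x_i), 1e-3)`.
#'
#' @param x numeric length-2 vector `c(p_a, p_B)`, interior to the simplex
#'   with margin at least the finite-difference step.
#' @param params a [model_params()] object (ignored when `fun` is given).
#' @param rel_step relative finite-difference step.
#' @param fun optional map to differentiate instead of the model's reduced
#'   step: a function taking and returning a length-2 numeric vector.
#' @return A 2x2 matrix: row i, column j holds the derivative of output
#'   coordinate i with respect to input coordinate j.
#' @export
map_jacobian <- function(x, params = NULL, rel_step = 1e-7, fun = NULL) {
  stopifnot(is.numeric(x), length(x) == 2L)
  if (is.null(fun)) {
    fun <- function(y) reduced_step(y, params)
    simplex <- TRUE
  } else {
    simplex <- FALSE
  }
  h <- rel_step * pmax(abs(x), 1e-3)
  if (simplex) {
    # shrink the step so the evaluations stay inside the simplex even for
    # equilibria lying within mutation-scale distance of its boundary
    margin_top <- 1 - sum(x)
    h <- pmin(h, 0.49 * x, 0.49 * margin_top)
  }
  J <- matrix(NA_real_, 2, 2)
  for (j in 1:2) {
    if (h[j] <= 0)
      stop("finite-difference evaluation leaves the frequency simplex; ",
           "use a smaller step", call. = FALSE)
    xp <- x; xm <- x
    xp[j] <- x[j] + h[j]
    xm[j] <- x[j] - h[j]
    J[, j] <- (fun(xp) - fun(xm)) / (2 * h[j])
  }
  J
}

#' Local stability of a fixed point of the recursion
#'
#' Linearizes the exact reduced map at `point` by finite differences and
#' reports the eigenvalue moduli.  The point is `stable` when both moduli
#' are below `1 - margin`; moduli within `margin` of 1 are reported as
#' neutral/inconclusive (`stable = NA`), as happens for the identity map
#' of the null (process-free) model.
#'
#' @param params a [model_params()] object.
#' @param point an [allele_freqs()] state (approximately a fixed point:
#'   one application of the map must move it by less than `fp_tol`).
#' @param rel_step finite-difference step passed to [map_jacobian()].
#' @param margin stability margin around modulus 1.
#' @param fp_tol maximum allowed movement of `point` under one generation.
#' @return An object of class `"stability_report"`: a list with elements
#'   `jacobian`, `eigenvalues` (complex), `moduli`, `stable` (`TRUE`,
#'   `FALSE` or `NA` for neutral), and `step`.
#' @export
stability_report <- function(params, point, rel_step = 1e-7,
                             margin = 1e-8, fp_tol = 1e-9) {
  validate_freqs(point, "allele")
  x <- c(point[["a"]], point[["B"]])
  moved <- max(abs(reduced_step(x, params) - x))
  if (moved >= fp_tol)
    stop("point is not a fixed point: one generation moves it by ",
         format(moved, digits = 4), " (allowed < ", fp_tol, ")",
         call. = FALSE)
  J <- map_jacobian(x, params, rel_step)
  ev <- eigen(J, only.values = TRUE)$values
  moduli <- Mod(ev)
  mx <- max(moduli)
  stable <- if (mx < 1 - margin) TRUE else if (mx > 1 + margin) FALSE
            else NA
  structure(list(jacobian = J, eigenvalues = as.complex(ev),
                 moduli = moduli, stable = stable,
                 step = rel_step * pmax(abs(x), 1e-3)),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Local stability report\n  eigenvalue moduli: ",
      paste(format(x$moduli, digits = 10), collapse = ", "), "\n",
      "  stable: ", if (is.na(x$stable)) "neutral/inconclusive"
                    else x$stable, "\n", sep = "")
  invisible(x)
}
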