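#' Small-rate scale of the first-order approximations
#'
#' The analytic equilibria are first-order Taylor approximations in the
#' input rates, which are assumed small relative to selection.  The scale
#' `zeta` is the largest of the mutation and forward epimutation rates,
#' including the reverse epimutation rate `t2` under the stable-epiallele
#' scenario (where `t2` is also assumed small) and excluding it under the
#' unstable-epiallele scenario (`t2` of order one).
#'
#' @param params a [model_params()] object.
#' @param small_t2 logical; is `t2` part of the small-rate scale?
#' @return The scale `zeta` (a single number).
#' @export
approximation_scale <- function(params, small_t2 = TRUE) {
  r <- params$rates
  max(r$u, r$z, r$u_prime, r$t1, if (small_t2) r$t2 else 0)
}

analytic_case_ids <- c("A1", "A2", "B3", "B4", "C5", "C6", "C7",
                       "D8", "D9", "D10", "E11", "E12")

# equations derived under the unstable-epiallele (t2 of order one) scenario
.large_t2_cases <- c("A2", "B4", "C7", "D10")

# effective selection/dominance coefficients from a fitness table
# (exact inverse of the incomplete-dominance builder, taking w_AA = 1)
effective_selection <- function(params) {
  if (!is.null(params$selection)) return(params$selection)
  w <- params$fitness
  s <- 1 - w[["aa"]]
  s2 <- 1 - w[["BB"]]
  h <- if (s > 0) (1 - w[["Aa"]]) / s else 0
  h2 <- if (s2 > 0) (1 - w[["AB"]]) / s2 else 0
  list(s = s, s2 = s2, h = h, h2 = h2,
       s3 = w[["Ba"]] - (1 - h2 * s2 - h * s))
}

check_denoms <- function(denoms) {
  bad <- denoms <= 0
  if (any(bad))
    stop("invalid regime: non-positive denominator(s) ",
         paste0(names(denoms)[bad], " = ", signif(denoms[bad], 6),
                collapse = ", "), call. = FALSE)
  denoms
}

# one evaluated constraint
cond <- function(label, lhs, rhs, type = c("gt", "lt", "much_lt",
                                           "approx_gt")) {
  type <- match.arg(type)
  holds <- switch(type,
                  gt = lhs > rhs,
                  lt = lhs < rhs,
                  much_lt = 10 * lhs < rhs,   # "<<" read as an order apart
                  approx_gt = lhs > rhs)      # ">=~" read as strict ">"
  marginal <- switch(type,
                     approx_gt = is.finite(rhs) && rhs != 0 &&
                       abs(lhs - rhs) < 0.25 * abs(rhs),
                     much_lt = holds && 100 * lhs >= rhs,
                     FALSE)
  data.frame(condition = label, lhs = lhs, rhs = rhs, type = type,
             holds = holds, marginal = marginal,
             stringsAsFactors = FALSE)
}

conds <- function(...) do.call(rbind, list(...))

#' First-order analytic equilibrium for a model case
#'
#' Evaluates the closed-form first-order equilibrium approximation for one
#' of the twelve tabulated equilibria, exactly as typeset (composite
#' denominators are not algebraically simplified), together with the
#' printed validity constraints for that equilibrium.  Case identifiers
#' combine the scenario letter with the equation number: `A1`, `A2`
#' (no paramutation, random mating), `B3`, `B4` (inbreeding), `C5`, `C6`,
#' `C7` (paramutation, random mating), `D8`, `D9`, `D10` (paramutation
#' and inbreeding), `E11`, `E12` (deleterious allele paramutagenic).
#'
#' @param case_id one of `"A1"`, `"A2"`, `"B3"`, `"B4"`, `"C5"`, `"C6"`,
#'   `"C7"`, `"D8"`, `"D9"`, `"D10"`, `"E11"`, `"E12"`.
#' @param params a [model_params()] object.
#' @return An object of class `"analytic_equilibrium"`: a list with
#'   elements `case_id`, `p` (named vector `A`, `B`, `a` of predicted
#'   frequencies), `validity` (data frame of evaluated constraints),
#'   `valid` (all constraints hold), `denominators`, and `scenario`
#'   (`"small_t2"` or `"large_t2"`).
#' @examples
#' pars <- model_params(rate_params(u = 1e-9, z = 1e-9, u_prime = 1e-9,
#'                                  t1 = 1e-5),
#'                      selection = selection_params(s = 0.01, s2 = 0.02))
#' analytic_equilibrium("A1", pars)
#' @export
analytic_equilibrium <- function(case_id, params) {
  case_id <- match.arg(case_id, analytic_case_ids)
  stopifnot(inherits(params, "model_params"))
  r <- params$rates
  w <- params$fitness
  sel <- effective_selection(params)
  s <- sel$s; s2 <- sel$s2; h <- sel$h; h2 <- sel$h2
  u <- r$u; z <- r$z; up <- r$u_prime
  t1 <- r$t1; t2 <- r$t2; m <- r$m1; m2 <- r$m2; f <- r$f
  wAA <- w[["AA"]]; wAB <- w[["AB"]]; wAa <- w[["Aa"]]
  wBB <- w[["BB"]]; wBa <- w[["Ba"]]; waa <- w[["aa"]]

  base_high_A <- conds(
    cond("w_AA > w_Aa", wAA, wAa),
    cond("w_Aa > w_aa", wAa, waa),
    cond("w_AA > w_AB", wAA, wAB),
    cond("w_AB > w_BB", wAB, wBB))

  res <- switch(
    case_id,
    A1 = {
      den <- check_denoms(c(hs = h * s, h2s2 = h2 * s2))
      list(pa = u / den[["hs"]], pB = t1 / den[["h2s2"]],
           v = rbind(base_high_A,
                     cond("u << h*s", u, h * s, "much_lt"),
                     cond("t1 << h2*s2", t1, h2 * s2, "much_lt")))
    },
    A2 = {
      den <- check_denoms(c(hs = h * s,
                            h2s2_t2 = h2 * s2 * (1 - t2) + t2))
      list(pa = u / den[["hs"]], pB = t1 / den[["h2s2_t2"]],
           v = rbind(base_high_A,
                     cond("u << h*s", u, h * s, "much_lt"),
                     cond("t1 << h2*s2", t1, h2 * s2, "much_lt"),
                     cond("t1 << t2", t1, t2, "much_lt")))
    },
    B3 = {
      den <- check_denoms(c(a = f * s + h * s * (1 - f),
                            B = f * s2 + h2 * s2 * (1 - f)))
      list(pa = u / den[["a"]], pB = t1 / den[["B"]],
           v = rbind(base_high_A,
                     cond("u << h*s", u, h * s, "much_lt"),
                     cond("u << f*s", u, f * s, "much_lt"),
                     cond("t1 << h2*s2", t1, h2 * s2, "much_lt"),
                     cond("t1 << f*s2", t1, f * s2, "much_lt")))
    },
    B4 = {
      den <- check_denoms(c(
        a = f * s + h * s * (1 - f),
        B = (f * s2 + h2 * s2 * (1 - f)) * (1 - t2) + t2))
      list(pa = u / den[["a"]], pB = t1 / den[["B"]],
           v = rbind(base_high_A,
                     cond("u << h*s", u, h * s, "much_lt"),
                     cond("u << f*s", u, f * s, "much_lt"),
                     cond("t1 << h2*s2", t1, h2 * s2, "much_lt"),
                     cond("t1 << f*s2", t1, f * s2, "much_lt"),
                     cond("t1 << t2", t1, t2, "much_lt")))
    },
    C5 = {
      den <- check_denoms(c(
        a = 1 - wAa,
        B = 1 - wAB + m * (wAB - 2 * wBB)))
      list(pa = u / den[["a"]], pB = t1 / den[["B"]],
           v = rbind(base_high_A,
                     cond("u << w_AA - w_Aa", u, wAA - wAa, "much_lt"),
                     cond("t1 << w_AA - w_AB + m*(w_AB - 2*w_BB)",
                          t1, wAA - wAB + m * (wAB - 2 * wBB), "much_lt"),
                     cond("m*(2*w_BB - w_AB) < w_AA - w_AB",
                          m * (2 * wBB - wAB), wAA - wAB, "lt")))
    },
    C6 = {
      den <- check_denoms(c(a = wBB - wBa,
                            A = wBB - wAB * (1 - m)))
      pa <- up * wBB / den[["a"]]
      pA <- t2 * wBB / den[["A"]]
      list(pa = pa, pB = 1 - pA - pa, pA = pA,
           v = conds(
             cond("w_AA > w_Aa", wAA, wAa),
             cond("w_Aa > w_aa", wAa, waa),
             cond("w_AA > w_AB", wAA, wAB),
             cond("w_AB > w_BB", wAB, wBB),
             cond("w_BB > w_Ba", wBB, wBa),
             cond("w_BB > w_AB*(1 - m)", wBB, wAB * (1 - m)),
             cond("2*w_BB > w_AB", 2 * wBB, wAB),
             cond("u' << w_BB - w_Ba", up, wBB - wBa, "much_lt"),
             cond("t2 << w_BB - w_AB*(1 - m)", t2,
                  wBB - wAB * (1 - m), "much_lt"),
             cond("m > (w_AB - w_BB)/w_AB", m, (wAB - wBB) / wAB)))
    },
    C7 = {
      den <- check_denoms(c(
        a = 1 - wAa,
        B = 1 - (1 - t2) * (wAB - m * (wAB - 2 * wBB))))
      list(pa = u / den[["a"]], pB = t1 / den[["B"]],
           v = rbind(base_high_A,
                     cond("u << w_AA - w_Aa", u, wAA - wAa, "much_lt"),
                     cond("t1 << 1 - (1-t2)*(w_AB - m*(w_AB - 2*w_BB))",
                          t1, den[["B"]], "much_lt")))
    },
    D8 = {
      den <- check_denoms(c(
        a = 1 - f * waa - (1 - f) * wAa,
        B = 1 - f * wBB - (1 - f) * (wAB - m * (wAB - 2 * wBB))))
      list(pa = u / den[["a"]], pB = t1 / den[["B"]],
           v = rbind(base_high_A,
                     cond("u << w_AA - f*w_aa - (1-f)*w_Aa",
                          u, wAA - f * waa - (1 - f) * wAa, "much_lt"),
                     cond("t1 << w_AA - f*w_BB - (1-f)*(w_AB - m*(w_AB - 2*w_BB))",
                          t1, wAA - f * wBB -
                            (1 - f) * (wAB - m * (wAB - 2 * wBB)),
                          "much_lt"),
                     cond("m*(1-f)*(2*w_BB - w_AB) < w_AA - f*w_BB - (1-f)*w_AB",
                          m * (1 - f) * (2 * wBB - wAB),
                          wAA - f * wBB - (1 - f) * wAB, "lt")))
    },
    D9 = {
      den <- check_denoms(c(
        a = wBB - wBa + f * (wBa - waa),
        A = wBB - f - (1 - f) * (1 - m) * wAB))
      pa <- up * wBB / den[["a"]]
      pA <- t2 * wBB / den[["A"]]
      pB <- 1 - wBB * (t2 / den[["A"]] + up / den[["a"]])
      list(pa = pa, pB = pB, pA = pA,
           v = conds(
             cond("w_AA > w_Aa", wAA, wAa),
             cond("w_AB > w_BB", wAB, wBB),
             cond("w_BB > w_aa", wBB, waa),
             cond("w_BB > w_Ba + f*(w_aa - w_Ba)",
                  wBB, wBa + f * (waa - wBa)),
             cond("w_BB > f + (1-f)*(1-m)*w_AB",
                  wBB, f + (1 - f) * (1 - m) * wAB),
             cond("2*w_BB > w_AB", 2 * wBB, wAB),
             cond("u' << w_BB - w_Ba - f*(w_aa - w_Ba)",
                  up, wBB - wBa - f * (waa - wBa), "much_lt"),
             cond("t2 << w_BB - f - (1-f)*(1-m)*w_AB",
                  t2, wBB - f - (1 - f) * (1 - m) * wAB, "much_lt"),
             cond("m*(1-f) > (f + (1-f)*w_AB - w_BB)/w_AB",
                  m * (1 - f), (f + (1 - f) * wAB - wBB) / wAB)))
    },
    D10 = {
      den <- check_denoms(c(
        a = 1 - f * waa - (1 - f) * wAa,
        B = 1 - (1 - t2) *
          (f * wBB + (1 - f) * (wAB - m * (wAB - 2 * wBB)))))
      list(pa = u / den[["a"]], pB = t1 / den[["B"]],
           v = rbind(base_high_A,
                     cond("u << w_AA - f*w_aa - (1-f)*w_Aa",
                          u, wAA - f * waa - (1 - f) * wAa, "much_lt"),
                     cond("t1 << 1 - (1-t2)*(f*w_BB + (1-f)*(w_AB - m*(w_AB - 2*w_BB)))",
                          t1, den[["B"]], "much_lt")))
    },
    E11 = {
      den <- check_denoms(c(
        a = 1 - f * waa - (1 - f) * (wAa - m2 * (wAa - wBa)),
        B = 1 - f * wBB - (1 - f) * (wAB - m * (wAB - 2 * wBB))))
      pa <- u / den[["a"]]
      pB <- t1 / den[["B"]] +
        (1 - f) * u * m2 * wBa / (den[["a"]] * den[["B"]])
      list(pa = pa, pB = pB,
           v = rbind(base_high_A,
                     cond("u << 1 - f*w_aa - (1-f)*(w_Aa - m2*(w_Aa - w_Ba))",
                          u, den[["a"]], "much_lt"),
                     cond("t1 << 1 - f*w_BB - (1-f)*(w_AB - m1*(w_AB - 2*w_BB))",
                          t1, den[["B"]], "much_lt"),
                     cond("m1*(1-f)*(2*w_BB - w_AB) < w_AA - f*w_BB - (1-f)*w_AB",
                          m * (1 - f) * (2 * wBB - wAB),
                          wAA - f * wBB - (1 - f) * wAB, "lt")))
    },
    E12 = {
      den <- check_denoms(c(
        a = waa - f - (1 - f) * (1 - m2) * wAa,
        B = waa - (1 - f) * wBa - f * wBB))
      pa <- 1 - z * waa *
        (waa - (1 - f) * (1 - m2) * wBa - f * wBB) /
        (den[["a"]] * den[["B"]])
      pB <- (1 - f) * z * m2 * waa * wBa / (den[["a"]] * den[["B"]])
      pA <- z * waa / den[["a"]]
      list(pa = pa, pB = pB, pA = pA,
           v = conds(
             cond("w_AA > w_Aa", wAA, wAa),
             cond("w_AA > w_AB", wAA, wAB),
             cond("w_aa > w_BB", waa, wBB),
             cond("w_aa > w_Ba", waa, wBa),
             cond("w_aa > f", waa, f),
             cond("z << w_aa - f - (1-f)*(1-m2)*w_Aa",
                  z, den[["a"]], "much_lt"),
             cond("z << w_aa - (1-f)*w_Ba - f*w_BB",
                  z, den[["B"]], "much_lt"),
             cond("m2*(1-f) > (f + (1-f)*w_Aa - w_aa)/w_Aa",
                  m2 * (1 - f), (f + (1 - f) * wAa - waa) / wAa)))
    })

  pa <- res$pa
  pB <- res$pB
  pA <- res$pA %||% (1 - pa - pB)
  structure(list(case_id = case_id,
                 p = c(A = unname(pA), B = unname(pB), a = unname(pa)),
                 validity = res$v,
                 valid = all(res$v$holds),
                 denominators = get("den"),
                 scenario = if (case_id %in% .large_t2_cases) "large_t2"
                            else "small_t2"),
            class = "analytic_equilibrium")
}

#' @export
print.analytic_equilibrium <- function(x, ...) {
  cat("Analytic equilibrium ", x$case_id, " (", x$scenario,
      " scenario)\n", sep = "")
  cat("  p_A = ", format(x$p[["A"]], digits = 10),
      ", p_B = ", format(x$p[["B"]], digits = 10),
      ", p_a = ", format(x$p[["a"]], digits = 10), "\n", sep = "")
  cat("  valid: ", x$valid, " (", sum(x$validity$holds), "/",
      nrow(x$validity), " constraints hold)\n", sep = "")
  invisible(x)
}
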