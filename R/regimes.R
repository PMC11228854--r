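#' Regime (validity) conditions for the tabulated equilibria of a case
#'
#' Evaluates, for every tabulated equilibrium of the given scenario
#' letter, each of its printed parameter conditions (fitness orderings,
#' rate-magnitude conditions, and paramutation-versus-selection
#' conditions) as a boolean with its numeric margin, plus an overall
#' verdict per equilibrium.  Conditions printed as "much less than" are
#' read as an order of magnitude apart; conditions printed as approximate
#' inequalities have no exact boundary and are treated as strict, with
#' verdicts near the boundary flagged as marginal.
#'
#' @param params a [model_params()] object.
#' @param case one of `"A"`, `"B"`, `"C"`, `"D"`, `"E"`.
#' @return An object of class `"regime_report"`: a data frame with one
#'   row per tabulated equilibrium (`equilibrium`, `verdict`, `marginal`,
#'   `n_hold`, `n_conditions`) and attribute `details`, a list of the
#'   evaluated condition tables.
#' @export
regime_conditions <- function(params, case = c("A", "B", "C", "D", "E")) {
  case <- match.arg(case)
  stopifnot(inherits(params, "model_params"))
  r <- params$rates
  w <- params$fitness
  sel <- effective_selection(params)
  s <- sel$s; s2 <- sel$s2; h <- sel$h; h2 <- sel$h2
  u <- r$u; z <- r$z; up <- r$u_prime
  t1 <- r$t1; t2 <- r$t2; m <- r$m1; m2 <- r$m2; f <- r$f
  wAA <- w[["AA"]]; wAB <- w[["AB"]]; wAa <- w[["Aa"]]
  wBB <- w[["BB"]]; wBa <- w[["Ba"]]; waa <- w[["aa"]]
  me <- 1 - f      # heterozygosity retention factor of effective paramutation
  rates_small <- function() conds(
    cond("u < min(t1, t2)", u, min(t1, t2), "lt"),
    cond("u' < min(t1, t2)", up, min(t1, t2), "lt"),
    cond("z < min(t1, t2)", z, min(t1, t2), "lt"))

  high_A <- conds(cond("w_AA > w_Aa", wAA, wAa),
                  cond("w_Aa > w_aa", wAa, waa),
                  cond("w_AA > w_AB", wAA, wAB),
                  cond("w_AB > w_BB", wAB, wBB))

  rows <- switch(case,
    A = list(
      "1" = rbind(high_A,
                  cond("u << h*s", u, h * s, "much_lt"),
                  cond("t1 << h2*s2", t1, h2 * s2, "much_lt")),
      "2" = rbind(high_A,
                  cond("u << h*s", u, h * s, "much_lt"),
                  cond("t1 << h2*s2", t1, h2 * s2, "much_lt"),
                  cond("t1 << t2", t1, t2, "much_lt"))),
    B = list(
      "3" = rbind(high_A,
                  cond("u << h*s", u, h * s, "much_lt"),
                  cond("u << f*s", u, f * s, "much_lt"),
                  cond("t1 << h2*s2", t1, h2 * s2, "much_lt"),
                  cond("t1 << f*s2", t1, f * s2, "much_lt")),
      "4" = rbind(high_A,
                  cond("u << h*s", u, h * s, "much_lt"),
                  cond("u << f*s", u, f * s, "much_lt"),
                  cond("t1 << h2*s2", t1, h2 * s2, "much_lt"),
                  cond("t1 << f*s2", t1, f * s2, "much_lt"),
                  cond("t1 << t2", t1, t2, "much_lt"))),
    C = list(
      "1" = rbind(high_A,
                  cond("u << w_AA - w_Aa", u, wAA - wAa, "much_lt"),
                  cond("t1 << w_AA - w_AB + m*(w_AB - 2*w_BB)", t1,
                       wAA - wAB + m * (wAB - 2 * wBB), "much_lt"),
                  cond("m*(2*w_BB - w_AB) < w_AA - w_AB",
                       m * (2 * wBB - wAB), wAA - wAB, "lt")),
      "2" = rbind(conds(cond("w_AA > w_Aa", wAA, wAa),
                        cond("w_AB > w_BB", wAB, wBB),
                        cond("w_BB > w_aa", wBB, waa),
                        cond("w_BB > w_Ba", wBB, wBa),
                        cond("2*w_BB > w_AB", 2 * wBB, wAB)),
                  rates_small(),
                  cond("m < (w_AB - w_BB)/w_AB", m,
                       (wAB - wBB) / wAB, "lt"),
                  cond("m > (w_AA - w_AB)/(2*w_BB - w_AB)", m,
                       (wAA - wAB) / (2 * wBB - wAB))),
      "3" = rbind(conds(cond("w_AA > w_Aa", wAA, wAa),
                        cond("w_AA > w_AB", wAA, wAB),
                        cond("w_Ba > w_aa", wBa, waa),
                        cond("w_Ba > w_BB", wBa, wBB)),
                  rates_small(),
                  cond("m >~ w_AA - w_BB", m, wAA - wBB, "approx_gt"),
                  cond("m >~ w_AA - w_aa", m, wAA - waa, "approx_gt")),
      "4" = rbind(conds(cond("w_AA > w_Aa", wAA, wAa),
                        cond("w_Aa > w_aa", wAa, waa),
                        cond("w_AA > w_AB", wAA, wAB),
                        cond("w_AB > w_BB", wAB, wBB),
                        cond("w_BB > w_Ba", wBB, wBa),
                        cond("w_BB > w_AB*(1-m)", wBB, wAB * (1 - m)),
                        cond("2*w_BB > w_AB", 2 * wBB, wAB)),
                  cond("u' << w_BB - w_Ba", up, wBB - wBa, "much_lt"),
                  cond("t2 << w_BB - w_AB*(1-m)", t2,
                       wBB - wAB * (1 - m), "much_lt"),
                  cond("m > (w_AB - w_BB)/w_AB", m, (wAB - wBB) / wAB)),
      "5" = rbind(conds(cond("w_AA > w_Aa", wAA, wAa),
                        cond("w_Aa > w_aa", wAa, waa),
                        cond("w_aa > w_Ba", waa, wBa),
                        cond("w_aa > w_BB", waa, wBB)),
                  rates_small(),
                  cond("m >~ w_AA - w_BB", m, wAA - wBB, "approx_gt"),
                  cond("m >~ w_AA - w_aa", m, wAA - waa, "approx_gt"))),
    D = list(
      "1" = rbind(high_A,
                  cond("u << w_AA - f*w_aa - (1-f)*w_Aa", u,
                       wAA - f * waa - (1 - f) * wAa, "much_lt"),
                  cond("t1 << w_AA - f*w_BB - (1-f)*(w_AB - m*(w_AB - 2*w_BB))",
                       t1, wAA - f * wBB -
                         (1 - f) * (wAB - m * (wAB - 2 * wBB)), "much_lt"),
                  cond("m*(1-f)*(2*w_BB - w_AB) < w_AA - f*w_BB - (1-f)*w_AB",
                       m * me * (2 * wBB - wAB),
                       wAA - f * wBB - (1 - f) * wAB, "lt")),
      "2" = rbind(conds(cond("w_AA > w_Aa", wAA, wAa),
                        cond("w_AB > w_BB", wAB, wBB),
                        cond("w_BB > w_aa", wBB, waa),
                        cond("w_BB > w_Ba", wBB, wBa),
                        cond("2*w_BB > w_AB", 2 * wBB, wAB)),
                  rates_small(),
                  # transcribed as printed; see package vignette on this row
                  cond("m*(1-f) < (f - w_BB - (1-f)*w_AB)/w_AB", m * me,
                       (f - wBB - (1 - f) * wAB) / wAB, "lt"),
                  cond("m*(1-f) > (w_AA - f*w_BB - (1-f)*w_AB)/(2*w_BB - w_AB)",
                       m * me,
                       (wAA - f * wBB - (1 - f) * wAB) /
                         (2 * wBB - wAB))),
      "3" = rbind(conds(cond("w_AA > w_Aa", wAA, wAa),
                        cond("w_AA > w_AB", wAA, wAB),
                        cond("w_Ba > w_aa", wBa, waa),
                        cond("w_Ba > w_BB", wBa, wBB)),
                  rates_small(),
                  cond("m*(1-f) >~ w_AA - w_BB", m * me, wAA - wBB,
                       "approx_gt"),
                  cond("m*(1-f) >~ w_AA - w_aa", m * me, wAA - waa,
                       "approx_gt")),
      "4" = rbind(conds(cond("w_AA > w_Aa", wAA, wAa),
                        cond("w_AB > w_BB", wAB, wBB),
                        cond("w_BB > w_aa", wBB, waa),
                        cond("w_BB > w_Ba", wBB, wBa),
                        cond("2*w_BB > w_AB", 2 * wBB, wAB)),
                  cond("u' << w_BB - w_Ba - f*(w_aa - w_Ba)", up,
                       wBB - wBa - f * (waa - wBa), "much_lt"),
                  cond("t2 << w_BB - f - (1-f)*(1-m)*w_AB", t2,
                       wBB - f - (1 - f) * (1 - m) * wAB, "much_lt"),
                  cond("m*(1-f) > (f + (1-f)*w_AB - w_BB)/w_AB", m * me,
                       (f + (1 - f) * wAB - wBB) / wAB)),
      "5" = rbind(conds(cond("w_AA > w_Aa", wAA, wAa),
                        cond("w_AB > w_aa", wAB, waa),
                        cond("w_aa > w_Ba", waa, wBa),
                        cond("w_Ba > w_BB", wBa, wBB)),
                  rates_small(),
                  cond("m*(1-f) >~ w_AA - w_BB", m * me, wAA - wBB,
                       "approx_gt"),
                  cond("m*(1-f) >~ w_AA - w_aa", m * me, wAA - waa,
                       "approx_gt"))),
    E = list(
      "1" = rbind(high_A,
                  cond("u << 1 - f*w_aa - (1-f)*(w_Aa - m2*(w_Aa - w_Ba))",
                       u, 1 - f * waa -
                         (1 - f) * (wAa - m2 * (wAa - wBa)), "much_lt"),
                  cond("t1 << 1 - f*w_BB - (1-f)*(w_AB - m1*(w_AB - 2*w_BB))",
                       t1, 1 - f * wBB -
                         (1 - f) * (wAB - m * (wAB - 2 * wBB)), "much_lt"),
                  cond("m1*(1-f)*(2*w_BB - w_AB) < w_AA - f*w_BB - (1-f)*w_AB",
                       m * me * (2 * wBB - wAB),
                       wAA - f * wBB - (1 - f) * wAB, "lt")),
      "2" = rbind(conds(cond("w_AA > w_Aa", wAA, wAa),
                        cond("w_AB > w_BB", wAB, wBB),
                        cond("w_BB > w_aa", wBB, waa),
                        cond("w_BB > w_Ba", wBB, wBa)),
                  cond("u' << w_BB - w_Ba - f*(w_aa - w_Ba)", up,
                       wBB - wBa - f * (waa - wBa), "much_lt"),
                  cond("t2 << w_BB - f - (1-f)*(1-m1)*w_AB", t2,
                       wBB - f - (1 - f) * (1 - m) * wAB, "much_lt"),
                  cond("m1*(1-f) > (f + (1-f)*w_AB - w_BB)/w_AB", m * me,
                       (f + (1 - f) * wAB - wBB) / wAB)),
      "3" = rbind(conds(cond("w_AA > w_Aa", wAA, wAa),
                        cond("w_AA > w_AB", wAA, wAB),
                        cond("w_Aa > w_aa", wAa, waa),
                        cond("w_AB > w_aa", wAB, waa),
                        cond("w_aa > w_BB", waa, wBB),
                        cond("w_aa > w_Ba", waa, wBa),
                        cond("w_aa > f", waa, f)),
                  cond("z << w_aa - f - (1-f)*(1-m2)*w_Aa", z,
                       waa - f - (1 - f) * (1 - m2) * wAa, "much_lt"),
                  cond("z << w_aa - (1-f)*w_Ba - f*w_BB", z,
                       waa - (1 - f) * wBa - f * wBB, "much_lt"),
                  cond("m2*(1-f) > (f + (1-f)*w_Aa - w_aa)/w_Aa", m2 * me,
                       (f + (1 - f) * wAa - waa) / wAa))))

  summary <- do.call(rbind, lapply(names(rows), function(id) {
    v <- rows[[id]]
    data.frame(equilibrium = id,
               verdict = all(v$holds),
               marginal = any(v$marginal),
               n_hold = sum(v$holds),
               n_conditions = nrow(v),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  structure(summary, details = rows, case = case,
            class = c("regime_report", "data.frame"))
}

#' @export
print.regime_report <- function(x, ...) {
  cat("Regime report, case ", attr(x, "case"), "\n", sep = "")
  print.data.frame(x)
  invisible(x)
}

#' Compare a numerically obtained equilibrium with its analytic formula
#'
#' The analytic equilibria are first-order approximations with error of
#' order `zeta^2`; agreement with the full recursion is asserted only
#' inside the tolerance policy: relative error at most `tol_rel` when
#' `zeta <= 1e-5` and every formula denominator is at least `1e2 * zeta`
#' (the relative first-order error scales as `zeta` over the denominator,
#' so this factor is what the 1 percent default guarantees).
#' Outside the policy the comparison is reported but not judged; when the
#' analytic validity constraints fail, the comparison refuses with status
#' `"invalid_regime"`.
#'
#' @param params a [model_params()] object.
#' @param numeric an [allele_freqs()] equilibrium from the full recursion.
#' @param analytic an `analytic_equilibrium` object.
#' @param tol_rel relative-error tolerance inside the policy.
#' @return A list with elements `status` (`"pass"`, `"fail"`,
#'   `"reported"`, or `"invalid_regime"`), `abs_error`, `rel_error`,
#'   `zeta`, and `policy_met`.
#' @export
compare_numeric_analytic <- function(params, numeric, analytic,
                                     tol_rel = 0.01) {
  stopifnot(inherits(analytic, "analytic_equilibrium"))
  validate_freqs(numeric, "allele")
  zeta <- approximation_scale(params,
                              small_t2 = analytic$scenario == "small_t2")
  if (!analytic$valid)
    return(list(status = "invalid_regime", abs_error = NULL,
                rel_error = NULL, zeta = zeta, policy_met = FALSE))
  pn <- c(A = numeric[["A"]], B = numeric[["B"]], a = numeric[["a"]])
  abs_err <- abs(pn - analytic$p)
  rel_err <- ifelse(analytic$p != 0, abs_err / abs(analytic$p), NA_real_)
  policy <- zeta <= 1e-5 && all(analytic$denominators >= 1e2 * zeta)
  status <- if (!policy) "reported"
            else if (all(rel_err <= tol_rel, na.rm = TRUE)) "pass"
            else "fail"
  list(status = status, abs_error = abs_err, rel_error = rel_err,
       zeta = zeta, policy_met = policy)
}
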