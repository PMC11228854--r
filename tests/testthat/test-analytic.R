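test_that("baseline closed forms evaluate as typeset", {
  pars <- case_a_params()
  a1 <- analytic_equilibrium("A1", pars)
  expect_equal(a1$p[["a"]], 2e-7)
  expect_equal(a1$p[["B"]], 1e-3)
  expect_equal(a1$p[["A"]], 1 - 2e-7 - 1e-3)
  expect_true(a1$valid)

  # zero forward epimutation removes the epiallele
  a0 <- analytic_equilibrium("A1", model_params(
    rate_params(u = 1e-9), selection = selection_params(s = 0.01,
                                                        s2 = 0.02)))
  expect_equal(a0$p[["B"]], 0)

  # neutral selection: the formula denominator vanishes
  expect_error(analytic_equilibrium("A1",
                                    model_params(rate_params(u = 1e-9))),
               "denominator")
})

test_that("complete epiallele resetting pins p_B to the forward rate", {
  pars <- case_a_params(t2 = 1 - 1e-12)
  expect_equal(analytic_equilibrium("A2", pars)$p[["B"]], 1e-5,
               tolerance = 1e-9)
  parsb <- case_b_params(f = 0.5, t2 = 1 - 1e-12)
  expect_equal(analytic_equilibrium("B4", parsb)$p[["B"]], 1e-5,
               tolerance = 1e-9)
})

test_that("inbreeding monotonically lowers both variants in the no-paramutation balance", {
  pars <- case_b_params()
  fs <- c(0.05, 0.2, 0.5, 0.9)
  preds <- t(vapply(fs, function(f)
    analytic_equilibrium("B3", set_param(pars, "f", f))$p, numeric(3)))
  expect_true(all(diff(preds[, "a"]) < 0))
  expect_true(all(diff(preds[, "B"]) < 0))
})

test_that("the formulas reduce to one another at their limits", {
  pars <- model_params(rate_params(u = 3e-9, z = 2e-9, u_prime = 4e-9,
                                   t1 = 2e-5, t2 = 1e-4, m1 = 0.008,
                                   m2 = 0, f = 0.15),
                       selection = selection_params(s = 0.012, s2 = 0.022,
                                                    s3 = 0.002))
  # no paramutation: the paramutation balance is the plain balance
  expect_equal(analytic_equilibrium("C5", set_param(pars, "m1", 0))$p,
               analytic_equilibrium("A1", set_param(pars, "m1", 0))$p)
  # no inbreeding: the inbred forms collapse to the random-mating forms
  expect_equal(analytic_equilibrium("D8", set_param(pars, "f", 0))$p,
               analytic_equilibrium("C5", set_param(pars, "f", 0))$p)
  expect_equal(analytic_equilibrium("D10", set_param(pars, "f", 0))$p,
               analytic_equilibrium("C7", set_param(pars, "f", 0))$p)
  # no deleterious-allele paramutation: case E collapses to case D
  expect_equal(analytic_equilibrium("E11", set_param(pars, "m2", 0))$p,
               analytic_equilibrium("D8", pars)$p)
})

test_that("paramutation shifts p_B in the direction set by 2*w_BB - w_AB", {
  pB_at <- function(pars, m)
    analytic_equilibrium("C5", set_param(pars, "m1", m))$p[["B"]]
  # mild epiallele selection: w_AB < 2 w_BB, paramutation raises p_B
  mild <- model_params(rate_params(u = 1e-9, t1 = 1e-5),
                       selection = selection_params(s = 0.01, s2 = 0.02))
  expect_gt(pB_at(mild, 0.004), pB_at(mild, 0))
  # drastic epiallele selection: w_AB > 2 w_BB, paramutation lowers p_B
  drastic <- model_params(rate_params(u = 1e-9, t1 = 1e-5),
                          selection = selection_params(s = 0.01, s2 = 0.9,
                                                       h2 = 0.58))
  w <- drastic$fitness
  expect_gt(w[["AB"]], 2 * w[["BB"]])
  expect_lt(pB_at(drastic, 0.2), pB_at(drastic, 0))
})

test_that("inbreeding direction in the epiallele-high balance follows w_aa - w_Ba", {
  pa_at <- function(pars, f)
    analytic_equilibrium("D9", set_param(pars, "f", f))$p[["a"]]
  # w_Ba > w_aa: inbreeding lowers p_a
  hi_Ba <- model_params(rate_params(u = 1e-9, z = 1e-9, u_prime = 1e-9,
                                    t1 = 1e-5, t2 = 1e-4, m1 = 0.5),
                        selection = selection_params(s = 0.03, s2 = 0.01))
  expect_gt(hi_Ba$fitness[["Ba"]], hi_Ba$fitness[["aa"]])
  expect_lt(pa_at(hi_Ba, 0.1), pa_at(hi_Ba, 0.05))
  # w_aa > w_Ba: inbreeding raises p_a
  hi_aa <- model_params(rate_params(u = 1e-9, z = 1e-9, u_prime = 1e-9,
                                    t1 = 1e-5, t2 = 1e-4, m1 = 0.5),
                        selection = selection_params(s = 0.01, s2 = 0.01,
                                                     h = 0.9))
  expect_gt(hi_aa$fitness[["aa"]], hi_aa$fitness[["Ba"]])
  expect_gt(pa_at(hi_aa, 0.1), pa_at(hi_aa, 0.05))
})

test_that("the deleterious-high balance needs a paramutagenic allele", {
  pars <- case_e_bistable_params()
  e12 <- analytic_equilibrium("E12", pars)
  expect_true(e12$valid)
  expect_gt(e12$p[["a"]], 0.99)

  # without m2 the A/a heterozygote advantage empties the regime: the
  # formula denominator w_aa - f - (1-f) w_Aa turns negative
  expect_error(analytic_equilibrium("E12", set_param(pars, "m2", 0)),
               "invalid regime")
  # high inbreeding (w_aa < f) is likewise excluded
  expect_error(analytic_equilibrium("E12", set_param(pars, "f", 0.995)),
               "invalid regime")
  # as is a fitter epiallele homozygote (w_aa < w_BB)
  swapped <- model_params(pars$rates,
                          selection = selection_params(s = 0.02, s2 = 0.01,
                                                       s3 = 0.001))
  expect_error(analytic_equilibrium("E12", swapped), "invalid regime")

  # the epiallele persists without forward epimutation, via m2 and u
  e11 <- analytic_equilibrium("E11", set_param(pars, "t1", 0))
  expect_gt(e11$p[["B"]], 0)
})

test_that("regime verdicts locate the figure parameter sets and are exclusive", {
  # compensatory regime: w_Ba > w_BB > w_aa with strong paramutation
  rr2a <- regime_conditions(preset("fig2a"), "C")
  expect_identical(rr2a$equilibrium[rr2a$verdict], "3")

  # cycling regime: w_aa > w_Ba > w_BB
  rr3 <- regime_conditions(preset("fig3-t2-1e-3"), "C")
  expect_identical(rr3$equilibrium[rr3$verdict], "5")

  # baseline: wild-type-high row
  rrA <- regime_conditions(case_a_params(), "A")
  expect_true(rr_row <- rrA$verdict[rrA$equilibrium == "1"])

  # neutral fitness: every strict-ordering condition fails
  rr0 <- regime_conditions(model_params(rate_params(u = 1e-9)), "C")
  expect_false(any(rr0$verdict))

  # mutual exclusivity at the printed parameter sets
  for (nm in c("fig2a", "fig2c", "fig3-t2-1e-3", "fig5-f0.1", "fig6-f0.25"))
    for (cs in c("C", "D"))
      expect_lte(sum(regime_conditions(preset(nm), cs)$verdict), 1)
})

test_that("inbred-case conditions reduce to random-mating conditions at f = 0", {
  pars <- set_param(preset("fig2a"), "f", 0)
  dc <- attr(regime_conditions(pars, "C"), "details")
  dd <- attr(regime_conditions(pars, "D"), "details")
  # the analytically tractable wild-type-high row matches condition by
  # condition once the (1 - f) factors collapse
  expect_equal(dd[["1"]]$lhs, dc[["1"]]$lhs, tolerance = 1e-12)
  expect_equal(dd[["1"]]$rhs, dc[["1"]]$rhs, tolerance = 1e-12)
  expect_identical(dd[["1"]]$holds, dc[["1"]]$holds)
  # the effective-paramutation bounds m (1 - f) >~ ... of the numerically
  # assessed rows also collapse to their random-mating counterparts
  for (row in c("3", "5")) {
    ic <- dc[[row]]$type == "approx_gt"
    id <- dd[[row]]$type == "approx_gt"
    expect_equal(dd[[row]]$lhs[id], dc[[row]]$lhs[ic], tolerance = 1e-15)
    expect_equal(dd[[row]]$rhs[id], dc[[row]]$rhs[ic], tolerance = 1e-15)
  }
})

test_that("full-recursion equilibria match the closed forms inside the policy", {
  start <- allele_freqs(0.98, 0.01, 0.01)
  check <- function(id, pars, max_rel = 0.01) {
    an <- analytic_equilibrium(id, pars)
    expect_true(an$valid, label = paste(id, "validity"))
    eq <- find_equilibrium(pars, start, fast_settings(max_gens = 1e7),
                           stability = FALSE)
    expect_true(eq$converged, label = paste(id, "convergence"))
    cmp <- compare_numeric_analytic(pars, eq$p, an)
    expect_identical(cmp$status, "pass", label = paste(id, "status"))
    invisible(cmp)
  }
  sel <- selection_params(s = 0.012, s2 = 0.022, s3 = 0.002)
  small <- function(...) rate_params(u = 1e-9, z = 1e-9, u_prime = 1e-9,
                                     t1 = 1e-5, ...)
  check("A1", model_params(small(t2 = 0), selection = sel))
  check("A2", model_params(small(t2 = 0.3), selection = sel))
  check("B3", model_params(small(t2 = 0, f = 0.5), selection = sel))
  check("B4", model_params(small(t2 = 0.3, f = 0.5), selection = sel))
  check("C5", model_params(small(t2 = 1e-5, m1 = 0.004), selection = sel))
  check("C7", set_param(preset("fig4-black"), "m1", 0.1))
  check("D8", model_params(small(t2 = 1e-5, m1 = 0.004, f = 0.2),
                           selection = sel))
  check("D10", set_param(preset("fig7-black-f0.25"), "m1", 0.1))
  check("E11", model_params(small(t2 = 1e-5, m1 = 0.004, m2 = 0.3,
                                  f = 0.1),
                            selection = selection_params(s = 0.01,
                                                         s2 = 0.02,
                                                         s3 = 0.001)))
  # a failed validity flag refuses the comparison (here the back-mutation
  # rate is far too large for the small-rate assumption)
  noisy <- set_param(case_e_bistable_params(), "z", 0.01)
  bad <- analytic_equilibrium("E12", noisy)
  expect_false(bad$valid)
  ref <- compare_numeric_analytic(noisy, allele_freqs(0.5, 0.25, 0.25),
                                  bad)
  expect_identical(ref$status, "invalid_regime")
})
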