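test_that("iteration of the null model stops at patience with constant state", {
  null <- model_params(rate_params())
  p <- allele_freqs(0.2, 0.3, 0.5)
  st <- convergence_settings(patience = 50, max_gens = 1e4)
  traj <- iterate(null, p, st)
  expect_true(attr(traj, "converged"))
  expect_equal(attr(traj, "generations"), 50)
  expect_true(all(traj$p_a == 0.5))
  eq <- find_equilibrium(null, p, st, stability = FALSE)
  expect_true(eq$converged)
  expect_lte(eq$generations, 50)
})

test_that("converged equilibria satisfy the fixed-point property", {
  st <- fast_settings()
  for (pars in list(case_a_params(), preset("fig2a"), preset("fig6-f0.25"))) {
    eq <- find_equilibrium(pars, allele_freqs(0.98, 0.01, 0.01), st,
                           stability = FALSE)
    expect_true(eq$converged)
    nxt <- generation_step(eq$p, pars)
    expect_lt(max(abs(as.numeric(nxt) - as.numeric(eq$p))), st$tol)
  }
})

test_that("the baseline equilibrium matches the mutation/epimutation balance", {
  eq <- find_equilibrium(case_a_params(), allele_freqs(0.98, 0.01, 0.01))
  expect_true(eq$converged)
  # u/(h s) and t1/(h2 s2)
  expect_lt(abs(eq$p[["a"]] / 2e-7 - 1), 0.01)
  expect_lt(abs(eq$p[["B"]] / 1e-3 - 1), 0.01)
  expect_true(eq$stability$stable)

  # all starts in the default grid reach the same point
  eqs <- lapply(default_init_grid(), function(i)
    find_equilibrium(case_a_params(), i, stability = FALSE))
  pts <- t(vapply(eqs, function(e) as.numeric(e$p), numeric(3)))
  expect_lt(max(apply(pts, 2, function(x) diff(range(x)))),
            10 * convergence_settings()$tol)
})

test_that("larger reverse epimutation lowers p_a and raises p_B", {
  eqs <- lapply(c("fig3-t2-1e-3", "fig3-t2-1e-2.7", "fig3-t2-1e-2.4"),
                function(nm) find_equilibrium(preset(nm),
                                              allele_freqs(0.98, 0.01, 0.01),
                                              stability = FALSE))
  pa <- vapply(eqs, function(e) e$p[["a"]], numeric(1))
  pB <- vapply(eqs, function(e) e$p[["B"]], numeric(1))
  expect_true(all(diff(pa) < 0))
  expect_true(all(diff(pB) > 0))
})

test_that("cycling diagnostics match a brute-force sign-change scan", {
  # synthetic damped oscillation around a fixed level
  t <- 0:200
  pa <- 0.4 + 0.1 * 0.9^t * cos(t)
  traj <- data.frame(generation = t, p_a = pa)
  rep <- detect_cycling(traj)
  # independent oracle: explicit loop over increments
  d <- pa[-1] - pa[-length(pa)]
  count <- 0L; last <- 0
  prev <- 0
  for (i in seq_along(d)) {
    s <- if (d[i] > 0) 1 else if (d[i] < 0) -1 else 0
    if (s != 0) {
      if (prev != 0 && s != prev) { count <- count + 1L; last <- t[i + 1] }
      prev <- s
    }
  }
  expect_identical(rep$oscillations, count)
  expect_equal(rep$duration, last)
  expect_equal(rep$amplitude, max(abs(pa - pa[length(pa)])))

  # strictly monotone series has no oscillations
  mono <- detect_cycling(data.frame(generation = 0:50,
                                    p_a = seq(0, 0.5, length.out = 51)))
  expect_identical(mono$oscillations, 0L)
  expect_equal(mono$duration, 0)
  expect_error(detect_cycling(data.frame(generation = 0:1,
                                         p_a = c(0, 1))), "short")
})

test_that("cycling trajectories oscillate and near-balance ones do not", {
  # paramutation stronger than selection with w_aa > w_Ba > w_BB: damped
  # cycling on the approach to equilibrium
  eq_cyc <- find_equilibrium(preset("fig6-f0"),
                             allele_freqs(0.98, 0.01, 0.01),
                             stability = FALSE)
  expect_gt(eq_cyc$cycling$oscillations, 2)
  expect_gt(eq_cyc$cycling$duration, 0)

  # near-equilibrium start in the compensatory regime approaches smoothly
  pars <- preset("fig2a")
  eq <- find_equilibrium(pars, allele_freqs(0.98, 0.01, 0.01),
                         stability = FALSE)
  traj <- iterate(pars, eq$p, convergence_settings(max_gens = 1e4))
  rep <- detect_cycling(traj, eps = convergence_settings()$tol)
  expect_lte(rep$oscillations, 1)
})

test_that("inbreeding lengthens cycling and shifts the balance toward B", {
  eqs <- lapply(c("fig6-f0", "fig6-f0.25", "fig6-f0.5"), function(nm)
    find_equilibrium(preset(nm), allele_freqs(0.98, 0.01, 0.01),
                     stability = FALSE))
  pa <- vapply(eqs, function(e) e$p[["a"]], numeric(1))
  pB <- vapply(eqs, function(e) e$p[["B"]], numeric(1))
  dur <- vapply(eqs, function(e) e$cycling$duration, numeric(1))
  expect_true(all(diff(pa) < 0))
  expect_true(all(diff(pB) > 0))
  expect_true(all(diff(dur) > 0))
})

test_that("equilibria are labelled by fixed frequency thresholds", {
  cls <- classify_equilibrium(allele_freqs(1 - 0.001 - 2e-7, 0.001, 2e-7))
  expect_equal(cls$A, "high")
  expect_equal(cls$B, "low")
  expect_equal(cls$a, "very_low")
  expect_equal(cls$max_variant, "A")

  tie <- classify_equilibrium(allele_freqs(1 / 3, 1 / 3, 1 / 3))
  expect_true(all(c(tie$A, tie$B, tie$a) == "moderate"))
  expect_equal(tie$max_variant, "A")   # ties break A < B < a

  cls2 <- classify_equilibrium(allele_freqs(0.02, 0.97, 0.01))
  expect_equal(cls2$B, "high")
  expect_equal(cls2$A, "low")
  expect_equal(cls2$a, "low")
  expect_equal(cls2$max_variant, "B")
})

test_that("a census over one neutral parameter set yields one class", {
  # the neutral map is the identity, so every start is its own fixed
  # point; with a single start the census reports exactly one class,
  # flagged neutral rather than stable
  st <- convergence_settings(max_gens = 1e4,
                             init_grid = list(allele_freqs(1/3, 1/3, 1/3)))
  cen <- enumerate_equilibria(list(model_params(rate_params())), st)
  expect_equal(nrow(cen$classes), 1L)
  expect_true(all(is.na(cen$runs$stable)))
})

test_that("bistable parameter sets reach different equilibria by start", {
  cen <- enumerate_equilibria(list(case_e_bistable_params()),
                              fast_settings())
  stable <- cen$classes[cen$classes$stable %in% TRUE, ]
  expect_equal(nrow(stable), 2L)
  expect_setequal(stable$max_variant, c("A", "a"))
})

test_that("bisection finds the paramutation threshold and flags flat regions", {
  crit <- find_critical_m(preset("fig4-black"), 0.05, 0.5,
                          settings = fast_settings())
  expect_lt(abs(crit$m_critical - 0.25), 0.01)
  expect_gt(abs(crit$stat_hi - crit$stat_lo) +
              abs(crit$stat_lo), 0)   # statistics were computed

  # with inbreeding the threshold moves to ~ t2 / ((1-f)(1-t2)) = 1/3
  crit_f <- find_critical_m(preset("fig7-black-f0.25"), 0.05, 0.5,
                            settings = fast_settings())
  expect_lt(abs(crit_f$m_critical - 1 / 3), 0.02)
  expect_gt(crit_f$m_critical, crit$m_critical)

  expect_error(find_critical_m(preset("fig4-black"), 0.05, 0.06,
                               settings = fast_settings()),
               "no branch change")
})

test_that("sweeps reproduce single equilibria and inbreeding directions", {
  st <- fast_settings()
  pars <- preset("fig5-f0")
  tab1 <- sweep_parameter(pars, "f", 0.1, settings = st)
  eq <- find_equilibrium(set_param(pars, "f", 0.1),
                         allele_freqs(0.98, 0.01, 0.01), st)
  expect_equal(tab1$p_a, eq$p[["a"]])
  expect_equal(tab1$p_B, eq$p[["B"]])

  # compensatory regime: inbreeding raises p_a and lowers p_B
  tab <- sweep_parameter(pars, "f", c(0, 0.1, 0.2), settings = st)
  expect_true(all(diff(tab$p_a) > 0))
  expect_true(all(diff(tab$p_B) < 0))
  expect_error(sweep_parameter(pars, "bogus", 0.1), "unknown parameter")
})

test_that("sweeping m traces the low branch and the post-threshold branches", {
  st <- fast_settings()
  # w_aa < w_BB: beyond the threshold p_B increases with m
  black <- sweep_parameter(preset("fig4-black"), "m1",
                           c(0.05, 0.15, 0.32, 0.4, 0.5), settings = st)
  expect_true(all(black$p_B[1:2] < 0.05))
  post <- black$p_B[3:5]
  expect_true(all(post > 0.05) && all(diff(post) > 0))
  # w_aa > w_BB: once m is well past the epiallele reversion rate the
  # epiallele stays moderate and decreases with m (deleterious allele up)
  gray <- sweep_parameter(preset("fig4-gray"), "m1",
                          c(0.45, 0.5, 0.65, 0.8), settings = st)
  expect_true(all(gray$p_B > 0.05 & gray$p_B < 0.5))
  expect_true(all(diff(gray$p_B) < 0))
  expect_true(all(diff(gray$p_a) > 0))
})
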