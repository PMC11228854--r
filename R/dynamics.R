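#' Convergence settings for equilibrium iteration
#'
#' @param tol absolute per-generation change below which a state is
#'   considered stationary.  The default 1e-13 sits far below the smallest
#'   equilibrium frequencies of interest (order 1e-7).
#' @param patience number of consecutive stationary generations required
#'   before declaring convergence.
#' @param max_gens iteration cap.
#' @param init_grid list of [allele_freqs()] starting points used by
#'   grid-based operations ([enumerate_equilibria()], [find_critical_m()]).
#' @return An object of class `"convergence_settings"`.
#' @export
convergence_settings <- function(tol = 1e-13, patience = 100L,
                                 max_gens = 1e7,
                                 init_grid = default_init_grid()) {
  stopifnot(is.numeric(tol), length(tol) == 1L, tol > 0,
            patience >= 1, max_gens >= 1, is.list(init_grid),
            length(init_grid) >= 1L)
  lapply(init_grid, validate_freqs, what = "allele")
  structure(list(tol = tol, patience = as.integer(patience),
                 max_gens = max_gens, init_grid = init_grid),
            class = "convergence_settings")
}

#' Default grid of starting frequencies
#'
#' Four starting points, one near fixation of each variant plus the
#' barycenter, so that every basin of attraction relevant to the model's
#' multi-equilibria regimes is probed.
#'
#' @return A list of [allele_freqs()] states.
#' @export
default_init_grid <- function() {
  list(allele_freqs(0.98, 0.01, 0.01),
       allele_freqs(0.01, 0.98, 0.01),
       allele_freqs(0.01, 0.01, 0.98),
       allele_freqs(1 / 3, 1 / 3, 1 / 3))
}

par_vector <- function(params) {
  r <- params$rates
  w <- params$fitness
  c(r$u, r$z, r$u_prime, r$t1, r$t2, r$m1, r$m2, r$f,
    w[["AA"]], w[["AB"]], w[["Aa"]], w[["BB"]], w[["Ba"]], w[["aa"]])
}

#' Iterate the recursion and record the trajectory
#'
#' Runs the single-generation map from `init`, recording every
#' `record_every`-th generation, and stops early once every frequency has
#' changed by less than `settings$tol` for `settings$patience` consecutive
#' generations.
#'
#' @param params a [model_params()] object.
#' @param init an [allele_freqs()] starting state.
#' @param settings a [convergence_settings()] object.
#' @param record_every record one row every this many generations.
#' @return A data frame of class `"trajectory"` with columns `generation`,
#'   `p_A`, `p_B`, `p_a`, `mean_fitness` (the zygote-pool mean fitness of
#'   the generation in each row), and attributes `converged` and
#'   `generations`.
#' @export
iterate <- function(params, init, settings = convergence_settings(),
                    record_every = 1L) {
  stopifnot(inherits(params, "model_params"),
            inherits(settings, "convergence_settings"))
  validate_freqs(init, "allele")
  res <- cpp_iterate(as.numeric(init), par_vector(params),
                     settings$tol, settings$patience, settings$max_gens,
                     as.integer(max(1L, record_every)),
                     cycle_eps = settings$tol)
  traj <- res$trajectory
  class(traj) <- c("trajectory", "data.frame")
  attr(traj, "converged") <- res$converged
  attr(traj, "generations") <- res$generations
  traj
}

#' Find an equilibrium of the recursion
#'
#' Iterates the map from `init` until convergence (or the iteration cap)
#' and attaches damped-cycling diagnostics and a local stability report.
#' Non-convergence is reported through the `converged` flag, not raised.
#'
#' @inheritParams iterate
#' @param stability if `TRUE`, attach a [stability_report()] at the final
#'   state (only computed when converged).
#' @return An object of class `"equilibrium_result"`: a list with elements
#'   `p` (final [allele_freqs()]), `generations`, `converged`, `cycling`
#'   (list with `oscillations`, `duration`, `amplitude`), `stability`
#'   (a [stability_report()] or `NULL`), and `params`.
#' @export
find_equilibrium <- function(params, init, settings = convergence_settings(),
                             stability = TRUE) {
  stopifnot(inherits(params, "model_params"),
            inherits(settings, "convergence_settings"))
  validate_freqs(init, "allele")
  res <- cpp_iterate(as.numeric(init), par_vector(params),
                     settings$tol, settings$patience, settings$max_gens,
                     0L, cycle_eps = settings$tol)
  p <- as_allele_freqs(res$p)
  stab <- NULL
  if (stability && res$converged)
    stab <- tryCatch(stability_report(params, p),
                     error = function(e) NULL)
  structure(list(p = p,
                 generations = res$generations,
                 converged = res$converged,
                 cycling = list(oscillations = res$oscillations,
                                duration = res$cycling_duration,
                                amplitude = res$amplitude),
                 stability = stab,
                 params = params),
            class = "equilibrium_result")
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat("Equilibrium result (", if (x$converged) "converged" else
      "NOT converged", " after ", format(x$generations, big.mark = ","),
      " generations)\n", sep = "")
  cat("  p_A = ", format(x$p[["A"]], digits = 10),
      ", p_B = ", format(x$p[["B"]], digits = 10),
      ", p_a = ", format(x$p[["a"]], digits = 10), "\n", sep = "")
  cat("  cycling: ", x$cycling$oscillations, " oscillation(s), duration ",
      x$cycling$duration, " generation(s)\n", sep = "")
  if (!is.null(x$stability))
    cat("  stability: ", if (isTRUE(x$stability$stable)) "stable"
        else if (is.na(x$stability$stable)) "neutral/inconclusive"
        else "unstable",
        " (|lambda| = ",
        paste(format(x$stability$moduli, digits = 8), collapse = ", "),
        ")\n", sep = "")
  invisible(x)
}

#' Damped-cycling diagnostics of a trajectory
#'
#' Measures oscillatory approach to equilibrium on the deleterious-allele
#' series: the oscillation count is the number of sign changes of the
#' per-generation increment of `p_a` (increments smaller than `eps` in
#' magnitude are treated as stationary), the cycling duration is the
#' generation at which the last sign change occurs, and the amplitude is
#' the largest excursion of `p_a` from its final value.
#'
#' @param traj a trajectory from [iterate()] (recorded every generation),
#'   or any data frame with columns `generation` and `p_a`.
#' @param eps increments with absolute value below `eps` carry no sign.
#' @return A list with elements `oscillations`, `duration`, `amplitude`.
#' @export
detect_cycling <- function(traj, eps = 0) {
  stopifnot(is.data.frame(traj), all(c("generation", "p_a") %in% names(traj)))
  if (nrow(traj) < 3L)
    stop("trajectory too short for cycling detection (need >= 3 rows)",
         call. = FALSE)
  pa <- traj$p_a
  d <- diff(pa)
  keep <- abs(d) >= eps & d != 0
  sgn <- sign(d[keep])
  gens <- traj$generation[-1L][keep]
  flips <- which(diff(sgn) != 0)
  list(oscillations = length(flips),
       duration = if (length(flips)) gens[flips[length(flips)] + 1L] else 0,
       amplitude = max(abs(pa - pa[length(pa)])))
}

.class_breaks <- c(very_low = 1e-4, low = 0.05, moderate = 0.5)

freq_label <- function(p) {
  if (p < .class_breaks[["very_low"]]) "very_low"
  else if (p < .class_breaks[["low"]]) "low"
  else if (p < .class_breaks[["moderate"]]) "moderate"
  else "high"
}

#' Qualitative classification of an equilibrium
#'
#' Labels each variant frequency as `very_low` (< 1e-4), `low` (< 0.05),
#' `moderate` (< 0.5) or `high` (>= 0.5), and identifies the
#' maximal-frequency variant (ties broken in the fixed order A, B, a).
#' The thresholds separate mutation-scale, epimutation-scale and
#' order-one frequencies across all regimes the model produces.
#'
#' @param eq an [allele_freqs()] state or an `equilibrium_result`.
#' @return An object of class `"equilibrium_class"`: a list with elements
#'   `A`, `B`, `a` (labels) and `max_variant`.
#' @examples
#' classify_equilibrium(allele_freqs(0.999, 0.0008, 0.0002))
#' @export
classify_equilibrium <- function(eq) {
  p <- if (inherits(eq, "equilibrium_result")) eq$p else eq
  validate_freqs(p, "allele")
  labs <- vapply(c(p[["A"]], p[["B"]], p[["a"]]), freq_label, character(1))
  mx <- c("A", "B", "a")[which.max(c(p[["A"]], p[["B"]], p[["a"]]))]
  structure(list(A = labs[1], B = labs[2], a = labs[3], max_variant = mx),
            class = "equilibrium_class")
}

#' @export
format.equilibrium_class <- function(x, ...) {
  paste0("A=", x$A, " B=", x$B, " a=", x$a, " (max ", x$max_variant, ")")
}

#' @export
print.equilibrium_class <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

class_key <- function(cls, stable) {
  paste0(cls$A, "|", cls$B, "|", cls$a, "|", cls$max_variant, "|",
         if (isTRUE(stable)) "stable" else if (is.na(stable)) "neutral"
         else "unstable")
}

#' Census of distinct equilibrium classes over parameter sets
#'
#' For each parameter set, runs [find_equilibrium()] from every starting
#' point in `settings$init_grid` and collects the distinct qualitative
#' equilibrium classes (per-variant labels plus maximal variant) together
#' with their stability flag.
#'
#' @param param_sets a list of [model_params()] objects.
#' @param settings a [convergence_settings()] object.
#' @return A list with elements `classes` (data frame of distinct
#'   (class, stable) outcomes with a representative parameter-set index)
#'   and `runs` (data frame of every individual run).
#' @export
enumerate_equilibria <- function(param_sets,
                                 settings = convergence_settings()) {
  stopifnot(is.list(param_sets), length(param_sets) >= 1L)
  runs <- list()
  k <- 0L
  for (i in seq_along(param_sets)) {
    for (j in seq_along(settings$init_grid)) {
      eq <- find_equilibrium(param_sets[[i]], settings$init_grid[[j]],
                             settings)
      cls <- classify_equilibrium(eq)
      stable <- if (is.null(eq$stability)) NA else eq$stability$stable
      k <- k + 1L
      runs[[k]] <- data.frame(
        param_set = i, init = j,
        p_A = eq$p[["A"]], p_B = eq$p[["B"]], p_a = eq$p[["a"]],
        converged = eq$converged, generations = eq$generations,
        label_A = cls$A, label_B = cls$B, label_a = cls$a,
        max_variant = cls$max_variant, stable = stable,
        key = class_key(cls, stable),
        stringsAsFactors = FALSE)
    }
  }
  runs <- do.call(rbind, runs)
  first <- !duplicated(runs$key)
  classes <- runs[first, c("key", "label_A", "label_B", "label_a",
                           "max_variant", "stable", "param_set")]
  classes$n_runs <- as.integer(table(runs$key)[classes$key])
  rownames(classes) <- NULL
  list(classes = classes, runs = runs)
}

grid_equilibria <- function(params, settings) {
  lapply(settings$init_grid, function(init)
    find_equilibrium(params, init, settings, stability = FALSE))
}

#' Bisection for the critical paramutation rate
#'
#' Locates the paramutation rate `m1` at which the equilibrium switches
#' branch, detected as a jump of more than `jump` in a branch statistic
#' (by default the largest equilibrium epiallele frequency reached from
#' the starting grid).  The statistic must differ by more than `jump`
#' between `m_lo` and `m_hi`; bisection then narrows the bracket to width
#' `tol_m` and returns its midpoint.
#'
#' @param params a [model_params()] object (its `m1` entry is overridden).
#' @param m_lo,m_hi bracket for the paramutation rate.
#' @param tol_m bracket width at which bisection stops.
#' @param settings a [convergence_settings()] object.
#' @param branch_statistic function mapping a list of `equilibrium_result`
#'   objects (one per grid start) to a single number.
#' @param jump minimum change in the statistic that counts as a branch
#'   switch.
#' @return A list with elements `m_critical`, `stat_lo`, `stat_hi` (the
#'   branch statistic just below and above the bracket), and `evaluations`.
#' @export
find_critical_m <- function(params, m_lo, m_hi, tol_m = 0.005,
                            settings = convergence_settings(),
                            branch_statistic = NULL, jump = 0.1) {
  stopifnot(inherits(params, "model_params"), m_lo < m_hi)
  if (is.null(branch_statistic))
    branch_statistic <- function(eqs)
      max(vapply(eqs, function(e) e$p[["B"]], numeric(1)))
  stat_at <- function(m)
    branch_statistic(grid_equilibria(set_param(params, "m1", m), settings))
  s_lo <- stat_at(m_lo)
  s_hi <- stat_at(m_hi)
  n_eval <- 2L
  if (abs(s_hi - s_lo) <= jump)
    stop("no branch change detected in [m_lo, m_hi]: statistic moves by ",
         format(abs(s_hi - s_lo), digits = 4), " (needs > ", jump, ")",
         call. = FALSE)
  # Branch membership is judged on the log scale when the statistic is
  # positive: the two branches of a frequency statistic typically live on
  # different orders of magnitude (e.g. epimutation-scale vs order one),
  # and log closeness makes the bisection home in on the knee where the
  # low branch terminates rather than on an arbitrary mid-crossing.
  dist <- function(a, b) {
    if (a > 0 && b > 0) abs(log(a) - log(b)) else abs(a - b)
  }
  lo <- m_lo; hi <- m_hi
  while (hi - lo > tol_m) {
    mid <- (lo + hi) / 2
    s_mid <- stat_at(mid)
    n_eval <- n_eval + 1L
    if (dist(s_mid, s_lo) <= dist(s_mid, s_hi)) {
      lo <- mid; s_lo <- s_mid
    } else {
      hi <- mid; s_hi <- s_mid
    }
  }
  list(m_critical = (lo + hi) / 2, stat_lo = s_lo, stat_hi = s_hi,
       evaluations = n_eval)
}

#' Sweep one parameter and record the equilibrium at each value
#'
#' @param params a [model_params()] object.
#' @param name name of a rate parameter (`u`, `z`, `u_prime`, `t1`, `t2`,
#'   `m1`, `m2`, `f`) or selection parameter (`s`, `s2`, `s3`, `h`, `h2`).
#' @param values numeric vector of values to sweep.
#' @param init an [allele_freqs()] starting state used for every value.
#' @param settings a [convergence_settings()] object.
#' @return A data frame with the swept parameter in the first column
#'   (named after it) and columns `p_A`, `p_B`, `p_a`, `converged`,
#'   `generations`, `stable`.
#' @export
sweep_parameter <- function(params, name, values,
                            init = allele_freqs(0.98, 0.01, 0.01),
                            settings = convergence_settings()) {
  stopifnot(length(values) >= 1L)
  rows <- lapply(values, function(v) {
    eq <- find_equilibrium(set_param(params, name, v), init, settings)
    data.frame(value = v,
               p_A = eq$p[["A"]], p_B = eq$p[["B"]], p_a = eq$p[["a"]],
               converged = eq$converged, generations = eq$generations,
               stable = if (is.null(eq$stability)) NA
                        else eq$stability$stable)
  })
  out <- do.call(rbind, rows)
  names(out)[1] <- name
  out
}
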