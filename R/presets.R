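#' Preset registry of published parameter sets
#'
#' Named parameter sets encoding the numerical experiments of the model's
#' reference figures: paramutation stronger than selection with a
#' compensatory B/a fitness (fig2a/b/c, differing in the order of `w_aa`
#' and `w_BB`), the reverse-epimutation grid under cycling (fig3-*),
#' paramutation-rate bifurcation scans with an unstable epiallele
#' (fig4-*/fig7-*, gray = `w_aa > w_BB`, black = `w_BB > w_aa`), the
#' inbreeding grid under compensatory fitness (fig5-*), the inbreeding
#' grid under cycling (fig6-*), and a baseline without paramutation
#' (caseA-baseline).
#'
#' @param name preset name; see [preset_names()].
#' @return For `preset()`, a [model_params()] object with attributes
#'   `preset` (the name) and `note` (provenance of the encoded values);
#'   for `preset_names()`, a character vector.
#' @examples
#' preset("fig2a")
#' preset_names()
#' @export
preset <- function(name) {
  reg <- preset_registry()
  if (!name %in% names(reg))
    stop("unknown preset '", name, "'; available: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  entry <- reg[[name]]
  params <- entry$params
  attr(params, "preset") <- name
  attr(params, "note") <- entry$note
  params
}

#' @rdname preset
#' @export
preset_names <- function() names(preset_registry())

std_rates <- function(t1 = 1e-5, t2 = 1e-4, m1 = 0.05, m2 = 0, f = 0)
  rate_params(u = 1e-9, z = 1e-9, u_prime = 1e-9, t1 = t1, t2 = t2,
              m1 = m1, m2 = m2, f = f)

# bifurcation-scan fitness tables: w_AA = 1, w_Ba = 0.985 and the
# remaining entries from the incomplete-dominance pairing with h = 0.5
fig4_fitness <- function(line = c("gray", "black")) {
  line <- match.arg(line)
  if (line == "gray")
    fitness_matrix(w_Aa = 0.995, w_AB = 0.99, w_Ba = 0.985,
                   w_aa = 0.99, w_BB = 0.98)
  else
    fitness_matrix(w_Aa = 0.99, w_AB = 0.995, w_Ba = 0.985,
                   w_aa = 0.98, w_BB = 0.99)
}

preset_registry <- function() {
  p <- function(params, note) list(params = params, note = note)
  incdom <- function(s, s2, s3, rates)
    model_params(rates, selection = selection_params(s = s, s2 = s2,
                                                     s3 = s3))
  scan <- function(line, f)
    model_params(std_rates(t2 = 0.2, m1 = 0.05, f = f),
                 fitness = fig4_fitness(line))
  list(
    "caseA-baseline" = p(
      incdom(0.01, 0.02, 0, std_rates(t2 = 0, m1 = 0)),
      "baseline without paramutation: s=0.01, s2=0.02, t1=1e-5, t2=0"),
    "fig2a" = p(incdom(0.02, 0.01, 0.012, std_rates()),
                "compensatory B/a, w_BB > w_aa (s=0.02, s2=0.01, s3=0.012)"),
    "fig2b" = p(incdom(0.02, 0.02, 0.012, std_rates()),
                "compensatory B/a, w_BB = w_aa (s=s2=0.02, s3=0.012)"),
    "fig2c" = p(incdom(0.01, 0.02, 0.012, std_rates()),
                "compensatory B/a, w_BB < w_aa (s=0.01, s2=0.02, s3=0.012)"),
    "fig3-t2-1e-3" = p(incdom(0.01, 0.02, 0.001, std_rates(t2 = 1e-3)),
                       "cycling regime, reverse epimutation 1e-3"),
    "fig3-t2-1e-2.7" = p(incdom(0.01, 0.02, 0.001, std_rates(t2 = 10^-2.7)),
                         "cycling regime, reverse epimutation 10^-2.7"),
    "fig3-t2-1e-2.4" = p(incdom(0.01, 0.02, 0.001, std_rates(t2 = 10^-2.4)),
                         "cycling regime, reverse epimutation 10^-2.4"),
    "fig4-gray" = p(scan("gray", 0),
                    "bifurcation scan, w_aa > w_BB, t2=0.2, f=0"),
    "fig4-black" = p(scan("black", 0),
                     "bifurcation scan, w_BB > w_aa, t2=0.2, f=0"),
    "fig5-f0" = p(incdom(0.01, 0.02, 0.012, std_rates()),
                  "compensatory B/a with inbreeding grid, f=0"),
    "fig5-f0.1" = p(incdom(0.01, 0.02, 0.012, std_rates(f = 0.1)),
                    "compensatory B/a with inbreeding grid, f=0.1"),
    "fig5-f0.2" = p(incdom(0.01, 0.02, 0.012, std_rates(f = 0.2)),
                    "compensatory B/a with inbreeding grid, f=0.2"),
    "fig6-f0" = p(incdom(0.01, 0.02, 0.001, std_rates(t2 = 1e-3)),
                  "cycling with inbreeding grid, f=0"),
    "fig6-f0.25" = p(incdom(0.01, 0.02, 0.001,
                            std_rates(t2 = 1e-3, f = 0.25)),
                     "cycling with inbreeding grid, f=0.25"),
    "fig6-f0.5" = p(incdom(0.01, 0.02, 0.001,
                           std_rates(t2 = 1e-3, f = 0.5)),
                    "cycling with inbreeding grid, f=0.5"),
    "fig7-gray-f0" = p(scan("gray", 0),
                       "bifurcation scan with inbreeding, w_aa > w_BB, f=0"),
    "fig7-gray-f0.25" = p(scan("gray", 0.25),
                          "bifurcation scan with inbreeding, w_aa > w_BB, f=0.25"),
    "fig7-black-f0" = p(scan("black", 0),
                        "bifurcation scan with inbreeding, w_BB > w_aa, f=0"),
    "fig7-black-f0.25" = p(scan("black", 0.25),
                           "bifurcation scan with inbreeding, w_BB > w_aa, f=0.25")
  )
}

#' Parameter sets realizing the strict orderings of the deleterious
#' (epi)genotype fitnesses
#'
#' Builds one parameter set per strict ordering of
#' `(w_aa, w_Ba, w_BB)` over the value triple `values`, crossed with the
#' given paramutation rates, holding `w_AA = 1` and
#' `w_Aa = w_AB = het_fitness`.  Used for equilibrium censuses over the
#' fitness-ordering regimes.  With `dominance = "complete"` the builder
#' instead derives the table from `s = 1 - w_aa`, `s2 = 1 - w_BB`
#' (forcing `w_Ba = w_BB`).
#'
#' @param m_values paramutation rates (`m1`) to cross with the orderings.
#' @param f inbreeding coefficient(s) to cross in.
#' @param values the three fitness values assigned, in each permutation,
#'   to `(w_aa, w_Ba, w_BB)`.
#' @param het_fitness fitness of both A-carrying heterozygotes.
#' @param rates base rates (`m1` and `f` entries are overridden).
#' @param dominance `"raw"` (direct table) or `"complete"`.
#' @return A list of [model_params()] objects, with attributes recording
#'   the ordering and rates of each entry.
#' @export
ordering_param_sets <- function(m_values, f = 0,
                                values = c(0.99, 0.985, 0.98),
                                het_fitness = 0.995,
                                rates = std_rates(),
                                dominance = c("raw", "complete")) {
  dominance <- match.arg(dominance)
  stopifnot(length(values) == 3L)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  out <- list()
  for (f_i in f) for (m_i in m_values) for (pm in perms) {
    v <- values[pm]   # (w_aa, w_Ba, w_BB)
    fit <- if (dominance == "raw")
      fitness_matrix(w_Aa = het_fitness, w_AB = het_fitness,
                     w_aa = v[1], w_Ba = v[2], w_BB = v[3])
    else
      fitness_complete_dominance(selection_params(s = 1 - v[1],
                                                  s2 = 1 - v[3]))
    rr <- unclass(rates)
    rr$m1 <- m_i
    rr$f <- f_i
    mp <- model_params(do.call(rate_params, rr), fitness = fit)
    attr(mp, "ordering") <- paste0("w_aa=", v[1], ",w_Ba=", v[2],
                                   ",w_BB=", v[3])
    attr(mp, "m1") <- m_i
    attr(mp, "f") <- f_i
    out[[length(out) + 1L]] <- mp
  }
  out
}
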