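#' (Epi)allele frequency vector
#'
#' The state of the model: frequencies of the wild-type allele A, the
#' epiallele B, and the deleterious allele a.  Frequencies must be
#' non-negative and sum to 1 (absolute tolerance 1e-12).
#'
#' @param p_A,p_B,p_a frequencies.
#' @return An object of class `"allele_freqs"`: a named numeric vector
#'   `c(A = p_A, B = p_B, a = p_a)`.
#' @examples
#' allele_freqs(0.98, 0.01, 0.01)
#' @export
allele_freqs <- function(p_A, p_B, p_a) {
  p <- c(A = p_A, B = p_B, a = p_a)
  validate_freqs(p, "allele")
  structure(p, class = "allele_freqs")
}

#' (Epi)genotype frequency vector
#'
#' Frequencies of the six unordered (epi)genotypes at the zygote stage.
#' Heterozygote entries are totals over both parental orderings.
#'
#' @param g_AA,g_AB,g_Aa,g_BB,g_Ba,g_aa frequencies.
#' @return An object of class `"genotype_freqs"`: a named numeric vector
#'   in the order `AA, AB, Aa, BB, Ba, aa`.
#' @export
genotype_freqs <- function(g_AA = 0, g_AB = 0, g_Aa = 0,
                           g_BB = 0, g_Ba = 0, g_aa = 0) {
  g <- c(AA = g_AA, AB = g_AB, Aa = g_Aa, BB = g_BB, Ba = g_Ba, aa = g_aa)
  validate_freqs(g, "genotype")
  structure(g, class = "genotype_freqs")
}

validate_freqs <- function(x, what) {
  if (any(!is.finite(x)) || any(x < -.freq_tol) || any(x > 1 + .freq_tol))
    stop("invalid ", what, " frequencies: entries must lie in [0, 1]",
         call. = FALSE)
  if (abs(sum(x) - 1) > .freq_tol)
    stop("invalid ", what, " frequencies: entries must sum to 1 ",
         "(got ", format(sum(x), digits = 17), ")", call. = FALSE)
  invisible(x)
}

as_allele_freqs <- function(p) {
  structure(c(A = unname(p[1]), B = unname(p[2]), a = unname(p[3])),
            class = "allele_freqs")
}

#' Zygote (epi)genotype frequencies after mating with inbreeding
#'
#' Forms zygotes from the current (epi)allele pool with inbreeding
#' coefficient `f`: each homozygote X/X receives `p_X^2 (1 - f) + p_X f`
#' and each unordered heterozygote X/Y receives `2 p_X p_Y (1 - f)`.
#' Mating does not change allele frequencies.
#'
#' @param p an [allele_freqs()] state.
#' @param f inbreeding coefficient in \[0, 1\].
#' @return A [genotype_freqs()] vector.
#' @examples
#' zygote_frequencies(allele_freqs(0.6, 0.4, 0), f = 0.5)
#' @export
zygote_frequencies <- function(p, f) {
  validate_freqs(p, "allele")
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f) || f < 0 || f > 1)
    stop("inbreeding coefficient f must lie in [0, 1]", call. = FALSE)
  pA <- p[["A"]]; pB <- p[["B"]]; pa <- p[["a"]]
  genotype_freqs(
    g_AA = pA^2 * (1 - f) + pA * f,
    g_AB = 2 * pA * pB * (1 - f),
    g_Aa = 2 * pA * pa * (1 - f),
    g_BB = pB^2 * (1 - f) + pB * f,
    g_Ba = 2 * pB * pa * (1 - f),
    g_aa = pa^2 * (1 - f) + pa * f
  )
}

#' Paramutation acting on zygote (epi)genotypes
#'
#' A/B zygotes are converted to B/B at rate `m1`; A/a zygotes are
#' converted to B/a at rate `m2` (relevant only when the deleterious
#' allele is paramutagenic).  Both conversions act simultaneously on the
#' post-mating zygote pool; total frequency is preserved.
#'
#' @param g a [genotype_freqs()] vector.
#' @param m1 paramutation rate A/B -> B/B.
#' @param m2 paramutation rate A/a -> B/a.
#' @return A [genotype_freqs()] vector.
#' @export
paramutation_step <- function(g, m1, m2 = 0) {
  validate_freqs(g, "genotype")
  for (m in c(m1, m2))
    if (!is.numeric(m) || length(m) != 1L || !is.finite(m) || m < 0 || m > 1)
      stop("paramutation rates must lie in [0, 1]", call. = FALSE)
  out <- unclass(g)
  out[["BB"]] <- out[["BB"]] + m1 * out[["AB"]]
  out[["AB"]] <- (1 - m1) * out[["AB"]]
  out[["Ba"]] <- out[["Ba"]] + m2 * out[["Aa"]]
  out[["Aa"]] <- (1 - m2) * out[["Aa"]]
  structure(out, class = "genotype_freqs")
}

#' Viability selection on (epi)genotypes
#'
#' Weights every (epi)genotype frequency by its relative fitness and
#' renormalizes by the mean fitness `wbar = sum(w * g)`.
#'
#' @param g a [genotype_freqs()] vector.
#' @param W a [fitness_matrix()].
#' @return A list with elements `g` (post-selection [genotype_freqs()])
#'   and `mean_fitness` (`wbar`).
#' @export
selection_step <- function(g, W) {
  validate_freqs(g, "genotype")
  stopifnot(inherits(W, "fitness_matrix"))
  w <- as.numeric(W)[match(names(g), names(W))]
  wbar <- sum(w * as.numeric(g))
  if (wbar <= 0)
    stop("degenerate population: mean fitness is zero", call. = FALSE)
  out <- structure(as.numeric(g) * w / wbar, names = names(g),
                   class = "genotype_freqs")
  list(g = out, mean_fitness = wbar)
}

#' (Epi)allele frequencies from (epi)genotype frequencies
#'
#' Each variant's frequency is its homozygote frequency plus half of each
#' heterozygote that carries it.
#'
#' @param g a [genotype_freqs()] vector.
#' @return An [allele_freqs()] state.
#' @export
allele_frequencies <- function(g) {
  validate_freqs(g, "genotype")
  as_allele_freqs(c(
    g[["AA"]] + 0.5 * (g[["AB"]] + g[["Aa"]]),
    g[["BB"]] + 0.5 * (g[["AB"]] + g[["Ba"]]),
    g[["aa"]] + 0.5 * (g[["Aa"]] + g[["Ba"]])
  ))
}

#' Spontaneous epimutation on the post-selection gamete pool
#'
#' Wild-type alleles epimutate to the epiallele at rate `t1`; epialleles
#' revert at rate `t2`.  The deleterious allele is unaffected.
#'
#' @param p an [allele_freqs()] state.
#' @param t1 forward epimutation rate A -> B.
#' @param t2 reverse epimutation rate B -> A.
#' @return An [allele_freqs()] state.
#' @export
epimutation_step <- function(p, t1, t2) {
  validate_freqs(p, "allele")
  pA <- p[["A"]]; pB <- p[["B"]]
  as_allele_freqs(c((1 - t1) * pA + t2 * pB,
                    (1 - t2) * pB + t1 * pA,
                    p[["a"]]))
}

#' Mutation as the final event of the life cycle
#'
#' The wild-type allele mutates to the deleterious allele at rate `u`, the
#' deleterious allele back-mutates at rate `z`, and the epiallele mutates
#' to the deleterious allele state at rate `u_prime`.
#'
#' @param p an [allele_freqs()] state.
#' @param u mutation rate A -> a.
#' @param z mutation rate a -> A.
#' @param u_prime mutation rate B -> a.
#' @return An [allele_freqs()] state.
#' @export
mutation_step <- function(p, u, z, u_prime) {
  validate_freqs(p, "allele")
  pA <- p[["A"]]; pB <- p[["B"]]; pa <- p[["a"]]
  as_allele_freqs(c(
    pA * (1 - u) + z * pa,
    pB * (1 - u_prime),
    pa * (1 - z) + u * pA + u_prime * pB
  ))
}

#' One full generation of the recursion
#'
#' Applies the life-cycle stages in order: mating (zygote formation with
#' inbreeding), paramutation, selection, gamete (allele) frequency
#' extraction, spontaneous epimutation, and mutation.  The map is exact
#' and deterministic; stages other than selection conserve total
#' frequency by construction, and a defensive renormalization is applied
#' only if accumulated floating-point drift exceeds 1e-12.
#'
#' @param p an [allele_freqs()] state.
#' @param params a [model_params()] object.
#' @param mean_fitness if `TRUE`, attach the zygote-pool mean fitness of
#'   this generation as attribute `"mean_fitness"`.
#' @return The next-generation [allele_freqs()] state.
#' @examples
#' pars <- model_params(rate_params(u = 1e-9, t1 = 1e-5, m1 = 0.05),
#'                      selection = selection_params(s = 0.02, s2 = 0.01,
#'                                                   s3 = 0.012))
#' generation_step(allele_freqs(0.98, 0.01, 0.01), pars)
#' @export
generation_step <- function(p, params, mean_fitness = FALSE) {
  stopifnot(inherits(params, "model_params"))
  r <- params$rates
  g <- zygote_frequencies(p, r$f)
  g <- paramutation_step(g, r$m1, r$m2)
  sel <- selection_step(g, params$fitness)
  q <- allele_frequencies(sel$g)
  q <- epimutation_step(q, r$t1, r$t2)
  q <- mutation_step(q, r$u, r$z, r$u_prime)
  drift <- sum(q) - 1
  if (abs(drift) > .freq_tol) q <- as_allele_freqs(q / sum(q))
  if (mean_fitness) attr(q, "mean_fitness") <- sel$mean_fitness
  q
}
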