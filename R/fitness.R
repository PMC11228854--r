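#' Selection and dominance parameters
#'
#' Bundles the selection coefficients and dominance coefficients that
#' parameterize the relative fitnesses of the six (epi)genotypes formed by
#' the wild-type allele A, the deleterious allele a, and the deleterious
#' epiallele B.
#'
#' @param s selection coefficient against the deleterious allele a.
#' @param s2 selection coefficient against the epiallele B.
#' @param s3 compensatory fitness term for the B/a (epi)genotype, capturing
#'   a partial recovery of fitness when the deleterious allele and the
#'   epiallele are paired in one genotype.
#' @param h dominance coefficient of a over A.
#' @param h2 dominance coefficient of B over A.
#'
#' @return An object of class `"selection_params"`: a named list with
#'   elements `s`, `s2`, `s3`, `h`, `h2`.
#' @examples
#' selection_params(s = 0.02, s2 = 0.01, s3 = 0.012)
#' @export
selection_params <- function(s = 0, s2 = 0, s3 = 0, h = 0.5, h2 = 0.5) {
  x <- list(s = s, s2 = s2, s3 = s3, h = h, h2 = h2)
  for (nm in names(x)) {
    v <- x[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v > 1)
      stop("selection parameter '", nm, "' must be a single value in [0, 1]",
           call. = FALSE)
  }
  structure(x, class = "selection_params")
}

genotype_names <- c("AA", "AB", "Aa", "BB", "Ba", "aa")

#' Relative fitness table for the six (epi)genotypes
#'
#' Constructs the table of relative fitnesses, one per unordered
#' (epi)genotype.  The wild-type homozygote A/A is assumed to be the most
#' fit genotype and all entries must lie in \[0, 1\].
#'
#' @param w_AA,w_AB,w_Aa,w_BB,w_Ba,w_aa relative fitnesses (dimensionless,
#'   each in \[0, 1\]).
#' @return An object of class `"fitness_matrix"`: a named numeric vector
#'   with elements `AA`, `AB`, `Aa`, `BB`, `Ba`, `aa`.
#' @seealso [fitness_incomplete_dominance()], [fitness_complete_dominance()]
#' @examples
#' fitness_matrix(w_Aa = 0.99, w_aa = 0.98, w_AB = 0.995, w_BB = 0.99,
#'                w_Ba = 0.997)
#' @export
fitness_matrix <- function(w_AA = 1, w_AB = 1, w_Aa = 1,
                           w_BB = 1, w_Ba = 1, w_aa = 1) {
  w <- c(AA = w_AA, AB = w_AB, Aa = w_Aa, BB = w_BB, Ba = w_Ba, aa = w_aa)
  bad <- !is.finite(w) | w < 0 | w > 1
  if (any(bad))
    stop("fitness entries outside [0, 1]: ",
         paste0("w_", genotype_names[bad], " = ",
                signif(w[bad], 6), collapse = ", "),
         call. = FALSE)
  if (any(w > w[["AA"]]))
    stop("w_AA must be the maximum fitness (wild-type homozygote is the ",
         "most fit genotype)", call. = FALSE)
  structure(w, class = "fitness_matrix")
}

#' @export
print.fitness_matrix <- function(x, ...) {
  cat("Relative fitnesses of (epi)genotypes:\n")
  print(setNames(as.numeric(x), paste0("w_", genotype_names)))
  invisible(x)
}

#' Fitness table under incomplete dominance
#'
#' Builds the six (epi)genotype fitnesses from selection and dominance
#' coefficients under incomplete dominance:
#' `w_AA = 1`, `w_Aa = 1 - h*s`, `w_aa = 1 - s`, `w_AB = 1 - h2*s2`,
#' `w_BB = 1 - s2`, and `w_Ba = 1 - h2*s2 - h*s + s3`, where `s3` is a
#' compensatory interaction term that can lift the fitness of the
#' epiallele/deleterious-allele pairing above that of either deleterious
#' homozygote.
#'
#' @param sel a [selection_params()] object.
#' @return A [fitness_matrix()].
#' @examples
#' fitness_incomplete_dominance(selection_params(s = 0.02, s2 = 0.01,
#'                                               s3 = 0.012))
#' @export
fitness_incomplete_dominance <- function(sel) {
  stopifnot(inherits(sel, "selection_params"))
  fitness_matrix(
    w_AA = 1,
    w_Aa = 1 - sel$h * sel$s,
    w_aa = 1 - sel$s,
    w_AB = 1 - sel$h2 * sel$s2,
    w_BB = 1 - sel$s2,
    w_Ba = 1 - sel$h2 * sel$s2 - sel$h * sel$s + sel$s3
  )
}

#' Fitness table under complete dominance
#'
#' Builds the six (epi)genotype fitnesses under the complete-dominance
#' scenario: the wild-type allele is fully dominant in any genotype that
#' carries it, and the epiallele is fully dominant when paired with the
#' deleterious allele.  Hence `w_AA = w_Aa = w_AB = 1`,
#' `w_BB = w_Ba = 1 - s2`, and `w_aa = 1 - s`.  Note `w_Ba = w_BB` always
#' holds under this scheme, so regimes requiring `w_Ba > w_BB` are
#' unreachable.
#'
#' @inheritParams fitness_incomplete_dominance
#' @return A [fitness_matrix()].
#' @export
fitness_complete_dominance <- function(sel) {
  stopifnot(inherits(sel, "selection_params"))
  fitness_matrix(
    w_AA = 1, w_Aa = 1, w_AB = 1,
    w_BB = 1 - sel$s2,
    w_Ba = 1 - sel$s2,
    w_aa = 1 - sel$s
  )
}
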