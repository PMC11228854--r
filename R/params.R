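#' Per-generation rates of mutation, epimutation and paramutation
#'
#' All rates are probabilities per generation and must lie in \[0, 1\].
#'
#' @param u mutation rate A -> a.
#' @param z mutation rate a -> A (back mutation).
#' @param u_prime mutation rate B -> a (the epiallele mutates to the
#'   deleterious allele state).
#' @param t1 forward spontaneous epimutation rate A -> B.
#' @param t2 reverse spontaneous epimutation rate B -> A (epiallele
#'   reversion/resetting).
#' @param m1 paramutation rate converting (epi)genotype A/B to B/B.
#' @param m2 paramutation rate converting genotype A/a to B/a (zero in most
#'   scenarios; nonzero when the deleterious allele is itself
#'   paramutagenic).
#' @param f inbreeding coefficient: the probability that the two
#'   (epi)alleles of a zygote are identical by descent; scales excess
#'   homozygosity at mating.
#' @return An object of class `"rate_params"`.
#' @examples
#' rate_params(u = 1e-9, z = 1e-9, u_prime = 1e-9, t1 = 1e-5, t2 = 1e-4,
#'             m1 = 0.05)
#' @export
rate_params <- function(u = 0, z = 0, u_prime = 0, t1 = 0, t2 = 0,
                        m1 = 0, m2 = 0, f = 0) {
  x <- list(u = u, z = z, u_prime = u_prime, t1 = t1, t2 = t2,
            m1 = m1, m2 = m2, f = f)
  for (nm in names(x)) {
    v <- x[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v > 1)
      stop("rate parameter '", nm, "' must be a single value in [0, 1]",
           call. = FALSE)
  }
  structure(x, class = "rate_params")
}

#' Full parameter set of the model
#'
#' Couples the per-generation rates with the (epi)genotype fitness table.
#' The fitness table may be given directly as a [fitness_matrix()], or as a
#' [selection_params()] object together with a `dominance` scheme, in which
#' case the corresponding builder is applied (and sweeps over selection
#' coefficients remain possible).
#'
#' @param rates a [rate_params()] object.
#' @param fitness a [fitness_matrix()], or `NULL` if `selection` is given.
#' @param selection a [selection_params()] object, or `NULL` if `fitness`
#'   is given directly.
#' @param dominance `"incomplete"` or `"complete"`; used only when
#'   `selection` is given.
#' @return An object of class `"model_params"` with elements `rates`,
#'   `fitness`, and (if supplied) `selection` and `dominance`.
#' @examples
#' model_params(rate_params(u = 1e-9, t1 = 1e-5),
#'              selection = selection_params(s = 0.01, s2 = 0.02))
#' @export
model_params <- function(rates = rate_params(), fitness = NULL,
                         selection = NULL,
                         dominance = c("incomplete", "complete")) {
  stopifnot(inherits(rates, "rate_params"))
  dominance <- match.arg(dominance)
  if (!is.null(fitness) && !is.null(selection))
    stop("supply either 'fitness' or 'selection', not both", call. = FALSE)
  if (is.null(fitness)) {
    if (is.null(selection)) selection <- selection_params()
    fitness <- switch(dominance,
                      incomplete = fitness_incomplete_dominance(selection),
                      complete = fitness_complete_dominance(selection))
  } else {
    stopifnot(inherits(fitness, "fitness_matrix"))
    selection <- NULL
  }
  structure(list(rates = rates, fitness = fitness, selection = selection,
                 dominance = if (!is.null(selection)) dominance),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  r <- unlist(x$rates)
  cat("Model parameters\n  rates: ",
      paste0(names(r), " = ", signif(r, 6), collapse = ", "), "\n", sep = "")
  if (!is.null(x$selection)) {
    s <- unlist(x$selection)
    cat("  selection (", x$dominance, " dominance): ",
        paste0(names(s), " = ", signif(s, 6), collapse = ", "), "\n",
        sep = "")
  }
  cat("  fitness: ",
      paste0("w_", genotype_names, " = ",
             signif(as.numeric(x$fitness)[match(genotype_names,
                                                names(x$fitness))], 6),
             collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Modify a parameter of a model parameter set
#'
#' Returns a copy of `params` with one named parameter replaced.  Rate
#' parameters (`u`, `z`, `u_prime`, `t1`, `t2`, `m1`, `m2`, `f`) are set
#' directly; selection parameters (`s`, `s2`, `s3`, `h`, `h2`) require the
#' parameter set to carry a selection specification, and the fitness table
#' is rebuilt with the stored dominance scheme.
#'
#' @param params a [model_params()] object.
#' @param name parameter name.
#' @param value new value.
#' @return A [model_params()] object.
#' @export
set_param <- function(params, name, value) {
  stopifnot(inherits(params, "model_params"))
  if (name %in% names(params$rates)) {
    r <- unclass(params$rates)
    r[[name]] <- value
    rates <- do.call(rate_params, r)
    return(model_params(rates,
                        fitness = if (is.null(params$selection)) params$fitness,
                        selection = params$selection,
                        dominance = params$dominance %||% "incomplete"))
  }
  if (name %in% c("s", "s2", "s3", "h", "h2")) {
    if (is.null(params$selection))
      stop("cannot set '", name, "': this parameter set was built from a ",
           "raw fitness table, not selection coefficients", call. = FALSE)
    s <- unclass(params$selection)
    s[[name]] <- value
    return(model_params(params$rates,
                        selection = do.call(selection_params, s),
                        dominance = params$dominance))
  }
  stop("unknown parameter name '", name, "'", call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
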