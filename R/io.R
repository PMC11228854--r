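#' Write a trajectory or sweep table as tab-separated text
#'
#' Tables are written with a single header line and numbers serialized
#' with 17 significant digits, so re-reading reproduces the doubles
#' bit-exactly.
#'
#' @param x a data frame (e.g. from [iterate()] or [sweep_parameter()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv17 <- function(x, path) {
  stopifnot(is.data.frame(x))
  fmt <- vapply(x, function(col) {
    if (is.numeric(col)) sprintf("%.17g", col) else as.character(col)
  }, FUN.VALUE = character(nrow(x)))
  fmt <- matrix(fmt, nrow = nrow(x))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(x), collapse = "\t"), con)
  writeLines(apply(fmt, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

config_keys <- c("u", "z", "u_prime", "t1", "t2", "m1", "m2", "f",
                 "s", "s2", "s3", "h", "h2",
                 "w_AA", "w_AB", "w_Aa", "w_BB", "w_Ba", "w_aa",
                 "dominance")

#' Read a model configuration file
#'
#' Configurations are flat YAML key-value files whose keys are the model's
#' parameter symbols: rates `u`, `z`, `u_prime`, `t1`, `t2`, `m1`, `m2`,
#' `f`; either selection coefficients `s`, `s2`, `s3`, `h`, `h2` (with
#' optional `dominance: incomplete|complete`) or a raw fitness table
#' `w_AA`, `w_AB`, `w_Aa`, `w_BB`, `w_Ba`, `w_aa`.  Unknown keys are
#' rejected; unspecified rates default to 0 and dominance coefficients to
#' 0.5.  Supplying both selection coefficients and raw fitness entries is
#' an error.
#'
#' @param path path to a YAML file.
#' @param overrides named list of `key = value` overrides applied after
#'   reading (e.g. from command-line `--set` flags).
#' @return A [model_params()] object.
#' @export
read_config <- function(path, overrides = list()) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping", call. = FALSE)
  cfg <- modifyList(cfg, as.list(overrides))
  config_to_params(cfg)
}

config_to_params <- function(cfg) {
  unknown <- setdiff(names(cfg), config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  rate_names <- c("u", "z", "u_prime", "t1", "t2", "m1", "m2", "f")
  sel_names <- c("s", "s2", "s3", "h", "h2")
  w_names <- c("w_AA", "w_AB", "w_Aa", "w_BB", "w_Ba", "w_aa")
  has_sel <- any(sel_names %in% names(cfg))
  has_w <- any(w_names %in% names(cfg))
  if (has_sel && has_w)
    stop("conflicting fitness specification: supply selection ",
         "coefficients (s, s2, s3, h, h2) or a raw fitness table ",
         "(w_*), not both", call. = FALSE)
  rates <- do.call(rate_params, cfg[intersect(rate_names, names(cfg))])
  if (has_w) {
    model_params(rates, fitness = do.call(fitness_matrix,
                                          cfg[intersect(w_names,
                                                        names(cfg))]))
  } else {
    model_params(rates,
                 selection = do.call(selection_params,
                                     cfg[intersect(sel_names, names(cfg))]),
                 dominance = cfg$dominance %||% "incomplete")
  }
}

#' Write a model configuration file
#'
#' Inverse of [read_config()]: serializes a [model_params()] object as a
#' flat YAML mapping (selection coefficients when available, otherwise
#' the raw fitness table), so that a written configuration re-loads to an
#' equal parameter set.
#'
#' @param params a [model_params()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path) {
  stopifnot(inherits(params, "model_params"))
  cfg <- unclass(params$rates)
  if (!is.null(params$selection)) {
    cfg <- c(cfg, unclass(params$selection),
             list(dominance = params$dominance))
  } else {
    w <- params$fitness
    cfg <- c(cfg, as.list(setNames(as.numeric(w),
                                   paste0("w_", names(w)))))
  }
  yaml::write_yaml(cfg, path, precision = 17)
  invisible(path)
}

#' Serialize an equilibrium or analytic record as structured text
#'
#' One `key<TAB>value` line per field, numbers at 17 significant digits;
#' used by the command-line interface for its equilibrium, stability and
#' analytic outputs.
#'
#' @param x an `equilibrium_result` or `analytic_equilibrium` object.
#' @return A character vector of lines.
#' @export
record_lines <- function(x) {
  num <- function(v) sprintf("%.17g", v)
  if (inherits(x, "equilibrium_result")) {
    lines <- c(paste0("p_A\t", num(x$p[["A"]])),
               paste0("p_B\t", num(x$p[["B"]])),
               paste0("p_a\t", num(x$p[["a"]])),
               paste0("generations\t", format(x$generations)),
               paste0("converged\t", x$converged),
               paste0("oscillations\t", x$cycling$oscillations),
               paste0("cycling_duration\t", x$cycling$duration),
               paste0("cycling_amplitude\t", num(x$cycling$amplitude)))
    if (!is.null(x$stability))
      lines <- c(lines,
                 paste0("eigenvalue_modulus_1\t", num(x$stability$moduli[1])),
                 paste0("eigenvalue_modulus_2\t", num(x$stability$moduli[2])),
                 paste0("stable\t", if (is.na(x$stability$stable)) "neutral"
                        else x$stability$stable))
    return(lines)
  }
  if (inherits(x, "analytic_equilibrium")) {
    lines <- c(paste0("case\t", x$case_id),
               paste0("scenario\t", x$scenario),
               paste0("p_A\t", num(x$p[["A"]])),
               paste0("p_B\t", num(x$p[["B"]])),
               paste0("p_a\t", num(x$p[["a"]])),
               paste0("valid\t", x$valid))
    return(c(lines, paste0("constraint[", x$validity$condition, "]\t",
                           x$validity$holds)))
  }
  stop("unsupported record type", call. = FALSE)
}
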