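# Shared fixtures: parameter sets used across test files.

# baseline without paramutation: wild-type-high regime
case_a_params <- function(t2 = 0)
  model_params(rate_params(u = 1e-9, z = 1e-9, u_prime = 1e-9,
                           t1 = 1e-5, t2 = t2),
               selection = selection_params(s = 0.01, s2 = 0.02))

# same with inbreeding
case_b_params <- function(f = 0.5, t2 = 0)
  model_params(rate_params(u = 1e-9, z = 1e-9, u_prime = 1e-9,
                           t1 = 1e-5, t2 = t2, f = f),
               selection = selection_params(s = 0.01, s2 = 0.02))

# deleterious-allele-paramutagenic scenario where both the
# wild-type-high and deleterious-high equilibria are valid
case_e_bistable_params <- function()
  model_params(rate_params(u = 1e-9, z = 1e-9, u_prime = 1e-9,
                           t1 = 1e-5, t2 = 1e-4, m1 = 0.005, m2 = 0.3,
                           f = 0.1),
               selection = selection_params(s = 0.01, s2 = 0.02,
                                            s3 = 0.001))

# random valid allele-frequency state (uniform on the simplex)
random_state <- function() {
  x <- -log(runif(3))
  x <- x / sum(x)
  allele_freqs(x[1], x[2], x[3])
}

# random valid parameter set with small rates and nontrivial selection
random_params <- function() {
  s <- runif(1, 0, 0.1)
  s2 <- runif(1, 0, 0.1)
  # keep w_Ba = 1 - h2 s2 - h s + s3 inside [0, 1]
  s3 <- runif(1, 0, 0.5 * (s + s2) / 2)
  model_params(
    rate_params(u = runif(1, 0, 0.01), z = runif(1, 0, 0.01),
                u_prime = runif(1, 0, 0.01), t1 = runif(1, 0, 0.05),
                t2 = runif(1, 0, 0.05), m1 = runif(1, 0, 0.5),
                m2 = runif(1, 0, 0.5), f = runif(1)),
    selection = selection_params(s = s, s2 = s2, s3 = s3))
}

fast_settings <- function(max_gens = 1e6)
  convergence_settings(max_gens = max_gens)

`%||%` <- function(a, b) if (is.null(a)) b else a
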