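# shared fixtures, built once per test run
.fix <- local({
  env <- new.env()
  function(name) {
    if (is.null(env[[name]])) {
      env[[name]] <- switch(name,
        space = build_state_space(),
        params = gen_default_parameters(),
        lt = gen_life_table(1L),
        stop("unknown fixture ", name))
    }
    env[[name]]
  }
})

default_space <- function() .fix("space")
default_params <- function() .fix("params")
default_lt <- function() .fix("lt")

# random but valid per-state probability inputs for matrix construction
random_matrix_inputs <- function(space, rng_scale = 0.2) {
  n <- nrow(space)
  list(p_mi = runif(n, 0, rng_scale),
       p_stroke = runif(n, 0, rng_scale),
       p_cv = runif(n, 0, rng_scale),
       p_ncv = runif(n, 0, rng_scale))
}

peace_cea <- local({
  env <- new.env()
  function() {
    if (is.null(env$res))
      env$res <- run_cea(gen_population("PEACE"), default_params(),
                         default_lt(), run_config(), default_space())
    env$res
  }
})
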