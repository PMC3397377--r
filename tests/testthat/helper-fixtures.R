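# Reference parameter sets used across tests
exp1_pars <- adaptive_params_defaults("exp1")
exp2_pars <- adaptive_params_defaults("exp2")

# A small labeled trial table built by hand: one block, known stimuli
toy_trials <- function() {
  data.frame(
    block = 1L, trial = 1:8,
    p_alt = 0.5,
    stimulus = c(1L, 1L, 1L, 2L, 2L, 1L, 1L, 1L),
    response = c(1L, 1L, 2L, 2L, 2L, 1L, 1L, 1L),
    correct  = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
    rt = c(0.40, 0.35, 0.30, 0.45, 0.50, 0.42, 0.38, 0.36))
}

# Random scaled parameter draws within the ranges the model visits
draw_ddm_params <- function(n, seed) {
  set.seed(seed)
  data.frame(
    z = runif(n, 0.05, 0.25),
    m = runif(n, 4, 30),
    xf = runif(n, -0.8, 0.8))  # x0 as a fraction of z
}
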