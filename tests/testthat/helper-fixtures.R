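# Shared fixtures: tiny protocols and quiet fitting wrappers.

EPS0 <- 8.8541878128e-12
GAS_R <- 8.314462618

quiet <- function(expr) suppressWarnings(suppressMessages(expr))

# two Arrhenius processes plus hopping conductivity, well separated inside
# the window over -50..-10 C; noise-free by default
two_process_protocol <- function(drift = c(1, 1), noise_sd = 0) {
  synthetic_protocol(
    processes = list(
      process_law("fast", "arrhenius", 10, Ea = 30, delta_eps = 2, a = 0.5),
      process_law("slow", "arrhenius", 12, Ea = 50, delta_eps = 5, a = 0.8)
    ),
    conductivity = conductivity_law(-11, 230, 20, 70, 0.35, 0.95),
    eps_inf = 3, temp_range_C = c(-50, -10), temp_step_C = 10,
    noise_sd = noise_sd, drift = drift, sample_id = "twoproc"
  )
}

two_process_config <- function(representation = "tan_delta", seed = 2,
                               n_starts = 16) {
  fit_config(
    list(process_spec("fast", delta_eps = 1, f0 = 1e3, a = 0.6),
         process_spec("slow", delta_eps = 1, f0 = 10, a = 0.6)),
    eps_inf = 3, representation = representation, weighting = "relative",
    n_starts = n_starts, seed = seed
  )
}

delta_of <- function(fit) {
  vapply(fit$model$processes, `[[`, numeric(1), "delta_eps")
}
f0_of <- function(fit) {
  vapply(fit$model$processes, `[[`, numeric(1), "f0")
}
a_of <- function(fit) {
  vapply(fit$model$processes, `[[`, numeric(1), "a")
}
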