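# Shared fixtures: protocols and small datasets built in code.

t1_params <- table1_parameters()

std_protocols <- list(
  uptake_tim2 = build_protocol("uptake", "tim2"),
  uptake_vector = build_protocol("uptake", "vector"),
  storage_tim2 = build_protocol("storage", "tim2"),
  export_tim2 = build_protocol("export", "tim2"),
  export_vector = build_protocol("export", "vector")
)

# uptake + storage dataset collection at given noise, as used for co-fitting
make_fit_data <- function(seed, cv = 0.10, n_reps = 3) {
  nm <- noise_model(cv = cv)
  as_timecourse_dataset(rbind(
    generate_dataset(t1_params, std_protocols$uptake_tim2, nm, n_reps,
                     seed = seed),
    generate_dataset(t1_params, std_protocols$uptake_vector, nm, n_reps,
                     seed = seed + 1L),
    generate_dataset(t1_params, std_protocols$storage_tim2, nm, n_reps,
                     seed = seed + 2L)))
}

# random valid positive state, away from the non-negativity boundary
random_state <- function() {
  v <- stats::runif(11, 0.01, 5)
  names(v) <- c("x1", "x2", "x3", "x4", "x5", "x6", "x7", "x8", "x9",
                "media_unbound", "media_exported")
  v
}
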