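# Shared fixtures: the four scheme/target pairs, built once per test run.
sch1cf <- color_scheme(1, "CF")
sch1cl <- color_scheme(1, "CL")
sch2cf <- color_scheme(2, "CF")
sch2cl <- color_scheme(2, "CL")
all_schemes <- list(CF1 = sch1cf, CF2 = sch2cf, CL1 = sch1cl, CL2 = sch2cl)

# quick small synthetic dataset for classifier tests
quick_dataset <- function(n_per_class = 20, seed = 7, scheme = sch1cf,
                          clutter = 0.5, use_secondary = FALSE) {
  generate_dataset(
    synth_config(image_size = 32, n_per_class = n_per_class,
                 clutter_level = clutter, use_secondary = use_secondary,
                 seed = seed),
    scheme
  )
}

quick_train_config <- function(epochs, seed = 11, ...) {
  train_config(initial_lr = 1e-3, epochs = epochs, input_size = 32,
               seed = seed, ...)
}
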