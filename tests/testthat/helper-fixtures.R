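# Shared fixtures: the reference parameter means and a small cohort setup.

ref_params <- function() model_params() # study sample means

small_config <- function(seed = 42, ...) {
  cohort_config(n_per_grade = 4, seed = seed, ...)
}

chengguan <- function() staircase_spec(0.15, 0.28, 1.36, 12, name = "Chengguan")

# random parameter tuples for property-style loops
random_tuples <- function(n, seed) {
  set.seed(seed)
  data.frame(
    v = runif(n, 0, 1.5),
    l = runif(n, 0.5, 1.1),
    pfc = runif(n, 0, 0.15),
    eta = runif(n, 0.02, 0.15),
    L = runif(n, 0.16, 0.30),
    d = runif(n, 0.05, 0.45),
    N = sample(2:15, n, replace = TRUE)
  )
}
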