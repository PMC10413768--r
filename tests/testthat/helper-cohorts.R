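# Shared fixtures built in code.

# A tiny fully-specified cohort for exact-arithmetic tests.
tiny_cohort <- function() {
  ree_cohort(data.frame(
    id = c("a", "b", "c", "d"),
    sex = c("male", "female", "male", "female"),
    age = c(8, 12, 15, 10),
    weight = c(30, 45, 60, 38),
    height = c(130, 150, 170, 140),
    fat_mass = c(6, 12, 14, 9),
    fat_free_mass = c(24, 33, 46, 29),
    measured_ree = c(1100, 1350, 1700, 1250),
    bmi_group = c("normal", "overweight", "obese", "normal"),
    stringsAsFactors = FALSE))
}

# A cohort whose predictions are forced equal to measurement: measured REE
# is set to what the FFM equation predicts.
perfect_cohort <- function() {
  co <- tiny_cohort()
  co$measured_ree <- 505.412 + 24.383 * co$fat_free_mass
  co
}

default_cohort <- function(seed, n = 275, ...) {
  args <- list(n = n, seed = seed, ...)
  if (n != 275 && !"group_sizes" %in% names(args)) {
    args["group_sizes"] <- list(NULL)
  }
  simulate_cohort(do.call(generator_config, args))
}

# Independent OLS oracle: explicit normal-equations solve.
ols_oracle <- function(X, y) {
  X1 <- cbind(1, X)
  solve(t(X1) %*% X1, t(X1) %*% y)[, 1]
}

synthetic_lms_path <- function() {
  system.file("extdata", "synthetic_lms_bmi.csv", package = "pedree")
}
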