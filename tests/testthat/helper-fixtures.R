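# shared builders for small deterministic fixtures

small_plan <- function(n_expressors = 10, raters_per_list = 2, seed = 11) {
  build_design(n_expressors = n_expressors, raters_per_list = raters_per_list,
               seed = seed)
}

# a confusion model with probability 1 on the diagonal
identity_confusion <- function() {
  m <- matrix(0, 5, 6,
              dimnames = list(expression_names(), response_categories()))
  m[cbind(expression_names(), expression_names())] <- 1
  confusion_model(m, concentration = NULL)
}

# random 5x6 count matrix with strictly positive marginals
random_cm <- function(min_count = 1, max_count = 30) {
  m <- matrix(sample(min_count:max_count, 30, replace = TRUE), 5, 6,
              dimnames = list(expression_names(), response_categories()))
  m
}

# ordinal model with all structural effects switched off
flat_ordinal <- function(model) {
  model$rater_intercept_sd <- 0
  model$male_effect <- 0
  model$mirror_effect <- 0
  model
}
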