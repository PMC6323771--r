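# Shared fixtures: the shipped parameter set and synthetic life table are
# deterministic, so build them once per test run.

.test_cache <- new.env(parent = emptyenv())

test_params <- function() {
  if (is.null(.test_cache$params)) .test_cache$params <- load_parameters()
  .test_cache$params
}

test_life_table <- function() {
  if (is.null(.test_cache$lt)) .test_cache$lt <- make_life_table()
  .test_cache$lt
}

test_base_case <- function() {
  if (is.null(.test_cache$base)) {
    .test_cache$base <- run_base_case(test_params(), test_life_table())
  }
  res <- .test_cache$base
  rownames(res) <- res$option_id
  res
}

# all transition probabilities zeroed and background mortality off: the
# cohort must then sit still in its start state
frozen_params <- function() {
  p <- test_params()
  probs <- grep("^(p_rec|p_death|p_prog|p_disc)", names(p$values), value = TRUE)
  p <- set_param_values(p, stats::setNames(rep(0, length(probs)), probs))
  p$scalars$include_background_mortality <- FALSE
  p
}

# collapse every distribution to its point value (SE = 0)
collapsed_params <- function() {
  p <- test_params()
  p$specs$se <- 0
  p
}
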