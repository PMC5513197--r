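# shared fixtures, all generated in code

# independent standard-normal exposures as a tibble
toy_exposures <- function(n, p, seed = 1) {
  set.seed(seed)
  E <- matrix(rnorm(n * p), n, p)
  colnames(E) <- paste0("e", seq_len(p))
  tibble::as_tibble(E)
}

# correlation model with pairs (i, i+k) correlated at rho, all else 0;
# PSD because it is block-diagonal in 2x2 blocks
proxy_pair_model <- function(k = 5, rho = 0.9) {
  p <- 2 * k
  M <- diag(p)
  for (i in seq_len(k)) {
    M[i, i + k] <- rho
    M[i + k, i] <- rho
  }
  correlation_model(M)
}

# p-variable equicorrelated model
equi_model <- function(p = 5, rho = 0.78) {
  M <- matrix(rho, p, p)
  diag(M) <- 1
  correlation_model(M)
}

# scenario row with overridden fields (e.g. custom sigma)
spec_with <- function(scenario_id, ...) {
  row <- scenario_spec(scenario_id)
  over <- list(...)
  for (nm in names(over)) row[[nm]] <- over[[nm]]
  row
}

# a small fast generator configuration used by several tests
default_model_cache <- new.env(parent = emptyenv())
cached_default_model <- function(seed = 1) {
  key <- paste0("m", seed)
  if (is.null(default_model_cache[[key]])) {
    default_model_cache[[key]] <-
      build_correlation_model(generator_config(seed = seed))
  }
  default_model_cache[[key]]
}
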