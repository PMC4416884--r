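# Independent oracles used across the suite. These deliberately reimplement
# the statistics the package computes, in the most literal way possible, so
# they stay independent of the package's vectorized code paths.

# Breslow-ties Cox log partial likelihood, coded directly from its definition.
oracle_log_partial_likelihood <- function(beta, x, time, event) {
  ll <- 0
  for (tk in unique(time[event == 1])) {
    deaths <- which(time == tk & event == 1)
    risk_set <- which(time >= tk)
    ll <- ll + sum(beta * x[deaths]) -
      length(deaths) * log(sum(exp(beta * x[risk_set])))
  }
  ll
}

# Standardized score statistic U(0)/sqrt(I(0)) by central numeric
# differentiation of the log partial likelihood at beta = 0.
oracle_cox_score <- function(x, time, event, h = 1e-4) {
  f <- function(b) oracle_log_partial_likelihood(b, x, time, event)
  U <- (f(h) - f(-h)) / (2 * h)
  I <- -(f(h) - 2 * f(0) + f(-h)) / h^2
  U / sqrt(I)
}

# Harrell's C by exhaustive enumeration of ordered pairs: a pair is usable
# when the sample with the strictly shorter time has an observed event.
oracle_harrell_c <- function(risk, time, event) {
  num <- 0
  den <- 0
  n <- length(risk)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (time[i] < time[j] && event[i] == 1) {
        den <- den + 1
        if (risk[i] > risk[j]) num <- num + 1
        else if (risk[i] == risk[j]) num <- num + 0.5
      }
    }
  }
  if (den == 0) stop("no usable pairs")
  num / den
}

# small random survival instance, optionally with tied times and censoring
random_surv_instance <- function(n, ties = FALSE, censoring = TRUE) {
  time <- if (ties) sample(1:5, n, replace = TRUE) else round(rexp(n, 0.2), 4) + 0.01
  event <- if (censoring) rbinom(n, 1, 0.7) else rep(1, n)
  if (sum(event) == 0) event[sample(n, 1)] <- 1
  survival_data(paste0("s", seq_len(n)), time, event)
}

# small expression matrix with named dims
random_expr <- function(n_genes, n_samples, prefix = "S") {
  m <- matrix(rnorm(n_genes * n_samples, mean = 7, sd = 2), nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("%s%03d", prefix, seq_len(n_samples))))
  m
}

# fast sim_config for unit tests (small but structurally faithful)
quick_cfg <- function(...) {
  sim_config(n_genes = 120, n_train = 60, n_test = 60, n_sets = 20,
             set_size_range = c(5, 12), n_informative = 3, ...)
}
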