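# Small shared fixtures, built in code at test time.

tiny_config <- function(seed = 7L, ...) {
  args <- list(...)
  if (!"n_volumes" %in% names(args)) args$n_volumes <- 40L
  do.call(sim_config, c(list(seed = seed), args))
}

tiny_protocol <- function(n_blocks = 2L, update_period = 0.5, begin_s = 10) {
  protocol_spec(task_s = 20, rest_s = 20, n_blocks = n_blocks,
                begin_s = begin_s, update_period = update_period)
}

# brute-force window count oracle: enumerate starts by hand
enumerate_windows <- function(n_samples, win_samples, step_samples) {
  starts <- integer()
  s <- 1L
  while (s + win_samples - 1L <= n_samples) {
    starts <- c(starts, s)
    s <- s + step_samples
  }
  starts
}

# batch OLS oracle for the incremental GLM
batch_ols <- function(X, y) {
  fit <- lm.fit(X, y)
  n <- nrow(X); p <- ncol(X)
  sigma2 <- sum(fit$residuals^2) / (n - p)
  list(beta = unname(fit$coefficients), sigma2 = sigma2)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# calibration reused across expensive tests (memoised per session)
shared_calibration <- local({
  cal <- NULL
  function() {
    if (is.null(cal)) {
      cfg <- sim_config(seed = 1)
      pr <- protocol_spec(task_s = 20, rest_s = 20, n_blocks = 4,
                          begin_s = 10, update_period = 0.5)
      cal <<- nfb_calibrate(cfg, pr)
    }
    cal
  }
})
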