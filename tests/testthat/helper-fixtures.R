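# Shared fixtures, built in code. The small simulation keeps the paradigm
# structure (instruction/task/rest, balanced labels) but shrinks rests and
# the EEG rate so module tests stay fast; cached per test run.

small_paradigm <- function(seed = 42, n_trials = 12, n_sessions = 1,
                           eeg_rate = 200) {
  paradigm_config(
    pre_rest_s = 6, instruction_s = 2, task_s = 10,
    rest_range_s = c(6, 7), post_rest_s = 6,
    n_trials_per_session = n_trials, n_sessions = n_sessions,
    eeg_rate_hz = eeg_rate, seed = seed
  )
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

small_sim <- function() {
  cached("small_sim", generate_dataset(small_paradigm()))
}

small_prep <- function() {
  cached("small_prep",
         preprocess_recording(small_sim()$recording,
                              eeg_downsample_factor = 1L))
}

# two-class epochs with exact per-trial channel covariances: each trial's
# channel-by-sample block is constructed by whitening Gaussian noise and
# rescaling, so sample covariance equals the requested matrix exactly
epochs_with_cov <- function(cov_ma, cov_bl, n_per_class = 6, n_samp = 100,
                            rate = 100) {
  n_ch <- nrow(cov_ma)
  make_trial <- function(C) {
    z <- matrix(rnorm(n_ch * n_samp), n_ch, n_samp)
    z <- z - rowMeans(z)
    S <- tcrossprod(z) / (n_samp - 1)
    w <- solve(t(chol(S)), z) # rows now exactly white
    t(chol(C)) %*% w
  }
  dat <- array(NA_real_, c(2 * n_per_class, n_ch, n_samp))
  labs <- rep(c("MA", "BL"), each = n_per_class)
  for (i in seq_len(2 * n_per_class)) {
    dat[i, , ] <- make_trial(if (labs[i] == "MA") cov_ma else cov_bl)
  }
  bci_epochs(dat, c(0, n_samp / rate), labs, rate, "EEG")
}

# independent oracle for CSP: trace-normalized class covariances and the
# generalized eigenproblem solved directly (non-symmetric route)
csp_oracle <- function(epochs) {
  d <- dim(epochs$data)
  covs <- list(MA = 0, BL = 0); n <- c(MA = 0, BL = 0)
  for (i in seq_len(d[1])) {
    x <- matrix(epochs$data[i, , ], d[2], d[3])
    x <- x - rowMeans(x)
    S <- tcrossprod(x) / (d[3] - 1)
    lab <- as.character(epochs$labels[i])
    covs[[lab]] <- covs[[lab]] + S / sum(diag(S))
    n[lab] <- n[lab] + 1
  }
  S1 <- covs$MA / n[["MA"]]; S2 <- covs$BL / n[["BL"]]
  ge <- eigen(solve(S1 + S2) %*% S1)
  ord <- order(Re(ge$values), decreasing = TRUE)
  list(values = Re(ge$values)[ord],
       vectors = Re(ge$vectors)[, ord, drop = FALSE],
       S1 = S1, S2 = S2)
}
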