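# shared fixtures, built in code

# independent brute-force oracle for the empirical Hoeffding phi-square:
# literal double loop over the n x n grid evaluating the copula step function
phi2_bruteforce <- function(x, y) {
  n <- length(x)
  u <- rank(x, ties.method = "average") / n
  v <- rank(y, ties.method = "average") / n
  s <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      C <- mean(u <= i / n & v <= j / n)
      s <- s + (C - (i / n) * (j / n))^2
    }
  }
  90 * s / n^2
}

# one 20-item response sheet; `correct` marks which items are answered right
make_sheet <- function(n_correct_verb = 10, n_correct_circ = 10,
                       dont_remember = FALSE, text_id = "AT1",
                       subject_id = "S01") {
  it <- rep(c("verb", "circumstantial"), each = 10)
  correct_opt <- rep("a", 20)
  chosen <- correct_opt
  chosen[which(it == "verb")[seq_len(10 - n_correct_verb)]] <- "b"
  chosen[which(it == "circumstantial")[seq_len(10 - n_correct_circ)]] <- "b"
  data.frame(subject_id = subject_id, text_id = text_id,
             item = seq_len(20), item_type = it,
             chosen_option = chosen, correct_option = correct_opt,
             is_dont_remember = rep(dont_remember, 20),
             stringsAsFactors = FALSE)
}

# a cohort config with no planted effects
null_config <- function(seed, n_timepoints = 8) {
  cohort_config(d_behavior = 0, d_atr = 0, delta_coupling = 0,
                rho_neuro_behavior = 0, n_timepoints = n_timepoints,
                seed = seed)
}

# small linearly separable two-class feature table for classifier tests
separable_features <- function(n_per_class = 19, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  grp <- rep(c("FLE", "CTL"), each = n_per_class)
  out <- data.frame(subject_id = sprintf("T%02d", seq_len(n)), group = grp,
                    stringsAsFactors = FALSE)
  out$x1 <- (grp == "FLE") * 10 + rnorm(n, sd = 0.3)
  for (k in 2:5) out[[paste0("x", k)]] <- rnorm(n)
  out$x_exact <- (grp == "FLE") * 10  # noiseless class indicator
  out
}
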