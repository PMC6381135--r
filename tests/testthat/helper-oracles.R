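# Independent brute-force interpreters of the verbal strategy rules,
# written against the opponent-action vector directly so they share no
# machinery with the package's automaton stepper.

oracle_prescribe <- function(abbr, opp) {
  t <- length(opp)
  last_n_all_d <- function(n) t >= n && all(opp[(t - n + 1):t] == "D")
  has_run_d <- function(n) {
    grepl(paste(rep("D", n), collapse = ""), paste(opp, collapse = ""),
          fixed = TRUE)
  }
  # punished iff a DD pair occurs strictly after the last CC pair
  two_for_two <- function() {
    if (t < 2) return(FALSE)
    pairs <- paste0(opp[-t], opp[-1])
    last_cc <- max(c(which(pairs == "CC"), 0L))
    any(which(pairs == "DD") > last_cc)
  }
  punished <- switch(abbr,
    ALLC = FALSE,
    ALLD = TRUE,
    TFT = t >= 1 && opp[t] == "D",
    DTFT = if (t == 0) TRUE else opp[t] == "D",
    TF2T = last_n_all_d(2),
    TF3T = last_n_all_d(3),
    `2TFT` = t >= 1 && "D" %in% opp[max(1, t - 1):t],
    `2TF2T` = two_for_two(),
    Grim = has_run_d(1),
    Grim2 = has_run_d(2),
    Grim3 = has_run_d(3),
    stop("oracle does not know strategy ", abbr)
  )
  if (punished) "D" else "C"
}

# Exhaustive grid-search oracle for the per-subject tremble fit: scans
# gamma over a fine grid and returns the maximiser of the uniform-prior
# mixture likelihood plus the normalised weights there.
oracle_grid_fit <- function(choices, prescriptions_list, grid = seq(0.01, 5, by = 0.01)) {
  T <- length(choices)
  m <- vapply(prescriptions_list, function(p) sum(choices != p), numeric(1))
  ll <- vapply(grid, function(g) {
    b <- 1 / (1 + exp(-1 / g))
    log(mean(b^(T - m) * (1 - b)^m))
  }, numeric(1))
  g_hat <- grid[which.max(ll)]
  b_hat <- 1 / (1 + exp(-1 / g_hat))
  lik <- b_hat^(T - m) * (1 - b_hat)^m
  list(gamma = g_hat, weights = lik / sum(lik), loglik = max(ll))
}

# Closed-form ordinary least squares for checking the Gaussian fits.
oracle_ols <- function(X, y) drop(solve(crossprod(X), crossprod(X, y)))

# All action sequences of a given length.
all_action_seqs <- function(len) {
  if (len == 0) return(list(character(0)))
  grid <- do.call(expand.grid, c(rep(list(c("C", "D")), len),
                                 stringsAsFactors = FALSE))
  lapply(seq_len(nrow(grid)), function(i) unname(unlist(grid[i, ])))
}
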