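# Fixture builders used across the suite. Everything is generated in code
# under fixed seeds; no data files.

# a random rooted binary tree with exponential branch lengths (not
# ultrametric; likelihood code must not assume clock-likeness)
random_tree <- function(n_tips, seed) {
  with_seed(seed, function() {
    tr <- ape::rtree(n_tips, br = function(n) stats::rexp(n, 4))
    tr$tip.label <- paste0("t", seq_len(n_tips))
    tr
  })
}

# a generic rate vector with all 8 rates positive, log-uniform in [0.2, 3]
random_rates <- function(seed) {
  with_seed(seed, function() exp(stats::runif(8, log(0.2), log(3))))
}

random_states <- function(tree, seed, unknown_prob = 0) {
  with_seed(seed, function() {
    s <- sample(composite_states(), length(tree$tip.label), replace = TRUE)
    if (unknown_prob > 0) {
      flip <- stats::runif(length(s)) < unknown_prob
      s[flip] <- "?"
    }
    names(s) <- tree$tip.label
    s
  })
}

# quick, deterministic optimizer settings for small-fixture fits
cheap_settings <- function(seed = 1L, n_restarts = 1L, maxit = 400L) {
  fit_settings(n_restarts = n_restarts, seed = seed, maxit = maxit,
               reltol = 1e-9)
}
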