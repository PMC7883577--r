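test_that("node marginals are proper distributions with trivial limits", {
  tr <- random_tree(6, 21)
  Q <- build_rate_matrix(random_rates(22))
  states <- random_states(tr, 23)
  rec <- marginal_ancestral_states(tr, states, Q, include_tips = TRUE)
  expect_true(max(abs(rowSums(rec$probs) - 1)) < 1e-10)
  expect_true(all(rec$probs >= 0 & rec$probs <= 1))
  # observed tips are one-hot
  tiprow <- rec$probs[as.character(1), ]
  expect_equal(unname(tiprow[states[tr$tip.label[1]]]), 1, tolerance = 1e-12)
  # no data: the root marginal is the root prior
  unknown <- stats::setNames(rep("?", 6), tr$tip.label)
  rec0 <- marginal_ancestral_states(tr, unknown, Q, root = "flat")
  root_row <- rec0$probs[as.character(length(tr$tip.label) + 1), ]
  expect_equal(unname(root_row), rep(0.25, 4), tolerance = 1e-10)
})

test_that("marginals match exact enumeration on random instances", {
  policies <- c("flat", "stationary", "fitzjohn")
  for (i in 1:30) {
    n <- 3 + (i %% 4)
    tr <- random_tree(n, seed = 400 + i)
    Q <- build_rate_matrix(random_rates(500 + i))
    states <- random_states(tr, 600 + i, unknown_prob = 0.1)
    policy <- policies[1 + (i %% 3)]
    rec <- marginal_ancestral_states(tr, states, Q, root = policy)
    exact <- enumerate_node_marginals(tr, states, Q, root = policy)
    expect_lt(max(abs(rec$probs[rownames(exact), ] - exact)), 1e-9)
  }
})

test_that("marginals survive zero-length branches (P(0) = I)", {
  tr <- read_newick(text = "((A:0,B:1):0.5,(C:1,D:1):0);")
  Q <- build_rate_matrix(random_rates(31))
  states <- c(A = "SC", B = "SA", C = "GC", D = "GA")
  rec <- marginal_ancestral_states(tr, states, Q)
  exact <- enumerate_node_marginals(tr, states, Q)
  expect_lt(max(abs(rec$probs[rownames(exact), ] - exact)), 1e-9)
})

test_that("marginals agree with sampled joint reconstructions", {
  # frequencies over 50,000 assignments drawn by their exact joint weights
  tr <- random_tree(5, 41)
  Q <- build_rate_matrix(random_rates(42))
  states <- random_states(tr, 43)
  en <- evopath:::.enumerate_root_partials(tr, states, Q)
  w <- evopath:::root_weights("flat")
  rs <- en$grid[, match(en$root, en$internal)]
  wt <- en$prob * w[rs]
  draws <- with_seed(44, function()
    sample.int(length(wt), 50000, replace = TRUE, prob = wt))
  rec <- marginal_ancestral_states(tr, states, Q)
  for (j in seq_along(en$internal)) {
    freq <- tabulate(en$grid[draws, j], nbins = 4) / 50000
    expect_lt(max(abs(freq - rec$probs[as.character(en$internal[j]), ])),
              1e-2)
  }
})

test_that("reconstruction is invariant to tip ordering", {
  tr <- read_newick(text = "((A:0.3,B:0.7):0.4,(C:0.2,D:0.5):0.6);")
  tr2 <- read_newick(text = "((D:0.5,C:0.2):0.6,(B:0.7,A:0.3):0.4);")
  Q <- build_rate_matrix(random_rates(51))
  states <- c(A = "SC", B = "SA", C = "GC", D = "GA")
  r1 <- marginal_ancestral_states(tr, states, Q)
  r2 <- marginal_ancestral_states(tr2, states, Q)
  # align rows via the descendant-tip hashes
  m1 <- r1$probs[order(r1$nodes$tips_hash), ]
  m2 <- r2$probs[order(r2$nodes$tips_hash), ]
  expect_lt(max(abs(m1 - m2)), 1e-12)
})

test_that("reconstruct_under_best uses the AIC-best model, not the general", {
  tree <- simulate_yule_tree(16, seed = 61, scale_depth = TRUE)
  sim <- simulate_traits(tree, build_rate_matrix(c(0, 3, 1, 1, 1.5, 2, 2, 1),
                                                 model_spec(zero = 1)),
                         root_state = "SA", seed = 62)
  res <- run_model_selection(tree, sim$tip_states,
                             specs = list(general_model(),
                                          model_spec_by_name("n1")),
                             settings = cheap_settings())
  rec <- reconstruct_under_best(tree, sim$tip_states, res$table, res$fits)
  expect_identical(rec$model, res$table$model[1])
  expect_error(reconstruct_under_best(tree, sim$tip_states,
                                      res$table[0, ], res$fits),
               "empty AIC table")
})

test_that("reconstructions round-trip through TSV and annotated Newick", {
  tr <- random_tree(8, 71)
  Q <- build_rate_matrix(random_rates(72))
  states <- random_states(tr, 73)
  rec <- marginal_ancestral_states(tr, states, Q, model_name = "general")
  f <- file.path(tempdir(), "recon.tsv")
  write_reconstruction_tsv(rec, f)
  back <- read_reconstruction_tsv(f)
  expect_identical(back$model, "general")
  expect_identical(back$root_policy, "flat")
  expect_lt(max(abs(back$probs - rec$probs)), 1e-12)
  nwk <- write_annotated_newick(tr, rec)
  expect_match(nwk, "SC=")
  reparsed <- ape::read.tree(text = nwk)
  expect_identical(sort(reparsed$tip.label), sort(tr$tip.label))
})

test_that("the root state is recoverable from simulated clades", {
  # simulate under a known generator with a solitary-aposematic root and ask
  # how often the root's modal marginal matches, reconstructing under truth.
  # The generator is scaled so a root-to-tip path expects exactly 2 events:
  # deep enough that the root state is not trivially conserved.
  hits <- 0L
  Q0 <- build_rate_matrix(c(0.5, 2, 1, 1, 1.2, 1.5, 1.5, 0.8))
  pi0 <- stationary_distribution(Q0)
  Q <- Q0 * (2 / sum(pi0 * -diag(Q0)))
  for (r in 1:20) {
    tree <- simulate_yule_tree(250, seed = 700 + r, scale_depth = TRUE)
    sim <- simulate_traits(tree, Q, root_state = "SA", seed = 800 + r)
    rec <- marginal_ancestral_states(tree, sim$tip_states, Q)
    root_row <- rec$probs[as.character(length(tree$tip.label) + 1L), ]
    if (names(which.max(root_row)) == "SA") hits <- hits + 1L
  }
  expect_gte(hits, 14L)
})
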