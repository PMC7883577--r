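test_that("degenerate cases have closed-form likelihoods", {
  # single tip on a zero branch: the root prior of the observed state
  tr1 <- read_newick(text = "(A:0);")
  expect_equal(prune_loglik(tr1, c(A = "SC"), build_rate_matrix(rep(1, 8))),
               log(1 / 4), tolerance = 1e-12)
  # all tips unknown: total probability 1 under any Q and any policy
  tr <- random_tree(8, 1)
  Q <- build_rate_matrix(random_rates(2))
  states <- stats::setNames(rep("?", 8), tr$tip.label)
  for (policy in c("flat", "stationary", "fitzjohn"))
    expect_equal(prune_loglik(tr, states, Q, root = policy), 0,
                 tolerance = 1e-10)
  # frozen cherry: Q = 0 keeps both tips in the root state
  cherry <- read_newick(text = "(A:1,B:1);")
  Q0 <- build_rate_matrix(rep(0, 8))
  expect_equal(prune_loglik(cherry, c(A = "SC", B = "SC"), Q0), log(1 / 4),
               tolerance = 1e-12)
  expect_equal(enumerate_assignments_loglik(cherry, c(A = "SC", B = "SC"), Q0),
               log(1 / 4), tolerance = 1e-12)
  # contradictory data under Q = 0 is impossible
  expect_error(prune_loglik(cherry, c(A = "SC", B = "GA"), Q0), "non-finite")
})

test_that("pruning equals brute-force enumeration on random instances", {
  policies <- c("flat", "stationary", "fitzjohn")
  for (i in 1:40) {
    n <- 3 + (i %% 4)
    tr <- random_tree(n, seed = 100 + i)
    Q <- build_rate_matrix(random_rates(200 + i))
    states <- random_states(tr, 300 + i, unknown_prob = 0.15)
    policy <- policies[1 + (i %% 3)]
    expect_equal(prune_loglik(tr, states, Q, root = policy),
                 enumerate_assignments_loglik(tr, states, Q, root = policy),
                 tolerance = 1e-9)
  }
  # polytomies prune correctly too
  poly <- read_newick(text = "((A:0.4,B:0.2,C:0.3):0.5,D:1,E:0.7);")
  st <- c(A = "SC", B = "SA", C = "GC", D = "GA", E = "?")
  Qp <- build_rate_matrix(random_rates(99))
  expect_equal(prune_loglik(poly, st, Qp),
               enumerate_assignments_loglik(poly, st, Qp), tolerance = 1e-9)
  expect_error(
    enumerate_assignments_loglik(random_tree(15, 1),
                                 random_states(random_tree(15, 1), 2),
                                 build_rate_matrix(rep(1, 8))),
    "refusing enumeration")
})

test_that("likelihood is invariant to child order and rate-time rescaling", {
  tr <- read_newick(text = "((A:0.3,B:0.7):0.4,(C:0.2,(D:0.5,E:0.1):0.3):0.6);")
  swapped <- read_newick(text = "(((D:0.5,E:0.1):0.3,C:0.2):0.6,(B:0.7,A:0.3):0.4);")
  q <- random_rates(11)
  states <- c(A = "SC", B = "SA", C = "GC", D = "GA", E = "SC")
  ll <- prune_loglik(tr, states, build_rate_matrix(q))
  expect_equal(prune_loglik(swapped, states, build_rate_matrix(q)), ll,
               tolerance = 1e-12)
  # multiply rates by c, divide branch lengths by c
  for (c_ in c(0.25, 3)) {
    tr_c <- tr
    tr_c$edge.length <- tr$edge.length / c_
    expect_equal(prune_loglik(tr_c, states, build_rate_matrix(q * c_)), ll,
                 tolerance = 1e-9)
  }
})

test_that("setting an observed tip to unknown never lowers the likelihood", {
  for (seed in 1:10) {
    tr <- random_tree(7, seed)
    Q <- build_rate_matrix(random_rates(seed + 50))
    states <- random_states(tr, seed + 80)
    ll <- prune_loglik(tr, states, Q)
    relaxed <- states
    relaxed[1 + (seed %% 7)] <- "?"
    expect_gte(prune_loglik(tr, relaxed, Q) + 1e-12, ll)
  }
})

test_that("root policies weight the same partial likelihoods differently", {
  tr <- random_tree(6, 3)
  Q <- build_rate_matrix(random_rates(4))
  states <- random_states(tr, 5)
  ll_flat <- prune_loglik(tr, states, Q, root = "flat")
  ll_fj <- prune_loglik(tr, states, Q, root = "fitzjohn")
  ll_st <- prune_loglik(tr, states, Q, root = "stationary")
  expect_false(isTRUE(all.equal(ll_flat, ll_fj, tolerance = 1e-10)))
  expect_false(isTRUE(all.equal(ll_flat, ll_st, tolerance = 1e-10)))
  # FitzJohn reweighting can only improve on the flat mixture
  expect_gte(ll_fj, ll_flat)
})

test_that("tip-state tables parse, validate, and report mismatches", {
  txt <- "tip\tstate\nA\tSC\nB\tsolitary-aposematic\nC\t?\n"
  st <- read_tip_states(text = txt)
  expect_identical(st, c(A = "SC", B = "SA", C = "?"))
  tr <- read_newick(text = "((A:1,B:1):1,C:2);")
  expect_silent(read_tip_states(text = txt, tree = tr))
  tr2 <- read_newick(text = "((A:1,D:1):1,C:2);")
  expect_error(read_tip_states(text = txt, tree = tr2),
               "tips without a state: D.*states without a tip: B")
  # a missing tip state is named
  expect_error(prune_loglik(tr, c(A = "SC", B = "SA"),
                            build_rate_matrix(rep(1, 8))),
               "tips without a state: C")
  expect_error(read_tip_states(text = "A\tSC\nA\tSA\n"), "duplicate")
})
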