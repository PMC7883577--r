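test_that("Yule trees are ultrametric, sized, and seed-deterministic", {
  t2 <- simulate_yule_tree(2, seed = 1)
  expect_identical(length(t2$tip.label), 2L)
  expect_true(is_ultrametric(t2, 1e-12))
  for (n in c(5, 50)) {
    tr <- simulate_yule_tree(n, birth_rate = 2, seed = 3)
    expect_identical(length(tr$tip.label), as.integer(n))
    expect_true(is_ultrametric(tr, 1e-9))
    expect_true(all(tr$edge.length >= 0))
  }
  expect_identical(write_newick(simulate_yule_tree(30, seed = 9)),
                   write_newick(simulate_yule_tree(30, seed = 9)))
  expect_false(identical(write_newick(simulate_yule_tree(30, seed = 9)),
                         write_newick(simulate_yule_tree(30, seed = 10))))
  expect_equal(tree_depth(simulate_yule_tree(25, seed = 4,
                                             scale_depth = TRUE)), 1,
               tolerance = 1e-12)
  expect_error(simulate_yule_tree(1), ">= 2")
  expect_error(simulate_yule_tree(5, birth_rate = 0), "positive")
})

test_that("the pure-birth process grows at its analytic rate", {
  lambda <- 1; T_ <- 1.5
  counts <- with_seed(123, function()
    replicate(2000, yule_lineage_count(lambda, T_)))
  expect_lt(abs(mean(counts) / exp(lambda * T_) - 1), 0.05)
})

test_that("trait simulation is faithful to the generator", {
  tr <- simulate_yule_tree(30, seed = 11, scale_depth = TRUE)
  # frozen chain: every node inherits the root state, no events
  sim0 <- simulate_traits(tr, build_rate_matrix(rep(0, 8)),
                          root_state = "GC", seed = 12)
  expect_true(all(sim0$tip_states == "GC"))
  expect_true(all(sim0$node_states == "GC"))
  expect_identical(sim0$n_events, 0L)
  # determinism
  Q <- build_rate_matrix(random_rates(13))
  s1 <- simulate_traits(tr, Q, root_state = "SA", seed = 14)
  s2 <- simulate_traits(tr, Q, root_state = "SA", seed = 14)
  expect_identical(s1$tip_states, s2$tip_states)
  expect_identical(s1$node_states, s2$node_states)
  # latent node states are returned for every node, tips consistent
  expect_identical(length(s1$node_states), length(tr$tip.label) + tr$Nnode)
  expect_identical(unname(s1$tip_states),
                   s1$node_states[seq_along(tr$tip.label)])
})

test_that("single-branch simulation matches expm transition probabilities", {
  cherry <- read_newick(text = "(A:0.7,B:0.7);")
  Q <- build_rate_matrix(c(0.5, 2, 1, 1, 1.5, 2, 2, 0.7))
  P <- transition_probabilities(Q, 0.7)
  ends <- with_seed(501, function()
    replicate(6000, simulate_traits(cherry, Q, root_state = "SC")$tip_states[1]))
  freq <- table(factor(ends, levels = composite_states())) / 6000
  expect_lt(max(abs(as.numeric(freq) - P["SC", ])), 0.02)
  # a very long branch reaches the stationary distribution
  long <- read_newick(text = "(A:250,B:250);")
  pi <- stationary_distribution(Q)
  ends2 <- with_seed(502, function()
    replicate(6000, simulate_traits(long, Q,
                                    root_state = "GA")$tip_states[1]))
  freq2 <- table(factor(ends2, levels = composite_states())) / 6000
  expect_lt(max(abs(as.numeric(freq2) - as.numeric(pi))), 0.02)
})

test_that("the study-scale generator hits its composition target", {
  cal <- calibrate_study_rates()
  expect_identical(unname(cal$rates[1]), 0)          # n1 truth: q1 = 0
  expect_lt(cal$max_dev, 0.03)
  expect_equal(as.numeric(cal$expected), as.numeric(study_composition()$freq),
               tolerance = 0.03)
  ds <- emulate_study_dataset(seed = 1)
  expect_identical(length(ds$tree$tip.label), 676L)
  expect_true(is_ultrametric(ds$tree, 1e-9))
  expect_identical(ds$spec$name, "n1")
  # realized solitary-cryptic fraction across the default seed bank
  sc <- vapply(1:20, function(s)
    mean(emulate_study_dataset(seed = s)$tip_states == "SC"), numeric(1))
  expect_true(all(sc >= 0.70 & sc <= 0.90))
})

test_that("the recovery harness contrasts q1 = 0 against q1 > 0 truths", {
  # the group-cryptic exit to group-aposematic (rate 7) is kept slow so a
  # nonzero rate 1 cannot be mimicked by the detour GC -> GA -> SA -> SC
  base <- c(3, 1.5, 1.5, 1, 1, 1.5, 0.3, 1)
  specs <- list(general_model(), model_spec_by_name("n1"))
  fit_q1 <- function(rates, spec, seed) {
    tree <- simulate_yule_tree(300, seed = seed, scale_depth = TRUE)
    sim <- simulate_traits(tree, build_rate_matrix(rates, spec),
                           root_state = "stationary", seed = seed + 1)
    run_model_selection(tree, sim$tip_states, specs = specs,
                        settings = cheap_settings(n_restarts = 2,
                                                  maxit = 800))
  }
  with_q1 <- fit_q1(base, general_model(), 901)
  no_q1 <- fit_q1(replace(base, 1, 0), model_spec(zero = 1), 902)
  # detectably different outcomes: the q1-free data support the general
  # model / a large q1 estimate, the q1 = 0 data support n1
  expect_identical(no_q1$table$model[1], "n1")
  expect_identical(with_q1$table$model[1], "general")
  expect_gt(with_q1$fits$general$rates[1], 10 * no_q1$fits$general$rates[1])
  daic_n1_with <- with(as.data.frame(with_q1$table),
                       AIC[model == "n1"] - AIC[model == "general"])
  daic_n1_without <- with(as.data.frame(no_q1$table),
                          AIC[model == "n1"] - AIC[model == "general"])
  expect_gt(daic_n1_with, daic_n1_without + 2)
})

test_that("zero replicates give an empty summary without error", {
  cfg <- list(n_tips = 10, true_spec = general_model(),
              true_rates = rep(1, 8), candidate_specs = list(general_model()))
  res <- recovery_experiment(cfg, 0)
  expect_identical(nrow(res$replicates), 0L)
  expect_identical(nrow(res$summary), 0L)
})
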