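#' Optimizer settings for model fitting
#'
#' @param n_restarts number of random restarts (log-uniform draws over the
#'   rate bounds) in addition to a fixed moderate start and, when supplied,
#'   a start projected from `init_rates`.
#' @param seed integer seed controlling the random restarts.
#' @param lower,upper box bounds on each rate (events per unit branch time).
#' @param reltol relative convergence tolerance on the log-likelihood.
#' @param maxit maximum function evaluations per start.
#' @return A list of class `fit_settings`.
#' @export
fit_settings <- function(n_restarts = 10L, seed = 1L, lower = 1e-9,
                         upper = 100, reltol = 1e-8, maxit = 2000L) {
  stopifnot(n_restarts >= 0, lower > 0, upper > lower, reltol > 0, maxit > 0)
  structure(list(n_restarts = as.integer(n_restarts), seed = as.integer(seed),
                 lower = lower, upper = upper, reltol = reltol,
                 maxit = as.integer(maxit)),
            class = "fit_settings")
}

#' Evaluate a function under a temporary RNG seed
#'
#' Runs `fn()` with the RNG seeded to `seed` and restores the caller's random
#' stream afterwards, so seeded simulations do not perturb surrounding code.
#'
#' @param seed integer seed, or `NULL` to run unseeded.
#' @param fn a zero-argument function.
#' @return The value of `fn()`.
#' @export
with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Fit one constrained model by maximum likelihood
#'
#' Maximizes the pruning log-likelihood over the model's free rates. Free
#' parameters are optimized in log space (positivity for free) by
#' Nelder-Mead simplex search with box bounds enforced by clamping plus a
#' quadratic penalty; multiple starts guard against local optima. The
#' best start wins.
#'
#' @param tree a `phylo` object.
#' @param states named character vector of tip states.
#' @param spec a [model_spec()].
#' @param settings a [fit_settings()].
#' @param root root policy passed to [prune_loglik()].
#' @param init_rates optional length-8 rate vector (e.g. the general-model
#'   MLE) projected onto the spec's constraints and used as an extra start.
#' @return An object of class `fit_result`: `name`, `spec`, `rates` (length 8,
#'   constrained entries exact), `loglik`, `K`, `aic = 2K - 2 loglik`,
#'   `convergence` (TRUE if any start converged), `boundary` (TRUE if a free
#'   rate ended within a factor ~1e-6 of a bound), `n_restarts`, `seed`,
#'   `root`, `reducible` (non-unique stationary distribution at the MLE).
#' @export
fit_model <- function(tree, states, spec, settings = fit_settings(),
                      root = "flat", init_rates = NULL) {
  validate_tree(tree)
  if (!inherits(spec, "model_spec")) spec <- model_spec_by_name(spec)
  idx <- free_rate_indices(spec)
  K <- spec$K
  stopifnot(length(idx) == K)
  po <- postorder_edges(tree)
  tp <- tip_partials(tree, states)
  nnode <- tree$Nnode
  lb <- log(settings$lower); ub <- log(settings$upper)

  negll <- function(theta) {
    thc <- pmin(pmax(theta, lb), ub)
    pen <- 100 * sum((theta - thc)^2)
    q <- expand_free_rates(exp(thc), spec)
    Q <- build_rate_matrix(q, spec)
    lp <- .root_logpartials_cpp(po$edge, po$length, tp, nnode, Q)
    ll <- combine_root(lp, root, Q)
    if (!is.finite(ll)) return(1e10 + pen)
    -ll + pen
  }

  starts <- list(rep(log(0.5), K))
  if (!is.null(init_rates)) {
    qi <- apply_spec_constraints(init_rates, spec)[idx]
    starts <- c(starts, list(log(pmin(pmax(qi, settings$lower),
                                      settings$upper))))
  }
  if (settings$n_restarts > 0) {
    rand <- with_seed(settings$seed, function()
      matrix(stats::runif(settings$n_restarts * K, lb, ub),
             nrow = settings$n_restarts))
    starts <- c(starts, lapply(seq_len(settings$n_restarts),
                               function(i) rand[i, ]))
  }

  best <- NULL
  converged <- FALSE
  for (th0 in starts) {
    opt <- if (K == 1L) {
      o <- stats::optimize(negll, c(lb - 1, ub + 1), tol = 1e-10)
      list(par = o$minimum, value = o$objective, convergence = 0L)
    } else {
      stats::optim(th0, negll, method = "Nelder-Mead",
                   control = list(maxit = settings$maxit,
                                  reltol = settings$reltol))
    }
    if (is.null(best) || opt$value < best$value) best <- opt
    if (opt$convergence == 0L) converged <- TRUE
  }
  # polish the winner: restart the simplex from the incumbent until the
  # objective stops improving (plain Nelder-Mead stalls on ridges)
  if (K > 1L) {
    for (round in 1:6) {
      opt <- stats::optim(best$par, negll, method = "Nelder-Mead",
                          control = list(maxit = settings$maxit,
                                         reltol = settings$reltol))
      improved <- best$value - opt$value
      if (opt$value < best$value) best <- opt
      if (improved < 1e-7) break
    }
  }

  theta <- pmin(pmax(best$par, lb), ub)
  qfree <- exp(theta)
  rates <- expand_free_rates(qfree, spec)
  names(rates) <- paste0("q", 1:8)
  Q <- build_rate_matrix(rates, spec)
  loglik <- combine_root(.root_logpartials_cpp(po$edge, po$length, tp,
                                               nnode, Q), root, Q)
  boundary <- any(theta < lb + 1e-6) || any(theta > ub - 1e-6)
  pi <- stationary_distribution(Q)
  structure(list(name = spec$name, spec = spec, rates = rates,
                 loglik = loglik, K = K, aic = 2 * K - 2 * loglik,
                 convergence = converged, boundary = boundary,
                 n_restarts = settings$n_restarts, seed = settings$seed,
                 root = root, reducible = !isTRUE(attr(pi, "unique"))),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result '%s': K = %d, logLik = %.4f, AIC = %.4f%s\n",
              x$name, x$K, x$loglik, x$aic,
              if (!x$convergence) " (NOT converged)" else ""))
  cat("rates:", paste(sprintf("%s=%.4g", names(x$rates), x$rates),
                      collapse = " "), "\n")
  invisible(x)
}

#' Serialise a fit result to JSON
#' @param fit a `fit_result`.
#' @return JSON string.
#' @export
fit_to_json <- function(fit) {
  jsonlite::toJSON(list(
    name = jsonlite::unbox(fit$name),
    zero = fit$spec$zero, equal = fit$spec$equal,
    rates = unname(fit$rates),
    loglik = jsonlite::unbox(fit$loglik),
    K = jsonlite::unbox(fit$K), aic = jsonlite::unbox(fit$aic),
    convergence = jsonlite::unbox(fit$convergence),
    boundary = jsonlite::unbox(fit$boundary),
    n_restarts = jsonlite::unbox(fit$n_restarts),
    seed = jsonlite::unbox(fit$seed),
    root = jsonlite::unbox(fit$root),
    reducible = jsonlite::unbox(fit$reducible)), digits = I(17))
}

#' Deserialise a fit result from JSON
#' @param json JSON string or file path ending in `.json`.
#' @return A `fit_result`.
#' @export
fit_from_json <- function(json) {
  if (length(json) == 1L && grepl("\\.json$", json) && file.exists(json))
    json <- paste(readLines(json, warn = FALSE), collapse = "\n")
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  equal <- x$equal
  if (is.matrix(equal)) equal <- split(equal, row(equal))
  if (is.null(equal) || (is.list(equal) && !length(equal))) equal <- list()
  if (is.numeric(equal)) equal <- list(equal)
  spec <- model_spec(zero = x$zero, equal = equal, name = x$name)
  rates <- as.numeric(x$rates)
  names(rates) <- paste0("q", 1:8)
  structure(list(name = x$name, spec = spec, rates = rates,
                 loglik = x$loglik, K = as.integer(x$K), aic = x$aic,
                 convergence = isTRUE(x$convergence),
                 boundary = isTRUE(x$boundary),
                 n_restarts = as.integer(x$n_restarts),
                 seed = as.integer(x$seed), root = x$root,
                 reducible = isTRUE(x$reducible)),
            class = "fit_result")
}

#' Write MLE rates as an 8-row TSV
#'
#' Columns: `index`, `from_state`, `to_state`, `mle`.
#'
#' @param fit a `fit_result`.
#' @param file output path.
#' @return The data.frame written, invisibly.
#' @export
write_rates_tsv <- function(fit, file) {
  map <- rate_mapping()
  df <- data.frame(index = map$rate, from_state = map$from,
                   to_state = map$to, mle = unname(fit$rates))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
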