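#' Read tip states from delimited text
#'
#' Expects two columns (tip label, state), tab/comma/whitespace separated,
#' with an optional header. States may be short codes (`SC`, `SA`, `GC`,
#' `GA`, `?`) or long names (`solitary-cryptic`, ...). When a tree is
#' supplied, labels are matched strictly against its tips and a report of
#' mismatches is raised on failure.
#'
#' @param file path to the table, or `NULL` if `text` given.
#' @param text the table as a string.
#' @param tree optional `phylo` object for strict label checking.
#' @return Named character vector: `states[tip_label] in {"SC","SA","GC","GA","?"}`.
#' @export
read_tip_states <- function(file = NULL, text = NULL, tree = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `file` or `text`")
  if (!is.null(file)) {
    if (!file.exists(file)) stop("trait file not found: ", file)
    lines <- readLines(file, warn = FALSE)
  } else lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("trait table is empty")
  parts <- strsplit(lines, "[\t,]+|[[:space:]]+")
  bad <- which(vapply(parts, length, integer(1)) < 2L)
  if (length(bad)) stop("trait table line(s) without 2 columns: ",
                        paste(bad, collapse = ", "))
  lab <- vapply(parts, `[[`, character(1), 1L)
  val <- vapply(parts, `[[`, character(1), 2L)
  # drop a header line if its state column is not a recognisable state
  if (is.na(.state_synonyms[tolower(val[1])])) {
    lab <- lab[-1]; val <- val[-1]
    if (!length(lab)) stop("trait table is empty after header")
  }
  states <- normalize_states(val)
  names(states) <- lab
  if (any(duplicated(lab)))
    stop("duplicate tip labels in trait table: ",
         paste(unique(lab[duplicated(lab)]), collapse = ", "))
  if (!is.null(tree)) check_tip_states(tree, states)
  states
}

#' Check tip states against a tree
#'
#' @param tree a `phylo` object.
#' @param states named character vector of states.
#' @return `states` (reordered to the tree's tips), invisibly on success.
#' @export
check_tip_states <- function(tree, states) {
  missing <- setdiff(tree$tip.label, names(states))
  extra <- setdiff(names(states), tree$tip.label)
  if (length(missing) || length(extra)) {
    msg <- "tip/state mismatch:"
    if (length(missing))
      msg <- paste0(msg, " tips without a state: ",
                    paste(missing, collapse = ", "), ".")
    if (length(extra))
      msg <- paste0(msg, " states without a tip: ",
                    paste(extra, collapse = ", "), ".")
    stop(msg)
  }
  invisible(states[tree$tip.label])
}

# 4 x ntip partial-likelihood matrix: one-hot for observed, ones for "?"
tip_partials <- function(tree, states) {
  states <- check_tip_states(tree, states)
  s <- composite_states()
  M <- matrix(0, 4, length(states), dimnames = list(s, names(states)))
  for (i in seq_along(states)) {
    if (states[i] == "?") M[, i] <- 1 else M[s == states[i], i] <- 1
  }
  M
}

# root prior weights for a policy; FITZJOHN is resolved from root partials
root_weights <- function(policy, Q = NULL) {
  switch(policy,
         flat = rep(0.25, 4),
         stationary = {
           pi <- stationary_distribution(Q)
           if (!isTRUE(attr(pi, "unique")))
             warning("stationary distribution is not unique (reducible chain); ",
                     "using one solution")
           as.numeric(pi)
         },
         stop("unknown root policy: ", policy))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Log-likelihood of tip states by the pruning algorithm
#'
#' Felsenstein's postorder recursion with per-node rescaling, so trees with
#' hundreds of tips and small rates do not underflow. The root policy sets
#' the weights `w` in `log sum_s w_s L_root(s)`: `"flat"` uses 1/4 each,
#' `"stationary"` the stationary distribution of `Q`, and `"fitzjohn"`
#' weights proportional to the root partial likelihoods themselves.
#'
#' @param tree a `phylo` object (validated).
#' @param states named character vector of tip states (`"?"` = unknown).
#' @param Q generator from [build_rate_matrix()].
#' @param root root policy: `"flat"` (default), `"stationary"`, `"fitzjohn"`.
#' @return Log-likelihood (scalar).
#' @export
prune_loglik <- function(tree, states, Q,
                         root = c("flat", "stationary", "fitzjohn")) {
  root <- match.arg(root)
  lp <- root_logpartials(tree, states, Q)
  ll <- combine_root(lp, root, Q)
  if (!is.finite(ll))
    stop("non-finite log-likelihood (data impossible under this generator?)")
  ll
}

# log partial likelihoods at the root, one per state
root_logpartials <- function(tree, states, Q) {
  po <- postorder_edges(tree)
  tp <- tip_partials(tree, states)
  .root_logpartials_cpp(po$edge, po$length, tp, tree$Nnode, Q)
}

combine_root <- function(lp, root, Q) {
  if (root == "fitzjohn") {
    # weights L_s / sum L: log sum L^2 - log sum L
    return(logsumexp(2 * lp) - logsumexp(lp))
  }
  w <- root_weights(root, Q)
  logsumexp(log(w) + lp)
}

#' Exact log-likelihood by enumerating all ancestral assignments
#'
#' Validation oracle: sums the joint probability over every assignment of
#' states to the internal nodes. Exponential in the number of internal nodes,
#' so refuses trees with more than 10 of them.
#'
#' @inheritParams prune_loglik
#' @return Log-likelihood (scalar), equal to [prune_loglik()] up to roundoff.
#' @export
enumerate_assignments_loglik <- function(tree, states, Q,
                                         root = c("flat", "stationary",
                                                  "fitzjohn")) {
  root <- match.arg(root)
  en <- .enumerate_root_partials(tree, states, Q)
  lp <- log(en$L_root)
  combine_root(lp, root, Q)
}

# Brute-force sum over internal-node assignments. Returns the root partial
# likelihood vector L_root(s) and, for marginals, the per-node, per-state
# summed weights.
.enumerate_root_partials <- function(tree, states, Q) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  if (nint > 10L)
    stop("refusing enumeration: ", nint, " internal nodes (max 10)")
  po <- postorder_edges(tree)
  tp <- tip_partials(tree, states)
  internal <- sort(unique(po$edge[, 1]))
  ncomb <- 4^nint
  grid <- as.matrix(expand.grid(rep(list(1:4), nint)))  # ncomb x nint
  colnames(grid) <- NULL
  prob <- rep(1, ncomb)
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    P <- transition_probabilities(Q, po$length[k])
    ps <- grid[, match(p, internal)]
    if (ch <= ntip) {
      # child observed (or unknown): sum over child states
      v <- as.numeric(P %*% tp[, ch])
      prob <- prob * v[ps]
    } else {
      cs <- grid[, match(ch, internal)]
      prob <- prob * P[cbind(ps, cs)]
    }
  }
  root <- po$edge[nrow(po$edge), 1]
  rs <- grid[, match(root, internal)]
  L_root <- vapply(1:4, function(s) sum(prob[rs == s]), numeric(1))
  list(L_root = L_root, prob = prob, grid = grid, internal = internal,
       root = root)
}

#' Exact node marginals by enumeration (oracle)
#'
#' Brute-force marginal probability of each internal node's state given the
#' tip data, for cross-checking [marginal_ancestral_states()] on small trees.
#'
#' @inheritParams prune_loglik
#' @return Matrix (internal nodes x 4 states) of posterior probabilities,
#'   rows named by ape node number.
#' @export
enumerate_node_marginals <- function(tree, states, Q,
                                     root = c("flat", "stationary",
                                              "fitzjohn")) {
  root <- match.arg(root)
  en <- .enumerate_root_partials(tree, states, Q)
  rs <- en$grid[, match(en$root, en$internal)]
  w <- if (root == "fitzjohn") en$L_root / sum(en$L_root)
       else root_weights(root, Q)
  wt <- en$prob * w[rs]
  out <- matrix(0, length(en$internal), 4,
                dimnames = list(en$internal, composite_states()))
  for (j in seq_along(en$internal)) {
    ns <- en$grid[, j]
    out[j, ] <- vapply(1:4, function(s) sum(wt[ns == s]), numeric(1))
  }
  out / rowSums(out)
}
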