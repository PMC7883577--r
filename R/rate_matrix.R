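#' Build the 4x4 transition-rate matrix
#'
#' Places the eight single-trait rates into the generator Q of the 4-state
#' correlated model according to the fixed numbering of [rate_mapping()],
#' applying a model spec's constraints: zeroed rates are forced to 0 and all
#' members of an equality class take the value of the class's lowest-index
#' member. The two dual transitions (SC<->GA, SA<->GC), in which both traits
#' would change at once, have rate 0 by model structure. Diagonal entries
#' close each row to zero.
#'
#' @param rates numeric vector of 8 nonnegative rates (q1..q8), in events per
#'   unit branch time.
#' @param spec a [model_spec()]; defaults to the general (unconstrained) model.
#' @return A 4x4 generator matrix with dimnames from [composite_states()].
#' @export
build_rate_matrix <- function(rates, spec = general_model()) {
  if (!inherits(spec, "model_spec")) stop("spec must be a model_spec")
  rates <- as.numeric(rates)
  if (length(rates) != 8L) stop("rates must have length 8 (q1..q8)")
  if (anyNA(rates)) stop("rates contain NA")
  if (any(rates < 0)) stop("negative transition rate(s)")
  q <- apply_spec_constraints(rates, spec)
  s <- composite_states()
  Q <- matrix(0, 4, 4, dimnames = list(s, s))
  map <- rate_mapping()
  for (i in 1:8) Q[map$from[i], map$to[i]] <- q[i]
  diag(Q) <- -rowSums(Q)
  Q
}

#' Apply a spec's constraints to a full rate vector
#'
#' @param rates numeric length-8 vector q1..q8.
#' @param spec a `model_spec`.
#' @return Length-8 vector with zeros and equalities enforced.
#' @export
apply_spec_constraints <- function(rates, spec) {
  q <- as.numeric(rates)
  for (cl in spec$equal) q[cl] <- q[min(cl)]
  q[spec$zero] <- 0
  q
}

# indices of the representative free parameter for each equality class /
# singleton, in ascending order; used by the fitter
free_rate_indices <- function(spec) {
  reps <- setdiff(1:8, spec$zero)
  for (cl in spec$equal) reps <- setdiff(reps, setdiff(cl, min(cl)))
  sort(reps)
}

# expand K free parameters (ordered as free_rate_indices) to q1..q8
expand_free_rates <- function(free, spec) {
  idx <- free_rate_indices(spec)
  stopifnot(length(free) == length(idx))
  q <- numeric(8)
  q[idx] <- free
  apply_spec_constraints(q, spec)
}

#' CTMC transition probabilities
#'
#' Computes `expm(Q t)`, the probability of ending in each state after time
#' `t` given the starting state (rows = from, columns = to). Uses a
#' scaling-and-squaring Pade matrix exponential, with an eigendecomposition
#' fast path when the eigenvector matrix is well-conditioned.
#'
#' @param Q generator matrix from [build_rate_matrix()].
#' @param t nonnegative time (branch length).
#' @return Stochastic matrix of the same dimension as `Q`.
#' @export
transition_probabilities <- function(Q, t) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop("t must be a single nonnegative number")
  P <- .expm_ctmc_cpp(Q, t)
  dimnames(P) <- dimnames(Q)
  P
}

#' Stationary distribution of the chain
#'
#' Solves pi Q = 0 with sum(pi) = 1 by least squares. When the chain is
#' reducible (rank of Q below n-1, e.g. a zero set that disconnects the
#' states or creates two closed classes) the stationary distribution is not
#' unique; the returned vector then carries `attr(, "unique") = FALSE` and is
#' only one solution of the system.
#'
#' @param Q generator matrix.
#' @return Probability vector over the states with a logical attribute
#'   `unique`.
#' @export
stationary_distribution <- function(Q) {
  n <- nrow(Q)
  unique_pi <- qr(Q)$rank == n - 1L
  A <- rbind(t(Q), rep(1, n))
  b <- c(rep(0, n), 1)
  # minimum-norm least squares via SVD (A may be rank-deficient when the
  # chain is reducible)
  sv <- svd(A)
  pos <- sv$d > max(sv$d) * 1e-12
  pi <- sv$v[, pos, drop = FALSE] %*%
    ((t(sv$u[, pos, drop = FALSE]) %*% b) / sv$d[pos])
  pi <- as.numeric(pi)
  pi[pi < 0 & pi > -1e-12] <- 0
  pi <- pi / sum(pi)
  names(pi) <- rownames(Q)
  attr(pi, "unique") <- unique_pi
  pi
}
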