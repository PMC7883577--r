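#' Marginal ancestral-state estimation
#'
#' For every internal node, the posterior probability of each of the four
#' composite states given all tip data, under a fixed generator `Q` and root
#' policy: the quantity displayed as pie charts at nodes in
#' plotRECON-style figures. Computed by combining the downward (pruning)
#' partial likelihoods with an upward pass carrying the likelihood of
#' everything outside the node's subtree; partial vectors are renormalized
#' per node so large trees do not underflow.
#'
#' @param tree a `phylo` object.
#' @param states named character vector of tip states.
#' @param Q generator from [build_rate_matrix()] (typically a fit's MLE).
#' @param root root policy as in [prune_loglik()].
#' @param include_tips also report rows for tips (one-hot for observed tips,
#'   posterior for unknown ones).
#' @param model_name optional model name recorded in the result.
#' @return An object of class `ancestral_reconstruction`: a list with
#'   `probs` (nodes x 4 matrix, rows summing to 1), `nodes` (the
#'   [node_identifiers()] table, plus tip rows if requested), `model`,
#'   `root_policy`.
#' @export
marginal_ancestral_states <- function(tree, states, Q, root = c("flat",
                                      "stationary", "fitzjohn"),
                                      include_tips = FALSE,
                                      model_name = NA_character_) {
  root <- match.arg(root)
  validate_tree(tree)
  ntip <- length(tree$tip.label)
  ntotal <- ntip + tree$Nnode
  po <- postorder_edges(tree)
  tp <- tip_partials(tree, states)

  # downward pass: normalized partial likelihoods D_v(s); keep each edge's
  # contribution P(t_child) D_child for the upward pass
  D <- matrix(1, 4, ntotal)
  D[, seq_len(ntip)] <- tp
  nE <- nrow(po$edge)
  Pmats <- vector("list", nE)
  contribs <- matrix(0, 4, nE)
  for (k in seq_len(nE)) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    Pmats[[k]] <- transition_probabilities(Q, po$length[k])
    contribs[, k] <- as.numeric(Pmats[[k]] %*% D[, ch])
    D[, p] <- D[, p] * contribs[, k]
    m <- max(D[, p])
    if (!is.finite(m) || m <= 0)
      stop("non-finite partial likelihood at node ", p)
    D[, p] <- D[, p] / m
  }
  root_node <- po$edge[nE, 1]
  w <- if (root == "fitzjohn") D[, root_node] / sum(D[, root_node])
       else root_weights(root, Q)

  # upward pass: U_v(s) carries root prior and everything outside v's
  # subtree. Sibling products are assembled by prefix/suffix products (no
  # division, so exact zeros in P(t) are handled).
  edges_by_parent <- split(seq_len(nE), po$edge[, 1])
  parents_preorder <- rev(unique(po$edge[, 1]))
  U <- matrix(0, 4, ntotal)
  U[, root_node] <- w
  for (p in parents_preorder) {
    ke <- edges_by_parent[[as.character(p)]]
    m <- length(ke)
    pre <- matrix(1, 4, m + 1L)   # pre[, j] = prod of contribs 1..j-1
    suf <- matrix(1, 4, m + 1L)   # suf[, j] = prod of contribs j+1..m
    for (j in seq_len(m)) pre[, j + 1L] <- pre[, j] * contribs[, ke[j]]
    for (j in rev(seq_len(m))) suf[, j] <- suf[, j + 1L] * contribs[, ke[j]]
    for (j in seq_len(m)) {
      k <- ke[j]
      ch <- po$edge[k, 2]
      above <- U[, p] * pre[, j] * suf[, j + 1L]
      U[, ch] <- as.numeric(t(Pmats[[k]]) %*% above)
      mx <- max(U[, ch])
      if (!is.finite(mx) || mx <= 0)
        stop("non-finite outside likelihood at node ", ch)
      U[, ch] <- U[, ch] / mx
    }
  }

  post <- U * D
  post <- sweep(post, 2, colSums(post), "/")

  ids <- node_identifiers(tree)
  rows <- ids$node
  nodes <- ids
  if (include_tips) {
    tiprows <- data.frame(node = seq_len(ntip), postorder = NA_integer_,
                          tips_hash = vapply(tree$tip.label, .djb2,
                                             character(1)),
                          n_tips = 1L, stringsAsFactors = FALSE)
    nodes <- rbind(tiprows, ids)
    rows <- nodes$node
  }
  probs <- t(post[, rows, drop = FALSE])
  colnames(probs) <- composite_states()
  rownames(probs) <- rows
  structure(list(probs = probs, nodes = nodes, model = model_name,
                 root_policy = root),
            class = "ancestral_reconstruction")
}

#' @export
print.ancestral_reconstruction <- function(x, ...) {
  cat("ancestral_reconstruction:", nrow(x$probs), "nodes, model =",
      x$model, ", root policy =", x$root_policy, "\n")
  print(utils::head(x$probs, 5))
  if (nrow(x$probs) > 5) cat("...\n")
  invisible(x)
}

#' Reconstruct ancestral states under the AIC-best model
#'
#' Convenience wrapper: takes a completed model sweep, picks the first row of
#' the AIC table, and runs [marginal_ancestral_states()] with that model's
#' MLE rates.
#'
#' @param tree,states data as elsewhere.
#' @param table an `aic_table` from [build_aic_table()].
#' @param fits named list of `fit_result`s covering the table's best model.
#' @param root root policy.
#' @return An `ancestral_reconstruction` with `model` set to the best model's
#'   name.
#' @export
reconstruct_under_best <- function(tree, states, table, fits, root = "flat") {
  if (!nrow(table)) stop("empty AIC table")
  best <- table$model[1]
  fit <- fits[[best]]
  if (is.null(fit)) stop("no fit stored for best model '", best, "'")
  Q <- build_rate_matrix(fit$rates, fit$spec)
  marginal_ancestral_states(tree, states, Q, root = root, model_name = best)
}

#' Write a reconstruction as TSV
#'
#' Columns: `node_id`, `descendant_tips_hash`, `p_SC`, `p_SA`, `p_GC`,
#' `p_GA`. A provenance header records the model and root policy.
#'
#' @param recon an `ancestral_reconstruction`.
#' @param file output path.
#' @return The data.frame written, invisibly.
#' @export
write_reconstruction_tsv <- function(recon, file) {
  df <- data.frame(node_id = recon$nodes$node,
                   descendant_tips_hash = recon$nodes$tips_hash,
                   p_SC = recon$probs[, "SC"], p_SA = recon$probs[, "SA"],
                   p_GC = recon$probs[, "GC"], p_GA = recon$probs[, "GA"])
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(paste0("# model=", recon$model),
               paste0("# root_policy=", recon$root_policy)), con)
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Read a reconstruction TSV written by [write_reconstruction_tsv()]
#' @param file TSV path.
#' @return An `ancestral_reconstruction`.
#' @export
read_reconstruction_tsv <- function(file) {
  hdr <- readLines(file, n = 2L)
  model <- sub("^# model=", "", hdr[1])
  rootp <- sub("^# root_policy=", "", hdr[2])
  df <- utils::read.table(file, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  probs <- as.matrix(df[, c("p_SC", "p_SA", "p_GC", "p_GA")])
  colnames(probs) <- composite_states()
  rownames(probs) <- df$node_id
  nodes <- data.frame(node = df$node_id, postorder = seq_len(nrow(df)),
                      tips_hash = df$descendant_tips_hash,
                      n_tips = NA_integer_, stringsAsFactors = FALSE)
  structure(list(probs = probs, nodes = nodes, model = model,
                 root_policy = rootp),
            class = "ancestral_reconstruction")
}

#' Annotated Newick with per-node state probabilities
#'
#' Writes the tree with internal-node labels of the form
#' `SC=0.91|SA=0.05|GC=0.02|GA=0.02` so the reconstruction travels with the
#' topology.
#'
#' @param tree the `phylo` object the reconstruction was computed on.
#' @param recon an `ancestral_reconstruction` (internal nodes only).
#' @param file output path or `NULL` for the string.
#' @param digits digits for the probabilities.
#' @return The Newick string (invisibly when writing to a file).
#' @export
write_annotated_newick <- function(tree, recon, file = NULL, digits = 4) {
  ntip <- length(tree$tip.label)
  lab <- rep("", tree$Nnode)
  internal <- recon$nodes$node[recon$nodes$node > ntip]
  pr <- recon$probs[as.character(internal), , drop = FALSE]
  lab[internal - ntip] <- apply(pr, 1, function(p)
    paste(sprintf("%s=%.*f", composite_states(), digits, p), collapse = "|"))
  tree$node.label <- lab
  write_newick(tree, file)
}
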