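#' Read a rooted phylogenetic tree from Newick
#'
#' Thin, validating wrapper around [ape::read.tree()]. The tree must be
#' rooted, carry a branch length on every non-root edge, and have unique,
#' non-empty tip labels. Quoted labels and square-bracket comments are
#' stripped; internal node labels are kept if present. Polytomies and
#' zero-length branches are accepted. A missing root edge length is treated
#' as 0.
#'
#' @param text a Newick string, or `NULL` if `file` is given.
#' @param file path to a Newick file, or `NULL`.
#' @return An object of class `phylo` (ape), validated.
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `text` or `file`")
  if (!is.null(file)) {
    if (!file.exists(file)) stop("tree file not found: ", file)
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  text <- .strip_newick_comments(text)
  .check_newick_syntax(text)
  qt <- .extract_quoted_labels(text)
  tree <- tryCatch(ape::read.tree(text = qt$text),
                   error = function(e) stop("Newick parse error: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse error: no tree found in input")
  if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
  if (length(qt$labels)) {
    hit <- match(tree$tip.label, names(qt$labels))
    tree$tip.label[!is.na(hit)] <- qt$labels[hit[!is.na(hit)]]
    if (!is.null(tree$node.label)) {
      hit <- match(tree$node.label, names(qt$labels))
      tree$node.label[!is.na(hit)] <- qt$labels[hit[!is.na(hit)]]
    }
  }
  validate_tree(tree)
  tree
}

# single-quoted labels may contain Newick metacharacters; swap them for
# placeholder tokens before parsing and restore the unquoted text afterwards
.extract_quoted_labels <- function(text) {
  labels <- character(0)
  i <- 0L
  repeat {
    m <- regmatches(text, regexpr("'[^']*'", text))
    if (!length(m)) break
    i <- i + 1L
    token <- sprintf("QUOTEDLABEL%dX", i)
    labels[token] <- substr(m, 2, nchar(m) - 1L)
    text <- sub("'[^']*'", token, text)
  }
  list(text = text, labels = labels)
}

# strip [...] comments (BEAST / NHX annotations) outside quoted labels
.strip_newick_comments <- function(text) {
  gsub("\\[[^]]*\\]", "", text)
}

# pre-scan for unbalanced parentheses / missing semicolon, reporting the
# 1-based character offset of the failure
.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  in_quote <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") in_quote <- !in_quote
    if (in_quote) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("Newick parse error at character ", i,
             ": unmatched closing parenthesis")
    }
  }
  if (depth > 0L)
    stop("Newick parse error at character ", length(chars),
         ": ", depth, " unclosed parenthesis(es)")
  if (!grepl(";", text, fixed = TRUE))
    stop("Newick parse error at character ", length(chars),
         ": missing terminating ';'")
  invisible(TRUE)
}

#' Validate a phylogenetic tree for likelihood work
#'
#' Checks that `tree` is a rooted `phylo` object with unique non-empty tip
#' labels and a nonnegative branch length on every edge. Polytomies are
#' permitted; a unary root (single-child root, as in a one-tip tree) is
#' tolerated as a degenerate case.
#'
#' @param tree a `phylo` object.
#' @return `tree`, invisibly, if valid; otherwise an error.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  lab <- tree$tip.label
  if (any(is.na(lab) | !nzchar(lab))) stop("empty or NA tip labels")
  dup <- unique(lab[duplicated(lab)])
  if (length(dup) > 0L)
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; lengths are required on all edges")
  if (anyNA(tree$edge.length))
    stop("missing branch length on ", sum(is.na(tree$edge.length)), " edge(s)")
  if (any(tree$edge.length < 0))
    stop("negative branch length(s) found")
  ntip <- length(lab)
  # every non-root node has exactly one parent; root has none
  root <- ntip + 1L
  kids <- tabulate(tree$edge[, 1], nbins = ntip + tree$Nnode)
  if (any(kids[seq_len(ntip)] > 0L)) stop("a tip appears as a parent")
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  nonroot_internal <- setdiff(internal, root)
  if (ntip > 1L && any(kids[nonroot_internal] < 2L))
    stop("internal non-root node with fewer than 2 children")
  parents <- tabulate(tree$edge[, 2], nbins = ntip + tree$Nnode)
  if (any(parents > 1L)) stop("node with more than one parent")
  if (parents[root] != 0L) stop("root node has a parent")
  invisible(tree)
}

#' Write a tree to Newick
#'
#' @param tree a `phylo` object.
#' @param file output path, or `NULL` to return the string.
#' @param digits significant digits for branch lengths.
#' @return The Newick string (invisibly when writing to a file).
#' @export
write_newick <- function(tree, file = NULL, digits = 12) {
  s <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Root-to-node path lengths
#'
#' @param tree a `phylo` object.
#' @return Numeric vector of distances from the root, indexed by node number
#'   (tips `1..ntip`, then internal nodes).
#' @export
node_depths <- function(tree) {
  ape::node.depth.edgelength(tree)
}

#' Is a tree ultrametric?
#'
#' True iff all root-to-tip path lengths agree within an absolute tolerance.
#'
#' @param tree a `phylo` object.
#' @param tolerance nonnegative absolute tolerance on tip depths.
#' @return Logical scalar.
#' @export
is_ultrametric <- function(tree, tolerance = 1e-8) {
  stopifnot(tolerance >= 0)
  d <- node_depths(tree)[seq_along(tree$tip.label)]
  max(d) - min(d) <= tolerance
}

#' Tree depth (maximum root-to-tip path length)
#' @param tree a `phylo` object.
#' @return Numeric scalar.
#' @export
tree_depth <- function(tree) {
  max(node_depths(tree)[seq_along(tree$tip.label)])
}

# postorder edge matrix (children before parents); ape's canonical reorder
postorder_edges <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  list(edge = tr$edge, length = tr$edge.length)
}

#' Stable identifiers for internal nodes
#'
#' Newick gives internal nodes no canonical order, so reconstructions are
#' keyed by the sorted set of descendant tip labels: the id is
#' `"<postorder index>|<hash>"` where the hash is a djb2 digest of the
#' comma-joined sorted labels.
#'
#' @param tree a `phylo` object.
#' @return data.frame with columns `node` (ape node number),
#'   `postorder` (postorder rank among internal nodes), `tips_hash`, and
#'   `n_tips` (clade size).
#' @export
node_identifiers <- function(tree) {
  ntip <- length(tree$tip.label)
  po <- postorder_edges(tree)
  internal_po <- unique(po$edge[, 1])          # parents in postorder
  clade_tips <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) clade_tips[[i]] <- tree$tip.label[i]
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    clade_tips[[p]] <- c(clade_tips[[p]], clade_tips[[ch]])
  }
  hash <- vapply(internal_po, function(n)
    .djb2(paste(sort(clade_tips[[n]]), collapse = ",")), character(1))
  data.frame(node = internal_po,
             postorder = seq_along(internal_po),
             tips_hash = hash,
             n_tips = vapply(clade_tips[internal_po], length, integer(1)),
             stringsAsFactors = FALSE)
}

# djb2 string hash, reported as 8 hex digits
.djb2 <- function(s) {
  h <- 5381
  for (v in utf8ToInt(s)) h <- (h * 33 + v) %% 4294967296
  sprintf("%08x", as.integer(h %% 2147483647))
}
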