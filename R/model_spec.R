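#' Constrained-model specifications
#'
#' A model spec constrains the eight transition rates of the correlated
#' 4-state model in two ways: a `zero` set (rates fixed at 0, the transition
#' impossible) and an `equal` partition (groups of rates sharing one free
#' parameter). The unconstrained model is `"general"` (K = 8). Zero models
#' are named `n` followed by the zeroed indices in ascending order (`n3`,
#' `n34`); equality models `eq` followed by the tied indices (`eq47`).
#'
#' @param zero integer vector of rate indices (1..8) fixed at zero.
#' @param equal list of integer vectors, each a class of >= 2 rate indices
#'   sharing one free parameter; classes must be disjoint from each other and
#'   from `zero`.
#' @param name optional name; derived canonically when omitted.
#' @return An object of class `model_spec` with elements `name`, `zero`,
#'   `equal`, `K`.
#' @export
model_spec <- function(zero = integer(0), equal = list(), name = NULL) {
  zero <- sort(unique(as.integer(zero)))
  if (length(zero) && (min(zero) < 1L || max(zero) > 8L))
    stop("zero indices must lie in 1..8")
  if (length(zero) == 8L)
    stop("all eight rates zero is not a valid model")
  equal <- lapply(unname(equal), function(cl) sort(unique(as.integer(cl))))
  if (length(equal)) {
    all_eq <- unlist(equal)
    if (any(all_eq < 1L | all_eq > 8L)) stop("equality indices must lie in 1..8")
    if (any(duplicated(all_eq))) stop("equality classes must be disjoint")
    if (any(all_eq %in% zero))
      stop("a rate cannot be both zeroed and in an equality class")
    if (any(vapply(equal, length, integer(1)) < 2L))
      stop("equality classes need at least 2 members")
    equal <- equal[order(vapply(equal, min, integer(1)))]
  }
  K <- 8L - length(zero) - sum(vapply(equal, length, integer(1)) - 1L)
  if (is.null(name)) {
    name <- if (!length(zero) && !length(equal)) "general"
    else if (!length(equal)) paste0("n", paste(zero, collapse = ""))
    else if (!length(zero)) paste0("eq", paste(unlist(equal), collapse = ""))
    else paste0("n", paste(zero, collapse = ""),
                "_eq", paste(unlist(equal), collapse = ""))
  }
  structure(list(name = name, zero = zero, equal = equal, K = K),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec '", x$name, "': K = ", x$K, sep = "")
  if (length(x$zero)) cat(", zero = {", paste(x$zero, collapse = ","), "}", sep = "")
  if (length(x$equal))
    cat(", equal = ", paste(vapply(x$equal, paste, character(1),
                                   collapse = "="), collapse = "; "), sep = "")
  cat("\n")
  invisible(x)
}

#' The unconstrained (general) model, K = 8
#' @return A `model_spec`.
#' @export
general_model <- function() model_spec()

#' All 254 zero-constrained models
#'
#' Every nonempty proper subset of the eight rates fixed at zero:
#' 2^8 - 2 = 254 models, named `n` plus the ascending zeroed indices.
#' Ordering is by number of zeroed rates, then by name.
#'
#' @return List of `model_spec` objects, length 254.
#' @export
enumerate_zero_models <- function() {
  out <- list()
  for (size in 1:7) {
    subsets <- utils::combn(8L, size, simplify = FALSE)
    out <- c(out, lapply(subsets, function(z) model_spec(zero = z)))
  }
  out
}

#' The eight equality-constrained models
#'
#' Four tie a transition to its reverse (symmetric rates): eq47, eq68, eq25,
#' eq13. Four tie the same single-trait move across the two contexts of the
#' other trait (trait independence): eq57, eq24, eq16, eq38. Each has K = 7.
#'
#' @return List of 8 `model_spec` objects.
#' @export
equality_models <- function() {
  pairs <- list(c(4L, 7L), c(6L, 8L), c(2L, 5L), c(1L, 3L),
                c(5L, 7L), c(2L, 4L), c(1L, 6L), c(3L, 8L))
  lapply(pairs, function(p) model_spec(equal = list(p)))
}

#' The full model set: general + 254 zero models + 8 equality models
#' @return List of 263 `model_spec` objects with unique names.
#' @export
all_model_specs <- function() {
  c(list(general_model()), enumerate_zero_models(), equality_models())
}

#' Look up a model spec by name
#'
#' Accepts `"general"`, zero-model names such as `"n1"` or `"n34"`, and
#' equality names such as `"eq47"`.
#'
#' @param name model name string.
#' @return A `model_spec`.
#' @export
model_spec_by_name <- function(name) {
  name <- trimws(name)
  if (identical(name, "general")) return(general_model())
  if (grepl("^n[1-8]+$", name)) {
    idx <- as.integer(strsplit(substring(name, 2), "")[[1]])
    if (any(duplicated(idx))) stop("unknown model name: ", name)
    return(model_spec(zero = idx))
  }
  if (grepl("^eq[1-8]+$", name)) {
    idx <- as.integer(strsplit(substring(name, 3), "")[[1]])
    spec <- model_spec(equal = list(idx))
    if (!identical(spec$name, name)) stop("unknown model name: ", name)
    return(spec)
  }
  stop("unknown model name: ", name)
}

#' Serialise a model spec to JSON
#' @param spec a `model_spec`.
#' @return A JSON string like `{"name":"n34","zero":[3,4],"equal":[]}`.
#' @export
model_spec_to_json <- function(spec) {
  jsonlite::toJSON(list(name = jsonlite::unbox(spec$name),
                        zero = spec$zero,
                        equal = spec$equal),
                   digits = I(17))
}

#' Deserialise a model spec from JSON
#' @param json JSON string as produced by [model_spec_to_json()].
#' @return A `model_spec`.
#' @export
model_spec_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  equal <- x$equal
  if (is.matrix(equal)) equal <- split(equal, row(equal))
  if (is.null(equal) || (is.list(equal) && !length(equal))) equal <- list()
  if (is.numeric(equal)) equal <- list(equal)
  model_spec(zero = x$zero, equal = equal, name = x$name)
}
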