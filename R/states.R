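#' Composite trait states
#'
#' The model tracks two binary traits jointly: colouration (cryptic vs
#' aposematic) and aggregation (solitary vs group-living). Their combination
#' gives four composite states with a fixed canonical order:
#'
#' | index | code | meaning              |
#' |-------|------|----------------------|
#' | 1     | SC   | solitary-cryptic     |
#' | 2     | SA   | solitary-aposematic  |
#' | 3     | GC   | group-cryptic        |
#' | 4     | GA   | group-aposematic     |
#'
#' @return Character vector of the four state codes, in canonical order.
#' @export
composite_states <- function() c("SC", "SA", "GC", "GA")

# long-form synonyms accepted in trait tables
.state_synonyms <- c(
  "sc" = "SC", "solitary-cryptic" = "SC", "solitary_cryptic" = "SC",
  "sa" = "SA", "solitary-aposematic" = "SA", "solitary_aposematic" = "SA",
  "gc" = "GC", "group-cryptic" = "GC", "group_cryptic" = "GC",
  "ga" = "GA", "group-aposematic" = "GA", "group_aposematic" = "GA",
  "?" = "?", "unknown" = "?", "na" = "?"
)

#' Normalise state labels to the four canonical codes
#'
#' Accepts the short codes (`SC`, `SA`, `GC`, `GA`), long names such as
#' `solitary-cryptic` (case-insensitive, `-` or `_`), and `?`/`unknown`/`NA`
#' for a missing observation.
#'
#' @param x character vector of state labels.
#' @return Character vector over `{"SC","SA","GC","GA","?"}`.
#' @export
normalize_states <- function(x) {
  key <- tolower(trimws(as.character(x)))
  key[is.na(key)] <- "?"
  out <- .state_synonyms[key]
  bad <- is.na(out)
  if (any(bad)) {
    stop("unrecognised state label(s): ",
         paste(unique(x[bad]), collapse = ", "))
  }
  unname(out)
}

#' The fixed mapping of rate indices to single-trait transitions
#'
#' Pagel-style correlated evolution on two binary traits permits only the
#' eight transitions that change one trait at a time (simultaneous change of
#' both traits has rate zero). The conventional numbering used throughout
#' this package is:
#'
#' q1: GC->SC, q2: SA->SC, q3: SC->GC, q4: GA->GC,
#' q5: SC->SA, q6: GA->SA, q7: GC->GA, q8: SA->GA.
#'
#' Rates 7, 6, 2, 3 form the "clockwise" cycle
#' (GC -> GA -> SA -> SC -> GC) and rates 4, 8, 5, 1 the counterclockwise
#' one. [derive_rate_mapping()] re-derives this table from the naming
#' constraints and is checked in the test suite.
#'
#' @return A data.frame with columns `rate`, `from`, `to`.
#' @export
rate_mapping <- function() {
  data.frame(
    rate = 1:8,
    from = c("GC", "SA", "SC", "GA", "SC", "GA", "GC", "SA"),
    to   = c("SC", "SC", "GC", "GC", "SA", "SA", "GA", "GA"),
    stringsAsFactors = FALSE
  )
}

# the 8 permitted directed transitions (one trait changes at a time)
.permitted_transitions <- function() {
  s <- composite_states()
  trait <- function(code) c(colour = substr(code, 2, 2), group = substr(code, 1, 1))
  out <- NULL
  for (a in s) for (b in s) {
    if (a == b) next
    d <- sum(trait(a) != trait(b))
    if (d == 1L) out <- rbind(out, data.frame(from = a, to = b,
                                              stringsAsFactors = FALSE))
  }
  out
}

#' Re-derive the rate-index mapping from its defining constraints
#'
#' The numbering in [rate_mapping()] is pinned down by four facts about how
#' the constrained models are named and drawn:
#' (a) rate 3 is the solitary-cryptic to group-cryptic transition;
#' (b) the pairs \{1,3\}, \{2,5\}, \{4,7\}, \{6,8\} are mutually reverse
#'     transitions (the "symmetric" equality models eq13/eq25/eq47/eq68);
#' (c) the pairs \{5,7\}, \{2,4\}, \{1,6\}, \{3,8\} are the same single-trait
#'     move in the two contexts of the other trait (the trait-independence
#'     models eq57/eq24/eq16/eq38);
#' (d) rates 7, 6, 2, 3 are consecutive arrows of one directed 4-cycle over
#'     the states.
#'
#' This function searches all assignments of indices to the eight permitted
#' transitions and returns the unique one satisfying (a)-(d).
#'
#' @return A data.frame in the same format as [rate_mapping()].
#' @export
derive_rate_mapping <- function() {
  tr <- .permitted_transitions()
  stopifnot(nrow(tr) == 8L)
  key <- paste(tr$from, tr$to, sep = ">")
  rev_key <- paste(tr$to, tr$from, sep = ">")
  rev_idx <- match(rev_key, key)  # position of the reverse transition
  # context partner: the same single-trait move with the *other* (unchanged)
  # trait flipped, e.g. SC->SA (colour move, solitary) pairs with GC->GA
  ctx_of <- function(from, to) {
    if (substr(from, 1, 1) != substr(to, 1, 1)) {
      # grouping changes: flip colour context
      paste(chartr("CA", "AC", from), chartr("CA", "AC", to), sep = ">")
    } else {
      # colour changes: flip grouping context
      paste(chartr("SG", "GS", from), chartr("SG", "GS", to), sep = ">")
    }
  }
  ctx_idx <- match(mapply(ctx_of, tr$from, tr$to), key)

  anchor <- match("SC>GC", key)
  sym_pairs <- list(c(1L, 3L), c(2L, 5L), c(4L, 7L), c(6L, 8L))
  ctx_pairs <- list(c(5L, 7L), c(2L, 4L), c(1L, 6L), c(3L, 8L))

  # perm[i] = which transition row carries rate index i
  solutions <- list()
  assign_next <- function(perm, used) {
    i <- length(perm) + 1L
    if (i > 8L) {
      solutions[[length(solutions) + 1L]] <<- perm
      return(invisible())
    }
    for (t in seq_len(8L)) {
      if (used[t]) next
      cand <- c(perm, t)
      if (i == 3L && t != anchor) next
      ok <- TRUE
      for (p in sym_pairs) {
        if (max(p) > i) next
        if (cand[p[1]] != rev_idx[cand[p[2]]]) { ok <- FALSE; break }
      }
      if (ok) for (p in ctx_pairs) {
        if (max(p) > i) next
        if (cand[p[1]] != ctx_idx[cand[p[2]]]) { ok <- FALSE; break }
      }
      # (d): consecutive arrows 7->6->2->3 chain head-to-tail
      if (ok) {
        chain <- c(7L, 6L, 2L, 3L)
        for (j in seq_len(3L)) {
          a <- chain[j]; b <- chain[j + 1L]
          if (max(a, b) > i) next
          if (tr$to[cand[a]] != tr$from[cand[b]]) { ok <- FALSE; break }
        }
      }
      if (ok) assign_next(cand, `[<-`(used, t, TRUE))
    }
  }
  assign_next(integer(0), rep(FALSE, 8L))
  if (length(solutions) != 1L) {
    stop("rate-mapping constraints do not identify a unique numbering (",
         length(solutions), " solutions)")
  }
  perm <- solutions[[1]]
  data.frame(rate = 1:8, from = tr$from[perm], to = tr$to[perm],
             stringsAsFactors = FALSE)
}
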