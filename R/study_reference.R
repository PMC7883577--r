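#' Reference tip-state composition of the caterpillar dataset
#'
#' The published 676-species caterpillar dataset counts 541 solitary-cryptic,
#' 82 solitary-aposematic, 21 group-cryptic and 32 group-aposematic species
#' (80.0 / 12.1 / 3.1 / 4.7 percent). These counts are the calibration target
#' of [emulate_study_dataset()] and the input of composition cross-checks.
#'
#' @return List with `counts` (named integer 4-vector), `n` (total), and
#'   `freq` (relative frequencies).
#' @export
study_composition <- function() {
  counts <- c(SC = 541L, SA = 82L, GC = 21L, GA = 32L)
  list(counts = counts, n = sum(counts), freq = counts / sum(counts))
}

#' Published top-10 model comparison for the caterpillar dataset
#'
#' The printed ten best models of the 263-model sweep on the real
#' 676-species tree: model name, free-parameter count K and log-likelihood
#' (the inputs), together with the printed AIC, delta-AIC and evidence
#' (likelihood) ratio. Used to cross-check the AIC arithmetic of
#' [build_aic_table()] against an independently computed table; the printed
#' values carry three decimals, so recomputed columns agree to about one
#' unit in the last printed digit. Akaike weights are not reproducible from
#' these rows alone because the published weights are normalized over the
#' full 263-model set.
#'
#' @return data.frame with columns `model`, `K`, `logLik` and printed
#'   `AIC`, `dAIC`, `LikRatio`, `AkaikeWeight`.
#' @export
study_model_table <- function() {
  data.frame(
    model = c("n1", "eq24", "eq13", "n18", "general", "eq38", "eq16",
              "n8", "eq47", "eq57"),
    K = c(7L, 7L, 7L, 6L, 8L, 7L, 7L, 7L, 7L, 7L),
    logLik = c(-362.705, -362.754, -362.765, -364.216, -362.705, -363.804,
               -364.034, -364.216, -364.674, -365.874),
    AIC = c(739.410, 739.508, 739.530, 740.431, 741.410, 741.609, 742.068,
            742.431, 743.347, 745.748),
    dAIC = c(0.000, 0.099, 0.120, 1.022, 2.000, 2.199, 2.659, 3.022,
             3.938, 6.338),
    LikRatio = c(1.000, 0.952, 0.942, 0.600, 0.368, 0.333, 0.265, 0.221,
                 0.140, 0.042),
    AkaikeWeight = c(0.201, 0.192, 0.190, 0.121, 0.074, 0.067, 0.053,
                     0.044, 0.028, 0.009),
    stringsAsFactors = FALSE
  )
}
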