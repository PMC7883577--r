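#' AIC comparison table
#'
#' Builds the model-comparison table from a list of fits: AIC, delta-AIC
#' against the best model, the evidence (likelihood) ratio
#' `exp((AIC_min - AIC)/2)`, and Akaike weights normalized over all supplied
#' models. Rows are sorted by ascending AIC with ties broken by model name.
#'
#' @param fits list of `fit_result` objects (or anything with `name`, `K`,
#'   `loglik` fields) with unique names.
#' @return A data.frame of class `aic_table` with columns `model`, `K`,
#'   `logLik`, `AIC`, `dAIC`, `LikRatio`, `AkaikeWeight`, and (when
#'   available) `convergence` and `reducible` flags.
#' @export
build_aic_table <- function(fits) {
  if (!length(fits)) stop("no fits supplied")
  name <- vapply(fits, function(f) f$name, character(1))
  if (any(duplicated(name)))
    stop("duplicate model names: ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  K <- vapply(fits, function(f) as.integer(f$K), integer(1))
  loglik <- vapply(fits, function(f) as.numeric(f$loglik), numeric(1))
  aic <- 2 * K - 2 * loglik
  tab <- data.frame(model = name, K = K, logLik = loglik, AIC = aic,
                    stringsAsFactors = FALSE)
  conv <- vapply(fits, function(f)
    if (is.null(f$convergence)) NA else isTRUE(f$convergence), logical(1))
  red <- vapply(fits, function(f)
    if (is.null(f$reducible)) NA else isTRUE(f$reducible), logical(1))
  if (!all(is.na(conv))) tab$convergence <- conv
  if (!all(is.na(red))) tab$reducible <- red
  tab <- tab[order(tab$AIC, tab$model), , drop = FALSE]
  tab$dAIC <- tab$AIC - tab$AIC[1]
  tab$LikRatio <- exp(-tab$dAIC / 2)
  tab$AkaikeWeight <- tab$LikRatio / sum(tab$LikRatio)
  rownames(tab) <- NULL
  cols <- c("model", "K", "logLik", "AIC", "dAIC", "LikRatio", "AkaikeWeight")
  tab <- tab[, c(cols, setdiff(names(tab), cols)), drop = FALSE]
  class(tab) <- c("aic_table", "data.frame")
  tab
}

#' Fit the full model set and compare by AIC
#'
#' Fits every supplied spec (by default the whole space: the general model,
#' the 254 zero-constrained models and the 8 equality models, 263 in all) and
#' returns the AIC table plus all per-model fits. The general model is fitted
#' first and its MLE, projected onto each spec's constraints, seeds one start
#' of every constrained fit. With a `checkpoint_dir`, each completed fit is
#' written as `<name>.json` and re-runs skip models already on disk, so an
#' interrupted sweep resumes where it stopped.
#'
#' @param tree a `phylo` object.
#' @param states named character vector of tip states.
#' @param specs list of [model_spec()]s; defaults to [all_model_specs()].
#' @param settings a [fit_settings()].
#' @param root root policy.
#' @param checkpoint_dir optional directory for resumable per-model JSON.
#' @param progress print one line per model to stderr.
#' @return List with `table` (an `aic_table`), `fits` (named list of
#'   `fit_result`), and `failures` (named character vector of error messages,
#'   empty when all fits succeeded).
#' @export
run_model_selection <- function(tree, states, specs = all_model_specs(),
                                settings = fit_settings(), root = "flat",
                                checkpoint_dir = NULL, progress = FALSE) {
  specs <- lapply(specs, function(s)
    if (inherits(s, "model_spec")) s else model_spec_by_name(s))
  nm <- vapply(specs, function(s) s$name, character(1))
  if (any(duplicated(nm)))
    stop("duplicate specs: ", paste(unique(nm[duplicated(nm)]), collapse = ", "))
  if (!is.null(checkpoint_dir) && !dir.exists(checkpoint_dir))
    dir.create(checkpoint_dir, recursive = TRUE)

  fits <- list()
  failures <- character(0)
  # general model first: its MLE seeds the constrained fits
  init <- NULL
  ord <- order(nm != "general")
  for (i in ord) {
    spec <- specs[[i]]
    ckpt <- if (!is.null(checkpoint_dir))
      file.path(checkpoint_dir, paste0(spec$name, ".json")) else NULL
    fit <- NULL
    if (!is.null(ckpt) && file.exists(ckpt)) {
      fit <- tryCatch(fit_from_json(ckpt), error = function(e) NULL)
    }
    if (is.null(fit)) {
      fit <- tryCatch(
        fit_model(tree, states, spec, settings = settings, root = root,
                  init_rates = init),
        error = function(e) e)
      if (inherits(fit, "error")) {
        failures[spec$name] <- conditionMessage(fit)
        if (progress) message("  ", spec$name, ": FAILED (",
                              conditionMessage(fit), ")")
        next
      }
      if (!is.null(ckpt)) writeLines(fit_to_json(fit), ckpt)
    }
    fits[[spec$name]] <- fit
    if (spec$name == "general") init <- fit$rates
    if (progress) message(sprintf("  %s: logLik %.4f AIC %.4f",
                                  spec$name, fit$loglik, fit$aic))
  }
  if (!length(fits)) stop("all model fits failed")
  list(table = build_aic_table(fits), fits = fits, failures = failures)
}

#' Write an AIC table as TSV
#'
#' Columns exactly `model, K, logLik, AIC, dAIC, LikRatio, AkaikeWeight`;
#' flag columns (`convergence`, `reducible`) stay in the in-memory table
#' only.
#'
#' @param table an `aic_table`.
#' @param file output path.
#' @param top optional number of leading rows to write (e.g. 10).
#' @return The data.frame written, invisibly.
#' @export
write_aic_table_tsv <- function(table, file, top = NULL) {
  df <- as.data.frame(table)[, c("model", "K", "logLik", "AIC", "dAIC",
                                 "LikRatio", "AkaikeWeight")]
  if (!is.null(top)) df <- utils::head(df, top)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Read an AIC table written by [write_aic_table_tsv()]
#' @param file TSV path.
#' @return An `aic_table` data.frame.
#' @export
read_aic_table_tsv <- function(file) {
  tab <- utils::read.table(file, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  class(tab) <- c("aic_table", "data.frame")
  tab
}
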