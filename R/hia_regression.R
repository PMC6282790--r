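# Logit-linear modelling of percentage human intestinal absorption (%HIA) on
# micelle-water partition coefficient (log Pmw) and polar surface area (PSA):
# the base-10 logit transform, OLS with a full diagnostic suite (R^2 family,
# PRESS-based predictive R^2, standardized coefficients, VIF), backward
# elimination, prediction/back-transform, and reproduction of the reference
# 18-compound study.

#' Base-10 logit of %HIA
#'
#' `logit(%HIA) = log10(%HIA / (100 - %HIA))`. Defined only on the open
#' interval (0, 100): completely absorbed (100%) or unabsorbed (0%) compounds
#' have an infinite logit and must be excluded from (or only validate) a
#' logit-linear model.
#'
#' @param hia_percent %HIA value(s) in (0, 100).
#' @return Logit value(s), base 10.
#' @export
#' @examples
#' logit_hia(50)  # 0
#' logit_hia(82)  # 0.65851
logit_hia <- function(hia_percent) {
  hia_percent <- as.numeric(hia_percent)
  if (anyNA(hia_percent)) stop("%HIA contains missing values", call. = FALSE)
  if (any(hia_percent <= 0 | hia_percent >= 100))
    stop("%HIA of 0 or 100 has no finite logit; such compounds are removed ",
         "from the training set", call. = FALSE)
  log10(hia_percent / (100 - hia_percent))
}

#' Inverse base-10 logit, back to %HIA
#'
#' Exact inverse of [logit_hia()]: `100 * 10^L / (1 + 10^L)`.
#'
#' @param L Logit value(s), finite.
#' @return %HIA value(s) in (0, 100).
#' @export
#' @examples
#' inverse_logit_hia(0)  # 50
inverse_logit_hia <- function(L) {
  L <- as.numeric(L)
  if (anyNA(L) || any(!is.finite(L)))
    stop("logit values must be finite", call. = FALSE)
  100 * 10^L / (1 + 10^L)
}

round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

check_records <- function(records, predictors, need_hia = TRUE) {
  req <- c("name", predictors, if (need_hia) "hia_percent")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("compound table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  invisible(records)
}

#' Fit the logit-linear %HIA regression
#'
#' Ordinary least squares of base-10 logit(%HIA) on the named predictors over
#' the training compounds, with the full diagnostic suite: coefficient
#' standard errors, t statistics and two-sided p values, 95% confidence
#' intervals (t distribution, n - p - 1 df), standardized coefficients
#' (beta_j * sd(x_j) / sd(y)), variance inflation factors (1 / (1 - R^2) of
#' each predictor regressed on the others; 1 for a single predictor), R^2 and
#' adjusted R^2 on the 0-100% scale, PRESS-based predictive R^2 (see
#' [r_squared_pred()]), residual standard error S in logit units, and the
#' overall F statistic with its p value.
#'
#' @param records data.frame of compounds with columns `name`, the predictor
#'   columns, `hia_percent`, and optionally `role` (`train` / `validation` /
#'   `excluded`). Only `role == "train"` rows are fitted; rows with %HIA of
#'   exactly 0 or 100 are excluded from training regardless of role (with a
#'   message), mirroring the exclusion rule for infinite logits.
#' @param predictors Character vector of predictor column names (default
#'   `c("log_pmw", "psa")`).
#' @return An object of class `hia_fit`.
#' @export
#' @examples
#' fit <- fit_mlr(paper_compounds())
#' coef(fit)
fit_mlr <- function(records, predictors = c("log_pmw", "psa")) {
  check_records(records, predictors)
  if (!"role" %in% names(records)) records$role <- "train"
  train <- records[records$role == "train", , drop = FALSE]
  at_bound <- train$hia_percent <= 0 | train$hia_percent >= 100
  if (any(at_bound)) {
    message("excluding from training (no finite logit at %HIA 0 or 100): ",
            paste(train$name[at_bound], collapse = ", "))
    train <- train[!at_bound, , drop = FALSE]
  }
  n <- nrow(train); p <- length(predictors)
  if (n <= p + 1L)
    stop("need more training compounds (", n, ") than predictors + 1 (",
         p + 1L, ")", call. = FALSE)
  for (v in predictors)
    if (anyNA(train[[v]]) || any(!is.finite(train[[v]])))
      stop("predictor '", v, "' has missing or non-finite values", call. = FALSE)

  y <- logit_hia(train$hia_percent)
  dat <- cbind(data.frame(.logit_hia = y), train[, predictors, drop = FALSE])
  fml <- stats::as.formula(paste(".logit_hia ~",
                                 paste(predictors, collapse = " + ")))
  fit <- stats::lm(fml, data = dat)
  if (fit$rank < p + 1L) {
    dropped <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("singular design matrix; collinear predictor(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  sm <- quiet_summary(fit)
  cf <- sm$coefficients
  ci <- quiet_perfect_fit(stats::confint(fit, level = 0.95))

  sdy <- stats::sd(y)
  std_coef <- vapply(predictors, function(v)
    cf[v, "Estimate"] * stats::sd(train[[v]]) / sdy, numeric(1))

  vif <- if (p == 1L) stats::setNames(1, predictors) else {
    vapply(predictors, function(v) {
      r2 <- summary(stats::lm(
        stats::as.formula(paste(v, "~", paste(setdiff(predictors, v),
                                              collapse = " + "))),
        data = train))$r.squared
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }

  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  f_stat <- unname(sm$fstatistic[1])
  f_p <- stats::pf(f_stat, p, n - p - 1L, lower.tail = FALSE)

  out <- structure(list(
    lm_fit = fit,
    predictor_names = predictors,
    coefficients = stats::coef(fit),
    standard_errors = cf[, "Std. Error"],
    t_statistics = cf[, "t value"],
    p_values = cf[, "Pr(>|t|)"],
    confidence_intervals = ci,
    standardized_coefficients = std_coef,
    vif = vif,
    r_squared = 100 * sm$r.squared,
    r_squared_adjusted = 100 * sm$adj.r.squared,
    s = sm$sigma,
    f_statistic = f_stat,
    f_p_value = f_p,
    sse = sse, sst = sst,
    n_train = n,
    training_names = train$name
  ), class = "hia_fit")
  out$r_squared_pred <- r_squared_pred(out)
  out
}

#' @export
coef.hia_fit <- function(object, ...) object$coefficients

#' @export
print.hia_fit <- function(x, ...) {
  cat("Logit-linear %HIA model:", x$n_train, "training compounds\n")
  cat("  logit(%HIA) =",
      paste0(format(x$coefficients, digits = 5), c("",
             paste0(" * ", x$predictor_names)), collapse = " + "), "\n")
  tab <- data.frame(estimate = x$coefficients, se = x$standard_errors,
                    t = x$t_statistics, p = signif(x$p_values, 3),
                    ci_lo = x$confidence_intervals[, 1],
                    ci_hi = x$confidence_intervals[, 2])
  print(round(tab, 5))
  cat(sprintf("  std coef: %s | VIF: %s\n",
              paste(sprintf("%s=%.3f", x$predictor_names,
                            x$standardized_coefficients), collapse = ", "),
              paste(sprintf("%s=%.2f", x$predictor_names, x$vif),
                    collapse = ", ")))
  cat(sprintf("  R^2 = %.2f%%, adj = %.2f%%, pred = %.2f%%, S = %.4f, F = %.2f (p = %.3g)\n",
              x$r_squared, x$r_squared_adjusted, x$r_squared_pred, x$s,
              x$f_statistic, x$f_p_value))
  invisible(x)
}

#' PRESS-based predictive R^2
#'
#' Leave-one-out predictive R^2 computed from the PRESS statistic:
#' `PRESS = sum((e_i / (1 - h_ii))^2)` with ordinary residuals `e` and hat
#' (leverage) values `h`, and `R^2_PRED = 100 * (1 - PRESS / SS_total)`. The
#' hat-matrix identity gives exactly the deleted residuals of an explicit
#' leave-one-out refit. A leverage of 1 (a point fitted exactly by its own
#' omission pattern) leaves the deleted residual undefined and is an error.
#'
#' @param fit An `hia_fit` from [fit_mlr()], or any `lm` fit.
#' @return Predictive R^2 on the 0-100 scale.
#' @export
r_squared_pred <- function(fit) {
  lmf <- if (inherits(fit, "hia_fit")) fit$lm_fit else fit
  stopifnot(inherits(lmf, "lm"))
  h <- stats::hatvalues(lmf)
  if (any(h >= 1 - 1e-10))
    stop("leverage of 1: exact-fit point; PRESS undefined", call. = FALSE)
  e <- stats::residuals(lmf)
  press <- sum((e / (1 - h))^2)
  y <- stats::model.response(stats::model.frame(lmf))
  sst <- sum((y - mean(y))^2)
  100 * (1 - press / sst)
}

#' Backward elimination with VIF screening
#'
#' Two-phase predictor selection on the logit-linear %HIA model: first, while
#' any variance inflation factor exceeds `vif_limit`, the predictor with the
#' highest VIF is removed (collinearity screen); then, while the largest
#' predictor p value exceeds `alpha_remove`, that predictor is removed. The
#' model is refitted after every removal.
#'
#' @inheritParams fit_mlr
#' @param candidates Character vector of candidate predictor columns.
#' @param alpha_remove p-value threshold above which a predictor is dropped
#'   (default 0.05).
#' @param vif_limit VIF above which a predictor is considered collinear
#'   (default 10).
#' @return The final `hia_fit`, with an `elimination_log` data.frame attached
#'   (columns `step`, `predictor`, `reason`, `statistic`). If every candidate
#'   is eliminated an intercept-only fit is returned with a warning.
#' @export
backward_eliminate <- function(records, candidates, alpha_remove = 0.05,
                               vif_limit = 10) {
  if (length(candidates) < 1L)
    stop("need at least one candidate predictor", call. = FALSE)
  keep <- candidates
  log_rows <- list()
  step <- 0L
  fit <- NULL
  # VIFs from the raw predictor matrix over the training rows, so exact
  # collinearity (VIF = Inf) is screened out before any full model is fitted
  if (!"role" %in% names(records)) records$role <- "train"
  train <- records[records$role == "train" & records$hia_percent > 0 &
                     records$hia_percent < 100, , drop = FALSE]
  predictor_vifs <- function(vars) {
    vapply(vars, function(v) {
      r2 <- quiet_summary(stats::lm(
        stats::as.formula(paste(v, "~", paste(setdiff(vars, v),
                                              collapse = " + "))),
        data = train))$r.squared
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  # phase 1: collinearity screen
  while (length(keep) > 1L) {
    vifs <- predictor_vifs(keep)
    if (max(vifs) <= vif_limit) break
    worst <- names(which.max(vifs))
    step <- step + 1L
    log_rows[[step]] <- data.frame(step = step, predictor = worst,
                                   reason = "vif",
                                   statistic = unname(vifs[worst]))
    keep <- setdiff(keep, worst)
  }
  # phase 2: p-value elimination, refitting after each removal
  while (length(keep) > 0L) {
    fit <- fit_mlr(records, predictors = keep)
    pv <- fit$p_values[keep]
    if (max(pv) <= alpha_remove) break
    worst <- names(which.max(pv))
    step <- step + 1L
    log_rows[[step]] <- data.frame(step = step, predictor = worst,
                                   reason = "p_value",
                                   statistic = unname(pv[worst]))
    keep <- setdiff(keep, worst)
    fit <- NULL
  }
  if (length(keep) == 0L) {
    warning("all candidate predictors eliminated; returning intercept-only fit",
            call. = FALSE)
    if (!"role" %in% names(records)) records$role <- "train"
    train <- records[records$role == "train" & records$hia_percent > 0 &
                       records$hia_percent < 100, , drop = FALSE]
    y <- logit_hia(train$hia_percent)
    lmf <- stats::lm(y ~ 1)
    fit <- structure(list(lm_fit = lmf, predictor_names = character(),
                          coefficients = stats::coef(lmf),
                          n_train = length(y), training_names = train$name,
                          r_squared = 0, r_squared_adjusted = 0,
                          s = summary(lmf)$sigma), class = "hia_fit")
  }
  fit$elimination_log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(step = integer(), predictor = character(),
               reason = character(), statistic = numeric())
  fit
}

#' Predict %HIA from a fitted logit-linear model
#'
#' Evaluates the fitted logit and back-transforms with
#' [inverse_logit_hia()]. Rounded predictions use nearest-integer rounding,
#' half away from zero, for comparison against integer-printed tables.
#'
#' @param fit An `hia_fit`.
#' @param newdata data.frame with the fit's predictor columns (and optionally
#'   `name`), or omitted to use individual predictor vectors via `...`.
#' @param ... Named predictor vectors (e.g. `log_pmw = 2.96, psa = 72.7`)
#'   used when `newdata` is missing.
#' @return data.frame with columns `name` (if available), `hia_predicted`
#'   (unrounded %) and `hia_predicted_rounded`.
#' @export
#' @examples
#' fit <- fit_mlr(paper_compounds())
#' predict_hia(fit, log_pmw = 2.96, psa = 72.7)  # terbutaline -> 34
predict_hia <- function(fit, newdata = NULL, ...) {
  stopifnot(inherits(fit, "hia_fit"))
  if (is.null(newdata)) newdata <- data.frame(...)
  miss <- setdiff(fit$predictor_names, names(newdata))
  if (length(miss))
    stop("newdata is missing predictor column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  X <- as.matrix(newdata[, fit$predictor_names, drop = FALSE])
  L <- as.numeric(cbind(1, X) %*% fit$coefficients)
  out <- data.frame(hia_predicted = inverse_logit_hia(L))
  out$hia_predicted_rounded <- round_half_up(out$hia_predicted)
  if ("name" %in% names(newdata)) out <- cbind(name = newdata$name, out)
  out
}

#' Validate a fitted model on held-out compounds
#'
#' Predicts %HIA (unrounded) for each validation compound and reports the
#' absolute difference from the experimental value, plus the minimum and
#' maximum across the set.
#'
#' @param fit An `hia_fit`.
#' @param records data.frame of compounds; rows with `role == "validation"`
#'   are used (all rows if there is no `role` column).
#' @return A `hia_validation`: list with `table` (per-compound data.frame),
#'   `min_difference`, `max_difference`.
#' @export
validate_model <- function(fit, records) {
  check_records(records, fit$predictor_names)
  if ("role" %in% names(records))
    records <- records[records$role == "validation", , drop = FALSE]
  if (nrow(records) == 0L)
    stop("no validation compounds supplied", call. = FALSE)
  pred <- predict_hia(fit, records)
  tab <- data.frame(name = records$name,
                    hia_experimental = records$hia_percent,
                    hia_predicted = pred$hia_predicted,
                    hia_predicted_rounded = pred$hia_predicted_rounded,
                    abs_difference = abs(pred$hia_predicted -
                                           records$hia_percent))
  structure(list(table = tab,
                 min_difference = min(tab$abs_difference),
                 max_difference = max(tab$abs_difference)),
            class = "hia_validation")
}

#' @export
print.hia_validation <- function(x, ...) {
  cat("Validation on", nrow(x$table), "compound(s):\n")
  print(transform(x$table, hia_predicted = round(hia_predicted, 2),
                  abs_difference = round(abs_difference, 2)),
        row.names = FALSE)
  cat(sprintf("  |difference|: min %.2f, max %.2f percentage points\n",
              x$min_difference, x$max_difference))
  invisible(x)
}

#' Load the bundled 18-compound reference table
#'
#' The packaged compound table: experimentally determined log Pmw (from the
#' bile-salt/lecithin MLC system), literature polar surface area, experimental
#' %HIA and the train/validation role for each of the 18 reference compounds.
#' Acetaminophen, ibuprofen and salicylic acid are the designated validation
#' compounds; acetaminophen's %HIA of 100 also triggers the logit exclusion
#' rule, so both reasons coincide on its role flag.
#'
#' @return data.frame with columns `name`, `log_pmw`, `psa`, `hia_percent`,
#'   `role`, `reference`.
#' @export
paper_compounds <- function() {
  read_compound_table(system.file("extdata", "paper_table1_table2.csv",
                                  package = "mlcHIA", mustWork = TRUE))
}

#' Read / write the compound-table CSV dialect
#'
#' Columns: `name, log_pmw, psa, hia_percent, role, reference` (the last two
#' optional on read; `role` defaults to `train`).
#'
#' @param path File path.
#' @return `read_compound_table()`: a data.frame.
#'   `write_compound_table()`: `path`, invisibly.
#' @export
read_compound_table <- function(path) {
  if (!file.exists(path)) stop("compound table not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, comment.char = "#", strip.white = TRUE)
  check_records(tab, c("log_pmw", "psa"))
  if (!"role" %in% names(tab)) tab$role <- "train"
  tab
}

#' @rdname read_compound_table
#' @param table data.frame to write.
#' @param header_comments Character vector written as leading `#` lines.
#' @export
write_compound_table <- function(table, path, header_comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_comments)) writeLines(paste0("# ", header_comments), con)
  utils::write.csv(table, con, row.names = FALSE)
  invisible(path)
}

#' Export / import a fitted model as structured text
#'
#' JSON schema: `predictor_names`, `coefficients` (named, intercept first),
#' `standard_errors`, `n_train`, `training_names`, and a `diagnostics` block
#' (R^2 family, S, F). A reloaded model predicts identically; inference
#' fields beyond those stored are not reconstructed.
#'
#' @param fit An `hia_fit`.
#' @param path File path.
#' @return `write_hia_model()`: `path`, invisibly. `read_hia_model()`: an
#'   `hia_fit` restricted to prediction.
#' @export
write_hia_model <- function(fit, path) {
  stopifnot(inherits(fit, "hia_fit"))
  obj <- list(
    format = "mlcHIA/hia_fit/1",
    predictor_names = fit$predictor_names,
    coefficients = as.list(fit$coefficients),
    standard_errors = as.list(fit$standard_errors),
    n_train = fit$n_train,
    training_names = fit$training_names,
    diagnostics = list(r_squared = fit$r_squared,
                       r_squared_adjusted = fit$r_squared_adjusted,
                       r_squared_pred = fit$r_squared_pred,
                       s = fit$s, f_statistic = fit$f_statistic)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_hia_model
#' @export
read_hia_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || !startsWith(obj$format, "mlcHIA/hia_fit"))
    stop("not a serialized hia_fit: ", path, call. = FALSE)
  structure(list(
    predictor_names = obj$predictor_names,
    coefficients = unlist(obj$coefficients),
    standard_errors = unlist(obj$standard_errors),
    n_train = obj$n_train,
    training_names = obj$training_names,
    r_squared = obj$diagnostics$r_squared,
    r_squared_adjusted = obj$diagnostics$r_squared_adjusted,
    r_squared_pred = obj$diagnostics$r_squared_pred,
    s = obj$diagnostics$s,
    f_statistic = obj$diagnostics$f_statistic
  ), class = "hia_fit")
}
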