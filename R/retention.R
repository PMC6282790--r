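# Retention analysis: chromatogram peak picking, dead time, retention factors,
# and the reciprocal-retention (Armstrong-Nome) binding fit that yields the
# micelle-water partition coefficient log Pmw.

#' Create a chromatogram
#'
#' A uniformly sampled detector trace for one injection: time (min) against
#' detector response, with the compound label and the total surfactant
#' concentration of the mobile phase as metadata.
#'
#' @param time Sample times (min), strictly increasing, length >= 50.
#' @param signal Detector response, same length as `time`.
#' @param drug Compound label.
#' @param total_surfactant_M Total surfactant concentration of the mobile
#'   phase (M), or `NA`.
#' @return An object of class `chromatogram`.
#' @export
chromatogram <- function(time, signal, drug = "unknown",
                         total_surfactant_M = NA_real_) {
  time <- as.numeric(time); signal <- as.numeric(signal)
  if (length(time) != length(signal))
    stop("time and signal must have the same length", call. = FALSE)
  if (length(time) < 50L)
    stop("a chromatogram needs at least 50 samples", call. = FALSE)
  if (anyNA(time) || anyNA(signal))
    stop("time and signal must not contain missing values", call. = FALSE)
  if (any(diff(time) <= 0))
    stop("time must be strictly increasing", call. = FALSE)
  structure(list(time = time, signal = signal, drug = as.character(drug),
                 total_surfactant_M = as.numeric(total_surfactant_M)),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("Chromatogram: %s, %d samples over %.3g-%.3g min",
              x$drug, length(x$time), min(x$time), max(x$time)))
  if (!is.na(x$total_surfactant_M))
    cat(sprintf(", total surfactant %.4g M", x$total_surfactant_M))
  cat("\n")
  invisible(x)
}

# summary.lm warns on zero-residual fits; noise-free ground-truth data is a
# designed use case here, so that one warning is muffled.
quiet_perfect_fit <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

quiet_summary <- function(fit) quiet_perfect_fit(summary(fit))

moving_average <- function(x, window) {
  if (window <= 1L) return(x)
  s <- as.numeric(stats::filter(x, rep(1 / window, window), sides = 2))
  s[is.na(s)] <- x[is.na(s)]  # edges: fall back to the raw signal
  s
}

#' Locate the apex of a chromatographic peak
#'
#' Smooths the trace with a centred moving average and returns the time of the
#' global maximum. In `multi = TRUE` mode all local maxima whose height above
#' the median baseline exceeds a prominence threshold are returned, sorted by
#' time — useful when a solvent-front peak precedes the analyte peak.
#'
#' @param chrom A [chromatogram()].
#' @param smoothing_window Odd number of samples for the moving average
#'   (default 5; 1 disables smoothing).
#' @param multi If `TRUE`, return all prominent local maxima.
#' @param prominence Minimum height above the median baseline for a peak in
#'   multi mode. Default: 5 x the baseline noise SD estimated as the median
#'   absolute deviation of the first 5% of samples.
#' @param noise_floor Signals whose smoothed range (max - min) does not exceed
#'   this are considered flat and raise a "no peak detected" error.
#' @return Apex time(s) in min.
#' @export
#' @examples
#' tt <- seq(0, 10, by = 0.01)
#' ch <- chromatogram(tt, exp(-(tt - 4)^2 / (2 * 0.1^2)))
#' detect_apex(ch)  # ~4.0
detect_apex <- function(chrom, smoothing_window = 5L, multi = FALSE,
                        prominence = NULL, noise_floor = 0) {
  stopifnot(inherits(chrom, "chromatogram"))
  n <- length(chrom$signal)
  smoothing_window <- as.integer(smoothing_window)
  if (smoothing_window < 1L || smoothing_window >= n)
    stop("smoothing_window must be >= 1 and shorter than the trace",
         call. = FALSE)
  if (smoothing_window %% 2L == 0L)
    stop("smoothing_window must be odd", call. = FALSE)
  s <- moving_average(chrom$signal, smoothing_window)
  if ((max(s) - min(s)) <= noise_floor)
    stop("no peak detected: signal is flat (range <= noise floor)",
         call. = FALSE)
  if (!multi) return(chrom$time[which.max(s)])
  if (is.null(prominence)) {
    head_n <- max(5L, ceiling(0.05 * n))
    prominence <- 5 * stats::mad(chrom$signal[seq_len(head_n)])
  }
  base <- stats::median(s)
  is_max <- c(FALSE, diff(sign(diff(s))) < 0, FALSE)
  idx <- which(is_max & (s - base) > prominence)
  if (length(idx) == 0L)
    stop("no peak detected above the prominence threshold", call. = FALSE)
  chrom$time[sort(idx)]
}

#' Estimate the column dead time from solvent-front replicates
#'
#' The dead time t0 is the transit time of an unretained tracer. It is taken
#' as the arithmetic mean of replicate solvent-front times; the reference
#' protocol averages at least 10 recordings, so a warning is emitted for
#' smaller replicate sets.
#'
#' @param replicate_times Solvent-front times (min), all > 0.
#' @return A `dead_time_estimate`: list with `t0`, `n`, `sd`,
#'   `replicate_times`.
#' @export
#' @examples
#' estimate_dead_time(rep(1.5, 10))
estimate_dead_time <- function(replicate_times) {
  replicate_times <- as.numeric(replicate_times)
  if (length(replicate_times) == 0L)
    stop("no solvent-front replicates supplied", call. = FALSE)
  if (anyNA(replicate_times) || any(replicate_times <= 0))
    stop("solvent-front times must all be positive", call. = FALSE)
  n <- length(replicate_times)
  if (n < 10L)
    warning("dead time estimated from ", n,
            " replicate(s); protocol calls for an average of at least 10",
            call. = FALSE)
  structure(list(t0 = mean(replicate_times), n = n,
                 sd = if (n > 1L) stats::sd(replicate_times) else 0,
                 replicate_times = replicate_times),
            class = "dead_time_estimate")
}

#' @export
print.dead_time_estimate <- function(x, ...) {
  cat(sprintf("Dead time t0 = %.4g min (n = %d, sd = %.3g)\n", x$t0, x$n, x$sd))
  invisible(x)
}

#' Retention factor k'
#'
#' `k' = (retention time - dead time) / dead time`. Dimensionless; 0 for an
#' unretained solute. A retention time before the solvent front is an error.
#'
#' @param retention_time_min Retention time(s) (min).
#' @param t0_min Dead time (min, > 0), or a `dead_time_estimate`.
#' @return k' (vectorised over `retention_time_min`).
#' @export
#' @examples
#' retention_factor(6, 3)  # 1
retention_factor <- function(retention_time_min, t0_min) {
  if (inherits(t0_min, "dead_time_estimate")) t0_min <- t0_min$t0
  t0_min <- as.numeric(t0_min)
  retention_time_min <- as.numeric(retention_time_min)
  if (length(t0_min) != 1L || is.na(t0_min) || t0_min <= 0)
    stop("t0 must be a single positive dead time", call. = FALSE)
  if (anyNA(retention_time_min) || any(retention_time_min < t0_min))
    stop("retention time before the solvent front (rt < t0)", call. = FALSE)
  (retention_time_min - t0_min) / t0_min
}

#' Assemble a per-drug binding series
#'
#' Collects (C_M, k') observations for one compound. Replicate k' values at
#' the same micellar concentration are averaged first, and the reciprocal of
#' the mean k' is the regression observation used by [fit_binding_model()].
#'
#' @param drug Compound label.
#' @param cm Micellar concentrations C_M (M), one per observation.
#' @param k_prime Retention factors, same length as `cm`; all > 0 for the
#'   reciprocal fit.
#' @return A `binding_series`: data.frame of per-level mean k' and 1/k' with
#'   attributes `drug` and `n_replicates`.
#' @export
binding_series <- function(drug, cm, k_prime) {
  cm <- as.numeric(cm); k_prime <- as.numeric(k_prime)
  if (length(cm) != length(k_prime))
    stop("cm and k_prime must have the same length", call. = FALSE)
  if (anyNA(cm) || any(cm < 0))
    stop("micellar concentrations must be >= 0", call. = FALSE)
  if (anyNA(k_prime) || any(k_prime <= 0))
    stop("all k' must be > 0 for the reciprocal fit", call. = FALSE)
  mk <- tapply(k_prime, cm, mean)
  levels <- as.numeric(names(mk))
  out <- data.frame(cm = levels, k_prime_mean = as.numeric(mk),
                    inv_k_prime = 1 / as.numeric(mk))
  out <- out[order(out$cm), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "drug") <- as.character(drug)
  attr(out, "n_replicates") <- as.integer(table(cm)[as.character(out$cm)])
  class(out) <- c("binding_series", "data.frame")
  out
}

#' Fit the reciprocal-retention binding model
#'
#' Ordinary least squares of 1/k' (per-level mean) on the micellar
#' concentration C_M. For a binding solute `1/k' = 1/k0 + (K_AM/k0) C_M`, so
#' the micelle-solute association constant is K_AM = slope/intercept and the
#' micelle-water partition coefficient is `log Pmw = log10(K_AM)`. The
#' literal intercept/slope ratio is available via `convention =
#' "intercept_over_slope"`; every fit records which convention produced it.
#'
#' Binding classification uses a two-sided t test on the slope: `binding` if
#' significantly positive, `antibinding` if significantly negative, otherwise
#' `none` (in which case `log_pmw` is `NA` and `reason` says why).
#'
#' @param series A [binding_series()].
#' @param alpha Significance level for the slope t test (default 0.05).
#' @param convention `"slope_over_intercept"` (default) or
#'   `"intercept_over_slope"`.
#' @return A `binding_fit`: list with `drug`, `slope`, `intercept`, `k_am`,
#'   `log_pmw`, `binding_class`, `r_squared`, `slope_p_value`, `convention`,
#'   `n_levels`, `reason`.
#' @export
#' @examples
#' cm <- c(0.0004, 0.002, 0.005, 0.009, 0.0124)
#' bs <- binding_series("demo", cm, 10 / (1 + 40 * cm))
#' fit_binding_model(bs)$log_pmw  # log10(40)
fit_binding_model <- function(series, alpha = 0.05,
                              convention = c("slope_over_intercept",
                                             "intercept_over_slope")) {
  stopifnot(inherits(series, "binding_series"))
  convention <- match.arg(convention)
  if (nrow(series) < 3L)
    stop("need at least 3 distinct micellar concentrations to fit",
         call. = FALSE)
  fit <- stats::lm(inv_k_prime ~ cm, data = series)
  cf <- quiet_summary(fit)$coefficients
  slope <- cf["cm", "Estimate"]; intercept <- cf["(Intercept)", "Estimate"]
  slope_p <- cf["cm", "Pr(>|t|)"]
  # exactly collinear points leave a 0/0 t test; treat as decisively sloped
  if (is.nan(slope_p)) slope_p <- if (abs(slope) > 0) 0 else 1
  int_p <- cf["(Intercept)", "Pr(>|t|)"]
  if (is.nan(int_p)) int_p <- if (abs(intercept) > 0) 0 else 1
  if (intercept <= 0)
    stop("non-physical fit: 1/k' intercept <= 0", call. = FALSE)
  if (slope_p >= alpha && int_p >= alpha && !(is.nan(slope_p) || is.nan(int_p)))
    stop("slope and intercept both indistinguishable from 0", call. = FALSE)
  binding_class <- if (slope_p < alpha && slope > 0) "binding"
    else if (slope_p < alpha && slope < 0) "antibinding"
    else "none"
  k_am <- switch(convention,
                 slope_over_intercept = slope / intercept,
                 intercept_over_slope = intercept / slope)
  reason <- NA_character_
  log_pmw <- NA_real_
  if (binding_class == "binding" && k_am > 0) {
    log_pmw <- log10(k_am)
  } else if (binding_class == "none") {
    reason <- "no concentration dependence: slope not distinguishable from 0"
  } else if (binding_class == "antibinding") {
    reason <- "antibinding solute: association constant not defined"
  }
  structure(list(drug = attr(series, "drug"), slope = slope,
                 intercept = intercept, k_am = k_am, log_pmw = log_pmw,
                 binding_class = binding_class,
                 r_squared = quiet_summary(fit)$r.squared,
                 slope_p_value = slope_p, convention = convention,
                 n_levels = nrow(series), reason = reason),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("Binding fit [%s]: %s\n", x$drug, x$binding_class))
  cat(sprintf("  1/k' = %.5g + %.5g * C_M  (R^2 = %.4f, %d levels)\n",
              x$intercept, x$slope, x$r_squared, x$n_levels))
  if (!is.na(x$log_pmw))
    cat(sprintf("  K_AM = %.5g M^-1 (%s), log Pmw = %.4f\n",
                x$k_am, x$convention, x$log_pmw))
  else cat("  log Pmw: NA (", x$reason, ")\n", sep = "")
  invisible(x)
}

#' Tabulate log Pmw across a collection of binding series
#'
#' Fits each drug's series with [fit_binding_model()]; per-drug failures are
#' captured in the table (NA `log_pmw` with the error message in `reason`)
#' rather than aborting the whole collection.
#'
#' @param series_list List of [binding_series()] objects.
#' @param ... Passed to [fit_binding_model()].
#' @return data.frame with columns `drug`, `slope`, `intercept`, `k_am`,
#'   `log_pmw`, `r_squared`, `binding_class`, `convention`, `reason`.
#' @export
logpmw_table <- function(series_list, ...) {
  cols <- c("drug", "slope", "intercept", "k_am", "log_pmw", "r_squared",
            "binding_class", "convention", "reason")
  if (length(series_list) == 0L) {
    empty <- data.frame(drug = character(), slope = numeric(),
                        intercept = numeric(), k_am = numeric(),
                        log_pmw = numeric(), r_squared = numeric(),
                        binding_class = character(), convention = character(),
                        reason = character(), stringsAsFactors = FALSE)
    return(empty[, cols])
  }
  rows <- lapply(series_list, function(bs) {
    drug <- attr(bs, "drug")
    res <- tryCatch(fit_binding_model(bs, ...), error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(drug = drug, slope = NA_real_, intercept = NA_real_,
                 k_am = NA_real_, log_pmw = NA_real_, r_squared = NA_real_,
                 binding_class = NA_character_, convention = NA_character_,
                 reason = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      data.frame(drug = res$drug, slope = res$slope, intercept = res$intercept,
                 k_am = res$k_am, log_pmw = res$log_pmw,
                 r_squared = res$r_squared, binding_class = res$binding_class,
                 convention = res$convention, reason = res$reason,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, cols]
}

#' Build binding series from a retention-time table
#'
#' Converts a long-format retention table (one row per injection) into a list
#' of per-drug [binding_series()]. Micellar concentration is taken from a
#' `cm` column if present, otherwise computed as `total_conc_M - cmc_M`.
#'
#' @param table data.frame with columns `drug`, `retention_time_min`, and
#'   either `cm` or `total_conc_M`; an optional `replicate` column is ignored.
#' @param t0_min Dead time (min) or [estimate_dead_time()] result.
#' @param cmc_M Mixture CMC (M); required when only `total_conc_M` is present.
#' @return Named list of [binding_series()].
#' @export
retention_table_to_series <- function(table, t0_min, cmc_M = NULL) {
  req <- c("drug", "retention_time_min")
  if (!all(req %in% names(table)))
    stop("retention table must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if ("cm" %in% names(table)) {
    cm <- as.numeric(table$cm)
  } else if ("total_conc_M" %in% names(table)) {
    if (is.null(cmc_M))
      stop("cmc_M is required to convert total_conc_M to micellar concentration",
           call. = FALSE)
    cm <- micellar_concentration(as.numeric(table$total_conc_M), cmc_M)
  } else {
    stop("retention table needs a 'cm' or 'total_conc_M' column", call. = FALSE)
  }
  kp <- retention_factor(table$retention_time_min, t0_min)
  split_idx <- split(seq_len(nrow(table)), table$drug)
  lapply(split_idx, function(i) binding_series(table$drug[i[1]], cm[i], kp[i]))
}

#' Read / write the retention-table CSV dialect
#'
#' Long format, one row per injection: `drug, total_conc_M (or cm),
#' replicate, retention_time_min`. Comment lines starting with `#` carry
#' provenance (seed, generator settings) and are skipped on read.
#'
#' @param path File path.
#' @return `read_retention_table()`: a data.frame. `write_retention_table()`:
#'   `path`, invisibly.
#' @export
read_retention_table <- function(path) {
  if (!file.exists(path)) stop("retention table not found: ", path, call. = FALSE)
  tab <- tryCatch(
    utils::read.csv(path, comment.char = "#", strip.white = TRUE),
    error = function(e) stop("malformed retention CSV ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(tab) == 0L) stop("retention table ", path, " is empty", call. = FALSE)
  tab
}

#' @rdname read_retention_table
#' @param table data.frame to write.
#' @param header_comments Character vector written as leading `#` lines.
#' @export
write_retention_table <- function(table, path, header_comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_comments))
    writeLines(paste0("# ", header_comments), con)
  utils::write.csv(table, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write the chromatogram CSV dialect
#'
#' Two columns (`time_min`, `signal`), comma- or tab-delimited, with leading
#' `#` comment lines carrying `drug=` and `total_surfactant_M=` metadata.
#'
#' @param path File path.
#' @return `read_chromatogram()`: a [chromatogram()].
#'   `write_chromatogram()`: `path`, invisibly.
#' @export
read_chromatogram <- function(path) {
  if (!file.exists(path)) stop("chromatogram not found: ", path, call. = FALSE)
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  drug <- "unknown"; total <- NA_real_
  m <- regmatches(meta, regexpr("drug=[^,;]+", meta))
  if (length(m)) drug <- trimws(sub("drug=", "", m[1]))
  m <- regmatches(meta, regexpr("total_surfactant_M=[0-9.eE+-]+", meta))
  if (length(m)) total <- as.numeric(sub("total_surfactant_M=", "", m[1]))
  sep <- if (any(grepl("\t", lines[!startsWith(lines, "#")][1]))) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#")
  chromatogram(tab[[1]], tab[[2]], drug = drug, total_surfactant_M = total)
}

#' @rdname read_chromatogram
#' @param chrom A [chromatogram()] to write.
#' @export
write_chromatogram <- function(chrom, path) {
  stopifnot(inherits(chrom, "chromatogram"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# drug=%s, total_surfactant_M=%s", chrom$drug,
                     format(chrom$total_surfactant_M)), con)
  utils::write.csv(data.frame(time_min = chrom$time, signal = chrom$signal),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
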