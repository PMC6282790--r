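# Mixed bile-salt/lecithin micellar system arithmetic: composition bookkeeping,
# mixture CMC, micellar concentration and dilution-series design.

#' Create a surfactant component
#'
#' A single surfactant (typically a bile salt) in a mixed micellar system,
#' with its preparation concentration and, optionally, the critical micellar
#' concentration (CMC) of the pure component under the working ionic strength
#' (0.15 M NaCl in the reference system).
#'
#' @param name Short label, e.g. `"NaTC"`. Must be non-empty.
#' @param conc_mM Molar concentration in the mixture (mM, >= 0).
#' @param cmc_M CMC of the pure component (M, > 0), or `NA` if unknown.
#'
#' @return An object of class `surfactant_component`.
#' @seealso [micellar_mixture()]
#' @export
#' @examples
#' surfactant_component("NaTC", conc_mM = 2.71, cmc_M = 0.004)
surfactant_component <- function(name, conc_mM, cmc_M = NA_real_) {
  if (!is.character(name) || length(name) != 1L || is.na(name) || !nzchar(name))
    stop("component 'name' must be a non-empty string", call. = FALSE)
  conc_mM <- as.numeric(conc_mM)
  cmc_M <- as.numeric(cmc_M)
  if (length(conc_mM) != 1L || is.na(conc_mM) || conc_mM < 0)
    stop("component '", name, "': conc_mM must be a single value >= 0",
         call. = FALSE)
  if (!is.na(cmc_M) && cmc_M <= 0)
    stop("component '", name, "': cmc_M must be > 0 when provided",
         call. = FALSE)
  structure(list(name = name, conc_mM = conc_mM, cmc_M = cmc_M),
            class = "surfactant_component")
}

#' Create a mixed micellar system description
#'
#' Describes a mixed bile-salt/lecithin micellar mobile phase: the bile-salt
#' components with their concentrations and CMCs, plus lecithin, counterion
#' and pH bookkeeping. The total bile-salt concentration and the mixture CMC
#' are derived, not stored: the total is the sum of the bile-salt component
#' concentrations (lecithin is tracked separately), and the mixture CMC is the
#' unweighted mean of the component CMCs.
#'
#' @param components List of [surfactant_component()] objects with unique names.
#' @param lecithin_mM Lecithin (phosphatidylcholine) concentration (mM).
#' @param nacl_M Background counterion (NaCl) concentration (M), informational.
#' @param ph Buffer pH, informational.
#'
#' @return An object of class `micellar_mixture`.
#' @export
#' @examples
#' mix <- paper_micellar_system()
#' total_concentration(mix)   # 17 mM
#' mixture_cmc(mix)           # ~0.0046 M
micellar_mixture <- function(components, lecithin_mM = 0, nacl_M = NA_real_,
                             ph = NA_real_) {
  if (!is.list(components) || length(components) == 0L)
    stop("a micellar mixture needs at least one surfactant component",
         call. = FALSE)
  ok <- vapply(components, inherits, logical(1), "surfactant_component")
  if (!all(ok))
    stop("'components' must all be surfactant_component objects", call. = FALSE)
  nm <- vapply(components, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop("duplicate component names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  lecithin_mM <- as.numeric(lecithin_mM)
  if (is.na(lecithin_mM) || lecithin_mM < 0)
    stop("lecithin_mM must be >= 0", call. = FALSE)
  structure(list(components = components, lecithin_mM = lecithin_mM,
                 nacl_M = as.numeric(nacl_M), ph = as.numeric(ph)),
            class = "micellar_mixture")
}

#' @export
print.micellar_mixture <- function(x, ...) {
  cat("Mixed micellar system:", length(x$components), "bile-salt component(s)\n")
  df <- as.data.frame(x)
  print(df, row.names = FALSE)
  cat(sprintf("total bile salt: %.2f mM; lecithin: %.2f mM\n",
              total_concentration(x), x$lecithin_mM))
  cmc <- tryCatch(mixture_cmc(x), error = function(e) NA_real_)
  if (!is.na(cmc)) cat(sprintf("mixture CMC (mean of component CMCs): %.4g M\n", cmc))
  if (!is.na(x$nacl_M)) cat(sprintf("NaCl: %.3g M", x$nacl_M))
  if (!is.na(x$ph)) cat(sprintf("; pH %.2f", x$ph))
  if (!is.na(x$nacl_M) || !is.na(x$ph)) cat("\n")
  invisible(x)
}

#' @export
as.data.frame.micellar_mixture <- function(x, ...) {
  data.frame(
    name = vapply(x$components, `[[`, character(1), "name"),
    conc_mM = vapply(x$components, `[[`, numeric(1), "conc_mM"),
    cmc_M = vapply(x$components, `[[`, numeric(1), "cmc_M"),
    stringsAsFactors = FALSE
  )
}

#' Total bile-salt concentration of a mixture
#'
#' Sum of the bile-salt component concentrations in mM. Lecithin is tracked
#' separately on the mixture and is not included: the conventional description
#' of such mobile phases (e.g. a "17 mM" stock) refers to the bile-salt total.
#'
#' @param mixture A [micellar_mixture()], or a numeric vector of component
#'   concentrations in mM.
#' @return Total concentration (mM).
#' @export
#' @examples
#' total_concentration(c(2.71, 2.00, 2.08, 2.08, 4.70, 3.43))  # 17
total_concentration <- function(mixture) {
  conc <- if (inherits(mixture, "micellar_mixture")) {
    vapply(mixture$components, `[[`, numeric(1), "conc_mM")
  } else {
    as.numeric(mixture)
  }
  if (length(conc) == 0L)
    stop("cannot compute a total over an empty component list", call. = FALSE)
  if (anyNA(conc) || any(conc < 0))
    stop("component concentrations must be non-negative and non-missing",
         call. = FALSE)
  sum(conc)
}

#' Mixture CMC as the mean of component CMCs
#'
#' The critical micellar concentration of a mixed micellar system is taken as
#' the unweighted arithmetic mean of the pure-component CMCs. For the
#' six-bile-salt reference system this gives 0.0046 M (2 significant figures).
#'
#' @param x A [micellar_mixture()], a list of [surfactant_component()]s, or a
#'   numeric vector of CMCs (M).
#' @return Mixture CMC (M).
#' @export
#' @examples
#' mixture_cmc(c(0.004, 0.0024, 0.0024, 0.0075, 0.009, 0.0022))
mixture_cmc <- function(x) {
  if (inherits(x, "micellar_mixture")) x <- x$components
  if (is.list(x)) {
    nm <- vapply(x, `[[`, character(1), "name")
    cmc <- vapply(x, `[[`, numeric(1), "cmc_M")
    if (anyNA(cmc))
      stop("missing CMC for component(s): ",
           paste(nm[is.na(cmc)], collapse = ", "), call. = FALSE)
  } else {
    cmc <- as.numeric(x)
    if (length(cmc) == 0L || anyNA(cmc))
      stop("missing CMC value(s)", call. = FALSE)
  }
  if (any(cmc <= 0)) stop("CMC values must be > 0", call. = FALSE)
  mean(cmc)
}

#' Micellar concentration C_M
#'
#' Concentration of surfactant present as micelles: total surfactant
#' concentration minus the CMC. Below the CMC no micellar phase exists and an
#' error is raised.
#'
#' @param total_M Total surfactant concentration (M).
#' @param cmc_M Mixture CMC (M).
#' @return C_M in M (vectorised over `total_M`).
#' @export
#' @examples
#' micellar_concentration(0.017, 0.0046)  # 0.0124
micellar_concentration <- function(total_M, cmc_M) {
  total_M <- as.numeric(total_M)
  cmc_M <- as.numeric(cmc_M)
  if (length(cmc_M) != 1L || is.na(cmc_M) || cmc_M < 0)
    stop("cmc_M must be a single value >= 0", call. = FALSE)
  if (anyNA(total_M)) stop("total_M contains missing values", call. = FALSE)
  if (any(total_M < cmc_M))
    stop("total surfactant concentration ",
         paste(format(total_M[total_M < cmc_M]), collapse = ", "),
         " M is below the CMC (", format(cmc_M),
         " M); no micellar phase", call. = FALSE)
  total_M - cmc_M
}

#' Design a dilution series from a micellar stock
#'
#' Computes, for each target concentration, the volume fraction of stock to
#' mix with diluent so that `target = f * stock + (1 - f) * diluent`. The
#' diluent is itself a surfactant solution at the constant monomer
#' concentration (2 mM in the reference protocol), so pure diluent is not a
#' valid micellar test level: targets must lie in `(diluent, stock]`.
#'
#' @param stock_mM Stock concentration (mM).
#' @param diluent_mM Diluent concentration (mM), strictly below `stock_mM`.
#' @param targets_mM Target concentrations (mM).
#' @return A `dilution_plan`: data.frame with columns `target_mM` and
#'   `stock_fraction`, plus attributes `stock_mM` and `diluent_mM`.
#' @export
#' @examples
#' dilution_fractions(17, 2, c(5, 9.5, 12, 17))
dilution_fractions <- function(stock_mM, diluent_mM, targets_mM) {
  stock_mM <- as.numeric(stock_mM); diluent_mM <- as.numeric(diluent_mM)
  targets_mM <- as.numeric(targets_mM)
  if (is.na(stock_mM) || is.na(diluent_mM) || diluent_mM >= stock_mM)
    stop("diluent concentration must be strictly below the stock concentration",
         call. = FALSE)
  bad <- is.na(targets_mM) | targets_mM <= diluent_mM | targets_mM > stock_mM
  if (any(bad))
    stop("target(s) outside (diluent, stock] = (", format(diluent_mM), ", ",
         format(stock_mM), "] mM: ",
         paste(format(targets_mM[bad]), collapse = ", "), call. = FALSE)
  plan <- data.frame(target_mM = targets_mM,
                     stock_fraction = (targets_mM - diluent_mM) /
                       (stock_mM - diluent_mM))
  attr(plan, "stock_mM") <- stock_mM
  attr(plan, "diluent_mM") <- diluent_mM
  class(plan) <- c("dilution_plan", "data.frame")
  plan
}

#' @export
print.dilution_plan <- function(x, ...) {
  cat(sprintf("Dilution plan: stock %.3g mM, diluent %.3g mM\n",
              attr(x, "stock_mM"), attr(x, "diluent_mM")))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Write a dilution plan to CSV
#'
#' @param plan A `dilution_plan` from [dilution_fractions()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dilution_plan <- function(plan, path) {
  stopifnot(inherits(plan, "dilution_plan"))
  utils::write.csv(as.data.frame(plan)[, c("target_mM", "stock_fraction")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a micellar system description from a YAML config
#'
#' Schema: `components` is a list of maps with keys `name`, `conc_mM`,
#' `cmc_M`; top-level keys `lecithin_mM`, `nacl_M`, `ph` are optional.
#'
#' @param path Path to a YAML file.
#' @return A [micellar_mixture()].
#' @export
read_micellar_system <- function(path) {
  if (!file.exists(path))
    stop("micellar system config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$components))
    stop("config ", path, " has no 'components' block", call. = FALSE)
  comps <- lapply(cfg$components, function(cc) {
    surfactant_component(cc$name, cc$conc_mM,
                         if (is.null(cc$cmc_M)) NA_real_ else cc$cmc_M)
  })
  micellar_mixture(comps,
                   lecithin_mM = if (is.null(cfg$lecithin_mM)) 0 else cfg$lecithin_mM,
                   nacl_M = if (is.null(cfg$nacl_M)) NA_real_ else cfg$nacl_M,
                   ph = if (is.null(cfg$ph)) NA_real_ else cfg$ph)
}

#' The bundled six-bile-salt/lecithin reference system
#'
#' Loads the packaged description of the physiologically mimetic mobile phase:
#' six bile salts (NaTC, NaTDC, NaDC, NaC, NaGC, NaGDC) totalling 17 mM with
#' 0.75 mM lecithin in 0.15 M NaCl at pH 6.5, and the component CMCs whose
#' mean gives the 0.0046 M mixture CMC.
#'
#' @return A [micellar_mixture()].
#' @export
paper_micellar_system <- function() {
  read_micellar_system(system.file("extdata", "micellar_system_paper.yaml",
                                   package = "mlcHIA", mustWork = TRUE))
}
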