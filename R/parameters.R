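#' @useDynLib camposc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

PAR_NAMES <- c("gNaF", "gNaP", "gKS", "gL", "gHCN", "gM", "dgHCN", "dgM",
               "ENa", "EK", "EL", "EHCN", "Cm", "IApp", "cAMP",
               "T", "Tref1", "Tref2", "Qm", "Qn", "Qh", "Qs", "Qr")

#' Default model parameters of the cAMP-modulated pyramidal neuron model
#'
#' Constructs the parameter set of the five-variable conductance-based model:
#' maximal conductances (mS/cm^2) of the fast and persistent Na+, slow K+,
#' leak, HCN and M currents, the cAMP-induced conductance increments of the
#' latter two, reversal potentials (mV), membrane capacitance (uF/cm^2),
#' applied current density (uA/cm^2), the binary cAMP flag, and the
#' temperatures and Q10 factors entering the rate corrections.
#'
#' @param ... named overrides of any default value, e.g. `IApp = 300`,
#'   `cAMP = 1`.
#' @return An object of class `neuron_parameters` (a named list).
#' @examples
#' p <- neuron_parameters(IApp = 250)
#' p$gNaF
#' @export
neuron_parameters <- function(...) {
  p <- list(
    gNaF = 1000, gNaP = 1, gKS = 40, gL = 11.3, gHCN = 23, gM = 50,
    dgHCN = 12, dgM = 50,
    ENa = 50, EK = -84, EL = -83.38, EHCN = -50,
    Cm = 0.9, IApp = 0, cAMP = 0,
    T = 37, Tref1 = 20, Tref2 = 35,
    Qm = 2.2, Qn = 2.2, Qh = 2.9, Qs = 3.0, Qr = 3.0)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(over)] <- over
  }
  validate_parameters(p)
  structure(p, class = "neuron_parameters")
}

validate_parameters <- function(p) {
  cond <- c("gNaF", "gNaP", "gKS", "gL", "gHCN", "gM", "dgHCN", "dgM")
  for (nm in cond) {
    if (!is.finite(p[[nm]]) || p[[nm]] < 0)
      stop("conductance ", nm, " must be finite and >= 0")
  }
  if (!is.finite(p$Cm) || p$Cm <= 0) stop("Cm must be positive")
  if (!(p$cAMP %in% c(0, 1))) stop("cAMP must be 0 or 1")
  for (nm in c("Qm", "Qn", "Qh", "Qs", "Qr")) {
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      stop("Q factor ", nm, " must be positive")
  }
  invisible(p)
}

#' @export
print.neuron_parameters <- function(x, ...) {
  cat("Neuron model parameters\n")
  v <- unlist(x[PAR_NAMES])
  print(v)
  invisible(x)
}

as_par_vector <- function(p) {
  stopifnot(inherits(p, "neuron_parameters") || is.list(p))
  v <- vapply(PAR_NAMES, function(nm) as.numeric(p[[nm]]), numeric(1))
  names(v) <- PAR_NAMES
  v
}

# Drug-condition presets: overrides of (gM, dgM, gHCN, dgHCN, cAMP).
CONDITION_TABLE <- data.frame(
  name  = c("Ctrl", "CGS", "ZD", "ZD+CGS", "XE", "XE+CGS", "FSK", "FSK+Lin"),
  gM    = c(50, 50, 50, 50, 0, 0, 50, 50),
  dgM   = c(50, 50, 50, 50, 0, 0, 50, 20),
  gHCN  = c(23, 23, 0, 0, 23, 23, 23, 23),
  dgHCN = c(12, 12, 0, 0, 12, 12, 12, 12),
  cAMP  = c(0, 1, 0, 1, 0, 1, 1, 1),
  stringsAsFactors = FALSE)

#' Names of the available drug-condition presets
#' @return Character vector of condition names.
#' @export
condition_names <- function() CONDITION_TABLE$name

#' Parameter set for a named drug condition
#'
#' Each condition maps a drug combination of the underlying experiments
#' (control, the A2aR agonist CGS21680, the HCN blocker ZD7288, the M-channel
#' blockers XE991 and Linopirdine, and the adenylate-cyclase activator
#' Forskolin) to overrides of the M and HCN conductances, their cAMP-induced
#' increments, and the binary cAMP flag.
#'
#' @param name one of [condition_names()].
#' @param base parameters to overwrite; defaults to [neuron_parameters()].
#' @param IApp optional applied current density (uA/cm^2) set on the result.
#' @return A `neuron_parameters` object.
#' @examples
#' condition_params("CGS", IApp = 300)
#' @export
condition_params <- function(name, base = neuron_parameters(), IApp = NULL) {
  i <- match(name, CONDITION_TABLE$name)
  if (is.na(i)) {
    stop("unknown condition '", name, "'; valid names: ",
         paste(CONDITION_TABLE$name, collapse = ", "))
  }
  row <- CONDITION_TABLE[i, ]
  for (nm in c("gM", "dgM", "gHCN", "dgHCN", "cAMP")) base[[nm]] <- row[[nm]]
  if (!is.null(IApp)) base$IApp <- IApp
  validate_parameters(base)
  structure(base, class = "neuron_parameters")
}

#' Temperature correction factor
#'
#' Q10-type rate scaling `Q^((T - T_ref)/10)`. The HCN gate uses the
#' reference temperature of 35 degC at which HCN channel properties were
#' characterized; the Na+/K+ gating rates use 20 degC.
#'
#' @param Q dimensionless Q10 factor (> 0).
#' @param T temperature (degC).
#' @param T_ref reference temperature (degC).
#' @return The dimensionless rate multiplier.
#' @examples
#' temperature_factor(3, 37, 35)
#' @export
temperature_factor <- function(Q, T, T_ref) {
  if (any(!is.finite(Q)) || any(Q <= 0))
    stop("invalid parameter: Q must be positive")
  Q^((T - T_ref) / 10)
}

#' Write parameters as a flat key = value text file
#' @param params a `neuron_parameters` object.
#' @param file path to write.
#' @export
write_parameters <- function(params, file) {
  v <- as_par_vector(params)
  writeLines(sprintf("%s = %.17g", names(v), v), file)
  invisible(file)
}

#' Read parameters from a flat key = value text file
#' @param file path written by [write_parameters()] (unknown keys rejected).
#' @return A `neuron_parameters` object.
#' @export
read_parameters <- function(file) {
  ln <- readLines(file)
  ln <- ln[nzchar(trimws(ln)) & !startsWith(trimws(ln), "#")]
  kv <- strsplit(ln, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- as.numeric(trimws(vapply(kv, `[`, "", 2)))
  args <- as.list(vals)
  names(args) <- keys
  do.call(neuron_parameters, args)
}
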