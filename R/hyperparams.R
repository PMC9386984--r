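#' Model hyperparameters
#'
#' Container for every prior used by the control-panel sampler and the
#' sticky HDP-HMM copy number sampler. The defaults are the settings used
#' throughout the analyses this package reproduces:
#'
#' * `psi`: Gamma(shape, scale) prior on each control's inverse dispersion
#'   `s_k`; default shape 1.5, scale 1e6.
#' * `phi`: Beta(c, d) prior on each locus bias `m_l`; default flat (1, 1).
#' * `gamma`: concentration of the stick-breaking (GEM) prior on the global
#'   state weights; default 1.
#' * `alpha_plus_kappa`: Gamma(shape, scale) prior on the total transition
#'   concentration (alpha + kappa); default (2000, 10).
#' * `rho`: Beta(a, b) prior on the self-transition (sticky) weight
#'   kappa / (alpha + kappa); default (100000, 100), i.e. strong spatial
#'   persistence of copy number states.
#' * `lambda`: Gamma(shape, scale) base distribution H on state RCN values;
#'   default (3, 1).
#' * `omega`: Gamma(shape, scale) prior on the sample inverse dispersion
#'   `s~`; default shape 1.5, scale 1e6.
#'
#' @param psi,phi,alpha_plus_kappa,rho,lambda,omega length-2 numeric vectors
#'   (shape/scale, or the two Beta shapes).
#' @param gamma positive scalar.
#' @return An object of class `rcn_hyperparams` (a validated list).
#' @export
rcn_hyperparams <- function(psi = c(shape = 1.5, scale = 1e6),
                            phi = c(c = 1, d = 1),
                            gamma = 1,
                            alpha_plus_kappa = c(shape = 2000, scale = 10),
                            rho = c(a = 1e5, b = 100),
                            lambda = c(shape = 3, scale = 1),
                            omega = c(shape = 1.5, scale = 1e6)) {
  hp <- list(psi = as.numeric(psi), phi = as.numeric(phi),
             gamma = as.numeric(gamma)[1],
             alpha_plus_kappa = as.numeric(alpha_plus_kappa),
             rho = as.numeric(rho), lambda = as.numeric(lambda),
             omega = as.numeric(omega))
  two <- c("psi", "phi", "alpha_plus_kappa", "rho", "lambda", "omega")
  for (nm in two) {
    if (length(hp[[nm]]) != 2L || any(!is.finite(hp[[nm]])) ||
        any(hp[[nm]] <= 0))
      stop("hyperparameter '", nm, "' must be two positive finite numbers")
  }
  if (!is.finite(hp$gamma) || hp$gamma <= 0)
    stop("hyperparameter 'gamma' must be a positive number")
  structure(hp, class = "rcn_hyperparams")
}

#' Read hyperparameters from a YAML or JSON configuration file
#'
#' Any field absent from the file keeps its default. Fields must be named
#' as in [rcn_hyperparams()].
#'
#' @param path configuration file (`.yaml`/`.yml` or `.json`).
#' @return An `rcn_hyperparams` object.
#' @export
read_hyperparams <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(cfg$hyperparams)) cfg <- cfg$hyperparams
  args <- cfg[intersect(names(cfg), names(formals(rcn_hyperparams)))]
  do.call(rcn_hyperparams, lapply(args, unlist))
}

#' @export
print.rcn_hyperparams <- function(x, ...) {
  cat("repeatcn hyperparameters:\n")
  for (nm in names(x))
    cat(sprintf("  %-18s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  invisible(x)
}
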