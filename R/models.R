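# Registry of the eight unstructured kinetic growth laws and the coupled
# substrate/biomass ODE system they plug into.

# Core parameters shared by every model.  Each growth law may add exactly one
# extra parameter (n, Ksx, A or L); the compiled RHS reserves one slot for it.
.kin_core_params <- c("mu_max", "Ks", "Y", "kd", "b")

.kin_core_bounds <- list(
  mu_max = c(1e-4, 1e2),   # 1/h
  Ks     = c(1e-4, 1e3),   # mg/L
  Y      = c(1e-3, 1e2),   # biomass per substrate (dimensionless)
  kd     = c(1e-5, 1e1),   # 1/h
  b      = c(1e-4, 1e3)    # mg/L biomass per measurement unit
)

# Growth laws.  Only Monod and Moser have a single canonical printed form in
# the batch-biodegradation literature this package follows; the remaining six
# are standard literature forms (flagged literature_sourced) and can be
# overridden by swapping the `growth` function on a copy of the model object.
.kin_registry <- list(
  list(
    id = 1L, name = "Monod", extra = NULL, literature_sourced = FALSE,
    citation = "Monod (1949) Annu. Rev. Microbiol. 3:371-394",
    growth = function(S, X, p) p$mu_max * S / (p$Ks + S)
  ),
  list(
    id = 2L, name = "Tessier", extra = NULL, literature_sourced = TRUE,
    citation = "Tessier (1942) Ann. Physiol. Physicochim. Biol. 12:527-586",
    growth = function(S, X, p) p$mu_max * (1 - exp(-S / p$Ks))
  ),
  list(
    id = 3L, name = "Contois", extra = "Ksx", literature_sourced = TRUE,
    citation = "Contois (1959) J. Gen. Microbiol. 21:40-50",
    growth = function(S, X, p) p$mu_max * S / (p$extras$Ksx * X + S)
  ),
  list(
    id = 4L, name = "Blackman", extra = NULL, literature_sourced = TRUE,
    citation = "Blackman (1905) Ann. Bot. 19:281-295",
    growth = function(S, X, p) p$mu_max * pmin(1, S / p$Ks)
  ),
  list(
    id = 5L, name = "Dabes", extra = "A", literature_sourced = TRUE,
    citation = "Dabes, Finn & Wilke (1973) Biotechnol. Bioeng. 15:1159-1177",
    growth = function(S, X, p) {
      # implicit law S = A*mu + Ks*mu/(mu_max - mu); smaller quadratic root
      q <- S + p$extras$A * p$mu_max + p$Ks
      disc <- pmax(q^2 - 4 * p$extras$A * S * p$mu_max, 0)
      (q - sqrt(disc)) / (2 * p$extras$A)
    }
  ),
  list(
    id = 6L, name = "Powell", extra = "L", literature_sourced = TRUE,
    citation = "Powell (1967) Microbial Physiology and Continuous Culture",
    growth = function(S, X, p) {
      q <- S + p$Ks + p$extras$L
      disc <- pmax(q^2 - 4 * p$extras$L * S, 0)
      p$mu_max * (q - sqrt(disc)) / (2 * p$extras$L)
    }
  ),
  list(
    id = 7L, name = "Moser", extra = "n", literature_sourced = FALSE,
    citation = "Moser (1958) The Dynamics of Bacterial Populations in the Chemostat",
    growth = function(S, X, p) {
      Sn <- S^p$extras$n
      p$mu_max * Sn / (p$Ks + Sn)
    }
  ),
  list(
    id = 8L, name = "Heijnen", extra = "n", literature_sourced = TRUE,
    citation = "Heijnen & Romein (1995) Biotechnol. Prog. 11:712-716",
    growth = function(S, X, p) {
      Sn <- S^p$extras$n
      p$mu_max * Sn / (p$Ks^p$extras$n + Sn)
    }
  )
)

.kin_extra_bounds <- list(
  n   = c(0.5, 5),       # Moser/Heijnen exponent, dimensionless
  Ksx = c(1e-4, 1e3),    # Contois constant, mg substrate / mg biomass
  A   = c(1e-4, 1e3),    # Dabes linear coefficient, h * mg/L
  L   = c(1e-4, 1e3)     # Powell diffusion-resistance constant, mg/L
)

#' Kinetic model registry
#'
#' Look up one of the eight unstructured kinetic growth-law models by its
#' integer id (1--8) or name: Monod, Tessier, Contois, Blackman, Dabes,
#' Powell, Moser, Heijnen.  Only the Monod and Moser forms are anchored to a
#' single canonical equation in the batch-biodegradation literature; the
#' remaining laws use standard literature forms (see each entry's `citation`
#' and `literature_sourced` fields) and the `growth` function of a spec may
#' be replaced to adopt a different form.
#'
#' Note on Contois: following the classic form \eqn{\mu = \mu_{max} S /
#' (K_{sx} X + S)}, the biomass-proportional constant is the extra parameter
#' `Ksx`; the core `Ks` slot is retained for interface uniformity but does
#' not enter the Contois rate law.
#'
#' @param model integer id in 1--8 or model name (case-insensitive).
#' @return An object of class `kin_model`: a list with fields `id`, `name`,
#'   `growth` (function of `S`, `X`, params), `param_names`,
#'   `default_bounds` (named list of `c(low, high)`), `extra` (name of the
#'   model-specific extra parameter or `NULL`), `citation`,
#'   `literature_sourced`.
#' @examples
#' m <- kin_model("Moser")
#' m$param_names
#' @export
kin_model <- function(model) {
  if (inherits(model, "kin_model")) return(model)
  entry <- NULL
  if (is.numeric(model)) {
    if (length(model) != 1 || is.na(model) || model < 1 || model > 8 ||
        model != as.integer(model)) {
      stop("unknown model id: ", model, " (registry ids are 1-8)",
           call. = FALSE)
    }
    entry <- .kin_registry[[as.integer(model)]]
  } else if (is.character(model)) {
    idx <- match(tolower(model), vapply(.kin_registry, function(e)
      tolower(e$name), character(1)))
    if (is.na(idx)) {
      stop("unknown model name: '", model, "'; see list_models()",
           call. = FALSE)
    }
    entry <- .kin_registry[[idx]]
  } else {
    stop("model must be an integer id (1-8) or a name", call. = FALSE)
  }
  bounds <- .kin_core_bounds
  pnames <- .kin_core_params
  if (!is.null(entry$extra)) {
    pnames <- c(pnames, entry$extra)
    bounds[[entry$extra]] <- .kin_extra_bounds[[entry$extra]]
  }
  structure(
    list(id = entry$id, name = entry$name, growth = entry$growth,
         param_names = pnames, default_bounds = bounds,
         extra = entry$extra, citation = entry$citation,
         literature_sourced = entry$literature_sourced),
    class = "kin_model"
  )
}

#' List the available kinetic models
#'
#' @return A data.frame with one row per registry entry: id, name, extra
#'   parameter (if any), number of parameters, and citation.
#' @examples
#' list_models()
#' @export
list_models <- function() {
  data.frame(
    id = vapply(.kin_registry, `[[`, integer(1), "id"),
    name = vapply(.kin_registry, `[[`, character(1), "name"),
    extra = vapply(.kin_registry, function(e)
      if (is.null(e$extra)) "" else e$extra, character(1)),
    n_params = vapply(.kin_registry, function(e)
      5L + !is.null(e$extra), integer(1)),
    literature_sourced = vapply(.kin_registry, `[[`, logical(1),
                                "literature_sourced"),
    citation = vapply(.kin_registry, `[[`, character(1), "citation"),
    stringsAsFactors = FALSE
  )
}

#' @export
print.kin_model <- function(x, ...) {
  cat("<kin_model ", x$id, ": ", x$name, ">\n", sep = "")
  cat("  parameters:", paste(x$param_names, collapse = ", "), "\n")
  if (x$literature_sourced)
    cat("  literature-sourced form:", x$citation, "\n")
  invisible(x)
}

#' Kinetic parameter set
#'
#' Bundle the five core parameters of the coupled batch ODE system with any
#' model-specific extras.  All values must be strictly positive, except
#' `mu_max` and `kd`, which may be 0 (growth switched off / no endogenous
#' decay).
#'
#' @param mu_max maximum specific growth rate (1/h).
#' @param Ks half-saturation constant (mg/L).
#' @param Y yield coefficient, biomass formed per substrate consumed
#'   (dimensionless on a mg/mg basis).
#' @param kd endogenous decay coefficient (1/h).
#' @param b linear scaling from the cell measurement (OD or counts) to
#'   biomass concentration, so that `X = b * C` (mg/L per measurement unit).
#' @param ... model-specific extra parameters by name (e.g. `n = 1.5` for
#'   Moser, `Ksx` for Contois, `A` for Dabes, `L` for Powell).
#' @return An object of class `kinetic_params`.
#' @examples
#' kinetic_params(mu_max = 0.25, Ks = 10, Y = 0.5, kd = 0.01, b = 2, n = 1.5)
#' @export
kinetic_params <- function(mu_max, Ks, Y, kd, b, ...) {
  extras <- list(...)
  if (length(extras) && (is.null(names(extras)) || any(names(extras) == "")))
    stop("extra parameters must be named", call. = FALSE)
  vals <- c(mu_max = mu_max, Ks = Ks, Y = Y, kd = kd, b = b, unlist(extras))
  if (any(!is.finite(vals)))
    stop("all kinetic parameters must be finite", call. = FALSE)
  # mu_max = 0 (growth switched off) and kd = 0 (no endogenous decay) are
  # legitimate degenerate settings; everything else must be > 0
  strict <- vals[setdiff(names(vals), c("mu_max", "kd"))]
  if (any(strict <= 0) || mu_max < 0 || kd < 0)
    stop("kinetic parameters must be positive (mu_max and kd may be 0)",
         call. = FALSE)
  structure(
    list(mu_max = mu_max, Ks = Ks, Y = Y, kd = kd, b = b, extras = extras),
    class = "kinetic_params"
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  v <- kin_params_vector(x)
  cat("<kinetic_params>\n")
  print(signif(v, 6))
  invisible(x)
}

#' Convert between parameter objects and named vectors
#'
#' `kin_params_vector()` flattens a [kinetic_params()] object to a named
#' numeric vector (core parameters first, extras after); `kin_params_from_vector()`
#' rebuilds the object in the order declared by a model spec.
#'
#' @param params a `kinetic_params` object.
#' @param x named numeric vector or unnamed vector in `spec$param_names`
#'   order.
#' @param spec a [kin_model()] spec (used for parameter ordering/validation).
#' @return A named numeric vector, or a `kinetic_params` object.
#' @export
kin_params_vector <- function(params) {
  c(mu_max = params$mu_max, Ks = params$Ks, Y = params$Y, kd = params$kd,
    b = params$b, unlist(params$extras))
}

#' @rdname kin_params_vector
#' @export
kin_params_from_vector <- function(x, spec) {
  spec <- kin_model(spec)
  pn <- spec$param_names
  if (is.null(names(x))) {
    if (length(x) != length(pn))
      stop("expected ", length(pn), " parameters for ", spec$name,
           call. = FALSE)
    names(x) <- pn
  }
  if (!all(pn %in% names(x)))
    stop("missing parameters: ", paste(setdiff(pn, names(x)), collapse = ", "),
         call. = FALSE)
  args <- as.list(x[pn])
  do.call(kinetic_params, args)
}

# Validate a parameter set against a model spec; returns params invisibly.
.kin_validate_params <- function(spec, params) {
  if (!inherits(params, "kinetic_params"))
    stop("params must be a kinetic_params object", call. = FALSE)
  need <- if (is.null(spec$extra)) character(0) else spec$extra
  have <- names(params$extras)
  missing <- setdiff(need, have)
  if (length(missing))
    stop(spec$name, " model requires extra parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(params)
}

# Parameter slots handed to the compiled RHS: mu_max, Ks, Y, kd, id, extra.
.kin_parms_vector <- function(spec, params) {
  extra <- if (is.null(spec$extra)) 0 else params$extras[[spec$extra]]
  c(params$mu_max, params$Ks, params$Y, params$kd, as.double(spec$id), extra)
}

#' Specific growth rate of a kinetic model
#'
#' Evaluate the growth law \eqn{\mu(S, X)} of a registry model.  Every law
#' returns 0 at `S = 0` (no substrate, no growth) and is non-negative on the
#' feasible domain.
#'
#' @param spec a [kin_model()] spec (or id/name).
#' @param S substrate concentration, mg/L (vectorized).
#' @param X biomass concentration, mg/L (only the Contois law uses it).
#' @param params a [kinetic_params()] object valid for the model.
#' @return Specific growth rate(s), 1/h.
#' @examples
#' p <- kinetic_params(mu_max = 1, Ks = 1, Y = 0.5, kd = 0.01, b = 1)
#' growth_rate("Monod", S = 1, X = 1, params = p)  # half-saturation: 0.5
#' @export
growth_rate <- function(spec, S, X, params) {
  spec <- kin_model(spec)
  .kin_validate_params(spec, params)
  if (any(S < 0) || any(X < 0))
    stop("S and X must be non-negative", call. = FALSE)
  mu <- spec$growth(S, X, params)
  mu[S == 0] <- 0
  if (any(!is.finite(mu)))
    stop("non-finite growth rate for model ", spec$name,
         " at S = ", S[which(!is.finite(mu))[1]], call. = FALSE)
  mu
}

#' Right-hand side of the coupled batch ODE system
#'
#' The time derivatives of substrate and biomass in a batch reactor with
#' endogenous decay:
#' \deqn{dS/dt = -(1/Y)\,\mu X, \qquad dX/dt = \mu X - k_d X.}
#'
#' @inheritParams growth_rate
#' @param state numeric vector `c(S, X)` in mg/L (optionally named).
#' @return Named numeric vector `c(dS, dX)` in mg/L/h.
#' @examples
#' p <- kinetic_params(mu_max = 1, Ks = 1, Y = 0.5, kd = 0.01, b = 1)
#' ode_rhs("Monod", c(S = 1, X = 2), p)
#' @export
ode_rhs <- function(spec, state, params) {
  spec <- kin_model(spec)
  .kin_validate_params(spec, params)
  S <- unname(state[1]); X <- unname(state[2])
  if (any(state < 0)) stop("state components must be non-negative",
                           call. = FALSE)
  mu <- growth_rate(spec, S, X, params)
  c(dS = -mu * X / params$Y, dX = (mu - params$kd) * X)
}

#' Default parameter search bounds for a model
#'
#' Broad positive boxes per parameter, scaled to the magnitudes encountered
#' in batch biodegradation fitting; override by passing a modified list to
#' the fitting functions.
#'
#' @inheritParams growth_rate
#' @return Named list of `c(low, high)` bounds in `spec$param_names` order.
#' @export
default_bounds <- function(spec) {
  spec <- kin_model(spec)
  spec$default_bounds[spec$param_names]
}
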