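#' Consortium state: per-strain optical densities
#'
#' The state of the two-strain coculture is the pair of optical densities
#' (OD600, 1 cm equivalent) of the xylose-eating, cellobiose-cleaving strain
#' (CP-X, denoted `X`) and the glucose-eating, xylobiose-cleaving strain
#' (CP-G, denoted `G`).
#'
#' @param X OD600 of strain CP-X (non-negative scalar).
#' @param G OD600 of strain CP-G (non-negative scalar).
#' @return An object of class `consortium_state`: a named numeric vector
#'   with elements `X` and `G`.
#' @examples
#' consortium_state(X = 0.01, G = 0.01)
#' @export
consortium_state <- function(X, G) {
  stopifnot(is.numeric(X), length(X) == 1L, is.finite(X),
            is.numeric(G), length(G) == 1L, is.finite(G))
  if (X < 0 || G < 0) {
    stop("consortium_state: optical densities must be non-negative (X = ",
         X, ", G = ", G, ")", call. = FALSE)
  }
  structure(c(X = unname(X), G = unname(G)), class = "consortium_state")
}

#' Model parameters of the consortium growth equations
#'
#' The five constants of the coupled logistic equations: maximum specific
#' growth rates of the two strains, the half-saturation-like constants of
#' the two cross-feeding factors, and the shared carrying capacity.
#' `C_x` and `C_g` are inversely proportional to the amounts of the
#' glycoside hydrolases BglC (in CP-X) and Xyl43A (in CP-G): more enzyme
#' means a smaller constant and a cross-feeding factor that saturates at
#' lower partner density.
#'
#' @param r_mx Maximum specific growth rate of CP-X (per hour).
#' @param r_mg Maximum specific growth rate of CP-G (per hour).
#' @param C_x Half-saturation constant of the cellobiose-to-glucose factor
#'   `X / (C_x + X)` (OD units).
#' @param C_g Half-saturation constant of the xylobiose-to-xylose factor
#'   `G / (C_g + G)` (OD units).
#' @param K Carrying capacity of the medium (OD units).
#' @return An object of class `model_parameters` (named numeric vector).
#' @examples
#' baseline_parameters()
#' model_parameters(r_mx = 0.22, r_mg = 0.34, C_x = 0.08, C_g = 0.02, K = 0.82)
#' @export
model_parameters <- function(r_mx, r_mg, C_x, C_g, K) {
  p <- c(r_mx = r_mx, r_mg = r_mg, C_x = C_x, C_g = C_g, K = K)
  if (!is.numeric(p) || length(p) != 5L || any(!is.finite(p))) {
    stop("model_parameters: all five parameters must be finite numbers",
         call. = FALSE)
  }
  if (any(p <= 0)) {
    bad <- names(p)[p <= 0]
    stop("model_parameters: all parameters must be strictly positive; ",
         "offending: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(p, class = "model_parameters")
}

#' Baseline fitted parameter set
#'
#' The parameter values obtained by fitting the model to the cooperating
#' consortium grown on 1 g/l cellobiose + 1 g/l xylobiose: all scenario
#' scaling factors equal to 1.
#'
#' @return A `model_parameters` object with `r_mx = 0.12`, `r_mg = 0.34`,
#'   `C_x = 0.04`, `C_g = 0.02`, `K = 0.82`.
#' @export
baseline_parameters <- function() {
  model_parameters(r_mx = 0.12, r_mg = 0.34, C_x = 0.04, C_g = 0.02, K = 0.82)
}

#' Scenario scaling factors
#'
#' Dimensionless multipliers used to project the fitted baseline model onto
#' new cultivation scenarios: `alpha_Dx` and `alpha_Dg` scale the
#' cross-feeding factors with the initial cellobiose and xylobiose amounts,
#' `alpha_Bx` scales the CP-X growth rate down under BglC expression and
#' degradation burden, and `alpha_Ex` scales `C_x` with the amount of BglC
#' enzyme.  The carrying capacity is scaled by the most restrictive factor,
#' `alpha_K = min(alpha_Ex, alpha_Dx, alpha_Dg)` (the burden factor
#' `alpha_Bx` does not limit the attainable biomass).
#'
#' @param alpha_Dx Cellobiose-amount scaling (relative to 1 g/l).
#' @param alpha_Dg Xylobiose-amount scaling (relative to 1 g/l).
#' @param alpha_Bx Expression/degradation burden scaling on `r_mx`.
#' @param alpha_Ex BglC-amount scaling on `C_x`.
#' @return An object of class `scaling_factors` (named numeric vector).
#' @examples
#' scaling_factors()                      # identity scenario, all 1
#' scaling_factors(alpha_Dx = 0.6, alpha_Dg = 1.4)
#' @export
scaling_factors <- function(alpha_Dx = 1, alpha_Dg = 1,
                            alpha_Bx = 1, alpha_Ex = 1) {
  a <- c(alpha_Dx = alpha_Dx, alpha_Dg = alpha_Dg,
         alpha_Bx = alpha_Bx, alpha_Ex = alpha_Ex)
  if (!is.numeric(a) || length(a) != 4L || any(!is.finite(a))) {
    stop("scaling_factors: all four factors must be finite numbers",
         call. = FALSE)
  }
  if (any(a <= 0)) {
    bad <- names(a)[a <= 0]
    stop("scaling_factors: all factors must be strictly positive; ",
         "offending: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(a, class = "scaling_factors")
}

#' Effective carrying-capacity scaling
#'
#' The carrying capacity is limited by whichever resource is most
#' restrictive: `alpha_K = min(alpha_Ex, alpha_Dx, alpha_Dg)`.  The burden
#' factor `alpha_Bx` slows CP-X but does not cap total biomass, so it is
#' excluded from the minimum.
#'
#' @param scaling A `scaling_factors` object.
#' @return The scalar `alpha_K`.
#' @examples
#' effective_alpha_K(scaling_factors(alpha_Dx = 0.6, alpha_Dg = 1.4))  # 0.6
#' @export
effective_alpha_K <- function(scaling) {
  scaling <- as_scaling_factors(scaling)
  unname(min(scaling[["alpha_Ex"]], scaling[["alpha_Dx"]],
             scaling[["alpha_Dg"]]))
}

#' Right-hand side of the consortium growth equations
#'
#' Evaluates the two coupled rates
#' \deqn{dX/dt = (r_{mx}/\alpha_{Bx}) \frac{\alpha_{Dg} G}{C_g + G}
#'   \left(1 - \frac{G + X}{\alpha_K K}\right) X}
#' \deqn{dG/dt = r_{mg} \frac{\alpha_{Dx} X}{C_x/\alpha_{Ex} + X}
#'   \left(1 - \frac{G + X}{\alpha_K K}\right) G}
#' Each strain grows logistically at a rate gated by a Monod-type factor in
#' the partner's density: CP-X needs xylose released by CP-G, CP-G needs
#' glucose released by CP-X.  With all scaling factors at 1 this reduces to
#' the base fitted model.
#'
#' @param state A `consortium_state` (or named vector with `X`, `G`).
#' @param params A `model_parameters` object.
#' @param scaling A `scaling_factors` object (default: identity scenario).
#' @return Named numeric vector `c(dX, dG)` in OD per hour.
#' @examples
#' consortium_derivatives(consortium_state(0.01, 0.01), baseline_parameters())
#' @export
consortium_derivatives <- function(state, params,
                                   scaling = scaling_factors()) {
  state <- as_consortium_state(state)
  params <- as_model_parameters(params)
  scaling <- as_scaling_factors(scaling)

  X <- state[["X"]]
  G <- state[["G"]]
  a_K <- effective_alpha_K(scaling)
  free <- 1 - (G + X) / (a_K * params[["K"]])

  dX <- (params[["r_mx"]] / scaling[["alpha_Bx"]]) *
    (scaling[["alpha_Dg"]] * G / (params[["C_g"]] + G)) * free * X
  dG <- params[["r_mg"]] *
    (scaling[["alpha_Dx"]] * X / (params[["C_x"]] / scaling[["alpha_Ex"]] + X)) *
    free * G
  c(dX = unname(dX), dG = unname(dG))
}

# internal coercers: accept either the class or a plain named vector/list
as_consortium_state <- function(x) {
  if (inherits(x, "consortium_state")) return(x)
  x <- unlist(x)
  if (!all(c("X", "G") %in% names(x))) {
    stop("expected a consortium_state or a named vector with X and G",
         call. = FALSE)
  }
  consortium_state(x[["X"]], x[["G"]])
}

as_model_parameters <- function(x) {
  if (inherits(x, "model_parameters")) return(x)
  x <- unlist(x)
  need <- c("r_mx", "r_mg", "C_x", "C_g", "K")
  if (!all(need %in% names(x))) {
    stop("expected model_parameters or a named vector with ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  model_parameters(x[["r_mx"]], x[["r_mg"]], x[["C_x"]], x[["C_g"]], x[["K"]])
}

as_scaling_factors <- function(x) {
  if (inherits(x, "scaling_factors")) return(x)
  x <- unlist(x)
  need <- c("alpha_Dx", "alpha_Dg", "alpha_Bx", "alpha_Ex")
  if (!all(need %in% names(x))) {
    stop("expected scaling_factors or a named vector with ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  scaling_factors(x[["alpha_Dx"]], x[["alpha_Dg"]], x[["alpha_Bx"]],
                  x[["alpha_Ex"]])
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Consortium model parameters (h^-1 for rates, OD units otherwise):\n")
  print(unclass(x), ...)
  invisible(x)
}

#' @export
print.scaling_factors <- function(x, ...) {
  cat("Scenario scaling factors (alpha_K = ",
      format(effective_alpha_K(x)), "):\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}
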