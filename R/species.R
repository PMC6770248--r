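#' Species of the ceria/ROS network
#'
#' The model tracks seven dynamic species, remapped to single letters:
#' P = H2O2 (hydrogen peroxide), O = O2 (molecular oxygen), D = OH-
#' (hydroxide), S = O2- (superoxide), C = Ce3+ (cerous), F = Ce4+ (ceric),
#' H = H+ (hydronium).  Water (W) appears in the reactions but is held
#' constant -- present in great excess -- and is flagged non-dynamic: it
#' never enters a rate law or an ODE.
#'
#' Of the seven dynamic species only six are integrated; F is algebraic
#' via the lattice conservation C + F = Ct.
#'
#' @return A data frame with columns `symbol`, `formula`, `name`,
#'   `dynamic` (logical) and `integrated` (logical), one row per species
#'   including W.
#' @examples
#' species_table()
#' @export
species_table <- function() {
  data.frame(
    symbol  = c("P", "O", "D", "S", "C", "F", "H", "W"),
    formula = c("H2O2", "O2", "OH-", "O2-", "Ce3+", "Ce4+", "H+", "H2O"),
    name    = c("hydrogen peroxide", "oxygen", "hydroxide", "superoxide",
                "cerous ion", "ceric ion", "hydronium ion", "water"),
    dynamic    = c(rep(TRUE, 7), FALSE),
    integrated = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

# integrated species, in the canonical state order
.species <- c("P", "O", "D", "S", "C", "H")

#' Mass-action rate constants
#'
#' The four rate constants of the network.  k1 (superoxide generation),
#' k3 (cerous oxidation) and k4 (catalase) multiply fourth-order rate
#' laws, k2 (ceric reduction) a second-order one; each therefore carries
#' the units that make its rate law come out in M/s.  Units are
#' documented, not enforced.
#'
#' @param k1,k2,k3,k4 Strictly positive, finite rate constants.
#' @return A named numeric vector of class `"rate_constants"`.
#' @examples
#' rate_constants(1, 1, 1, 1)
#' @export
rate_constants <- function(k1 = 1, k2 = 1, k3 = 1, k4 = 1) {
  k <- c(k1 = k1, k2 = k2, k3 = k3, k4 = k4)
  if (!is.numeric(k) || length(k) != 4L || any(!is.finite(k)) || any(k <= 0))
    stop("rate constants must be strictly positive finite numbers",
         call. = FALSE)
  structure(k, class = "rate_constants")
}

.as_rate_constants <- function(k) {
  if (inherits(k, "rate_constants")) return(k)
  if (is.numeric(k) && length(k) == 4L)
    return(rate_constants(k[[1]], k[[2]], k[[3]], k[[4]]))
  stop("`k` must be a rate_constants object or a numeric vector of length 4",
       call. = FALSE)
}

#' Dimensional concentration state
#'
#' Concentrations (molarity) of the seven dynamic species together with
#' the total ceria concentration `Ct`.  The ceric concentration `F` is
#' derived as `Ct - C` unless supplied, in which case `C + F = Ct` must
#' hold to within `tol`.
#'
#' @param P,O,D,S,C,H Nonnegative concentrations (M).
#' @param Ct Total ceria concentration (M), `Ct >= C`.
#' @param F Optional ceric concentration; defaults to `Ct - C`.
#' @param tol Tolerance for the conservation check when `F` is supplied.
#' @return A list of class `"dim_state"` with fields P, O, D, S, C, F, H, Ct.
#' @examples
#' dim_state(P = 1, O = 1, D = 1, S = 1, C = 0.5, H = 1, Ct = 1)
#' @export
dim_state <- function(P, O, D, S, C, H, Ct, F = NULL, tol = 1e-8) {
  x <- c(P = P, O = O, D = D, S = S, C = C, H = H)
  bad <- names(x)[!is.finite(x) | x < 0]
  if (length(bad))
    stop("negative or non-finite concentration for species: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (!is.finite(Ct) || Ct < 0)
    stop("`Ct` must be a nonnegative finite number", call. = FALSE)
  if (is.null(F)) {
    F <- Ct - C
    if (F < -tol)
      stop("cerous concentration C exceeds total ceria Ct", call. = FALSE)
    F <- max(F, 0)
  } else {
    if (!is.finite(F) || F < 0)
      stop("negative or non-finite concentration for species: F",
           call. = FALSE)
    if (abs(C + F - Ct) > tol)
      stop("ceria conservation violated: C + F differs from Ct by ",
           format(abs(C + F - Ct)), call. = FALSE)
  }
  structure(list(P = P, O = O, D = D, S = S, C = C, F = F, H = H, Ct = Ct),
            class = "dim_state")
}

#' Non-dimensional (hatted) state
#'
#' Each variable is the concentration divided by its characteristic scale.
#' The hatted cerous fraction lies in \[0, 1\] and the hatted ceric
#' fraction is `1 - C`.
#'
#' @param P,O,D,S,H Nonnegative hatted concentrations.
#' @param C Hatted cerous fraction, in \[0, 1\].
#' @return A named numeric vector of class `"nondim_state"` over
#'   `(P, O, D, S, C, H)`.
#' @examples
#' nondim_state(P = 1, O = 1, D = 1, S = 1, C = 0, H = 1)
#' @export
nondim_state <- function(P, O, D, S, C, H) {
  x <- c(P = P, O = O, D = D, S = S, C = C, H = H)
  bad <- names(x)[!is.finite(x) | x < 0]
  if (length(bad))
    stop("negative or non-finite hatted concentration for species: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (C > 1 + 1e-12)
    stop("hatted cerous fraction C must lie in [0, 1]", call. = FALSE)
  structure(x, class = "nondim_state")
}

.as_nondim_state <- function(x) {
  if (inherits(x, "nondim_state")) return(x)
  if (is.numeric(x) && length(x) == 6L) {
    if (is.null(names(x))) names(x) <- .species
    return(nondim_state(x[["P"]], x[["O"]], x[["D"]], x[["S"]],
                        x[["C"]], x[["H"]]))
  }
  stop("expected a nondim_state or a numeric vector of length 6",
       call. = FALSE)
}

#' @export
print.dim_state <- function(x, ...) {
  cat("<dim_state> (molarity)\n")
  v <- unlist(x[c("P", "O", "D", "S", "C", "F", "H")])
  print(signif(v, 6))
  cat("Ct =", format(x$Ct), "\n")
  invisible(x)
}

#' @export
print.nondim_state <- function(x, ...) {
  cat("<nondim_state> (hatted, F = 1 - C)\n")
  print(signif(unclass(x), 6))
  invisible(x)
}
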