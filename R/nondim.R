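#' Characteristic scales of the non-dimensional system
#'
#' The scales divide each variable so that the dynamics depend only on
#' three dimensionless groups:
#' \preformatted{
#'   tc = (k4/k1)^2 / (Ct * k3)            time
#'   Pc = k3/k4                            peroxide
#'   Oc = Hc = k1/k4                       oxygen, hydronium
#'   Dc = Sc = Cc = Fc = Ct                hydroxide, superoxide, ceria
#' }
#' The `k1/k4` reading for Oc and Hc is the one under which the
#' non-dimensional hydroxide and superoxide equations take their
#' parameter-free forms (`dD = -2*P*O*D^2`, see [rhs_nondim()]) and the
#' chain rule maps the dimensional system onto the non-dimensional one.
#'
#' @param k A [rate_constants()] object (or numeric length-4 vector).
#' @param Ct Total ceria concentration, positive.
#' @return Named numeric vector of class `"scale_set"` with entries
#'   `tc, Pc, Oc, Dc, Sc, Cc, Fc, Hc`.
#' @examples
#' characteristic_scales(rate_constants(2, 1, 1, 1), Ct = 1)
#' @export
characteristic_scales <- function(k, Ct) {
  k <- .as_rate_constants(k)
  if (!is.numeric(Ct) || length(Ct) != 1L || !is.finite(Ct) || Ct <= 0)
    stop("`Ct` must be a positive finite number", call. = FALSE)
  structure(c(tc = (k[["k4"]] / k[["k1"]])^2 / (Ct * k[["k3"]]),
              Pc = k[["k3"]] / k[["k4"]],
              Oc = k[["k1"]] / k[["k4"]],
              Dc = Ct, Sc = Ct, Cc = Ct, Fc = Ct,
              Hc = k[["k1"]] / k[["k4"]]),
            class = "scale_set")
}

#' Dimensionless parameter groups
#'
#' The three groups that fully parameterize the non-dimensional system:
#' `a = (k4/k3) * Ct` (peroxide-equation prefactor), `b = (k4/k1) * Ct`
#' (oxygen/hydronium prefactor) and `g = (k2/k3) * (k4/k1)^2` (the
#' dismutation group multiplying the ceric-reduction monomial).  With
#' all rate-constant ratios and Ct equal to one, `a = b = g = 1`.
#'
#' @inheritParams characteristic_scales
#' @return Named numeric vector of class `"dimensionless_groups"` with
#'   entries `a`, `b`, `g`.
#' @examples
#' dimensionless_groups(rate_constants(5, 1, 1, 1), Ct = 1)  # b=0.2, g=0.04
#' @export
dimensionless_groups <- function(k, Ct) {
  k <- .as_rate_constants(k)
  if (!is.numeric(Ct) || length(Ct) != 1L || !is.finite(Ct) || Ct <= 0)
    stop("`Ct` must be a positive finite number", call. = FALSE)
  structure(c(a = (k[["k4"]] / k[["k3"]]) * Ct,
              b = (k[["k4"]] / k[["k1"]]) * Ct,
              g = (k[["k2"]] / k[["k3"]]) * (k[["k4"]] / k[["k1"]])^2),
            class = "dimensionless_groups")
}

.as_groups <- function(g) {
  if (inherits(g, "dimensionless_groups")) return(g)
  g <- unlist(g)
  if (is.numeric(g) && length(g) == 3L) {
    if (is.null(names(g))) names(g) <- c("a", "b", "g")
    if (any(!is.finite(g)) || any(g <= 0))
      stop("dimensionless groups must be positive and finite", call. = FALSE)
    return(structure(g[c("a", "b", "g")], class = "dimensionless_groups"))
  }
  stop("expected dimensionless_groups or a numeric vector (a, b, g)",
       call. = FALSE)
}

#' Transform between dimensional and hatted states
#'
#' `to_nondim` divides each concentration by its characteristic scale;
#' `from_nondim` multiplies back.  The round trip is the identity.
#'
#' @param state A [dim_state()].
#' @param nstate A [nondim_state()].
#' @param scales A [characteristic_scales()] result.
#' @return `to_nondim`: a [nondim_state()]; `from_nondim`: a
#'   [dim_state()] with `Ct = Cc`.
#' @examples
#' k <- rate_constants(2, 1, 1, 1)
#' sc <- characteristic_scales(k, Ct = 1)
#' x <- dim_state(P = 0.5, O = 1, D = 1, S = 1, C = 0.5, H = 2, Ct = 1)
#' from_nondim(to_nondim(x, sc), sc)
#' @export
to_nondim <- function(state, scales) {
  stopifnot(inherits(state, "dim_state"), inherits(scales, "scale_set"))
  nondim_state(P = state$P / scales[["Pc"]],
               O = state$O / scales[["Oc"]],
               D = state$D / scales[["Dc"]],
               S = state$S / scales[["Sc"]],
               C = state$C / scales[["Cc"]],
               H = state$H / scales[["Hc"]])
}

#' @rdname to_nondim
#' @export
from_nondim <- function(nstate, scales) {
  nstate <- .as_nondim_state(nstate)
  stopifnot(inherits(scales, "scale_set"))
  dim_state(P = nstate[["P"]] * scales[["Pc"]],
            O = nstate[["O"]] * scales[["Oc"]],
            D = nstate[["D"]] * scales[["Dc"]],
            S = nstate[["S"]] * scales[["Sc"]],
            C = nstate[["C"]] * scales[["Cc"]],
            H = nstate[["H"]] * scales[["Hc"]],
            Ct = scales[["Cc"]])
}

#' Non-dimensional ODE right-hand side
#'
#' The hatted system, re-derived by substituting the characteristic
#' scales into the dimensional mass-action equations.  With monomials
#' `m1 = P*O*D^2`, `m2 = (1-C)*S`, `m3 = C*S*H^2`, `m4 = P*C^2*H^2`:
#' \preformatted{
#'   dP = a * (m3 - m1 - m4)        dS = 2 m1 - g m2 - m3
#'   dO = b * (g m2 - m1)           dC = g m2 - m3 - 2 m4
#'   dD = -2 m1                     dH = -2 b (m3 + m4)
#' }
#' The hydroxide and superoxide equations are parameter-free, and the
#' whole system depends only on the three groups `(a, b, g)`.  The
#' chain rule guarantees equivalence with [rhs_dimensional()]: for a
#' dimensional state `x` with scales `sc`,
#' `rhs_nondim(to_nondim(x, sc), groups)` equals
#' `rhs_dimensional(x, k) * tc / scale` component-wise.
#'
#' @param nstate A [nondim_state()] (hatted concentrations).
#' @param groups A [dimensionless_groups()] result.
#' @return Named numeric hatted derivative vector over
#'   `(P, O, D, S, C, H)`.
#' @examples
#' rhs_nondim(nondim_state(1, 1, 1, 1, 1, 1), dimensionless_groups(
#'   rate_constants(), Ct = 1))  # (-1, -1, -2, 1, -3, -4)
#' @export
rhs_nondim <- function(nstate, groups) {
  x <- .as_nondim_state(nstate)
  groups <- .as_groups(groups)
  a <- groups[["a"]]; b <- groups[["b"]]; g <- groups[["g"]]
  m1 <- x[["P"]] * x[["O"]] * x[["D"]]^2
  m2 <- (1 - x[["C"]]) * x[["S"]]
  m3 <- x[["C"]] * x[["S"]] * x[["H"]]^2
  m4 <- x[["P"]] * x[["C"]]^2 * x[["H"]]^2
  c(P = a * (m3 - m1 - m4),
    O = b * (g * m2 - m1),
    D = -2 * m1,
    S = 2 * m1 - g * m2 - m3,
    C = g * m2 - m3 - 2 * m4,
    H = -2 * b * (m3 + m4))
}
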