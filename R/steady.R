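#' Enumerate the steady-state families of the non-dimensional system
#'
#' All time derivatives of the hatted system vanish exactly when the four
#' monomials `P*O*D^2`, `(1-C)*S`, `C*S*H^2` and `P*C^2*H^2` vanish
#' simultaneously (the hydroxide equation forces the first, the hydronium
#' equation the last two, the superoxide equation the second).  The
#' enumeration performs that case analysis mechanically: each monomial
#' contributes its possible vanishing conditions (a species at zero, or
#' the cerous fraction at one), conflicting combinations are discarded,
#' and only minimal constraint sets -- maximal solution families -- are
#' kept.  Every returned family is verified by substituting random
#' admissible values for its free variables into [rhs_nondim()].
#'
#' There are exactly eight families: three "non-ideal" ones in which
#' superoxide `S*` is free (all with `C* = 1` and `H* = 0`), and five
#' "ideal" ones with `S* = 0`.
#'
#' @param groups A [dimensionless_groups()] result (any positive groups;
#'   the family list does not depend on their values).
#' @param verify Number of random substitution checks per family
#'   (0 to skip).
#' @return A list of eight `"steady_family"` objects, non-ideal families
#'   first.  Each has fields `id`, `label` (the tuple notation, e.g.
#'   `"(P*,O*,0,S*,1,0)"`), `zero` (species forced to 0), `fixed`
#'   (named values, e.g. `c(C = 1)`), `free` (unconstrained species) and
#'   `ideal` (TRUE when `S* = 0`).
#' @examples
#' fams <- enumerate_families(c(a = 1, b = 1, g = 1))
#' vapply(fams, `[[`, character(1), "label")
#' @export
enumerate_families <- function(groups = c(a = 1, b = 1, g = 1),
                               verify = 100L) {
  groups <- .as_groups(groups)
  # vanishing conditions per monomial ("X0" = species X is 0, "C1" = C is 1)
  conds <- list(m1 = c("P0", "O0", "D0"),
                m2 = c("S0", "C1"),
                m3 = c("S0", "C0", "H0"),
                m4 = c("P0", "C0", "H0"))
  combos <- expand.grid(conds, stringsAsFactors = FALSE)
  sets <- unique(lapply(seq_len(nrow(combos)), function(i)
    sort(unique(unlist(combos[i, ])))))
  sets <- Filter(function(s) !all(c("C0", "C1") %in% s), sets)
  minimal <- Filter(function(s)
    !any(vapply(sets, function(o)
      length(o) < length(s) && all(o %in% s), logical(1))), sets)
  minimal <- unique(minimal)

  fams <- lapply(minimal, function(s) {
    zero  <- sub("0$", "", grep("0$", s, value = TRUE))
    fixed <- if ("C1" %in% s) c(C = 1) else stats::setNames(numeric(0),
                                                            character(0))
    free  <- setdiff(.species, c(zero, names(fixed)))
    tuple <- vapply(.species, function(sp) {
      if (sp %in% zero) "0"
      else if (sp %in% names(fixed)) format(fixed[[sp]])
      else paste0(sp, "*")
    }, character(1))
    structure(list(id = NA_character_,
                   label = paste0("(", paste(tuple, collapse = ","), ")"),
                   zero = zero, fixed = fixed, free = free,
                   ideal = "S" %in% zero),
              class = "steady_family")
  })
  # non-ideal families listed first, deterministic order within groups
  ord <- order(vapply(fams, `[[`, logical(1), "ideal"),
               vapply(fams, `[[`, character(1), "label"))
  fams <- fams[ord]
  n_non <- sum(!vapply(fams, `[[`, logical(1), "ideal"))
  for (i in seq_along(fams))
    fams[[i]]$id <- if (i <= n_non) paste0("nonideal-", i)
                    else paste0("ideal-", i - n_non)

  if (verify > 0L) {
    for (fam in fams) {
      for (j in seq_len(verify)) {
        x <- family_member(fam, runif_free = TRUE)
        if (any(rhs_nondim(x, groups) != 0))
          stop("internal error: family ", fam$label,
               " fails the substitution check", call. = FALSE)
      }
    }
  }
  fams
}

#' Construct a state belonging to a steady-state family
#'
#' Fills the family's zero and fixed constraints and assigns its free
#' variables, either from `values` or uniformly at random on (0, 2].
#'
#' @param family A `"steady_family"` from [enumerate_families()].
#' @param values Named values for the free variables (recycled defaults
#'   to 1 for any free variable not given).
#' @param runif_free If TRUE, draw free variables uniformly from (0, 2]
#'   (the cerous fraction from (0, 1]).
#' @return A [nondim_state()].
#' @export
family_member <- function(family, values = NULL, runif_free = FALSE) {
  stopifnot(inherits(family, "steady_family"))
  x <- stats::setNames(numeric(6), .species)
  x[names(family$fixed)] <- family$fixed
  for (sp in family$free) {
    v <- if (!is.null(values) && sp %in% names(values)) values[[sp]]
         else if (runif_free) stats::runif(1, 1e-6, if (sp == "C") 1 else 2)
         else 1
    x[[sp]] <- v
  }
  .as_nondim_state(x)
}

#' Classify a state against the steady-state families
#'
#' Returns every family whose zero constraints hold to within `tol` and
#' whose fixed constraints (the cerous fraction at 1) hold to within
#' `tol`.  Families overlap at boundary states, so several matches are
#' possible; an empty result means the state is not (near) a steady
#' state.  Callers wanting a unique answer can pick the match with the
#' most zero constraints.
#'
#' @param nstate A [nondim_state()].
#' @param tol Nonnegative tolerance on each constraint.
#' @param families Family list, defaulting to [enumerate_families()]
#'   (unverified, for speed).
#' @return Character vector of matching family labels (possibly empty),
#'   with the matching `"steady_family"` objects in attribute
#'   `"families"`.
#' @examples
#' classify_endpoint(nondim_state(0.4, 1.2, 0, 0, 0.3, 0))
#' @export
classify_endpoint <- function(nstate, tol = 1e-6,
                              families = enumerate_families(verify = 0L)) {
  x <- .as_nondim_state(nstate)
  hit <- vapply(families, function(f) {
    all(abs(x[f$zero]) <= tol) &&
      (length(f$fixed) == 0L ||
         all(abs(x[names(f$fixed)] - f$fixed) <= tol))
  }, logical(1))
  structure(vapply(families[hit], `[[`, character(1), "label"),
            families = families[hit])
}

#' @export
print.steady_family <- function(x, ...) {
  cat(sprintf("<steady_family %s> %s  [%s]\n", x$id, x$label,
              if (x$ideal) "ideal: S* = 0" else "non-ideal: S* free"))
  invisible(x)
}

# ---- analytic steady-state ratio (as printed) -----------------------

#' Steady-state cerous/ceric ratio
#'
#' The analytic steady-state ratio obtained from `d[Ce4+]/dt = 0`:
#' `[Ce3+]/[Ce4+] = k2*S / (k3*H*S + k4*H*P)`, implemented exactly in
#' its printed first-power-of-H form.  Note this form descends from a
#' rate expression that differs from the time-dependent mass-action
#' system (which carries `H^2`, `C^2` and a factor 2 on the catalase
#' term); [mass_action_ceria_balance()] exposes the mass-action
#' counterpart so the two can be compared programmatically.
#'
#' @param S,P,H Superoxide, peroxide and hydronium concentrations (M);
#'   `H > 0` and at least one of `S`, `P` positive.
#' @param k A [rate_constants()] object.
#' @return Dimensionless ratio `[Ce3+]/[Ce4+]`.
#' @examples
#' steady_state_ratio(S = 1, P = 0, H = 1, k = rate_constants())  # 1
#' @export
steady_state_ratio <- function(S, P, H, k) {
  k <- .as_rate_constants(k)
  stopifnot(S >= 0, P >= 0, H >= 0)
  den <- k[["k3"]] * H * S + k[["k4"]] * H * P
  if (den == 0)
    stop("ratio undefined: k3*H*S + k4*H*P is zero", call. = FALSE)
  k[["k2"]] * S / den
}

#' Limiting cases of the steady-state ratio
#'
#' `ratio_case1` is the disease-state limit `S >> P`:
#' `[Ce3+]/[Ce4+] = k2/(k3*H)` -- the redox couple is in self-regulating
#' balance.  `ratio_case2` is the healthy-state limit `P >> S`:
#' `[Ce3+]/[Ce4+] = k2*S/(k4*H*P)` -- the ceric state dominates and the
#' system shuts itself down.
#'
#' @inheritParams steady_state_ratio
#' @return Dimensionless ratio.
#' @examples
#' ratio_case1(rate_constants(), H = 1)  # 1
#' @export
ratio_case1 <- function(k, H) {
  k <- .as_rate_constants(k)
  if (H <= 0) stop("ratio undefined: k3*H is zero or negative",
                   call. = FALSE)
  k[["k2"]] / (k[["k3"]] * H)
}

#' @rdname ratio_case1
#' @export
ratio_case2 <- function(k, S, P, H) {
  k <- .as_rate_constants(k)
  stopifnot(S >= 0)
  if (H <= 0 || P <= 0)
    stop("ratio undefined: k4*H*P is zero or negative", call. = FALSE)
  k[["k2"]] * S / (k[["k4"]] * H * P)
}

#' Mass-action ceria balance at steady state
#'
#' Checks the ceria balance implied by the time-dependent mass-action
#' system (`dC/dt = 0`): `k2*F*S = k3*C*S*H^2 + 2*k4*P*C^2*H^2`.  This
#' is the mass-action counterpart of the printed steady-state ratio
#' ([steady_state_ratio()]), which uses first powers of H and Ce3+; comparing the
#' two quantifies the discrepancy between the analytic ratio and the
#' system actually integrated.
#'
#' @param state A [dim_state()].
#' @param k A [rate_constants()] object.
#' @param tol Tolerance for the `balanced` flag.
#' @return A list with `lhs` (`k2*F*S`), `rhs`
#'   (`k3*C*S*H^2 + 2*k4*P*C^2*H^2`), `residual = lhs - rhs`, and
#'   logical `balanced`.
#' @export
mass_action_ceria_balance <- function(state, k, tol = 1e-10) {
  stopifnot(inherits(state, "dim_state"))
  k <- .as_rate_constants(k)
  lhs <- k[["k2"]] * state$F * state$S
  rhs <- k[["k3"]] * state$C * state$S * state$H^2 +
    2 * k[["k4"]] * state$P * state$C^2 * state$H^2
  list(lhs = lhs, rhs = rhs, residual = lhs - rhs,
       balanced = abs(lhs - rhs) <= tol)
}
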