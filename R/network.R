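#' The four-reaction stoichiometric network
#'
#' Builds the fixed reaction network: reactant-side mass-action orders,
#' net stoichiometry over all species (including non-dynamic water), and
#' the 6 x 4 stoichiometry matrix `N` restricted to the integrated
#' species (P, O, D, S, C, H).  The ceric row satisfies
#' `N[F, j] = -N[C, j]` for every reaction: the lattice conserves total
#' ceria.
#'
#' @return A list of class `"stoich_network"` with elements
#'   \describe{
#'     \item{reactions}{list of 4 reactions, each with `orders`
#'       (reactant-side exponents), `net` (net stoichiometry over
#'       P, O, D, S, C, F, H, W) and `rate_constant` name;}
#'     \item{N}{6 x 4 stoichiometry matrix over the integrated species;}
#'     \item{N_full}{8 x 4 matrix over all species incl. F and W.}
#'   }
#' @examples
#' net <- stoich_network()
#' net$N
#' @export
stoich_network <- function() {
  all_sp <- c("P", "O", "D", "S", "C", "F", "H", "W")
  vec <- function(...) {
    v <- stats::setNames(numeric(8), all_sp)
    args <- c(...)
    v[names(args)] <- args
    v
  }
  reactions <- list(
    # (1) H2O2 + O2 + 2 OH- -> 2 O2- + 2 H2O
    list(label = "H2O2 + O2 + 2 OH- -> 2 O2- + 2 H2O",
         rate_constant = "k1",
         orders = vec(P = 1, O = 1, D = 2),
         net    = vec(P = -1, O = -1, D = -2, S = 2, W = 2)),
    # (2) Ce4+ + O2- -> Ce3+ + O2
    list(label = "Ce4+ + O2- -> Ce3+ + O2",
         rate_constant = "k2",
         orders = vec(F = 1, S = 1),
         net    = vec(F = -1, S = -1, C = 1, O = 1)),
    # (3) Ce3+ + O2- + 2 H+ -> Ce4+ + H2O2
    list(label = "Ce3+ + O2- + 2 H+ -> Ce4+ + H2O2",
         rate_constant = "k3",
         orders = vec(C = 1, S = 1, H = 2),
         net    = vec(C = -1, S = -1, H = -2, F = 1, P = 1)),
    # (4) H2O2 + 2 Ce3+ + 2 H+ -> 2 Ce4+ + 2 H2O
    list(label = "H2O2 + 2 Ce3+ + 2 H+ -> 2 Ce4+ + 2 H2O",
         rate_constant = "k4",
         orders = vec(P = 1, C = 2, H = 2),
         net    = vec(P = -1, C = -2, H = -2, F = 2, W = 2))
  )
  N_full <- vapply(reactions, `[[`, numeric(8), "net")
  colnames(N_full) <- paste0("r", 1:4)
  structure(list(reactions = reactions,
                 N = N_full[.species, , drop = FALSE],
                 N_full = N_full),
            class = "stoich_network")
}

#' Mass-action reaction rates
#'
#' Evaluates the four rate laws at a dimensional state:
#' `r1 = k1*P*O*D^2`, `r2 = k2*F*S`, `r3 = k3*C*S*H^2`,
#' `r4 = k4*P*C^2*H^2`.
#'
#' @param state A [dim_state()].
#' @param k A [rate_constants()] object (or numeric length-4 vector).
#' @return Named numeric vector `c(r1, r2, r3, r4)`, all nonnegative.
#' @examples
#' s <- dim_state(P = 2, O = 1, D = 3, S = 0, C = 1, H = 1, Ct = 1)
#' reaction_rates(s, rate_constants())  # (18, 0, 0, 2)
#' @export
reaction_rates <- function(state, k) {
  stopifnot(inherits(state, "dim_state"))
  k <- .as_rate_constants(k)
  x <- state
  c(r1 = k[["k1"]] * x$P * x$O * x$D^2,
    r2 = k[["k2"]] * x$F * x$S,
    r3 = k[["k3"]] * x$C * x$S * x$H^2,
    r4 = k[["k4"]] * x$P * x$C^2 * x$H^2)
}

#' Dimensional ODE right-hand side
#'
#' Time derivatives of the six integrated species under the mass-action
#' system, with the ceric concentration reconstructed algebraically as
#' `F = Ct - C` so that ceria conservation holds exactly:
#' \preformatted{
#'   dP = -r1 + r3 - r4      dS = 2 r1 - r2 - r3
#'   dO = -r1 + r2           dC =  r2 - r3 - 2 r4
#'   dD = -2 r1              dH = -2 r3 - 2 r4
#' }
#' This equals the stoichiometry-matrix product `N %*% r` restricted to
#' the integrated species.  Hydroxide and hydronium are only consumed:
#' `dD <= 0` and `dH <= 0` for every nonnegative state.
#'
#' @inheritParams reaction_rates
#' @return Named numeric derivative vector over `(P, O, D, S, C, H)`
#'   in M/s.
#' @examples
#' s <- dim_state(P = 1, O = 1, D = 1, S = 1, C = 1, H = 1, Ct = 2)
#' rhs_dimensional(s, rate_constants())  # (-1, 0, -2, 0, -2, -4)
#' @export
rhs_dimensional <- function(state, k) {
  r <- reaction_rates(state, k)
  c(P = -r[["r1"]] + r[["r3"]] - r[["r4"]],
    O = -r[["r1"]] + r[["r2"]],
    D = -2 * r[["r1"]],
    S = 2 * r[["r1"]] - r[["r2"]] - r[["r3"]],
    C = r[["r2"]] - r[["r3"]] - 2 * r[["r4"]],
    H = -2 * r[["r3"]] - 2 * r[["r4"]])
}

#' Ceria conservation defect of a trajectory
#'
#' Maximum over time of `|C + F - Ct|`.  Zero in exact arithmetic; for
#' trajectories from this package it is exactly zero by construction
#' because F is reconstructed algebraically, never integrated.
#'
#' @param ts A time-series data frame with columns `C` and `F` (a
#'   `ros_timeseries` from [integrate_nondim()] or
#'   [integrate_dimensional()], or any data frame with those columns).
#' @param Ct Total ceria; defaults to the trajectory's `Ct` attribute,
#'   or 1 for non-dimensional trajectories.
#' @return Nonnegative scalar.
#' @export
ceria_conservation_defect <- function(ts, Ct = NULL) {
  stopifnot(is.data.frame(ts), all(c("C", "F") %in% names(ts)))
  if (is.null(Ct)) Ct <- attr(ts, "Ct")
  if (is.null(Ct)) Ct <- 1
  if (nrow(ts) == 0L) return(0)
  max(abs(ts$C + ts$F - Ct))
}

#' Net reaction and its multiplicities
#'
#' The reaction cycle reduces to the net reaction
#' `H2O2 + 2 O2- + 2 H+ -> 2 H2O + 2 O2`, in which ceria cancels: it is
#' a true catalyst.  The multiset of reaction multiplicities that sums to
#' the net reaction is found by solving the small integer cancellation
#' problem `N_full %*% m = net` over all eight species.
#'
#' The unique nonnegative solution is m = (0, 2, 0, 1): twice the ceric
#' reduction (2) plus once the catalase reaction (4).  No combination
#' containing reaction (1) can work, because (1) consumes hydroxide and
#' the net reaction contains none; hydroxide appears in no other
#' reaction, forcing m1 = 0, and then oxygen fixes m2 = 2, superoxide
#' m3 = 0 and cerous m4 = 1.
#'
#' @return A list with `multiplicities` (named numeric over r1..r4),
#'   `net` (net stoichiometry over all species) and `label` (the net
#'   reaction as text).  The cerous and ceric entries of `net` are zero.
#' @examples
#' net_reaction()$multiplicities
#' @export
net_reaction <- function() {
  nw <- stoich_network()
  target <- stats::setNames(numeric(8), rownames(nw$N_full))
  target[c("P", "S", "H", "W", "O")] <- c(-1, -2, -2, 2, 2)
  # least-squares solve of the overdetermined 8x4 system, then verify
  m <- stats::setNames(as.numeric(qr.solve(nw$N_full, target)),
                       colnames(nw$N_full))
  m <- round(m, 10)
  achieved <- drop(nw$N_full %*% m)
  if (max(abs(achieved - target)) > 1e-8)
    stop("net-reaction cancellation problem has no exact solution",
         call. = FALSE)
  if (any(abs(achieved[c("C", "F")]) > 1e-8))
    stop("ceria species fail to cancel in the net reaction", call. = FALSE)
  list(multiplicities = m,
       net = achieved,
       label = "H2O2 + 2 O2- + 2 H+ -> 2 H2O + 2 O2")
}

# ---- plain-text reaction listing ------------------------------------

.formula_of <- c(P = "H2O2", O = "O2", D = "OH-", S = "O2-",
                 C = "Ce3+", F = "Ce4+", H = "H+", W = "H2O")

.side_text <- function(coefs) {
  parts <- vapply(names(coefs), function(sp) {
    n <- coefs[[sp]]
    if (n == 1) .formula_of[[sp]] else paste(n, .formula_of[[sp]])
  }, character(1))
  paste(parts, collapse = " + ")
}

#' Serialize the network to a plain-text reaction listing
#'
#' One reaction per line in the dialect
#' `"H2O2 + O2 + 2 OH- -> 2 O2- + 2 H2O ; k1"`.  [parse_reactions()]
#' reads the same dialect back; the round trip reproduces the
#' mass-action orders and net stoichiometry of [stoich_network()].
#'
#' @param network A [stoich_network()].
#' @return Character vector of four lines.
#' @export
format_reactions <- function(network = stoich_network()) {
  stopifnot(inherits(network, "stoich_network"))
  vapply(network$reactions, function(r) {
    lhs <- r$orders[r$orders > 0]
    prod <- r$net + r$orders        # products = net + consumed reactants
    rhs <- prod[prod > 0]
    paste0(.side_text(as.list(lhs)), " -> ", .side_text(as.list(rhs)),
           " ; ", r$rate_constant)
  }, character(1))
}

#' Parse a plain-text reaction listing
#'
#' Inverse of [format_reactions()] for this fixed dialect (integer
#' coefficients, `->` arrow, `; k` rate-constant tag).  Not a general
#' chemistry parser.
#'
#' @param lines Character vector, one reaction per line.
#' @return A list of reactions in the [stoich_network()] per-reaction
#'   format (`orders`, `net`, `rate_constant`).
#' @export
parse_reactions <- function(lines) {
  sym_of <- stats::setNames(names(.formula_of), .formula_of)
  parse_side <- function(txt) {
    v <- stats::setNames(numeric(8), names(.formula_of))
    # split on " + " with surrounding spaces: "+" may end an ion formula
    for (term in strsplit(txt, " + ", fixed = TRUE)[[1]]) {
      term <- trimws(term)
      mt <- regmatches(term, regexec("^([0-9]+)\\s+(.*)$", term))[[1]]
      if (length(mt)) {
        n <- as.numeric(mt[2]); f <- mt[3]
      } else {
        n <- 1; f <- term
      }
      if (!f %in% names(sym_of))
        stop("unknown chemical formula in reaction line: ", f, call. = FALSE)
      v[[sym_of[[f]]]] <- v[[sym_of[[f]]]] + n
    }
    v
  }
  lapply(lines, function(ln) {
    main <- strsplit(ln, "\\s*;\\s*")[[1]]
    if (length(main) != 2L)
      stop("reaction line lacks a '; k' rate-constant tag: ", ln,
           call. = FALSE)
    sides <- strsplit(main[1], "\\s*->\\s*")[[1]]
    if (length(sides) != 2L)
      stop("reaction line lacks a single '->' arrow: ", ln, call. = FALSE)
    lhs <- parse_side(sides[1])
    rhs <- parse_side(sides[2])
    list(label = trimws(main[1]), rate_constant = trimws(main[2]),
         orders = lhs, net = rhs - lhs)
  })
}

#' @export
print.stoich_network <- function(x, ...) {
  cat("<stoich_network> 4 mass-action reactions over",
      "P O D S C F H (+ constant W)\n")
  cat(paste0("  ", format_reactions(x), collapse = "\n"), "\n")
  invisible(x)
}
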