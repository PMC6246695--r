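#' Flux balance analysis and model quality control
#'
#' The linear-programming core: maximize \eqn{c \cdot v} subject to the
#' steady-state mass balance \eqn{S v = 0} and flux bounds
#' \eqn{lb \le v \le ub}. In \code{"free-growth"} mode every exchange
#' reaction is opened to \eqn{(-1000, 1000)} before solving — the
#' permissive convention used to test whether reactions can carry flux at
#' all.
#'
#' @param model a [GSModel-class].
#' @param objective objective reaction id; defaults to the model's
#'   objective.
#' @param mode \code{"as-is"} or \code{"free-growth"}.
#' @param maximize maximize (default) or minimize the objective.
#' @return \code{fba()}: list with \code{status}
#'   (\code{"optimal"}/\code{"infeasible"}/\code{"unbounded"}),
#'   \code{objective} (LP optimum; NA unless optimal) and \code{fluxes}
#'   (named vector; any optimal vertex — only the optimum is contractual,
#'   degenerate optima may return different vertices).
#' @examples
#' m <- newModel("chain", c(c = "cytosol", e = "extracellular"))
#' m <- addMetabolite(m, "A_c"); m <- addMetabolite(m, "B_c")
#' m <- addReaction(m, "EX_A", c(A_c = 1), lb = 0, ub = 10)
#' m <- addReaction(m, "R_AB", c(A_c = -1, B_c = 1))
#' m <- addReaction(m, "EX_B", c(B_c = -1))
#' fba(m, "R_AB")$objective   # 10, limited by the uptake bound
#' @export
fba <- function(model, objective = NULL, mode = c("as-is", "free-growth"),
                maximize = TRUE) {
  mode <- match.arg(mode)
  if (is.null(objective)) objective <- model@objective
  p <- fluxProblem(model, mode)
  j <- match(objective, p$rxnIds)
  if (is.na(j)) stop("objective reaction not found: ", objective)
  cc <- numeric(length(p$rxnIds)); cc[j] <- 1
  sol <- solveLP(p$S, p$lb, p$ub, cc, maximize = maximize)
  list(status = sol$status, objective = sol$fval,
       fluxes = if (sol$status == "optimal")
         stats::setNames(sol$v, p$rxnIds) else NULL)
}

# model -> dense stoichiometric matrix + bounds; free-growth opens exchanges
fluxProblem <- function(model, mode = "as-is") {
  rxn <- model@reactions
  metIds <- model@metabolites$id
  S <- matrix(0, nrow = length(metIds), ncol = nrow(rxn),
              dimnames = list(metIds, rxn$id))
  for (i in seq_len(nrow(rxn))) {
    s <- rxn$stoich[[i]]
    S[names(s), i] <- s
  }
  lb <- rxn$lb; ub <- rxn$ub
  if (mode == "free-growth") {
    ex <- rxn$is_exchange
    lb[ex] <- -1000; ub[ex] <- 1000
  }
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("unbounded flux bounds; the LP would be unbounded — set finite bounds")
  list(S = S, lb = lb, ub = ub, rxnIds = rxn$id)
}

# bounded-variable LP via pracma::linprog in standard form:
# substitute x = v - lb >= 0, upper bounds as inequality rows,
# optimum corrected by c.lb. The big-M phase is numerically sensitive to
# the penalty magnitude, so a ladder of penalties is tried before a
# problem is declared infeasible.
solveLP <- function(S, lb, ub, cc, maximize = TRUE) {
  n <- length(lb)
  if (n == 0L) return(list(status = "optimal", fval = 0, v = numeric(0)))
  lastMsg <- ""
  for (bigM in c(1e5, 1e3, 1e6, 1e4, 1e7)) {
    res <- tryCatch(
      suppressWarnings(pracma::linprog(cc, A = diag(n), b = ub - lb,
                      Aeq = S, beq = as.numeric(-S %*% lb),
                      maximize = maximize, bigM = bigM, maxiter = 10000L)),
      error = function(e) list(errno = -99L, message = conditionMessage(e),
                               fval = NA_real_))
    if (!is.null(res$fval) && length(res$fval) == 1L && !is.na(res$fval))
      return(list(status = "optimal", fval = res$fval + sum(cc * lb),
                  v = res$x + lb))
    lastMsg <- tolower(res$message %||% "")
  }
  status <- if (grepl("unbounded", lastMsg)) "unbounded" else "infeasible"
  list(status = status, fval = NA_real_, v = NULL)
}

#' @rdname fba
#' @param reactions2 reaction ids to range; default all.
#' @return \code{fva()}: data.frame with \code{id}, \code{min_flux},
#'   \code{max_flux}, \code{blocked} (both extrema within tolerance of
#'   zero). No objective fixing is applied — ranges are over the whole
#'   feasible region, matching the carry-flux test.
#' @param tolerance absolute flux below which a reaction counts as unable
#'   to carry flux.
#' @export
fva <- function(model, reactions2 = NULL, mode = c("as-is", "free-growth"),
                tolerance = 1e-6) {
  mode <- match.arg(mode)
  p <- fluxProblem(model, mode)
  if (is.null(reactions2)) reactions2 <- p$rxnIds
  idx <- match(reactions2, p$rxnIds)
  if (anyNA(idx)) stop("unknown reaction(s): ",
                       paste(reactions2[is.na(idx)], collapse = ", "))
  mins <- maxs <- numeric(length(idx))
  for (k in seq_along(idx)) {
    cc <- numeric(length(p$rxnIds)); cc[idx[k]] <- 1
    lo <- solveLP(p$S, p$lb, p$ub, cc, maximize = FALSE)
    hi <- solveLP(p$S, p$lb, p$ub, cc, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("model infeasible under mode '", mode, "'")
    mins[k] <- lo$fval; maxs[k] <- hi$fval
  }
  data.frame(id = reactions2, min_flux = mins, max_flux = maxs,
             blocked = abs(mins) < tolerance & abs(maxs) < tolerance,
             stringsAsFactors = FALSE)
}

#' Find blocked reactions
#'
#' A reaction is blocked when it cannot carry flux above tolerance in
#' either direction under any feasible steady state; tested in free-growth
#' mode (all exchanges open), the permissive, reproducible convention.
#'
#' @inheritParams fva
#' @return character vector of blocked reaction ids (order-invariant set).
#' @export
findBlocked <- function(model, tolerance = 1e-6) {
  res <- fva(model, mode = "free-growth", tolerance = tolerance)
  sort(res$id[res$blocked])
}

#' Test whether a metabolite can be produced
#'
#' Adds a temporary demand (sink) reaction consuming the metabolite and
#' maximizes its flux in free-growth mode; the temporary reaction does not
#' survive the call.
#'
#' @param model a [GSModel-class].
#' @param metabolite metabolite id.
#' @param tolerance minimum demand flux counted as producible.
#' @return TRUE/FALSE.
#' @export
producible <- function(model, metabolite, tolerance = 1e-6) {
  if (is.na(metaboliteRow(model, metabolite)))
    stop("no such metabolite: ", metabolite)
  tmpId <- "DM_tmp_producible_"
  while (tmpId %in% model@reactions$id) tmpId <- paste0(tmpId, "x")
  trial <- addReaction(model, tmpId,
                       stats::setNames(-1, metabolite), lb = 0, ub = 1000,
                       is_exchange = FALSE)
  sol <- fba(trial, tmpId, mode = "free-growth")
  sol$status == "optimal" && sol$objective > tolerance
}
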