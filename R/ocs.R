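# Contribution-optimization scenarios: thresholds, baselines, solver
# front-end, and the fractional program for kinship at native alleles.

#' Rate of inbreeding implied by an effective population size
#'
#' @param Ne effective population size (> 0).
#' @return `deltaF = 1 / (2 Ne)`, the per-generation rate of inbreeding.
#' @export
deltaF_from_Ne <- function(Ne) {
  stopifnot(Ne > 0)
  1 / (2 * Ne)
}

#' Upper bound on offspring mean classical kinship
#'
#' Converts a target rate of inbreeding into the classical-kinship
#' constraint `ub.fA = fbar + (1 - fbar) * deltaF`, where `fbar` is the
#' average kinship among the selection candidates.
#'
#' @param mean_fA average candidate kinship, in `[0, 1)`.
#' @param deltaF target per-generation rate of inbreeding, in `(0, 1)`
#'   (0 allowed for the no-drift limit).
#' @return the kinship upper bound.
#' @export
ub_fA_from_deltaF <- function(mean_fA, deltaF) {
  stopifnot(mean_fA >= 0, mean_fA < 1, deltaF >= 0, deltaF < 1)
  mean_fA + (1 - mean_fA) * deltaF
}

#' Number of sires in the truncation-selection baseline
#'
#' Smallest number of sires such that, with `n_dams` dams and equal family
#' sizes, the effective population size `1/Ne = 1/(4 Nsire) + 1/(4 Ndam)`
#' reaches the target.
#'
#' @param Ne_target target effective population size.
#' @param n_dams number of dams.
#' @return integer number of sires.
#' @export
ts_sire_count <- function(Ne_target, n_dams) {
  stopifnot(Ne_target > 0, n_dams >= 1)
  inv <- 1 / Ne_target - 1 / (4 * n_dams)
  if (inv <= 0) stop("dam number too small for target Ne")
  as.integer(ceiling(1 / (4 * inv)))
}

#' Interpolated constraint bounds between the reference and the optimum
#'
#' Each bound is placed a fraction `lambda` of the way from its value in the
#' equal-contribution reference scenario toward its single-constraint
#' optimum (the scenario optimizing that criterion under the classical
#' kinship bound alone): `bound = lambda * optimum + (1 - lambda) * ref`.
#'
#' @param lambda proportion of the maximum progress to require, in `[0, 1]`.
#' @param optima named numeric vector of single-constraint optima; names
#'   among `fB`, `fC`, `fD`, `MC`, `EBV`.
#' @param ref_values named numeric vector of reference-scenario values with
#'   the same names.
#' @param which criteria to derive (default: all names in `optima`).
#' @return named list with elements among `ub_fB`, `ub_fC`, `ub_fD`,
#'   `ub_MC`, `lb_EBV`.
#' @export
derive_bounds <- function(lambda, optima, ref_values,
                          which = names(optima)) {
  stopifnot(lambda >= 0, lambda <= 1)
  out <- list()
  for (crit in which) {
    if (!crit %in% names(optima) || !crit %in% names(ref_values)) {
      stop("missing single-constraint optimum or reference value for ", crit)
    }
    val <- lambda * optima[[crit]] + (1 - lambda) * ref_values[[crit]]
    key <- if (crit == "EBV") "lb_EBV" else paste0("ub_", crit)
    out[[key]] <- unname(val)
  }
  out
}

#' Selected-sire fraction and spread of male contributions
#'
#' A sire counts as selected when its contribution reaches the non-zero
#' threshold (default 0.00025, absorbing numerical noise of the solver).
#' The standard deviation is over all male contributions including zeros.
#'
#' @param c_males numeric vector of male contributions.
#' @param threshold non-zero contribution threshold.
#' @return list with `fraction` and `sd`.
#' @export
count_selected <- function(c_males, threshold = 0.00025) {
  list(fraction = mean(c_males >= threshold),
       sd = stats::sd(c_males))
}

# ---- scenario specification --------------------------------------------

.objectives <- c(minfB = "min_fB", minfC = "min_fC", minfD = "min_fD",
                 minMC = "min_MC", maxEBV = "max_EBV", minfA = "min_fA")
.suffix_keys <- c(A = "ub_fA", B = "ub_fB", C = "ub_fC", D = "ub_fD",
                  MC = "ub_MC", EBV = "lb_EBV")

#' Parse a scenario name into objective and constraint set
#'
#' Scenario names consist of an objective prefix (`minfB`, `minfC`, `minfD`,
#' `minMC`, `maxEBV`) and a dot-separated suffix of constraint letters
#' (`A`, `B`, `C`, `D`, `MC`, `EBV`), e.g. `"maxEBV.A.D.MC"`.
#'
#' @param name scenario name string.
#' @return list with `objective` (e.g. `"max_EBV"`) and `constraints`
#'   (bound keys, e.g. `c("ub_fA", "ub_fD", "ub_MC")`).
#' @export
parse_scenario <- function(name) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  if (!parts[1] %in% names(.objectives)) {
    stop("unknown objective prefix: ", parts[1])
  }
  suf <- parts[-1]
  if (!all(suf %in% names(.suffix_keys))) {
    stop("unknown constraint letter(s): ",
         paste(setdiff(suf, names(.suffix_keys)), collapse = ", "))
  }
  list(objective = unname(.objectives[parts[1]]),
       constraints = unname(.suffix_keys[suf]))
}

#' Specify an optimization scenario
#'
#' @param objective one of `"min_fB"`, `"min_fC"`, `"min_fD"`, `"min_MC"`,
#'   `"max_EBV"` (and `"min_fA"`, for validation).
#' @param bounds named list of active bounds among `ub_fA`, `ub_fB`,
#'   `ub_fC`, `ub_fD`, `ub_MC`, `lb_EBV`.
#' @param name scenario label; derived from objective and bounds if omitted.
#' @param optimize_both_sexes reserved switch; only male optimization is
#'   implemented (female contributions are fixed equal).
#' @return a `nocs_scenario` list.
#' @export
scenario_spec <- function(objective, bounds = list(), name = NULL,
                          optimize_both_sexes = FALSE) {
  stopifnot(objective %in% .objectives)
  bad <- setdiff(names(bounds), unname(.suffix_keys))
  if (length(bad)) stop("unknown bound(s): ", paste(bad, collapse = ", "))
  if (optimize_both_sexes) {
    stop("both-sexes optimization is not implemented")
  }
  if (is.null(name)) {
    pre <- names(.objectives)[match(objective, .objectives)]
    suf <- names(.suffix_keys)[match(names(bounds), .suffix_keys)]
    name <- paste(c(pre, suf), collapse = ".")
  }
  structure(list(objective = objective, bounds = bounds, name = name),
            class = "nocs_scenario")
}

# ---- problem assembly ---------------------------------------------------

# Expands c'Mc over c = (x, wf) into male-variable form
# x'Qx + l'x + const, with the fixed equal female block absorbed.
.expand_quad <- function(M, males, females, wf) {
  Mmm <- M[males, males, drop = FALSE]
  Mmf <- M[males, females, drop = FALSE]
  Mff <- M[females, females, drop = FALSE]
  fcol <- drop(Mmf %*% rep(wf, length(females)))
  list(Q = Mmm, l = 2 * fcol,
       const = sum(Mff) * wf^2)
}

.expand_lin <- function(v, males, females, wf) {
  list(l = v[males], const = sum(v[females]) * wf)
}

# Builds objective and constraint list in male variables. `kin` is a
# pedigree_kinships() set covering all candidates; `cands` must be
# normalized. Returns the internal problem representation.
build_problem <- function(spec, kin, cands, fD_eps = 1e-8) {
  stopifnot(inherits(spec, "nocs_scenario"),
            inherits(cands, "nocs_candidates"))
  if (is.null(cands$data$ebv_norm)) {
    stop("candidates must be EBV-normalized (normalize_ebv)")
  }
  males <- cands$males
  females <- cands$females
  wf <- 0.5 / length(females)
  vec <- function(col) stats::setNames(cands$data[[col]], cands$data$id)
  qfA <- .expand_quad(kin$fA, males, females, wf)
  qfB <- .expand_quad(kin$fB, males, females, wf)
  qfC <- .expand_quad(kin$fC, males, females, wf)
  qfN <- .expand_quad(kin$fN, males, females, wf)
  qK  <- .expand_quad(kin$Knat, males, females, wf)
  lMC  <- .expand_lin(vec("mc"), males, females, wf)
  lEBV <- .expand_lin(vec("ebv_norm"), males, females, wf)

  cons <- list()
  b <- spec$bounds
  addq <- function(cons, q, ub, name) {
    c(cons, list(list(Q = q$Q, l = q$l, ub = ub - q$const, name = name)))
  }
  if (!is.null(b$ub_fA)) cons <- addq(cons, qfA, b$ub_fA, "ub_fA")
  if (!is.null(b$ub_fB)) cons <- addq(cons, qfB, b$ub_fB, "ub_fB")
  if (!is.null(b$ub_fC)) cons <- addq(cons, qfC, b$ub_fC, "ub_fC")
  if (!is.null(b$ub_fD)) {
    # fD(c) <= ub  <=>  c'fB c + (1 - ub) c'fN c <= 1; PSD when ub <= 1.
    w <- 1 - b$ub_fD
    q <- list(Q = qfB$Q + w * qfN$Q, l = qfB$l + w * qfN$l,
              const = qfB$const + w * qfN$const)
    if (w < 0) {
      ev <- min(eigen(q$Q, symmetric = TRUE, only.values = TRUE)$values)
      if (ev < -1e-8) stop("fD bound above 1 yields a non-convex constraint")
    }
    cons <- addq(cons, q, 1, "ub_fD")
  }
  if (!is.null(b$ub_MC)) {
    cons <- c(cons, list(list(Q = NULL, l = lMC$l,
                              ub = b$ub_MC - lMC$const, name = "ub_MC")))
  }
  if (!is.null(b$lb_EBV)) {
    cons <- c(cons, list(list(Q = NULL, l = -lEBV$l,
                              ub = -(b$lb_EBV - lEBV$const),
                              name = "lb_EBV")))
  }
  obj <- switch(spec$objective,
    min_fA = list(Q = qfA$Q, l = qfA$l, const = qfA$const, sense = "min"),
    min_fB = list(Q = qfB$Q, l = qfB$l, const = qfB$const, sense = "min"),
    min_fC = list(Q = qfC$Q, l = qfC$l, const = qfC$const, sense = "min"),
    min_MC = list(Q = NULL, l = lMC$l, const = lMC$const, sense = "min"),
    max_EBV = list(Q = NULL, l = -lEBV$l, const = -lEBV$const,
                   sense = "min"),
    min_fD = list(fractional = TRUE, num = qK, den = qfN, sense = "min"))
  list(spec = spec, obj = obj, cons = cons, n = length(males),
       males = males, females = females, wf = wf, fD_eps = fD_eps)
}

.full_contrib <- function(x, prob) {
  stats::setNames(c(x, rep(prob$wf, length(prob$females))),
                  c(prob$males, prob$females))
}

.achieved <- function(contrib, kin, cands, fD_eps = 1e-8) {
  vec <- function(col) stats::setNames(cands$data[[col]], cands$data$id)
  c(fA = mean_kinship(contrib, kin$fA),
    fB = mean_kinship(contrib, kin$fB),
    fC = mean_kinship(contrib, kin$fC),
    fD = fD_of_contributions(contrib, kin$fB, kin$fN, eps = fD_eps),
    MC = sum(contrib * vec("mc")[names(contrib)]),
    EBV = sum(contrib * vec("ebv_norm")[names(contrib)]))
}

.make_result <- function(x, status, prob, kin, cands, threshold = 0.00025) {
  contrib <- .full_contrib(x, prob)
  sel <- count_selected(x, threshold)
  structure(list(name = prob$spec$name,
                 c = contrib,
                 c_males = stats::setNames(x, prob$males),
                 achieved = .achieved(contrib, kin, cands, prob$fD_eps),
                 selected_fraction = sel$fraction,
                 sd_male_contributions = sel$sd,
                 solver_status = status,
                 bounds = prob$spec$bounds),
            class = "nocs_result")
}

#' @export
print.nocs_result <- function(x, digits = 3, ...) {
  cat(sprintf("Scenario %s [%s]\n", x$name, x$solver_status))
  print(round(x$achieved, digits))
  cat(sprintf("selected sires: %.3f of candidates; sd(c_males) = %.4f\n",
              x$selected_fraction, x$sd_male_contributions))
  invisible(x)
}

#' Equal-contribution reference scenario
#'
#' All selection candidates are parents with equal contributions within
#' each sex (each sex summing to 0.5).
#'
#' @param cands normalized [select_candidates()] object.
#' @param kin [pedigree_kinships()] set over the candidates.
#' @return a `nocs_result`.
#' @export
ref_scenario <- function(cands, kin) {
  prob <- build_problem(scenario_spec("max_EBV", name = "REF"), kin, cands)
  x <- rep(0.5 / length(cands$males), length(cands$males))
  .make_result(x, "optimal", prob, kin, cands)
}

#' Truncation-selection baseline
#'
#' The top sires by normalized EBV (count from [ts_sire_count()] for the
#' target effective population size and the number of female candidates)
#' receive equal contributions; all females contribute equally. Ties at the
#' EBV cutoff are broken by ascending id.
#'
#' @inheritParams ref_scenario
#' @param Ne_target target effective population size (default 50).
#' @return a `nocs_result`.
#' @export
ts_scenario <- function(cands, kin, Ne_target = 50) {
  n_need <- ts_sire_count(Ne_target, length(cands$females))
  males <- cands$males
  if (n_need >= length(males)) {
    warning("target Ne requires all ", length(males), " male candidates")
    n_need <- length(males)
  }
  ebv <- cands$data$ebv_norm[match(males, cands$data$id)]
  top <- males[order(-ebv, males)][seq_len(n_need)]
  x <- numeric(length(males))
  x[males %in% top] <- 0.5 / n_need
  prob <- build_problem(scenario_spec("max_EBV", name = "TS"), kin, cands)
  .make_result(x, "optimal", prob, kin, cands)
}

#' Solve a contribution-optimization scenario
#'
#' Convex objectives (minimizing `fB`, `fC`, `MC`, maximizing `EBV`, and the
#' validation objective `fA`) are solved to optimality with an interior-point
#' barrier method; the fractional objective `fD` is routed through
#' [minimize_fD()] and reported with status `"local"`. Female contributions
#' are fixed equal at `0.5 / n_females`; male contributions satisfy
#' `c >= 0`, `sum = 0.5`, `c <= 0.5`.
#'
#' @param spec a [scenario_spec()] (or scenario name string).
#' @param kin [pedigree_kinships()] set over the candidates.
#' @param cands normalized [select_candidates()] object.
#' @param bounds optional named list of bound values substituted into a
#'   scenario given by name.
#' @param tol feasibility tolerance on bounds for the returned solution.
#' @param ... passed to [minimize_fD()] for fractional objectives.
#' @return a `nocs_result`; `solver_status` is `"optimal"`, `"local"` or
#'   `"infeasible"`.
#' @export
solve_scenario <- function(spec, kin, cands, bounds = NULL, tol = 1e-6,
                           ...) {
  if (is.character(spec)) {
    parsed <- parse_scenario(spec)
    use <- bounds[parsed$constraints]
    if (any(vapply(use, is.null, logical(1)))) {
      stop("missing bound value(s) for scenario ", spec)
    }
    spec <- scenario_spec(parsed$objective, use, name = spec)
  }
  if (spec$objective == "min_fD") {
    return(minimize_fD(kin, cands, spec$bounds, name = spec$name, ...))
  }
  prob <- build_problem(spec, kin, cands)
  sol <- .solve_convex(prob$obj, prob$cons, prob$n)
  if (sol$status == "infeasible") {
    res <- .make_result(sol$x, "infeasible", prob, kin, cands)
    res$violated <- sol$violated
    return(res)
  }
  .check_bounds(sol$x, prob, tol)
  .make_result(sol$x, sol$status, prob, kin, cands)
}

.check_bounds <- function(x, prob, tol) {
  for (con in prob$cons) {
    v <- .qp_eval(con, x)
    if (v > tol) {
      stop("solution violates ", con$name, " by ", signif(v, 3))
    }
  }
  if (abs(sum(x) - 0.5) > 1e-8) stop("male contributions do not sum to 0.5")
  invisible(TRUE)
}

#' Minimize the kinship at native alleles
#'
#' Minimizing `fD(c) = c'Knat c / c'fN c` is a fractional - and in general
#' non-convex - program. It is solved by Dinkelbach iteration: for the
#' current ratio `q`, the subproblem `min c'Knat c - q c'fN c` is made
#' convex by linearizing the concave term `-q c'fN c` around the current
#' iterate (a convex-concave step), and `q` is updated to the achieved
#' ratio until the fixed point `|q_{k+1} - q_k| < tol`. Several seeded
#' starts (equal contributions, the classical-kinship minimizer, and random
#' feasible points) guard against poor local solutions; the best is
#' returned with status `"local"`.
#'
#' @param kin [pedigree_kinships()] set over the candidates.
#' @param cands normalized [select_candidates()] object.
#' @param bounds named list of active bounds (as in [scenario_spec()]).
#' @param tol fixed-point tolerance on the ratio.
#' @param n_starts number of starts (>= 1; the first two are deterministic).
#' @param seed seed for the random starts.
#' @param name scenario label.
#' @param feas_tol feasibility tolerance on bounds.
#' @return a `nocs_result` with status `"local"` (or `"infeasible"`).
#' @export
minimize_fD <- function(kin, cands, bounds = list(), tol = 1e-8,
                        n_starts = 5L, seed = 1L, name = NULL,
                        feas_tol = 1e-6) {
  spec <- scenario_spec("min_fD", bounds, name = name)
  prob <- build_problem(spec, kin, cands)
  n <- prob$n
  num <- prob$obj$num
  den <- prob$obj$den
  ratio <- function(x) {
    (drop(crossprod(x, num$Q %*% x)) + sum(num$l * x) + num$const) /
      (drop(crossprod(x, den$Q %*% x)) + sum(den$l * x) + den$const)
  }
  starts <- list(rep(0.5 / n, n))
  minA <- .solve_convex(list(Q = .expand_quad(kin$fA, prob$males,
                                              prob$females, prob$wf)$Q,
                             l = .expand_quad(kin$fA, prob$males,
                                              prob$females, prob$wf)$l),
                        prob$cons, n)
  if (minA$status != "infeasible") starts <- c(starts, list(minA$x))
  if (n_starts > length(starts)) {
    extra <- withr::with_seed(as.integer(seed), {
      lapply(seq_len(n_starts - length(starts)), function(i) {
        w <- stats::rexp(n)
        0.5 * w / sum(w)
      })
    })
    starts <- c(starts, extra)
  }
  best <- NULL
  for (x0 in starts) {
    p1 <- .phase1(prob$cons, rep(0, n), rep(0.5, n),
                  matrix(1, 1, n), 0.5, x0)
    if (!p1$feasible) next
    x <- p1$x
    q <- ratio(x)
    for (it in seq_len(50L)) {
      # convex subproblem: num(x) - q * linearized den around x
      gden <- 2 * drop(den$Q %*% x) + den$l
      sub <- list(Q = num$Q, l = num$l - q * gden)
      sol <- .solve_convex(sub, prob$cons, n, x0 = x, gap_tol = 1e-10)
      if (sol$status == "infeasible") break
      qn <- ratio(sol$x)
      x <- sol$x
      if (abs(qn - q) < tol) {
        q <- qn
        break
      }
      q <- qn
    }
    if (is.null(best) || q < best$q) best <- list(x = x, q = q)
  }
  if (is.null(best)) {
    res <- .make_result(rep(0.5 / n, n), "infeasible", prob, kin, cands)
    return(res)
  }
  .check_bounds(best$x, prob, feas_tol)
  .make_result(best$x, "local", prob, kin, cands)
}

#' Run a full scenario suite with interpolated bounds
#'
#' Computes the reference and truncation-selection baselines, derives the
#' classical-kinship bound from the target rate of inbreeding, solves the
#' five single-constraint scenarios (`minfB.A`, `minfC.A`, `minfD.A`,
#' `minMC.A`, `maxEBV.A`), interpolates all other bounds between the
#' reference values and these optima with weight `lambda`, and solves the
#' requested scenarios.
#'
#' @param kin [pedigree_kinships()] set over the candidates.
#' @param cands normalized [select_candidates()] object.
#' @param scenarios character vector of scenario names (see
#'   [parse_scenario()]); baselines and single-constraint scenarios are
#'   always included.
#' @param lambda proportion of maximum progress required of each
#'   constrained criterion (default 0.3).
#' @param Ne_target target effective population size (default 50) driving
#'   both the kinship bound and the truncation baseline.
#' @param mean_fA average candidate kinship used for the `fA` bound;
#'   defaults to the off-diagonal mean of the candidate `fA` block.
#' @param ... passed to [solve_scenario()].
#' @return list with `results` (named list of `nocs_result`), `bounds`
#'   (derived bound values) and `table` (a [summarize_scenarios()] report).
#' @export
run_ocs <- function(kin, cands, scenarios = character(), lambda = 0.3,
                    Ne_target = 50, mean_fA = NULL, ...) {
  if (is.null(mean_fA)) {
    fAc <- kin$fA
    mean_fA <- mean(fAc[row(fAc) != col(fAc)])
  }
  ub_fA <- ub_fA_from_deltaF(mean_fA, deltaF_from_Ne(Ne_target))
  results <- list(REF = ref_scenario(cands, kin),
                  TS = ts_scenario(cands, kin, Ne_target))
  singles <- c("minfB.A", "minfC.A", "minfD.A", "minMC.A", "maxEBV.A")
  base_bounds <- list(ub_fA = ub_fA)
  for (s in singles) {
    results[[s]] <- solve_scenario(s, kin, cands, bounds = base_bounds, ...)
  }
  crit_of <- c(minfB.A = "fB", minfC.A = "fC", minfD.A = "fD",
               minMC.A = "MC", maxEBV.A = "EBV")
  optima <- vapply(names(crit_of), function(s) {
    results[[s]]$achieved[[crit_of[[s]]]]
  }, numeric(1))
  names(optima) <- unname(crit_of)
  refv <- results$REF$achieved[c("fB", "fC", "fD", "MC", "EBV")]
  bounds <- c(base_bounds, derive_bounds(lambda, optima, refv))
  for (s in setdiff(scenarios, names(results))) {
    results[[s]] <- solve_scenario(s, kin, cands, bounds = bounds, ...)
  }
  list(results = results, bounds = bounds,
       table = summarize_scenarios(results, bounds))
}
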