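# Shared fixtures. The canonical small pedigrees come from the package's
# own fixture_suite(); the synthetic candidate population is built once per
# test run and memoized because the kinship matrices are the expensive part.

fx <- fixture_suite()

.pop_cache <- new.env(parent = emptyenv())

get_population <- function() {
  if (is.null(.pop_cache$pop)) {
    pop <- generate_pedigree(synth_config(seed = 11L))
    cands <- candidates_from_population(pop, seed = 11L)
    kin <- pedigree_kinships(pop$pedigree, pop$origin, cands$data$id)
    .pop_cache$pop <- list(pop = pop, cands = cands, kin = kin)
  }
  .pop_cache$pop
}

# memoized baseline + single-constraint suite over the population
get_ocs_suite <- function() {
  if (is.null(.pop_cache$suite)) {
    p <- get_population()
    .pop_cache$suite <- run_ocs(
      p$kin, p$cands,
      scenarios = c("maxEBV.A.MC", "maxEBV.A.B.MC", "maxEBV.A.D.MC"))
  }
  .pop_cache$suite
}

# small candidate set over a fixture pedigree, with synthetic EBVs
toy_candidates <- function(fixture, n_males = 3L, n_females = 2L,
                           ebv = NULL, seed = 5L) {
  ped <- fixture$pedigree
  org <- fixture$origin
  ok <- !ped$phantom & !is.na(ped$sire)
  males <- utils::head(ped$id[ped$sex == "M" & ok], n_males)
  females <- utils::head(ped$id[ped$sex == "F" & ok], n_females)
  stopifnot(length(males) == n_males, length(females) == n_females)
  ids <- c(males, females)
  if (is.null(ebv)) {
    ebv <- withr::with_seed(seed, stats::rnorm(length(ids)))
  }
  cands <- structure(list(
    males = males, females = females,
    data = data.frame(id = ids,
                      sex = rep(c("M", "F"), c(n_males, n_females)),
                      ebv = ebv,
                      mc = org$mc[match(ids, org$id)],
                      stringsAsFactors = FALSE)),
    class = "nocs_candidates")
  normalize_ebv(cands)
}

# brute-force simplex grid search over male contributions (females fixed
# equal); step is the contribution resolution
grid_search <- function(kin, cands, objective, cons = list(), step = 1e-3) {
  males <- cands$males
  females <- cands$females
  stopifnot(length(males) %in% 2:3)
  wf <- 0.5 / length(females)
  qfun <- function(M) {
    Qm <- M[males, males, drop = FALSE]
    l <- 2 * drop(M[males, females, drop = FALSE] %*%
                    rep(wf, length(females)))
    cst <- sum(M[females, females]) * wf^2
    function(X) rowSums((X %*% Qm) * X) + drop(X %*% l) + cst
  }
  vfun <- function(v) {
    vv <- stats::setNames(v, cands$data$id)
    function(X) drop(X %*% vv[males]) + sum(vv[females]) * wf
  }
  funs <- list(fA = qfun(kin$fA), fB = qfun(kin$fB), fC = qfun(kin$fC),
               fN = qfun(kin$fN), Knat = qfun(kin$Knat),
               MC = vfun(cands$data$mc), EBV = vfun(cands$data$ebv_norm))
  evalobj <- function(X) {
    switch(objective,
           min_fB = funs$fB(X), min_fC = funs$fC(X), min_fA = funs$fA(X),
           min_MC = funs$MC(X), max_EBV = -funs$EBV(X),
           min_fD = funs$Knat(X) / funs$fN(X))
  }
  feasible <- function(X) {
    ok <- rep(TRUE, nrow(X))
    if (!is.null(cons$ub_fA)) ok <- ok & funs$fA(X) <= cons$ub_fA
    if (!is.null(cons$ub_fB)) ok <- ok & funs$fB(X) <= cons$ub_fB
    if (!is.null(cons$ub_fC)) ok <- ok & funs$fC(X) <= cons$ub_fC
    if (!is.null(cons$ub_fD)) {
      ok <- ok & (funs$fB(X) + (1 - cons$ub_fD) * funs$fN(X)) <= 1
    }
    if (!is.null(cons$ub_MC)) ok <- ok & funs$MC(X) <= cons$ub_MC
    if (!is.null(cons$lb_EBV)) ok <- ok & funs$EBV(X) >= cons$lb_EBV
    ok
  }
  best <- Inf
  bx <- NULL
  take <- function(X) {
    v <- evalobj(X)
    v[!feasible(X)] <- Inf
    i <- which.min(v)
    if (v[i] < best) {
      best <<- v[i]
      bx <<- X[i, ]
    }
  }
  if (length(males) == 2L) {
    a <- seq(0, 0.5, by = step)
    take(cbind(a, 0.5 - a))
  } else {
    for (a in seq(0, 0.5, by = step)) {
      b <- seq(0, 0.5 - a, by = step)
      take(cbind(a, b, 0.5 - a - b))
    }
  }
  list(value = best, x = bx)
}
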