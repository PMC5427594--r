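# Classical and origin-aware kinship recursions (tabular method).

# Joint tabular recursion over the ancestor-closed pedigree. All four
# matrices share the half-parent rule
#   f(i,j) = (f(s_i,j) + f(d_i,j)) / 2,        i later in the order,
# and differ only in diagonal and founder base cases:
#   fA   : founder diag 1/2,    cross 0,            diag (1 + f(s,d))/2
#   fN   : founder diag n_i,    cross n_i * n_j,    diag (n_i + f(s,d))/2
#   fM   : as fN with m_i = mc_i
#   Knat : founder diag n_i/2,  cross 0,            diag (n_i + f(s,d))/2
# where n_i is the expected native fraction of i's genome. Diagonals use the
# with-replacement convention, so c'fc is the offspring-generation mean.
.kinship_core <- function(ped, origin = NULL,
                          need = c("fA", "fN", "fM", "Knat")) {
  n <- nrow(ped)
  fo <- .founder_mask(ped)
  # founders come first in an as_pedigree() ordering; enforce defensively
  if (any(which(fo) > sum(fo))) {
    ord <- order(!fo, seq_len(n))
    ped <- ped[ord, , drop = FALSE]
    fo <- .founder_mask(ped)
  }
  nf <- sum(fo)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  want_origin <- any(c("fN", "fM", "Knat") %in% need)
  if (want_origin) {
    if (is.null(origin) || is.null(origin$mc)) {
      stop("origin annotation with migrant contributions required")
    }
    mc <- origin$mc[match(ped$id, origin$id)]
    if (any(is.na(mc))) stop("origin annotation does not cover pedigree")
    nat <- 1 - mc
  }
  out <- list()
  if ("fA" %in% need) {
    A <- matrix(0, n, n)
    diag(A)[seq_len(nf)] <- 0.5
    out$fA <- A
  }
  if ("fN" %in% need) {
    N <- matrix(0, n, n)
    N[seq_len(nf), seq_len(nf)] <- outer(nat[seq_len(nf)], nat[seq_len(nf)])
    diag(N)[seq_len(nf)] <- nat[seq_len(nf)]
    out$fN <- N
  }
  if ("fM" %in% need) {
    M <- matrix(0, n, n)
    M[seq_len(nf), seq_len(nf)] <- outer(mc[seq_len(nf)], mc[seq_len(nf)])
    diag(M)[seq_len(nf)] <- mc[seq_len(nf)]
    out$fM <- M
  }
  if ("Knat" %in% need) {
    K <- matrix(0, n, n)
    diag(K)[seq_len(nf)] <- nat[seq_len(nf)] / 2
    out$Knat <- K
  }
  if (n > nf) {
    hasA <- !is.null(out$fA); hasN <- !is.null(out$fN)
    hasM <- !is.null(out$fM); hasK <- !is.null(out$Knat)
    A <- out$fA; N <- out$fN; M <- out$fM; K <- out$Knat
    for (i in (nf + 1L):n) {
      s <- si[i]; d <- di[i]; js <- seq_len(i - 1L)
      if (hasA) {
        r <- (A[s, js] + A[d, js]) / 2
        A[i, js] <- r; A[js, i] <- r
        A[i, i] <- (1 + A[s, d]) / 2
      }
      if (hasN) {
        r <- (N[s, js] + N[d, js]) / 2
        N[i, js] <- r; N[js, i] <- r
        N[i, i] <- (nat[i] + N[s, d]) / 2
      }
      if (hasM) {
        r <- (M[s, js] + M[d, js]) / 2
        M[i, js] <- r; M[js, i] <- r
        M[i, i] <- (mc[i] + M[s, d]) / 2
      }
      if (hasK) {
        r <- (K[s, js] + K[d, js]) / 2
        K[i, js] <- r; K[js, i] <- r
        K[i, i] <- (nat[i] + K[s, d]) / 2
      }
    }
    if (hasA) out$fA <- A
    if (hasN) out$fN <- N
    if (hasM) out$fM <- M
    if (hasK) out$Knat <- K
  }
  for (nm in names(out)) dimnames(out[[nm]]) <- list(ped$id, ped$id)
  out
}

.kin_subset <- function(mats, ids) {
  lapply(mats, function(m) m[ids, ids, drop = FALSE])
}

#' Classical pedigree kinship (tabular method)
#'
#' Probability that two alleles at a locus, one drawn from each individual
#' (with replacement for self-pairs), are identical by descent.
#'
#' @param ped a [as_pedigree()] object.
#' @param ids candidate identifiers defining the returned block (default:
#'   all non-phantom individuals).
#' @return symmetric kinship matrix over `ids`.
#' @export
kinship_classical <- function(ped, ids = NULL) {
  ids <- .default_ids(ped, ids)
  sub <- prune_pedigree(ped, ids)
  .kinship_core(sub, need = "fA")$fA[ids, ids, drop = FALSE]
}

.default_ids <- function(ped, ids) {
  if (is.null(ids)) ped$id[!ped$phantom] else as.character(ids)
}

#' Probability that both sampled alleles are of native origin
#'
#' @inheritParams kinship_classical
#' @param origin a [compute_mc()] annotation.
#' @return symmetric matrix `fN` over `ids`.
#' @export
native_pair_prob <- function(ped, origin, ids = NULL) {
  ids <- .default_ids(ped, ids)
  sub <- prune_pedigree(ped, ids)
  .kinship_core(sub, origin, need = "fN")$fN[ids, ids, drop = FALSE]
}

#' Probability that both sampled alleles are of migrant origin
#'
#' @inheritParams native_pair_prob
#' @return symmetric matrix `fM` over `ids`.
#' @export
migrant_pair_prob <- function(ped, origin, ids = NULL) {
  ids <- .default_ids(ped, ids)
  sub <- prune_pedigree(ped, ids)
  .kinship_core(sub, origin, need = "fM")$fM[ids, ids, drop = FALSE]
}

#' Probability that both sampled alleles are IBD and of native origin
#'
#' @inheritParams native_pair_prob
#' @return symmetric matrix `Knat` over `ids`.
#' @export
native_ibd_kinship <- function(ped, origin, ids = NULL) {
  ids <- .default_ids(ped, ids)
  sub <- prune_pedigree(ped, ids)
  .kinship_core(sub, origin, need = "Knat")$Knat[ids, ids, drop = FALSE]
}

#' Assemble the kinship fB (IBD or at least one migrant allele)
#'
#' Alleles that are IBD are copies of a single founder allele and therefore
#' never of mixed origin, so the union decomposes into the disjoint sum
#' `fB = Knat + (1 - fN)`.
#'
#' @param Knat,fN matrices with matching id order.
#' @return symmetric matrix `fB`.
#' @export
assemble_fB <- function(Knat, fN) {
  .check_match(Knat, fN)
  fB <- Knat + (1 - fN)
  .check_unit_range(fB, "fB")
  fB
}

#' Assemble the kinship fC (IBD or both alleles migrant)
#'
#' IBD-and-both-migrant pairs are already contained in the both-migrant
#' probability, so `fC = Knat + fM` (the IBD-and-both-native part plus the
#' both-migrant part; mixed-origin IBD pairs do not exist).
#'
#' @param Knat,fM matrices with matching id order.
#' @return symmetric matrix `fC`.
#' @export
assemble_fC <- function(Knat, fM) {
  .check_match(Knat, fM)
  fC <- Knat + fM
  .check_unit_range(fC, "fC")
  fC
}

.check_match <- function(a, b) {
  if (!identical(dim(a), dim(b)) ||
      !identical(rownames(a), rownames(b))) {
    stop("matrices have mismatching ids")
  }
}

.check_unit_range <- function(m, what, tol = 1e-9) {
  if (any(m < -tol) || any(m > 1 + tol)) {
    stop("internal consistency error: ", what, " outside [0, 1]")
  }
}

#' Compute the full kinship set over candidates
#'
#' Computes `fA`, `fN`, `fM` and `Knat` by pedigree recursion over the
#' ancestor closure of `ids`, and derives `fB = Knat + (1 - fN)` and
#' `fC = Knat + fM`.
#'
#' @inheritParams native_pair_prob
#' @return an object of class `nocs_kinships`: a list of the six matrices
#'   plus `ids`.
#' @export
pedigree_kinships <- function(ped, origin, ids = NULL) {
  ids <- .default_ids(ped, ids)
  sub <- prune_pedigree(ped, ids)
  mats <- .kin_subset(.kinship_core(sub, origin), ids)
  mats$fB <- assemble_fB(mats$Knat, mats$fN)
  mats$fC <- assemble_fC(mats$Knat, mats$fM)
  mats$ids <- ids
  class(mats) <- "nocs_kinships"
  mats
}

#' @export
print.nocs_kinships <- function(x, ...) {
  cat(sprintf("Kinship set over %d candidates: %s\n", length(x$ids),
              paste(setdiff(names(x), "ids"), collapse = ", ")))
  invisible(x)
}

#' Offspring-generation mean kinship
#'
#' The expected kinship in the offspring generation given genetic
#' contributions `c` is the quadratic form `c' M c`.
#'
#' @param contrib named numeric contribution vector summing to 1.
#' @param M kinship matrix whose rownames cover `names(contrib)`.
#' @return scalar `c' M c`.
#' @export
mean_kinship <- function(contrib, M) {
  if (is.null(names(contrib)) || !all(names(contrib) %in% rownames(M))) {
    stop("contribution vector does not match matrix ids")
  }
  if (abs(sum(contrib) - 1) > 1e-6) {
    stop("contributions must sum to 1")
  }
  m <- M[names(contrib), names(contrib), drop = FALSE]
  drop(crossprod(contrib, m %*% contrib))
}

#' Kinship at native alleles of an offspring generation
#'
#' The conditional probability that two alleles drawn from the offspring
#' generation are IBD given that both descended from native founders:
#' `fD(c) = 1 - (1 - c'fB c) / (c'fN c)`, algebraically equal to
#' `c'Knat c / c'fN c`.
#'
#' @param contrib named contribution vector summing to 1.
#' @param fB,fN kinship matrices with matching ids.
#' @param eps smallest admissible native-pair probability; below this the
#'   offspring generation has no native ancestry and `fD` is undefined.
#' @return scalar `fD(c)`.
#' @export
fD_of_contributions <- function(contrib, fB, fN, eps = 1e-8) {
  den <- mean_kinship(contrib, fN)
  if (den <= eps) stop("no native ancestry in offspring generation")
  1 - (1 - mean_kinship(contrib, fB)) / den
}
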