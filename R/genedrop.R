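# Gene-dropping and exhaustive transmission-enumeration oracles.
# These estimate/compute the same probabilities as the kinship recursions by
# simulating (or enumerating) allele transmission from uniquely labeled
# founder alleles, and serve as independent correctness checks.

.drop_setup <- function(ped, origin, ids) {
  fo <- .founder_mask(ped)
  if (any(which(fo) > sum(fo))) stop("pedigree not founder-first ordered")
  mig <- origin$migrant[match(ped$id, origin$id)]
  if (any(fo & is.na(mig))) stop("founder without origin flag")
  list(n = nrow(ped), nf = sum(fo),
       si = match(ped$sire, ped$id), di = match(ped$dam, ped$id),
       # founder k carries alleles 2k-1, 2k; lookup: is allele migrant?
       allele_mig = rep(mig[fo], each = 2L),
       sub = match(ids, ped$id))
}

.pair_index <- function(k) {
  which(upper.tri(matrix(0, k, k), diag = TRUE), arr.ind = TRUE)
}

#' Monte-Carlo gene dropping through a pedigree
#'
#' Each replicate assigns two uniquely labeled alleles to every founder
#' (phantoms included) and transmits one uniformly chosen parental allele
#' per meiosis. For every pair of subset individuals one allele is then
#' drawn from each (with replacement for self-pairs) and the indicators
#' IBD, both-native, both-migrant and IBD-and-both-native are averaged over
#' replicates. Migrant contributions are estimated as the migrant-allele
#' frequency of each individual.
#'
#' @param ped a [as_pedigree()] object.
#' @param origin a [classify_origin()]/[compute_mc()] annotation.
#' @param ids subset of individuals for which pairwise estimates are formed.
#' @param replicates number of Monte-Carlo replicates (>= 1).
#' @param seed integer seed; results are reproducible for a fixed seed.
#' @param chunk replicates processed per vectorized block.
#' @return an object of class `nocs_drop`: list with matrices `fA`, `fN`,
#'   `fM`, `Knat` over `ids`, vector `mc`, and fields `replicates`, `seed`,
#'   `exact = FALSE`.
#' @export
gene_drop <- function(ped, origin, ids = NULL, replicates = 10000L,
                      seed = 1L, chunk = 100000L) {
  stopifnot(replicates >= 1)
  ids <- .default_ids(ped, ids)
  ped <- prune_pedigree(ped, ids)
  st <- .drop_setup(ped, origin, ids)
  k <- length(ids)
  pr <- .pair_index(k)
  acc <- list(fA = numeric(nrow(pr)), fN = numeric(nrow(pr)),
              fM = numeric(nrow(pr)), Knat = numeric(nrow(pr)),
              mc = numeric(k))
  withr::with_seed(as.integer(seed), {
    left <- as.integer(replicates)
    while (left > 0L) {
      m <- min(left, as.integer(chunk))
      left <- left - m
      P <- matrix(0, st$n, m)  # paternal allele labels
      Q <- matrix(0, st$n, m)  # maternal allele labels
      for (i in seq_len(st$nf)) {
        P[i, ] <- 2 * i - 1
        Q[i, ] <- 2 * i
      }
      if (st$n > st$nf) {
        for (i in (st$nf + 1L):st$n) {
          b <- stats::runif(m) < 0.5
          P[i, ] <- ifelse(b, P[st$si[i], ], Q[st$si[i], ])
          b <- stats::runif(m) < 0.5
          Q[i, ] <- ifelse(b, P[st$di[i], ], Q[st$di[i], ])
        }
      }
      # two independent with-replacement draws per subset individual
      A1 <- matrix(0, k, m)
      A2 <- matrix(0, k, m)
      for (u in seq_len(k)) {
        i <- st$sub[u]
        b <- stats::runif(m) < 0.5
        A1[u, ] <- ifelse(b, P[i, ], Q[i, ])
        b <- stats::runif(m) < 0.5
        A2[u, ] <- ifelse(b, P[i, ], Q[i, ])
        acc$mc[u] <- acc$mc[u] +
          sum(st$allele_mig[P[i, ]]) / 2 + sum(st$allele_mig[Q[i, ]]) / 2
      }
      for (r in seq_len(nrow(pr))) {
        u <- pr[r, 1L]; v <- pr[r, 2L]
        x <- A1[u, ]
        y <- if (u == v) A2[u, ] else A1[v, ]
        ibd <- x == y
        xn <- !st$allele_mig[x]; yn <- !st$allele_mig[y]
        acc$fA[r] <- acc$fA[r] + sum(ibd)
        acc$fN[r] <- acc$fN[r] + sum(xn & yn)
        acc$fM[r] <- acc$fM[r] + sum(!xn & !yn)
        acc$Knat[r] <- acc$Knat[r] + sum(ibd & xn)
      }
    }
  })
  out <- lapply(acc[c("fA", "fN", "fM", "Knat")], function(s) {
    mm <- matrix(0, k, k, dimnames = list(ids, ids))
    mm[pr] <- s / replicates
    mm[pr[, 2:1, drop = FALSE]] <- s / replicates
    mm
  })
  out$mc <- stats::setNames(acc$mc / replicates, ids)
  out$replicates <- as.integer(replicates)
  out$seed <- as.integer(seed)
  out$exact <- FALSE
  class(out) <- "nocs_drop"
  out
}

#' Binomial standard error of a gene-drop estimate
#'
#' @param p estimated probability (scalar, vector or matrix).
#' @param replicates replicate count the estimate is based on.
#' @return standard error(s) `sqrt(p (1 - p) / replicates)`.
#' @export
drop_se <- function(p, replicates) sqrt(p * (1 - p) / replicates)

#' Exact probabilities by exhaustive transmission enumeration
#'
#' Enumerates all `2^T` equiprobable inheritance patterns (`T` = number of
#' meioses = twice the number of non-founders in the ancestor closure) and
#' the four equiprobable within-pair allele draws, yielding exact
#' probabilities: every value is a dyadic rational represented exactly in
#' double precision.
#'
#' @inheritParams gene_drop
#' @param max_meioses enumeration bound; pedigrees with more meioses must
#'   use [gene_drop()].
#' @param chunk_bits patterns are processed in blocks of `2^chunk_bits`.
#' @return an object of class `nocs_drop` with `exact = TRUE`.
#' @export
enumerate_transmissions <- function(ped, origin, ids = NULL,
                                    max_meioses = 24L, chunk_bits = 18L) {
  ids <- .default_ids(ped, ids)
  ped <- prune_pedigree(ped, ids)
  st <- .drop_setup(ped, origin, ids)
  nonf <- (st$nf + 1L):st$n
  TT <- 2L * (st$n - st$nf)
  if (st$n == st$nf) TT <- 0L
  if (TT > max_meioses) {
    stop("pedigree has ", TT, " meioses (> ", max_meioses,
         "); use gene_drop() instead")
  }
  k <- length(ids)
  pr <- .pair_index(k)
  acc <- list(fA = numeric(nrow(pr)), fN = numeric(nrow(pr)),
              fM = numeric(nrow(pr)), Knat = numeric(nrow(pr)),
              mc = numeric(k))
  total <- 2^TT
  block <- min(total, 2^chunk_bits)
  done <- 0
  while (done < total) {
    pat <- done + seq_len(block) - 1  # pattern ids as exact doubles
    P <- vector("list", st$n)
    Q <- vector("list", st$n)
    for (i in seq_len(st$nf)) {
      P[[i]] <- 2 * i - 1
      Q[[i]] <- 2 * i
    }
    if (st$n > st$nf) {
      bit <- function(b) floor(pat / 2^b) %% 2
      for (w in seq_along(nonf)) {
        i <- nonf[w]
        b <- bit(2 * (w - 1))
        P[[i]] <- P[[st$si[i]]] * (1 - b) + Q[[st$si[i]]] * b
        b <- bit(2 * w - 1)
        Q[[i]] <- P[[st$di[i]]] * (1 - b) + Q[[st$di[i]]] * b
      }
    }
    for (u in seq_len(k)) {
      i <- st$sub[u]
      acc$mc[u] <- acc$mc[u] +
        sum((st$allele_mig[P[[i]]] + st$allele_mig[Q[[i]]]) / 2 +
              0 * pat)  # recycle founder scalars over the block
    }
    for (r in seq_len(nrow(pr))) {
      u <- pr[r, 1L]; v <- pr[r, 2L]
      i <- st$sub[u]; j <- st$sub[v]
      one <- rep(1, length(pat))
      ax <- list(P[[i]] * one, Q[[i]] * one)
      ay <- list(P[[j]] * one, Q[[j]] * one)
      for (cx in 1:2) for (cy in 1:2) {
        x <- ax[[cx]]; y <- ay[[cy]]
        ibd <- x == y
        xn <- !st$allele_mig[x]; yn <- !st$allele_mig[y]
        acc$fA[r] <- acc$fA[r] + sum(ibd) / 4
        acc$fN[r] <- acc$fN[r] + sum(xn & yn) / 4
        acc$fM[r] <- acc$fM[r] + sum(!xn & !yn) / 4
        acc$Knat[r] <- acc$Knat[r] + sum(ibd & xn & yn) / 4
      }
    }
    done <- done + block
  }
  out <- lapply(acc[c("fA", "fN", "fM", "Knat")], function(s) {
    mm <- matrix(0, k, k, dimnames = list(ids, ids))
    mm[pr] <- s / total
    mm[pr[, 2:1, drop = FALSE]] <- s / total
    mm
  })
  out$mc <- stats::setNames(acc$mc / total, ids)
  out$replicates <- total
  out$seed <- NA_integer_
  out$exact <- TRUE
  class(out) <- "nocs_drop"
  out
}

#' @export
print.nocs_drop <- function(x, ...) {
  cat(sprintf("%s allele-transmission result over %d individuals (%s)\n",
              if (x$exact) "Exact" else "Monte-Carlo",
              length(x$mc),
              if (x$exact) sprintf("%g patterns", x$replicates)
              else sprintf("%d replicates, seed %d", x$replicates, x$seed)))
  invisible(x)
}
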