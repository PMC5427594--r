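# Pedigree container, origin classification and migrant contributions.

#' Build a validated, topologically sorted pedigree
#'
#' Validates a pedigree table, inserts phantom founders for unknown-parent
#' slots of non-founders, and sorts records so that every parent precedes its
#' offspring (founders, including phantoms, come first).
#'
#' @param df data frame with at least columns `id`, `sire`, `dam`; optional
#'   columns `sex` (`"M"`/`"F"`, `male`/`female`, or `1`/`2`), `born`
#'   (integer birth year), `breed` (breed code) and `ebv` (estimated breeding
#'   value). Missing parents, breeds and years may be encoded with any of the
#'   `missing_codes` sentinels or `NA`.
#' @param missing_codes character sentinels treated as missing in `sire`,
#'   `dam`, `breed`, `born` and `ebv`. Defaults to `""` and `"0"`, the two
#'   common pedigree-file dialects.
#' @param generation_interval years subtracted from an offspring's birth year
#'   to date a phantom parent created for a single unknown-parent slot.
#'   The default 0 dates the phantom with the offspring's own birth year, so
#'   the migrant-classification cutoff applies to the offspring's cohort.
#' @return an object of class `nocs_pedigree`: a data frame with columns
#'   `id`, `sire`, `dam`, `sex`, `born`, `breed`, `ebv`, `phantom`, sorted
#'   topologically with founders first.
#' @details Sex is inferred from parent usage when absent: identifiers used
#'   as sires are male, identifiers used as dams are female. An identifier
#'   used as both sire and dam, a duplicated identifier, or a cycle in the
#'   parentage graph is a hard error.
#' @export
#' @examples
#' ped <- as_pedigree(data.frame(
#'   id = c("S", "D", "X"), sire = c(NA, NA, "S"), dam = c(NA, NA, "D"),
#'   sex = c("M", "F", "F"), born = c(1960, 1961, 1980)))
#' ped
as_pedigree <- function(df, missing_codes = c("", "0"),
                        generation_interval = 0) {
  stopifnot(is.data.frame(df))
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(df))) {
    stop("pedigree needs columns: ", paste(setdiff(need, names(df)),
                                           collapse = ", "))
  }
  blank <- function(x) {
    x <- trimws(as.character(x))
    x[x %in% missing_codes | is.na(x)] <- NA_character_
    x
  }
  id    <- blank(df$id)
  sire  <- blank(df$sire)
  dam   <- blank(df$dam)
  sex   <- if ("sex" %in% names(df)) .norm_sex(df$sex) else
    rep(NA_character_, nrow(df))
  born  <- if ("born" %in% names(df))
    suppressWarnings(as.integer(blank(df$born))) else rep(NA_integer_, nrow(df))
  breed <- if ("breed" %in% names(df)) blank(df$breed) else
    rep(NA_character_, nrow(df))
  ebv   <- if ("ebv" %in% names(df))
    suppressWarnings(as.numeric(blank(df$ebv))) else rep(NA_real_, nrow(df))

  if (any(is.na(id))) stop("missing individual id in row(s): ",
                           paste(which(is.na(id)), collapse = ", "))
  if (anyDuplicated(id)) {
    stop("duplicate id: ", id[duplicated(id)][1L])
  }
  if (any(id == sire, na.rm = TRUE)) {
    stop("cycle detected involving: ", id[which(id == sire)][1L])
  }
  if (any(id == dam, na.rm = TRUE)) {
    stop("cycle detected involving: ", id[which(id == dam)][1L])
  }
  both <- intersect(stats::na.omit(sire), stats::na.omit(dam))
  if (length(both)) {
    stop("sex conflict: id used as both sire and dam: ", both[1L])
  }
  # parent usage fixes/checks sex
  as_sire <- id %in% sire
  as_dam  <- id %in% dam
  if (any(as_sire & !is.na(sex) & sex == "F")) {
    stop("sex conflict: female record used as sire: ",
         id[which(as_sire & sex == "F")][1L])
  }
  if (any(as_dam & !is.na(sex) & sex == "M")) {
    stop("sex conflict: male record used as dam: ",
         id[which(as_dam & sex == "M")][1L])
  }
  sex[as_sire] <- "M"
  sex[as_dam]  <- "F"

  # unknown parents referenced but not recorded are treated as records
  ghosts <- setdiff(c(stats::na.omit(sire), stats::na.omit(dam)), id)
  if (length(ghosts)) {
    id    <- c(id, ghosts)
    sire  <- c(sire, rep(NA_character_, length(ghosts)))
    dam   <- c(dam, rep(NA_character_, length(ghosts)))
    sex   <- c(sex, ifelse(ghosts %in% sire, "M", "F"))
    born  <- c(born, rep(NA_integer_, length(ghosts)))
    breed <- c(breed, rep(NA_character_, length(ghosts)))
    ebv   <- c(ebv, rep(NA_real_, length(ghosts)))
  }
  phantom <- rep(FALSE, length(id))

  # phantom founders for single unknown-parent slots of non-founders
  half <- which(xor(is.na(sire), is.na(dam)))
  if (length(half)) {
    pid <- ifelse(is.na(sire[half]),
                  paste0(".ps.", id[half]), paste0(".pd.", id[half]))
    if (any(pid %in% id)) stop("phantom id collision: ",
                               pid[pid %in% id][1L])
    psex  <- ifelse(is.na(sire[half]), "M", "F")
    pborn <- born[half] - as.integer(generation_interval)
    sire[half][is.na(sire[half])] <- pid[psex == "M"]
    dam[half][is.na(dam[half])]   <- pid[psex == "F"]
    id      <- c(id, pid)
    sire    <- c(sire, rep(NA_character_, length(pid)))
    dam     <- c(dam, rep(NA_character_, length(pid)))
    sex     <- c(sex, psex)
    born    <- c(born, pborn)
    breed   <- c(breed, rep(NA_character_, length(pid)))
    ebv     <- c(ebv, rep(NA_real_, length(pid)))
    phantom <- c(phantom, rep(TRUE, length(pid)))
  }

  n <- length(id)
  si <- match(sire, id)
  di <- match(dam, id)
  # generation depth; failure to converge = cycle
  depth <- rep(NA_integer_, n)
  depth[is.na(si) & is.na(di)] <- 0L
  repeat {
    todo <- which(is.na(depth))
    if (!length(todo)) break
    ready <- todo[!is.na(depth[si[todo]]) & !is.na(depth[di[todo]])]
    if (!length(ready)) {
      stop("cycle detected involving: ", id[todo[1L]])
    }
    depth[ready] <- pmax(depth[si[ready]], depth[di[ready]]) + 1L
  }
  ord <- order(depth, seq_len(n))
  out <- data.frame(id = id, sire = sire, dam = dam, sex = sex, born = born,
                    breed = breed, ebv = ebv, phantom = phantom,
                    stringsAsFactors = FALSE)[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("nocs_pedigree", "data.frame")
  out
}

.norm_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[x %in% c("m", "male", "1", "bull", "sire")] <- "M"
  out[x %in% c("f", "female", "2", "cow", "dam")] <- "F"
  out
}

#' Read a pedigree file
#'
#' Reads a delimited pedigree table and returns a validated
#' [as_pedigree()] object.
#'
#' @param path path to a delimited text file with a header row.
#' @param dialect named character vector mapping the canonical column names
#'   `id`, `sire`, `dam`, `sex`, `born`, `breed`, `ebv` to the column names
#'   used in the file. Only `id`, `sire` and `dam` are required.
#' @param sep field separator (default `","`).
#' @inheritParams as_pedigree
#' @return an object of class `nocs_pedigree`.
#' @export
read_pedigree <- function(path,
                          dialect = c(id = "id", sire = "sire", dam = "dam",
                                      sex = "sex", born = "born",
                                      breed = "breed", ebv = "ebv"),
                          sep = ",", missing_codes = c("", "0"),
                          generation_interval = 0) {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  defaults <- c(id = "id", sire = "sire", dam = "dam", sex = "sex",
                born = "born", breed = "breed", ebv = "ebv")
  defaults[names(dialect)] <- dialect
  need <- defaults[c("id", "sire", "dam")]
  if (!all(need %in% names(raw))) {
    stop("file lacks mapped column(s): ",
         paste(setdiff(need, names(raw)), collapse = ", "))
  }
  df <- data.frame(id = raw[[defaults["id"]]],
                   sire = raw[[defaults["sire"]]],
                   dam = raw[[defaults["dam"]]],
                   stringsAsFactors = FALSE)
  for (col in c("sex", "born", "breed", "ebv")) {
    if (defaults[col] %in% names(raw)) df[[col]] <- raw[[defaults[col]]]
  }
  as_pedigree(df, missing_codes = missing_codes,
              generation_interval = generation_interval)
}

#' @export
print.nocs_pedigree <- function(x, ...) {
  nf <- sum(is.na(x$sire) & is.na(x$dam))
  cat(sprintf("Pedigree: %d individuals (%d founders, %d phantom)\n",
              nrow(x), nf, sum(x$phantom)))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

.founder_mask <- function(ped) is.na(ped$sire) & is.na(ped$dam)

#' Classify pedigree founders as native or migrant
#'
#' Applies the herdbook rule: a founder (parentless record, including
#' phantoms) is native if its breed code belongs to the native breed(s), or
#' if its breed is unknown and it was born before the cutoff year. Founders
#' from other breeds, and founders with unknown pedigree born in or after the
#' cutoff year, are migrants.
#'
#' @param ped a [as_pedigree()] object.
#' @param native_breeds character vector of breed codes counted as native.
#' @param cutoff_year founders of unknown breed born before this year are
#'   assumed native (default 1970).
#' @param unknown_policy what to do with a founder whose breed and birth year
#'   are both unknown: `"error"` (default) or `"migrant"`.
#' @return data frame with columns `id`, `founder` (logical) and `migrant`
#'   (logical; `NA` for non-founders).
#' @export
classify_origin <- function(ped, native_breeds, cutoff_year = 1970,
                            unknown_policy = c("error", "migrant")) {
  stopifnot(inherits(ped, "nocs_pedigree"), length(native_breeds) >= 1L)
  unknown_policy <- match.arg(unknown_policy)
  fo <- .founder_mask(ped)
  migrant <- rep(NA, nrow(ped))
  nat_breed <- !is.na(ped$breed) & ped$breed %in% native_breeds
  unk_breed <- is.na(ped$breed)
  old <- !is.na(ped$born) & ped$born < cutoff_year
  migrant[fo] <- !(nat_breed[fo] | (unk_breed[fo] & old[fo]))
  dark <- fo & unk_breed & is.na(ped$born)
  if (any(dark)) {
    if (unknown_policy == "error") {
      stop("founder with unknown breed and unknown birth year: ",
           ped$id[which(dark)][1L],
           " (set unknown_policy = \"migrant\" to classify such founders)")
    }
    migrant[dark] <- TRUE
  }
  data.frame(id = ped$id, founder = fo, migrant = migrant,
             stringsAsFactors = FALSE)
}

#' Compute migrant contributions from founder origins
#'
#' The migrant contribution (MC) of an animal is the expected fraction of
#' its genome descending from migrant founders: 1 for migrant founders, 0
#' for native founders, and the parental average elsewhere.
#'
#' @param ped a [as_pedigree()] object.
#' @param origin output of [classify_origin()] (founder flags).
#' @return an object of class `nocs_origin`: the `origin` data frame with
#'   columns `mc` (migrant contribution) and `native` (`1 - mc`) appended.
#' @export
compute_mc <- function(ped, origin) {
  stopifnot(inherits(ped, "nocs_pedigree"))
  origin <- origin[match(ped$id, origin$id), , drop = FALSE]
  if (any(is.na(origin$id))) stop("origin annotation does not cover pedigree")
  fo <- .founder_mask(ped)
  if (any(fo & is.na(origin$migrant))) {
    stop("founder without origin flag: ",
         ped$id[which(fo & is.na(origin$migrant))][1L])
  }
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  mc <- numeric(nrow(ped))
  mc[fo] <- as.numeric(origin$migrant[fo])
  for (i in which(!fo)) mc[i] <- (mc[si[i]] + mc[di[i]]) / 2
  out <- origin
  out$mc <- mc
  out$native <- 1 - mc
  rownames(out) <- NULL
  class(out) <- c("nocs_origin", "data.frame")
  out
}

#' Select and annotate breeding candidates
#'
#' Male selection candidates are the herdbook-purebred sires with at least
#' one progeny born inside the given window. Female candidates are `n_dams`
#' herdbook-purebred females sampled without replacement (reproducibly for a
#' fixed seed). Purebred status is taken from the breed code, not from a
#' zero migrant contribution: herdbook animals typically carry migrant
#' ancestry.
#'
#' @param ped a [as_pedigree()] object with breeding values.
#' @param origin a [compute_mc()] annotation.
#' @param native_breeds breed codes defining herdbook membership.
#' @param progeny_window two-sided inclusive birth-year window of progeny
#'   defining male candidacy (default `c(2005, 2006)`).
#' @param n_dams number of female candidates to sample (default 1000).
#' @param seed integer seed for the dam sample.
#' @param dam_birth_window optional inclusive birth-year window restricting
#'   eligible dams. Independently of this window, females born inside or
#'   after the progeny window are never eligible: dams must predate the
#'   cohort they are to produce.
#' @return an object of class `nocs_candidates`: a list with `males`,
#'   `females` (sorted id vectors) and `data`, a data frame of
#'   `id`, `sex`, `ebv`, `mc` over all candidates (males first).
#' @export
select_candidates <- function(ped, origin, native_breeds,
                              progeny_window = c(2005, 2006),
                              n_dams = 1000, seed = 1L,
                              dam_birth_window = NULL) {
  stopifnot(inherits(ped, "nocs_pedigree"), length(progeny_window) == 2L,
            progeny_window[1] <= progeny_window[2])
  purebred <- !ped$phantom & !is.na(ped$breed) & ped$breed %in% native_breeds
  in_win <- !is.na(ped$born) &
    ped$born >= progeny_window[1] & ped$born <= progeny_window[2]
  window_sires <- unique(ped$sire[in_win])
  males <- sort(ped$id[purebred & ped$sex %in% "M" &
                         ped$id %in% window_sires])
  if (!length(males)) stop("no eligible male candidates in progeny window ",
                           progeny_window[1], "-", progeny_window[2])
  # dams must predate the progeny cohort they are to produce
  elig_f <- purebred & ped$sex %in% "F" &
    (is.na(ped$born) | ped$born < progeny_window[1])
  if (!is.null(dam_birth_window)) {
    elig_f <- elig_f & !is.na(ped$born) &
      ped$born >= dam_birth_window[1] & ped$born <= dam_birth_window[2]
  }
  pool <- sort(ped$id[elig_f])
  if (n_dams > length(pool)) {
    stop("n_dams (", n_dams, ") exceeds eligible purebred females (",
         length(pool), ")")
  }
  females <- if (n_dams == length(pool)) pool else
    sort(withr::with_seed(as.integer(seed), sample(pool, n_dams)))
  ids <- c(males, females)
  ix <- match(ids, ped$id)
  ebv <- ped$ebv[ix]
  if (any(is.na(ebv))) {
    stop("candidate without EBV: ", ids[which(is.na(ebv))][1L])
  }
  mc <- compute_mc_lookup(origin, ids)
  out <- list(males = males, females = females,
              data = data.frame(id = ids,
                                sex = rep(c("M", "F"),
                                          c(length(males), length(females))),
                                ebv = ebv, mc = mc,
                                stringsAsFactors = FALSE))
  class(out) <- "nocs_candidates"
  out
}

compute_mc_lookup <- function(origin, ids) {
  mc <- origin$mc[match(ids, origin$id)]
  if (any(is.na(mc))) stop("no migrant contribution for: ",
                           ids[which(is.na(mc))][1L])
  mc
}

#' Normalize candidate breeding values
#'
#' Centers and scales the EBVs of all candidates (both sexes pooled) to mean
#' 0 and standard deviation 1, so that results are comparable across breeds.
#'
#' @param cands a [select_candidates()] object.
#' @param divisor `"n"` (population standard deviation, the default) or
#'   `"n-1"` (sample standard deviation).
#' @return `cands` with a column `ebv_norm` appended to `cands$data`.
#' @export
normalize_ebv <- function(cands, divisor = c("n", "n-1")) {
  stopifnot(inherits(cands, "nocs_candidates"))
  divisor <- match.arg(divisor)
  x <- cands$data$ebv
  if (length(x) < 2L) stop("need at least two candidates to normalize EBV")
  mu <- mean(x)
  ss <- sum((x - mu)^2)
  if (ss == 0) stop("all candidate EBV identical; normalization undefined")
  s <- sqrt(ss / if (divisor == "n") length(x) else length(x) - 1L)
  cands$data$ebv_norm <- (x - mu) / s
  cands
}

#' @export
print.nocs_candidates <- function(x, ...) {
  cat(sprintf("Candidates: %d males, %d females%s\n",
              length(x$males), length(x$females),
              if (!is.null(x$data$ebv_norm)) " (EBV normalized)" else ""))
  invisible(x)
}

#' Prune a pedigree to a set of individuals and their ancestors
#'
#' @param ped a [as_pedigree()] object.
#' @param ids identifiers whose ancestor closure is retained.
#' @return the pruned `nocs_pedigree` (original order preserved).
#' @export
prune_pedigree <- function(ped, ids) {
  stopifnot(inherits(ped, "nocs_pedigree"))
  keep <- ped$id %in% ids
  if (sum(keep) != length(unique(ids))) {
    stop("unknown id(s): ",
         paste(utils::head(setdiff(ids, ped$id)), collapse = ", "))
  }
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  for (i in rev(seq_len(nrow(ped)))) {
    if (keep[i]) {
      if (!is.na(si[i])) keep[si[i]] <- TRUE
      if (!is.na(di[i])) keep[di[i]] <- TRUE
    }
  }
  out <- ped[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("nocs_pedigree", "data.frame")
  out
}
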