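# Synthetic pedigrees with historical migrant introgression.
# The generator emulates the breeding history of a local cattle breed:
# native founders around 1950, discrete 12-year generations, migrant sires
# injected in configurable waves, a final progeny cohort defining the male
# selection candidates, and breeding values positively correlated with
# migrant contributions.

#' Configuration for the synthetic pedigree generator
#'
#' Defaults emulate a small local dual-purpose cattle breed with heavy
#' historical introgression: migrant sires in every parent generation so
#' that candidate migrant contributions average about 0.6, 200 male and
#' 1100 eligible female candidates, and a positive correlation of about
#' 0.33 between breeding values and migrant contributions.
#'
#' @param n_founders_native native founders (born just before 1950).
#' @param n_founders_migrant_per_wave migrant sires available per wave.
#' @param generations number of discrete parent generations after the
#'   founders; the last one supplies the selection candidates.
#' @param gen_size individuals per intermediate generation.
#' @param final_size individuals in the candidate generation (half female).
#' @param waves data frame with columns `year` (generation birth year the
#'   wave applies to) and `frac` (fraction of matings sired by migrants).
#' @param founder_year birth year around which founders are born.
#' @param interval generation interval in years.
#' @param n_sires sires of the final progeny cohort (the male candidates).
#' @param progeny_per_sire progeny records per selected sire.
#' @param progeny_years birth years of the progeny cohort.
#' @param native_breed,migrant_breed herdbook breed codes written to the
#'   pedigree.
#' @param sire_concentration,dam_concentration gamma shape of the random
#'   usage weights with which parents are drawn for each mating. Small
#'   values concentrate matings on a few popular parents, emulating the
#'   intensive use of artificial-insemination sires that drives inbreeding
#'   in real breeds; sires are much more concentrated than dams.
#' @param target_corr_ebv_mc target correlation between EBV and migrant
#'   contribution among the candidate generation, in (-1, 1).
#' @param ebv_noise_sd standard deviation of the EBV noise term.
#' @param trend_per_gen additive genetic trend per generation.
#' @param seed integer seed.
#' @return a `nocs_synth_config` list.
#' @export
synth_config <- function(n_founders_native = 200L,
                         n_founders_migrant_per_wave = 40L,
                         generations = 4L,
                         gen_size = 300L,
                         final_size = 2200L,
                         waves = NULL,
                         founder_year = 1948L,
                         interval = 12L,
                         n_sires = 200L,
                         progeny_per_sire = 2L,
                         progeny_years = c(2005L, 2006L),
                         native_breed = "NAT",
                         migrant_breed = "MIG",
                         sire_concentration = 0.1,
                         dam_concentration = 2,
                         target_corr_ebv_mc = 0.33,
                         ebv_noise_sd = 1,
                         trend_per_gen = 0,
                         seed = 1L) {
  gen_years <- founder_year + 2L + interval * seq_len(generations)
  if (is.null(waves)) {
    waves <- data.frame(year = gen_years, frac = 0.45)
  }
  stopifnot(n_founders_native >= 2L, generations >= 1L, gen_size >= 4L,
            final_size >= 4L, abs(target_corr_ebv_mc) < 1,
            ebv_noise_sd > 0, all(waves$frac >= 0), all(waves$frac < 1))
  structure(list(n_founders_native = n_founders_native,
                 n_founders_migrant_per_wave = n_founders_migrant_per_wave,
                 generations = generations, gen_size = gen_size,
                 final_size = final_size, waves = waves,
                 founder_year = founder_year, interval = interval,
                 gen_years = gen_years, n_sires = n_sires,
                 progeny_per_sire = progeny_per_sire,
                 progeny_years = progeny_years,
                 native_breed = native_breed, migrant_breed = migrant_breed,
                 sire_concentration = sire_concentration,
                 dam_concentration = dam_concentration,
                 target_corr_ebv_mc = target_corr_ebv_mc,
                 ebv_noise_sd = ebv_noise_sd,
                 trend_per_gen = trend_per_gen,
                 seed = as.integer(seed)),
            class = "nocs_synth_config")
}

#' Generate a synthetic pedigree with migrant introgression
#'
#' Produces a discrete-generation pedigree whose founders are native; at
#' each wave a configurable fraction of matings is sired by new migrant
#' founders. Breed codes and birth years are written so that
#' [classify_origin()] reconstructs the ground-truth founder flags exactly:
#' native founders carry the native breed code or an unknown breed with a
#' pre-cutoff birth year, migrant founders carry the migrant breed code,
#' and all bred animals carry the native (herdbook) code. EBVs are
#' simulated as `alpha * MC + trend + noise`, with `alpha` calibrated in
#' closed form so the EBV-MC correlation in the candidate generation hits
#' the target.
#'
#' @param config a [synth_config()].
#' @return list with `pedigree` (a `nocs_pedigree`), `origin` (ground-truth
#'   [compute_mc()] annotation) and `config`.
#' @export
generate_pedigree <- function(config = synth_config()) {
  stopifnot(inherits(config, "nocs_synth_config"))
  cf <- config
  withr::with_seed(cf$seed, {
    rows <- list()
    add <- function(id, sire, dam, sex, born, breed) {
      rows[[length(rows) + 1L]] <<- data.frame(
        id = id, sire = sire, dam = dam, sex = sex, born = born,
        breed = breed, stringsAsFactors = FALSE)
    }
    nf <- cf$n_founders_native
    f_ids <- sprintf("F%03d", seq_len(nf))
    f_sex <- rep(c("M", "F"), length.out = nf)
    # half the native founders are herdbook-coded, half rely on the
    # pre-cutoff birth-year rule
    f_breed <- rep(c(cf$native_breed, NA_character_), length.out = nf)
    add(f_ids, NA_character_, NA_character_, f_sex,
        cf$founder_year + sample(0:4, nf, replace = TRUE), f_breed)
    prev_m <- f_ids[f_sex == "M"]
    prev_f <- f_ids[f_sex == "F"]
    for (g in seq_len(cf$generations)) {
      year <- cf$gen_years[g]
      size <- if (g == cf$generations) cf$final_size else cf$gen_size
      wfrac <- cf$waves$frac[match(year, cf$waves$year)]
      if (is.na(wfrac)) wfrac <- 0
      mig_pool <- character(0)
      if (wfrac > 0) {
        mig_pool <- sprintf("M%d_%03d", g,
                            seq_len(cf$n_founders_migrant_per_wave))
        add(mig_pool, NA_character_, NA_character_, "M",
            year - 5L, cf$migrant_breed)
      }
      ids <- sprintf("G%d_%04d", g, seq_len(size))
      sex <- sample(rep(c("M", "F"), length.out = size))
      use_mig <- stats::runif(size) < wfrac
      # popular-sire structure: usage weights are gamma draws, so a few
      # sires dominate each cohort while dam usage is only mildly uneven
      wsire <- function(k) {
        stats::rgamma(k, shape = cf$sire_concentration) + 1e-12
      }
      sire <- character(size)
      if (any(use_mig)) {
        sire[use_mig] <- sample(mig_pool, sum(use_mig), replace = TRUE,
                                prob = wsire(length(mig_pool)))
      }
      sire[!use_mig] <- sample(prev_m, sum(!use_mig), replace = TRUE,
                               prob = wsire(length(prev_m)))
      dam <- sample(prev_f, size, replace = TRUE,
                    prob = stats::rgamma(length(prev_f),
                                         shape = cf$dam_concentration))
      add(ids, sire, dam, sex, rep(year, size),
          rep(cf$native_breed, size))
      prev_m <- ids[sex == "M"]
      prev_f <- ids[sex == "F"]
    }
    # progeny cohort defining male candidacy
    sires <- sample(prev_m, cf$n_sires)
    n_prog <- cf$n_sires * cf$progeny_per_sire
    prog <- sprintf("P%04d", seq_len(n_prog))
    add(prog, rep(sires, each = cf$progeny_per_sire),
        sample(prev_f, n_prog, replace = TRUE),
        sample(rep(c("M", "F"), length.out = n_prog)),
        sample(cf$progeny_years, n_prog, replace = TRUE),
        rep(cf$native_breed, n_prog))
    df <- do.call(rbind, rows)
    ped <- as_pedigree(df)
    origin <- compute_mc(ped, classify_origin(
      ped, native_breeds = cf$native_breed))
    # EBV: alpha * MC + trend + noise, alpha calibrated to the target
    # correlation using the realized MC spread of the candidate generation
    cand_gen <- grepl(sprintf("^G%d_", cf$generations), ped$id)
    s_mc <- stats::sd(origin$mc[cand_gen])
    rho <- cf$target_corr_ebv_mc
    if (rho != 0 && (is.na(s_mc) || s_mc == 0)) {
      stop("target EBV-MC correlation unachievable: no MC variation")
    }
    alpha <- if (rho == 0) 0 else
      rho * cf$ebv_noise_sd / (s_mc * sqrt(1 - rho^2))
    gen_of <- findInterval(ped$born, c(-Inf, cf$gen_years)) - 1
    ebv <- alpha * origin$mc + cf$trend_per_gen * pmax(gen_of, 0) +
      stats::rnorm(nrow(ped), 0, cf$ebv_noise_sd)
    ped$ebv <- ebv
    ped$ebv[grepl("^P", ped$id)] <- NA  # progeny not yet evaluated
    list(pedigree = ped, origin = origin, config = cf)
  })
}

#' Selection candidates of a synthetic population
#'
#' Convenience wrapper applying the candidate rules to a
#' [generate_pedigree()] result: sires of the progeny cohort become male
#' candidates and `n_dams` dams are sampled from the candidate generation.
#' EBVs are normalized across all candidates.
#'
#' @param pop a [generate_pedigree()] result.
#' @param n_dams number of female candidates (default 1000).
#' @param seed seed for the dam sample.
#' @return a normalized `nocs_candidates` object.
#' @export
candidates_from_population <- function(pop, n_dams = 1000, seed = 1L) {
  cf <- pop$config
  last_year <- cf$gen_years[cf$generations]
  cands <- select_candidates(pop$pedigree, pop$origin,
                             native_breeds = cf$native_breed,
                             progeny_window = cf$progeny_years,
                             n_dams = n_dams, seed = seed,
                             dam_birth_window = c(last_year, last_year))
  normalize_ebv(cands)
}

#' Canonical test fixtures
#'
#' Small pedigrees used throughout the package tests: textbook
#' relationships, a migrant-by-native F1 family, a three-generation mixed
#' pedigree small enough for exhaustive transmission enumeration, a random
#' 50-individual mixed pedigree, and (optionally) the full synthetic
#' candidate population.
#'
#' @param include_population also build the 200-sire/1000-dam synthetic
#'   population (slower); default `FALSE`.
#' @param seed seed for the random fixtures.
#' @return named list of fixtures; each element has `pedigree` and (where
#'   meaningful) `origin` with migrant contributions, using native breed
#'   code `"NAT"`.
#' @export
fixture_suite <- function(include_population = FALSE, seed = 42L) {
  mk <- function(df) {
    ped <- as_pedigree(df)
    origin <- compute_mc(ped, classify_origin(ped, native_breeds = "NAT"))
    list(pedigree = ped, origin = origin)
  }
  out <- list()
  out$parent_offspring <- mk(data.frame(
    id = c("S", "D", "X"), sire = c(NA, NA, "S"), dam = c(NA, NA, "D"),
    sex = c("M", "F", "F"), born = c(1960, 1960, 1975),
    breed = "NAT"))
  out$full_sibs <- mk(data.frame(
    id = c("S", "D", "X", "Y"), sire = c(NA, NA, "S", "S"),
    dam = c(NA, NA, "D", "D"), sex = c("M", "F", "M", "F"),
    born = c(1960, 1960, 1975, 1976), breed = "NAT"))
  out$f1_family <- mk(data.frame(
    id = c("MIG", "NATF", "F1", "NATU"),
    sire = c(NA, NA, "MIG", NA), dam = c(NA, NA, "NATF", NA),
    sex = c("M", "F", "F", "M"), born = c(1980, 1960, 1990, 1960),
    breed = c("X", "NAT", "NAT", "NAT")))
  # three generations mixing origins; 5 non-founders = 10 meioses
  out$mixed_3gen <- mk(data.frame(
    id = c("M1", "N1", "N2", "N3", "A", "B", "C", "D", "E"),
    sire = c(NA, NA, NA, NA, "M1", "N2", "A", "A", "C"),
    dam = c(NA, NA, NA, NA, "N1", "N1", "B", "B", "D"),
    sex = c("M", "F", "M", "M", "M", "F", "M", "F", "F"),
    born = c(1985, 1960, 1960, 1960, 1990, 1991, 2000, 2001, 2008),
    breed = c("X", "NAT", "NAT", "NAT", "NAT", "NAT", "NAT", "NAT",
              "NAT")))
  out$random_50 <- withr::with_seed(as.integer(seed), {
    n_f <- 12L
    ids <- sprintf("R%02d", 1:50)
    sex <- rep(c("M", "F"), 25)
    sire <- dam <- rep(NA_character_, 50)
    for (i in (n_f + 1L):50L) {
      prev_m <- ids[seq_len(i - 1L)][sex[seq_len(i - 1L)] == "M"]
      prev_f <- ids[seq_len(i - 1L)][sex[seq_len(i - 1L)] == "F"]
      sire[i] <- sample(prev_m, 1L)
      dam[i] <- sample(prev_f, 1L)
    }
    mk(data.frame(
      id = ids, sire = sire, dam = dam, sex = sex,
      born = c(rep(1960, 4), rep(1980, 8), 1990 + seq_len(38)),
      breed = c(rep("NAT", 4), rep(c("X", "NAT"), 4), rep("NAT", 38))))
  })
  if (include_population) {
    out$population <- generate_pedigree(synth_config(seed = seed))
  }
  out
}
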