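test_that("pedigree files are read, validated and topologically sorted", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,sire,dam,sex,born,breed",
               "S,0,0,M,1960,NAT",
               "D,0,0,F,1961,NAT",
               "X,S,D,F,1980,NAT"), path)
  ped <- read_pedigree(path)
  expect_s3_class(ped, "nocs_pedigree")
  expect_equal(nrow(ped), 3L)
  expect_true(match("S", ped$id) < match("X", ped$id))
  expect_true(match("D", ped$id) < match("X", ped$id))

  # offspring listed before parents gives the same pedigree
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,sire,dam,sex,born,breed",
               "X,S,D,F,1980,NAT",
               "S,0,0,M,1960,NAT",
               "D,0,0,F,1961,NAT"), path2)
  expect_equal(as.data.frame(read_pedigree(path2)), as.data.frame(ped))

  # custom column mapping
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("animal,father,mother", "X,S,D", "S,,", "D,,"), path3)
  ped3 <- read_pedigree(path3, dialect = c(id = "animal", sire = "father",
                                           dam = "mother"))
  expect_equal(sort(ped3$id), c("D", "S", "X"))
})

test_that("invalid pedigrees are rejected with informative errors", {
  expect_error(as_pedigree(data.frame(id = c("A", "A"), sire = NA,
                                      dam = NA)),
               "duplicate id: A")
  expect_error(as_pedigree(data.frame(id = c("A", "B"), sire = c("B", "A"),
                                      dam = c(NA, NA))),
               "cycle")
  expect_error(as_pedigree(data.frame(id = c("A", "B", "C"),
                                      sire = c(NA, "A", NA),
                                      dam = c(NA, NA, "A"))),
               "both sire and dam")
  expect_error(as_pedigree(data.frame(id = c("A", "B"), sire = c(NA, "A"),
                                      dam = c(NA, NA),
                                      sex = c("F", "M"))),
               "female record used as sire")
})

test_that("phantom founders are created for single unknown-parent slots", {
  ped <- as_pedigree(data.frame(id = c("S", "X"), sire = c(NA, "S"),
                                dam = c(NA, ""), born = c(1950, 1980),
                                sex = c("M", "M")))
  expect_equal(sum(ped$phantom), 1L)
  ph <- ped[ped$phantom, ]
  expect_equal(ph$sex, "F")
  expect_equal(ph$born, 1980L)  # default generation interval 0
  expect_true(is.na(ph$sire) && is.na(ph$dam))
  ped5 <- as_pedigree(data.frame(id = c("S", "X"), sire = c(NA, "S"),
                                 dam = c(NA, ""), born = c(1950, 1980),
                                 sex = c("M", "M")),
                      generation_interval = 6)
  expect_equal(ped5[ped5$phantom, ]$born, 1974L)
})

test_that("founder origin follows the herdbook and cutoff-year rules", {
  ped <- as_pedigree(data.frame(
    id = c("A", "B", "C", "D"), sire = NA, dam = NA,
    sex = c("M", "M", "M", "F"),
    born = c(1965, 1960, 1980, NA),
    breed = c(NA, "FOREIGN", NA, "NAT")))
  org <- classify_origin(ped, native_breeds = "NAT")
  flag <- function(id) org$migrant[org$id == id]
  expect_false(flag("A"))  # unknown breed born before 1970 -> native
  expect_true(flag("B"))   # foreign breed -> migrant even if born early
  expect_true(flag("C"))   # unknown breed born after 1970 -> migrant
  expect_false(flag("D"))  # herdbook breed -> native

  dark <- as_pedigree(data.frame(id = "Z", sire = NA, dam = NA, sex = "M"))
  expect_error(classify_origin(dark, native_breeds = "NAT"),
               "unknown breed and unknown birth year")
  org2 <- classify_origin(dark, native_breeds = "NAT",
                          unknown_policy = "migrant")
  expect_true(org2$migrant[1])
})

test_that("migrant contributions follow the parental-average recursion", {
  f <- fx$f1_family
  mc <- stats::setNames(f$origin$mc, f$origin$id)
  expect_equal(unname(mc["F1"]), 0.5)
  expect_equal(unname(mc["NATU"]), 0)
  # F1 x native founder -> 0.25
  ped2 <- as_pedigree(data.frame(
    id = c("MIG", "NATF", "F1", "NATU", "BC"),
    sire = c(NA, NA, "MIG", NA, "NATU"),
    dam = c(NA, NA, "NATF", NA, "F1"),
    sex = c("M", "F", "F", "M", "M"),
    born = c(1980, 1960, 1990, 1960, 2000),
    breed = c("X", "NAT", "NAT", "NAT", "NAT")))
  org2 <- compute_mc(ped2, classify_origin(ped2, native_breeds = "NAT"))
  expect_equal(org2$mc[org2$id == "BC"], 0.25)
  expect_equal(org2$mc + org2$native, rep(1, nrow(org2)))
})

test_that("MC is bracketed by parental MC and fixed at the extremes", {
  pop <- generate_pedigree(synth_config(
    n_founders_native = 30L, generations = 2L, gen_size = 40L,
    final_size = 40L, n_sires = 5L, progeny_per_sire = 2L, seed = 3L))
  ped <- pop$pedigree
  org <- pop$origin
  mc <- stats::setNames(org$mc, org$id)
  nonf <- !is.na(ped$sire)
  expect_true(all(mc[ped$id[nonf]] >=
                    pmin(mc[ped$sire[nonf]], mc[ped$dam[nonf]]) - 1e-12))
  expect_true(all(mc[ped$id[nonf]] <=
                    pmax(mc[ped$sire[nonf]], mc[ped$dam[nonf]]) + 1e-12))
  # all-native pedigree has mc identically zero
  allnat <- generate_pedigree(synth_config(
    n_founders_native = 20L, generations = 2L, gen_size = 30L,
    final_size = 30L, n_sires = 4L,
    waves = data.frame(year = integer(), frac = numeric()),
    target_corr_ebv_mc = 0, seed = 4L))
  expect_true(all(allnat$origin$mc == 0))
})

test_that("MC and origin are invariant under row permutation", {
  f <- fx$mixed_3gen
  df <- as.data.frame(f$pedigree)[, c("id", "sire", "dam", "sex", "born",
                                      "breed")]
  shuffled <- df[rev(seq_len(nrow(df))), ]
  ped2 <- as_pedigree(shuffled)
  org2 <- compute_mc(ped2, classify_origin(ped2, native_breeds = "NAT"))
  m1 <- stats::setNames(f$origin$mc, f$origin$id)
  m2 <- stats::setNames(org2$mc, org2$id)
  expect_equal(m2[names(m1)], m1)
})

test_that("candidate selection applies the progeny-window and dam rules", {
  pop <- get_population()$pop
  cands <- candidates_from_population(pop, seed = 11L)
  expect_equal(length(cands$males), 200L)
  expect_equal(length(cands$females), 1000L)
  # male candidates are exactly the sires with progeny in the window
  ped <- pop$pedigree
  win <- !is.na(ped$born) & ped$born %in% 2005:2006
  expect_setequal(cands$males, unique(ped$sire[win]))
  # same seed, same dams; different seed, different dams
  again <- candidates_from_population(pop, seed = 11L)
  expect_identical(again$females, cands$females)
  other <- candidates_from_population(pop, seed = 12L)
  expect_false(identical(other$females, cands$females))
  # asking for every eligible female returns the full pool
  n_pool <- sum(ped$breed %in% "NAT" & ped$sex %in% "F" &
                  !is.na(ped$born) & ped$born == 1998, na.rm = TRUE)
  all_f <- select_candidates(ped, pop$origin, native_breeds = "NAT",
                             n_dams = n_pool, seed = 99L,
                             dam_birth_window = c(1998, 1998))
  expect_equal(length(all_f$females), n_pool)
  expect_error(select_candidates(ped, pop$origin, native_breeds = "NAT",
                                 n_dams = n_pool + 1L,
                                 dam_birth_window = c(1998, 1998)),
               "exceeds eligible")
  expect_error(select_candidates(ped, pop$origin, native_breeds = "NAT",
                                 progeny_window = c(1800, 1801),
                                 n_dams = 10),
               "no eligible male")
})

test_that("EBV normalization is pooled, exact and guards degeneracy", {
  f <- fx$full_sibs
  cands <- toy_candidates(f, n_males = 1L, n_females = 1L, ebv = NULL)
  ped3 <- fx$mixed_3gen
  c3 <- toy_candidates(ped3, n_males = 2L, n_females = 1L,
                       ebv = c(1, 2, 3))
  z <- c3$data$ebv_norm
  expect_equal(z, c(-1, 0, 1) * sqrt(3 / 2))  # population-sd convention
  expect_equal(mean(z), 0)
  expect_equal(sqrt(mean(z^2)), 1)
  # sample-sd convention on request
  c3b <- normalize_ebv(c3, divisor = "n-1")
  expect_equal(sd(c3b$data$ebv_norm), 1)
  # an already-normalized vector is unchanged
  c3$data$ebv <- c3$data$ebv_norm
  expect_equal(normalize_ebv(c3)$data$ebv_norm, c3$data$ebv_norm)
  c3$data$ebv <- c(5, 5, 5)
  expect_error(normalize_ebv(c3), "identical")
})
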