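test_that("CSV reading validates and preserves structure", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sex,A,B", "m,0,0", "f,0,0", "f,0,0"), path)
  coh <- suppressMessages(read_cohort(path, stratum_col = "sex"))
  expect_equal(n_patients(coh), 3L)
  expect_equal(n_conditions(coh), 2L)
  expect_equal(condition_prevalence(coh)$prevalence, c(0, 0))
  expect_equal(coh$strata, c("m", "f", "f"))

  writeLines(c("A,B", "1,0", "2,1"), path)
  expect_error(read_cohort(path), "'A'.*row 2")

  writeLines(c("A,B", "true,FALSE", "f,T"), path)
  coh2 <- read_cohort(path)
  expect_equal(unname(coh2$presence), rbind(c(1L, 0L), c(0L, 1L)))

  writeLines("A,B", path)
  expect_error(read_cohort(path), "empty")
  expect_error(read_cohort(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("cohort constructor rejects invalid input", {
  expect_error(cohort(cbind(A = 1, A = 1)), "duplicate")
  expect_error(cohort(cbind(A = c(1, NA), B = c(0, 1))), "missing value")
  expect_error(cohort(cbind(A = 1, B = 0)[0, , drop = FALSE]), "empty")
  expect_error(cohort(matrix(0, 3, 2)), "names")
})

test_that("hand-counted fixture gives the expected margins", {
  tab <- pairwise_counts(fixture_ab())
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$N_i, 3L)
  expect_equal(tab$N_j, 3L)
  expect_equal(tab$N_ij, 1L)
  cells <- pair_cells(tab)
  expect_equal(cells$a + cells$b + cells$c + cells$d, tab$N)
})

test_that("pairwise counts match the brute-force patient loop", {
  coh <- fixture_random_cohort(50, 6, rng_seed = 11)
  got <- pairwise_counts(coh)
  want <- oracle_pair_counts(coh$presence)
  expect_equal(got[c("i", "j", "N", "N_i", "N_j", "N_ij")], want,
               ignore_attr = TRUE)
  # larger randomized case
  coh2 <- fixture_random_cohort(1000, 10, rng_seed = 12)
  got2 <- pairwise_counts(coh2)
  want2 <- oracle_pair_counts(coh2$presence)
  expect_equal(got2[c("N_i", "N_j", "N_ij")], want2[c("N_i", "N_j", "N_ij")],
               ignore_attr = TRUE)
  expect_equal(nrow(got2), choose(10, 2))
})

test_that("stratification subsets patients and commutes with counting", {
  strata <- rep(c("men", "women"), c(3, 7))
  coh <- fixture_random_cohort(10, 4, rng_seed = 3, strata = strata)
  men <- stratify(coh, "men")
  expect_equal(n_patients(men), 3L)
  expect_identical(condition_names(men), condition_names(coh))
  expect_error(stratify(coh, "children"), "unknown stratum")
  expect_error(stratify(fixture_ab(), "men"), "no strata")

  # additivity: per-stratum margins sum to whole-cohort margins
  tw <- pairwise_counts(stratify(coh, "women"))
  tm <- pairwise_counts(men)
  tall <- pairwise_counts(coh)
  expect_equal(tm$N_i + tw$N_i, tall$N_i)
  expect_equal(tm$N_ij + tw$N_ij, tall$N_ij)

  # stratify-then-count equals filtering rows first
  sub <- suppressMessages(cohort(coh$presence[strata == "men", ]))
  expect_equal(pairwise_counts(men), pairwise_counts(sub))
})

test_that("binding stratified cohorts restores the whole cohort", {
  strata <- rep(c("a", "b"), c(4, 6))
  coh <- fixture_random_cohort(10, 3, rng_seed = 5, strata = strata)
  rebuilt <- bind_cohorts(list(a = stratify(coh, "a"),
                               b = stratify(coh, "b")))
  expect_equal(rebuilt$presence, coh$presence, ignore_attr = TRUE)
  expect_equal(pairwise_counts(rebuilt)$N_ij, pairwise_counts(coh)$N_ij)
})

test_that("condition-count histogram conserves N and reports moments", {
  all_zero <- suppressMessages(
    cohort(matrix(0L, 10, 2, dimnames = list(NULL, c("A", "B")))))
  h <- condition_count_histogram(all_zero)
  expect_equal(h$histogram, c("0" = 10L))
  expect_equal(h$mean, 0)

  two <- cohort(cbind(A = c(1L, 1L), B = c(1L, 0L), C = c(0L, 0L)))
  h2 <- condition_count_histogram(two)
  expect_equal(h2$histogram, c("0" = 0L, "1" = 1L, "2" = 1L))
  expect_equal(h2$mean, 1.5)

  coh <- fixture_random_cohort(200, 5, rng_seed = 9)
  expect_equal(sum(condition_count_histogram(coh)$histogram), 200L)
})

test_that("cohort CSV and summary JSON round-trip", {
  coh <- fixture_random_cohort(30, 4, rng_seed = 2,
                               strata = rep(c("m", "w"), 15))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path, stratum_col = "sex")
  back <- read_cohort(path, stratum_col = "sex")
  expect_equal(back$presence, coh$presence)
  expect_equal(back$strata, coh$strata)

  jpath <- withr::local_tempfile(fileext = ".json")
  write_cohort_summary(coh, jpath)
  js <- jsonlite::read_json(jpath)
  expect_equal(js$n_patients, 30L)
  expect_equal(length(js$prevalence), 4L)
})

test_that("long-format records convert to the same cohort", {
  coh <- fixture_random_cohort(20, 3, rng_seed = 4)
  idx <- which(coh$presence == 1L, arr.ind = TRUE)
  rec <- data.frame(patient = idx[, 1L],
                    condition = condition_names(coh)[idx[, 2L]])
  back <- suppressMessages(
    cohort_from_long(rec, patients = 1:20,
                     conditions = condition_names(coh)))
  expect_equal(back$presence, coh$presence, ignore_attr = TRUE)
  expect_error(cohort_from_long(rec, patients = 1:20, conditions = "C1"),
               "not in panel")
})
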