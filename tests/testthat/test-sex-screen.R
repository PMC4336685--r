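make_calls <- function(rows, ids) {
  calls <- tibble::tibble(locus_id = sprintf("L%05d", seq_along(rows)),
                          position = 10L)
  for (k in seq_along(ids)) {
    calls[[ids[k]]] <- vapply(rows, `[`, character(1), k)
  }
  calls
}

test_that("parent filtering keeps informative rows and logs the rest", {
  ids <- c("mother", "father", "kid")
  calls <- make_calls(list(
    c("A/G", "G/G", "A/G"),   # kept: parents differ
    c("A/A", "A/A", "A/A"),   # monomorphic
    c("./.", "G/G", "A/G")    # parent missing
  ), ids)
  f <- filter_parent_polymorphic(calls, "mother", "father")
  expect_equal(nrow(f$calls), 1)
  expect_equal(setNames(f$log$n, f$log$reason),
               c(kept = 1L, monomorphic = 1L, parent_missing = 1L))
  expect_error(filter_parent_polymorphic(calls, "mom", "father"),
               "unknown parent")
})

test_that("a perfect female-het/male-hom split is a ZW-type candidate", {
  ids <- c("mother", "father", sprintf("F%d", 1:8), sprintf("M%d", 1:8))
  sexes <- setNames(c("female", "male", rep("female", 8), rep("male", 8)),
                    ids)
  calls <- make_calls(list(
    c("C/T", "T/T", rep("C/T", 8), rep("T/T", 8))
  ), ids)
  cand <- screen_sex_association(calls, sexes)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$heterogametic_sex, "female")
  expect_equal(cand$iupac, "Y")
  expect_equal(cand$female_genotype, "C/T")
  expect_equal(cand$male_genotype, "T/T")
})

test_that("one discordant male disqualifies a candidate", {
  ids <- c("mother", "father", sprintf("F%d", 1:8), sprintf("M%d", 1:8))
  sexes <- setNames(c("female", "male", rep("female", 8), rep("male", 8)),
                    ids)
  gts <- c("C/T", "T/T", rep("C/T", 8), rep("T/T", 7), "C/T")
  cand <- screen_sex_association(make_calls(list(gts), ids), sexes)
  expect_equal(nrow(cand), 0)
})

test_that("the hom base must belong to the het pair", {
  ids <- c("f1", "f2", "m1", "m2")
  sexes <- setNames(c("female", "female", "male", "male"), ids)
  ok <- screen_sex_association(
    make_calls(list(c("A/G", "A/G", "G/G", "G/G")), ids), sexes)
  expect_equal(nrow(ok), 1)
  bad <- screen_sex_association(
    make_calls(list(c("A/G", "A/G", "C/C", "C/C")), ids), sexes)
  expect_equal(nrow(bad), 0)
})

test_that("screening matches a brute-force row scan on random matrices", {
  set.seed(301)
  for (rep in 1:40) {
    m <- informative_genotype_matrix(60, 4, 4)
    # sprinkle mirror rows and missing calls
    prog <- setdiff(names(m$sexes), c("mother", "father"))
    m$calls[[sample(prog, 1)]][sample(60, 5)] <- "./."
    cand <- screen_sex_association(m$calls, m$sexes, max_missing = 0)
    want <- oracle_screen(m$calls, m$sexes, max_missing = 0)
    expect_equal(sort(cand$locus_id), sort(m$calls$locus_id[want$row]))
  }
})

test_that("heterogamety inference follows the candidate polarity", {
  f <- tibble::tibble(heterogametic_sex = rep("female", 8))
  expect_equal(infer_sex_system(f)$system, "ZW")
  m <- tibble::tibble(heterogametic_sex = rep("male", 3))
  expect_equal(infer_sex_system(m)$system, "XY")
  mix <- tibble::tibble(heterogametic_sex = c("female", "female",
                                              "male", "male"))
  expect_equal(infer_sex_system(mix)$system, "undetermined")
  none <- tibble::tibble(heterogametic_sex = character(0))
  expect_equal(infer_sex_system(none)$system, "undetermined")
})

test_that("chance cosegregation probability follows the closed form", {
  expect_equal(chance_cosegregation_probability(8, 8), 2 * 0.5^16)
  expect_equal(chance_cosegregation_probability(8, 8), 3.0517578125e-05)
  expect_equal(chance_cosegregation_probability(1, 1), 0.5)
  expect_error(chance_cosegregation_probability(0, 5))
})

test_that("IUPAC codes cover every unordered base pair", {
  expect_equal(iupac_code("C", "A"), "M")
  expect_equal(iupac_code("T", "A"), "W")
  expect_equal(iupac_code("G", "T"), "K")
  expect_equal(iupac_code("A", "G"), "R")
  expect_equal(iupac_code("G", "A"), "R")  # unordered
  expect_equal(iupac_code("C", "G"), "S")
  expect_equal(iupac_code("C", "T"), "Y")
  expect_error(iupac_code("A", "A"), "distinct")
})

test_that("validation panels score by the heterogamety rule", {
  cand <- tibble::tibble(marker_name = "SNP-X-L00001",
                         heterogametic_sex = "female")
  panel <- tibble::tibble(
    individual_id = sprintf("p%d", 1:10),
    sex = rep(c("female", "male"), each = 5),
    `SNP-X-L00001` = c(rep("A/G", 5), rep("G/G", 5)))
  sc <- score_validation_panel(cand, panel)
  expect_equal(sc$accuracy, 1)
  expect_true(sc$validated)

  panel2 <- panel
  panel2$`SNP-X-L00001`[10] <- "A/G"   # one het male
  sc2 <- score_validation_panel(cand, panel2)
  expect_equal(sc2$accuracy, 0.9)
  expect_false(sc2$validated)

  panel3 <- panel
  panel3$`SNP-X-L00001`[1] <- "./."
  sc3 <- score_validation_panel(cand, panel3)
  expect_equal(sc3$n_missing, 1)
  expect_equal(sc3$accuracy, 1)

  expect_error(score_validation_panel(cand, panel[0, ]), "empty")
})

test_that("candidate flanking sequences bracket the SNP as in marker tables", {
  run <- tiny_run()
  expect_gt(nrow(run$candidates), 0)
  fl <- run$candidates$flanking_sequence[1]
  pos <- variant_positions_from_bracketed(fl)
  expect_equal(pos, run$candidates$position[1])
  expect_equal(nchar(unbracket_sequence(fl)), 82)
  expect_true(startsWith(fl, "AATTC") || run$candidates$position[1] <= 5)
})
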