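test_that("confusion matrices count correctly", {
  cm <- confusionMatrix(c("A", "A", "B"), c("A", "B", "B"))
  expect_equal(unclass(cm), matrix(c(1, 0, 1, 1), 2,
                                   dimnames = list(reference = c("A", "B"),
                                                   predicted = c("A", "B"))),
               ignore_attr = TRUE)
  expect_equal(sum(cm), 3)                     # conservation
  ident <- confusionMatrix(letters[1:5], letters[1:5])
  expect_true(all(unclass(ident)[upper.tri(ident) | lower.tri(ident)] == 0))
  expect_error(confusionMatrix(c("A", "B"), "A"), "length")
})

test_that("accuracy and kappa match hand-computed values", {
  m <- matrix(c(40, 20, 10, 30), 2)
  expect_equal(overallAccuracy(m), 0.70)
  expect_equal(cohensKappa(m), 0.40)
  diagm <- diag(c(5, 7, 9))
  expect_equal(overallAccuracy(diagm), 1)
  expect_equal(cohensKappa(diagm), 1)
  off <- matrix(c(0, 3, 4, 0), 2)
  expect_equal(overallAccuracy(off), 0)
  # permutation invariance
  perm <- m[2:1, 2:1]
  expect_equal(cohensKappa(perm), cohensKappa(m))
  expect_equal(overallAccuracy(perm), overallAccuracy(m))
})

test_that("kappa is near zero for independent labels", {
  set.seed(8)
  ref <- sample(c("x", "y"), 10000, TRUE)
  pred <- sample(c("x", "y"), 10000, TRUE)
  expect_lt(abs(cohensKappa(confusionMatrix(ref, pred))), 0.03)
})

test_that("kappa bounds and relation to accuracy hold on random matrices", {
  set.seed(19)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    m <- matrix(rpois(k * k, 20), k)
    kap <- cohensKappa(m)
    expect_gte(kap, -1); expect_lte(kap, 1)
    expect_lte(kap, overallAccuracy(m) + 1e-12)
  }
})

test_that("kappa agrees with the e1071 reference implementation", {
  set.seed(27)
  for (i in 1:10) {
    m <- matrix(rpois(9, 15) + 1, 3)
    expect_equal(cohensKappa(m), e1071::classAgreement(m)$kappa,
                 tolerance = 1e-12)
  }
})

test_that("kappa quality adjectives follow the published scales", {
  q <- kappaQuality(0.65)
  expect_equal(unname(q["monserud"]), "good")
  expect_equal(unname(q["landis_koch"]), "substantial")
  expect_equal(unname(kappaQuality(0.816)["monserud"]), "very good")
})
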