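test_that("transaction construction builds correct per-item tid-sets", {
  db <- buildTransactionDB(list(c("a=1"), c("a=1", "b=2"), c("b=2")))
  expect_equal(nTransactions(db), 3L)
  expect_equal(tidsOf(db, "a=1"), c(1L, 2L))
  expect_equal(tidsOf(db, "b=2"), c(2L, 3L))
  expect_equal(supportCount(db, c("a=1", "b=2")), 1L)
  expect_equal(supportCount(db, character(0)), 3L)
})

test_that("degenerate inputs are rejected with diagnostics", {
  expect_error(buildTransactionDB(list()), "empty database")
  expect_error(buildTransactionDB(list(c("a=1", "a=2"))),
               "transaction 1 .* attribute 'a'")
  db <- buildTransactionDB(list(c("a=1")))
  expect_error(supportCount(db, "zz=9"), "unknown item.*zz=9")
  expect_error(tidsOf(db, c("a=1", "q=1")), "q=1")
})

test_that("support is anti-monotone under itemset growth", {
  set.seed(42)
  for (rep in 1:25) {
    db <- randomDB(sample(4:10, 1), sample(3:8, 1), p = 0.5)
    items <- itemUniverse(db)
    if (length(items) < 2) next
    J <- sample(items, sample(seq_len(length(items) - 1), 1))
    extra <- sample(setdiff(items, J), 1)
    expect_gte(supportCount(db, J), supportCount(db, c(J, extra)))
  }
})

test_that("tid-set of a union is the intersection of tid-sets", {
  set.seed(7)
  db <- randomDB(8, 6, p = 0.5)
  items <- itemUniverse(db)
  for (kJ in 0:2) {
    for (kH in 0:2) {
      if (kJ + kH == 0) next
      J <- items[seq_len(kJ)]
      H <- items[seq(length(items), by = -1, length.out = kH)]
      expect_equal(tidsOf(db, union(J, H)),
                   intersect(tidsOf(db, J), tidsOf(db, H)))
    }
  }
})

test_that("rule tables round-trip through write/read at printed precision", {
  db <- buildTransactionDB(rep(list(c("WHR=4", "FPG=3")), 3))
  rules <- ClosedARM:::.newRuleSet(list(list(
    antecedent = c("FPG=3", "HbA1c=4", "TG=3", "WHR=4"),
    consequent = "BOP=3",
    sigma_rule = 14L, sigma_head = 14L, sigma_tail = 74L,
    conf = 100, comp = 100 * 14 / 74, lift = 143 * 14 / (14 * 74))),
    143L, list())
  path <- withr::local_tempfile(fileext = ".tsv")
  writeRuleTable(rules, path)
  back <- readRuleTable(path, n = 143)
  expect_equal(back@rules$antecedent[[1]],
               c("FPG=3", "HbA1c=4", "TG=3", "WHR=4"))
  expect_equal(back@rules$consequent[[1]], "BOP=3")
  expect_identical(back@rules$sigma_rule, 14L)
  expect_identical(back@rules$sigma_head, 14L)
  expect_identical(back@rules$sigma_tail, 74L)
  expect_identical(back@rules$conf, 100.00)
  expect_identical(back@rules$comp, 18.92)  # 14/74 rounded half-up
  expect_identical(back@rules$lift, 1.93)   # 1.9324... prints as 1.93
})

test_that("an empty rule set writes a header-only file", {
  rules <- ClosedARM:::.newRuleSet(list(), 10L, list())
  path <- withr::local_tempfile(fileext = ".tsv")
  writeRuleTable(rules, path)
  expect_length(readLines(path), 1L)
})

test_that("clinical CSV reader validates codes against attribute domains", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject,group,FPG,HbA1c,BMI",
               "p1,1,3,4,3",
               "p2,5,1,1,2"), path)
  rec <- readClinicalTable(path)
  expect_equal(rec$FPG, c(3L, 1L))
  expect_equal(rec$group, c(1L, 5L))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject,group,BMI", "p1,1,6"), bad)
  expect_error(readClinicalTable(bad), "subject p1.*BMI.*6")

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("subject,group,BMI", empty)
  expect_error(readClinicalTable(empty), "empty clinical table")
})

test_that("header aliases can be remapped via config", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,grp,glucose", "p1,2,3"), path)
  rec <- readClinicalTable(path, headerMap = c(glucose = "FPG"),
                           subjectCol = "id", groupCol = "grp")
  expect_equal(rec$FPG, 3L)
})

test_that("expression matrix reader preserves values and probe ids", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("probe\ts1\ts2", "229026_at\t1.5\t2.5", "223130_s_at\t-1\t0"),
             path)
  se <- readExpressionMatrix(path, groups = c(s1 = 1, s2 = 2))
  m <- SummarizedExperiment::assay(se, "exprs")
  expect_equal(rownames(m), c("229026_at", "223130_s_at"))
  expect_equal(unname(m["229026_at", ]), c(1.5, 2.5))
  expect_equal(SummarizedExperiment::colData(se)$group, c(1L, 2L))

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("probe\ts1", "p1\tNA"), bad)
  expect_error(readExpressionMatrix(bad), "missing cell")

  dup <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("probe\ts1", "p1\t1", "p1\t2"), dup)
  expect_error(readExpressionMatrix(dup), "duplicated probe")
})

test_that("combineDB joins gene and clinical universes over shared subjects", {
  d1 <- buildTransactionDB(stats::setNames(list("g1=+1", "g2=-1"), c("A", "B")),
                           labels = c(1, 2))
  d2 <- buildTransactionDB(stats::setNames(list("FPG=3", "FPG=1"), c("A", "B")))
  db <- combineDB(d1, d2)
  expect_setequal(itemUniverse(db), c("g1=+1", "g2=-1", "FPG=3", "FPG=1"))
  expect_equal(supportCount(db, c("g1=+1", "FPG=3")), 1L)
  d3 <- buildTransactionDB(stats::setNames(list("x=1"), "C"))
  expect_error(combineDB(d1, d3), "same transactions")
})
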