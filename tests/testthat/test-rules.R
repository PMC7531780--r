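test_that("rule metrics reproduce the printed confidence and lift values", {
  expect_equal(ruleMetrics(14, 14, 74, 143),
               c(conf = 100.00, comp = 18.92, lift = 1.93))
  expect_equal(ruleMetrics(22, 26, 74, 143)[["conf"]], 84.62)
  expect_equal(ruleMetrics(22, 26, 74, 143)[["lift"]], 1.64)
  expect_equal(ruleMetrics(5, 5, 5, 10),
               c(conf = 100.00, comp = 100.00, lift = 2.00))
  expect_error(ruleMetrics(5, 4, 5, 10), "ordering")
  expect_error(ruleMetrics(0, 1, 1, 10), ">= 1")
  expect_error(ruleMetrics(3, 3, 11, 10), "ordering")
})

test_that("display rounding is half-up at 2 decimals", {
  expect_equal(roundHalfUp(1.932432), 1.93)
  expect_equal(roundHalfUp(84.615384), 84.62)
  expect_equal(roundHalfUp(2.005), 2.01)  # half goes up, not to even
  expect_equal(roundHalfUp(71.425), 71.43)
})

test_that("rule generation on a hand-counted toy database is exact", {
  ## 5 subjects share {x=1, BOP=3}; 2 more have BOP=3 alone
  tx <- c(rep(list(c("x=1", "BOP=3")), 5), rep(list("BOP=3"), 2),
          rep(list("y=1"), 3))
  db <- buildTransactionDB(tx)
  closed <- mineClosed(db, 2)
  rules <- generateRules(closed, db, 0.7,
                         consequentConstraint(pool = "BOP",
                                              required = "BOP=3"))
  expect_equal(nRules(rules), 1L)
  r <- rules@rules
  expect_equal(r$antecedent[[1]], "x=1")
  expect_equal(r$consequent[[1]], "BOP=3")
  expect_equal(r$conf, 100)
  expect_equal(r$sigma_rule, 5)
  expect_equal(r$sigma_tail, 7)
  ## closed sets without a constraint item yield nothing
  rules0 <- generateRules(closed, db, 0.7,
                          consequentConstraint(pool = "z", required = "z=9"))
  expect_equal(nRules(rules0), 0L)
  ## unattainable confidence yields nothing
  expect_equal(nRules(generateRules(closed, db, 1.01,
                                    consequentConstraint(pool = "BOP",
                                                         required = "BOP=3"))),
               0L)
})

test_that("generated rules match an independent brute-force enumerator", {
  set.seed(55)
  for (rep in 1:8) {
    db <- randomDB(8, 6, p = 0.5)
    minSup <- 2; minConf <- 0.6
    constraint <- consequentConstraint(
      pool = sprintf("a%02d", 1:3), mode = "any")
    got <- generateRules(mineClosed(db, minSup), db, minConf, constraint)
    expect_identical(ruleKeys(got), naiveRules(db, minSup, minConf, constraint))
  }
})

test_that("stored metrics equal metrics recomputed from raw tid-sets", {
  set.seed(66)
  db <- randomDB(10, 7, p = 0.5)
  rules <- generateRules(mineClosed(db, 2), db, 0.5,
                         consequentConstraint(pool = sprintf("a%02d", 1:7),
                                              mode = "any"))
  df <- rules@rules
  n <- nTransactions(db)
  for (i in seq_len(nrow(df))) {
    J <- df$antecedent[[i]]; H <- df$consequent[[i]]
    sr <- length(intersect(tidsOf(db, J), tidsOf(db, H)))
    sh <- supportCount(db, J); st <- supportCount(db, H)
    expect_identical(df$sigma_rule[i], sr)
    expect_identical(df$sigma_head[i], sh)
    expect_identical(df$sigma_tail[i], st)
    expect_equal(df$conf[i], 100 * sr / sh)
    expect_equal(df$comp[i], 100 * sr / st)
    expect_equal(df$lift[i], n * sr / (sh * st))
  }
  ## lift >= conf (as fractions), equality iff the consequent is universal
  expect_true(all(df$lift >= df$conf / 100 - 1e-12))
  eq <- abs(df$lift - df$conf / 100) < 1e-12
  expect_identical(unname(eq), unname(df$sigma_tail == n))
})

test_that("confidence and completeness swap under rule reversal", {
  set.seed(8)
  db <- randomDB(10, 6, p = 0.55)
  items <- itemUniverse(db)
  for (rep in 1:20) {
    J <- sample(items, 2); H <- sample(setdiff(items, J), 1)
    sr <- length(intersect(tidsOf(db, J), tidsOf(db, H)))
    if (sr == 0) next
    fwd <- ruleMetrics(sr, supportCount(db, J), supportCount(db, H),
                       nTransactions(db))
    rev <- ruleMetrics(sr, supportCount(db, H), supportCount(db, J),
                       nTransactions(db))
    expect_equal(fwd[["conf"]], rev[["comp"]])
    expect_equal(fwd[["comp"]], rev[["conf"]])
    expect_equal(fwd[["lift"]], rev[["lift"]])
  }
})

test_that("ranking orders by the criteria profile, descending and stable", {
  mk <- function(ante, conf, comp) {
    list(antecedent = ante, consequent = "BOP=3", sigma_rule = 5L,
         sigma_head = 5L, sigma_tail = 7L, conf = conf, comp = comp,
         lift = 1.5)
  }
  rules <- ClosedARM:::.newRuleSet(list(
    mk(c("FPG=3", "HbA1c=4"), 95, 50),          # 2 altered codes
    mk(c("FPG=1", "HbA1c=1"), 100, 50),         # 0 altered
    mk(c("FPG=3", "TG=3"), 100, 50)             # 2 altered, higher conf
  ), 143L, list())
  ranked <- rankRules(rules, profile = c("altered", "conf"))
  expect_equal(vapply(ranked@rules$antecedent, paste, "", collapse = "+"),
               c("FPG=3+TG=3", "FPG=3+HbA1c=4", "FPG=1+HbA1c=1"))
  ## CF+DEG profile prefers an over-expressed gene item, all else equal
  g <- ClosedARM:::.newRuleSet(list(
    mk(c("FPG=3", "p1=-1"), 100, 60),
    mk(c("FPG=3", "p2=+1"), 100, 60)
  ), 30L, list())
  ranked <- rankRules(g, profile = c("altered", "over_gene", "conf", "comp"))
  expect_true("p2=+1" %in% ranked@rules$antecedent[[1]])
  expect_error(rankRules(rules, profile = "sparkle"), "unknown ranking key")
  empty <- ClosedARM:::.newRuleSet(list(), 10L, list())
  expect_equal(nRules(rankRules(empty)), 0L)
})
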