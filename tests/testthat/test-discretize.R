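test_that("fixed-cutoff attributes discretize per the printed domains", {
  expect_equal(discretizeAttribute("FPG", c(99.9, 100, 125.9, 126, 300)),
               c(1L, 2L, 2L, 3L, 3L))
  expect_equal(discretizeAttribute("HbA1c", c(5.6, 5.7, 6.4, 6.5, 8, 12)),
               c(1L, 2L, 2L, 3L, 4L, 4L))
  ## HDL's middle bin is closed on both ends, ">60" strict
  expect_equal(discretizeAttribute("HDL", c(39.9, 40, 60, 60.1)),
               c(1L, 2L, 2L, 3L))
  expect_equal(discretizeAttribute("BMI", c(18.4, 18.5, 25, 30, 35, 50)),
               c(1L, 2L, 3L, 4L, 5L, 5L))
  expect_equal(discretizeAttribute("SUPP", c(0.5, 1, 15.9, 16)),
               c(1L, 2L, 2L, 3L))
  ## percentage periodontal bins: [30, 50] medium, >50 high
  expect_equal(discretizeAttribute("BOP", c(29.9, 30, 50, 50.1)),
               c(1L, 2L, 2L, 3L))
  expect_equal(discretizeAttribute("PPDi6mm", c(29.9, 30, 80)),
               c(1L, 2L, 2L))
  expect_error(discretizeAttribute("FPG", -1), "negative")
  expect_error(discretizeAttribute("nope", 1), "unknown")
  expect_error(discretizeAttribute("WHR", 0.8), "stratified")
})

test_that("waist/hip ratio uses sex- and age-stratified cutoffs", {
  expect_equal(discretizeWHR(0.85, "female", 45), 3L)
  expect_equal(discretizeWHR(1.05, "male", 55), 4L)
  expect_equal(discretizeWHR(0.72, "female", 30), 2L)
  ## stratum boundaries: 39 belongs to the younger stratum, 49 to the middle
  expect_equal(discretizeWHR(0.85, "female", 39), 4L)
  expect_equal(discretizeWHR(0.87, "female", 49), 3L)
  ## 0.72 is moderate up to age 39, low in the (39, 49] stratum
  expect_equal(discretizeWHR(0.72, "female", 39.5), 1L)
  ## male middle stratum: high is [0.96, 1]
  expect_equal(discretizeWHR(c(0.95, 0.96, 1.0, 1.001), "male", 45),
               c(2L, 3L, 3L, 4L))
})

test_that("abdominal circumference uses sex-specific cutoffs", {
  expect_equal(discretizeAC(90, "female"), 3L)
  expect_equal(discretizeAC(95, "male"), 2L)
  expect_equal(discretizeAC(79.9, "female"), 1L)
  expect_equal(discretizeAC(c(80, 88), "female"), c(2L, 3L))
  expect_equal(discretizeAC(c(93.9, 94, 102), "male"), c(1L, 2L, 3L))
})

test_that("every discretization partitions the measurement axis", {
  ## fine grid across each attribute's span (plus the printed cutoffs
  ## themselves): exactly one code everywhere, codes cover the domain
  cfg <- clinicalCutoffs()
  for (a in setdiff(clinicalAttributes(), c("Sex", "WHR", "AC"))) {
    att <- cfg$attributes[[a]]
    edges <- c(att$bins$lower, att$bins$upper)
    edges <- edges[!is.na(edges)]
    grid <- sort(unique(c(seq(att$span[1], att$span[2], length.out = 401),
                          edges, edges - 1e-9, edges + 1e-9)))
    grid <- grid[grid >= 0]
    codes <- discretizeAttribute(a, grid)
    expect_false(anyNA(codes), label = paste("gaps in", a))
    expect_setequal(unique(codes), attributeDomain(a))
  }
  for (sex in c("female", "male")) {
    for (age in c(30, 39, 45, 49, 55)) {
      grid <- seq(0.5, 1.3, by = 0.001)
      codes <- discretizeWHR(grid, sex, age)
      expect_false(anyNA(codes))
      expect_setequal(unique(codes), 1:4)
    }
    codes <- discretizeAC(seq(50, 140, by = 0.1), sex)
    expect_false(anyNA(codes))
    expect_setequal(unique(codes), 1:3)
  }
})

test_that("already-coded records pass through unchanged", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject,group,FPG,HbA1c,TG", "p1,1,3,4,3", "p2,3,1,2,1"), path)
  rec <- readClinicalTable(path, values = "coded")
  expect_identical(rec$FPG, c(3L, 1L))
  expect_identical(rec$HbA1c, c(4L, 2L))
  expect_identical(rec$TG, c(3L, 1L))
})

test_that("the CF subset has 17 attributes and excludes mutagenesis", {
  expect_length(cfAttributes(), 17L)
  expect_false(any(c("NDI", "MNCF", "MNF", "FNB", "Sex", "Age") %in%
                     cfAttributes()))
  cohort <- generateClinical(syntheticSpec(), seed = 11)
  db <- selectCFSubset(cohort$coded)
  expect_equal(nTransactions(db), 143L)
  expect_setequal(unique(ClosedARM:::itemAttribute(itemUniverse(db))),
                  cfAttributes())
  ## every subject carries one item per attribute
  expect_true(all(rowSums(db@incidence) == 17L))
})

test_that("a missing code yields a shorter transaction and a warning", {
  coded <- generateClinical(syntheticSpec(), seed = 3)$coded[1:5, ]
  coded$GI[2] <- NA
  expect_warning(db <- selectCFSubset(coded), "missing value")
  expect_equal(sort(unname(rowSums(db@incidence))), c(16L, 17L, 17L, 17L, 17L))
})

test_that("diabetic-dyslipidemia selection needs raw lipids and respects bounds", {
  raw <- data.frame(subject = c("a", "b", "c", "d"),
                    group = c(2, 1, 3, 2),
                    TG = c(204, 203.9, 300, 250),
                    HDL = c(37.9, 30, 30, 38))
  sel <- selectDiabeticDyslipidemia(raw)
  expect_equal(sel$subject, "a")  # boundary TG>=204 & HDL<38; group 3 and HDL=38 excluded
  expect_error(selectDiabeticDyslipidemia(raw[, c("subject", "group")]),
               "raw TG and HDL")
})

test_that("the generator plants exactly the requested ddlp subset", {
  cohort <- generateClinical(syntheticSpec(), seed = 5)
  sel <- selectDiabeticDyslipidemia(cohort$raw)
  expect_equal(sort(sel$subject), sort(cohort$truth$ddlp))
  expect_length(cohort$truth$ddlp, 10L)
})
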