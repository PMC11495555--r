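# Chance-level tests, FDR, design coding, Stroop contrasts, cost-RT slope.

test_that("chance level and design codes match the study conventions", {
  expect_equal(chanceLevel(7), 1 / 7)
  des <- conditionDesign()
  expect_equal(nrow(des), 6L)
  expect_setequal(des$congruencyCode, c(-0.5, 0.5))
  expect_setequal(des$pcCode, c(-0.5, 0, 0.5))
  expect_equal(des$interaction, des$congruencyCode * des$pcCode)
  expect_equal(des$congruencyCode[des$congruency == "incongruent"],
               rep(-0.5, 3))
  expect_equal(des$pcCode[des$pc == "PC25"], rep(-0.5, 2))
})

test_that("one-sample t-test matches the textbook closed form", {
  res <- ttestVsChance(c(0.2, 0.3, 0.4), 0.1429)
  expect_equal(res$mean, 0.3)
  expect_equal(res$se, 0.1 / sqrt(3))
  expect_equal(res$t, (0.3 - 0.1429) / (0.1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(res$t, 2.7211, tolerance = 1e-4)
  expect_equal(res$p, 2 * pt(-abs(res$t), df = 2))
  expect_equal(res$d, (0.3 - 0.1429) / 0.1)
  # degenerate sample exactly at the null
  null <- ttestVsChance(rep(0.25, 5), 0.25)
  expect_equal(c(null$t, null$p, null$d), c(0, 1, 0))
  expect_error(ttestVsChance(rep(0.3, 5), 0.25),
               class = "msbridgeUndefinedStatisticError")
  expect_error(ttestVsChance(0.3, 0.25),
               class = "msbridgeUndefinedStatisticError")
})

test_that("BH adjustment matches the hand step-up and the classical rule", {
  res <- fdrBH(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(res$adjusted, rep(0.04, 4))
  expect_true(all(res$rejected))
  expect_equal(fdrBH(rep(1, 5))$adjusted, rep(1, 5))
  expect_false(any(fdrBH(rep(1, 5))$rejected))
  expect_equal(fdrBH(0.03)$adjusted, 0.03)
  expect_length(fdrBH(numeric())$adjusted, 0L)
  # random families: rejections equal the classical step-up rule, and
  # adjusted p-values are monotone in raw p-values
  set.seed(51)
  for (r in 1:10) {
    p <- runif(20)^2
    res <- fdrBH(p, alpha = 0.05)
    m <- length(p); o <- order(p)
    kmax <- suppressWarnings(max(which(p[o] <= seq_len(m) / m * 0.05)))
    classical <- logical(m)
    if (is.finite(kmax)) classical[o[seq_len(kmax)]] <- TRUE
    expect_equal(res$rejected, classical)
    expect_true(all(diff(res$adjusted[o]) >= -1e-15))
  }
})

test_that("effect tables carry the FDR family over all outcome x effect rows", {
  rows <- expand.grid(outcome = sprintf("state%d", 1:7),
                      effect = c("intercept", "congruency", "pc",
                                 "congruency:pc"),
                      stringsAsFactors = FALSE)
  rows$p <- seq(0.001, 0.9, length.out = nrow(rows))
  tab <- effectTable(rows)
  expect_equal(attr(tab, "familySize"), 28L)
  expect_true(all(tab$pFdr >= tab$p))
  expect_error(effectTable(data.frame(p = 0.1)),
               class = "msbridgeInputError")
})

test_that("Stroop effect is incongruent minus congruent and antisymmetric", {
  tbl <- expand.grid(subject = 1:3, congruency = c("congruent",
                                                   "incongruent"),
                     pc = c("PC25", "PC50"), stringsAsFactors = FALSE)
  tbl$value <- ifelse(tbl$congruency == "incongruent", 0.05, 0.03)
  d <- stroopEffect(tbl)
  expect_equal(d$delta, rep(0.02, 6))
  tblEq <- tbl; tblEq$value <- 0.04
  expect_equal(stroopEffect(tblEq)$delta, rep(0, 6))
  # swapping the labels flips the sign
  sw <- tbl
  sw$congruency <- ifelse(sw$congruency == "congruent", "incongruent",
                          "congruent")
  expect_equal(stroopEffect(sw)$delta, -d$delta)
  expect_error(stroopEffect(tbl[-1, ]), class = "msbridgeMissingCellError")
})

test_that("cost-RT association recovers an exact linear relation", {
  set.seed(52)
  d <- expand.grid(subject = 1:20, pc = c("PC25", "PC50", "PC75"),
                   stringsAsFactors = FALSE)
  d$deltaRt <- rnorm(nrow(d), 50, 20)
  d$deltaCost <- 0.1 * d$deltaRt + 1e-9 * rnorm(nrow(d))
  res <- costRtAssociation(d)
  expect_equal(res$slope, 0.1, tolerance = 1e-6)
  expect_lt(res$p, 1e-10)
  expect_equal(nrow(res$perPc), 3L)
  expect_equal(res$perPc$slope, rep(0.1, 3), tolerance = 1e-6)
  dconst <- d; dconst$deltaRt <- 5
  expect_error(costRtAssociation(dconst),
               class = "msbridgeUndefinedSlopeError")
})

test_that("permuting the pairing destroys the association", {
  set.seed(53)
  d <- data.frame(subject = 1:40, pc = "PC50",
                  deltaRt = rnorm(40, 50, 20))
  d$deltaCost <- 0.05 * d$deltaRt + rnorm(40, sd = 0.5)
  obs <- costRtAssociation(d)$slope
  perms <- replicate(200, {
    dp <- d; dp$deltaCost <- sample(dp$deltaCost)
    costRtAssociation(dp)$slope
  })
  expect_lt(abs(mean(perms)), abs(obs) / 4)
  expect_gt(mean(abs(perms) < abs(obs)), 0.9)
})

test_that("pooled slope recovery across a simulated cohort", {
  set.seed(54)
  hits <- replicate(60, {
    d <- expand.grid(subject = 1:44, pc = c("PC25", "PC50", "PC75"),
                     stringsAsFactors = FALSE)
    d$deltaRt <- rnorm(nrow(d), 50, 20)
    d$deltaCost <- 0.05 * d$deltaRt + rnorm(nrow(d), sd = 1)
    res <- costRtAssociation(d)
    abs(res$slope - 0.05) <= 2 * res$se
  })
  expect_gte(mean(hits), 0.9)
})

test_that("long-format export attaches the design codes", {
  tbl <- data.frame(subject = c(1, 1), outcome = "cost",
                    congruency = c("incongruent", "congruent"),
                    pc = c("PC25", "PC75"), value = c(0.1, 0.05))
  out <- exportLongFormat(tbl)
  expect_equal(out$congruencyCode, c(-0.5, 0.5))
  expect_equal(out$pcCode, c(-0.5, 0.5))
  expect_equal(out$interaction, c(0.25, 0.25))
  dir <- withr::local_tempdir()
  p <- file.path(dir, "long.csv")
  exportLongFormat(tbl, p)
  expect_equal(read.csv(p)$value, tbl$value)
})
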