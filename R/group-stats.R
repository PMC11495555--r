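# Group-level statistics: coverage tests against chance, BH-FDR over the
# effect family, condition design coding, Stroop-effect contrasts, and the
# cost-RT association summary. Full mixed-effects inference is delegated
# to external tooling via the long-format export.

#' Chance coverage level under a uniform state distribution
#'
#' The null coverage probability of each of K equiprobable microstates,
#' `1 / K` (0.1429 for the canonical K = 7).
#'
#' @param K number of microstates.
#' @return `1 / K`.
#' @export
chanceLevel <- function(K) {
  if (K < 1) msbStop("msbridgeParameterError", "K must be >= 1")
  1 / K
}

#' Condition design codes for the congruency x PC design
#'
#' Effect coding used throughout: congruency incongruent = -0.5,
#' congruent = +0.5; proportion-of-congruency PC25 = -0.5, PC50 = 0,
#' PC75 = +0.5; interaction = product.
#'
#' @return data.frame with one row per condition: `condition`,
#'   `congruency`, `pc`, `congruencyCode`, `pcCode`, `interaction`.
#' @export
conditionDesign <- function() {
  g <- expand.grid(congruency = c("incongruent", "congruent"),
                   pc = c("PC25", "PC50", "PC75"),
                   stringsAsFactors = FALSE)
  g$congruencyCode <- ifelse(g$congruency == "congruent", 0.5, -0.5)
  g$pcCode <- c(PC25 = -0.5, PC50 = 0, PC75 = 0.5)[g$pc]
  g$interaction <- g$congruencyCode * g$pcCode
  g$condition <- paste(g$congruency, g$pc, sep = "_")
  g[, c("condition", "congruency", "pc", "congruencyCode", "pcCode",
        "interaction")]
}

#' One-sample t-test against a chance level
#'
#' Two-tailed one-sample t-test of per-subject values against
#' `nullValue`, with Cohen's d = (mean - null) / sd.
#'
#' @param values per-subject numeric values (n >= 2).
#' @param nullValue null hypothesis value (e.g. `chanceLevel(7)`).
#' @return list with `t`, `p`, `d`, `mean`, `se`, `df`, `n`.
#' @export
ttestVsChance <- function(values, nullValue) {
  n <- length(values)
  if (n < 2L)
    msbStop("msbridgeUndefinedStatisticError",
            "need >= 2 values for a one-sample t-test, got %d", n)
  s <- stats::sd(values)
  m <- mean(values)
  if (s == 0) {
    # degenerate sample exactly at the null: report the null outcome
    if (m == nullValue)
      return(list(t = 0, p = 1, d = 0, mean = m, se = 0, df = n - 1L,
                  n = n))
    msbStop("msbridgeUndefinedStatisticError",
            "zero variance: t statistic undefined")
  }
  se <- s / sqrt(n)
  tt <- (m - nullValue) / se
  list(t = tt, p = 2 * stats::pt(-abs(tt), df = n - 1L),
       d = (m - nullValue) / s, mean = m, se = se, df = n - 1L, n = n)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR control over a family of p-values: adjusted p-values via
#' `stats::p.adjust(method = "BH")` (monotone, capped at 1), with
#' rejection flags equal to the classical step-up rule at level `alpha`.
#'
#' @param pvalues numeric vector of raw p-values in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return list with `adjusted` and logical `rejected`, same length as
#'   input (empty input gives empty output).
#' @export
fdrBH <- function(pvalues, alpha = 0.05) {
  if (!length(pvalues)) return(list(adjusted = numeric(),
                                    rejected = logical()))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    msbStop("msbridgeParameterError", "p-values must lie in [0, 1]")
  adj <- stats::p.adjust(pvalues, method = "BH")
  list(adjusted = adj, rejected = adj <= alpha)
}

#' Assemble and FDR-adjust a family of effect estimates
#'
#' Binds per-outcome, per-effect rows (e.g. one row per microstate per
#' fixed effect) into a single effect table and applies
#' Benjamini-Hochberg correction over the whole family, which is the
#' multiplicity unit for the per-microstate models (all fixed effects of
#' all outcomes: with 7 microstates and 4 effects, a family of 28).
#'
#' @param rows data.frame with at least `outcome`, `effect`, `p`; typically
#'   also `estimate`, `se`, `t`.
#' @param alpha FDR level (default 0.05).
#' @return The input with `pFdr` and `significant` columns appended;
#'   `familySize` attribute holds the family size m.
#' @export
effectTable <- function(rows, alpha = 0.05) {
  need <- c("outcome", "effect", "p")
  if (!all(need %in% names(rows)))
    msbStop("msbridgeInputError",
            "effect table needs columns outcome, effect, p")
  fd <- fdrBH(rows$p, alpha)
  rows$pFdr <- fd$adjusted
  rows$significant <- fd$rejected
  attr(rows, "familySize") <- nrow(rows)
  rows
}

#' Stroop-effect contrast (incongruent minus congruent)
#'
#' For each subject x PC cell, the difference
#' `value(incongruent) - value(congruent)`. Works identically for
#' transition costs, response times, or any per-condition measure.
#'
#' @param tbl data.frame with columns `subject`, `congruency`
#'   ("incongruent"/"congruent"), `pc`, `value`.
#' @return data.frame `(subject, pc, delta)`.
#' @export
stroopEffect <- function(tbl) {
  need <- c("subject", "congruency", "pc", "value")
  if (!all(need %in% names(tbl)))
    msbStop("msbridgeInputError",
            "need columns subject, congruency, pc, value")
  cells <- unique(tbl[, c("subject", "pc")])
  out <- lapply(seq_len(nrow(cells)), function(r) {
    sub <- cells$subject[r]; pc <- cells$pc[r]
    inc <- tbl$value[tbl$subject == sub & tbl$pc == pc &
                     tbl$congruency == "incongruent"]
    con <- tbl$value[tbl$subject == sub & tbl$pc == pc &
                     tbl$congruency == "congruent"]
    if (length(inc) != 1L || length(con) != 1L)
      msbStop("msbridgeMissingCellError",
              "subject %s, %s: need exactly one value per congruency level",
              as.character(sub), as.character(pc))
    data.frame(subject = sub, pc = pc, delta = inc - con)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Association between Stroop effects in cost and in response time
#'
#' Pooled fixed-effect slope of the cost Stroop effect on the RT Stroop
#' effect: ordinary least squares of `deltaCost` on `deltaRt` with
#' PC-level intercepts, plus per-PC simple-slope summaries. (The full
#' random-slope mixed model of the reference analysis is delegated to
#' external tooling via [exportLongFormat()].)
#'
#' @param deltas data.frame with columns `subject`, `pc`, `deltaCost`,
#'   `deltaRt` (>= 3 subjects).
#' @return list with `slope`, `se`, `t`, `p`, `n`, and `perPc`
#'   data.frame `(pc, slope, se, t, p)`.
#' @export
costRtAssociation <- function(deltas) {
  need <- c("subject", "pc", "deltaCost", "deltaRt")
  if (!all(need %in% names(deltas)))
    msbStop("msbridgeInputError",
            "need columns subject, pc, deltaCost, deltaRt")
  if (length(unique(deltas$subject)) < 3L)
    msbStop("msbridgeInputError", "need >= 3 subjects")
  if (stats::sd(deltas$deltaRt) == 0)
    msbStop("msbridgeUndefinedSlopeError",
            "deltaRt is constant: slope undefined")
  multiPc <- length(unique(deltas$pc)) > 1L
  fit <- if (multiPc) stats::lm(deltaCost ~ deltaRt + factor(pc),
                                data = deltas)
         else stats::lm(deltaCost ~ deltaRt, data = deltas)
  cf <- summary(fit)$coefficients["deltaRt", ]
  perPc <- lapply(split(deltas, deltas$pc), function(d) {
    if (nrow(d) < 3L || stats::sd(d$deltaRt) == 0)
      return(data.frame(pc = d$pc[1L], slope = NA_real_, se = NA_real_,
                        t = NA_real_, p = NA_real_))
    cf2 <- summary(stats::lm(deltaCost ~ deltaRt, data = d))$coefficients
    data.frame(pc = d$pc[1L], slope = cf2["deltaRt", 1L],
               se = cf2["deltaRt", 2L], t = cf2["deltaRt", 3L],
               p = cf2["deltaRt", 4L])
  })
  perPc <- do.call(rbind, perPc)
  rownames(perPc) <- NULL
  list(slope = unname(cf[1L]), se = unname(cf[2L]), t = unname(cf[3L]),
       p = unname(cf[4L]), n = nrow(deltas), perPc = perPc)
}

#' Export a long-format table for external mixed-model tooling
#'
#' One row per subject x outcome x condition with the design codes of
#' [conditionDesign()] attached — directly consumable by lme4-style
#' mixed-effects tools.
#'
#' @param tbl data.frame with columns `subject`, `outcome`, `congruency`,
#'   `pc`, `value`.
#' @param path optional CSV destination; when given the table is written
#'   there.
#' @return The long-format data.frame (invisibly when `path` is given).
#' @export
exportLongFormat <- function(tbl, path = NULL) {
  need <- c("subject", "outcome", "congruency", "pc", "value")
  if (!all(need %in% names(tbl)))
    msbStop("msbridgeInputError",
            "need columns subject, outcome, congruency, pc, value")
  des <- conditionDesign()
  m <- match(paste(tbl$congruency, tbl$pc, sep = "_"), des$condition)
  if (anyNA(m))
    msbStop("msbridgeInputError", "unknown congruency/pc combination")
  out <- data.frame(subject = tbl$subject, outcome = tbl$outcome,
                    congruencyCode = des$congruencyCode[m],
                    pcCode = des$pcCode[m],
                    interaction = des$interaction[m],
                    value = tbl$value)
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
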