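# Kaplan-Meier estimation, log-rank testing, and median-split stratification
# of genes, signatures and ligand-receptor pairs in bulk cohorts.
# Estimation and testing delegate to the survival package; this module owns
# the stratification rules and the KMCurve container.

#' Median split into High/Low groups
#'
#' High means strictly above the median; ties at the median go Low, so High
#' is strictly above-median by construction. Invariant under additive shifts.
#'
#' @param values per-sample numeric vector (>= 2 samples, not all equal).
#' @return factor with levels Low, High, named like `values`.
#' @export
medianSplit <- function(values) {
    if (length(values) < 2) stop("need at least 2 samples")
    if (max(values) == min(values))
        stop("all values identical; no median split possible")
    med <- stats::median(values)
    factor(ifelse(values > med, "High", "Low"), levels = c("Low", "High"))
}

#' Kaplan-Meier product-limit estimate
#'
#' @param surv data.frame with columns time (nonnegative) and event (0/1).
#' @param group label stored on the curve.
#' @return a [KMCurve-class] over the distinct observed times; censored-only
#'   times reduce the risk set without dropping the curve.
#' @export
kmEstimate <- function(surv, group = "all") {
    if (!nrow(surv)) stop("empty survival table")
    if (any(surv$time < 0)) stop("negative survival time")
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = surv)
    new("KMCurve", time = fit$time, nRisk = fit$n.risk,
        nEvent = fit$n.event, surv = fit$surv, group = group)
}

#' Two-group log-rank test
#'
#' Standard log-rank: at each distinct event time the risk sets are pooled,
#' expected events are allocated proportionally to risk-set share, and the
#' statistic is referred to chi-square with 1 df.
#'
#' @param groupA,groupB survival data.frames (time, event), both nonempty,
#'   with at least one event overall.
#' @return list(chisq, p).
#' @export
logrankTest <- function(groupA, groupB) {
    if (!nrow(groupA) || !nrow(groupB)) stop("empty group")
    if (sum(groupA$event) + sum(groupB$event) == 0)
        stop("no events in either group")
    dat <- rbind(data.frame(time = groupA$time, event = groupA$event,
                            grp = "A"),
                 data.frame(time = groupB$time, event = groupB$event,
                            grp = "B"))
    sd <- survival::survdiff(survival::Surv(time, event) ~ grp, data = dat)
    chisq <- unname(sd$chisq)
    list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Survival stratification by a ligand-receptor pair
#'
#' Stratifies bulk samples by the pair's combined expression and compares
#' the High and Low groups by Kaplan-Meier / log-rank. The default rule
#' scores each sample as the mean of the z-scored `log2(x + 1)` expression
#' of ligand and receptor, then median-splits the score; `rule = "both-high"`
#' instead calls High only the samples strictly above the median on both
#' genes.
#'
#' @param bulk bulk [SummarizedExperiment::SummarizedExperiment].
#' @param surv data.frame (sample, time, event); samples must match bulk
#'   columns.
#' @param ligand,receptor gene ids present in bulk (the same gene twice
#'   reduces to single-gene stratification).
#' @param rule "mean-z" (default) or "both-high".
#' @return list(high = KMCurve, low = KMCurve, chisq, p, groups).
#' @export
lrPairSurvival <- function(bulk, surv, ligand, receptor,
                           rule = c("mean-z", "both-high")) {
    rule <- match.arg(rule)
    vals <- as.matrix(SummarizedExperiment::assay(bulk, 1))
    missing <- setdiff(c(ligand, receptor), rownames(vals))
    if (length(missing))
        stop("gene(s) absent from bulk: ", paste(missing, collapse = ", "))
    bad <- setdiff(surv$sample, colnames(vals))
    if (length(bad))
        stop("survival sample(s) not in bulk: ",
             paste(utils::head(bad, 5), collapse = ", "))
    surv <- surv[match(intersect(colnames(vals), surv$sample),
                       surv$sample), , drop = FALSE]
    lv <- log2(vals[ligand, surv$sample] + 1)
    rv <- log2(vals[receptor, surv$sample] + 1)
    if (rule == "mean-z") {
        score <- (as.numeric(scale(lv)) + as.numeric(scale(rv))) / 2
        grp <- medianSplit(stats::setNames(score, surv$sample))
    } else {
        grp <- factor(ifelse(lv > stats::median(lv) &
                             rv > stats::median(rv), "High", "Low"),
                      levels = c("Low", "High"))
        if (length(unique(grp)) < 2)
            stop("both-high rule yields a single group")
        names(grp) <- surv$sample
    }
    hi <- surv[grp == "High", , drop = FALSE]
    lo <- surv[grp == "Low", , drop = FALSE]
    lr <- logrankTest(hi, lo)
    list(high = kmEstimate(hi, "High"), low = kmEstimate(lo, "Low"),
         chisq = lr$chisq, p = lr$p, groups = grp)
}
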