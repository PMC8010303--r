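## Per-protein random-intercept linear mixed models for longitudinal
## screening: y_it = b0 + b_i + b1 * t_it + e_it, b_i ~ N(0, sigma_b^2),
## fitted by REML (nlme), with the inner-outer denominator df
## n_obs - n_subjects - 1 for the within-subject time slope.

#' Fit a random-intercept, fixed-slope mixed model to one protein
#'
#' Subjects contributing fewer than 2 observations are excluded before
#' fitting. The model is estimated by REML via [nlme::lme()]; in the
#' degenerate near-zero-residual case where the REML fit fails, a
#' fixed-effects fallback (OLS with subject indicator variables, which
#' shares the same slope estimator as the mixed model when the residual
#' variance vanishes) is used and flagged in the result. The slope's
#' denominator df is `n_obs - n_subjects - 1`; p is two-sided from the t
#' distribution.
#'
#' @param values numeric vector of log abundances (NA allowed: dropped).
#' @param times months from baseline per observation.
#' @param subjects subject identifier per observation.
#' @return list of class `LmmFit`: `n_obs`, `n_subjects`, `intercept`,
#'   `slope`, `slope_se`, `sigma_b2`, `sigma2`, `df`, `t`, `p`, `method`
#'   (`"reml"` or `"ols_fallback"`).
#' @export
fitProteinLmm <- function(values, times, subjects) {
    keep <- !is.na(values) & !is.na(times)
    d <- data.frame(y = values[keep], t = times[keep],
                    subject = factor(subjects[keep]))
    tab <- table(d$subject)
    d <- d[d$subject %in% names(tab)[tab >= 2L], ]
    d$subject <- droplevels(d$subject)
    nSubj <- nlevels(d$subject)
    if (nSubj < 2L)
        stop("need at least 2 subjects with >= 2 observations each")
    withinVar <- vapply(split(d$t, d$subject), stats::var, 0)
    if (all(withinVar == 0))
        stop("no within-subject time variation; slope not identifiable")
    nObs <- nrow(d)
    df <- nObs - nSubj - 1L
    fit <- tryCatch({
        m <- nlme::lme(y ~ t, random = ~ 1 | subject, data = d,
                       method = "REML")
        vc <- nlme::VarCorr(m)
        tt <- summary(m)$tTable
        list(intercept = unname(nlme::fixef(m)[1L]),
             slope = unname(nlme::fixef(m)[2L]),
             slope_se = unname(tt["t", "Std.Error"]),
             sigma_b2 = as.numeric(vc["(Intercept)", "Variance"]),
             sigma2 = m$sigma^2, method = "reml")
    }, error = function(e) NULL)
    if (is.null(fit)) {
        ## the zero-residual limit: lm warns about a perfect fit, which is
        ## exactly the regime this fallback serves
        m <- stats::lm(y ~ t + subject, data = d)
        cf <- suppressWarnings(summary(m))$coefficients
        subjEff <- stats::coef(m)[-(1:2)]
        fit <- list(intercept = unname(stats::coef(m)[1L]),
                    slope = unname(cf["t", "Estimate"]),
                    slope_se = unname(cf["t", "Std. Error"]),
                    sigma_b2 = if (length(subjEff) > 1L)
                        stats::var(c(0, unname(subjEff))) else 0,
                    sigma2 = suppressWarnings(summary(m))$sigma^2,
                    method = "ols_fallback")
    }
    tStat <- fit$slope / fit$slope_se
    structure(c(list(n_obs = nObs, n_subjects = nSubj), fit,
                list(df = df, t = tStat,
                     p = 2 * stats::pt(-abs(tStat), df))),
              class = "LmmFit")
}

#' Screen all proteins for longitudinal abundance change
#'
#' Observations are restricted to subjects with at least `minVisits`
#' distinct visits in the metadata; each protein with at least
#' `minSubjects` contributing subjects (>= 2 observed values each) is fitted
#' with [fitProteinLmm()]; slope p-values are BH-adjusted across fitted
#' proteins and each protein is classified `increasing` / `decreasing`
#' (sign of the slope when adjusted p < `alpha`) or `null`.
#'
#' @param x a log-scale [ProteinAbundance-class].
#' @param sampleInfo validated metadata (see [readSampleInfo()]); defaults
#'   to `colData(x)`.
#' @param alpha BH threshold (default 0.1).
#' @param minSubjects minimum subjects with >= 2 observed values per protein
#'   (default 5).
#' @param minVisits minimum visits for a subject to enter (default 2).
#' @return data.frame, one row per fitted protein, with the `LmmFit`
#'   fields plus `p_adj` and `direction`; skipped proteins are counted in
#'   the `"skipped"` attribute.
#' @export
longitudinalScreen <- function(x, sampleInfo = NULL, alpha = 0.1,
                               minSubjects = 5L, minVisits = 2L) {
    stopifnot(is(x, "ProteinAbundance"))
    if (abundanceScale(x) != "log")
        stop("longitudinalScreen expects log-scale values")
    if (is.null(sampleInfo))
        sampleInfo <- as.data.frame(colData(x))
    info <- sampleInfo[match(sampleIds(x), sampleInfo$sample_id), ]
    visits <- table(info$subject_id)
    lonSubjects <- names(visits)[visits >= minVisits]
    use <- info$subject_id %in% lonSubjects
    if (sum(use) < 4L) stop("no longitudinal samples available")
    v <- abundanceValues(x)[, use, drop = FALSE]
    times <- info$months_from_baseline[use]
    subjects <- info$subject_id[use]
    rows <- vector("list", nrow(v))
    skipped <- 0L
    for (i in seq_len(nrow(v))) {
        yi <- v[i, ]
        obsSubj <- table(subjects[!is.na(yi)])
        if (sum(obsSubj >= 2L) < minSubjects) { skipped <- skipped + 1L; next }
        fit <- tryCatch(fitProteinLmm(yi, times, subjects),
                        error = function(e) NULL)
        if (is.null(fit)) { skipped <- skipped + 1L; next }
        rows[[i]] <- data.frame(protein_id = rownames(v)[i],
                                n_obs = fit$n_obs,
                                n_subjects = fit$n_subjects,
                                intercept = fit$intercept,
                                slope = fit$slope, slope_se = fit$slope_se,
                                sigma_b2 = fit$sigma_b2, sigma2 = fit$sigma2,
                                df = fit$df, t = fit$t, p = fit$p,
                                method = fit$method, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
    if (is.null(out) || nrow(out) == 0L) stop("no protein could be fitted")
    out$p_adj <- bhAdjust(out$p)
    out$direction <- ifelse(out$p_adj < alpha,
                            ifelse(out$slope > 0, "increasing", "decreasing"),
                            "null")
    rownames(out) <- NULL
    attr(out, "skipped") <- skipped
    out
}
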