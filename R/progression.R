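#' Dominant-pattern assignment with an "unassigned" floor
#'
#' A scan is assigned to its argmax pattern only when that pattern's
#' probability STRICTLY exceeds the threshold (default 0.5); otherwise it
#' is "unassigned" and excluded from survival analyses. Exact argmax ties
#' go to the lowest pattern index.
#'
#' @param probs n x M probability matrix (rows on the simplex).
#' @param threshold strict probability cutoff, default 0.5. A threshold
#'   outside (1/M, 1] triggers a warning (below 1/M several patterns could
#'   qualify; argmax resolves that, but the setting is suspicious).
#' @return factor with levels \code{P1..PM, unassigned}.
#' @export
assignDominantPattern <- function(probs, threshold = 0.5) {
  probs <- as.matrix(probs)
  M <- ncol(probs)
  if (any(abs(rowSums(probs) - 1) > 1e-6) || any(probs < -1e-9))
    stop("probability rows must lie on the simplex")
  if (threshold <= 1 / M || threshold > 1)
    warning("threshold outside (1/M, 1]: multiple patterns could exceed it")
  idx <- patternLabels(probs)
  top <- probs[cbind(seq_len(nrow(probs)), idx)]
  lv <- c(paste0("P", seq_len(M)), "unassigned")
  factor(ifelse(top > threshold, paste0("P", idx), "unassigned"), levels = lv)
}

#' Build a pattern-conversion event table from longitudinal probabilities
#'
#' For every subject whose baseline (first visit) expresses the source
#' pattern above \code{baselineThreshold}, the event is the FIRST visit at
#' which any target pattern's probability strictly exceeds
#' \code{threshold}; competing targets are recorded as distinct event
#' types. Subjects never converting are censored at their last visit.
#' Event times are years from baseline; between-visit times are not
#' interpolated.
#'
#' @param probs long data.frame with columns \code{participant_id},
#'   \code{visit_time} and pattern probability columns \code{P1..PM} (e.g.
#'   from [stageProbabilities()] or from [predictProbabilities()] output
#'   bound to visit metadata).
#' @param source source pattern name (default \code{"P1"}).
#' @param targets target pattern names (default \code{c("P2", "P3")}).
#' @param threshold conversion threshold (strict; default 0.5).
#' @param baselineThreshold baseline source-pattern filter (strict; default
#'   0.7, the published choice for analyses originating from the preserved
#'   pattern).
#' @return data.frame of class additionally \code{"patternEventTable"}:
#'   \code{participant_id}, \code{time}, \code{event} (factor, levels
#'   censored + targets), \code{status} (0 censored, else index into
#'   \code{targets}), and baseline risk features
#'   \code{baseline_<target>}.
#' @export
buildPatternEventTable <- function(probs, source = "P1",
                                   targets = c("P2", "P3"),
                                   threshold = 0.5, baselineThreshold = 0.7) {
  need <- c("participant_id", "visit_time", source, targets)
  miss <- setdiff(need, colnames(probs))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  out <- list()
  for (id in unique(probs$participant_id)) {
    px <- probs[probs$participant_id == id, , drop = FALSE]
    if (nrow(px) < 2L) next
    if (is.unsorted(px$visit_time, strictly = FALSE))
      stop("visit times are unordered for participant ", id)
    if (px[[source]][1] <= baselineThreshold) next
    t0 <- px$visit_time[1]
    tm <- as.matrix(px[, targets, drop = FALSE])
    hit <- which(apply(tm > threshold, 1, any))
    if (length(hit)) {
      v <- hit[1]
      ev <- which.max(tm[v, ])     # strongest target; ties -> lowest index
      rec <- data.frame(participant_id = id, time = px$visit_time[v] - t0,
                        event = targets[ev], status = as.integer(ev))
    } else {
      rec <- data.frame(participant_id = id,
                        time = px$visit_time[nrow(px)] - t0,
                        event = "censored", status = 0L)
    }
    for (tg in targets) rec[[paste0("baseline_", tg)]] <- px[[tg]][1]
    out[[length(out) + 1L]] <- rec
  }
  if (!length(out)) stop("no subject passed the baseline filter")
  res <- do.call(rbind, out)
  res$event <- factor(res$event, levels = c("censored", targets))
  class(res) <- c("patternEventTable", class(res))
  res
}

#' Kaplan-Meier survival curve (product-limit, Greenwood band)
#'
#' Thin wrapper over \code{survival::survfit} treating any non-censored
#' event type as the event. With all subjects censored the curve is
#' identically 1 and a warning is emitted.
#'
#' @param events an event table from [buildPatternEventTable()] or any
#'   data.frame with \code{time} and \code{status} (0 = censored).
#' @param group optional factor for stratified curves.
#' @param conf confidence level of the Greenwood band (default 0.95).
#' @return data.frame: \code{time, nRisk, nEvent, surv, lower, upper}
#'   (+ \code{group}); the \code{survfit} object as attribute
#'   \code{"fit"}.
#' @export
kaplanMeier <- function(events, group = NULL, conf = 0.95) {
  st <- as.integer(events$status > 0)
  if (all(st == 0)) warning("all subjects censored: S(t) = 1 everywhere")
  df <- data.frame(time = events$time, status = st)
  if (is.null(group)) {
    fit <- survival::survfit(survival::Surv(time, status) ~ 1, data = df,
                             conf.int = conf)
    out <- data.frame(time = fit$time, nRisk = fit$n.risk,
                      nEvent = fit$n.event, surv = fit$surv,
                      lower = fit$lower, upper = fit$upper)
  } else {
    df$group <- group
    fit <- survival::survfit(survival::Surv(time, status) ~ group, data = df,
                             conf.int = conf)
    out <- data.frame(time = fit$time, nRisk = fit$n.risk,
                      nEvent = fit$n.event, surv = fit$surv,
                      lower = fit$lower, upper = fit$upper,
                      group = rep(sub("^group=", "", names(fit$strata)),
                                  fit$strata))
  }
  attr(out, "fit") <- fit
  out
}

#' Log-rank test between groups
#'
#' @inheritParams kaplanMeier
#' @param group grouping factor (required).
#' @return list with \code{chisq}, \code{df}, \code{p}.
#' @export
logRankTest <- function(events, group) {
  df <- data.frame(time = events$time, status = as.integer(events$status > 0),
                   group = group)
  sd <- survival::survdiff(survival::Surv(time, status) ~ group, data = df)
  dfree <- length(sd$n) - 1
  list(chisq = sd$chisq, df = dfree,
       p = stats::pchisq(sd$chisq, dfree, lower.tail = FALSE))
}

#' Aalen-Johansen cumulative incidence under competing risks
#'
#' Cause-specific cumulative incidence curves for competing event types
#' (e.g. conversion to P2 versus P3 from the preserved pattern), via the
#' multi-state Aalen-Johansen estimator. At every time the cause
#' incidences plus the event-free probability sum to 1; with a single
#' event type and no competing events the incidence equals 1 minus the
#' Kaplan-Meier curve.
#'
#' @param events an event table with \code{time} and factor \code{event}
#'   whose FIRST level is the censoring code.
#' @return data.frame: \code{time}, one incidence column per event type,
#'   and \code{eventFree}; the multi-state \code{survfit} as attribute
#'   \code{"fit"}.
#' @export
cumulativeIncidence <- function(events) {
  ev <- events$event
  if (!is.factor(ev)) ev <- factor(ev)
  df <- data.frame(time = events$time, ev = ev)
  fit <- survival::survfit(survival::Surv(time, ev) ~ 1, data = df,
                           conf.type = "none")
  states <- fit$states
  inc <- fit$pstate
  colnames(inc) <- ifelse(states == "(s0)", "eventFree", states)
  out <- data.frame(time = fit$time, inc, check.names = FALSE)
  attr(out, "fit") <- fit
  out
}

#' Harrell's concordance index
#'
#' Fraction of comparable pairs ordered correctly by the risk score. A
#' pair is comparable when the earlier subject had an observed event and
#' the other subject's time is strictly longer; higher risk should go with
#' the shorter time. Ties in risk count 0.5. Refuses when no pair is
#' comparable.
#'
#' @param risk numeric per-subject risk scores (higher = earlier event).
#' @param time event/censoring times.
#' @param status 1 (or any positive integer) = event, 0 = censored.
#' @return numeric in [0, 1].
#' @export
concordanceIndex <- function(risk, time, status) {
  stopifnot(length(risk) == length(time), length(time) == length(status))
  status <- as.integer(status > 0)
  conc <- 0; n <- 0
  for (i in which(status == 1L)) {
    j <- which(time > time[i])
    if (!length(j)) next
    n <- n + length(j)
    conc <- conc + sum(risk[i] > risk[j]) + 0.5 * sum(risk[i] == risk[j])
  }
  if (n == 0) stop("no comparable pairs: concordance undefined")
  conc / n
}

#' Repeated two-fold cross-validated Cox concordance
#'
#' The published protocol for judging a feature set's predictive ability:
#' per repeat, subjects are split at random into two halves; a Cox
#' proportional-hazards model (delegated to \code{survival::coxph}) is
#' fitted on one half and its linear predictor — the partial hazard, used
#' as the composite risk score — is evaluated on the other half via
#' Harrell's C. Both fold directions are used, so \code{nRepeats} repeats
#' yield \code{2 nRepeats} validation C values.
#'
#' @param features numeric matrix or data.frame of baseline features.
#' @param time,status survival outcome (0 = censored).
#' @param nRepeats number of repeats (published protocol: 100).
#' @param seed integer seed for the splits.
#' @return list with \code{cindex} (vector, NA for non-convergent fits),
#'   \code{mean}, \code{sd}.
#' @export
repeatedCVCoxCindex <- function(features, time, status, nRepeats = 100L,
                                seed = 1L) {
  X <- as.matrix(features)
  n <- nrow(X)
  stopifnot(length(time) == n, length(status) == n)
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  cidx <- numeric(0)
  for (r in seq_len(nRepeats)) {
    idx <- .withSeed(seed + r, sample.int(n))
    half <- list(idx[seq_len(floor(n / 2))], idx[(floor(n / 2) + 1):n])
    for (h in 1:2) {
      tr <- half[[h]]; va <- half[[3 - h]]
      cc <- tryCatch({
        dtr <- data.frame(time = time[tr], status = as.integer(status[tr] > 0),
                          X[tr, , drop = FALSE])
        fit <- survival::coxph(
          survival::Surv(time, status) ~ ., data = dtr,
          control = survival::coxph.control(iter.max = 50))
        lp <- as.numeric(X[va, , drop = FALSE] %*% stats::coef(fit))
        concordanceIndex(lp, time[va], status[va])
      }, error = function(e) NA_real_, warning = function(w) {
        # retry once accepting the warning (e.g. slow convergence)
        tryCatch({
          dtr <- data.frame(time = time[tr],
                            status = as.integer(status[tr] > 0),
                            X[tr, , drop = FALSE])
          fit <- suppressWarnings(survival::coxph(
            survival::Surv(time, status) ~ ., data = dtr,
            control = survival::coxph.control(iter.max = 50)))
          lp <- as.numeric(X[va, , drop = FALSE] %*% stats::coef(fit))
          concordanceIndex(lp, time[va], status[va])
        }, error = function(e) NA_real_)
      })
      cidx <- c(cidx, cc)
    }
  }
  if (anyNA(cidx)) message(sum(is.na(cidx)), " fold(s) failed to converge")
  list(cindex = cidx, mean = mean(cidx, na.rm = TRUE),
       sd = stats::sd(cidx, na.rm = TRUE))
}

#' Horizon discrimination by a baseline probability
#'
#' For each horizon X the binary outcome is "converted before X"; subjects
#' censored before X without an event are excluded at that horizon. The
#' baseline score is used directly, without fitting any model: reported
#' are the AUC (Mann-Whitney, mid-ranks for ties) and the optimal
#' discrimination threshold at which TPR + FPR = 1 (sensitivity =
#' specificity), located by linear interpolation on the ROC. A horizon
#' with no positives or no negatives is reported as missing.
#'
#' @param score per-subject baseline score (e.g. baseline P2 probability).
#' @param time,status survival outcome (0 = censored).
#' @param horizons positive years.
#' @return data.frame: \code{horizon, nPos, nNeg, auc, threshold,
#'   tprPlusFpr} (the achieved TPR + FPR at the returned threshold).
#' @export
horizonDiscrimination <- function(score, time, status, horizons) {
  stopifnot(all(horizons > 0))
  status <- as.integer(status > 0)
  out <- lapply(horizons, function(X) {
    pos <- status == 1L & time <= X
    neg <- time > X
    keep <- pos | neg
    y <- pos[keep]; s <- score[keep]
    nP <- sum(y); nN <- sum(!y)
    if (nP == 0 || nN == 0)
      return(data.frame(horizon = X, nPos = nP, nNeg = nN, auc = NA_real_,
                        threshold = NA_real_, tprPlusFpr = NA_real_))
    r <- rank(s)
    auc <- (sum(r[y]) - nP * (nP + 1) / 2) / (nP * nN)
    th <- .sensEqSpecThreshold(s, y)
    data.frame(horizon = X, nPos = nP, nNeg = nN, auc = auc,
               threshold = th$threshold, tprPlusFpr = th$tpr + th$fpr)
  })
  do.call(rbind, out)
}

# threshold where sensitivity = specificity, by linear interpolation over
# candidate cutoffs (classify positive when score >= cutoff)
.sensEqSpecThreshold <- function(score, y) {
  cuts <- sort(unique(score))
  cuts <- c(cuts, max(cuts) + 1)           # all-negative endpoint
  sens <- vapply(cuts, function(c) mean(score[y] >= c), numeric(1))
  spec <- vapply(cuts, function(c) mean(score[!y] < c), numeric(1))
  d <- sens - spec                          # non-increasing in the cutoff
  k <- which(d <= 0)[1]
  if (is.na(k)) k <- length(cuts)
  if (k == 1L || d[k] == 0)
    return(list(threshold = cuts[k], tpr = sens[k], fpr = 1 - spec[k]))
  w <- d[k - 1] / (d[k - 1] - d[k])
  list(threshold = (1 - w) * cuts[k - 1] + w * cuts[k],
       tpr = (1 - w) * sens[k - 1] + w * sens[k],
       fpr = 1 - ((1 - w) * spec[k - 1] + w * spec[k]))
}
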