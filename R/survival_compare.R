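#' Kaplan-Meier product-limit estimate
#'
#' Computes the product-limit survival curve
#' `S(t) = prod over event times t_i <= t of (1 - d_i / n_i)`, where d_i is
#' the number of events and n_i the number at risk at t_i.  Subjects
#' censored at an event time are counted at risk for that time (events
#' precede censorings at ties, the standard convention).
#'
#' @param time Follow-up times (days >= 0).
#' @param event 1 = event, 0 = censored.
#' @return A `km_curve` data frame with one row per distinct event time:
#'   `time`, `n_risk`, `n_event`, `n_censor` (censorings since the
#'   previous event time), and `surv`.
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) == length(event), length(time) >= 1)
  if (any(time < 0)) stop("negative follow-up time")
  event <- as.integer(event)
  stopifnot(all(event %in% 0:1))
  et <- sort(unique(time[event == 1]))
  n_risk <- vapply(et, function(t) sum(time >= t), 0L)
  n_event <- vapply(et, function(t) sum(time == t & event == 1), 0L)
  surv <- cumprod(1 - n_event / n_risk)
  n_censor <- vapply(seq_along(et), function(i) {
    lo <- if (i == 1) -Inf else et[i - 1]
    sum(time >= lo & time < et[i] & event == 0) +
      sum(time == et[i] & event == 0)
  }, 0L)
  structure(data.frame(time = et, n_risk = n_risk, n_event = n_event,
                       n_censor = n_censor, surv = surv),
            class = c("km_curve", "data.frame"))
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' @param curve A [km_estimate()] result.
#' @param times Times at which to read off the step function.
#' @return Survival probabilities (1 before the first event).
#' @export
km_survival_at <- function(curve, times) {
  vapply(times, function(t) {
    i <- which(curve$time <= t)
    if (!length(i)) 1 else curve$surv[max(i)]
  }, 0)
}

#' Log-rank test
#'
#' Observed-vs-expected event counts with hypergeometric variance.  At
#' each distinct event time t with d total events among n at risk, group j
#' contributes expected events `d * n_j / n` and the variance-covariance
#' `V_jl = d (n - d) / (n - 1) * (n_j / n) (delta_jl - n_l / n)`.  For two
#' groups the statistic is `(sum(O - E))^2 / sum(V)`; for K groups it is
#' the quadratic form `z' V^- z` over K-1 groups.  The p-value refers the
#' statistic to chi-square with K-1 degrees of freedom.
#'
#' @param time Follow-up times.
#' @param event 1 = event, 0 = censored.
#' @param group Group labels (>= 2 groups, >= 1 event overall).
#' @return A `logrank_result`: `statistic`, `df`, `p_value`, `observed`
#'   and `expected` per group.
#' @export
logrank_test <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  if (any(time < 0)) stop("negative follow-up time")
  event <- as.integer(event)
  g <- factor(group)
  k <- nlevels(g)
  if (k < 2) stop("log-rank test needs at least 2 groups")
  if (sum(event) == 0) stop("degenerate input: no events observed")
  et <- sort(unique(time[event == 1]))
  obs <- exp_ <- stats::setNames(numeric(k), levels(g))
  v <- matrix(0, k, k)
  for (t in et) {
    at <- time >= t
    n <- sum(at)
    nj <- tabulate(g[at], nbins = k)
    dj <- tabulate(g[time == t & event == 1], nbins = k)
    d <- sum(dj)
    obs <- obs + dj
    exp_ <- exp_ + d * nj / n
    if (n > 1) {
      p <- nj / n
      v <- v + d * (n - d) / (n - 1) * (diag(p, k) - tcrossprod(p))
    }
  }
  z <- (obs - exp_)[-k]
  vs <- v[-k, -k, drop = FALSE]
  stat <- tryCatch(drop(t(z) %*% solve(vs, z)), error = function(e) {
    sv <- svd(vs)
    pos <- sv$d > max(sv$d) * 1e-12
    drop(t(z) %*% sv$v[, pos, drop = FALSE] %*%
           ((t(sv$u[, pos, drop = FALSE]) %*% z) / sv$d[pos]))
  })
  structure(list(statistic = stat, df = k - 1L,
                 p_value = stats::pchisq(stat, k - 1L, lower.tail = FALSE),
                 observed = obs, expected = exp_,
                 n = as.integer(table(g))),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("log-rank test: chi-square = %.4f on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Compare the prognostic separation of two call sources
#'
#' Runs one log-rank test per call source, each restricted to its own
#' subject set: reference calls (e.g. pathologist consensus) on subject
#' set A and model-produced calls on a disjoint subject set B.  This is
#' the design for asking whether model calls stratify survival as well as
#' the reference calls without sharing any subjects between the two
#' analyses.
#'
#' @param records Data frame with `sample_id`, `time` (or
#'   `survival_days`), and `event` covering all subjects in both sets.
#' @param calls_ref Named vector: group call per subject of set A (names
#'   are sample ids).
#' @param calls_model Named vector: group call per subject of set B; B
#'   must be disjoint from A.
#' @return A `call_source_comparison`: per source, the `logrank_result`
#'   and group sizes.
#' @export
compare_call_sources <- function(records, calls_ref, calls_model) {
  tcol <- if ("time" %in% names(records)) "time" else "survival_days"
  stopifnot(all(c("sample_id", tcol, "event") %in% names(records)))
  ids_a <- names(calls_ref); ids_b <- names(calls_model)
  if (is.null(ids_a) || is.null(ids_b))
    stop("calls must be named by sample id")
  overlap <- intersect(ids_a, ids_b)
  if (length(overlap))
    stop("design error: subject sets overlap (e.g. ",
         utils::head(overlap, 1), "); call sources must be compared on ",
         "disjoint subject sets")
  one <- function(calls, ids, source) {
    i <- match(ids, records$sample_id)
    if (anyNA(i))
      stop("subject(s) missing from records: ",
           paste(utils::head(ids[is.na(i)], 5), collapse = ", "))
    grp <- calls[ids]
    if (length(unique(grp)) < 2)
      stop("call source '", source, "' has fewer than 2 groups")
    list(test = logrank_test(records[[tcol]][i], records$event[i], grp),
         group_sizes = table(grp), n = length(ids))
  }
  structure(list(reference = one(calls_ref, ids_a, "reference"),
                 model = one(calls_model, ids_b, "model")),
            class = "call_source_comparison")
}

#' @export
print.call_source_comparison <- function(x, ...) {
  cat(sprintf("reference calls (n = %d): chi-square = %.3f, p = %.4g\n",
              x$reference$n, x$reference$test$statistic,
              x$reference$test$p_value))
  cat(sprintf("model calls     (n = %d): chi-square = %.3f, p = %.4g\n",
              x$model$n, x$model$test$statistic, x$model$test$p_value))
  invisible(x)
}
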