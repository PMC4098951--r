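#' Kaplan-Meier survival estimates
#'
#' Product-limit estimates per group, with at-risk bookkeeping and an
#' optional restriction horizon (e.g. 5-year analyses: follow-up beyond the
#' horizon is administratively censored at it).
#'
#' @param records Tibble with columns `time` (positive) and `event` (0/1),
#'   one row per patient.
#' @param group Optional name of a grouping column in `records`.
#' @param horizon Optional positive restriction horizon in the cohort's time
#'   unit.
#' @return A `km_fit` tibble: `group`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `estimate`, `std_error`, `conf_low`, `conf_high`.
#' @export
#' @examples
#' rec <- tibble::tibble(time = c(2, 4, 6, 8), event = c(1, 1, 0, 1))
#' km_estimate(rec)
km_estimate <- function(records, group = NULL, horizon = NULL) {
  records <- restrict_horizon(records, horizon)
  check_survival_records(records)
  if (is.null(group)) {
    g <- factor(rep("all", nrow(records)))
  } else {
    g <- records[[group]]
    if (!is.factor(g)) g <- factor(g)
    empty <- levels(g)[tabulate(g, nbins = nlevels(g)) == 0]
    if (length(empty)) {
      abort(paste0("Empty group(s): ", paste(empty, collapse = ", "), "."),
            class = "budquant_survival_error")
    }
  }
  fit <- survival::survfit(survival::Surv(records$time, records$event) ~ g,
                           conf.type = "log")
  s <- summary(fit, censored = TRUE)
  grp <- if (is.null(s$strata)) rep(levels(g)[1], length(s$time)) else
    sub("^g=", "", as.character(s$strata))
  out <- tibble::tibble(
    group = grp, time = s$time, n_risk = s$n.risk, n_event = s$n.event,
    n_censor = s$n.censor, estimate = s$surv, std_error = s$std.err,
    conf_low = s$lower, conf_high = s$upper
  )
  class(out) <- c("km_fit", class(out))
  attr(out, "horizon") <- horizon
  out
}

#' Log-rank (Mantel-Cox) test between two groups
#'
#' @param records Tibble with `time`, `event` and the grouping column.
#' @param group Name of the grouping column (exactly two non-empty groups).
#' @param horizon Optional restriction horizon.
#' @return A one-row tibble: `statistic` (chi-square, 1 df), `df`, `p_value`.
#' @export
logrank_test <- function(records, group = "group", horizon = NULL) {
  records <- restrict_horizon(records, horizon)
  check_survival_records(records)
  g <- factor(records[[group]])
  g <- droplevels(g)
  if (nlevels(g) < 2) {
    abort("logrank_test requires two groups.", class = "budquant_survival_error")
  }
  if (sum(records$event) < 1) {
    abort("At least one event is required.", class = "budquant_survival_error")
  }
  sd <- survival::survdiff(survival::Surv(records$time, records$event) ~ g)
  df <- length(sd$n) - 1
  tibble::tibble(statistic = sd$chisq, df = df,
                 p_value = pchisq(sd$chisq, df, lower.tail = FALSE))
}

# Vectorised log-rank statistic for every admissible threshold of a
# continuous variable.  For each candidate cut (midpoints of consecutive
# distinct values, both groups at least ceiling(min_group_frac * n)), the
# two-group Mantel-Cox chi-square is computed from cumulative at-risk /
# event matrices over patients sorted by the variable, so one scan costs
# O(T * n) rather than one survdiff call per candidate.
logrank_scan <- function(values, time, event, min_group_frac = 0.1) {
  prep <- logrank_scan_prepare(values, time, event, min_group_frac)
  res <- logrank_scan_exec(prep, values)
  tibble::tibble(cutoff = prep$cuts, n_above = prep$m,
                 statistic = res$statistic, p_value = res$p_value)
}

# Precompute everything that depends only on the survival records and the
# multiset of values: candidate cuts, group sizes, at-risk / event matrices
# over distinct event times, and the cumulative-membership indicator.  A
# permutation of the values changes only the patient order, so one prepare
# serves the whole Monte Carlo correction.
logrank_scan_prepare <- function(values, time, event, min_group_frac) {
  n <- length(values)
  v_distinct <- sort(unique(values))
  if (length(v_distinct) < 2) {
    abort("values must not be constant.", class = "budquant_survival_error")
  }
  cuts <- (v_distinct[-length(v_distinct)] + v_distinct[-1]) / 2
  v_sorted <- sort(values, decreasing = TRUE)
  m <- vapply(cuts, function(cc) sum(v_sorted > cc), integer(1))
  floor_n <- ceiling(min_group_frac * n)
  keep <- m >= floor_n & (n - m) >= floor_n
  cuts <- cuts[keep]; m <- m[keep]
  if (!length(cuts)) {
    abort("No admissible cut-point satisfies the group-size floor.",
          class = "budquant_survival_error")
  }
  tau <- sort(unique(time[event == 1]))
  A <- outer(tau, time, function(a, b) as.numeric(b >= a))
  D <- outer(tau, time, function(a, b) as.numeric(b == a)) *
    matrix(event, length(tau), n, byrow = TRUE)
  n_i <- rowSums(A); d_i <- rowSums(D)
  # membership matrix: column j marks the first m_j (value-sorted) patients
  M <- outer(seq_len(n), m, function(i, mm) as.numeric(i <= mm))
  list(cuts = cuts, m = m, A = A, D = D, n_i = n_i, d_i = d_i,
       vw = ifelse(n_i > 1, d_i * (n_i - d_i) / (n_i - 1), 0),
       M = M, n = n)
}

logrank_scan_exec <- function(prep, values) {
  ord <- order(values, decreasing = TRUE)
  N1 <- prep$A[, ord, drop = FALSE] %*% prep$M
  D1 <- prep$D[, ord, drop = FALSE] %*% prep$M
  O1 <- colSums(D1)
  E1 <- colSums(N1 * (prep$d_i / prep$n_i))
  f1 <- N1 / prep$n_i
  V <- colSums(f1 * (1 - f1) * prep$vw)
  stat <- ifelse(V > 0, (O1 - E1)^2 / V, 0)
  p <- ifelse(V > 0, pchisq(stat, 1, lower.tail = FALSE), 1)
  list(statistic = stat, p_value = p)
}

#' Find the minimum-p-value survival cut-point of a variable
#'
#' Scans every admissible threshold of the variable (midpoints between
#' consecutive distinct values, excluding splits leaving fewer than
#' `min_group_frac` of patients on either side), computes the two-group
#' log-rank statistic of above-versus-below at each, and returns the
#' threshold maximising the statistic (ties broken towards the smaller
#' cut-off). The minimum raw p-value is optimistically biased by the search;
#' correct it with [monte_carlo_corrected_p()].
#'
#' An optional split-sample mode derives the cut-off on a random half of the
#' cohort and evaluates its p-value on the other half.
#'
#' @param records Tibble with the feature column plus `time` and `event`.
#' @param variable Name of the feature column (non-constant, >= 10 patients).
#' @param min_group_frac Minimum fraction of patients on each side of an
#'   admissible split.
#' @param method `"minp"` (default) or `"split"`.
#' @param split_seed Seed for the split-sample halves.
#' @param horizon Optional restriction horizon.
#' @return A `cutpoint_result`: `variable`, `cutoff`, `statistic`, `raw_p`,
#'   `corrected_p` (`NA` until corrected), `n_monte_carlo`, `n`, and the
#'   full `scan` table (candidate cut-off, group size, statistic, p).
#' @export
find_optimal_cutpoint <- function(records, variable, min_group_frac = 0.1,
                                  method = c("minp", "split"),
                                  split_seed = 1L, horizon = NULL) {
  method <- match.arg(method)
  records <- restrict_horizon(records, horizon)
  check_survival_records(records)
  x <- records[[variable]]
  if (is.null(x)) {
    abort(paste0("No column '", variable, "' in records."),
          class = "budquant_survival_error")
  }
  if (length(x) < 10) {
    abort("At least 10 patients are required.",
          class = "budquant_survival_error")
  }
  if (length(unique(x)) < 2) {
    abort("values must not be constant.", class = "budquant_survival_error")
  }
  if (method == "split") {
    return(split_sample_cutpoint(records, variable, min_group_frac,
                                 split_seed))
  }
  scan <- logrank_scan(x, records$time, records$event, min_group_frac)
  best <- which(scan$statistic == max(scan$statistic))
  best <- best[which.min(scan$cutoff[best])]
  structure(
    list(variable = variable, cutoff = scan$cutoff[best],
         statistic = scan$statistic[best], raw_p = scan$p_value[best],
         corrected_p = NA_real_, n_monte_carlo = NA_integer_,
         n = length(x), min_group_frac = min_group_frac,
         method = "minp", scan = scan),
    class = "cutpoint_result"
  )
}

split_sample_cutpoint <- function(records, variable, min_group_frac, seed) {
  n <- nrow(records)
  with_seed(seed, {
    train <- sample.int(n, floor(n / 2))
    sc <- logrank_scan(records[[variable]][train], records$time[train],
                       records$event[train], min_group_frac)
    best <- which(sc$statistic == max(sc$statistic))
    best <- best[which.min(sc$cutoff[best])]
    cutoff <- sc$cutoff[best]
    test <- records[-train, , drop = FALSE]
    test$group <- factor(ifelse(test[[variable]] > cutoff, "above", "below"),
                         levels = c("below", "above"))
    lr <- if (nlevels(droplevels(test$group)) == 2 && sum(test$event) >= 1) {
      logrank_test(test, "group")
    } else {
      tibble::tibble(statistic = NA_real_, df = NA, p_value = NA_real_)
    }
    structure(
      list(variable = variable, cutoff = cutoff,
           statistic = lr$statistic, raw_p = lr$p_value,
           corrected_p = NA_real_, n_monte_carlo = NA_integer_,
           n = n, min_group_frac = min_group_frac,
           method = "split", scan = sc),
      class = "cutpoint_result"
    )
  })
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat("<cutpoint_result> ", x$variable, ": cutoff ", signif(x$cutoff, 4),
      ", chi-sq ", sprintf("%.2f", x$statistic),
      ", raw p ", format.pval(x$raw_p, digits = 3), sep = "")
  if (!is.na(x$corrected_p)) {
    cat(", corrected p ", format.pval(x$corrected_p, digits = 3),
        " (", x$n_monte_carlo, " permutations)", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Monte Carlo correction of the minimum-p cut-point
#'
#' The minimum p-value over a cut-point search is optimistically biased.
#' This permutation correction re-runs the full search on `n_sim` random
#' permutations of the feature against the survival records and reports
#' `(1 + #(simulated min-p <= observed min-p)) / (1 + n_sim)` -- the
#' Monte Carlo p-value of the observed search minimum under the null of no
#' feature-survival association.
#'
#' @param records Tibble with the feature plus `time` and `event`.
#' @param variable Feature column name.
#' @param n_sim Number of permutations (values under 100 warn: the
#'   correction is unstable).
#' @param seed Integer seed; the correction is deterministic given it.
#' @param min_group_frac,horizon As in [find_optimal_cutpoint()].
#' @param result Optional precomputed [find_optimal_cutpoint()] result for
#'   these records (avoids recomputing the observed scan).
#' @return The `cutpoint_result` with `corrected_p` and `n_monte_carlo`
#'   filled in.
#' @export
monte_carlo_corrected_p <- function(records, variable, n_sim = 1000L,
                                    seed = 1L, min_group_frac = 0.1,
                                    horizon = NULL, result = NULL) {
  if (n_sim < 100) {
    warn("n_sim < 100 permutations gives an unstable correction.")
  }
  records <- restrict_horizon(records, horizon)
  if (is.null(result)) {
    result <- find_optimal_cutpoint(records, variable,
                                    min_group_frac = min_group_frac)
  }
  obs_min_p <- min(result$scan$p_value)
  x <- records[[variable]]
  prep <- logrank_scan_prepare(x, records$time, records$event, min_group_frac)
  hits <- with_seed(seed, {
    vapply(seq_len(n_sim), function(i) {
      xp <- sample(x)
      min(logrank_scan_exec(prep, xp)$p_value) <= obs_min_p
    }, logical(1))
  })
  result$corrected_p <- (1 + sum(hits)) / (1 + n_sim)
  result$n_monte_carlo <- as.integer(n_sim)
  result
}

#' Cox proportional-hazards regression
#'
#' Univariate mode fits one model per term; multivariable mode fits all
#' terms jointly. Ties are handled by the Efron approximation. Hazard
#' ratios are `exp(coef)` with Wald 95% confidence intervals.
#'
#' @param records Tibble with `time`, `event` and the term columns.
#' @param terms Character vector of covariate column names.
#' @param type `"univariate"` or `"multivariable"`.
#' @param horizon Optional restriction horizon.
#' @return A `cox_result` tibble: `term`, `hr`, `conf_low`, `conf_high`,
#'   `p_value`, `n_events`, `model_type`, `separation_flag`.
#' @export
cox_regression <- function(records, terms,
                           type = c("univariate", "multivariable"),
                           horizon = NULL) {
  type <- match.arg(type)
  records <- restrict_horizon(records, horizon)
  check_survival_records(records)
  if (anyDuplicated(terms)) {
    abort("Duplicated covariates supplied (collinear by construction).",
          class = "budquant_survival_error")
  }
  for (tm in terms) {
    x <- records[[tm]]
    if (is.null(x)) {
      abort(paste0("No column '", tm, "' in records."),
            class = "budquant_survival_error")
    }
    if (length(unique(x[!is.na(x)])) < 2) {
      abort(paste0("Term '", tm, "' is constant."),
            class = "budquant_survival_error")
    }
  }
  n_events <- sum(records$event)
  term_sets <- if (type == "univariate") as.list(terms) else list(terms)
  rows <- lapply(term_sets, function(ts) {
    if (n_events < 5 * length(ts)) {
      warn(sprintf("Only %d events for %d term(s); estimates may be unstable.",
                   n_events, length(ts)))
    }
    fml <- stats::as.formula(paste(
      "survival::Surv(time, event) ~",
      paste(vapply(ts, function(t) paste0("`", t, "`"), character(1)),
            collapse = " + ")))
    converged <- TRUE
    fit <- withCallingHandlers(
      survival::coxph(fml, data = records, ties = "efron"),
      warning = function(w) {
        if (grepl("converge|infinite|beta may be infinite", conditionMessage(w))) {
          converged <<- FALSE
        }
        invokeRestart("muffleWarning")
      }
    )
    sm <- summary(fit)
    co <- sm$coefficients
    ci <- sm$conf.int
    sep_flag <- !converged | abs(co[, "coef"]) > 10
    if (!converged && any(abs(co[, "coef"]) > 20)) {
      abort(paste0("Cox model failed to converge for term(s) ",
                   paste(ts, collapse = ", "),
                   " (likely complete separation; max |coef| = ",
                   sprintf("%.1f", max(abs(co[, "coef"]))), ")."),
            class = "budquant_survival_error")
    }
    tibble::tibble(
      term = rownames(co),
      hr = unname(co[, "exp(coef)"]),
      conf_low = unname(ci[, "lower .95"]),
      conf_high = unname(ci[, "upper .95"]),
      p_value = unname(co[, "Pr(>|z|)"]),
      n_events = n_events,
      model_type = type,
      separation_flag = unname(sep_flag)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cox_result", class(out))
  out
}

#' Pearson correlation with Bonferroni adjustment
#'
#' Sample Pearson correlation with its two-sided p-value multiplied by the
#' number of tests in the family (capped at 1).
#'
#' @param x,y Paired numeric vectors (at least 3 finite pairs, both with
#'   positive variance).
#' @param n_tests Size of the test family.
#' @return A one-row tibble: `r`, `p_value`, `p_adjusted`, `n`, `n_tests`.
#' @export
pearson_bonferroni <- function(x, y, n_tests = 1L) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) {
    abort("At least 3 paired finite values are required.",
          class = "budquant_survival_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Zero variance in x or y.", class = "budquant_survival_error")
  }
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate),
                 p_value = ct$p.value,
                 p_adjusted = min(1, ct$p.value * n_tests),
                 n = length(x), n_tests = as.integer(n_tests))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values, monotone non-decreasing in rank order and
#' capped at 1.
#'
#' @param p_values Numeric vector of raw p-values in `(0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    abort("All p-values must lie in (0, 1].", class = "budquant_survival_error")
  }
  p.adjust(p_values, method = "BH")
}

restrict_horizon <- function(records, horizon) {
  if (is.null(horizon)) return(records)
  stopifnot(horizon > 0)
  over <- records$time > horizon
  records$event[over] <- 0L
  records$time[over] <- horizon
  records
}

check_survival_records <- function(records) {
  if (is.null(records$time) || is.null(records$event)) {
    abort("records must contain 'time' and 'event' columns.",
          class = "budquant_survival_error")
  }
  if (any(records$time <= 0)) {
    abort("All survival times must be positive.",
          class = "budquant_survival_error")
  }
  if (!all(records$event %in% c(0, 1))) {
    abort("event must be binary (0 = censored, 1 = event).",
          class = "budquant_survival_error")
  }
  invisible(records)
}
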