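# Design-based estimation for stratified multistage cluster samples.
# Point estimates are ratio-weighted means (combined sample x non-response
# x post-stratification weight); variance is by Taylor linearization with
# clusters as primary sampling units within strata (with-replacement
# approximation, no finite-population correction); confidence intervals
# use a t reference distribution with (#PSUs - #strata) degrees of freedom,
# by default on the logit scale so that intervals for rare outcomes stay
# inside [0, 1].

#' Design-based weighted prevalence with 95% confidence interval
#'
#' Estimates `p = sum(w * x) / sum(w)` over non-missing `x` (within the
#' optional domain), with Taylor-linearized variance under stratified
#' cluster sampling. Domain (subpopulation) estimation keeps every cluster
#' of the full design in the variance computation, as is standard.
#'
#' @param x Logical (or 0/1) outcome vector; `NA` values are excluded and
#'   counted in `n_missing`.
#' @param weight Strictly positive survey weights.
#' @param stratum,cluster Design identifiers per record. `NULL` means a
#'   single stratum / each record its own cluster (simple random sampling
#'   analogue).
#' @param domain Optional logical vector restricting the estimate to a
#'   subpopulation while retaining the full design for variance.
#' @param ci_method `"logit"` (default): symmetric t interval on the logit
#'   scale, back-transformed; `"wald"`: symmetric interval on the
#'   proportion scale, clamped to `[0, 1]`. Provided for comparability;
#'   Wald intervals for rare outcomes can cross zero before clamping.
#' @param conf_level Confidence level, default 0.95.
#' @return One-row data frame: `proportion`, `se`, `ci_low`, `ci_high`,
#'   `n_unweighted`, `n_missing`, `sum_weights`, `df`, `method`. If any
#'   stratum has fewer than two clusters the variance is unavailable: the
#'   point estimate is still returned, with `se` and the CI set to `NA` and
#'   the method annotated.
#' @export
#' @examples
#' weighted_proportion(c(1, 0, 1, 1), rep(1, 4))$proportion # 0.75
#' weighted_proportion(c(1, 0), c(2, 1))$proportion         # 2/3
weighted_proportion <- function(x, weight, stratum = NULL, cluster = NULL,
                                domain = NULL, ci_method = c("logit", "wald"),
                                conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  n_all <- length(x)
  if (length(weight) != n_all) stop("x and weight must have equal length")
  if (anyNA(weight) || any(weight <= 0)) {
    stop("weights must be strictly positive and non-missing")
  }
  if (is.null(stratum)) stratum <- rep("_one", n_all)
  if (is.null(cluster)) cluster <- seq_len(n_all)
  if (length(stratum) != n_all || length(cluster) != n_all) {
    stop("stratum and cluster must align with x")
  }
  if (is.null(domain)) domain <- rep(TRUE, n_all)
  domain <- !is.na(domain) & domain

  n_missing <- sum(domain & is.na(x))
  d <- domain & !is.na(x)
  empty <- data.frame(
    proportion = NA_real_, se = NA_real_, ci_low = NA_real_,
    ci_high = NA_real_, n_unweighted = 0L, n_missing = n_missing,
    sum_weights = 0, df = NA_real_, method = paste0(ci_method, "; empty domain"),
    stringsAsFactors = FALSE
  )
  if (!any(d)) return(empty)

  xv <- as.numeric(x)
  xv[!d] <- 0
  sw <- sum(weight[d])
  p <- sum(weight[d] * xv[d]) / sw

  # Linearized scores; records outside the domain contribute zero but their
  # clusters still count toward the variance and degrees of freedom.
  e <- ifelse(d, weight * (xv - p), 0)
  skey <- as.character(stratum)
  ckey <- paste(skey, as.character(cluster), sep = "\x1f")
  e_cl <- rowsum(e, ckey, reorder = TRUE)[, 1]
  cl_stratum <- sub("\x1f.*$", "", names(e_cl))

  per_stratum <- split(e_cl, cl_stratum)
  n_h <- vapply(per_stratum, length, integer(1))
  n_clusters <- length(e_cl)
  n_strata <- length(per_stratum)
  df <- n_clusters - n_strata

  if (any(n_h < 2)) {
    variance <- NA_real_
    note <- "; variance undefined (stratum with a single PSU)"
  } else {
    v_h <- vapply(per_stratum, function(eh) {
      nh <- length(eh)
      nh / (nh - 1) * sum((eh - mean(eh))^2)
    }, numeric(1))
    variance <- sum(v_h) / sw^2
    note <- ""
  }
  se <- sqrt(variance)

  if (is.na(se)) {
    ci <- c(NA_real_, NA_real_)
  } else if (se == 0 || p <= 0 || p >= 1) {
    ci <- c(p, p)
  } else {
    tq <- stats::qt(1 - (1 - conf_level) / 2, df = df)
    if (ci_method == "logit") {
      lg <- stats::qlogis(p)
      se_lg <- se / (p * (1 - p))
      ci <- stats::plogis(lg + c(-1, 1) * tq * se_lg)
    } else {
      ci <- pmin(pmax(p + c(-1, 1) * tq * se, 0), 1)
    }
  }

  data.frame(
    proportion = p, se = se, ci_low = ci[1], ci_high = ci[2],
    n_unweighted = sum(d), n_missing = n_missing, sum_weights = sw,
    df = df, method = paste0(ci_method, note), stringsAsFactors = FALSE
  )
}

#' Grouped design-based prevalence estimates
#'
#' One estimate per combination of grouping-variable level (including the
#' `(all)` margin for each variable) and outcome, in the layout of the
#' standard survey report tables (e.g. men/women/total by age group).
#'
#' @param data Data frame holding outcomes, grouping variables and design
#'   variables.
#' @param outcomes Character vector of logical outcome column names; names
#'   of the vector, if any, are used as outcome labels.
#' @param by Character vector of grouping column names (default none:
#'   overall estimates only). Margins over each variable are labelled
#'   `(all)`.
#' @param weight,stratum,cluster Names of the design columns.
#' @param ci_method,conf_level Passed to [weighted_proportion()].
#' @return Data frame with one row per group x outcome: the grouping
#'   columns, `outcome`, and the estimate columns of
#'   [weighted_proportion()].
#' @export
prevalence_table <- function(data, outcomes, by = character(0),
                             weight = "weight", stratum = "stratum_id",
                             cluster = "cluster_id",
                             ci_method = c("logit", "wald"),
                             conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  labels <- names(outcomes) %||% outcomes
  labels[labels == ""] <- outcomes[labels == ""]
  missing_cols <- setdiff(c(outcomes, by, weight, stratum, cluster), names(data))
  if (length(missing_cols)) {
    stop("columns not found in data: ", paste(missing_cols, collapse = ", "))
  }
  if (length(by)) {
    levels_list <- lapply(by, function(v) {
      lev <- if (is.factor(data[[v]])) levels(data[[v]])
             else sort(unique(as.character(data[[v]])))
      c(lev, "(all)")
    })
    names(levels_list) <- by
    grid <- expand.grid(levels_list, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  } else {
    grid <- data.frame(row.names = 1)
  }
  rows <- list()
  for (g in seq_len(max(nrow(grid), 1L))) {
    domain <- rep(TRUE, nrow(data))
    for (v in by) {
      val <- grid[[v]][g]
      if (val != "(all)") domain <- domain & as.character(data[[v]]) == val
    }
    for (i in seq_along(outcomes)) {
      est <- weighted_proportion(
        data[[outcomes[i]]], data[[weight]], stratum = data[[stratum]],
        cluster = data[[cluster]], domain = domain, ci_method = ci_method,
        conf_level = conf_level)
      meta <- if (length(by)) grid[g, , drop = FALSE] else data.frame(row.names = 1)
      meta$outcome <- labels[i]
      rows[[length(rows) + 1L]] <- cbind(meta, est, row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
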