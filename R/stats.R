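#' Adjusted R-squared
#'
#' \code{1 - (1 - r2) * (n - 1) / (n - k - 1)} for a model with \code{k}
#' predictor terms fit to \code{n} observations.
#'
#' @param r2 Coefficient of determination.
#' @param n Number of observations.
#' @param k Number of predictor terms (excluding the intercept).
#' @return Adjusted R-squared (can be negative).
#' @export
adjusted_r2 <- function(r2, n, k) {
  if (n <= k + 1) stop_input("need n > k + 1")
  1 - (1 - r2) * (n - 1) / (n - k - 1)
}

#' Stepwise linear regression by partial-F p-values
#'
#' Forward-backward stepwise selection in the style of MATLAB's
#' \code{stepwiselm} default criterion: starting from the intercept-only
#' model, repeatedly add the candidate term with the smallest partial-F
#' p-value below \code{p_enter}, then remove any included term whose
#' partial-F p-value exceeds \code{p_remove}. Candidate terms are the main
#' effects of every supplied predictor and (when \code{max_degree >= 2}) all
#' pairwise interactions; hierarchy is enforced — an interaction is only
#' eligible once both parent mains are in the model, and a main effect is not
#' removable while one of its interactions remains. Rows with missing values
#' in the response or any candidate are dropped listwise.
#'
#' @param response Numeric response vector.
#' @param candidates Named data.frame (or named list) of candidate predictor
#'   vectors.
#' @param p_enter Entry threshold on the partial-F p-value (default 0.05).
#' @param p_remove Removal threshold (default 0.10).
#' @param max_degree 1 for main effects only, 2 to include pairwise
#'   interactions (default).
#' @return An object of class \code{stepwise_fit}: list with
#'   \code{selected_terms}, \code{coefficients}, \code{term_pvalues}
#'   (partial-F p per selected term), \code{adj_r2}, \code{n}, and the final
#'   \code{fit}.
#' @export
stepwise_lm <- function(response, candidates, p_enter = 0.05,
                        p_remove = 0.10, max_degree = 2) {
  candidates <- as.data.frame(candidates)
  if (is.null(names(candidates)) || any(names(candidates) == ""))
    stop_input("candidates must be named")
  dat <- cbind(data.frame(.y = response), candidates)
  dat <- dat[complete.cases(dat), , drop = FALSE]
  mains <- names(candidates)
  inters <- if (max_degree >= 2 && length(mains) >= 2) {
    cmb <- utils::combn(mains, 2)
    paste(cmb[1, ], cmb[2, ], sep = ":")
  } else character(0)
  if (nrow(dat) < length(mains) + length(inters) + 2)
    stop_input("too few complete observations for the candidate set")
  for (m in mains) {
    if (var(dat[[m]]) == 0)
      stop_input("candidate '", m, "' is constant (singular design)")
  }

  current <- character(0)
  fit_current <- function() {
    f <- if (length(current) == 0) ".y ~ 1"
         else paste(".y ~", paste(current, collapse = " + "))
    lm(as.formula(f), data = dat)
  }
  parents <- function(term) strsplit(term, ":", fixed = TRUE)[[1]]
  fit <- fit_current()
  visited <- character(0)
  repeat {
    state <- paste(sort(current), collapse = "+")
    if (state %in% visited) break  # cycle guard
    visited <- c(visited, state)
    changed <- FALSE
    # entry: eligible = mains not in model, interactions with both parents in
    elig <- c(setdiff(mains, current),
              Filter(function(tt) all(parents(tt) %in% current),
                     setdiff(inters, current)))
    if (length(elig) > 0) {
      a1 <- add1(fit, scope = as.formula(paste("~ . +", paste(elig, collapse = " + "))),
                 test = "F")
      pv <- a1[elig, "Pr(>F)"]
      if (any(!is.na(pv)) && min(pv, na.rm = TRUE) < p_enter) {
        current <- c(current, elig[which.min(pv)])
        fit <- fit_current()
        changed <- TRUE
      }
    }
    # removal: drop1 honours marginality (mains under an interaction stay)
    if (length(current) > 0) {
      d1 <- drop1(fit, test = "F")
      cand <- rownames(d1)[-1]
      pv <- d1[cand, "Pr(>F)"]
      if (length(pv) > 0 && any(!is.na(pv)) && max(pv, na.rm = TRUE) > p_remove) {
        current <- setdiff(current, cand[which.max(pv)])
        fit <- fit_current()
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  sm <- summary(fit)
  k <- length(current)
  term_p <- if (k > 0) {
    d1 <- drop1(fit, test = "F")
    setNames(d1[rownames(d1)[-1], "Pr(>F)"], rownames(d1)[-1])
  } else numeric(0)
  structure(list(selected_terms = current,
                 coefficients = coef(fit),
                 term_pvalues = term_p,
                 r2 = sm$r.squared,
                 adj_r2 = if (k == 0) 0 else
                   adjusted_r2(sm$r.squared, nrow(dat), k),
                 n = nrow(dat), fit = fit),
            class = "stepwise_fit")
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat("Stepwise linear model (partial-F entry/removal)\n")
  if (length(x$selected_terms) == 0) cat("  selected: (intercept only)\n")
  else cat("  selected:", paste(x$selected_terms, collapse = ", "), "\n")
  cat(sprintf("  n = %d, adj R^2 = %.4f\n", x$n, x$adj_r2))
  invisible(x)
}

# groups input -> long data.frame; accepts named list or (values, labels)
as_groups <- function(groups) {
  if (is.data.frame(groups) && all(c("value", "group") %in% names(groups))) {
    d <- data.frame(value = groups$value, group = factor(groups$group))
  } else if (is.list(groups)) {
    if (is.null(names(groups))) stop_input("groups must be named")
    d <- data.frame(value = unlist(groups, use.names = FALSE),
                    group = factor(rep(names(groups), lengths(groups)),
                                   levels = names(groups)))
  } else stop_input("groups must be a named list or a value/group data.frame")
  if (nlevels(d$group) < 2) stop_input("need at least 2 groups")
  if (any(tabulate(d$group) == 0)) stop_input("every group needs >= 1 value")
  d
}

#' One-way analysis of variance
#'
#' Classic between/within sum-of-squares decomposition via \code{stats::aov};
#' the p-value comes from the F distribution. Perfect separation (zero
#' within-group variance with distinct means) returns \code{F = Inf},
#' \code{p = 0}.
#'
#' @param groups Named list of numeric vectors (one per group), or a
#'   data.frame with \code{value} and \code{group} columns.
#' @return An object of class \code{anova_oneway}: group labels and means,
#'   \code{F}, \code{p_value}, \code{df_between}, \code{df_within}.
#' @export
anova_oneway <- function(groups) {
  d <- as_groups(groups)
  if (nrow(d) <= nlevels(d$group)) stop_input("total observations must exceed groups")
  fit <- aov(value ~ group, data = d)
  tab <- summary(fit)[[1]]
  Fv <- tab["group", "F value"]
  pv <- tab["group", "Pr(>F)"]
  if (is.na(Fv) || (tab["Residuals", "Sum Sq"] < 1e-300 &&
                    tab["group", "Sum Sq"] > 0)) {
    Fv <- Inf; pv <- 0
  }
  m <- tapply(d$value, d$group, mean)
  structure(list(labels = levels(d$group),
                 means = setNames(as.numeric(m), names(m)),
                 F = Fv, p_value = pv,
                 df_between = tab["group", "Df"],
                 df_within = tab["Residuals", "Df"],
                 fit = fit),
            class = "anova_oneway")
}

#' Tukey-Kramer honestly significant difference test
#'
#' All pairwise group comparisons after a one-way ANOVA, using the
#' studentized-range distribution with the Tukey-Kramer allowance for
#' unequal group sizes (via \code{stats::TukeyHSD}, which evaluates the
#' studentized-range CDF numerically). Family-wise significance at 0.05.
#'
#' @inheritParams anova_oneway
#' @param conf_level Family-wise confidence level (default 0.95).
#' @return A data.frame of class \code{tukey_hsd}: \code{group_a},
#'   \code{group_b}, \code{diff} (mean of a minus mean of b), \code{lwr},
#'   \code{upr}, \code{p_adj}, \code{significant}.
#' @export
tukey_hsd <- function(groups, conf_level = 0.95) {
  d <- as_groups(groups)
  if (nrow(d) <= nlevels(d$group)) stop_input("total observations must exceed groups")
  fit <- aov(value ~ group, data = d)
  tk <- TukeyHSD(fit, conf.level = conf_level)$group
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  out <- data.frame(group_a = vapply(pairs, `[`, "", 1),
                    group_b = vapply(pairs, `[`, "", 2),
                    diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
                    p_adj = tk[, "p adj"],
                    significant = tk[, "p adj"] < 1 - conf_level,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("tukey_hsd", "data.frame")
  out
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Two-sided test on the maximum absolute difference between the empirical
#' CDFs, with the asymptotic Kolmogorov p-value (appropriate for the large
#' samples this analysis deals in; ties, ubiquitous in sample-discretized
#' translocation times, are handled by the ECDF definition of D).
#'
#' @param x,y Nonempty numeric samples.
#' @return An object of class \code{ks_result}: \code{D} and \code{p_value}.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop_input("samples must be nonempty")
  kt <- suppressWarnings(ks.test(x, y, exact = FALSE))
  structure(list(D = unname(kt$statistic), p_value = kt$p.value),
            class = "ks_result")
}

#' MAD-based outlier flags
#'
#' Flags value \code{i} iff \code{|x_i - median(x)| / (1.4826 * MAD) > k},
#' with \code{MAD = median(|x - median(x)|)}; the 1.4826 factor scales the
#' MAD to the standard deviation under normality (the usual scaled-MAD
#' convention). When the MAD is zero (over half the values identical) any
#' value different from the median has infinite scaled distance and is
#' flagged.
#'
#' @param values Numeric vector, length >= 3.
#' @param k Threshold in scaled-MAD units (default 3).
#' @return Logical vector of flags.
#' @export
mad_outliers <- function(values, k = 3) {
  if (length(values) < 3) stop_input("need at least 3 values")
  m <- median(values)
  s <- mad(values)  # includes the 1.4826 scaling
  if (s == 0) return(values != m)
  abs(values - m) / s > k
}
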