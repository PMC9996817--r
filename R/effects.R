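# Tank-level laboratory effects: pooled mortality proportions, exact
# comparison against control, and the lethal-threshold rule that feeds the
# dispersal and impact stages (the lowest dose with significantly elevated
# mortality defines the lethal water concentration).

#' Pooled mortality proportion of a treatment
#'
#' Dead shrimp pooled over all replicate tanks of one treatment, divided by
#' the pooled total.
#'
#' @param outcomes data frame of exposure outcomes (columns `n`, `dead`)
#'   for a single treatment.
#' @return fraction dead in \[0, 1\].
#' @export
mortality_proportion <- function(outcomes) {
  ntot <- sum(outcomes$n)
  if (ntot <= 0) abort_data("no shrimp in the treatment group")
  if (any(outcomes$dead < 0 | outcomes$dead > outcomes$n))
    abort_domain("'dead' must lie in [0, n] per tank")
  sum(outcomes$dead) / ntot
}

# Two-sided exact p for a 2x2 dead/alive table by full hypergeometric
# enumeration: condition on both margins, enumerate every attainable table,
# sum the probabilities of those no more likely than the observed one.
exact_p_2x2 <- function(d1, n1, d2, n2) {
  D <- d1 + d2
  if (D == 0L || D == n1 + n2) return(1)  # degenerate: only one table possible? (all alive or all dead)
  x <- max(0L, D - n2):min(D, n1)
  pr <- dhyper(x, n1, n2, D)
  p_obs <- dhyper(d1, n1, n2, D)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Tank-level randomization test: permute tank labels between the two groups
# and compare the absolute difference in pooled mortality proportions.
# Complete enumeration when feasible, Monte Carlo otherwise.
randomization_p <- function(treat, control, n_perm = 10000, seed = NULL) {
  dead <- c(treat$dead, control$dead)
  n <- c(treat$n, control$n)
  k <- nrow(treat)
  m <- length(dead)
  stat <- function(idx) {
    abs(sum(dead[idx]) / sum(n[idx]) - sum(dead[-idx]) / sum(n[-idx]))
  }
  obs <- stat(seq_len(k))
  if (choose(m, k) <= 5000) {
    idxs <- utils::combn(m, k, simplify = FALSE)
    mean(vapply(idxs, stat, 0) >= obs - 1e-12)
  } else {
    with_local_seed(seed, {
      draws <- replicate(n_perm, stat(sample.int(m, k)))
      (1 + sum(draws >= obs - 1e-12)) / (n_perm + 1)
    })
  }
}

#' Compare a treatment to control
#'
#' Excess mortality (absolute difference of pooled proportions) and a
#' two-sided p-value. The default test is an exact conditional test on the
#' pooled 2x2 dead/alive table, computed by full hypergeometric enumeration;
#' a tank-level randomization test is available as an alternative that
#' respects the tank as the experimental unit.
#'
#' @param treatment,control exposure-outcome data frames (columns
#'   `treatment`, `n`, `dead`) for one dose group and the control.
#' @param method `"pooled-exact"` (default) or `"tank-randomization"`.
#' @param n_perm Monte Carlo permutations when complete enumeration of tank
#'   assignments is infeasible.
#' @param seed seed for Monte Carlo permutations.
#' @return object of class `treatment_comparison`: `dose`, `mortality_prop`,
#'   `control_prop`, `excess_vs_control`, `p_value`, `method`.
#' @export
compare_to_control <- function(treatment, control,
                               method = c("pooled-exact", "tank-randomization"),
                               n_perm = 10000, seed = NULL) {
  method <- match.arg(method)
  if (nrow(treatment) == 0L || nrow(control) == 0L)
    abort_data("both treatment and control groups must be non-empty")
  pt <- mortality_proportion(treatment)
  pc <- mortality_proportion(control)
  p <- if (method == "pooled-exact") {
    exact_p_2x2(sum(treatment$dead), sum(treatment$n),
                sum(control$dead), sum(control$n))
  } else {
    randomization_p(treatment, control, n_perm, seed)
  }
  structure(list(dose = treatment$treatment[1L], mortality_prop = pt,
                 control_prop = pc, excess_vs_control = pt - pc,
                 p_value = p, method = method),
            class = "treatment_comparison")
}

#' @export
print.treatment_comparison <- function(x, ...) {
  cat(sprintf("Dose %g ng/L: mortality %.0f%% (control %.0f%%), excess %+.0f%%, p = %.4g [%s]\n",
              x$dose, 100 * x$mortality_prop, 100 * x$control_prop,
              100 * x$excess_vs_control, x$p_value, x$method))
  invisible(x)
}

#' Lethal-effect threshold dose
#'
#' The lowest tested dose with a significant (p < alpha) and positive excess
#' mortality over control. Returns `NA` (with attribute `no_effect = TRUE`)
#' when no dose qualifies.
#'
#' @param comparisons list of [compare_to_control()] results, one per
#'   non-control dose (any order; sorted internally).
#' @param alpha significance level (default 0.05; a stricter 0.005 mode is
#'   available for conservative reporting).
#' @return the threshold dose in ng L^-1, or `NA_real_`.
#' @export
lethal_threshold <- function(comparisons, alpha = 0.05) {
  if (length(comparisons) == 0L) abort_data("no dose comparisons supplied")
  doses <- vapply(comparisons, `[[`, 0, "dose")
  comparisons <- comparisons[order(doses)]
  for (cmp in comparisons) {
    if (cmp$p_value < alpha && cmp$excess_vs_control > 0)
      return(cmp$dose)
  }
  structure(NA_real_, no_effect = TRUE)
}

#' Full effects analysis of an exposure experiment
#'
#' Convenience wrapper: splits outcomes by dose (dose 0 is the control),
#' compares each non-control dose to control and applies the threshold rule.
#'
#' @param outcomes exposure-outcome data frame (columns `treatment`, `tank`,
#'   `n`, `dead`).
#' @param alpha significance level.
#' @param method test passed to [compare_to_control()].
#' @return object of class `effects_analysis`: `comparisons` (list),
#'   `threshold` (ng L^-1 or NA), `alpha`.
#' @examples
#' out <- gen_mortality(seed = 7)
#' analyze_exposure(out)
#' @export
analyze_exposure <- function(outcomes, alpha = 0.05,
                             method = "pooled-exact") {
  doses <- sort(unique(outcomes$treatment))
  if (!0 %in% doses) abort_config("control group (dose 0) is missing")
  control <- outcomes[outcomes$treatment == 0, , drop = FALSE]
  cmps <- lapply(setdiff(doses, 0), function(d) {
    compare_to_control(outcomes[outcomes$treatment == d, , drop = FALSE],
                       control, method = method)
  })
  structure(list(comparisons = cmps,
                 threshold = lethal_threshold(cmps, alpha), alpha = alpha),
            class = "effects_analysis")
}

#' @export
print.effects_analysis <- function(x, ...) {
  cat("Exposure effects analysis (vs control, alpha =", x$alpha, ")\n")
  for (cmp in x$comparisons) print(cmp)
  if (is.na(x$threshold)) {
    cat("No lethal effect at the tested doses.\n")
  } else {
    cat(sprintf("Lethal-effect threshold: %g ng/L\n", x$threshold))
  }
  invisible(x)
}
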