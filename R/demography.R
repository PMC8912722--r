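# Scenario contrast of population-decline amplitude: the posterior
# distribution of Ne_t1/Ne_t2 per species under each scenario, compared
# between scenarios with a rank test.

#' Posterior distribution of the decline ratio Ne_t1 / Ne_t2
#'
#' Elementwise ratio of the (regression-adjusted, by default) retained size
#' parameters for one species, carrying the ABC weights, with the weighted
#' mode and 2.5/97.5 percentiles. Non-positive sizes are excluded and
#' counted.
#'
#' @param post result of [estimate_posteriors()] (uses `$adjusted` and
#'   `$weights`), or a list with those elements.
#' @param species `"cau"` or `"mor"`.
#' @param adjusted use regression-adjusted draws (default) or raw retained
#'   values (then pass an [abc_reject()] result via `rej`).
#' @param rej optional [abc_reject()] result for `adjusted = FALSE`.
#' @return list of class `decline_ratio`: `ratios`, `weights`, `mode`,
#'   `q2.5`, `q97.5`, `n_excluded`, `species`.
#' @export
decline_ratios <- function(post, species = c("cau", "mor"),
                           adjusted = TRUE, rej = NULL) {
  species <- match.arg(species)
  p1 <- paste0("ne_", species, "_t1")
  p2 <- paste0("ne_", species, "_t2")
  if (adjusted) {
    stopifnot(all(c(p1, p2) %in% colnames(post$adjusted)))
    a <- post$adjusted[, p1]; b <- post$adjusted[, p2]
    w <- post$weights
  } else {
    stopifnot(!is.null(rej))
    a <- rej$retained[[p1]]; b <- rej$retained[[p2]]
    d <- rej$retained$dist
    w <- 1 - (d / max(d, 1e-300))^2
    w[w <= 0] <- 1e-8
  }
  ok <- is.finite(a) & is.finite(b) & a > 0 & b > 0
  n_excluded <- sum(!ok)
  if (n_excluded > 0)
    message(n_excluded, " draws with non-positive sizes excluded")
  r <- a[ok] / b[ok]
  w <- w[ok]
  q <- weighted_quantile(r, w, c(0.025, 0.975))
  structure(list(ratios = r, weights = w, mode = weighted_mode(r, w),
                 q2.5 = q[1], q97.5 = q[2],
                 n_excluded = n_excluded, species = species),
            class = "decline_ratio")
}

#' Mann-Whitney U rank test
#'
#' Rank-sum U with tie correction; exact enumeration (via the exact
#' Wilcoxon distribution) for small untied samples, normal approximation
#' with continuity correction otherwise.
#'
#' @param a,b numeric samples (both non-empty).
#' @param exact_max use the exact distribution when both samples are at most
#'   this large and untied.
#' @return list with `U` (for the first sample), `p` (two-sided), `method`.
#' @export
mann_whitney_u <- function(a, b, exact_max = 20) {
  if (length(a) == 0 || length(b) == 0) stop("empty sample")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && length(a) <= exact_max && length(b) <= exact_max
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' Compare decline amplitude between two scenarios
#'
#' Rank-tests the two posterior ratio distributions (e.g., secondary contact
#' vs strict isolation) for one species and reports which scenario's decline
#' is stochastically larger, alongside both posterior summaries.
#'
#' The posterior draws being compared are weighted retained simulations from
#' the same observed data, not independent experimental units; the p-value
#' is reported as published practice but should be read descriptively (see
#' `caveat`).
#'
#' @param post_a,post_b two [decline_ratios()] results for the same species.
#' @param labels scenario labels for the report.
#' @return list: `species`, `larger` (label of the scenario with the larger
#'   median ratio), `U`, `p`, `summaries`, `caveat`.
#' @export
compare_scenarios <- function(post_a, post_b, labels = c("SC", "SI")) {
  stopifnot(inherits(post_a, "decline_ratio"),
            inherits(post_b, "decline_ratio"),
            post_a$species == post_b$species)
  mw <- mann_whitney_u(post_a$ratios, post_b$ratios)
  med <- c(stats::median(post_a$ratios), stats::median(post_b$ratios))
  list(species = post_a$species,
       larger = labels[which.max(med)],
       U = mw$U, p = mw$p,
       summaries = data.frame(
         scenario = labels,
         mode = c(post_a$mode, post_b$mode),
         q2.5 = c(post_a$q2.5, post_b$q2.5),
         q97.5 = c(post_a$q97.5, post_b$q97.5)),
       caveat = paste("posterior draws are correlated retained simulations,",
                      "not independent observations; the rank-test p-value",
                      "is descriptive"))
}
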