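# Approximate Bayesian computation: prior sampling, reference-table
# simulation, rejection, model choice, goodness of fit, and
# regression-adjusted weighted posterior estimation.

.param_names <- c("ne_anc", "ne_cau_t1", "ne_mor_t1", "ne_cau_t2",
                  "ne_mor_t2", "m1", "m2", "t1", "t2")

#' Prior specification for the demographic parameters
#'
#' Defaults: log-uniform effective sizes on `[1e2, 1e6]`, uniform divergence
#' time `t1` on `[1e3, 1e5]` generations with `t2 ~ U(0, t1)` (conditional
#' draw, so `t2 < t1` holds by construction), log-uniform migration rates on
#' `[1e-6, 1e-2]` for models with gene flow (0 under SI), and a fixed
#' mutation rate. The model prior is uniform over the four scenarios.
#'
#' @param ne_bounds,t1_bounds,m_bounds lower/upper bounds.
#' @param mu fixed per-locus mutation rate used for every simulation.
#' @param models character vector of scenarios to include.
#' @return a `prior_spec` object.
#' @export
prior_spec <- function(ne_bounds = c(1e2, 1e6), t1_bounds = c(1e3, 1e5),
                       m_bounds = c(1e-6, 1e-2), mu = 5e-4,
                       models = c("SI", "AM", "SC", "CM")) {
  stopifnot(ne_bounds[1] > 0, ne_bounds[1] < ne_bounds[2],
            t1_bounds[1] > 0, t1_bounds[1] < t1_bounds[2],
            m_bounds[1] > 0, m_bounds[1] < m_bounds[2])
  structure(list(ne_bounds = ne_bounds, t1_bounds = t1_bounds,
                 m_bounds = m_bounds, mu = mu, models = models),
            class = "prior_spec")
}

.r_logunif <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))

#' Sample demographic parameters from the prior
#'
#' @param prior a [prior_spec()].
#' @param n number of draws.
#' @param model scenario the draws are for (`m1`,`m2` are set to 0 under
#'   `"SI"`); `NULL` draws the model uniformly per row.
#' @return data frame with columns `model` and the nine demographic
#'   parameters; `t2 < t1` in every row.
#' @export
sample_priors <- function(prior, n, model = NULL) {
  stopifnot(n >= 1)
  models <- if (is.null(model))
    sample(prior$models, n, replace = TRUE) else rep(model, n)
  ne <- replicate(5, .r_logunif(n, prior$ne_bounds[1], prior$ne_bounds[2]))
  t1 <- stats::runif(n, prior$t1_bounds[1], prior$t1_bounds[2])
  t2 <- stats::runif(n, 0, t1)
  m1 <- .r_logunif(n, prior$m_bounds[1], prior$m_bounds[2])
  m2 <- .r_logunif(n, prior$m_bounds[1], prior$m_bounds[2])
  m1[models == "SI"] <- 0
  m2[models == "SI"] <- 0
  out <- data.frame(model = models, ne[, 1], ne[, 2], ne[, 3], ne[, 4],
                    ne[, 5], m1, m2, t1, t2)
  names(out) <- c("model", .param_names)
  out
}

#' Simulate the ABC reference table
#'
#' Draws parameters from the prior, simulates a dataset under each draw, and
#' records the summary-statistic vector. Reproducible given the R RNG state
#' (call `set.seed()` first). Simulation failures are skipped and counted,
#' never imputed.
#'
#' @param prior a [prior_spec()].
#' @param n_sim number of simulations.
#' @param n_loci,n_cau,n_mor design of each simulated dataset.
#' @param path optional TSV path; the table is streamed there in chunks.
#' @param chunk_size rows per chunk when streaming.
#' @return data frame: `model`, the nine parameters, and the 16 summary
#'   statistics; attribute `"n_failed"` counts skipped rows.
#' @export
run_reference_table <- function(prior, n_sim, n_loci = 17L,
                                n_cau = 20L, n_mor = 20L,
                                path = NULL, chunk_size = 1000L) {
  draws <- sample_priors(prior, n_sim)
  stat_names <- names(summary_stat_vector(
    simulate_dataset(scenario_spec("SI", 100, 100, 100, 100, 100,
                                   t1 = 100, t2 = 50, mu = 0,
                                   n_loci = 1L, n_cau = 2L, n_mor = 2L))))
  stats_m <- matrix(NA_real_, n_sim, length(stat_names),
                    dimnames = list(NULL, stat_names))
  n_failed <- 0L
  for (i in seq_len(n_sim)) {
    d <- draws[i, ]
    s <- tryCatch({
      sp <- scenario_spec(d$model, d$ne_anc, d$ne_cau_t1, d$ne_mor_t1,
                          d$ne_cau_t2, d$ne_mor_t2, d$m1, d$m2, d$t1, d$t2,
                          mu = prior$mu, n_loci = n_loci,
                          n_cau = n_cau, n_mor = n_mor)
      summary_stat_vector(simulate_dataset(sp))
    }, error = function(e) NULL)
    if (is.null(s) || any(!is.finite(s))) { n_failed <- n_failed + 1L; next }
    stats_m[i, ] <- s
  }
  out <- cbind(draws, as.data.frame(stats_m))
  out <- out[stats::complete.cases(stats_m), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_failed") <- n_failed
  attr(out, "stat_names") <- stat_names
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

.stat_cols <- function(table) {
  sn <- attr(table, "stat_names")
  if (!is.null(sn)) return(intersect(sn, names(table)))
  setdiff(names(table), c("model", .param_names))
}

#' Standardize and rank simulations by distance to the observed statistics
#'
#' Statistics are standardized by the median and MAD of the reference table
#' (columns with MAD zero are dropped with a warning); the retained set is
#' the `n_keep` rows of smallest Euclidean distance, ties broken by row
#' order.
#'
#' @param table reference table from [run_reference_table()].
#' @param observed named summary-statistic vector of the observed data.
#' @param n_keep number of simulations to retain.
#' @return list with `retained` (rows of `table` plus a `dist` column),
#'   `dist` (all distances), `center`/`scale`, and `stat_cols`.
#' @export
abc_reject <- function(table, observed, n_keep) {
  if (n_keep > nrow(table)) stop("n_keep exceeds table size")
  cols <- .stat_cols(table)
  S <- as.matrix(table[, cols, drop = FALSE])
  center <- apply(S, 2, stats::median)
  scale_ <- apply(S, 2, stats::mad)
  keep_col <- scale_ > 0
  if (any(!keep_col))
    warning("dropping zero-MAD statistics: ",
            paste(cols[!keep_col], collapse = ", "))
  cols <- cols[keep_col]
  S <- sweep(sweep(S[, keep_col, drop = FALSE], 2, center[keep_col]),
             2, scale_[keep_col], "/")
  obs <- (observed[cols] - center[cols]) / scale_[cols]
  d <- sqrt(rowSums(sweep(S, 2, obs)^2))
  ord <- order(d)           # stable: ties keep row order
  idx <- ord[seq_len(n_keep)]
  retained <- table[idx, , drop = FALSE]
  retained$dist <- d[idx]
  list(retained = retained, dist = d, index = idx,
       center = center[cols], scale = scale_[cols], stat_cols = cols,
       observed_std = obs)
}

#' Model posterior probabilities and Bayes factors
#'
#' `method = "rejection"` uses model frequencies in the retained set;
#' `"mnlogistic"` (default) fits a weighted multinomial logistic regression
#' of the model label on the standardized statistics of the retained set
#' (Epanechnikov weights on distance) and evaluates it at the observed
#' vector; `"neuralnet"` uses a single-hidden-layer network instead.
#' Posterior probabilities are clipped to `[1e-4, 1]` and renormalized
#' before Bayes factors are formed (`BF[i,j] = PP_i / PP_j`, valid under the
#' uniform model prior).
#'
#' @param rej result of [abc_reject()] on a multi-model table.
#' @param method one of `"mnlogistic"`, `"rejection"`, `"neuralnet"`.
#' @param models model labels to report (default: those in the table).
#' @return list with `pp` (named probabilities), `bf` (matrix), `method`.
#' @export
model_posterior <- function(rej, method = c("mnlogistic", "rejection",
                                            "neuralnet"),
                            models = NULL) {
  method <- match.arg(method)
  ret <- rej$retained
  if (is.null(models)) models <- sort(unique(ret$model))
  if (length(models) < 2) stop("need >= 2 models for model selection")
  absent <- setdiff(models, unique(ret$model))
  if (length(absent) > 0)
    warning("models absent from retained set: ", paste(absent, collapse = ", "))
  w <- 1 - (ret$dist / max(ret$dist, 1e-300))^2
  w[w <= 0] <- 1e-8
  if (method == "rejection" || length(unique(ret$model)) < 2) {
    tab <- table(factor(ret$model, levels = models))
    pp <- as.numeric(tab) / sum(tab)
    names(pp) <- models
  } else {
    S <- sweep(sweep(as.matrix(ret[, rej$stat_cols, drop = FALSE]), 2,
                     rej$center), 2, rej$scale, "/")
    df <- data.frame(model = factor(ret$model, levels = models), S)
    newd <- as.data.frame(t(rej$observed_std))
    names(newd) <- colnames(S)
    present <- levels(droplevels(df$model))
    df$model <- droplevels(df$model)
    if (method == "mnlogistic") {
      fit <- nnet::multinom(model ~ ., data = df, weights = w,
                            trace = FALSE, maxit = 500)
      pr <- stats::predict(fit, newdata = newd, type = "probs")
    } else {
      fit <- nnet::nnet(model ~ ., data = df, weights = w, size = 5,
                        decay = 1e-3, trace = FALSE, maxit = 500)
      pr <- stats::predict(fit, newdata = newd, type = "raw")
    }
    pp <- stats::setNames(numeric(length(models)), models)
    if (length(present) == 2) {
      pp[present[2]] <- as.numeric(pr)[length(as.numeric(pr))]
      pp[present[1]] <- 1 - pp[present[2]]
    } else {
      pr <- drop(as.matrix(pr))
      pp[names(pr)] <- pr
    }
  }
  pp <- pmin(pmax(pp, 1e-4), 1)
  pp <- pp / sum(pp)
  bf <- outer(pp, pp, "/")
  dimnames(bf) <- list(models, models)
  list(pp = pp, bf = bf, method = method)
}

#' Goodness-of-fit p-value for the selected model
#'
#' Marginal-density style test: the test statistic is the Euclidean distance
#' (in standardized statistic space) to the mean statistic of the model's
#' simulations; the null distribution is that distance for `n_rep`
#' simulated datasets from the model, and
#' `p = P(simulated distance > observed distance)`. An observed vector at
#' the centre of the cloud gives `p` near 1; one far outside gives `p` near
#' 0.
#'
#' @param table_model reference-table rows of the best model.
#' @param observed observed summary-statistic vector.
#' @param n_rep number of null replicates (rows subsampled from
#'   `table_model`; a warning is issued below 100).
#' @return list with `p`, `d_obs`, `d_null`.
#' @export
goodness_of_fit <- function(table_model, observed, n_rep = 1000) {
  if (n_rep < 100) warning("n_rep < 100 gives a low-resolution p-value")
  cols <- .stat_cols(table_model)
  S <- as.matrix(table_model[, cols, drop = FALSE])
  center <- apply(S, 2, stats::median)
  scale_ <- apply(S, 2, stats::mad)
  ok <- scale_ > 0
  Z <- sweep(sweep(S[, ok, drop = FALSE], 2, center[ok]), 2, scale_[ok], "/")
  mu <- colMeans(Z)
  obs <- (observed[cols[ok]] - center[ok]) / scale_[ok]
  d_obs <- sqrt(sum((obs - mu)^2))
  idx <- sample.int(nrow(Z), min(n_rep, nrow(Z)))
  d_null <- sqrt(rowSums(sweep(Z[idx, , drop = FALSE], 2, mu)^2))
  list(p = mean(d_null > d_obs), d_obs = d_obs, d_null = d_null)
}

#' Weighted empirical quantile
#' @param x numeric values.
#' @param w non-negative weights.
#' @param probs quantile levels.
#' @return numeric vector of quantiles.
#' @export
weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

#' Weighted kernel-density mode
#' @param x numeric values.
#' @param w non-negative weights.
#' @return location of the maximum of the weighted Gaussian KDE.
#' @export
weighted_mode <- function(x, w) {
  if (length(unique(x)) == 1) return(x[1])
  d <- suppressWarnings(stats::density(x, weights = w / sum(w)))
  d$x[which.max(d$y)]
}

#' Regression-adjusted weighted posterior estimates
#'
#' For each parameter: Epanechnikov weights on rejection distance (bandwidth
#' = largest retained distance), a weighted local-linear regression of the
#' parameter on the standardized statistics (strictly positive parameters
#' are log-transformed before adjustment and back-transformed after), then
#' the weighted-KDE mode and weighted 2.5% / 97.5% percentiles of the
#' adjusted values. A singular regression design falls back to unadjusted
#' weighted quantiles with a warning.
#'
#' @param rej result of [abc_reject()], typically restricted to one model.
#' @param params parameter columns to summarise.
#' @param bounds optional named list of `c(lower, upper)` prior bounds; a
#'   bounded parameter is adjusted on the logit scale of its prior range,
#'   which keeps adjusted draws inside the prior support even when the
#'   observation sits at the edge of the simulated cloud.
#' @return list with `summary` (data frame: mode, q2.5, q97.5 per
#'   parameter), `adjusted` (matrix of adjusted retained draws), `weights`.
#' @export
estimate_posteriors <- function(rej, params = .param_names, bounds = NULL) {
  ret <- rej$retained
  params <- intersect(params, names(ret))
  d <- ret$dist
  h <- max(d, 1e-300)
  w <- 1 - (d / h)^2
  w[w <= 0] <- min(w[w > 0], 1e-8)
  S <- sweep(sweep(as.matrix(ret[, rej$stat_cols, drop = FALSE]), 2,
                   rej$center), 2, rej$scale, "/")
  obs <- rej$observed_std
  adj <- matrix(NA_real_, nrow(ret), length(params),
                dimnames = list(NULL, params))
  for (p in params) {
    y <- ret[[p]]
    bnd <- if (!is.null(bounds) && p %in% names(bounds)) bounds[[p]] else NULL
    if (!is.null(bnd)) {
      eps <- (bnd[2] - bnd[1]) * 1e-6
      yc <- pmin(pmax(y, bnd[1] + eps), bnd[2] - eps)
      yt <- stats::qlogis((yc - bnd[1]) / (bnd[2] - bnd[1]))
      logged <- FALSE
    } else {
      logged <- all(y > 0)
      yt <- if (logged) log(y) else y
    }
    fit <- tryCatch(stats::lm.wfit(cbind(1, S), yt, w), error = function(e) NULL)
    if (is.null(fit)) {
      warning("singular regression design for '", p,
              "'; using unadjusted weighted quantiles")
      ya <- yt
    } else {
      # aliased (exactly collinear) columns get zero coefficients; the
      # projection itself is unaffected
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      pred_obs <- sum(beta * c(1, obs))
      ya <- pred_obs + fit$residuals
    }
    adj[, p] <- if (!is.null(bnd))
      bnd[1] + (bnd[2] - bnd[1]) * stats::plogis(ya)
    else if (logged) exp(ya) else ya
  }
  summary <- do.call(rbind, lapply(params, function(p) {
    q <- weighted_quantile(adj[, p], w, c(0.025, 0.975))
    # the KDE can smooth a boundary-adjacent mode slightly past the
    # weighted percentiles; keep the reported mode inside its interval
    m <- min(max(weighted_mode(adj[, p], w), q[1]), q[2])
    data.frame(parameter = p, mode = m, q2.5 = q[1], q97.5 = q[2])
  }))
  list(summary = summary, adjusted = adj, weights = w)
}

#' Convert generations to years
#'
#' @param t_generations time in generations (the coalescent's natural unit).
#' @param years_per_generation generation time in years; the package default
#'   of 5 reflects a tree that needs about five years to mature and flower.
#' @return list with `years` and `kyr` (rounded to the nearest kyr).
#' @export
generations_to_years <- function(t_generations, years_per_generation = 5) {
  stopifnot(t_generations >= 0, years_per_generation > 0)
  yr <- t_generations * years_per_generation
  list(years = yr, kyr = round(yr / 1000))
}
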