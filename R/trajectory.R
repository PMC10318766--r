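#' Latent-class polynomial trajectory model (group-based trajectory model)
#'
#' Fits a K-class Gaussian finite mixture of polynomial mean curves to
#' longitudinal non-HDL cholesterol by EM: the E-step computes posterior
#' class probabilities from the Gaussian likelihood of each participant's
#' observed visits, the M-step refits each class curve by
#' posterior-weighted least squares and updates the shared residual
#' variance and class weights. Missing visits contribute nothing (the
#' likelihood runs over observed time points only; no imputation). The
#' best of `n_starts` seeded initializations (k-means on per-participant
#' mean/slope summaries, then jittered restarts) is returned.
#'
#' @param series Long data frame with columns `participant_id`, `years`
#'   (observation times) and `non_hdl` (mg/dL). Every participant needs at
#'   least 2 observations at strictly increasing times.
#' @param K Number of latent classes (>= 1).
#' @param degree Polynomial degree of the class mean curves (0, 1 or 2).
#' @param max_iter,tol EM stopping rule: stop when the relative
#'   log-likelihood change falls below `tol` or after `max_iter`
#'   iterations.
#' @param n_starts Number of random initializations.
#' @param seed Integer seed controlling initialization.
#' @return Object of class `trajectory_model`: `K`, `degree`,
#'   `coefficients` (K x (degree+1), mg/dL per year^p), `residual_sd`,
#'   `class_weights`, `log_likelihood`, `loglik_trace` (per-iteration for
#'   the winning start), `posteriors` (n x K, rows sum to 1), `labels`
#'   (argmax class index per participant), `label_order` (class indices
#'   sorted by fitted mean at the last observed time), `t_range`.
#' @export
fit_trajectory_model <- function(series, K = 2L, degree = 1L,
                                 max_iter = 200L, tol = 1e-8,
                                 n_starts = 10L, seed = 1L) {
  stopifnot(is.data.frame(series), K >= 1L)
  if (degree > 2L) stop("degree must be <= 2")
  dat <- prepare_series(series)
  n <- length(dat$ids)
  if (K > n) stop("K exceeds the number of participants")

  X <- outer(dat$t, 0:degree, `^`)
  y <- dat$y
  grp <- dat$obs_group                      # participant index per obs
  n_i <- tabulate(grp, nbins = n)

  if (stats::var(y) < 1e-12 && K >= 2L)
    warning("degenerate fit: all series identical with K >= 2")

  # per-participant (mean, slope) summaries for initialization
  mh <- rowsum(y, grp)[, 1] / n_i
  tc <- dat$t - (rowsum(dat$t, grp)[, 1] / n_i)[grp]
  stt <- rowsum(tc * tc, grp)[, 1]
  sl <- rowsum(tc * y, grp)[, 1] / pmax(stt, 1e-12)
  summ <- cbind(mh, sl)

  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    r0 <- init_posteriors(summ, K, jitter = (s > 1L))
    fit <- em_mixture(X, y, grp, n_i, r0, K, max_iter, tol)
    if (is.null(best) || fit$log_likelihood > best$log_likelihood)
      best <- fit
  }

  post <- best$posteriors
  rownames(post) <- dat$ids
  tmax <- max(dat$t)
  fitted_end <- drop(outer(tmax, 0:degree, `^`) %*% t(best$coefficients))
  labels <- max.col(post, ties.method = "first")
  tie <- abs(post - post[cbind(seq_len(n), labels)]) < 1e-12
  n_tied <- rowSums(tie)
  if (any(n_tied > 1L))
    warning(sum(n_tied > 1L),
            " participants with tied posteriors assigned to the lower class index")

  out <- list(K = K, degree = degree,
              coefficients = best$coefficients,
              residual_sd = best$residual_sd,
              class_weights = best$class_weights,
              log_likelihood = best$log_likelihood,
              loglik_trace = best$loglik_trace,
              posteriors = post,
              labels = stats::setNames(labels, dat$ids),
              tie_flag = stats::setNames(n_tied > 1L, dat$ids),
              label_order = order(fitted_end),
              t_range = range(dat$t),
              n = n)
  class(out) <- "trajectory_model"
  out
}

prepare_series <- function(series) {
  need <- c("participant_id", "years", "non_hdl")
  if (!all(need %in% names(series)))
    stop("series needs columns participant_id, years, non_hdl")
  series <- series[order(series$participant_id, series$years), ]
  ids <- unique(series$participant_id)
  grp <- match(series$participant_id, ids)
  n_i <- tabulate(grp, nbins = length(ids))
  if (any(n_i < 2L))
    stop("every participant needs >= 2 observed visits ",
         "(baseline plus at least one follow-up)")
  dup <- stats::ave(series$years, grp, FUN = function(t) anyDuplicated(t))
  if (any(dup > 0)) stop("observation times must be strictly increasing")
  list(ids = ids, obs_group = grp, t = series$years, y = series$non_hdl)
}

init_posteriors <- function(summ, K, jitter) {
  n <- nrow(summ)
  if (K == 1L) return(matrix(1, n, 1))
  z <- scale(summ)
  z[!is.finite(z)] <- 0
  if (jitter) z <- z + matrix(stats::rnorm(length(z), 0, 0.75), nrow = n)
  km <- tryCatch(stats::kmeans(z, centers = K, nstart = 1),
                 error = function(e) NULL)
  cl <- if (is.null(km)) sample.int(K, n, replace = TRUE) else km$cluster
  r <- matrix(0.1 / (K - 1), n, K)
  r[cbind(seq_len(n), cl)] <- 0.9
  r
}

em_mixture <- function(X, y, grp, n_i, r, K, max_iter, tol) {
  n <- length(n_i)
  N <- length(y)
  p <- ncol(X)
  coefs <- matrix(0, K, p)
  trace <- numeric()
  ll_old <- -Inf
  sigma <- stats::sd(y)
  if (!is.finite(sigma) || sigma <= 0) sigma <- 1

  for (it in seq_len(max_iter)) {
    # M-step from current responsibilities
    w_k <- colSums(r)
    ss_tot <- 0
    for (k in seq_len(K)) {
      w <- r[grp, k]
      XtW <- crossprod(X, w * X)
      bk <- tryCatch(solve(XtW, crossprod(X, w * y)),
                     error = function(e) qr.coef(qr(sqrt(w) * X), sqrt(w) * y))
      bk[is.na(bk)] <- 0
      coefs[k, ] <- bk
      ss_tot <- ss_tot + sum(w * (y - drop(X %*% bk))^2)
    }
    sigma <- sqrt(max(ss_tot / N, 1e-12))
    pi_k <- pmax(w_k / n, 1e-12)
    pi_k <- pi_k / sum(pi_k)

    # E-step: participant-level class log-likelihoods
    res2 <- (matrix(y, N, K) - X %*% t(coefs))^2
    ss_ik <- rowsum(res2, grp)
    ll_ik <- -0.5 * ss_ik / sigma^2 -
      n_i * (log(sigma) + 0.5 * log(2 * pi))
    lw <- sweep(ll_ik, 2L, log(pi_k), `+`)
    mx <- apply(lw, 1L, max)
    lse <- mx + log(rowSums(exp(lw - mx)))
    r <- exp(lw - lse)
    ll <- sum(lse)
    trace <- c(trace, ll)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + 1e-3)) break
    ll_old <- ll
  }
  list(coefficients = coefs, residual_sd = sigma, class_weights = pi_k,
       log_likelihood = trace[length(trace)], loglik_trace = trace,
       posteriors = r)
}

#' @export
print.trajectory_model <- function(x, ...) {
  cat("trajectory_model: K =", x$K, ", degree =", x$degree,
      ", logL =", format(x$log_likelihood), ", sigma =",
      format(x$residual_sd, digits = 4), "\n")
  cat("class weights:", format(x$class_weights, digits = 3), "\n")
  invisible(x)
}

#' Choose the number of trajectory classes by BIC
#'
#' Fits K = 1..K_max latent-class models and returns the K minimizing
#' BIC = -2 logL + p log(n), with p = K(degree+1) + (K-1) + 1 free
#' parameters and n the number of participants. Ties break toward the
#' smaller K.
#'
#' @inheritParams fit_trajectory_model
#' @param K_max Largest class count to consider.
#' @return Integer, with the BIC table in attribute `"bic"`.
#' @export
select_num_classes <- function(series, K_max = 5L, degree = 1L, seed = 1L,
                               n_starts = 10L) {
  K_max <- as.integer(K_max)
  if (K_max < 1L) stop("K_max must be >= 1")
  bics <- numeric(K_max)
  for (K in seq_len(K_max)) {
    fit <- fit_trajectory_model(series, K = K, degree = degree,
                                n_starts = n_starts, seed = seed + K)
    p <- K * (degree + 1L) + (K - 1L) + 1L
    bics[K] <- -2 * fit$log_likelihood + p * log(fit$n)
  }
  best <- which.min(bics)          # which.min takes the first (smallest K)
  structure(as.integer(best), bic = bics)
}

#' Name the two trajectory classes "stable" and "increasing"
#'
#' The class whose fitted mean at the last observed exposure time is
#' higher and whose net fitted change over the window is positive is
#' named "increasing"; the other is "stable". Participants take the name
#' of their maximum-posterior class, so relabeling class indices cannot
#' change group names. When the shape rule cannot distinguish the classes
#' (identical or symmetric fits) the tie is broken by class index with a
#' warning.
#'
#' @param model A `trajectory_model` with K = 2.
#' @return Named character vector ("stable"/"increasing") per participant;
#'   attribute `"increasing_class"` gives the class index called
#'   increasing, and `"tie_flag"` marks participants whose posterior was
#'   exactly split (assigned to the lower class index).
#' @export
assign_groups <- function(model) {
  stopifnot(inherits(model, "trajectory_model"))
  if (model$K != 2L)
    stop("assign_groups needs K = 2; relabel classes manually for other K")
  tmax <- model$t_range[2]
  tmin <- model$t_range[1]
  basis <- function(t) outer(t, 0:model$degree, `^`)
  f_end <- drop(basis(tmax) %*% t(model$coefficients))
  f_start <- drop(basis(tmin) %*% t(model$coefficients))
  net <- f_end - f_start

  cand <- which(f_end == max(f_end) & net > 0)
  if (length(cand) == 1L) {
    inc <- cand
  } else {
    if (abs(diff(f_end)) < 1e-9 && abs(diff(net)) < 1e-9) {
      warning("classes indistinguishable by shape; tie broken by class index")
      inc <- 2L
    } else {
      inc <- which.max(f_end)
      if (net[inc] <= 0)
        warning("higher-endpoint class has non-positive net change; ",
                "named increasing by endpoint rule")
    }
  }
  nm <- c("stable", "stable")
  nm[inc] <- "increasing"
  out <- stats::setNames(nm[model$labels], names(model$labels))
  attr(out, "increasing_class") <- inc
  attr(out, "tie_flag") <- model$tie_flag
  out
}

#' Class-mean trajectory curves for plotting
#'
#' @param model A `trajectory_model`.
#' @param times Evaluation times in years (default: 25 points across the
#'   observed range).
#' @return Data frame `class`, `years`, `fitted_non_hdl`.
#' @export
trajectory_curves <- function(model, times = NULL) {
  if (is.null(times))
    times <- seq(model$t_range[1], model$t_range[2], length.out = 25L)
  basis <- outer(times, 0:model$degree, `^`)
  fit <- basis %*% t(model$coefficients)
  data.frame(class = rep(seq_len(model$K), each = length(times)),
             years = rep(times, model$K),
             fitted_non_hdl = as.vector(fit))
}
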