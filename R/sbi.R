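# Amortized posterior inference over the nine pair parameters: prior
# sampling, batch simulation with TE-significance filtering, conditional
# density training, posterior access and MAP extraction.

#' Sample parameter vectors from the uniform prior box
#'
#' @param n number of draws
#' @param prior data.frame as returned by [prior_box()]
#' @return `n` x 9 matrix with named columns, i.i.d. uniform over the box
#' @export
sample_prior <- function(n, prior = prior_box()) {
  stopifnot(n >= 1)
  m <- vapply(seq_len(nrow(prior)),
              function(i) runif(n, prior$lower[i], prior$upper[i]),
              numeric(n))
  m <- matrix(m, nrow = n)
  colnames(m) <- prior$name
  m
}

#' Build a training set of (theta, summary) pairs
#'
#' Draws parameters from the prior, simulates each pair, extracts the six
#' summary statistics, and keeps only rows whose transfer entropy indicates
#' a significant pre-to-post interaction (the vectors flagged valid).
#' Attrition is recorded, never silent.
#'
#' @param n number of attempted simulations
#' @param duration simulated time per draw \[ms\]
#' @param dt integration step \[ms\]
#' @param seed root seed; simulation seeds are derived from it
#' @param prior a [prior_box()] data.frame
#' @param config a [te_config()]
#' @param progress print progress every 100 simulations
#' @return object of class `training_set`: list with `theta` (kept n x 9),
#'   `stats` (kept n x 6), `n_attempted`, `n_valid`, `seed`, `duration`
#' @export
build_training_set <- function(n, duration = 5000, dt = 0.1, seed = 1,
                               prior = prior_box(), config = te_config(),
                               progress = FALSE) {
  stopifnot(n >= 1)
  set.seed(seed)
  thetas <- sample_prior(n, prior)
  sim_seeds <- sample.int(.Machine$integer.max - 1L, n)
  keep_theta <- list(); keep_stats <- list()
  for (i in seq_len(n)) {
    sim <- run_pair_simulation(as.list(thetas[i, ]),
                               simulation_config(duration = duration, dt = dt,
                                                 seed = sim_seeds[i]))
    set.seed(sim_seeds[i] %% 1000000L + 7L) # surrogate stream
    st <- extract_summary(sim, config)
    if (isTRUE(st$valid)) {
      keep_theta[[length(keep_theta) + 1]] <- thetas[i, ]
      keep_stats[[length(keep_stats) + 1]] <-
        unlist(st[1, summary_stat_names()])
    }
    if (progress && i %% 100 == 0)
      message(sprintf("simulated %d / %d (kept %d)", i, n, length(keep_theta)))
  }
  if (!length(keep_theta))
    stop("no simulation passed the significance filter: empty training set")
  structure(list(theta = do.call(rbind, keep_theta),
                 stats = do.call(rbind, keep_stats),
                 n_attempted = n, n_valid = length(keep_theta),
                 seed = seed, duration = duration),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat("Training set:", x$n_valid, "kept of", x$n_attempted,
      "attempted simulations (", x$duration, "ms each )\n")
  invisible(x)
}

#' Train the amortized posterior q(theta | x)
#'
#' Fits a mixture density network to the z-scored (summary, parameter)
#' pairs of a training set by maximum likelihood (negative log-likelihood
#' loss, Adam, early stopping on a validation split). Deterministic given
#' `seed`.
#'
#' @param ts a [build_training_set()] result, or any list with matrices
#'   `theta` and `stats`
#' @param n_comp mixture components
#' @param n_hidden units per hidden layer (two layers)
#' @param max_epochs,patience,batch,lr optimizer settings
#' @param min_rows refuse to train below this many rows
#' @param seed RNG seed for initialization and batching
#' @param transform summary-statistic preprocessing before z-scoring:
#'   `"log-rates"` (default) maps the heavy-tailed firing rates through
#'   `log1p`, which stabilizes the conditioning features; `"none"` leaves
#'   all six statistics linear
#' @return object of class `posterior_model`
#' @export
train_posterior <- function(ts, n_comp = 10, n_hidden = 64, max_epochs = 500,
                            patience = 20, batch = 256, lr = 1e-3,
                            min_rows = 500, seed = 1,
                            transform = c("log-rates", "none")) {
  transform <- match.arg(transform)
  theta <- as.matrix(ts$theta); stats <- as.matrix(ts$stats)
  stopifnot(nrow(theta) == nrow(stats))
  if (nrow(theta) < min_rows)
    stop("training set too small: ", nrow(theta), " rows < ", min_rows)
  if (any(!is.finite(theta)) || any(!is.finite(stats)))
    stop("non-finite entries in training data")
  stats_t <- stat_transform(stats, transform)
  # parameters are fitted in logit space: the box maps bijectively to R^9,
  # so a Gaussian mixture can represent flat (prior-like) posteriors with
  # correct edge mass, and every sample maps back inside the box
  u <- theta_to_u(theta)
  zx <- zfit(stats_t); zt <- zfit(u)
  set.seed(seed)
  fit <- mdn_train(zapply(zx, stats_t), zapply(zt, u), n_comp = n_comp,
                   n_hidden = n_hidden, batch = batch, lr = lr,
                   max_epochs = max_epochs, patience = patience)
  structure(list(net = fit$net, zx = zx, zt = zt, prior = prior_box(),
                 transform = transform,
                 training_log = fit$history, best_epoch = fit$best_epoch,
                 n_train = nrow(theta), seed = seed),
            class = "posterior_model")
}

# fixed feature maps for the conditioning statistics; rows or matrices
stat_transform <- function(x, transform) {
  if (transform == "none") return(x)
  cols <- c("f_pre", "f_post")
  if (is.matrix(x)) {
    x[, cols] <- log1p(pmax(x[, cols], 0))
  } else {
    x[cols] <- log1p(pmax(x[cols], 0))
  }
  x
}

# bijection between the prior box and R^9 (elementwise logit), plus the
# log-Jacobian of theta -> u needed to express densities on the theta scale
theta_to_u <- function(theta) {
  box <- prior_box()
  if (is.null(dim(theta))) theta <- matrix(theta, nrow = 1)
  p <- sweep(sweep(theta, 2, box$lower, "-"), 2, box$upper - box$lower, "/")
  qlogis(pmin(pmax(p, 1e-9), 1 - 1e-9))
}

u_to_theta <- function(u) {
  box <- prior_box()
  th <- sweep(sweep(plogis(u), 2, box$upper - box$lower, "*"), 2, box$lower, "+")
  colnames(th) <- box$name
  th
}

log_jacobian_u <- function(theta) {
  box <- prior_box()
  if (is.null(dim(theta))) theta <- matrix(theta, nrow = 1)
  p <- sweep(sweep(theta, 2, box$lower, "-"), 2, box$upper - box$lower, "/")
  p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
  -rowSums(log(p) + log(1 - p) +
             rep(log(box$upper - box$lower), each = nrow(p)))
}

zfit <- function(m) {
  mu <- colMeans(m); s <- apply(m, 2, sd)
  s[s < 1e-12] <- 1
  list(mu = mu, sd = s, names = colnames(m))
}
zapply <- function(z, m) sweep(sweep(m, 2, z$mu, "-"), 2, z$sd, "/")
zinvert <- function(z, m) sweep(sweep(m, 2, z$sd, "*"), 2, z$mu, "+")

#' @export
print.posterior_model <- function(x, ...) {
  cat("Amortized posterior model (MDN,", x$net$K, "components,",
      x$net$H, "hidden units) trained on", x$n_train, "simulations;",
      "best epoch", x$best_epoch, "\n")
  invisible(x)
}

#' Condition the amortized posterior on one observation
#'
#' No retraining: the density network is evaluated at the observed summary
#' vector. The estimator lives in logit-transformed parameter space, so
#' every sample maps back strictly inside the prior box (no posterior mass
#' leaks outside it; the reported acceptance fraction is 1 by
#' construction). Densities are reported on the natural theta scale via the
#' change of variables.
#'
#' @param model a [train_posterior()] result
#' @param x_obs summary vector: `summary_stats` row, named list/vector in
#'   the order `f_pre, f_post, v_pre, v_post, p_syn, lag`
#' @param warn_sd warn if any standardized component exceeds this magnitude
#'   (observation far outside the training support)
#' @return object of class `pair_posterior` with functions `sample(n)` and
#'   `log_density(theta)` (theta: matrix or vector on the natural scale),
#'   plus `x_obs`
#' @export
posterior_for_observation <- function(model, x_obs, warn_sd = 5) {
  x <- as_summary_vector(x_obs)
  if (any(!is.finite(x))) stop("non-finite observed summary vector")
  tf <- if (is.null(model$transform)) "none" else model$transform
  xz <- drop(zapply(model$zx, matrix(stat_transform(x, tf), nrow = 1)))
  if (any(abs(xz) > warn_sd))
    warning("observation lies > ", warn_sd,
            " scale units outside the training support")
  sample_fn <- function(n) {
    uz <- mdn_sample_at(model$net, xz, n)
    th <- u_to_theta(zinvert(model$zt, uz))
    attr(th, "acceptance") <- 1
    th
  }
  logd_fn <- function(theta) {
    if (is.null(dim(theta))) theta <- matrix(theta, nrow = 1)
    uz <- zapply(model$zt, theta_to_u(theta))
    mdn_logdens_at(model$net, xz, uz) - sum(log(model$zt$sd)) +
      log_jacobian_u(theta)
  }
  structure(list(sample = sample_fn, log_density = logd_fn, x_obs = x,
                 xz = xz, model = model),
            class = "pair_posterior")
}

as_summary_vector <- function(x) {
  nm <- summary_stat_names()
  if (inherits(x, "summary_stats") || is.data.frame(x)) {
    unlist(x[1, nm])
  } else if (!is.null(names(x))) {
    unlist(x)[nm]
  } else {
    stopifnot(length(x) == 6)
    x <- as.numeric(x); names(x) <- nm; x
  }
}

#' Maximum a posteriori estimate
#'
#' Draws `n_samples` from the learned posterior, keeps the `n_top` with the
#' highest density, and runs monotone (backtracking) gradient ascent from
#' each; returns the best endpoint. The mode is defined and searched in the
#' unconstrained (logit) parameter space where the density estimator lives:
#' on the natural scale the change-of-variables Jacobian creates integrable
#' density spikes at the prior-box boundary, so maximizing the
#' natural-scale density would chase representation artifacts rather than
#' the region of posterior mass (the same convention Stan uses for
#' constrained parameters). `log_density` is reported in that
#' unconstrained parameterization and, because every accepted step
#' improves it, never falls below the density of any initializing sample.
#'
#' @param model a [train_posterior()] result
#' @param x_obs observed summary vector (see [posterior_for_observation()])
#' @param n_samples posterior draws used for initialization
#' @param n_top ascent starts
#' @param n_steps,step_size ascent iterations and initial step in
#'   standardized units (per-start steps shrink on failed moves)
#' @return object of class `map_estimate`: list with `theta_star` (named,
#'   inside the prior box by construction), `log_density`, `n_starts`
#' @export
map_estimate <- function(model, x_obs, n_samples = 10000, n_top = 200,
                         n_steps = 100, step_size = 1e-2) {
  post <- posterior_for_observation(model, x_obs)
  th <- post$sample(n_samples)
  Yall <- zapply(model$zt, theta_to_u(th))
  ld_all <- mdn_logdens_at(model$net, post$xz, Yall)
  top <- order(ld_all, decreasing = TRUE)[seq_len(min(n_top, nrow(th)))]
  Y <- Yall[top, , drop = FALSE]
  ld <- ld_all[top]
  step <- rep(step_size, length(top))
  for (s in seq_len(n_steps)) {
    cand <- Y + step * mdn_grad_y_at(model$net, post$xz, Y)
    ld_c <- mdn_logdens_at(model$net, post$xz, cand)
    ok <- is.finite(ld_c) & ld_c >= ld
    Y[ok, ] <- cand[ok, , drop = FALSE]
    ld[ok] <- ld_c[ok]
    step[ok] <- pmin(step[ok] * 1.2, 1)
    step[!ok] <- step[!ok] / 2
  }
  i <- which.max(ld)
  theta_star <- drop(u_to_theta(zinvert(model$zt, Y[i, , drop = FALSE])))
  names(theta_star) <- model$prior$name
  structure(list(theta_star = theta_star, log_density = ld[i],
                 n_starts = length(top)),
            class = "map_estimate")
}
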