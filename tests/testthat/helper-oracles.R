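# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use different algorithms / code paths than the package.

# plug-in conditional MI by explicit data.frame enumeration with table()
oracle_te <- function(x, y, k, delta, cond = NULL) {
  n <- length(x)
  k0 <- max(k, delta)
  idx <- (k0 + 1):n
  df <- data.frame(xt = x[idx], ys = y[idx - delta])
  for (j in seq_len(k)) df[[paste0("p", j)]] <- x[idx - j]
  if (!is.null(cond)) {
    for (ci in seq_along(cond)) df[[paste0("z", ci)]] <- cond[[ci]][idx - 1]
  }
  past_cols <- setdiff(names(df), c("xt", "ys"))
  past_key <- do.call(paste, df[past_cols])
  tab <- table(df$xt, df$ys, past_key)
  nt <- sum(tab)
  te <- 0
  for (z in dimnames(tab)[[3]]) {
    sl <- tab[, , z]
    cz <- sum(sl)
    for (xi in 1:2) for (yi in 1:2) {
      c3 <- sl[xi, yi]
      if (c3 > 0) te <- te + c3 / nt * log2(c3 * cz / (sum(sl[xi, ]) * sum(sl[, yi])))
    }
  }
  max(te, 0)
}

# postsynaptic spike probability by direct double loop
oracle_psyn <- function(pre, post, lag, delta_t) {
  if (!length(post)) return(0)
  hits <- 0
  for (tp in post) {
    if (any(abs(tp - (pre + lag)) <= delta_t)) hits <- hits + 1
  }
  min(1, hits / length(pre))
}

# order-preserving spike matching by exhaustive recursion (small inputs),
# maximizing match count then minimizing total latency
oracle_match <- function(a, b, max_latency) {
  a <- sort(a); b <- sort(b)
  best <- list(n = -1, lat = Inf)
  rec <- function(i, j, n, lat) {
    if (i > length(a) || j > length(b)) {
      if (n > best$n || (n == best$n && lat < best$lat))
        best <<- list(n = n, lat = lat)
      return()
    }
    rec(i + 1, j, n, lat)                  # skip a[i]
    rec(i, j + 1, n, lat)                  # skip b[j]
    d <- b[j] - a[i]
    if (d > 0 && d <= max_latency) rec(i + 1, j + 1, n + 1, lat + d)
  }
  rec(1, 1, 0, 0)
  best
}

# empirical KS statistic by direct ECDF evaluation on the pooled grid
oracle_ks <- function(a, b) {
  g <- sort(unique(c(a, b)))
  max(abs(ecdf(a)(g) - ecdf(b)(g)))
}

# argmax of the beta-function profile on a fine grid (with local refinement)
oracle_tau_peak <- function(tau1, tau2, w = 1) {
  kin <- synaptic_kinetics(tau1, tau2)
  tmax <- 5 * max(tau1, tau2)
  t <- seq(0, tmax, length.out = 20001)
  t0 <- t[which.max(beta_conductance(t, w, kin))]
  t2 <- seq(max(0, t0 - tmax / 10000), t0 + tmax / 10000, length.out = 20001)
  t2[which.max(beta_conductance(t2, w, kin))]
}
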