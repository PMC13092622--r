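# Downstream analyses over inferred parameters and summary statistics:
# correlation structure, model-vs-data deviation, KL divergence, and
# condition comparisons (KS, Kruskal-Wallis + Dunn).

#' Correlations between summary statistics and parameters
#'
#' Pearson correlations of each of the six summary statistics with each of
#' the nine parameters across simulations.
#'
#' @param thetas n x 9 parameter matrix
#' @param stats n x 6 summary matrix (columns in [summary_stat_names()]
#'   order)
#' @return 6 x 9 matrix of correlations in \[-1, 1\]; entries for
#'   zero-variance columns are NA and flagged in attribute `undefined`
#' @export
correlation_matrix <- function(thetas, stats) {
  thetas <- as.matrix(thetas); stats <- as.matrix(stats)
  stopifnot(nrow(thetas) == nrow(stats), nrow(thetas) >= 3)
  keep <- stats::complete.cases(thetas, stats)
  thetas <- thetas[keep, , drop = FALSE]; stats <- stats[keep, , drop = FALSE]
  sd_t <- apply(thetas, 2, sd); sd_s <- apply(stats, 2, sd)
  cc <- suppressWarnings(cor(stats, thetas))
  cc[sd_s < 1e-12, ] <- NA
  cc[, sd_t < 1e-12] <- NA
  attr(cc, "undefined") <- which(is.na(cc), arr.ind = TRUE)
  cc
}

#' Min-max normalized deviation between two summary vectors
#'
#' `|x_sim - x_obs| / (max - min)` per statistic, with the ranges taken
#' over a reference population (e.g., the prior simulations).
#'
#' @param x_sim,x_obs summary vectors (named, or `summary_stats` rows)
#' @param ranges data.frame/matrix with rownames = statistic names and
#'   columns `min`, `max`
#' @return named deviation vector, 0 when identical
#' @export
minmax_normalized_deviation <- function(x_sim, x_obs, ranges) {
  xs <- as_summary_vector(x_sim); xo <- as_summary_vector(x_obs)
  rng <- as.matrix(ranges)
  stopifnot(all(summary_stat_names() %in% rownames(rng)))
  rng <- rng[summary_stat_names(), , drop = FALSE]
  span <- rng[, "max"] - rng[, "min"]
  if (any(span <= 0)) stop("degenerate statistic range (max <= min)")
  abs(xs - xo) / span
}

#' Kullback-Leibler divergence between binned distributions
#'
#' `sum p log2(p/q)` over bins, after normalizing and adding a small
#' smoothing mass `eps` (fraction of total) to every bin so the divergence
#' stays finite.
#'
#' @param p_hist,q_hist bin counts or probabilities over identical binnings
#' @param eps additive smoothing as a fraction of total mass per histogram
#' @return divergence \[bits\], non-negative
#' @export
kl_divergence <- function(p_hist, q_hist, eps = 1e-6) {
  if (length(p_hist) != length(q_hist))
    stop("incompatible binnings: histogram lengths differ")
  stopifnot(all(p_hist >= 0), all(q_hist >= 0), sum(p_hist) > 0, sum(q_hist) > 0)
  p <- p_hist / sum(p_hist); q <- q_hist / sum(q_hist)
  p <- (p + eps) / (1 + length(p) * eps)
  q <- (q + eps) / (1 + length(q) * eps)
  sum(p * log2(p / q))
}

#' Sample skewness
#' @param x numeric vector
#' @return adjusted Fisher-Pearson skewness coefficient
#' @export
sample_skewness <- function(x) {
  n <- length(x)
  stopifnot(n >= 3)
  m <- mean(x); s <- sqrt(mean((x - m)^2))
  if (s == 0) return(0)
  sqrt(n * (n - 1)) / (n - 2) * mean((x - m)^3) / s^3
}

#' Bundle one experimental condition
#'
#' @param label condition name (e.g., "before", "after_0_5min")
#' @param maps per-pair MAP parameter matrix (n x 9, named columns)
#' @param stats per-pair summary matrix / data.frame (n x 6)
#' @return object of class `condition_dataset`
#' @export
condition_dataset <- function(label, maps, stats = NULL) {
  maps <- as.matrix(maps)
  stopifnot(nrow(maps) >= 2)
  if (!is.null(stats)) {
    stats <- as.data.frame(stats)
    stopifnot(nrow(stats) == nrow(maps))
  }
  structure(list(label = label, maps = maps, stats = stats),
            class = "condition_dataset")
}

#' Compare inferred parameter distributions across two conditions
#'
#' Two-sided two-sample Kolmogorov-Smirnov test per parameter (or per
#' summary statistic), with Benjamini-Hochberg adjustment across the tested
#' columns, the median shift (b minus a), and the sample skewness of each
#' condition.
#'
#' @param a,b [condition_dataset()] objects
#' @param what `"maps"` (parameters) or `"stats"` (summary statistics)
#' @return data.frame with one row per column: `name`, `D`, `p`,
#'   `p_adjusted`, `median_shift`, `skew_a`, `skew_b`
#' @export
compare_conditions <- function(a, b, what = c("maps", "stats")) {
  what <- match.arg(what)
  ma <- if (what == "maps") a$maps else as.matrix(a$stats[, summary_stat_names()])
  mb <- if (what == "maps") b$maps else as.matrix(b$stats[, summary_stat_names()])
  stopifnot(!is.null(ma), !is.null(mb), nrow(ma) >= 2, nrow(mb) >= 2)
  rows <- lapply(colnames(ma), function(nm) {
    ks <- suppressWarnings(ks.test(ma[, nm], mb[, nm]))
    data.frame(name = nm, D = unname(ks$statistic), p = ks$p.value,
               median_shift = median(mb[, nm]) - median(ma[, nm]),
               skew_a = sample_skewness(ma[, nm]),
               skew_b = sample_skewness(mb[, nm]))
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- p.adjust(out$p, method = "BH")
  out[, c("name", "D", "p", "p_adjusted", "median_shift", "skew_a", "skew_b")]
}

#' Kruskal-Wallis omnibus test with Dunn's post-hoc comparisons
#'
#' For a metric observed under three or more conditions: the Kruskal-Wallis
#' rank-sum omnibus test followed by Dunn's pairwise z-tests on mean ranks
#' (with tie correction), Benjamini-Hochberg adjusted.
#'
#' @param values numeric vector of observations
#' @param groups factor/character of condition labels (>= 2 per group)
#' @return list with `omnibus` (`statistic`, `df`, `p`) and `pairwise`
#'   data.frame (`a`, `b`, `z`, `p`, `p_adjusted`, `median_shift`)
#' @export
kruskal_dunn <- function(values, groups) {
  groups <- as.factor(groups)
  if (any(table(groups) < 2)) stop("need >= 2 observations per group")
  kw <- kruskal.test(values, groups)
  n <- length(values)
  r <- rank(values)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  lv <- levels(groups)
  combs <- utils::combn(lv, 2, simplify = FALSE)
  pw <- lapply(combs, function(gp) {
    ra <- r[groups == gp[1]]; rb <- r[groups == gp[2]]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) *
                 (1 / length(ra) + 1 / length(rb)))
    z <- (mean(ra) - mean(rb)) / se
    data.frame(a = gp[1], b = gp[2], z = z, p = 2 * pnorm(-abs(z)),
               median_shift = median(values[groups == gp[2]]) -
                 median(values[groups == gp[1]]))
  })
  pw <- do.call(rbind, pw)
  pw$p_adjusted <- p.adjust(pw$p, method = "BH")
  list(omnibus = list(statistic = unname(kw$statistic),
                      df = unname(kw$parameter), p = kw$p.value),
       pairwise = pw[, c("a", "b", "z", "p", "p_adjusted", "median_shift")])
}
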