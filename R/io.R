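# Shared formats and configuration: spike CSV tables and the YAML run
# configuration whose defaults reproduce the model's parameter table.

#' Read a spike-table CSV
#'
#' Expected columns: `unit_id`, `time_ms`, optionally `pair_id` and `site`.
#' Rows are validated (no negative or unparsable times), sorted, and
#' duplicate (unit, time) rows collapsed with a warning.
#'
#' @param path CSV file
#' @return data.frame sorted by (pair_id, unit_id, time_ms), with attribute
#'   `trains`: named list of spike-time vectors keyed `pair_id/unit_id`
#' @export
read_spike_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("unit_id", "time_ms")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!("pair_id" %in% names(df))) df$pair_id <- "pair1"
  t <- suppressWarnings(as.numeric(df$time_ms))
  bad <- which(!is.finite(t))
  if (length(bad))
    stop("unparsable time_ms at data line ", bad[1])
  neg <- which(t < 0)
  if (length(neg))
    stop("negative spike time at data line ", neg[1])
  df$time_ms <- t
  df <- df[order(df$pair_id, df$unit_id, df$time_ms), , drop = FALSE]
  dup <- duplicated(df[, c("pair_id", "unit_id", "time_ms")])
  if (any(dup)) {
    warning("collapsed ", sum(dup), " duplicate (unit, time) row(s)")
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  key <- paste(df$pair_id, df$unit_id, sep = "/")
  attr(df, "trains") <- split(df$time_ms, key)
  df
}

#' Write a spike-table CSV
#'
#' @param df data.frame with columns `unit_id`, `time_ms` (and optionally
#'   `pair_id`, `site`); times written at 0.01 ms precision
#' @param path output file
#' @export
write_spike_csv <- function(df, path) {
  stopifnot(all(c("unit_id", "time_ms") %in% names(df)))
  df$time_ms <- round(df$time_ms, 2)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' Nested list whose `model` section reproduces the fixed biophysical
#' parameter table field for field, with prior bounds, simulation, TE and
#' SBI settings.
#'
#' @return named list (see [validate_config()])
#' @export
default_config <- function() {
  list(
    model = list(r_a = 100, c_m = 1, g_na = 0.05, g_k = 0.005, g_l = 3e-4,
                 e_l = -39.2, e_na = 70, e_k = -80, v_t = -30.4,
                 temperature = 37),
    prior = as.list(setNames(
      lapply(seq_len(nrow(prior_box())),
             function(i) c(prior_box()$lower[i], prior_box()$upper[i])),
      prior_box()$name)),
    simulation = list(duration = 10000, dt = 0.1, seed = 1, settle = 200),
    te = list(bin_ms = 1, tau_source = 10, tau_target = 5,
              tau_target_mte = 10, n_perm = 200, alpha = 0.05),
    stats = list(delta_t_sim = 0.5, delta_t_exp = 1),
    sbi = list(n_train = 2000, n_comp = 10, n_hidden = 64)
  )
}

#' Validate (and default-fill) a run configuration
#'
#' Unknown keys and out-of-range values raise schema errors; missing keys
#' are filled from [default_config()].
#'
#' @param raw possibly partial nested list (e.g., from [read_config()])
#' @return completed, validated configuration list
#' @export
validate_config <- function(raw = list()) {
  def <- default_config()
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), names(def))
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  cfg <- def
  for (sec in names(raw)) {
    bad <- setdiff(names(raw[[sec]]), names(def[[sec]]))
    if (length(bad))
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "))
    cfg[[sec]][names(raw[[sec]])] <- raw[[sec]]
  }
  with(cfg$simulation, {
    if (!(dt > 0 && dt <= 0.1)) stop("simulation$dt must be in (0, 0.1]")
    if (duration <= 0) stop("simulation$duration must be positive")
  })
  with(cfg$te, {
    if (bin_ms <= 0) stop("te$bin_ms must be positive")
    if (n_perm < 1) stop("te$n_perm must be >= 1")
    if (alpha <= 0 || alpha >= 1) stop("te$alpha must be in (0, 1)")
  })
  with(cfg$model, {
    if (g_na < 0 || g_k < 0 || g_l < 0) stop("conductances must be >= 0")
    if (!(e_k < e_l && e_l < e_na)) stop("need e_k < e_l < e_na")
  })
  for (nm in names(cfg$prior)) {
    b <- cfg$prior[[nm]]
    if (length(b) != 2 || b[1] >= b[2])
      stop("prior$", nm, " must be (lower, upper) with lower < upper")
  }
  cfg
}

#' Read a YAML run configuration
#' @param path YAML file with any subset of the [default_config()] sections
#' @return validated configuration list
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}
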