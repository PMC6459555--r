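# Synthetic flow-cytometry populations: one or two log-normal modes of
# the Red:Green ratio, realized as correlated RFP/GFP intensity pairs.

#' Specification of a synthetic flow population
#'
#' Events are generated per mode: a log10 ratio is drawn as
#' `Normal(log10(median_ratio), log_sd)`, a GFP intensity as a log-normal
#' around `gfp_scale`, and RFP = ratio * GFP times multiplicative channel
#' noise; the per-mode median of RFP/GFP therefore converges to the
#' specified `median_ratio`.
#'
#' @param n_events number of events.
#' @param modes list of modes, each a list/vector with `fraction`,
#'   `median_ratio` (> 0) and `log_sd` (SD of log10 ratio); fractions must
#'   sum to 1.
#' @param channel_noise_sd SD of multiplicative log10 channel noise
#'   applied to each intensity (cancels in the ratio only partially;
#'   default 0.05).
#' @param gfp_scale median GFP intensity (arbitrary units).
#' @param seed integer seed.
#' @return a validated `flow_pop_spec`.
#' @export
flow_pop_spec <- function(n_events = 10000L,
                          modes = list(list(fraction = 1, median_ratio = 1,
                                            log_sd = 0.1)),
                          channel_noise_sd = 0.05,
                          gfp_scale = 1000,
                          seed = 1L) {
  fr <- vapply(modes, function(m) m$fraction, numeric(1))
  med <- vapply(modes, function(m) m$median_ratio, numeric(1))
  if (abs(sum(fr) - 1) > 1e-8)
    pf_stop("invalid_spec", "mode fractions must sum to 1 (got %g)", sum(fr))
  if (any(med <= 0))
    pf_stop("invalid_spec", "mode median ratios must be positive")
  if (any(fr < 0))
    pf_stop("invalid_spec", "mode fractions must be nonnegative")
  structure(list(n_events = as.integer(n_events), modes = modes,
                 channel_noise_sd = channel_noise_sd, gfp_scale = gfp_scale,
                 seed = as.integer(seed)),
            class = "flow_pop_spec")
}

#' Generate a synthetic flow population
#'
#' @param spec a [flow_pop_spec()].
#' @param sample_id value for the `sample_id` column.
#' @return data frame with one row per event: `sample_id`, `mode` (true
#'   mode index), `RFP`, `GFP`. Reproducible by seed.
#' @export
generate_flow_population <- function(spec, sample_id = "sample1") {
  with_seed(spec$seed, {
    fr <- vapply(spec$modes, function(m) m$fraction, numeric(1))
    n_mode <- as.vector(rmultinom(1, spec$n_events, fr))
    rows <- vector("list", length(spec$modes))
    for (i in seq_along(spec$modes)) {
      m <- spec$modes[[i]]
      n <- n_mode[i]
      if (n == 0) next
      log_ratio <- rnorm(n, log10(m$median_ratio), m$log_sd)
      gfp <- spec$gfp_scale *
        10^rnorm(n, 0, spec$channel_noise_sd)
      rfp <- 10^log_ratio * gfp *
        10^rnorm(n, 0, spec$channel_noise_sd)
      # attribute the ratio noise to RFP so RFP/GFP has the drawn median
      rows[[i]] <- data.frame(sample_id = sample_id, mode = i,
                              RFP = rfp, GFP = gfp)
    }
    df <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    rownames(df) <- NULL
    df
  })
}
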