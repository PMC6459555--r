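# Tandem-fluorescent reporter flux statistics from per-event flow data:
# Red:Green ratios, quantile summaries with reference normalization,
# bimodal deconvolution (two-class variance minimization on log-ratio),
# and fold-repression scoring.

#' Per-event Red:Green ratios
#'
#' Computes `ratio = RFP / GFP` per event. Events with `GFP <= 0` (or
#' non-finite intensities) cannot carry a ratio; they are excluded and
#' tallied in the `n_excluded` attribute rather than silently dropped.
#'
#' @param pop data frame with numeric columns `RFP` and `GFP` (one row per
#'   event).
#' @return numeric vector of ratios with attribute `n_excluded`.
#' @export
compute_ratios <- function(pop) {
  ok <- is.finite(pop$RFP) & is.finite(pop$GFP) & pop$GFP > 0
  if (!any(ok))
    pf_stop("empty_population", "no events with positive GFP intensity")
  r <- pop$RFP[ok] / pop$GFP[ok]
  attr(r, "n_excluded") <- sum(!ok)
  r
}

#' Summarize a ratio distribution
#'
#' Median, inner quartiles and 10th/90th percentiles of the per-event
#' Red:Green ratio, using linear ("type 7") quantile interpolation (the
#' rule is fixed and documented because gating software does not publish
#' one). Populations below `min_events` raise an insufficient-events
#' error; the default floor of 1,000 events matches standard flow
#' practice for these summaries.
#'
#' @param ratios numeric ratio vector (from [compute_ratios()]) or a data
#'   frame accepted by it.
#' @param min_events minimum retained events (default 1000).
#' @return a `flux_summary`: `median`, `q25`, `q75`, `p10`, `p90`, `n`,
#'   `normalized_to`.
#' @export
summarize_flux <- function(ratios, min_events = 1000) {
  if (is.data.frame(ratios)) ratios <- compute_ratios(ratios)
  n <- length(ratios)
  if (n < min_events)
    pf_stop("insufficient_events", "only %d events (< %d required)", n,
            min_events)
  q <- quantile(ratios, c(0.10, 0.25, 0.50, 0.75, 0.90), type = 7,
                names = FALSE)
  structure(list(median = q[3], q25 = q[2], q75 = q[4], p10 = q[1],
                 p90 = q[5], n = n, normalized_to = "none"),
            class = "flux_summary")
}

#' @export
print.flux_summary <- function(x, ...) {
  cat(sprintf(
    "<flux_summary> n=%d median=%.4g IQR=[%.4g, %.4g] P10/P90=[%.4g, %.4g] (normalized to %s)\n",
    x$n, x$median, x$q25, x$q75, x$p10, x$p90, x$normalized_to))
  invisible(x)
}

#' Normalize a flux summary to a reference population
#'
#' Divides every quantile by the reference population's median (the
#' convention when plotting reporter panels against a lysosomal-inhibition
#' reference such as BafA1 treatment). Order of quantiles is preserved.
#'
#' @param summary a `flux_summary`.
#' @param reference_summary the reference `flux_summary` (median > 0).
#' @param label stored in `normalized_to`.
#' @return normalized `flux_summary`.
#' @export
normalize_flux_summary <- function(summary, reference_summary,
                                   label = "reference") {
  ref <- reference_summary$median
  if (!is.finite(ref) || ref <= 0)
    pf_stop("invalid_parameter", "reference median must be positive")
  for (f in c("median", "q25", "q75", "p10", "p90"))
    summary[[f]] <- summary[[f]] / ref
  summary$normalized_to <- label
  summary
}

#' Deconvolve a bimodal population
#'
#' Splits a (possibly bimodal) ratio distribution at a threshold chosen in
#' an unbiased, parameter-free way: two-class within-variance minimization
#' (Otsu's criterion) over a 256-bin histogram of log10 ratio. The
#' threshold is scale-equivariant (multiplying all ratios by a constant
#' shifts it by the same factor). When the best split explains less than
#' `min_between_frac` of the total variance the population is flagged
#' degenerate (effectively unimodal) instead of erroring.
#'
#' @param ratios numeric ratio vector or data frame for [compute_ratios()].
#' @param n_bins histogram bins (default 256).
#' @param min_events minimum events (default 1000).
#' @param min_between_frac floor on the between-class variance fraction
#'   below which the gate is flagged degenerate. The default 0.8 sits
#'   above the ~0.64 a single Gaussian's optimal two-class split already
#'   explains, so unimodal populations are reliably flagged.
#' @return a `bifurcation_gate`: `threshold` (ratio scale),
#'   `log10_threshold`, `fraction_low`, `fraction_high`, `median_low`,
#'   `median_high`, `between_variance_fraction`, `degenerate`.
#' @export
bifurcate <- function(ratios, n_bins = 256, min_events = 1000,
                      min_between_frac = 0.8) {
  if (is.data.frame(ratios)) ratios <- compute_ratios(ratios)
  if (length(ratios) < min_events)
    pf_stop("insufficient_events", "only %d events (< %d required)",
            length(ratios), min_events)
  lr <- log10(ratios)
  rng <- range(lr)
  if (rng[2] <= rng[1]) {
    gate <- list(threshold = 10^rng[1], log10_threshold = rng[1],
                 fraction_low = 1, fraction_high = 0,
                 median_low = median(ratios), median_high = NA_real_,
                 between_variance_fraction = 0, degenerate = TRUE)
    return(structure(gate, class = "bifurcation_gate"))
  }
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(lr, br, rightmost.closed = TRUE), nbins = n_bins)
  mids <- (br[-1] + br[-length(br)]) / 2
  n <- sum(h)
  # exhaustive scan of all bin boundaries for the max between-class variance
  w <- cumsum(h) / n
  mu_cum <- cumsum(h * mids) / n
  mu_tot <- mu_cum[n_bins]
  valid <- w > 0 & w < 1
  between <- rep(-Inf, n_bins)
  between[valid] <- (mu_tot * w[valid] - mu_cum[valid])^2 /
    (w[valid] * (1 - w[valid]))
  k <- which.max(between)
  thr_log <- br[k + 1L]
  tot_var <- sum(h * (mids - mu_tot)^2) / n
  bvf <- if (tot_var > 0) between[k] / tot_var else 0
  low <- ratios[lr <= thr_log]
  high <- ratios[lr > thr_log]
  gate <- list(threshold = 10^thr_log, log10_threshold = thr_log,
               fraction_low = length(low) / length(ratios),
               fraction_high = length(high) / length(ratios),
               median_low = if (length(low)) median(low) else NA_real_,
               median_high = if (length(high)) median(high) else NA_real_,
               between_variance_fraction = bvf,
               degenerate = bvf < min_between_frac)
  structure(gate, class = "bifurcation_gate")
}

#' @export
print.bifurcation_gate <- function(x, ...) {
  cat(sprintf(
    "<bifurcation_gate> threshold=%.4g  low %.1f%% (median %.3g) / high %.1f%% (median %.3g)%s\n",
    x$threshold, 100 * x$fraction_low, x$median_low, 100 * x$fraction_high,
    x$median_high, if (x$degenerate) "  [degenerate: unimodal]" else ""))
  invisible(x)
}

#' Fold repression of reporter flux
#'
#' `(median_gene - median_atg9a) / (median_control - median_atg9a)`:
#' a 0-1 score of how fully a knockout represses reporter flux, anchored
#' on the assumption that the ATG9A knockout is a true autophagy-null
#' phenotype (score 0) and the non-targeting control is unaffected
#' (score 1). Values outside `[0, 1]` are reported as-is with a `flagged`
#' attribute, never clamped. The score is invariant under any affine map
#' `x -> a*x + b` (a > 0) of all three medians.
#'
#' @param median_gene,median_atg9a,median_control population medians of
#'   the Red:Green ratio.
#' @return numeric score with attribute `flagged` (TRUE when outside
#'   `[0, 1]`).
#' @export
fold_repression <- function(median_gene, median_atg9a, median_control) {
  denom <- median_control - median_atg9a
  if (!is.finite(denom) || denom == 0)
    pf_stop("undefined_score",
            "control and ATG9A medians coincide; fold repression undefined")
  s <- (median_gene - median_atg9a) / denom
  attr(s, "flagged") <- s < 0 | s > 1
  s
}

#' Fold-repression matrix across reporters
#'
#' Builds the heat-map-ready genes x reporters matrix of fold-repression
#' scores from per-sample medians.
#'
#' @param medians data frame with columns `gene`, `reporter`, `median`;
#'   must contain rows for `atg9a_gene` and `control_gene` in every
#'   reporter.
#' @param atg9a_gene,control_gene names of the null-phenotype and control
#'   rows.
#' @return numeric matrix (genes x reporters), reference rows included
#'   (ATG9A row 0, control row 1).
#' @export
fold_repression_matrix <- function(medians, atg9a_gene = "ATG9A",
                                   control_gene = "control") {
  reporters <- sort(unique(medians$reporter))
  genes <- unique(medians$gene)
  out <- matrix(NA_real_, length(genes), length(reporters),
                dimnames = list(genes, reporters))
  for (rep_id in reporters) {
    sub <- medians[medians$reporter == rep_id, ]
    m_atg <- sub$median[sub$gene == atg9a_gene]
    m_ctl <- sub$median[sub$gene == control_gene]
    if (length(m_atg) != 1L || length(m_ctl) != 1L)
      pf_stop("invalid_input",
              "reporter %s lacks a unique %s or %s row", rep_id, atg9a_gene,
              control_gene)
    for (g in unique(sub$gene))
      out[g, rep_id] <- as.numeric(
        fold_repression(sub$median[sub$gene == g], m_atg, m_ctl))
  }
  out
}

#' Read per-event flow data from CSV
#'
#' Expects columns `sample_id`, `RFP`, `GFP` (extra columns are kept).
#'
#' @param path CSV path.
#' @return data frame of events.
#' @export
read_flow_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "RFP", "GFP")
  if (!all(need %in% names(df)))
    pf_stop("invalid_input", "flow CSV must have columns %s",
            paste(need, collapse = ", "))
  df
}
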