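## Coupled MCP / RNAPII burst traces with known ground truth, built on
## the promoter-loading simulator.

#' Generate coupled MCP and RNAPII traces with ground-truth bursts
#'
#' For each nucleus, runs the loading simulator and returns the paired
#' traces sampled every `subsampleInterval` seconds: the MCP channel is
#' proportional to the number of polymerases on the gene body and the
#' RNAPII channel is the gene-region enrichment, both plus additive
#' Gaussian noise. The ground-truth burst interval is the contiguous
#' period with at least one engaged polymerase.
#'
#' @param config a [PolIISimConfig-class] object.
#' @param noiseSigma additive noise sd, in each channel's units.
#' @param nNuclei number of independent nuclei.
#' @param seed global seed (per-nucleus seeds are derived).
#' @param duration simulated time, s; defaults as in [sweepKon()].
#' @return list with one element per nucleus, each holding `trace`
#'   (data.frame `time`, `mcp`, `rnapii`; noisy, unsmoothed), `truth`
#'   (data.frame `start`, `end`, `duration` in s) and `sim`.
#' @export
generateCoupledTraces <- function(config = polIISimConfig(),
                                  noiseSigma = 0, nNuclei = 1, seed = 1L,
                                  duration = NULL) {
  if (is.null(duration))
    duration <- config@tOn * 60 +
      config@geneLength / config@rElongation * 60 + 60
  lapply(seq_len(nNuclei), function(i) {
    cfg <- config
    cfg@seed <- deriveSeed(seed, paste0("traces-", i))
    tr <- simulateTrace(cfg, duration)
    raw <- tr$raw
    if (noiseSigma > 0) {
      set.seed(deriveSeed(seed, paste0("traces-noise-", i)))
      raw$mcp <- raw$mcp + rnorm(nrow(raw)) * noiseSigma
      raw$rnapii <- raw$rnapii + rnorm(nrow(raw)) * noiseSigma
    }
    on <- which(tr$sim$engaged > 0)
    truth <- if (length(on)) {
      data.frame(start = tr$sim$time[min(on)], end = tr$sim$time[max(on)],
                 duration = tr$sim$time[max(on)] - tr$sim$time[min(on)])
    } else {
      data.frame(start = numeric(0), end = numeric(0), duration = numeric(0))
    }
    list(trace = raw, truth = truth, sim = tr$sim)
  })
}
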