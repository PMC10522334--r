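# Shared fixtures: the published group-median parameter sets and small
# designs used across the suite.

paramsPupil <- function() gainParams(Z = 3.44, w = 0.61, n = 0.01,
                                     Rmax = 0.00023)
paramsEeg1F <- function() gainParams(Z = 2.62, w = 0.02, n = 0.15,
                                     Rmax = 0.00336)
paramsEeg2F <- function() gainParams(Z = 3.71, w = 0.02, n = 0.07,
                                     Rmax = 0.0031)
paramsMatching <- function() gainParams(Z = 0.30, w = 0.09, n = 5.10)

# 10-s unit-rate time base (t in [0, 10), rate samples/s)
timeBase <- function(rate, dur = 10) {
  seq(0, dur - 1 / rate, by = 1 / rate)
}

# summed squared radial-distance between two contours (matched by
# ratio/side), the metric used to compare a measured contour against the
# canonical predictions
contourDistance <- function(a, b) {
  m <- merge(a, b, by = c("ratio", "side"), suffixes = c("", ".ref"))
  sum((sqrt(m$cL^2 + m$cR^2) - sqrt(m$cL.ref^2 + m$cR.ref^2))^2)
}

# psychometric fits for every condition of a simulated matching session
fitAllConditions <- function(trials) {
  key <- unique(trials[c("ratio", "side", "standard_pct")])
  do.call(rbind, lapply(seq_len(nrow(key)), function(i) {
    d <- trials[trials$ratio == key$ratio[i] &
                trials$side == key$side[i] &
                trials$standard_pct == key$standard_pct[i], ]
    f <- fitPsychometric(d$level_db, d$response)
    data.frame(participant = d$participant[1], ratio = key$ratio[i],
               side = key$side[i], standard_pct = key$standard_pct[i],
               pse_db = f$pse, converged = f$converged)
  }))
}
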