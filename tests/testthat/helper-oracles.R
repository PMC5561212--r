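# Independent oracles used across the suite. Each is deliberately written as
# brute force / direct numerics so it shares no code path with the package.

# Radial moments of a uniform annulus a <= r <= b (fractions of the colony
# radius) by numeric integration of the density f(r) dr ~ 2 pi r dr.
annulus_moments <- function(a, b) {
  m0 <- integrate(function(r) 2 * pi * r, a, b)$value
  m1 <- integrate(function(r) 2 * pi * r^2, a, b)$value / m0
  m2 <- integrate(function(r) 2 * pi * r^3, a, b)$value / m0
  list(position = m1, sd = sqrt(m2 - m1^2))
}

# AUC by exhaustive pair counting (lower score = positive class), ties 1/2.
pair_count_auc <- function(score, positive) {
  pos <- score[positive]
  neg <- score[!positive]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p < q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# The LDC breakpoint rule evaluated literally on a significance pattern:
# scan every dose and ask "is this dose and every higher dose significant?".
brute_force_ldc_feature <- function(sig, doses) {
  for (j in seq_along(doses)) {
    if (all(sig[j:length(doses)])) return(doses[j])
  }
  NA_real_
}

# A manual colony geometry for analytic feature checks (bypasses detection).
disk_geometry <- function(n = 512, radius = 200) {
  ctr <- (n + 1) / 2
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  r_px <- sqrt((rows - ctr)^2 + (cols - ctr)^2)
  mask <- r_px <= radius
  list(geom = structure(list(mask = mask, center = c(ctr, ctr),
                             radius = sqrt(sum(mask) / pi)),
                        class = "colony_geometry"),
       r_norm = r_px / sqrt(sum(mask) / pi))
}

fixture_table <- function() reference_compounds()
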