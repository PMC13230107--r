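# Synthetic host reference codon usage.
#
# The analyses need a host-genome codon-usage reference (the natural choice
# for S. aureus phages is the host's own usage table). This constructor
# builds a synthetic but realistic stand-in for a strongly AT-biased
# Firmicute: amino-acid composition follows typical bacterial proteome
# frequencies, and within every synonymous family one A/T-ending codon
# dominates (T-ending where available, otherwise A-ending), with the
# remaining codons at low relative weights. The dominance strength sets both
# how low the effective number of codons of a host-faithful gene falls and
# how high its CAI rises; the default weights are calibrated once so that
# fully host-adapted genes of typical length show the strong bias regime of
# host-adapted phage genes (CAI around 0.72-0.75, Nc in the mid 30s, GC3
# far below 25 percent). The table is labelled synthetic everywhere; any
# real Kazusa-dialect table can be supplied instead through
# read_codon_usage_table().

# Typical bacterial amino-acid composition (fractions; normalised below).
.AA_COMPOSITION <- c(
  A = 0.078, R = 0.050, N = 0.045, D = 0.053, C = 0.010, Q = 0.040,
  E = 0.063, G = 0.072, H = 0.022, I = 0.070, L = 0.098, K = 0.060,
  M = 0.024, F = 0.044, P = 0.040, S = 0.062, T = 0.053, W = 0.011,
  Y = 0.033, V = 0.066)

#' Synthetic host codon-usage table
#'
#' Deterministically constructs the AT-biased reference usage table described
#' above, scaled to about one million codons. Used as the default reference
#' for CAI weights and for the synthetic CDS generator.
#'
#' @param dominant_weight relative weight of each family's dominant
#'   (A/T-ending) codon.
#' @param minor_at,minor_c,minor_g relative weights of the non-dominant
#'   codons by third base (A/T, C, G).
#' @return a [codon_usage_table()].
#' @export
host_usage_table <- function(dominant_weight = 7, minor_at = 2.0,
                             minor_c = 1.2, minor_g = 0.8) {
  aa_frac <- .AA_COMPOSITION / sum(.AA_COMPOSITION)
  fams <- synonymous_families()
  total_sense <- 997000
  counts <- setNames(numeric(64L), all_codons())
  minor_w <- c(T = minor_at, A = minor_at, C = minor_c, G = minor_g)
  for (aa in names(fams)) {
    codons <- fams[[aa]]
    third <- substr(codons, 3L, 3L)
    w <- minor_w[third]
    dom <- if (any(third == "T")) which(third == "T")[1L]
           else which(third == "A")[1L]
    w[dom] <- dominant_weight
    counts[codons] <- round(total_sense * aa_frac[[aa]] * w / sum(w))
  }
  # stop codons: TAA-dominated, ~3 per 1000
  counts["TAA"] <- 1950
  counts["TAG"] <- 450
  counts["TGA"] <- 600
  total <- sum(counts)
  freq <- round(1000 * counts / total, 2)
  codon_usage_table(names(counts), freq, counts)
}
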