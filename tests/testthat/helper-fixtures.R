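# Deterministic constructed fixtures shared across test files.

# ~230 bp sequence with exactly one plantable ORF on '+': SD + 6 nt + ATG +
# n_extra sense codons + TAA in a poly-C background (no start codons or SD
# sites can arise in poly-C / poly-G context on either strand).
planted_orf_seq <- function(n_extra = 30) {
  paste0(strrep("C", 60), "AGGAGGT", strrep("C", 6),
         "ATG", strrep("AAA", n_extra), "TAA", strrep("C", 60))
}

# Noise-free one-step curve on a 5-min grid: infective centers at 1e6 with
# lysis (rise) at 40 min; total phage rise from 20 min to a 4.4e8 plateau by
# 50 min -> eclipse 20, latent 40, burst 440.
constructed_growth_curve <- function() {
  t <- seq(0, 120, by = 5)
  total <- ifelse(t < 20, 1e6,
                  pmin(4.4e8, 4e6 * 110^((t - 20) / 30)))
  ic <- ifelse(t < 40, 1e6,
               pmin(4.4e8, 4e6 * 110^((t - 40) / 30)))
  data.frame(time = t, total_pfu = total, infective_centers = ic)
}

# Two synthetic spike-like proteins whose planted regions (a: 103-211,
# b: 156-264; 109 aa) share exactly 49 identical columns -> gapless identity
# 100 * 49 / 109.
spike_region_pair <- function() {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(20120)
  a <- sample(aa, 300, replace = TRUE)
  b <- sample(aa, 400, replace = TRUE)
  region <- a[103:211]
  flip <- sort(sample(109, 60))
  for (i in flip) region[i] <- sample(setdiff(aa, a[102 + i]), 1)
  # un-flipped columns are identical; flipped ones differ by construction
  b[156:264] <- region
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""),
       expected_identity = 100 * 49 / 109)
}
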