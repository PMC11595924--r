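# Independent oracles used across the suite. These deliberately share no code
# with the package implementation.

# Brute-force Duncan protected stepwise rule. Returns the k x k boolean
# "not significantly different" matrix over the descending-sorted means:
# a pair (i, j) is non-significant iff SOME enclosing pair (a, b) fails its
# raw range test diff < LSR(span) -- the closure of Duncan's protection rule.
oracle_duncan_ns <- function(means_sorted, n_h, mse, error_df, alpha) {
  k <- length(means_sorted)
  lsr <- function(span) {
    qtukey((1 - alpha)^(span - 1), nmeans = span, df = error_df) *
      sqrt(mse / n_h)
  }
  raw_ns <- matrix(FALSE, k, k)
  for (a in 1:(k - 1)) {
    for (b in (a + 1):k) {
      raw_ns[a, b] <- (means_sorted[a] - means_sorted[b]) < lsr(b - a + 1)
    }
  }
  ns <- diag(k) > 0
  for (i in 1:(k - 1)) {
    for (j in (i + 1):k) {
      encl <- FALSE
      for (a in 1:i) {
        for (b in j:k) {
          if (raw_ns[a, b]) encl <- TRUE
        }
      }
      ns[i, j] <- ns[j, i] <- encl
    }
  }
  ns
}

# "shares at least one letter" matrix from a duncan_letters() result, in the
# result's own (sorted) level order
letters_share_matrix <- function(duncan) {
  lets <- strsplit(duncan$groups$letters, "")
  k <- length(lets)
  outer(seq_len(k), seq_len(k), Vectorize(function(i, j) {
    length(intersect(lets[[i]], lets[[j]])) > 0
  }))
}

# random small study table: continuous positive values for all 12 traits
# (tie-free with probability 1)
random_study <- function(n_acc = 4, n_reps = 3, traits = trait_names()) {
  grid <- expand.grid(
    accession = sprintf("AC%d", seq_len(n_acc)),
    treatment = c("T0", "T1", "T2"),
    replicate = seq_len(n_reps),
    trait = traits,
    stringsAsFactors = FALSE
  )
  base <- runif(length(traits), 5, 50)
  names(base) <- traits
  grid$value <- base[grid$trait] * runif(nrow(grid), 0.5, 1.5)
  grid$value[grid$trait == "GP"] <- runif(sum(grid$trait == "GP"), 10, 99)
  study_table(grid)
}
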