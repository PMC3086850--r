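# Shared fixtures and independent oracles used across the suite.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

# Exhaustive enumeration over all 3^n label paths compatible with the
# observed symbols: the independent oracle for Viterbi and posterior
# decoding.  Kept free of any code from the decoding path it checks.
brute_decode <- function(params, symbols) {
  obs <- match(symbols, c("H", "L", "M"))
  n <- length(obs)
  grid <- as.matrix(do.call(expand.grid, rep(list(1:3), n)))
  lp <- apply(grid, 1, function(li) {
    st <- (li - 1L) * 3L + obs
    v <- log(params$initial[st[1]])
    if (n > 1) for (i in 2:n) v <- v + log(params$transition[st[i - 1], st[i]])
    v
  })
  ll <- logsumexp(lp)
  marg <- t(vapply(seq_len(n), function(i) {
    vapply(1:3, function(a) exp(logsumexp(lp[grid[, i] == a]) - ll),
           numeric(1))
  }, numeric(3)))
  colnames(marg) <- c("+", "-", "o")
  list(max_log_prob = max(lp), marginals = marg, log_lik = ll)
}

# Random valid parameter set (positive everywhere, as after smoothing).
random_params <- function(seed, concentration = 1) {
  withr::with_seed(seed, {
    g <- matrix(rgamma(81, concentration), 9, 9)
    transition <- g / rowSums(g)
    init <- rgamma(9, concentration)
    dimnames(transition) <- list(hmm_states(), hmm_states())
    list(initial = setNames(init / sum(init), hmm_states()),
         transition = transition)
  })
}

# A small annotation: `n` probes per chromosome, `bands` equal cytobands,
# probes 1 kb long every 10 kb.
make_annotation <- function(n = 10, chroms = "chr1", bands = 2) {
  purrr::map_dfr(chroms, function(chrom) {
    tibble::tibble(
      probe_id = sprintf("%s_g%03d", chrom, seq_len(n)),
      chrom = chrom,
      start = (seq_len(n) - 1) * 10000,
      end = (seq_len(n) - 1) * 10000 + 1000,
      cytoband = paste0(sub("chr", "", chrom), "b",
                        ceiling(seq_len(n) / (n / bands)))
    )
  }) |>
    genome_annotation()
}
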