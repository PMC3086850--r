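#' Compose symbol and label sequences into a hidden-state path
#'
#' Superimposes observed expression symbols on copy-number labels to form the
#' composite states used for supervised training: position `i` with symbol
#' `b` and label `a` maps to state `ba` (e.g. `H`, `+` -> `H+`).
#'
#' @param symbols Character vector over `H`/`L`/`M`.
#' @param labels Character vector over `+`/`-`/`o`, same length.
#' @return Integer vector of state indices (1-9, canonical order), with the
#'   state names as names.
#' @seealso [decompose_path()]
#' @export
compose_path <- function(symbols, labels) {
  if (length(symbols) != length(labels)) {
    abort("symbols and labels differ in length")
  }
  si <- match(symbols, cna_symbols)
  li <- match(labels, cna_labels)
  if (anyNA(si)) abort("unknown expression symbol")
  if (anyNA(li)) abort("unknown copy-number label")
  st <- (li - 1L) * 3L + si
  setNames(st, hmm_states()[st])
}

#' Decompose a state path into symbols and labels
#'
#' Inverse of [compose_path()].
#'
#' @param path Integer vector of state indices (1-9).
#' @return List with character vectors `symbols` and `labels`.
#' @export
decompose_path <- function(path) {
  stopifnot(all(path %in% 1:9))
  list(symbols = cna_symbols[state_symbol_of[path]],
       labels = cna_labels[state_label_of[path]])
}

## Constructor for the fitted-model container.
new_cna_hmm <- function(chromosomes, pseudocount, config = list()) {
  structure(list(chromosomes = chromosomes, pseudocount = pseudocount,
                 config = config),
            class = "cna_hmm")
}

#' @export
print.cna_hmm <- function(x, ...) {
  cat("<cna_hmm> 9-state copy-number HMM\n")
  cat("  chromosomes:", paste(names(x$chromosomes), collapse = ", "), "\n")
  cat("  pseudocount:", x$pseudocount, "\n")
  invisible(x)
}

## MLE with additive smoothing for one chromosome given an integer state
## matrix (probes x samples).  Emissions are structurally degenerate --
## state (b, a) emits b with probability 1 -- and are never estimated:
## because training states carry the observed symbol, the emission MLE is
## identically degenerate, and hard-coding it avoids 0/0 for unvisited
## states.
train_chrom <- function(states, pseudocount) {
  m <- nrow(states)
  n_init <- tabulate(states[1, ], nbins = 9)
  initial <- (n_init + pseudocount) / (ncol(states) + 9 * pseudocount)
  A <- matrix(0, 9, 9)
  if (m > 1) {
    from <- states[-m, , drop = FALSE]
    to <- states[-1, , drop = FALSE]
    A[] <- tabulate((as.vector(to) - 1L) * 9L + as.vector(from), nbins = 81)
  }
  transition <- (A + pseudocount) / (rowSums(A) + 9 * pseudocount)
  if (pseudocount == 0) {
    # rows with no observed outgoing transition stay uniform (harmless:
    # unreachable at decode time without smoothing)
    empty <- rowSums(A) == 0
    transition[empty, ] <- 1 / 9
  }
  dimnames(transition) <- list(hmm_states(), hmm_states())
  list(initial = setNames(initial, hmm_states()), transition = transition,
       counts = list(A = A, n_init = n_init, n = ncol(states)))
}

#' Train per-chromosome HMMs by maximum likelihood
#'
#' Fits one nine-state HMM per chromosome from paired, discretized data:
#' expression symbols ([symbolize()]) superimposed on copy-number labels
#' ([project_segments()]) give fully observed state paths, so transition and
#' initial probabilities are closed-form MLE counts with additive smoothing:
#' `a_kl = (A_kl + c) / sum_l'(A_kl' + c)` and
#' `pi_l = (N_l + c) / (N + 9c)`, where `A_kl` counts transitions, `N_l`
#' counts chain starts in state `l` and `N` is the number of training
#' samples.  Training never mixes probes across chromosomes.
#'
#' @param symbols Symbol tibble/matrix (probes x samples over `H`/`L`/`M`).
#' @param labels Copy-number matrix or tibble (same shape, `+`/`-`/`o`).
#' @param annotation The [genome_annotation()] both are aligned to.
#' @param pseudocount Additive smoothing constant `c >= 0` applied to
#'   transition and initial counts; default 0.5.  A positive value keeps
#'   never-observed transitions decodable.
#' @param config Optional named list of thresholds recorded into the model
#'   (written out by [write_model()]).
#' @return A `cna_hmm` object: per-chromosome `initial` (length 9) and
#'   `transition` (9 x 9, row-stochastic) distributions plus the raw counts.
#' @export
train_hmm <- function(symbols, labels, annotation, pseudocount = 0.5,
                      config = list()) {
  if (pseudocount < 0) abort("pseudocount must be >= 0")
  S <- if (is.matrix(symbols)) symbols else expr_matrix_chr(symbols)
  L <- if (is.matrix(labels)) labels else expr_matrix_chr(labels)
  if (!identical(dim(S), dim(L))) abort("symbols and labels differ in shape")
  if (ncol(S) < 1) abort("no training samples")
  if (nrow(S) != nrow(annotation)) abort("matrices not aligned to annotation")
  states <- matrix(compose_path(as.vector(S), as.vector(L)),
                   nrow(S), ncol(S))
  idx <- ann_chrom_index(annotation)
  chroms <- lapply(idx, function(i) {
    train_chrom(states[i, , drop = FALSE], pseudocount)
  })
  new_cna_hmm(chroms, pseudocount = pseudocount, config = config)
}

## Symbols (character) -> integer observation sequence.
obs_index <- function(symbols) {
  o <- match(symbols, cna_symbols)
  if (anyNA(o)) abort("unknown expression symbol in observations")
  o
}

#' Viterbi decoding of one chromosome
#'
#' Finds the single most probable hidden-state path for an observation
#' sequence under one chromosome's parameters.  Because emissions are
#' degenerate, only the three states compatible with the observed symbol are
#' reachable at each position; the dynamic program runs in natural-log
#' space.  Ties are broken toward the earliest state in canonical order, so
#' decoding is deterministic.
#'
#' @param params One chromosome's parameter list (`initial`, `transition`),
#'   e.g. `model$chromosomes[["chr1"]]`.
#' @param symbols Character vector of observed symbols over `H`/`L`/`M`.
#' @return List: `path` (integer state indices), `labels` (the path's
#'   copy-number components) and `log_prob` (log joint probability of path
#'   and observations).
#' @export
viterbi <- function(params, symbols) {
  obs <- obs_index(symbols)
  m <- length(obs)
  if (m == 0) abort("empty observation sequence")
  lpi <- log(params$initial)
  lA <- log(params$transition)
  delta <- matrix(-Inf, m, 9)
  back <- matrix(NA_integer_, m, 9)
  compat <- lapply(1:3, function(b) which(state_symbol_of == b))
  c1 <- compat[[obs[1]]]
  delta[1, c1] <- lpi[c1]
  if (m > 1) {
    for (i in 2:m) {
      ci <- compat[[obs[i]]]
      prev <- delta[i - 1, ]
      for (l in ci) {
        v <- prev + lA[, l]
        k <- which.max(v)   # earliest canonical index wins ties
        delta[i, l] <- v[k]
        back[i, l] <- k
      }
    }
  }
  last <- compat[[obs[m]]]
  best <- last[which.max(delta[m, last])]
  if (!is.finite(delta[m, best])) {
    abort("all state paths have zero probability; retrain with a positive pseudocount")
  }
  path <- integer(m)
  path[m] <- best
  if (m > 1) for (i in m:2) path[i - 1] <- back[i, path[i]]
  list(path = setNames(path, hmm_states()[path]),
       labels = cna_labels[state_label_of[path]],
       log_prob = delta[m, best])
}

#' Posterior decoding of one chromosome
#'
#' Scaled forward-backward algorithm returning, for each position, the
#' marginal probability of each copy-number label.  With degenerate
#' emissions the label marginal equals the posterior of the single composite
#' state compatible with the observed symbol, so the three probabilities per
#' position sum to one.
#'
#' @inheritParams viterbi
#' @return List: `prob` (positions x 3 matrix over `+`/`-`/`o`) and
#'   `log_lik` (log likelihood of the observations).
#' @export
posterior <- function(params, symbols) {
  obs <- obs_index(symbols)
  m <- length(obs)
  if (m == 0) abort("empty observation sequence")
  A <- params$transition
  compat <- lapply(1:3, function(b) which(state_symbol_of == b))

  alpha <- matrix(0, m, 9)
  scale <- numeric(m)
  a <- numeric(9)
  c1 <- compat[[obs[1]]]
  a[c1] <- params$initial[c1]
  scale[1] <- sum(a)
  if (scale[1] <= 0) {
    abort("observations have zero probability; retrain with a positive pseudocount")
  }
  alpha[1, ] <- a / scale[1]
  if (m > 1) {
    for (i in 2:m) {
      ci <- compat[[obs[i]]]
      a <- numeric(9)
      a[ci] <- as.vector(alpha[i - 1, ] %*% A[, ci, drop = FALSE])
      scale[i] <- sum(a)
      if (scale[i] <= 0) {
        abort("observations have zero probability; retrain with a positive pseudocount")
      }
      alpha[i, ] <- a / scale[i]
    }
  }

  beta <- matrix(0, m, 9)
  beta[m, compat[[obs[m]]]] <- 1
  if (m > 1) {
    for (i in (m - 1):1) {
      ci1 <- compat[[obs[i + 1]]]
      b <- as.vector(A[, ci1, drop = FALSE] %*% beta[i + 1, ci1])
      beta[i, ] <- b / scale[i + 1]
    }
  }

  gamma <- alpha * beta
  norm <- rowSums(gamma)
  if (any(abs(norm - 1) > 1e-9)) {
    abort("forward and backward passes disagree beyond tolerance")
  }
  gamma <- gamma / norm

  prob <- matrix(0, m, 3, dimnames = list(NULL, cna_labels))
  for (a_idx in 1:3) {
    prob[, a_idx] <- rowSums(gamma[, which(state_label_of == a_idx),
                                   drop = FALSE])
  }
  list(prob = prob, log_lik = sum(log(scale)))
}

#' Call copy-number labels from posterior marginals
#'
#' @param prob Positions x 3 matrix of label marginals (columns `+`, `-`,
#'   `o`) from [posterior()].
#' @param cutoff Posterior probability cutoff in `[0.5, 1]`.  At exactly 0.5
#'   a position with both aberrant marginals equal to 0.5 is neutral.
#' @return Character vector of labels: `"+"` where `P(+) >= cutoff`, `"-"`
#'   where `P(-) >= cutoff`, else `"o"`.
#' @export
call_posterior <- function(prob, cutoff = 0.5) {
  if (!(cutoff >= 0.5 && cutoff <= 1)) {
    abort("cutoff must lie in [0.5, 1]")
  }
  if (is.null(colnames(prob))) colnames(prob) <- cna_labels
  plus <- prob[, "+"] >= cutoff
  minus <- prob[, "-"] >= cutoff
  out <- rep("o", nrow(prob))
  out[plus & !minus] <- "+"
  out[minus & !plus] <- "-"
  out   # both >= cutoff only possible at cutoff 0.5 with a 0.5/0.5 tie -> "o"
}

#' Sample a state path and observations from one chromosome's HMM
#'
#' Ancestral sampling; the emitted symbol is deterministic from the state.
#'
#' @inheritParams viterbi
#' @param n Sequence length (>= 1).
#' @param seed Optional integer seed for reproducibility.
#' @return List with integer `path` and character `symbols`.
#' @export
sample_hmm <- function(params, n, seed = NULL) {
  if (n < 1) abort("n must be >= 1")
  draw <- function() {
    path <- integer(n)
    path[1] <- sample.int(9, 1, prob = params$initial)
    if (n > 1) {
      for (i in 2:n) {
        path[i] <- sample.int(9, 1, prob = params$transition[path[i - 1], ])
      }
    }
    list(path = setNames(path, hmm_states()[path]),
         symbols = cna_symbols[state_symbol_of[path]])
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Predict copy-number labels for new samples
#'
#' Decodes each sample's symbol sequence chromosome by chromosome with a
#' trained model, by the most probable path (Viterbi) or by thresholded
#' posterior marginals.
#'
#' @param object A `cna_hmm` from [train_hmm()] or [read_model()].
#' @param symbols Symbol tibble or matrix (probes x samples).
#' @param annotation The matching [genome_annotation()].
#' @param decoder `"viterbi"` or `"posterior"`.
#' @param cutoff Posterior cutoff (posterior decoder only); default 0.5.
#' @param ... Unused.
#' @return A tibble `probe_id`, `chrom`, `sample_id`, `label`, plus
#'   `p_gain`, `p_loss`, `p_normal` for the posterior decoder.
#' @export
predict.cna_hmm <- function(object, symbols, annotation,
                            decoder = c("viterbi", "posterior"),
                            cutoff = 0.5, ...) {
  decoder <- match.arg(decoder)
  S <- if (is.matrix(symbols)) symbols else expr_matrix_chr(symbols)
  res <- decode_matrix(object, S, annotation, decoder, cutoff)
  out <- matrix_to_tbl(res$labels) |>
    tidyr::pivot_longer(-"probe_id", names_to = "sample_id",
                        values_to = "label") |>
    left_join(as_tibble(annotation)[c("probe_id", "chrom")], by = "probe_id") |>
    select("probe_id", "chrom", "sample_id", "label")
  if (decoder == "posterior") {
    probs <- purrr::map_dfr(colnames(S), function(s) {
      p <- res$prob[[s]]
      tibble(probe_id = rownames(S), sample_id = s,
             p_gain = unname(p[, "+"]), p_loss = unname(p[, "-"]),
             p_normal = unname(p[, "o"]))
    })
    out <- left_join(out, probs, by = c("probe_id", "sample_id"))
  }
  out
}

## Matrix-level decoding used by predict() and loocv(): returns a character
## label matrix aligned to the annotation, plus per-sample posterior tracks
## when requested.
decode_matrix <- function(model, S, annotation, decoder = "viterbi",
                          cutoff = 0.5) {
  idx <- ann_chrom_index(annotation)
  missing_chr <- setdiff(names(idx), names(model$chromosomes))
  if (length(missing_chr) > 0) {
    abort(paste0("model lacks chromosome(s): ",
                 paste(missing_chr, collapse = ", ")))
  }
  labels <- matrix("o", nrow(S), ncol(S), dimnames = dimnames(S))
  prob <- if (decoder == "posterior")
    setNames(vector("list", ncol(S)), colnames(S)) else NULL
  for (s in seq_len(ncol(S))) {
    if (decoder == "posterior") {
      prob[[s]] <- matrix(NA_real_, nrow(S), 3,
                          dimnames = list(rownames(S), cna_labels))
    }
    for (chrom in names(idx)) {
      i <- idx[[chrom]]
      par <- model$chromosomes[[chrom]]
      if (decoder == "viterbi") {
        labels[i, s] <- viterbi(par, S[i, s])$labels
      } else {
        p <- posterior(par, S[i, s])$prob
        prob[[s]][i, ] <- p
        labels[i, s] <- call_posterior(p, cutoff)
      }
    }
  }
  list(labels = labels, prob = prob)
}
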