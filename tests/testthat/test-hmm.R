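test_that("state composition is bijective and canonically ordered", {
  expect_equal(hmm_states(),
               c("H+", "L+", "M+", "H-", "L-", "M-", "Ho", "Lo", "Mo"))
  expect_equal(names(compose_path("H", "+")), "H+")
  expect_equal(names(compose_path("M", "o")), "Mo")
  withr::with_seed(3, {
    for (rep in 1:20) {
      sym <- sample(c("H", "L", "M"), 15, TRUE)
      lab <- sample(c("+", "-", "o"), 15, TRUE)
      d <- decompose_path(compose_path(sym, lab))
      expect_identical(d$symbols, sym)
      expect_identical(d$labels, lab)
    }
  })
  expect_error(compose_path(c("H", "L"), "+"), "length")
})

test_that("MLE training reproduces hand-counted transition and initial probabilities", {
  # two training chains on one 4-probe chromosome:
  #   sample A: Mo Mo H+ H+   sample B: Mo Lo Lo Mo
  ann <- make_annotation(n = 4)
  S <- matrix(c("M", "M", "H", "H",
                "M", "L", "L", "M"), ncol = 2,
              dimnames = list(ann$probe_id, c("A", "B")))
  L <- matrix(c("o", "o", "+", "+",
                "o", "o", "o", "o"), ncol = 2,
              dimnames = dimnames(S))
  model <- train_hmm(S, L, ann, pseudocount = 0)
  a <- model$chromosomes$chr1$transition
  # transitions out of Mo: Mo->Mo, Mo->H+ (sample A), Mo->Lo (sample B)
  expect_equal(a["Mo", "Mo"], 1 / 3)
  expect_equal(a["Mo", "H+"], 1 / 3)
  expect_equal(a["Mo", "Lo"], 1 / 3)
  expect_equal(unname(model$chromosomes$chr1$initial["Mo"]), 1)

  # rows and initial sum to one after any training call
  expect_equal(rowSums(a), setNames(rep(1, 9), hmm_states()),
               tolerance = 1e-12)
  expect_equal(sum(model$chromosomes$chr1$initial), 1, tolerance = 1e-12)

  # with a positive pseudocount a never-visited state's row is uniform
  model_c <- train_hmm(S, L, ann, pseudocount = 0.5)
  expect_equal(unname(model_c$chromosomes$chr1$transition["L-", ]),
               rep(1 / 9, 9))
})

test_that("training recovers known parameters from sampled paths", {
  params <- random_params(101, concentration = 2)
  n_paths <- 200
  len <- 500
  ann <- make_annotation(n = len, bands = 1)
  withr::with_seed(202, {
    draws <- lapply(seq_len(n_paths), function(i) sample_hmm(params, len))
  })
  S <- vapply(draws, function(d) d$symbols, character(len))
  L <- vapply(draws, function(d) decompose_path(d$path)$labels,
              character(len))
  dimnames(S) <- dimnames(L) <- list(ann$probe_id,
                                     paste0("s", seq_len(n_paths)))
  fit <- train_hmm(S, L, ann, pseudocount = 0)
  expect_lt(max(abs(fit$chromosomes$chr1$transition - params$transition)),
            0.02)
})

test_that("Viterbi matches exhaustive enumeration and breaks ties deterministically", {
  withr::with_seed(55, seeds <- sample.int(1e6, 30))
  for (k in seq_along(seeds)) {
    params <- random_params(seeds[k])
    n <- withr::with_seed(seeds[k] + 1, sample(1:8, 1))
    obs <- withr::with_seed(seeds[k] + 2, sample(c("H", "L", "M"), n, TRUE))
    v <- viterbi(params, obs)
    b <- brute_decode(params, obs)
    expect_equal(v$log_prob, b$max_log_prob, tolerance = 1e-10)
    # the returned path attains the reported probability
    st <- v$path
    lp <- log(params$initial[st[1]])
    if (n > 1) for (i in 2:n) {
      lp <- lp + log(params$transition[st[i - 1], st[i]])
    }
    expect_equal(unname(lp), v$log_prob, tolerance = 1e-12)
  }

  # length-1: argmax over the three compatible initial states
  params <- random_params(9)
  v1 <- viterbi(params, "H")
  hi <- match(c("H+", "H-", "Ho"), hmm_states())
  expect_equal(unname(v1$path), hi[which.max(params$initial[hi])])

  # a chain pinned to the normal sub-chain stays there
  pinned <- list(
    initial = setNames(c(rep(0.001, 8), 0.992), hmm_states()),
    transition = matrix(1e-4, 9, 9, dimnames = list(hmm_states(), hmm_states()))
  )
  diag(pinned$transition[7:9, 7:9]) <- 0.33
  pinned$transition <- pinned$transition / rowSums(pinned$transition)
  vp <- viterbi(pinned, rep("M", 6))
  expect_true(all(names(vp$path) == "Mo"))
})

test_that("posterior marginals match exhaustive enumeration and normalize", {
  withr::with_seed(77, seeds <- sample.int(1e6, 30))
  for (k in seq_along(seeds)) {
    params <- random_params(seeds[k])
    n <- withr::with_seed(seeds[k] + 1, sample(1:8, 1))
    obs <- withr::with_seed(seeds[k] + 2, sample(c("H", "L", "M"), n, TRUE))
    p <- posterior(params, obs)
    b <- brute_decode(params, obs)
    expect_equal(p$prob, b$marginals, tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(p$log_lik, b$log_lik, tolerance = 1e-10)
    expect_equal(rowSums(p$prob), rep(1, n), tolerance = 1e-9)
  }

  # length-1 uniform initial: each label marginal is 1/3
  uni <- list(initial = setNames(rep(1 / 9, 9), hmm_states()),
              transition = matrix(1 / 9, 9, 9,
                                  dimnames = list(hmm_states(), hmm_states())))
  expect_equal(unname(posterior(uni, "H")$prob[1, ]), rep(1 / 3, 3))
})

test_that("Viterbi log-probability dominates the concatenated posterior path", {
  withr::with_seed(88, seeds <- sample.int(1e6, 15))
  for (s in seeds) {
    params <- random_params(s)
    obs <- withr::with_seed(s, sample(c("H", "L", "M"), 12, TRUE))
    v <- viterbi(params, obs)
    post <- posterior(params, obs)$prob
    lab_idx <- apply(post, 1, which.max)
    st <- (lab_idx - 1L) * 3L + match(obs, c("H", "L", "M"))
    lp <- log(params$initial[st[1]])
    for (i in 2:length(st)) lp <- lp + log(params$transition[st[i - 1], st[i]])
    expect_gte(v$log_prob, unname(lp) - 1e-12)
  }
})

test_that("posterior calls respect the cutoff and are monotone in it", {
  prob <- rbind(c(0.7, 0.1, 0.2),
                c(0.55, 0.05, 0.40),
                c(0.2, 0.65, 0.15))
  colnames(prob) <- c("+", "-", "o")
  expect_equal(call_posterior(prob, 0.6), c("+", "o", "-"))
  expect_equal(call_posterior(rbind(c(0.5, 0.5, 0)), 0.5), "o")  # tie -> o
  expect_error(call_posterior(prob, 0.4), "0.5")
  expect_error(call_posterior(prob, 1.1), "0.5")

  withr::with_seed(4, {
    for (rep in 1:20) {
      g <- matrix(rgamma(25 * 3, 1), 25, 3)
      track <- g / rowSums(g)
      colnames(track) <- c("+", "-", "o")
      n_calls <- vapply(c(0.5, 0.6, 0.7, 0.8, 0.9), function(cut) {
        sum(call_posterior(track, cut) != "o")
      }, numeric(1))
      expect_true(all(diff(n_calls) <= 0))
    }
  })
})

test_that("ancestral sampling is reproducible and matches its parameters", {
  params <- random_params(31, concentration = 3)
  expect_identical(sample_hmm(params, 50, seed = 5),
                   sample_hmm(params, 50, seed = 5))
  expect_false(identical(sample_hmm(params, 50, seed = 5)$path,
                         sample_hmm(params, 50, seed = 6)$path))
  expect_error(sample_hmm(params, 0), ">= 1")

  # degenerate chain: all mass on Mo stays on Mo
  pinned <- list(initial = setNames(c(rep(0, 8), 1), hmm_states()),
                 transition = diag(9))
  dimnames(pinned$transition) <- list(hmm_states(), hmm_states())
  d <- sample_hmm(pinned, 20, seed = 1)
  expect_true(all(names(d$path) == "Mo"))
  expect_true(all(d$symbols == "M"))

  # empirical transition frequencies over a long chain match the
  # parameters; the z bound is Bonferroni-adjusted for the 81 simultaneous
  # comparisons (~4.2 sigma at a 1% family-wise level)
  long <- sample_hmm(params, 1e5, seed = 99)$path
  from <- long[-length(long)]
  to <- long[-1]
  z <- qnorm(1 - 0.01 / (2 * 81))
  for (k in 1:9) {
    n_k <- sum(from == k)
    emp <- tabulate(to[from == k], 9) / n_k
    tol <- z * sqrt(params$transition[k, ] *
                      (1 - params$transition[k, ]) / n_k)
    expect_true(all(abs(emp - params$transition[k, ]) <= tol + 1e-12))
  }
})

test_that("zero-probability observations raise an actionable error", {
  # pseudocount 0 and a never-seen start symbol
  ann <- make_annotation(n = 3)
  S <- matrix(c("M", "M", "M"), 3, 1, dimnames = list(ann$probe_id, "A"))
  L <- matrix("o", 3, 1, dimnames = dimnames(S))
  model <- train_hmm(S, L, ann, pseudocount = 0)
  expect_error(viterbi(model$chromosomes$chr1, c("H", "M", "M")),
               "pseudocount")
  expect_error(posterior(model$chromosomes$chr1, c("H", "M", "M")),
               "pseudocount")
})

test_that("prediction tibble is aligned and posterior columns sum to one", {
  cohort <- simulate_cohort(cohort_config(
    n_samples = 8,
    chromosomes = tibble::tibble(chrom = c("chr1", "chr5"), n_probes = 40L),
    n_cytobands = 4L,
    hotspots = tibble::tibble(chrom = c("chr1", "chr5"),
                              label = c("+", "-"),
                              band_lo = c(3L, 1L), band_hi = c(4L, 2L),
                              frequency = c(0.5, 0.5))
  ), seed = 21)
  S <- symbolize(cohort$expression)
  model <- train_hmm(S, cohort$truth, cohort$annotation)
  pred <- predict(model, S, cohort$annotation, decoder = "posterior",
                  cutoff = 0.6)
  expect_equal(nrow(pred), 80 * 8)
  expect_true(all(pred$label %in% c("+", "-", "o")))
  expect_equal(unname(pred$p_gain + pred$p_loss + pred$p_normal),
               rep(1, nrow(pred)), tolerance = 1e-9)
  # labels consistent with the cutoff rule
  expect_identical(pred$label == "+", unname(pred$p_gain >= 0.6))
})
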