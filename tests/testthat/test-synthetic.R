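test_that("intercept calibration has the right closed forms and MC accuracy", {
  expect_equal(calibrate_intercept(0.3, c(0, 0), c(1, 1)), qlogis(0.3))
  expect_equal(calibrate_intercept(0.17, 0, 0), log(0.17 / 0.83))
  b0 <- calibrate_intercept(0.2, c(log(1.3), log(0.9)), c(1.5, 1.5), seed = 11)
  set.seed(99)
  X <- matrix(rpois(2e5 * 2, 1.5), ncol = 2)
  prev <- mean(plogis(b0 + X %*% c(log(1.3), log(0.9))))
  expect_lt(abs(prev - 0.2), 3e-3)  # MC SE of the check draws is ~9e-4
})

test_that("generator configuration is validated", {
  rates <- matrix(0.3, 2, 5, dimnames = list(c("a", "b"), NULL))
  beta <- matrix(0, 2, 3)
  cp <- matrix(1 / 15, 3, 5)
  expect_s3_class(generator_config(10, cp, rates, beta, beta0 = matrix(0, 3, 5)),
                  "srf_gen_config")
  expect_error(generator_config(10, cp * 2, rates, beta, beta0 = matrix(0, 3, 5)))
  expect_error(generator_config(10, cp, rates - 1, beta, beta0 = matrix(0, 3, 5)))
  expect_error(generator_config(10, cp, rates, beta), "beta0 or cell_prevalence")
})

test_that("default_config encodes the study conditions", {
  lex <- toy_lexicon()
  cfg <- default_config(lex, n_sessions = 1000)
  expect_equal(sum(cfg$cell_probs), 1)
  expect_equal(unname(exp(cfg$true_beta["previous_attempt", c("female", "male")])),
               c(1.29, 1.26))
  expect_equal(unname(exp(cfg$true_beta["loneliness", c("female", "male")])),
               c(1.07, 1.00))
  expect_equal(unname(exp(cfg$true_beta["bullying", "female"])), 0.91)
  # per-chat totals identical across categories; depression late-weighted
  expect_equal(unname(rowSums(cfg$stage_rates)), rep(1.5, 20))
  expect_true(all(diff(cfg$stage_rates["depression", ]) > 0))
  expect_true(all(abs(diff(cfg$stage_rates["hopelessness", ])) < 1e-12))
  # deterministic construction
  cfg2 <- default_config(lex, n_sessions = 1000)
  expect_identical(cfg$beta0, cfg2$beta0)
})

test_that("filler/lexicon collisions are hard errors", {
  lex <- as_srf_lexicon(list(hope = "no hope"))
  rates <- matrix(0.3, 1, 5, dimnames = list("hope", NULL))
  cfg <- generator_config(5, {cp <- matrix(0, 3, 5); cp[1, 1] <- 1; cp},
                          rates, matrix(0, 1, 3), beta0 = matrix(0, 3, 5),
                          filler = c(default_filler_vocab(), "hope"))
  expect_error(generate_corpus(cfg, lex, seed = 1), "collision")
})

test_that("non-plantable lexicons are rejected for rendering", {
  lex <- as_srf_lexicon(list(A = "all alone", B = "alone"))  # B matches inside A
  expect_error(srflex:::validate_plantable(lex, default_filler_vocab()),
               "not uniquely plantable")
})

test_that("generated corpora are deterministic given config and seed", {
  lex <- toy_lexicon()
  cfg <- default_config(lex, n_sessions = 30)
  g1 <- generate_corpus(cfg, lex, seed = 77)
  g2 <- generate_corpus(cfg, lex, seed = 77)
  expect_identical(g1$ground_truth$counts_stage, g2$ground_truth$counts_stage)
  expect_identical(g1$ground_truth$sessions, g2$ground_truth$sessions)
  expect_identical(lapply(g1$sessions, `[[`, "messages"),
                   lapply(g2$sessions, `[[`, "messages"))
  g3 <- generate_corpus(cfg, lex, seed = 78)
  expect_false(identical(g1$ground_truth$counts_stage, g3$ground_truth$counts_stage))
})

test_that("matcher-recovered counts equal planted ground truth at every fraction", {
  lex <- toy_lexicon()
  cfg <- default_config(lex, n_sessions = 120)
  gen <- generate_corpus(cfg, lex, seed = 5)
  cats <- lexicon_categories(lex)
  for (f in c(0.2, 0.4, 0.6, 0.8, 1.0)) {
    ft <- featurize_sessions(gen$sessions, lex, fraction = f)
    gtf <- ground_truth_features(gen$ground_truth, f)
    expect_identical(unname(as.matrix(ft[, cats])),
                     unname(as.matrix(gtf[, cats])),
                     label = paste("fraction", f))
  }
  # stage character lengths are exactly equal within each session
  for (s in gen$sessions[1:10]) {
    lens <- nchar(clean_text(s$messages$text[s$messages$speaker == "help_seeker"]))
    stage_len <- tapply(lens, rep(1:5, each = length(lens) / 5), sum)
    expect_true(max(stage_len) - min(stage_len) == 0)
  }
})

test_that("an all-zero-rate corpus has zero features and intercept-driven prevalence", {
  lex <- as_srf_lexicon(list(a = "no hope", b = "so lonely"))
  rates <- matrix(0, 2, 5, dimnames = list(c("a", "b"), NULL))
  beta <- matrix(log(1.5), 2, 3, dimnames = list(c("a", "b"), NULL))
  cp <- matrix(0, 3, 5); cp[1, 1] <- 1
  cfg <- generator_config(5000, cp, rates, beta, beta0 = matrix(qlogis(0.25), 3, 5))
  gen <- generate_corpus(cfg, lex, seed = 3, render_text = FALSE)
  expect_true(all(gen$ground_truth$counts_total == 0))
  expect_equal(mean(gen$ground_truth$sessions$sr_label), 0.25, tolerance = 0.02)
})

test_that("subgroup prevalences hit the reference targets in expectation", {
  lex <- toy_lexicon()
  cfg <- default_config(lex)
  tab <- crisis_sample_table()
  reps <- 8
  acc_g <- matrix(0, reps, 3, dimnames = list(NULL, srflex:::srf_genders))
  acc_a <- matrix(0, reps, 4, dimnames = list(NULL, c("10-17", "18-20", "21-40", "41+")))
  for (r in seq_len(reps)) {
    gt <- generate_corpus(cfg, seed = 600 + r, render_text = FALSE)$ground_truth$sessions
    acc_g[r, ] <- tapply(gt$sr_label, factor(gt$gender, srflex:::srf_genders), mean)
    acc_a[r, ] <- tapply(gt$sr_label, factor(gt$age_group, colnames(acc_a)), mean)[colnames(acc_a)]
  }
  tg <- tab$prevalence[match(c("female", "male"), tab$subgroup)]
  expect_true(all(abs(colMeans(acc_g)[c("female", "male")] - tg) < 0.01))
  ta <- tab$prevalence[tab$dimension == "age"][1:4]
  expect_true(all(abs(colMeans(acc_a) - ta) < 0.01))
})

test_that("seventeen-thousand-record corpora survive the session format round trip", {
  lex <- toy_lexicon()
  cfg <- default_config(lex, n_sessions = 60)
  gen <- generate_corpus(cfg, lex, seed = 8)
  path <- tempfile(fileext = ".jsonl")
  write_sessions(gen$sessions, path)
  back <- read_sessions(path)
  expect_length(back, 60L)
  expect_equal(back, gen$sessions)
})
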