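test_that("solenoid generation is deterministic and truth-consistent", {
  r1 <- make_solenoid_record("p", n_repeats = 5, substitution_rate = 0.15,
                             seed = 13)
  r2 <- make_solenoid_record("p", n_repeats = 5, substitution_rate = 0.15,
                             seed = 13)
  expect_identical(r1, r2)
  # truth intervals abut and sit inside the sequence
  iv <- r1$truth$motif_intervals
  expect_true(all(iv$start[-1] == iv$end[-nrow(iv)] + 1L))
  expect_lte(max(iv$end), r1$record$length)
  # all annotation tracks reference valid positions
  ann <- r1$annotations
  pos <- ann$position[!is.na(ann$position)]
  expect_true(all(pos >= 1 & pos <= r1$record$length))
  # zero-noise construction contains exact consensus copies
  r0 <- make_solenoid_record("p", substitution_rate = 0, seed = 13)
  expect_equal(stringr::str_count(r0$record$sequence,
                                  stringr::fixed(SOLENOID_CONSENSUS)), 5L)
  expect_error(make_solenoid_record("p", n_repeats = 1L), "n_repeats")
})

test_that("planted repeats diverge from each other at the expected rate", {
  # with per-position substitution rate 0.15, two independently mutated
  # copies match where neither mutated plus coincidental cross-matches:
  # 0.85^2 + ~2*0.15*0.85/19 + ~(0.15^2)/19 ~ 0.736
  idents <- unlist(lapply(1:100, function(seed) {
    r <- make_solenoid_record("p", n_repeats = 2, substitution_rate = 0.15,
                              seed = seed)
    a <- strsplit(r$truth$motif_sequences[1], "")[[1]]
    b <- strsplit(r$truth$motif_sequences[2], "")[[1]]
    mean(a == b)
  }))
  expect_gt(mean(idents), 0.72 - 0.1)
  expect_lt(mean(idents), 0.72 + 0.1)
})

test_that("negative records carry no repeats and low linker signal", {
  n <- make_negative_record("n", length = 300, seed = 21)
  expect_equal(nrow(detect_repeats_naive(n$record$sequence)), 0L)
  lk <- n$annotations[n$annotations$annotation_type == "linker_score", ]
  expect_true(all(lk$score <= 0.15))
  expect_identical(n, make_negative_record("n", length = 300, seed = 21))

  # shuffled-solenoid preserves the residue multiset of its paired positive
  pos <- make_solenoid_record("p", seed = 22)
  sh <- make_negative_record("s", composition = "shuffled-solenoid",
                             seed = 23,
                             paired_sequence = pos$record$sequence)
  expect_equal(sort(strsplit(sh$record$sequence, "")[[1]]),
               sort(strsplit(pos$record$sequence, "")[[1]]))
})

test_that("the benchmark emits a labeled, complete descriptor set", {
  bm <- make_benchmark(n_pos = 12, n_neg = 10, seed = 2)
  expect_equal(nrow(bm$descriptors), 22L)
  expect_setequal(unique(bm$descriptors$class),
                  c("solenoid", "non-solenoid"))
  expect_equal(ncol(bm$descriptors), 63L)  # id + 61 features + class
  expect_false(anyNA(bm$descriptors))
  # annotations cover every protein's residues consistently
  expect_setequal(unique(bm$annotations$protein_id), bm$proteins$id)
})

test_that("the toy proteome lists truth for planted and decoy proteins", {
  toy <- make_toy_proteome(n_planted_pto = 2, n_planted_nonpto = 1,
                           n_decoys = 3, seed = 4)
  expect_equal(sum(toy$truth$kind == "planted_pto"), 2L)
  expect_equal(sum(toy$truth$kind == "planted_nonpto"), 1L)
  expect_equal(sum(toy$truth$kind == "decoy"), 3L)
  expect_setequal(toy$truth$protein_id, toy$proteins$id)
  expect_equal(nrow(toy$seeds), 12L)
  # non-pto planted proteins carry no organelle votes
  nonpto <- toy$truth$protein_id[toy$truth$kind == "planted_nonpto"]
  v <- consensus_pto(toy$votes, ids = nonpto)
  expect_false(any(v$pto))
})

test_that("honest mode regenerates repeat rows with the naive detector", {
  toy <- make_toy_proteome(n_planted_pto = 2, n_decoys = 2, seed = 6)
  honest <- naive_repeat_annotations(toy$proteins, toy$annotations,
                                     min_identity = 0.5)
  planted <- toy$truth$protein_id[toy$truth$kind == "planted_pto"]
  rep_rows <- honest[honest$annotation_type == "repeat", ]
  expect_true(all(planted %in% rep_rows$protein_id))
  decoys <- toy$truth$protein_id[toy$truth$kind == "decoy"]
  expect_false(any(decoys %in% rep_rows$protein_id))
})

test_that("result plots build without evaluation errors", {
  e <- tibble::tibble(node_a = c("a", "b"), node_b = c("b", "c"),
                      weight = 5)
  p1 <- ggplot2::autoplot(markov_cluster(e, inflation = 2))
  expect_s3_class(p1, "ggplot")
  d <- make_benchmark(n_pos = 10, n_neg = 10, seed = 3)$descriptors
  m <- train_rf(d, rf_hyperparams(n_estimators = 20), seed = 1)
  expect_s3_class(ggplot2::autoplot(m), "ggplot")
  bias <- tibble::tibble(cluster = 1L, size = 5L, position = 1:2,
                         frequency = c(0.8, 0.2), biased = TRUE,
                         biased_position = 1L)
  expect_s3_class(plot_positional_bias(bias), "ggplot")
  verdicts <- tibble::tibble(protein_id = c("a", "b"),
                             pass = c(TRUE, FALSE),
                             failed_step = c("none", "linkers"))
  expect_s3_class(plot_dt_verdicts(verdicts), "ggplot")
  expect_no_error(print(m))
})
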