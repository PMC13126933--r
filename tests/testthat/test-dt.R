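# build a protein + annotations satisfying every decision-tree threshold,
# then perturb single aspects per test
dt_fixture <- function(n_linkers = 5L, spacing = 40L, helix_frac = 0.70,
                       n_repeats = 3L, repeat_len = 38L, tm = NULL,
                       organelle_votes = 2L) {
  linker_pos <- 30L + spacing * (seq_len(n_linkers) - 1L)
  len <- max(linker_pos) + 60L
  span <- max(linker_pos) - min(linker_pos) + 1L
  n_h <- round(helix_frac * span)
  h_pos <- min(linker_pos) + seq_len(n_h) - 1L
  rep_start <- seq(1L, by = repeat_len + 2L, length.out = n_repeats)
  ann <- dplyr::bind_rows(
    tibble::tibble(protein_id = "p", annotation_type = "repeat",
                   start = rep_start, end = rep_start + repeat_len - 1L,
                   position = NA, score = NA, label = NA, tool = NA),
    tibble::tibble(protein_id = "p", annotation_type = "linker_score",
                   start = NA, end = NA, position = linker_pos, score = 0.9,
                   label = NA, tool = NA),
    tibble::tibble(protein_id = "p", annotation_type = "ss",
                   start = NA, end = NA, position = h_pos, score = NA,
                   label = "H", tool = NA))
  if (!is.null(tm)) {
    ann <- dplyr::bind_rows(ann, tibble::tibble(
      protein_id = "p", annotation_type = "tm", start = tm[1], end = tm[2],
      position = NA, score = NA, label = NA, tool = NA))
  }
  votes <- solenoidscan:::mock_votes("p", organelle_votes)
  proteins <- fasta_records("p", random_aa(len, seed = 77))
  list(proteins = proteins, annotations = ann, votes = votes)
}

test_that("a protein meeting every threshold passes the decision tree", {
  fx <- dt_fixture()
  v <- dt_classify(fx$proteins, fx$annotations, fx$votes)
  expect_true(v$pass)
  expect_equal(v$failed_step, "none")
  expect_equal(v$n_linkers, 5L)
  expect_equal(v$helix_fraction, 0.70, tolerance = 0.01)
})

test_that("each filter step fails for the matching defect, in order", {
  # 3 linkers < 4
  fx <- dt_fixture(n_linkers = 3L)
  expect_equal(dt_classify(fx$proteins, fx$annotations, fx$votes)$failed_step,
               "linkers")
  # consecutive linkers 401 aa apart
  fx <- dt_fixture(spacing = 401L)
  expect_equal(dt_classify(fx$proteins, fx$annotations, fx$votes)$failed_step,
               "linkers")
  # spacing bounds are inclusive: 400 and 32 both pass the linker step
  for (s in c(32L, 400L)) {
    fx <- dt_fixture(spacing = s)
    expect_true(dt_classify(fx$proteins, fx$annotations, fx$votes)$pass)
  }
  # helix fraction below 65%
  fx <- dt_fixture(helix_frac = 0.60)
  expect_equal(dt_classify(fx$proteins, fx$annotations, fx$votes)$failed_step,
               "helix_fraction")
  # no repeat of >= 29 aa
  fx <- dt_fixture(repeat_len = 28L)
  expect_equal(dt_classify(fx$proteins, fx$annotations, fx$votes)$failed_step,
               "repeats")
  # TM helix after the N-terminal part short-circuits everything
  fx <- dt_fixture(tm = c(100L, 122L))
  v <- dt_classify(fx$proteins, fx$annotations, fx$votes)
  expect_equal(v$failed_step, "tm")
  expect_true(is.na(v$n_linkers))
  # a single organelle vote fails the targeting quorum
  fx <- dt_fixture(organelle_votes = 1L)
  expect_equal(dt_classify(fx$proteins, fx$annotations, fx$votes)$failed_step,
               "targeting")
})

test_that("threshold monotonicity holds for helix fraction and linkers", {
  fx <- dt_fixture(helix_frac = 0.80)
  for (thr in c(0.5, 0.65, 0.75)) {
    expect_true(dt_classify(fx$proteins, fx$annotations, fx$votes,
                            dt_params(min_helix_fraction = thr))$pass)
  }
  expect_false(dt_classify(fx$proteins, fx$annotations, fx$votes,
                           dt_params(min_helix_fraction = 0.85))$pass)
  # adding a validly spaced linker never breaks the linker step
  fx4 <- dt_fixture(n_linkers = 4L)
  fx5 <- dt_fixture(n_linkers = 5L)
  expect_true(dt_classify(fx4$proteins, fx4$annotations, fx4$votes)$pass)
  expect_true(dt_classify(fx5$proteins, fx5$annotations, fx5$votes)$pass)
})

test_that("the results-text preset switches to 2 repeats of >= 26 aa", {
  p <- dt_params(preset = "results-text")
  expect_equal(p$min_repeat_len, 26L)
  expect_equal(p$min_repeat_count, 2L)
  fx <- dt_fixture(n_repeats = 1L, repeat_len = 27L)
  expect_equal(dt_classify(fx$proteins, fx$annotations, fx$votes,
                           p)$failed_step, "repeats")
  fx2 <- dt_fixture(n_repeats = 2L, repeat_len = 27L)
  expect_true(dt_classify(fx2$proteins, fx2$annotations, fx2$votes, p)$pass)
})

test_that("the parameter sweep selects a separating combination", {
  # two positives passing at helix >= 0.65 and two negatives at 0.45
  pos1 <- dt_fixture(helix_frac = 0.70)
  pos2 <- dt_fixture(helix_frac = 0.80)
  neg1 <- dt_fixture(helix_frac = 0.45)
  neg2 <- dt_fixture(helix_frac = 0.40)
  rename_fx <- function(fx, id) {
    fx$proteins$id <- id
    fx$annotations$protein_id <- id
    fx$votes$protein_id <- id
    fx
  }
  fxs <- purrr::map2(list(pos1, pos2, neg1, neg2),
                     c("a", "b", "c", "d"), rename_fx)
  proteins <- dplyr::bind_rows(purrr::map(fxs, "proteins"))
  ann <- dplyr::bind_rows(purrr::map(fxs, "annotations"))
  votes <- dplyr::bind_rows(purrr::map(fxs, "votes"))
  labels <- tibble::tibble(protein_id = c("a", "b", "c", "d"),
                           solenoid = c(TRUE, TRUE, FALSE, FALSE))
  sweep <- dt_parameter_sweep(proteins, ann, votes, labels,
                              grid = list(min_helix_fraction = c(0.3, 0.65)))
  expect_equal(nrow(sweep), 2L)
  best <- sweep[attr(sweep, "best"), ]
  expect_equal(best$min_helix_fraction, 0.65)
  expect_equal(best$F1, 1.0)
  # single-combination grid returns that combination
  one <- dt_parameter_sweep(proteins, ann, votes, labels,
                            grid = list(min_helix_fraction = 0.65))
  expect_equal(nrow(one), 1L)
  expect_equal(attr(one, "best"), 1L)
  # degenerate all-positive labels: specificity undefined -> NA
  all_pos <- labels
  all_pos$solenoid <- TRUE
  deg <- dt_parameter_sweep(proteins, ann, votes, all_pos,
                            grid = list(min_helix_fraction = 0.65))
  expect_true(is.na(deg$specificity))
  expect_error(dt_parameter_sweep(proteins, ann, votes, labels, list()),
               "empty")
})
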