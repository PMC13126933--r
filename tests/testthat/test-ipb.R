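test_that("hit length filter keeps -6/+2 around the canonical length", {
  hits <- tibble::tibble(protein_id = "p", start = 1L,
                         end = c(31L, 32L, 40L, 41L),
                         length = c(31L, 32L, 40L, 41L))
  kept <- filter_hit_length(hits, "OPR")
  expect_equal(kept$length, c(32L, 40L))
  # PPR window derives from canonical 35: 29..37
  hits$length <- c(28L, 29L, 37L, 38L)
  hits$end <- hits$length
  expect_equal(filter_hit_length(hits, "PPR")$length, c(29L, 37L))
  # idempotent; empty in, empty out
  expect_equal(filter_hit_length(kept, "OPR"), kept)
  expect_equal(nrow(filter_hit_length(hits[0, ], "OPR")), 0L)
})

test_that("overlap resolution merges, keeps, or eliminates by the 20/80 rule", {
  mk <- function(s, e) tibble::tibble(protein_id = "p", start = s, end = e,
                                      length = e - s + 1L,
                                      evalue = c(1e-9, 1e-5)[seq_along(s)])
  # > 80% overlap: merged to the minimum overlapping region
  out <- resolve_overlaps(mk(c(10L, 12L), c(47L, 49L)))
  expect_equal(nrow(out), 1L)
  expect_equal(c(out$start, out$end), c(12L, 47L))

  # < 20% overlap: both kept unchanged
  out <- resolve_overlaps(mk(c(10L, 45L), c(47L, 82L)))
  expect_equal(nrow(out), 2L)
  expect_equal(out$start, c(10L, 45L))

  # 20%..80%: both eliminated
  out <- resolve_overlaps(mk(c(10L, 30L), c(47L, 67L)))
  expect_equal(nrow(out), 0L)
})

test_that("no surviving hit pair overlaps by more than 80% after resolution", {
  for (seed in 1:10) {
    hits <- withr::with_seed(seed, {
      k <- sample(3:8, 1)
      s <- sort(sample.int(300, k))
      tibble::tibble(protein_id = "p", start = s,
                     end = s + sample(32:40, k, replace = TRUE) - 1L,
                     evalue = stats::runif(k, 1e-12, 1e-3))
    })
    hits$length <- hits$end - hits$start + 1L
    out <- resolve_overlaps(hits)
    if (nrow(out) >= 2L) {
      for (i in seq_len(nrow(out) - 1L)) {
        for (j in (i + 1L):nrow(out)) {
          inter <- min(out$end[i], out$end[j]) -
            max(out$start[i], out$start[j]) + 1L
          shorter <- min(out$end[i] - out$start[i],
                         out$end[j] - out$start[j]) + 1L
          expect_lte(inter / shorter, 0.8)
        }
      }
    }
  }
})

test_that("gap-column filtering is strict and preserves rows", {
  msa <- c(a = "PE-WL", b = "PE-WL", c = "PEKWL", d = "PE-WL",
           e = "PE-WL", f = "PE-WL", g = "PE-WL", h = "PE-WL",
           i = "PE-WL", j = "PE-WL")
  # column 3 has 9/10 gaps -> removed
  out <- filter_gap_columns(msa)
  expect_equal(unname(out[3]), "PEWL")
  expect_equal(names(out), names(msa))

  # gap-free alignment is unchanged
  clean <- c(x = "PEW", y = "PEW")
  expect_equal(filter_gap_columns(clean), clean)

  # a column with exactly 80% gaps is kept (strict >)
  msa80 <- c(a = "P-", b = "P-", c = "P-", d = "P-", e = "PK")
  expect_equal(unname(filter_gap_columns(msa80)), c("P-", "P-", "P-", "P-", "PK"))
})

test_that("inflation selection prefers clean family partitions", {
  # two clean motif families: high within-family, low cross-family identity
  fam1 <- vapply(1:5, function(i) mutate_sequence(SOLENOID_CONSENSUS, 0.1,
                                                  seed = 100 + i), character(1))
  alt <- random_aa(38, seed = 999)
  fam2 <- vapply(1:5, function(i) mutate_sequence(alt, 0.1, seed = 200 + i),
                 character(1))
  motifs <- tibble::tibble(id = paste0("m", 1:10),
                           sequence = c(fam1, fam2))
  edges <- pairwise_motif_similarity(motifs, t = 1e-3)
  sel <- select_inflation(motifs, edges, gap_cap = 18L)
  part <- tidy(sel$clustering)
  f1 <- part$cluster[part$node %in% paste0("m", 1:5)]
  f2 <- part$cluster[part$node %in% paste0("m", 6:10)]
  expect_equal(length(unique(f1)), 1L)
  expect_equal(length(unique(f2)), 1L)
  expect_false(unique(f1) == unique(f2))
  expect_true(all(vapply(sel$msas, solenoidscan:::gap_load, integer(1)) <= 18L))

  # single motif: one singleton cluster with zero gap load
  sel1 <- select_inflation(motifs[1, ], edges[0, ], gap_cap = 18L)
  expect_equal(sel1$clustering$n_clusters, 1L)
  expect_equal(solenoidscan:::gap_load(sel1$msas[[1]]), 0L)

  # identical partitions across the whole grid -> lowest inflation returned
  iso <- tibble::tibble(id = c("a", "b"), sequence = fam1[1:2])
  iso_e <- pairwise_motif_similarity(iso, t = 1e-3)
  sel2 <- select_inflation(iso, iso_e, gap_cap = 18L)
  expect_equal(sel2$inflation, 1.1)
  expect_error(select_inflation(motifs[0, ], edges, 18L), "empty")
})

test_that("profile search recovers a planted motif and rejects decoys", {
  unit <- SOLENOID_CONSENSUS
  cluster <- vapply(1:5, function(i) mutate_sequence(unit, 0.05,
                                                     seed = 400 + i),
                    character(1))
  msa <- solenoidscan:::center_star_msa(stats::setNames(cluster,
                                                        paste0("m", 1:5)))
  target <- fasta_records("t1", paste0(random_aa(80, 41), unit,
                                       random_aa(60, 42)))
  bg <- solenoidscan:::background_frequencies(target)
  prof <- build_profile(msa, bg, id = "p1")
  hits <- search_profiles(list(prof), target)
  expect_gte(nrow(hits), 1L)
  expect_lte(abs(hits$start[1] - 81L), 2L)
  expect_lte(abs(hits$end[1] - (81L + 37L)), 2L)

  # shuffled decoy proteome: no hits at the default significance
  decoys <- fasta_records(paste0("d", 1:10), vapply(1:10, function(i) {
    withr::with_seed(500 + i,
                     paste(sample(strsplit(paste(rep(unit, 3), collapse = ""),
                                           "")[[1]]), collapse = ""))
  }, character(1)))
  expect_equal(nrow(search_profiles(list(prof), decoys)), 0L)

  # empty proteome
  expect_equal(nrow(search_profiles(list(prof), target[0, ])), 0L)
})

test_that("the iterative loop converges and recovers seed source proteins", {
  # seeds that hit nothing: decoy-only proteome, convergence at iteration 1
  seeds <- make_seed_motifs(6, seed = 2)
  decoys <- fasta_records(paste0("d", 1:6), vapply(1:6, function(i) {
    random_aa(300, seed = 600 + i)
  }, character(1)))
  votes <- tibble::tibble(protein_id = "d1", tool = "deeploc",
                          label = "chloroplast")
  res <- run_ipb(seeds, decoys, votes, max_iterations = 5)
  expect_true(res$converged)
  expect_equal(res$iterations, 1L)
  expect_equal(nrow(tidy(res)), 0L)

  # self-recovery: a protein that carries a seed motif verbatim is found
  host <- fasta_records("host", paste0(random_aa(60, 71), seeds$sequence[1],
                                       random_aa(50, 72)))
  votes2 <- tibble::tibble(protein_id = "host",
                           tool = c("deeploc", "targetp"),
                           label = c("chloroplast", "mitochondrion"))
  res2 <- run_ipb(seeds, host, votes2, max_iterations = 3)
  cand <- tidy(res2)
  expect_equal(cand$protein_id, "host")
  expect_true(cand$pto)
  # the recovered interval covers the planted seed position within 2 aa
  expect_lte(abs(as.integer(sub("-.*", "", cand$coordinates)) - 61L), 2L)
})

test_that("motif and candidate sets grow monotonically across iterations", {
  toy <- make_toy_proteome(n_planted_pto = 3, n_decoys = 4, seed = 5)
  res <- run_ipb(toy$seeds, toy$proteins, toy$votes, max_iterations = 4)
  h <- res$history
  expect_true(all(diff(h$n_motifs) >= 0))
  expect_true(all(h$n_new_candidates >= 0))
  # seeds never disappear from the state
  expect_true(all(toy$seeds$id %in% res$motifs$id))
})
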